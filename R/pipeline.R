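#' Extract the full EEG feature table from a paired cohort
#'
#' Runs the standard per-recording chain: common average re-referencing;
#' Welch cross-spectra on the continuous cleaned signal with per-band iCOH
#' and weighted network metrics (GE, LE, T); band-limited 8-s epochs at
#' 200 Hz (optionally amplitude-screened) for the four nonlinear complexity
#' metrics. Everything lands in one long tibble ready for
#' [run_paired_analysis()].
#'
#' @param cohort Tibble with columns `subject`, `condition`, `recording`
#'   (list of [eeg_recording()]), as produced by [simulate_eeg_cohort()].
#' @param bands Band tibble ([eeg_bands()] or a subset).
#' @param epoch_len,fs_out,amp_thresh Passed to the epoching stage.
#' @param m,r,Q Complexity parameters (see [complexity_profile()]).
#' @param window_len,overlap Welch parameters.
#' @return Long tibble: `subject`, `condition`, `metric`, `band`, `feature`,
#'   `value`. Pair features are `"chA-chB"`, electrode features the channel
#'   name, global metrics `"global"`.
#' @export
eeg_feature_table <- function(cohort, bands = eeg_bands(), epoch_len = 8,
                              fs_out = 200, amp_thresh = NULL,
                              m = 2, r = 0.2, Q = 8,
                              window_len = 1, overlap = 0.5) {
  stopifnot(is.data.frame(cohort),
            all(c("subject", "condition", "recording") %in% names(cohort)))
  purrr::pmap(cohort, function(subject, condition, recording, ...) {
    rec <- rereference_car(recording)
    cs <- welch_cross_spectra(rec, window_len = window_len, overlap = overlap)
    conn <- purrr::pmap(bands, function(band, lo, hi) {
      W <- icoh(cs, band_spec(band, lo, hi))
      dplyr::bind_rows(
        tidy(W) |>
          dplyr::transmute(
            metric = "iCOH", band = .data$band,
            feature = paste(.data$ch_i, .data$ch_j, sep = "-"),
            value = .data$icoh
          ),
        network_metrics(W) |>
          dplyr::transmute(metric = .data$metric, band = .data$band,
                           feature = .data$node, value = .data$value)
      )
    }) |> dplyr::bind_rows()
    eps <- band_epochs(rec, bands, epoch_len = epoch_len, fs_out = fs_out,
                       amp_thresh = amp_thresh)
    cx <- complexity_profile(eps, m = m, r = r, Q = Q) |>
      dplyr::transmute(metric = .data$metric, band = .data$band,
                       feature = .data$channel, value = .data$value)
    dplyr::bind_rows(conn, cx) |>
      dplyr::mutate(subject = subject, condition = condition, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Per-band tally of iCOH pair changes
#'
#' Partitions a band's electrode pairs into increases (`z < 0`), decreases
#' (`z > 0`) and ties, with raw-significant subcounts, mirroring the
#' "x decreased, y increased, k significant" reporting style.
#'
#' @param table Output of [run_paired_analysis()].
#' @param band Band name to tally.
#' @param n_pairs Expected number of pair rows (210 for the 21-channel
#'   montage); a mismatch is an error.
#' @param alpha Raw significance threshold.
#' @return One-row tibble: `band`, `n_increased`, `n_decreased`, `n_ties`,
#'   `n_sig_increase`, `n_sig_decrease`.
#' @export
summarize_pair_counts <- function(table, band, n_pairs = 210, alpha = 0.05) {
  tb <- dplyr::filter(table, .data$metric == "iCOH", .data$band == !!band)
  if (nrow(tb) != n_pairs) {
    stop(sprintf("expected %d iCOH pair rows for band %s, found %d",
                 n_pairs, band, nrow(tb)), call. = FALSE)
  }
  tibble::tibble(
    band = band,
    n_increased = sum(tb$z < 0),
    n_decreased = sum(tb$z > 0),
    n_ties = sum(tb$z == 0),
    n_sig_increase = sum(tb$z < 0 & tb$p < alpha),
    n_sig_decrease = sum(tb$z > 0 & tb$p < alpha)
  )
}

#' Per-subject pre-post delta blocks
#'
#' `eeg_deltas()` pivots an EEG feature table into one wide block of
#' post - pre deltas (columns named `metric.band.feature`);
#' `taxa_deltas()` does the same for relative abundances at a taxonomic
#' rank. Both feed [correlation_screen()].
#'
#' @param features Long feature table from [eeg_feature_table()].
#' @param metrics Which metrics to keep (default the four nonlinear ones).
#' @return Wide tibble: `subject` plus one delta column per feature.
#' @export
eeg_deltas <- function(features, metrics = c("FD", "QSE", "QG", "VG")) {
  stopifnot(is.data.frame(features))
  features |>
    dplyr::filter(.data$metric %in% metrics) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    dplyr::mutate(delta = .data$post - .data$pre,
                  name = paste(.data$metric, .data$band, .data$feature,
                               sep = ".")) |>
    dplyr::select("subject", "name", "delta") |>
    tidyr::pivot_wider(names_from = "name", values_from = "delta")
}

#' @rdname eeg_deltas
#' @param tt A [taxa_table()].
#' @param rank Taxonomic rank for the abundance deltas.
#' @export
taxa_deltas <- function(tt, rank = "genus") {
  stopifnot(inherits(tt, "taxa_table"))
  cc <- collapse_rank(tt, rank)
  prop <- t(t(cc) / colSums(cc))
  man <- tt$manifest
  long <- tibble::as_tibble(prop, rownames = "lineage") |>
    tidyr::pivot_longer(-"lineage", names_to = "sample",
                        values_to = "abundance") |>
    dplyr::inner_join(man, by = "sample") |>
    dplyr::select(-"sample") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "abundance")
  long |>
    dplyr::mutate(delta = .data$post - .data$pre) |>
    dplyr::select("subject", "lineage", "delta") |>
    tidyr::pivot_wider(names_from = "lineage", values_from = "delta")
}

#' Assemble a pipeline configuration
#'
#' Bundles simulation specs (or input paths), band set, complexity and
#' statistics parameters, permutation counts and seeds into one validated,
#' JSON-serializable list consumed by [run_pipeline()].
#'
#' @param eeg An [eeg_sim_spec()], or `NULL` to load recordings from
#'   `eeg_manifest` (TSV with columns `subject`, `condition`, `path` of
#'   matrix+sidecar fixtures, see [write_recording()]).
#' @param taxa A [microbiome_sim_spec()], or `NULL` to load a taxa table
#'   from `taxa_counts` / `taxa_manifest` TSV paths.
#' @param out_dir Output directory for the stage TSVs and run manifest.
#' @param bands Character vector of canonical band names.
#' @param eeg_manifest,taxa_counts,taxa_manifest Input paths (used when the
#'   corresponding spec is `NULL`).
#' @param epoch_len,fs_out,amp_thresh,m,r,Q,alpha,q_threshold,n_perm,
#'   shift_rank,correlation_rank,seed Analysis parameters with the package
#'   defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, eeg = NULL, taxa = NULL,
                       bands = eeg_bands()$band,
                       eeg_manifest = NULL, taxa_counts = NULL,
                       taxa_manifest = NULL,
                       epoch_len = 8, fs_out = 200, amp_thresh = NULL,
                       m = 2, r = 0.2, Q = 8,
                       alpha = 0.05, q_threshold = 0.10, n_perm = 999,
                       shift_rank = "genus", correlation_rank = "genus",
                       seed = 1) {
  if (is.null(eeg) && is.null(eeg_manifest)) {
    abort_field("eeg", "supply an eeg_sim_spec or an eeg_manifest path")
  }
  if (is.null(taxa) && (is.null(taxa_counts) || is.null(taxa_manifest))) {
    abort_field("taxa", "supply a microbiome_sim_spec or taxa table paths")
  }
  eeg_bands(bands)  # validates names
  structure(
    list(out_dir = out_dir, eeg = eeg, taxa = taxa, bands = bands,
         eeg_manifest = eeg_manifest, taxa_counts = taxa_counts,
         taxa_manifest = taxa_manifest,
         epoch_len = epoch_len, fs_out = fs_out, amp_thresh = amp_thresh,
         m = m, r = r, Q = Q, alpha = alpha, q_threshold = q_threshold,
         n_perm = n_perm, shift_rank = shift_rank,
         correlation_rank = correlation_rank, seed = seed),
    class = "run_config"
  )
}

.stage_msg <- function(...) message("[gutbrain] ", sprintf(...))

#' Run the full paired EEG + microbiome analysis
#'
#' Executes every stage end to end — synthesize or ingest, preprocess,
#' connectivity and complexity metrics, paired statistics, microbiome
#' diversity/shift analysis, and the EEG-taxa correlation screen — writing
#' each stage's table as TSV plus a JSON run manifest with all resolved
#' parameters and seeds. Idempotent under fixed seeds. Stage failures abort
#' with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of all stage tibbles.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    .stage_msg("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- list()
  bands <- eeg_bands(config$bands)

  cohort <- stage("ingest-eeg", {
    if (!is.null(config$eeg)) {
      simulate_eeg_cohort(config$eeg)
    } else {
      man <- readr::read_tsv(config$eeg_manifest, show_col_types = FALSE)
      man |>
        dplyr::mutate(recording = purrr::map(.data$path, read_recording)) |>
        dplyr::select("subject", "condition", "recording")
    }
  })
  tt <- stage("ingest-taxa", {
    if (!is.null(config$taxa)) {
      simulate_taxa_tables(config$taxa)
    } else {
      read_taxa_table(config$taxa_counts, config$taxa_manifest)
    }
  })

  out$features <- stage("eeg-metrics", eeg_feature_table(
    cohort, bands = bands, epoch_len = config$epoch_len,
    fs_out = config$fs_out, amp_thresh = config$amp_thresh,
    m = config$m, r = config$r, Q = config$Q
  ))

  out$paired_stats <- stage("paired-stats", run_paired_analysis(
    dplyr::filter(out$features, .data$condition == "pre"),
    dplyr::filter(out$features, .data$condition == "post"),
    alpha = config$alpha, q_threshold = config$q_threshold
  ))

  n_ch <- nrow(cohort$recording[[1]]$data)
  out$pair_counts <- stage("pair-counts", purrr::map_dfr(
    bands$band, function(b) summarize_pair_counts(
      out$paired_stats, b, n_pairs = pairs_count(n_ch), alpha = config$alpha)
  ))

  out$alpha_diversity <- stage("alpha-diversity", alpha_diversity(tt))
  out$alpha_tests <- stage("alpha-tests",
                           alpha_kruskal(out$alpha_diversity, tt$manifest))
  beta <- stage("beta-diversity", beta_diversity(tt))
  cond <- tt$manifest$condition[match(colnames(tt$counts),
                                      tt$manifest$sample)]
  out$permanova <- stage("permanova", purrr::map_dfr(
    names(beta), function(metric) {
      permanova_test(beta[[metric]], cond, n_perm = config$n_perm,
                     seed = config$seed) |>
        dplyr::mutate(metric = metric, .before = 1)
    }
  ))
  pc <- stage("pcoa", pcoa_ord(beta$bray_curtis))
  out$pcoa <- pc$coordinates
  out$shifts <- stage("taxon-shifts", taxon_shifts(tt, config$shift_rank))

  out$correlations <- stage("correlate", correlation_screen(
    eeg_deltas(out$features),
    taxa_deltas(tt, config$correlation_rank)
  ))

  stage("write", {
    for (nm in names(out)) {
      readr::write_tsv(out[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".tsv")))
    }
    for (metric in names(beta)) {
      utils::write.table(beta[[metric]],
                         file.path(config$out_dir, paste0("beta_", metric, ".tsv")),
                         sep = "\t", quote = FALSE)
    }
    manifest <- config
    manifest$eeg <- if (!is.null(config$eeg)) unclass(config$eeg) else NULL
    manifest$taxa <- if (!is.null(config$taxa)) unclass(config$taxa) else NULL
    manifest$version <- as.character(utils::packageVersion("gutbrain"))
    jsonlite::write_json(unclass(manifest),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  })
  .stage_msg("done: %d stage tables in %s", length(out), config$out_dir)
  invisible(out)
}
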