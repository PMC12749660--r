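#' Specification for simulated paired taxa count tables
#'
#' Dirichlet-multinomial model of paired stool samples: each subject draws a
#' pre-condition composition from a Dirichlet centered on the base
#' proportions (concentration = `overdispersion`; larger means compositions
#' closer to the base), the post composition is the pre composition
#' multiplied by the per-taxon fold changes and renormalized, and read
#' counts are multinomial at the given depth.
#'
#' @param n_subjects Number of subjects.
#' @param n_taxa Number of taxa (ignored when `base_proportions` is given).
#' @param depth Reads per sample.
#' @param base_proportions Simplex vector of expected relative abundances
#'   (default: a geometric decay over `n_taxa`, normalized).
#' @param lineage Character vector of `;`-delimited lineage strings; a
#'   synthetic six-rank lineage is generated by default.
#' @param fold_changes Per-taxon post/pre multiplicative factors (default
#'   all 1).
#' @param overdispersion Dirichlet concentration; `Inf` gives every subject
#'   exactly the base composition.
#' @param seed Integer seed.
#' @return A `microbiome_sim_spec` object.
#' @export
microbiome_sim_spec <- function(n_subjects, n_taxa = 20, depth = 1e5,
                                base_proportions = NULL, lineage = NULL,
                                fold_changes = NULL, overdispersion = 200,
                                seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort_field("n_subjects", "need at least one subject")
  }
  if (!is.numeric(depth) || depth <= 0) {
    abort_field("depth", "reads per sample must be positive")
  }
  if (is.null(base_proportions)) {
    base_proportions <- 0.7^seq_len(n_taxa)
    base_proportions <- base_proportions / sum(base_proportions)
  }
  n_taxa <- length(base_proportions)
  if (any(base_proportions < 0) ||
      abs(sum(base_proportions) - 1) > 1e-6) {
    abort_field("base_proportions", "must be a simplex vector (nonnegative, sum 1)")
  }
  if (is.null(fold_changes)) fold_changes <- rep(1, n_taxa)
  if (length(fold_changes) != n_taxa || any(fold_changes <= 0)) {
    abort_field("fold_changes", "need one positive factor per taxon")
  }
  if (is.null(lineage)) {
    lineage <- vapply(seq_len(n_taxa), function(i) {
      paste(sprintf(c("Phylum%d", "Class%d", "Order%d", "Family%d",
                      "Genus%d", "Species%d"),
                    c(rep((i - 1) %/% 5 + 1, 4), i, i)),
            collapse = ";")
    }, character(1))
  }
  if (length(lineage) != n_taxa) {
    abort_field("lineage", "need one lineage per taxon")
  }
  if (!is.numeric(overdispersion) || overdispersion <= 0) {
    abort_field("overdispersion", "Dirichlet concentration must be positive")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_taxa = n_taxa,
         depth = as.integer(depth), base_proportions = base_proportions,
         lineage = lineage, fold_changes = fold_changes,
         overdispersion = overdispersion, seed = as.integer(seed)),
    class = "microbiome_sim_spec"
  )
}

#' Simulate paired pre/post taxa count tables
#'
#' @param spec A [microbiome_sim_spec()].
#' @return A [taxa_table()] holding both conditions for every subject
#'   (samples named `subXX_pre` / `subXX_post`).
#' @export
#' @examples
#' tt <- simulate_taxa_tables(microbiome_sim_spec(n_subjects = 3, n_taxa = 6,
#'                                                depth = 1000, seed = 2))
#' tt
simulate_taxa_tables <- function(spec) {
  stopifnot(inherits(spec, "microbiome_sim_spec"))
  with_seed(spec$seed, {
    cols <- list()
    man <- list()
    for (sub in seq_len(spec$n_subjects)) {
      id <- sprintf("sub%02d", sub)
      p_pre <- if (is.infinite(spec$overdispersion)) {
        spec$base_proportions
      } else {
        g <- rgamma(spec$n_taxa,
                    shape = spec$overdispersion * spec$base_proportions)
        if (sum(g) == 0) spec$base_proportions else g / sum(g)
      }
      p_post <- p_pre * spec$fold_changes
      p_post <- p_post / sum(p_post)
      cols[[paste0(id, "_pre")]] <- rmultinom(1, spec$depth, p_pre)[, 1]
      cols[[paste0(id, "_post")]] <- rmultinom(1, spec$depth, p_post)[, 1]
      man[[id]] <- tibble::tibble(
        sample = paste0(id, c("_pre", "_post")),
        subject = id, condition = c("pre", "post")
      )
    }
    counts <- do.call(cbind, cols)
    taxa_table(counts, spec$lineage, dplyr::bind_rows(man))
  })
}
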