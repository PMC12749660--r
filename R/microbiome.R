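.ranks <- c("phylum", "class", "order", "family", "genus", "species")

#' Construct a paired taxa count table
#'
#' Container for a taxa-by-sample count matrix with per-taxon lineage
#' strings and a paired sample manifest (each subject contributes at most
#' one `pre` and one `post` sample).
#'
#' @param counts Nonnegative integer matrix, taxa x samples, with column
#'   names matching the manifest's `sample` column.
#' @param lineage Character vector of `;`-delimited lineage strings
#'   (phylum;class;order;family;genus;species), one per row of `counts`.
#' @param manifest Data frame with columns `sample`, `subject`, `condition`
#'   (`"pre"` or `"post"`).
#' @return A `taxa_table` object.
#' @export
taxa_table <- function(counts, lineage, manifest) {
  if (!is.matrix(counts) || !is.numeric(counts) || any(counts < 0)) {
    abort_field("counts", "must be a nonnegative numeric taxa x samples matrix")
  }
  if (any(counts != round(counts))) abort_field("counts", "counts must be integers")
  if (any(colSums(counts) <= 0)) abort_field("counts", "every sample needs reads")
  if (length(lineage) != nrow(counts)) {
    abort_field("lineage", "one lineage string per taxon required")
  }
  tok <- strsplit(lineage, ";", fixed = TRUE)
  if (any(lengths(tok) != length(.ranks))) {
    abort_field("lineage", sprintf("each lineage needs %d ;-delimited ranks (%s)",
                                   length(.ranks), paste(.ranks, collapse = ";")))
  }
  manifest <- tibble::as_tibble(manifest)
  if (!all(c("sample", "subject", "condition") %in% names(manifest))) {
    abort_field("manifest", "need columns sample, subject, condition")
  }
  if (!all(manifest$condition %in% c("pre", "post"))) {
    abort_field("manifest", "condition must be 'pre' or 'post'")
  }
  if (!setequal(colnames(counts), manifest$sample)) {
    abort_field("manifest", "manifest samples must match count table columns")
  }
  dup <- manifest |>
    dplyr::count(.data$subject, .data$condition) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort_field("manifest", "a subject has more than one sample per condition")
  }
  structure(list(counts = counts, lineage = lineage, manifest = manifest),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("<taxa_table> %d taxa x %d samples (%d subjects)\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$manifest$subject)))
  invisible(x)
}

#' Read / write a taxa table as TSV
#'
#' The count table is a TSV whose first column `lineage` holds the
#' `;`-delimited lineage string and remaining columns are per-sample counts;
#' the manifest is a TSV with `sample`, `subject`, `condition`.
#'
#' @param tt A [taxa_table()].
#' @param counts_path,manifest_path File paths.
#' @return `write_taxa_table()` returns `counts_path` invisibly;
#'   `read_taxa_table()` returns a [taxa_table()].
#' @export
write_taxa_table <- function(tt, counts_path, manifest_path) {
  stopifnot(inherits(tt, "taxa_table"))
  df <- tibble::as_tibble(tt$counts) |>
    dplyr::mutate(lineage = tt$lineage, .before = 1)
  readr::write_tsv(df, counts_path)
  readr::write_tsv(tt$manifest, manifest_path)
  invisible(counts_path)
}

#' @rdname write_taxa_table
#' @export
read_taxa_table <- function(counts_path, manifest_path) {
  df <- readr::read_tsv(counts_path, show_col_types = FALSE)
  lineage <- df$lineage
  counts <- as.matrix(df[setdiff(names(df), "lineage")])
  rownames(counts) <- NULL
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  taxa_table(counts, lineage, manifest)
}

#' Alpha diversity indices per sample
#'
#' Bias-corrected Chao1 richness `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`
#' (singletons F1, doubletons F2), Shannon entropy in nats, and the
#' Gini-Simpson index `1 - sum p_i^2`.
#'
#' @param x A [taxa_table()] or a nonnegative integer taxa x samples matrix.
#' @return Tibble with columns `sample`, `chao1`, `shannon`, `simpson`.
#' @export
#' @examples
#' m <- cbind(a = c(10, 10, 10, 1, 1))
#' alpha_diversity(m)
alpha_diversity <- function(x) {
  counts <- if (inherits(x, "taxa_table")) x$counts else x
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) abort_field("counts", "negative counts")
  if (any(colSums(counts) <= 0)) abort_field("counts", "empty sample")
  comm <- t(counts)  # vegan convention: samples x taxa
  est <- vegan::estimateR(round(comm))
  tibble::tibble(
    sample = colnames(counts) %||% paste0("s", seq_len(ncol(counts))),
    chao1 = unname(est["S.chao1", ]),
    shannon = unname(vegan::diversity(comm, index = "shannon")),
    simpson = unname(vegan::diversity(comm, index = "simpson"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beta diversity distance matrices
#'
#' Bray-Curtis dissimilarity on relative abundances and classic Jaccard
#' distance on presence/absence.
#'
#' @inheritParams alpha_diversity
#' @return List of two symmetric zero-diagonal distance matrices,
#'   `bray_curtis` and `jaccard`, values in `[0, 1]`.
#' @export
beta_diversity <- function(x) {
  counts <- if (inherits(x, "taxa_table")) x$counts else x
  if (ncol(counts) < 2) abort_field("counts", "need at least 2 samples")
  if (any(colSums(counts) <= 0)) abort_field("counts", "all-zero sample")
  prop <- t(t(counts) / colSums(counts))
  bc <- as.matrix(vegan::vegdist(t(prop), method = "bray"))
  jc <- as.matrix(vegan::vegdist(t(counts), method = "jaccard", binary = TRUE))
  list(bray_curtis = bc, jaccard = jc)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' Gower matrix, coordinates scaled by the square root of the eigenvalues.
#' Negative eigenvalues (non-Euclidean distances) are reported, never
#' silently dropped; explained-variance fractions use the positive
#' eigenvalues.
#'
#' @param d Symmetric zero-diagonal distance matrix (or `dist`).
#' @param k Number of axes to return (default all with positive eigenvalue).
#' @return A `gb_pcoa` object: `coordinates` tibble (`sample`, `PC1`, ...),
#'   `eigenvalues`, `explained` fractions.
#' @export
pcoa_ord <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort_field("d", "distance matrix must be symmetric")
  }
  n <- nrow(m)
  # non-Euclidean distances legitimately produce negative eigenvalues,
  # which we report; cmdscale's warning about them is expected
  full <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1,
                                           eig = TRUE))
  eig <- full$eig
  npos <- sum(eig > 1e-10)
  if (is.null(k)) k <- max(1, npos)
  k <- min(k, ncol(full$points))
  coords <- full$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample = rownames(m) %||% paste0("s", seq_len(n))),
        tibble::as_tibble(coords)
      ),
      eigenvalues = eig,
      explained = ifelse(eig > 0, eig / sum(eig[eig > 0]), 0)
    ),
    class = "gb_pcoa"
  )
}

#' @export
print.gb_pcoa <- function(x, ...) {
  cat(sprintf("<gb_pcoa> %d samples, %d positive axes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$coordinates), sum(x$eigenvalues > 1e-10),
              100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else NA))
  invisible(x)
}

#' Kruskal-Wallis comparison of alpha diversity between conditions
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p for each alpha index,
#' comparing the `pre` and `post` groups (conditions treated as independent
#' groups, as in the named procedure). Each index is its own correction
#' family, so the reported q equals p.
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param manifest Manifest tibble (`sample`, `subject`, `condition`).
#' @return Tibble with columns `index`, `H`, `p`, `q`.
#' @export
alpha_kruskal <- function(alpha, manifest) {
  stopifnot(is.data.frame(alpha), is.data.frame(manifest))
  df <- dplyr::inner_join(alpha, manifest, by = "sample")
  if (dplyr::n_distinct(df$condition) < 2) {
    abort_field("manifest", "need both pre and post samples")
  }
  purrr::map_dfr(c("chao1", "shannon", "simpson"), function(idx) {
    if (length(unique(df[[idx]])) == 1) {
      # all values identical: no rank information, H = 0 by convention
      return(tibble::tibble(index = idx, H = 0, p = 1))
    }
    kt <- stats::kruskal.test(df[[idx]], factor(df$condition))
    tibble::tibble(index = idx, H = unname(kt$statistic), p = kt$p.value)
  }) |>
    dplyr::mutate(q = .data$p)
}

#' Permutation PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance:
#' `pseudo-F = (SS_between / (k - 1)) / (SS_within / (N - k))` from the
#' squared-distance partition, with the permutation p-value
#' `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`. Deterministic under `seed`.
#'
#' @param d Distance matrix (or `dist`) over samples.
#' @param labels Group label per sample; every group needs at least 2
#'   members.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return Tibble with `pseudo_F`, `p`, `n_perm`, `df_between`, `df_within`.
#' @export
permanova_test <- function(d, labels, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) {
    abort_field("labels", "one label per sample required")
  }
  sizes <- table(labels)
  if (length(sizes) < 2) abort_field("labels", "need at least 2 groups")
  if (any(sizes < 2)) {
    abort_field("labels", paste("group(s) with fewer than 2 samples:",
                                paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  df <- data.frame(grp = factor(labels))
  fit <- with_seed(seed, vegan::adonis2(stats::as.dist(m) ~ grp, data = df,
                                        permutations = n_perm))
  tibble::tibble(
    pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm,
    df_between = fit$Df[1], df_within = fit$Df[2]
  )
}

#' Collapse a taxa table to a taxonomic rank
#'
#' @param tt A [taxa_table()].
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Matrix of counts with one row per distinct lineage prefix at the
#'   rank; rownames are the full prefix.
#' @export
collapse_rank <- function(tt, rank) {
  stopifnot(inherits(tt, "taxa_table"))
  k <- match(rank, .ranks)
  if (is.na(k)) {
    abort_field("rank", paste("unknown rank; use one of",
                              paste(.ranks, collapse = ", ")))
  }
  tok <- strsplit(tt$lineage, ";", fixed = TRUE)
  prefix <- vapply(tok, function(t) paste(t[seq_len(k)], collapse = ";"),
                   character(1))
  rowsum(tt$counts, prefix)
}

#' Per-taxon relative-abundance shifts between conditions
#'
#' Collapses the table to a rank, converts to relative abundances, and
#' summarizes each taxon: mean relative abundance in the pre and post
#' condition, percent change `100 (post - pre) / pre` (defined only when the
#' pre mean is positive; taxa absent before and present after are flagged
#' `emergent`), and a paired Wilcoxon p across subjects with both samples
#' (`NA` where the paired test is undefined, e.g. too few nonzero
#' differences).
#'
#' @inheritParams collapse_rank
#' @return Tibble: `rank`, `taxon`, `lineage`, `mean_pre`, `mean_post`,
#'   `pct_change`, `emergent`, `p`.
#' @export
taxon_shifts <- function(tt, rank) {
  stopifnot(inherits(tt, "taxa_table"))
  cc <- collapse_rank(tt, rank)
  prop <- t(t(cc) / colSums(cc))
  man <- tt$manifest
  pre_s <- man$sample[man$condition == "pre"]
  post_s <- man$sample[man$condition == "post"]
  paired <- intersect(man$subject[man$condition == "pre"],
                      man$subject[man$condition == "post"])
  pre_of <- function(sub) man$sample[man$subject == sub & man$condition == "pre"]
  post_of <- function(sub) man$sample[man$subject == sub & man$condition == "post"]
  purrr::map_dfr(seq_len(nrow(prop)), function(i) {
    mp <- mean(prop[i, pre_s])
    ma <- mean(prop[i, post_s])
    emergent <- mp == 0 && ma > 0
    pct <- if (mp > 0) 100 * (ma - mp) / mp else NA_real_
    pv <- tryCatch({
      pr <- vapply(paired, function(s) prop[i, pre_of(s)], numeric(1))
      po <- vapply(paired, function(s) prop[i, post_of(s)], numeric(1))
      wilcoxon_signed_rank(pr, po)$p
    }, error = function(e) NA_real_)
    lin <- rownames(prop)[i]
    tibble::tibble(
      rank = rank,
      taxon = utils::tail(strsplit(lin, ";", fixed = TRUE)[[1]], 1),
      lineage = lin, mean_pre = mp, mean_post = ma,
      pct_change = pct, emergent = emergent, p = pv
    )
  })
}
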