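# All permutations of 1..n as rows (n <= 9 keeps this comfortably in memory).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[c(sub)], nrow(sub)))
  }))
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau-b with a two-sided p-value: exact by full enumeration
#' of the permutation null (all `n!` orderings of `y`, ties handled
#' naturally) for `n <= exact_max`, otherwise the normal approximation with
#' the tie-corrected variance of the concordance statistic S.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`, non-constant.
#' @param exact_max Largest n for the exact enumeration (default 9).
#' @return One-row tibble: `n`, `tau`, `p`, `method`.
#' @export
#' @examples
#' kendall_tau(1:6, c(2, 1, 4, 3, 6, 5))
kendall_tau <- function(x, y, exact_max = 9) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort_field("x/y", "need equal-length numeric vectors")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort_field("x/y", "need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("zero variance: a constant vector has no rank correlation",
         call. = FALSE)
  }
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sx <- sign(x[pair[, 2]] - x[pair[, 1]])
  sy <- sign(y[pair[, 2]] - y[pair[, 1]])
  s_obs <- sum(sx * sy)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- s_obs / sqrt((n0 - n1) * (n0 - n2))
  if (n <= exact_max) {
    P <- .permutations(n)
    SY <- outer(y, y, function(a, b) sign(b - a))
    s_all <- numeric(nrow(P))
    for (k in seq_len(nrow(pair))) {
      s_all <- s_all + sx[k] * SY[cbind(P[, pair[k, 1]], P[, pair[k, 2]])]
    }
    p <- mean(abs(s_all) >= abs(s_obs) - 1e-9)
    method <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- s_obs / sqrt(var_s)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(n = n, tau = tau, p = p, method = method)
}

#' Screen EEG feature deltas against taxa abundance shifts
#'
#' Tests every EEG-feature x taxon pair of per-subject pre-post deltas with
#' Kendall's tau-b, applies Benjamini-Hochberg FDR over the full grid of
#' tested pairs, and follows up pairs with uncorrected Kendall `p <
#' spearman_threshold` with Spearman's rank correlation (the follow-up set
#' is exactly that subset; Spearman is never computed otherwise). Missing
#' subjects are dropped listwise per pair; pairs with fewer than `min_n`
#' complete subjects, or with a constant vector, are kept in the grid with
#' `NA` results and excluded from the correction family.
#'
#' @param eeg_deltas Wide tibble: `subject` column plus one column per EEG
#'   feature (post - pre deltas).
#' @param taxa_deltas Wide tibble: `subject` column plus one column per
#'   taxon (post - pre relative-abundance deltas).
#' @param min_n Minimum complete pairs per test (default 5).
#' @param spearman_threshold Raw Kendall p-value below which the Spearman
#'   follow-up runs (default 0.001).
#' @return Tibble with one row per feature x taxon pair: `feature`, `taxon`,
#'   `n`, `tau`, `p`, `q`, `spearman_rho`, `spearman_p`, `family_size`;
#'   sorted by `q`.
#' @export
correlation_screen <- function(eeg_deltas, taxa_deltas, min_n = 5,
                               spearman_threshold = 0.001) {
  for (nm in c("eeg_deltas", "taxa_deltas")) {
    tb <- get(nm)
    if (!is.data.frame(tb) || !"subject" %in% names(tb) || ncol(tb) < 2) {
      abort_field(nm, "need a `subject` column plus at least one feature column")
    }
  }
  feats <- setdiff(names(eeg_deltas), "subject")
  taxa <- setdiff(names(taxa_deltas), "subject")
  joined <- dplyr::inner_join(eeg_deltas, taxa_deltas, by = "subject",
                              suffix = c("..eeg", "..taxa"))
  if (!nrow(joined)) stop("no common subjects between the delta blocks",
                          call. = FALSE)
  grid <- tidyr::expand_grid(feature = feats, taxon = taxa)
  if (!nrow(grid)) stop("empty feature x taxon grid", call. = FALSE)
  col_of <- function(base, side) {
    if (base %in% names(joined)) base else paste0(base, "..", side)
  }
  res <- purrr::pmap_dfr(grid, function(feature, taxon) {
    xv <- joined[[col_of(feature, "eeg")]]
    yv <- joined[[col_of(taxon, "taxa")]]
    ok <- stats::complete.cases(xv, yv)
    out <- tibble::tibble(feature = feature, taxon = taxon,
                          n = sum(ok), tau = NA_real_, p = NA_real_)
    if (sum(ok) < min_n) return(out)
    kt <- tryCatch(kendall_tau(xv[ok], yv[ok]), error = function(e) NULL)
    if (is.null(kt)) return(out)
    out$tau <- kt$tau
    out$p <- kt$p
    out
  })
  tested <- !is.na(res$p)
  res$q <- NA_real_
  if (any(tested)) res$q[tested] <- bh_fdr(res$p[tested])
  res$family_size <- sum(tested)
  res$spearman_rho <- NA_real_
  res$spearman_p <- NA_real_
  follow <- which(tested & res$p < spearman_threshold)
  for (i in follow) {
    xv <- joined[[col_of(res$feature[i], "eeg")]]
    yv <- joined[[col_of(res$taxon[i], "taxa")]]
    ok <- stats::complete.cases(xv, yv)
    ct <- suppressWarnings(stats::cor.test(xv[ok], yv[ok], method = "spearman"))
    res$spearman_rho[i] <- unname(ct$estimate)
    res$spearman_p[i] <- ct$p.value
  }
  dplyr::arrange(res, .data$q)
}
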