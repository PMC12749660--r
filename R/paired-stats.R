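#' Paired Wilcoxon signed-rank test with the reporting sign convention
#'
#' Tests paired pre/post values per feature. Differences `d = pre - post`
#' have zero differences dropped and midranks assigned to ties;
#' `W+ = sum of ranks of positive d`. The signed normal statistic
#' `z = (W+ - n(n+1)/4) / sigma` uses the tie-corrected variance, so an
#' increase after the intervention (post > pre) carries a negative z. For
#' `n <= 12` retained pairs the two-sided p-value is exact, from full
#' enumeration of all `2^n` sign assignments on the observed ranks;
#' otherwise it comes from the normal approximation (no continuity
#' correction).
#'
#' @param pre,post Equal-length numeric vectors of per-subject values.
#' @return One-row tibble: `n` (pairs retained), `n_zero` (dropped zero
#'   differences), `w_plus`, `z`, `p`, `direction`
#'   (`"increase"`/`"decrease"`/`"none"`), `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(pre = c(1, 2, 3, 4, 5, 6), post = c(2, 3, 4, 5, 6, 7))
wilcoxon_signed_rank <- function(pre, post) {
  if (!is.numeric(pre) || !is.numeric(post) || length(pre) != length(post)) {
    abort_field("pre/post", "need equal-length numeric vectors")
  }
  d <- pre - post
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("no signal: all paired differences are zero", call. = FALSE)
  if (n < 5) {
    stop(sprintf("only %d nonzero paired differences; need at least 5", n),
         call. = FALSE)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
  if (n <= 12) {
    # exact null distribution of W+ over all sign assignments of the ranks
    w_all <- 0
    for (rk in r) w_all <- c(w_all, w_all + rk)
    eps <- 1e-9
    p <- 2 * min(mean(w_all <= w_plus + eps), mean(w_all >= w_plus - eps))
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  direction <- if (z < 0) "increase" else if (z > 0) "decrease" else "none"
  tibble::tibble(n = n, n_zero = n_zero, w_plus = w_plus, z = z, p = p,
                 direction = direction, method = method)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} m p_(j) / j` restored to the input order.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values, elementwise `>= pvalues`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues <= 0 | pvalues > 1)) {
    abort_field("pvalues", "p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Paired pre/post inference across all features with per-family FDR
#'
#' Runs [wilcoxon_signed_rank()] for every `(metric, band, feature)` cell of
#' a long-format feature table, then applies Benjamini-Hochberg correction
#' within each `(metric, band)` family, but only for the metrics named in
#' `fdr_metrics` (by default the four nonlinear complexity metrics, matching
#' the reporting convention of correcting each nonlinear metric separately;
#' connectivity and network metrics keep raw p-values with `q = NA`).
#'
#' @param pre,post Long tibbles with columns `subject`, `metric`, `band`,
#'   `feature`, `value`; subjects must match cell by cell.
#' @param fdr_metrics Metrics whose `(metric, band)` families receive FDR
#'   correction.
#' @param alpha Raw significance threshold (default 0.05).
#' @param q_threshold FDR significance threshold (default 0.10).
#' @return Tibble: `metric`, `band`, `feature`, `n`, `z`, `p`, `q`,
#'   `direction`, `sig_raw`, `sig_fdr`, `family_size`.
#' @export
run_paired_analysis <- function(pre, post,
                                fdr_metrics = c("FD", "QSE", "QG", "VG"),
                                alpha = 0.05, q_threshold = 0.10) {
  need <- c("subject", "metric", "band", "feature", "value")
  for (nm in c("pre", "post")) {
    tb <- get(nm)
    if (!is.data.frame(tb) || !all(need %in% names(tb))) {
      abort_field(nm, paste("need columns", paste(need, collapse = ", ")))
    }
  }
  key <- function(tb) paste(tb$subject, tb$metric, tb$band, tb$feature, sep = "\r")
  miss_post <- setdiff(key(pre), key(post))
  miss_pre <- setdiff(key(post), key(pre))
  if (length(miss_post) || length(miss_pre)) {
    offenders <- gsub("\r", "/", utils::head(c(miss_post, miss_pre), 5))
    stop("subject keys do not match between pre and post; offenders: ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::rename(pre, pre = "value"),
    dplyr::rename(post, post = "value"),
    by = c("subject", "metric", "band", "feature")
  )
  res <- joined |>
    dplyr::group_by(.data$metric, .data$band, .data$feature) |>
    dplyr::group_modify(function(df, key) wilcoxon_signed_rank(df$pre, df$post)) |>
    dplyr::ungroup()
  res <- res |>
    dplyr::group_by(.data$metric, .data$band) |>
    dplyr::mutate(
      family_size = dplyr::n(),
      q = if (.data$metric[1] %in% fdr_metrics) bh_fdr(.data$p) else NA_real_
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sig_raw = .data$p < alpha,
      sig_fdr = !is.na(.data$q) & .data$q < q_threshold
    ) |>
    dplyr::select("metric", "band", "feature", "n", "z", "p", "q",
                  "direction", "sig_raw", "sig_fdr", "family_size")
  res
}

#' Electrode-by-band z map of a paired-stat table
#'
#' Reshapes electrode-level results for one metric into a wide z table
#' (electrodes in montage order, one column per band) suitable for
#' topographic rendering, with the matching significance flags attached as
#' the `"sig"` attribute. Electrodes missing from the table are filled with
#' `NA` and flagged with a warning.
#'
#' @param table Output of [run_paired_analysis()].
#' @param metric Which metric to map (e.g. `"FD"`).
#' @param montage Electrode order for the rows.
#' @param path Optional TSV path; when given, the z map is also written out.
#' @return Wide tibble of z values with attribute `sig` (same shape, logical
#'   FDR significance).
#' @export
zmap_export <- function(table, metric, montage = montage_1020(), path = NULL) {
  stopifnot(is.data.frame(table))
  tb <- dplyr::filter(table, .data$metric == !!metric)
  if (!nrow(tb)) abort_field("metric", "no rows for the requested metric")
  missing <- setdiff(montage, unique(tb$feature))
  if (length(missing)) {
    warning("montage electrodes missing from table: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  zw <- tb |>
    dplyr::select("feature", "band", "z") |>
    tidyr::pivot_wider(names_from = "band", values_from = "z") |>
    dplyr::right_join(tibble::tibble(feature = montage), by = "feature") |>
    dplyr::arrange(match(.data$feature, montage)) |>
    dplyr::rename(electrode = "feature")
  sw <- tb |>
    dplyr::select("feature", "band", "sig_fdr") |>
    tidyr::pivot_wider(names_from = "band", values_from = "sig_fdr") |>
    dplyr::right_join(tibble::tibble(feature = montage), by = "feature") |>
    dplyr::arrange(match(.data$feature, montage)) |>
    dplyr::rename(electrode = "feature")
  attr(zw, "sig") <- sw
  if (!is.null(path)) readr::write_tsv(zw, path)
  zw
}
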