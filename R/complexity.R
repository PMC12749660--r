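#' Katz fractal dimension of a waveform
#'
#' Uses the ordinate-only reading of Katz's construction: curve length
#' `L = sum |x[k+1] - x[k]|`, extent `d = max_k |x[k] - x[1]|`, and
#' `n = length(x) - 1` steps, giving
#' `FD = log10(n) / (log10(n) + log10(d / L))`. A straight line has `d = L`
#' and so FD exactly 1; degenerate signals (`L = 0` or `d = 0`) are defined
#' as 1. This form is invariant under positive affine rescaling of the
#' signal, so pre/post contrasts do not depend on amplitude units.
#'
#' @param x Numeric vector of at least 2 samples.
#' @return Scalar fractal dimension, `>= 1` for typical waveforms.
#' @export
#' @examples
#' katz_fd(0.5 * (1:1600) + 2)  # straight line -> 1
#' katz_fd(rnorm(1600))         # noise -> larger
katz_fd <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    abort_field("x", "need a numeric signal with at least 2 samples")
  }
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) return(1)
  n <- length(x) - 1
  log10(n) / (log10(n) + log10(d / L))
}

#' Sample entropy and quadratic sample entropy
#'
#' `sample_entropy()` computes SampEn(m, r_abs) by Chebyshev template
#' matching with self-matches excluded. `qse()` adds the `log(2 r_abs)`
#' offset (tolerance expressed in the signal's amplitude units,
#' `r_abs = r * sd(x)`), which removes the tolerance dependence of SampEn;
#' the result is in nats. Epochs with zero variance, or with no template
#' matches at either length, yield `NA` and are excluded from epoch averages
#' upstream.
#'
#' @param x Numeric epoch signal.
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the epoch standard deviation
#'   (default 0.2).
#' @return `sample_entropy()`: list with `sampen`, match counts `A`, `B`, and
#'   the absolute tolerance `r_abs`. `qse()`: scalar QSE in nats (`NA` if
#'   undefined).
#' @export
#' @examples
#' qse(sin(2 * pi * (1:400) / 20))
sample_entropy <- function(x, m = 2, r = 0.2) {
  if (!is.numeric(x) || length(x) <= m + 1) {
    abort_field("x", sprintf("need more than m + 1 = %d samples", m + 1))
  }
  if (m < 1) abort_field("m", "embedding length must be >= 1")
  if (r <= 0) abort_field("r", "tolerance fraction must be positive")
  s <- stats::sd(x)
  if (s == 0) {
    return(list(sampen = NA_real_, A = 0, B = 0, r_abs = 0,
                flag = "zero variance"))
  }
  r_abs <- r * s
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r_abs)
  a <- cnt[1]; b <- cnt[2]
  sampen <- if (a > 0 && b > 0) -log(a / b) else NA_real_
  list(sampen = sampen, A = a, B = b, r_abs = r_abs,
       flag = if (is.na(sampen)) "no template matches" else NA_character_)
}

#' @rdname sample_entropy
#' @export
qse <- function(x, m = 2, r = 0.2) {
  se <- sample_entropy(x, m = m, r = r)
  if (is.na(se$sampen)) return(NA_real_)
  se$sampen + log(2 * se$r_abs)
}

#' Quantile-graph transition network and mean jump length
#'
#' Samples are assigned to `Q` amplitude quantiles (empirical type-7
#' boundaries; boundary ties go to the lower quantile), and consecutive
#' samples define a weighted directed transition graph. The mean jump length
#' averages `|a - b|` over all observed transitions, i.e. occupancy-weighted
#' row-normalized transition probabilities with occupancy taken over
#' transition origins.
#'
#' @param x Numeric signal with at least `Q` samples and at least `Q`
#'   distinct values.
#' @param Q Number of quantiles (default 8).
#' @return `quantile_graph()`: list with row-normalized transition matrix
#'   `W`, raw transition `counts`, origin occupancy `pi`, and the per-sample
#'   quantile sequence. `qg_mean_jump()`: scalar mean jump in quantile units,
#'   bounded by `Q - 1`.
#' @export
#' @examples
#' g <- quantile_graph(rnorm(1600), Q = 8)
#' qg_mean_jump(g)
quantile_graph <- function(x, Q = 8) {
  if (!is.numeric(Q) || Q < 2) abort_field("Q", "need at least 2 quantiles")
  if (!is.numeric(x) || length(x) < Q) {
    abort_field("x", "signal shorter than the number of quantiles")
  }
  if (length(unique(x)) < Q) {
    abort_field("Q", sprintf(
      "only %d distinct values for %d quantiles; use a smaller Q",
      length(unique(x)), Q))
  }
  breaks <- stats::quantile(x, probs = seq(0, 1, length.out = Q + 1),
                            names = FALSE, type = 7)
  # (b[q], b[q+1]] intervals: boundary values fall into the lower quantile;
  # heavily tied data may collapse some boundaries, which findInterval
  # handles (the affected quantile simply stays empty)
  qseq <- findInterval(x, breaks, left.open = TRUE, rightmost.closed = FALSE)
  qseq[qseq == 0L] <- 1L     # minimum lands in the first quantile
  qseq[qseq > Q] <- Q
  from <- qseq[-length(qseq)]
  to <- qseq[-1]
  counts <- matrix(0, Q, Q)
  for (t in seq_along(from)) counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
  rs <- rowSums(counts)
  W <- counts / ifelse(rs > 0, rs, 1)
  W[rs == 0, ] <- 0
  list(W = W, counts = counts, pi = rs / sum(rs), quantiles = qseq, Q = Q)
}

#' @rdname quantile_graph
#' @param g A quantile graph from `quantile_graph()`.
#' @export
qg_mean_jump <- function(g) {
  stopifnot(is.list(g), !is.null(g$counts))
  jump <- abs(row(g$counts) - col(g$counts))
  sum(g$counts * jump) / sum(g$counts)
}

#' Natural visibility graph and graph-index complexity
#'
#' `visibility_graph()` links samples `a < b` whenever every intermediate
#' sample lies strictly below the straight line joining them (natural
#' visibility; adjacent samples are always linked, so the path graph is a
#' subgraph). `vg_gic()` maps the largest adjacency eigenvalue onto `[0, 1]`:
#' `c = (lambda_max - 2 cos(pi / (n + 1))) / (n - 1 - 2 cos(pi / (n + 1)))`
#' and `GIC = 4 c (1 - c)`; a monotone ramp gives the bare path graph and
#' GIC 0.
#'
#' @param x Numeric signal of length at least 2.
#' @return `visibility_graph()`: list with the 2-column `edges` matrix
#'   (1-based node indices, `a < b`) and `n`. `vg_gic()`: scalar in `[0, 1]`.
#' @export
#' @examples
#' vg <- visibility_graph(c(3, 1, 4, 1, 5, 2))
#' vg_gic(vg)
visibility_graph <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    abort_field("x", "need a numeric signal with at least 2 samples")
  }
  list(edges = vg_edges_cpp(as.numeric(x)), n = length(x))
}

# Largest adjacency eigenvalue: dense symmetric eigensolver for small
# graphs (exact even for the near-degenerate path-graph spectrum of
# monotone signals), ARPACK via igraph above 400 nodes.
.vg_lambda_max <- function(vg) {
  n <- vg$n
  e <- vg$edges
  if (n <= 400) {
    A <- matrix(0, n, n)
    A[e] <- 1
    A[e[, c(2, 1), drop = FALSE]] <- 1
    return(max(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  }
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  # ARPACK draws its start vector from R's RNG; pin it so repeated runs are
  # byte-identical
  with_seed(1L, igraph::eigen_centrality(g, weights = NA)$value)
}

#' @rdname visibility_graph
#' @param vg A visibility graph from `visibility_graph()`.
#' @export
vg_gic <- function(vg) {
  stopifnot(is.list(vg), !is.null(vg$edges), !is.null(vg$n))
  n <- vg$n
  lam <- .vg_lambda_max(vg)
  base <- 2 * cos(pi / (n + 1))
  cc <- (lam - base) / (n - 1 - base)
  cc <- min(max(cc, 0), 1)
  4 * cc * (1 - cc)
}

#' Per-channel complexity profile of banded epochs
#'
#' Computes all four nonlinear metrics (Katz FD, QSE, quantile-graph mean
#' jump, visibility-graph GIC) for every epoch and channel of each band,
#' then averages across epochs; epochs flagged by a metric (zero variance or
#' no entropy template matches) are excluded from that metric's average.
#'
#' @param ep An `eeg_epochs` object or a named list of them (one per band,
#'   as produced by [band_epochs()]).
#' @param m,r QSE parameters, see [sample_entropy()].
#' @param Q Quantile count for the quantile graph.
#' @return Tibble with columns `band`, `channel`, `metric`
#'   (`"FD"`, `"QSE"`, `"QG"`, `"VG"`), `value`, `n_epochs_used`.
#' @export
complexity_profile <- function(ep, m = 2, r = 0.2, Q = 8) {
  if (inherits(ep, "eeg_epochs")) ep <- list(all = ep)
  stopifnot(is.list(ep), length(ep) > 0)
  purrr::imap(ep, function(e, band) {
    stopifnot(inherits(e, "eeg_epochs"))
    d <- dim(e$x)
    if (d[1] < 1) stop("no valid epochs in band ", band, call. = FALSE)
    grid <- tidyr::expand_grid(epoch = seq_len(d[1]), channel = seq_len(d[2]))
    vals <- purrr::pmap(grid, function(epoch, channel) {
      x <- e$x[epoch, channel, ]
      tibble::tibble(
        channel = e$labels[channel],
        metric = c("FD", "QSE", "QG", "VG"),
        value = c(
          katz_fd(x),
          qse(x, m = m, r = r),
          qg_mean_jump(quantile_graph(x, Q = Q)),
          vg_gic(visibility_graph(x))
        )
      )
    })
    dplyr::bind_rows(vals) |>
      dplyr::group_by(.data$channel, .data$metric) |>
      dplyr::summarise(
        n_epochs_used = sum(!is.na(.data$value)),
        value = mean(.data$value, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(band = band, .before = 1) |>
      dplyr::select("band", "channel", "metric", "value", "n_epochs_used")
  }) |>
    dplyr::bind_rows()
}
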