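#' Welch cross-spectral density estimate
#'
#' Segments the recording into Hanning-tapered windows (1 s, 50% overlap by
#' default), linearly detrends each segment, and averages the one-sided
#' cross-periodograms into a channels x channels x frequency array of
#' cross-spectral densities.
#'
#' @param rec An [eeg_recording()] lasting at least two window lengths.
#' @param window_len Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments in `[0, 1)`.
#' @return A `cross_spectra` object: complex array `S` (channel x channel x
#'   frequency, Hermitian at each frequency with real nonnegative diagonal),
#'   `freqs` in Hz, `labels`, `n_segments`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 2000), 2), fs = 200)
#' cs <- welch_cross_spectra(rec)
#' cs$freqs[1:5]
welch_cross_spectra <- function(rec, window_len = 1, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    abort_field("overlap", "must be in [0, 1)")
  }
  n_win <- as.integer(round(window_len * rec$fs))
  n <- ncol(rec$data)
  if (n < 2 * n_win) {
    stop(sprintf("recording too short for Welch estimate: need >= %g s, have %.2f s",
                 2 * window_len, rec_duration(rec)), call. = FALSE)
  }
  step <- max(1L, as.integer(round(n_win * (1 - overlap))))
  starts <- seq(1L, n - n_win + 1L, by = step)
  k <- length(starts)
  n_ch <- nrow(rec$data)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n_win - 1) / (n_win - 1)))  # Hanning
  n_f <- n_win %/% 2 + 1L
  # FFT of every tapered, detrended segment for every channel
  X <- array(0i, dim = c(n_f, k, n_ch))
  tt <- seq_len(n_win)
  tc <- tt - mean(tt)
  ss_t <- sum(tc^2)
  for (s in seq_len(k)) {
    seg <- rec$data[, starts[s]:(starts[s] + n_win - 1L), drop = FALSE]
    # linear detrend per channel (closed-form regression on the time index)
    beta <- (seg %*% tc) / ss_t
    seg <- seg - rowMeans(seg) - beta %*% rbind(tc)
    fx <- stats::mvfft(t(seg) * w)
    X[, s, ] <- fx[seq_len(n_f), , drop = FALSE]
  }
  scale <- 1 / (rec$fs * sum(w^2) * k)
  S <- array(0i, dim = c(n_ch, n_ch, n_f))
  for (i in seq_len(n_ch)) {
    for (j in i:n_ch) {
      sij <- rowSums(X[, , i, drop = FALSE][, , 1] *
                       Conj(X[, , j, drop = FALSE][, , 1])) * scale
      S[i, j, ] <- sij
      if (j > i) S[j, i, ] <- Conj(sij)
    }
  }
  # diagonal is real by construction up to rounding
  for (i in seq_len(n_ch)) S[i, i, ] <- complex(real = Re(S[i, i, ]))
  structure(
    list(
      S = S, freqs = seq(0, n_win %/% 2) * rec$fs / n_win,
      labels = rec$labels, window_len = window_len, overlap = overlap,
      n_segments = k
    ),
    class = "cross_spectra"
  )
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("<cross_spectra> %d channels, %d frequencies (0-%g Hz), %d segments\n",
              dim(x$S)[1], length(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' Band-averaged imaginary coherence matrix
#'
#' Coherency `C_ij(f) = S_ij / sqrt(S_ii S_jj)` is normalized at each
#' frequency; the connectivity weight is the arithmetic mean of `|Im(C)|`
#' over the in-band frequency bins. The imaginary part is insensitive to
#' zero-lag (volume-conducted) coupling, which is the motivation for using it
#' on scalp EEG.
#'
#' @param cs A `cross_spectra` object from [welch_cross_spectra()].
#' @param band One-row band tibble (see [eeg_bands()]), or a band name from
#'   the canonical set.
#' @return An `icoh_matrix`: symmetric `W` in `[0, 1]` with zero diagonal,
#'   plus band metadata.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 4000), 2), fs = 200)
#' W <- icoh(welch_cross_spectra(rec), "alpha")
#' W$W
icoh <- function(cs, band) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (is.character(band)) band <- eeg_bands(band)
  stopifnot(is.data.frame(band), nrow(band) == 1)
  sel <- which(cs$freqs >= band$lo & cs$freqs <= band$hi)
  if (!length(sel)) abort_field("band", "no frequency bins inside the band")
  n_ch <- dim(cs$S)[1]
  auto <- vapply(seq_len(n_ch), function(i) Re(cs$S[i, i, sel]),
                 numeric(length(sel)))
  auto <- matrix(auto, nrow = length(sel))
  bad <- which(apply(auto, 2, function(a) any(a <= 0)))
  if (length(bad)) {
    stop(sprintf("zero autospectrum in band for channel(s): %s",
                 paste(cs$labels[bad], collapse = ", ")), call. = FALSE)
  }
  W <- matrix(0, n_ch, n_ch, dimnames = list(cs$labels, cs$labels))
  for (i in seq_len(n_ch)) {
    for (j in seq_len(n_ch)) {
      if (j <= i) next
      cij <- cs$S[i, j, sel] / sqrt(auto[, i] * auto[, j])
      W[i, j] <- W[j, i] <- mean(abs(Im(cij)))
    }
  }
  structure(
    list(W = W, band = band$band, lo = band$lo, hi = band$hi,
         labels = cs$labels),
    class = "icoh_matrix"
  )
}

#' @export
print.icoh_matrix <- function(x, ...) {
  cat(sprintf("<icoh_matrix> band %s (%g-%g Hz), %d channels, mean iCOH %.3f\n",
              x$band, x$lo, x$hi, nrow(x$W),
              mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

#' @describeIn icoh Long-format tibble of the unordered electrode pairs.
#' @param x An `icoh_matrix`.
#' @param ... Unused.
#' @export
#' @method tidy icoh_matrix
tidy.icoh_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$W), arr.ind = TRUE)
  tibble::tibble(
    band = x$band,
    ch_i = x$labels[idx[, 1]],
    ch_j = x$labels[idx[, 2]],
    icoh = x$W[idx]
  )
}

#' Number of unordered electrode pairs
#'
#' @param n_channels Number of channels (at least 2).
#' @return `n (n - 1) / 2`; a 21-channel montage gives 210 pairs.
#' @export
#' @examples
#' pairs_count(21)
pairs_count <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 ||
      n_channels != round(n_channels) || n_channels < 2) {
    abort_field("n_channels", "need an integer >= 2")
  }
  n_channels * (n_channels - 1) / 2
}

# Weighted shortest-path length matrix with edge length 1/weight.
.sp_lengths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n < 2 || all(W <= 0)) return(D)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  igraph::distances(g, algorithm = "dijkstra")
}

.as_weight_matrix <- function(W) {
  if (inherits(W, "icoh_matrix")) W <- W$W
  stopifnot(is.matrix(W), is.numeric(W))
  if (any(W < 0)) abort_field("W", "edge weights must be nonnegative")
  if (max(abs(W - t(W))) > 1e-10) abort_field("W", "weight matrix must be symmetric")
  diag(W) <- 0
  W
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs, with edge
#' length `1/w`; unreachable pairs contribute zero. For weights in `[0, 1]`
#' the result is in `[0, 1]`, reaching 1 on the complete unit-weight graph.
#'
#' @param W Symmetric nonnegative weight matrix (or an `icoh_matrix`).
#' @return Scalar efficiency.
#' @export
#' @examples
#' global_efficiency(matrix(c(0, 1, 1, 0), 2))
global_efficiency <- function(W) {
  W <- .as_weight_matrix(W)
  n <- nrow(W)
  if (n < 2) return(0)
  D <- .sp_lengths(W)
  sum(1 / D[row(D) != col(D)]) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' Per-node global efficiency of the subgraph induced by that node's
#' neighbors (nodes connected by a positive weight); nodes with fewer than
#' two neighbors score zero.
#'
#' @inheritParams global_efficiency
#' @return Named numeric vector, one value per node.
#' @export
local_efficiency <- function(W) {
  W <- .as_weight_matrix(W)
  n <- nrow(W)
  le <- rlang::set_names(numeric(n), rownames(W))
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) >= 2) {
      le[i] <- global_efficiency(W[nb, nb, drop = FALSE])
    }
  }
  le
}

#' Weighted transitivity
#'
#' Ratio of the geometric-mean triangle intensity to the number of connected
#' triples: `sum_i sum_{j,h} (w_ij w_ih w_jh)^(1/3) / sum_i k_i (k_i - 1)`,
#' where `k_i` counts a node's positive-weight neighbors. Returns 0 when no
#' node has two neighbors.
#'
#' @inheritParams global_efficiency
#' @return Scalar in `[0, 1]` for weights in `[0, 1]`.
#' @export
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' transitivity_w(tri)
transitivity_w <- function(W) {
  W <- .as_weight_matrix(W)
  k <- rowSums(W > 0)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  Wc <- W^(1 / 3)
  sum(diag(Wc %*% Wc %*% Wc)) / denom
}

#' All weighted network metrics of a connectivity matrix
#'
#' @param W An `icoh_matrix` or symmetric nonnegative weight matrix.
#' @return Tibble with columns `metric` (`"GE"`, `"LE"`, `"T"`), `node`
#'   (channel name for LE, `"global"` otherwise) and `value`.
#' @export
network_metrics <- function(W) {
  band <- if (inherits(W, "icoh_matrix")) W$band else NA_character_
  labels <- if (inherits(W, "icoh_matrix")) W$labels else rownames(W)
  Wm <- .as_weight_matrix(W)
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(Wm)))
  le <- local_efficiency(Wm)
  dplyr::bind_rows(
    tibble::tibble(metric = "GE", node = "global",
                   value = global_efficiency(Wm)),
    tibble::tibble(metric = "LE", node = labels, value = unname(le)),
    tibble::tibble(metric = "T", node = "global", value = transitivity_w(Wm))
  ) |>
    dplyr::mutate(band = band, .before = 1)
}
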