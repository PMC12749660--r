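# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (Floyd-Warshall, triple loops, full
# enumeration) so they share no code path with the implementation.

oracle_sp_lengths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_ge <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_sp_lengths(W)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1))
}

oracle_le <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) >= 2) out[i] <- oracle_ge(W[nb, nb, drop = FALSE])
  }
  out
}

oracle_transitivity <- function(W) {
  n <- nrow(W)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (h in seq_len(n)) {
    if (i != j && i != h && j != h) {
      num <- num + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
  }
  denom <- 0
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    denom <- denom + k * (k - 1)
  }
  if (denom == 0) 0 else num / denom
}

random_weight_graph <- function(n, p_edge = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 0.05, 1)
  }
  W
}

# O(N^2) plain-R sample-entropy counter (Chebyshev, self-matches excluded).
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (d <= r) {
        B <- B + 1
        if (max(d, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# O(n^3) visibility scan: every intermediate sample strictly below the chord.
oracle_vg_adjacency <- function(x) {
  n <- length(x)
  A <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    vis <- TRUE
    if (b > a + 1) {
      for (cc in (a + 1):(b - 1)) {
        bound <- x[b] + (x[a] - x[b]) * (b - cc) / (b - a)
        if (x[cc] >= bound) { vis <- FALSE; break }
      }
    }
    if (vis) A[a, b] <- A[b, a] <- 1L
  }
  A
}

vg_to_adjacency <- function(vg) {
  A <- matrix(0L, vg$n, vg$n)
  A[vg$edges] <- 1L
  A[vg$edges[, c(2, 1), drop = FALSE]] <- 1L
  A
}

# Step-up BH recursion done by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  q_prev <- 1
  for (i in m:1) {
    q_prev <- min(q_prev, m * p[o[i]] / i)
    q_sorted[i] <- q_prev
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Exact two-sided signed-rank p by explicit enumeration of every sign matrix.
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

# Kendall tau-b by explicit double loop over pairs.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  s / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# PERMANOVA pseudo-F from the explicit squared-distance partition.
oracle_pseudo_f <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  sst <- sum(D[upper.tri(D)]^2) / n
  ssw <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    Dg <- D[idx, idx, drop = FALSE]
    ssw <- ssw + sum(Dg[upper.tri(Dg)]^2) / length(idx)
  }
  k <- length(unique(labels))
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# Small long-format paired feature tables for run_paired_analysis.
make_feature_tables <- function(n_subjects, features, metric = "QSE",
                                band = "delta", effect = 0, sd = 1) {
  subj <- sprintf("s%02d", seq_len(n_subjects))
  grid <- tidyr::expand_grid(subject = subj, feature = features)
  pre <- grid |>
    dplyr::mutate(metric = metric, band = band, value = rnorm(dplyr::n(), 0, sd))
  post <- grid |>
    dplyr::mutate(metric = metric, band = band,
                  value = rnorm(dplyr::n(), effect, sd))
  list(pre = pre, post = post)
}
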