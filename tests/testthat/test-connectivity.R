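test_that("Welch cross-spectra behave like periodograms of known signals", {
  fs <- 200
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t))
  dup <- eeg_recording(rbind(x, x), fs = fs)
  cs <- welch_cross_spectra(dup)
  expect_equal(cs$S[1, 2, ], cs$S[1, 1, ], tolerance = 1e-10)
  expect_lt(max(abs(Im(cs$S[1, 2, ]))), 1e-10)

  tone <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs = fs)
  ct <- welch_cross_spectra(tone)
  p <- Re(ct$S[1, 1, ])
  peak <- p[which.min(abs(ct$freqs - 10))]
  expect_gt(peak, 100 * median(p))

  # independent noise: cross terms stay far below the geometric mean
  set.seed(21)
  long <- eeg_recording(matrix(rnorm(2 * 300 * fs), 2), fs = fs)
  cl <- welch_cross_spectra(long)
  ratio <- Mod(cl$S[1, 2, ]) / sqrt(Re(cl$S[1, 1, ]) * Re(cl$S[2, 2, ]))
  expect_lt(max(ratio[-1]), 0.1)

  expect_error(welch_cross_spectra(
    eeg_recording(matrix(rnorm(2 * 150), 2), fs = 200)), "too short")
})

test_that("imaginary coherence has its defining closed-form limits", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)

  # identical channels: coherency is real 1, so iCOH is 0 in every band
  x <- rnorm(length(t))
  same <- welch_cross_spectra(eeg_recording(rbind(x, x), fs = fs))
  for (b in c("delta", "alpha", "gamma")) {
    expect_equal(icoh(same, b)$W[1, 2], 0, tolerance = 1e-8)
  }

  # quadrature pair: coherency is +/- i at the tone, band mean -> 1
  quad <- welch_cross_spectra(eeg_recording(
    rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)), fs = fs))
  expect_gt(icoh(quad, "alpha")$W[1, 2], 0.99)

  # zero-lag mixture: coherent but not imaginary-coherent
  set.seed(31)
  s <- rnorm(length(t))
  mix <- welch_cross_spectra(eeg_recording(
    rbind(s, s + 0.5 * rnorm(length(t))), fs = fs))
  W <- icoh(mix, "alpha")
  coh <- Mod(mix$S[1, 2, ]) / sqrt(Re(mix$S[1, 1, ]) * Re(mix$S[2, 2, ]))
  expect_gt(mean(coh[mix$freqs >= 7 & mix$freqs <= 12]), 0.8)
  expect_lt(W$W[1, 2], 0.05)

  # positive rescaling of a channel leaves coherency unchanged
  y <- rnorm(length(t))
  r1 <- welch_cross_spectra(eeg_recording(rbind(s, y), fs = fs))
  r2 <- welch_cross_spectra(eeg_recording(rbind(s, 7.3 * y), fs = fs))
  expect_equal(icoh(r1, "alpha")$W, icoh(r2, "alpha")$W, tolerance = 1e-10)

  # bounds
  expect_true(all(icoh(mix, "all")$W >= 0 & icoh(mix, "all")$W <= 1))
})

test_that("pair combinatorics match the montage", {
  expect_equal(pairs_count(21), 210)
  expect_equal(pairs_count(2), 1)
  expect_equal(pairs_count(6), nrow(t(combn(6, 2))))
  expect_error(pairs_count(1), "n_channels")
  expect_equal(nrow(tidy(structure(
    list(W = matrix(0, 21, 21), band = "alpha", lo = 7, hi = 12,
         labels = montage_1020()),
    class = "icoh_matrix"))), 210)
})

test_that("network metrics match closed forms on canonical graphs", {
  complete4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(global_efficiency(complete4), 1)
  expect_equal(unname(local_efficiency(complete4)), rep(1, 4))

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(global_efficiency(path3), 5 / 6)

  two <- matrix(c(0, 0.37, 0.37, 0), 2)
  expect_equal(global_efficiency(two), 0.37)

  star <- matrix(0, 5, 5); star[1, -1] <- star[-1, 1] <- 1
  expect_equal(unname(local_efficiency(star)), rep(0, 5))

  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(transitivity_w(tri), 1)
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- path4[cbind(2:4, 1:3)] <- 1
  expect_equal(transitivity_w(path4), 0)

  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
})

test_that("efficiency and transitivity equal exhaustive enumeration", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    W <- random_weight_graph(n)
    expect_equal(global_efficiency(W), oracle_ge(W), tolerance = 1e-10)
    expect_equal(unname(local_efficiency(W)), oracle_le(W), tolerance = 1e-10)
    expect_equal(transitivity_w(W), oracle_transitivity(W), tolerance = 1e-10)
  }
})

test_that("global efficiency never decreases when an edge is added", {
  # GE is genuinely monotone (extra edges can only shorten paths); LE and T
  # are not — a pendant edge enlarges neighbor subgraphs and the connected-
  # triple denominator without adding triangles
  set.seed(43)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    W <- (random_weight_graph(n, p_edge = 0.4) > 0) * 1
    absent <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample(nrow(absent), 1), ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- 1
    expect_gte(global_efficiency(W2), global_efficiency(W) - 1e-12)
  }
  # the documented counterexample: triangle plus a pendant edge
  tri <- matrix(1, 3, 3) - diag(3)
  tri_pendant <- rbind(cbind(tri, c(1, 0, 0)), c(1, 0, 0, 0))
  expect_lt(transitivity_w(tri_pendant), transitivity_w(tri))
  expect_lt(local_efficiency(tri_pendant)[1], local_efficiency(tri)[1])
})
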