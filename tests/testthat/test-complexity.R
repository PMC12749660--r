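test_that("Katz FD hits its closed-form anchors", {
  expect_equal(katz_fd(0.5 * (1:1600) + 2), 1, tolerance = 1e-12)
  expect_equal(katz_fd(rep(4.2, 100)), 1)

  # alternating series: value equals the formula evaluated step by step
  x <- rep(c(1, -1), 800)
  L <- 0
  for (k in seq_len(length(x) - 1)) L <- L + abs(x[k + 1] - x[k])
  d <- 0
  for (k in seq_along(x)) d <- max(d, abs(x[k] - x[1]))
  n <- length(x) - 1
  expect_equal(katz_fd(x), log10(n) / (log10(n) + log10(d / L)),
               tolerance = 1e-12)

  expect_error(katz_fd(3), "at least 2 samples")

  # noise is rougher than a tone of the same length
  set.seed(5)
  t <- (1:1600) / 200
  expect_gt(katz_fd(rnorm(1600)), katz_fd(sin(2 * pi * 10 * t)))
})

test_that("sample entropy matches an independent quadratic-time matcher", {
  set.seed(15)
  for (i in 1:5) {
    x <- rnorm(200)
    r_abs <- 0.2 * sd(x)
    got <- sample_entropy(x, m = 2, r = 0.2)
    ora <- oracle_sampen_counts(x, 2, r_abs)
    expect_equal(got$A, unname(ora["A"]))
    expect_equal(got$B, unname(ora["B"]))
    expect_equal(got$sampen, -log(ora["A"] / ora["B"]), ignore_attr = TRUE)
  }
})

test_that("QSE handles its degenerate and periodic limits", {
  # periodic staircase with well-separated levels: every m-match extends
  x <- rep(c(0, 5, 1, 8, 3), 80)
  se <- sample_entropy(x)
  expect_equal(se$sampen, 0)
  expect_equal(qse(x), log(2 * 0.2 * sd(x)))

  const <- sample_entropy(rep(1, 100))
  expect_true(is.na(const$sampen))
  expect_identical(const$flag, "zero variance")
  expect_true(is.na(qse(rep(1, 100))))

  expect_error(sample_entropy(c(1, 2, 3), m = 2), "samples")
})

test_that("quantile graph reproduces hand-enumerated jump sequences", {
  # cyclic staircase (ends on a wrap sample so all four transitions balance)
  x <- c(rep(1:4, 8), 1)
  g <- quantile_graph(x, Q = 4)
  expect_equal(qg_mean_jump(g), 1.5)

  # strictly monotone 8 samples into 4 quantiles: jumps 0,1,0,1,0,1,0
  g2 <- quantile_graph(as.numeric(1:8), Q = 4)
  expect_equal(qg_mean_jump(g2), 3 / 7)

  expect_error(quantile_graph(rep(c(1, 2), 10), Q = 4), "smaller Q")

  # row-stochastic transitions and the jump bound
  set.seed(25)
  y <- rnorm(400)
  g3 <- quantile_graph(y, Q = 8)
  rs <- rowSums(g3$W)
  expect_true(all(abs(rs[rowSums(g3$counts) > 0] - 1) < 1e-12))
  expect_lte(qg_mean_jump(g3), 7)
  expect_equal(sum(g3$pi), 1)
})

test_that("visibility graph equals the cubic-time scan and its GIC anchors", {
  # printed example series
  x <- c(3, 1, 4, 1, 5, 2)
  vg <- visibility_graph(x)
  expect_equal(vg_to_adjacency(vg), oracle_vg_adjacency(x))
  A <- oracle_vg_adjacency(x)
  lam <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  base <- 2 * cos(pi / (length(x) + 1))
  cc <- (lam - base) / (length(x) - 1 - base)
  expect_equal(vg_gic(vg), 4 * cc * (1 - cc), tolerance = 1e-10)

  # strict collinearity: a ramp is exactly the path graph, GIC 0
  ramp <- 0.5 * (1:100) + 2
  vr <- visibility_graph(ramp)
  expect_equal(nrow(vr$edges), 99)
  expect_equal(vg_gic(vr), 0, tolerance = 1e-9)

  set.seed(35)
  for (i in 1:10) {
    y <- rnorm(64)
    expect_equal(vg_to_adjacency(visibility_graph(y)),
                 oracle_vg_adjacency(y))
  }

  # path graph is always a subgraph; GIC bounded in [0, 1]
  y <- rnorm(128)
  Ay <- vg_to_adjacency(visibility_graph(y))
  expect_true(all(Ay[cbind(1:127, 2:128)] == 1))
  g <- vg_gic(visibility_graph(y))
  expect_gte(g, 0); expect_lte(g, 1)

  expect_error(visibility_graph(1), "at least 2 samples")
})

test_that("all four metrics are invariant under positive affine rescaling", {
  set.seed(45)
  x <- rnorm(400)
  y <- 3.7 * x + 11
  expect_equal(katz_fd(x), katz_fd(y), tolerance = 1e-10)
  expect_equal(sample_entropy(x)$sampen, sample_entropy(y)$sampen,
               tolerance = 1e-10)
  expect_equal(qg_mean_jump(quantile_graph(x)),
               qg_mean_jump(quantile_graph(y)), tolerance = 1e-10)
  expect_equal(vg_gic(visibility_graph(x)), vg_gic(visibility_graph(y)),
               tolerance = 1e-8)
})

test_that("complexity profiles epoch-average correctly", {
  set.seed(55)
  make_ep <- function(x) {
    structure(list(x = x, fs = 200, labels = paste0("ch", seq_len(dim(x)[2])),
                   epoch_len = dim(x)[3] / 200, log = "test"),
              class = "eeg_epochs")
  }
  one <- array(rnorm(1 * 2 * 400), c(1, 2, 400))
  p1 <- complexity_profile(make_ep(one), Q = 4)
  expect_equal(nrow(p1), 8)  # 2 channels x 4 metrics
  expect_true(all(p1$n_epochs_used == 1))

  dup <- array(0, c(2, 2, 400))
  dup[1, , ] <- one[1, , ]; dup[2, , ] <- one[1, , ]
  p2 <- complexity_profile(make_ep(dup), Q = 4)
  expect_equal(p2$value, p1$value, tolerance = 1e-12)

  three <- array(rnorm(3 * 1 * 400), c(3, 1, 400))
  p3 <- complexity_profile(make_ep(three), Q = 4)
  fd_by_hand <- mean(vapply(1:3, function(e) katz_fd(three[e, 1, ]),
                            numeric(1)))
  expect_equal(p3$value[p3$metric == "FD"], fd_by_hand, tolerance = 1e-12)
})
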