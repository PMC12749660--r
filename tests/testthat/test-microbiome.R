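make_tt <- function(counts, lineage = NULL) {
  if (is.null(lineage)) {
    lineage <- sprintf("P%d;C%d;O%d;F%d;G%d;S%d", 1:nrow(counts),
                       1:nrow(counts), 1:nrow(counts), 1:nrow(counts),
                       1:nrow(counts), 1:nrow(counts))
  }
  ns <- ncol(counts) / 2
  manifest <- tibble::tibble(
    sample = colnames(counts),
    subject = rep(sprintf("s%d", seq_len(ns)), each = 2),
    condition = rep(c("pre", "post"), ns)
  )
  taxa_table(counts, lineage, manifest)
}

test_that("alpha diversity matches hand-computed index values", {
  single <- cbind(a = c(500, 0, 0))
  al <- alpha_diversity(single)
  expect_equal(al$shannon, 0)
  expect_equal(al$simpson, 0)
  expect_equal(al$chao1, 1)

  even <- cbind(a = c(100, 100))
  al2 <- alpha_diversity(even)
  expect_equal(al2$shannon, log(2))
  expect_equal(al2$simpson, 0.5)

  # bias-corrected Chao1 with two singletons, no doubletons
  sing <- cbind(a = c(10, 10, 10, 1, 1))
  expect_equal(alpha_diversity(sing)$chao1, 6)

  expect_error(alpha_diversity(cbind(a = c(-1, 2))), "negative")
})

test_that("beta diversity hits its boundary values", {
  same <- cbind(a = c(5, 5), b = c(50, 50))  # identical compositions
  d <- beta_diversity(same)
  expect_equal(d$bray_curtis[1, 2], 0)
  expect_equal(d$jaccard[1, 2], 0)

  disjoint <- cbind(a = c(10, 0), b = c(0, 10))
  d2 <- beta_diversity(disjoint)
  expect_equal(d2$bray_curtis[1, 2], 1)
  expect_equal(d2$jaccard[1, 2], 1)

  hand <- cbind(a = c(1, 3), b = c(3, 1))
  d3 <- beta_diversity(hand)
  expect_equal(d3$bray_curtis[1, 2], 0.5)

  for (m in d3) {
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_error(beta_diversity(cbind(a = c(1, 2))), "2 samples")
})

test_that("PCoA reproduces known geometry and keeps negative eigenvalues", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  pc <- pcoa_ord(d3)
  pos <- pc$eigenvalues[pc$eigenvalues > 1e-8]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-8)
  emb <- as.matrix(pc$coordinates[, -1])
  expect_equal(as.matrix(dist(emb)), unname(d3), tolerance = 1e-8,
               ignore_attr = TRUE)

  # Euclidean round trip from planted 2-D points
  set.seed(12)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  pc2 <- pcoa_ord(d)
  emb2 <- as.matrix(pc2$coordinates[, -1])
  expect_equal(as.matrix(dist(emb2)), unname(d), tolerance = 1e-8,
               ignore_attr = TRUE)

  # duplicated sample lands on coincident coordinates
  d_dup <- as.matrix(dist(pts[c(1, 1, 2:6), ]))
  pc3 <- pcoa_ord(d_dup)
  c1 <- as.numeric(pc3$coordinates[1, -1])
  c2 <- as.numeric(pc3$coordinates[2, -1])
  expect_equal(c1, c2, tolerance = 1e-8)

  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  gl <- glance(pc2)
  expect_equal(gl$n_samples, 6)
  expect_identical(tidy(pc2), pc2$coordinates)
})

test_that("Kruskal-Wallis wrapper matches rank arithmetic", {
  counts <- cbind(s1 = c(40, 30, 20), s2 = c(35, 30, 25),
                  s3 = c(20, 30, 40), s4 = c(25, 30, 35))
  tt <- make_tt(counts)
  al <- alpha_diversity(tt)
  res <- alpha_kruskal(al, tt$manifest)
  expect_equal(nrow(res), 3)
  expect_true(all(res$q == res$p))

  # hand-ranked two-group example: H = 3.857
  kt <- kruskal.test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(kt$statistic), 3.857, tolerance = 1e-3)

  # all-identical values fall back to H = 0, p = 1
  flat <- alpha_kruskal(
    tibble::tibble(sample = colnames(counts), chao1 = 3, shannon = 1,
                   simpson = 0.5),
    tt$manifest)
  expect_true(all(flat$H == 0) && all(flat$p == 1))
})

test_that("PERMANOVA matches the explicit sum-of-squares partition", {
  set.seed(22)
  toy <- matrix(rnorm(12), 6)
  d_toy <- as.matrix(dist(toy))
  lab_toy <- rep(c("a", "b"), each = 3)
  expect_equal(permanova_test(d_toy, lab_toy, n_perm = 9, seed = 1)$pseudo_F,
               oracle_pseudo_f(d_toy, lab_toy), tolerance = 1e-10)

  # two tight, well-separated clusters: observed F beats every permutation
  # that changes the partition (groups large enough that partition-preserving
  # permutations are vanishingly rare)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10))
  d <- as.matrix(dist(pts))
  labels <- rep(c("a", "b"), each = 10)
  res <- permanova_test(d, labels, n_perm = 999, seed = 3)
  expect_equal(res$p, 1 / 1000)

  # seed reproducibility and sample-order invariance
  res2 <- permanova_test(d, labels, n_perm = 999, seed = 3)
  expect_identical(res$p, res2$p)
  perm <- sample(20)
  res3 <- permanova_test(d[perm, perm], labels[perm], n_perm = 999, seed = 3)
  expect_equal(res3$pseudo_F, res$pseudo_F, tolerance = 1e-10)

  expect_error(permanova_test(d_toy, c(rep("a", 5), "b")), "fewer than 2")
})

test_that("PERMANOVA null p-values are calibrated", {
  set.seed(32)
  hits <- 0
  reps <- 150
  for (i in seq_len(reps)) {
    pts <- matrix(rnorm(20), 10)
    d <- as.matrix(dist(pts))
    p <- permanova_test(d, rep(c("a", "b"), each = 5), n_perm = 99,
                        seed = i)$p
    hits <- hits + (p < 0.05)
  }
  # binomial 99% envelope around 0.05 at 150 replicates
  expect_gte(hits / reps, 0.01)
  expect_lte(hits / reps, 0.11)
})

test_that("taxon shifts follow the reporting conventions", {
  # pre mean 0.01, post mean 0.0348 -> +248%
  counts <- cbind(
    s1_pre = c(100, 9900), s1_post = c(348, 9652),
    s2_pre = c(100, 9900), s2_post = c(348, 9652)
  )
  tt <- make_tt(counts, lineage = c("P1;C1;O1;F1;G1;SpeciesA",
                                    "P1;C1;O1;F1;G2;SpeciesB"))
  sh <- taxon_shifts(tt, "species")
  expect_equal(sh$pct_change[sh$taxon == "SpeciesA"], 248, tolerance = 1e-10)

  # emergent taxon: absent pre, present post
  counts2 <- cbind(
    s1_pre = c(0, 1000), s1_post = c(10, 990),
    s2_pre = c(0, 1000), s2_post = c(12, 988)
  )
  tt2 <- make_tt(counts2, lineage = c("P1;C1;O1;F1;G1;New",
                                      "P1;C1;O1;F1;G2;Old"))
  sh2 <- taxon_shifts(tt2, "species")
  row <- sh2[sh2$taxon == "New", ]
  expect_true(row$emergent)
  expect_true(is.na(row$pct_change))

  # simulated halving is recovered near -49%
  spec <- microbiome_sim_spec(
    13, depth = 1e5,
    base_proportions = c(0.05, rep(0.95 / 9, 9)),
    fold_changes = c(0.51, rep(1, 9)),
    overdispersion = Inf, seed = 8)
  sh3 <- taxon_shifts(simulate_taxa_tables(spec), "genus")
  expect_equal(sh3$pct_change[sh3$taxon == "Genus1"], -49, tolerance = 0.08)

  expect_error(taxon_shifts(tt, "domain"), "rank")
})

test_that("taxa tables validate and round-trip through TSV", {
  counts <- cbind(s1_pre = c(3, 5), s1_post = c(4, 4))
  lineage <- c("P1;C1;O1;F1;G1;S1", "P1;C1;O1;F1;G2;S2")
  tt <- make_tt(counts, lineage)
  dir <- withr::local_tempdir()
  write_taxa_table(tt, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  back <- read_taxa_table(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  expect_equal(unname(back$counts), unname(tt$counts))
  expect_identical(back$lineage, tt$lineage)

  expect_error(taxa_table(counts, c("bad_lineage", lineage[2]),
                          tt$manifest), "lineage")
  expect_error(taxa_table(cbind(s1_pre = c(0, 0), s1_post = c(1, 1)),
                          lineage, tt$manifest), "reads")
  dup_man <- tt$manifest
  dup_man$condition <- c("pre", "pre")
  expect_error(taxa_table(counts, lineage, dup_man), "more than one sample")
})
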