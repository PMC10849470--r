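test_that("pairwise diversity matches direct expectations and the brute-force loop", {
  d0 <- cds_diversity(c(a = "ACGT", b = "ACGT"), c("p", "p"))
  expect_equal(d0$within$p$gene_diversity, 0)

  d1 <- cds_diversity(c(a = "AAAA", b = "AAAT"), c("p", "p"))
  expect_equal(d1$within$p$gene_diversity, 0.25)
  expect_equal(unname(d1$within$p$per_sample_mean_distance), c(0.25, 0.25))

  set.seed(14)
  seqs <- vapply(1:6, function(i) hlakir:::random_dna(120), "")
  names(seqs) <- paste0("s", 1:6)
  dv <- cds_diversity(seqs, rep("p", 6))
  expect_equal(dv$within$p$gene_diversity, diversity_bruteforce(seqs))

  # between-population divergence equals the cross-pair brute force
  lab <- rep(c("x", "y"), each = 3)
  dv2 <- cds_diversity(seqs, lab)
  cross <- outer(1:3, 4:6, Vectorize(function(i, j)
    sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]]) / 120))
  expect_equal(dv2$between["x", "y"], mean(cross))

  expect_error(cds_diversity(c(a = "ACGT"), "p"), "at least two")
  expect_error(cds_diversity(c(a = "ACGT", b = "ACG"), c("p", "p")), "aligned")
  # single-sequence population has undefined diversity
  dv3 <- cds_diversity(seqs[1:3], c("x", "x", "y"))
  expect_true(is.na(dv3$within$y$gene_diversity))
})

test_that("permutation test separates groups and never reports zero", {
  set.seed(21)
  # strongly separated groups: between-distance ~10x within
  n <- 16
  pts <- c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 10, 0.1))
  D <- as.matrix(dist(pts))
  lab <- rep(c("a", "b"), each = n / 2)
  res <- permutation_test(D, lab, n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$p_value, 0)

  expect_error(permutation_test(D, rep("a", n), n_perm = 999), "two")
  expect_error(permutation_test(D, lab, n_perm = 10), "at least 100")
})

test_that("gene-wise permutation p-values are Bonferroni adjusted", {
  set.seed(3)
  n <- 12
  lab <- rep(c("a", "b"), each = n / 2)
  Ds <- lapply(1:4, function(i) as.matrix(dist(rnorm(n))))
  names(Ds) <- paste0("g", 1:4)
  res <- divergence_permutation_tests(Ds, lab, n_perm = 200, seed = 5)
  expect_equal(res$p_adj, pmin(1, res$p_value * 4))
})

test_that("depth normalization maps the diploid cohort to two copies", {
  # sample with gene depth equal to the control median -> step-1 value 2
  ctrl <- matrix(rep(c(10, 20, 30), 4), nrow = 3)
  gd <- matrix(c(10, 20, 30), ncol = 1,
               dimnames = list(c("s1", "s2", "s3"), "g"))
  out <- normalize_depth(gd, ctrl)
  expect_equal(attr(out, "step1")[, 1], c(s1 = 2, s2 = 2, s3 = 2))
  # identical step-1 values give step-2 values of exactly 2
  expect_equal(out$normalized_cn, rep(2, 3))
  expect_equal(out$call, rep("present", 3))
})

test_that("genotypes are invariant to a global per-sample depth scaling", {
  d <- simulate_depth_cohort(n_samples = 30, seed = 17)
  base <- normalize_depth(d$gene_depths, d$control_depths)
  gd <- d$gene_depths; cd <- d$control_depths
  gd[5, ] <- gd[5, ] * 3; cd[5, ] <- cd[5, ] * 3
  scaled <- normalize_depth(gd, cd)
  expect_equal(scaled$normalized_cn, base$normalized_cn)
  expect_equal(scaled$call, base$call)
})

test_that("zero control medians exclude the sample with a warning", {
  ctrl <- matrix(c(0, 20, 30, 0, 20, 30), nrow = 3)
  gd <- matrix(c(10, 20, 30), ncol = 1,
               dimnames = list(c("s1", "s2", "s3"), "g"))
  expect_warning(out <- normalize_depth(gd, ctrl), "excluded")
  expect_equal(nrow(out), 2)
})

test_that("copy-number likelihood follows the scaled-normal model", {
  m <- structure(list(mu = 1, sigma = 0.05, transform = "sqrt",
                      calibration_fraction = 0.3, anchor_genes = character(0)),
                 class = "cn_model")
  expect_equal(copynumber_likelihood(1, 1, m), dnorm(1, 1, 0.05))
  expect_equal(copynumber_likelihood(2, 2, m), dnorm(2, 2, 0.10))
  # x = mu: the 1/c prefactor favours c = 1
  expect_equal(estimate_cn(1, m), 1L)
  # x = 2 mu at sigma = 0.05 mu: brute-force scan agrees
  scan <- vapply(1:6, function(c) copynumber_likelihood(2, c, m), 0)
  expect_equal(which.max(scan), 2L)
  expect_equal(estimate_cn(2, m), 2L)
  bad <- m; bad$sigma <- 0
  expect_error(copynumber_likelihood(1, 1, bad), "positive")
})

test_that("the fitted single-copy component recovers the simulation truth", {
  sim <- simulate_abundance(seed = 1)
  m <- fit_copynumber_model(sim$abundance)
  expect_lt(abs(m$mu - 1), 0.05)
  expect_lt(abs(m$sigma - 0.1), 0.03)
  # anchor genes pool into the calibration set
  genes <- sim$gene
  m2 <- fit_copynumber_model(sim$abundance, genes = genes,
                             anchor_genes = "HLX1")
  expect_s3_class(m2, "cn_model")
  expect_error(fit_copynumber_model(sim$abundance, anchor_genes = "HLX1"),
               "no per-allele genes")
})
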