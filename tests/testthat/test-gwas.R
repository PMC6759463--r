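test_that("identity kinship reduces the scan to ordinary least squares", {
  sim <- small_sim(n_per_pop = 30, n_loci = 100, missing = 0.05, seed = 71)
  ids <- sample_ids(sim$geno)
  set.seed(72)
  y <- stats::setNames(stats::rnorm(length(ids)), ids)
  K <- diag(1, length(ids))
  dimnames(K) <- list(ids, ids)
  scan <- mixed_model_scan(sim$geno, y, K)
  M <- gbspop:::impute_mean(sim$geno$calls)
  for (l in seq(1, 100, by = 7)) {
    x <- M[, l]
    if (stats::sd(x) == 0) next
    ols <- summary(stats::lm(y ~ x))$coefficients
    expect_equal(scan$beta[l], ols["x", "Estimate"], tolerance = 1e-8)
    expect_equal(scan$p_value[l], ols["x", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(73)
  for (i in 1:20) {
    p <- stats::runif(50)^stats::runif(1, 0.5, 2)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # q-values are monotone in p-value rank
  p <- stats::runif(100)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("a planted causal marker tops the scan", {
  top <- vapply(1:10, function(s) {
    sp <- sim_spec(
      n_pops = 3, samples_per_pop = 60, n_loci = 300,
      differentiation = 0.25, n_admixed = 0, duplicate_groups = list(),
      missing_rate = 0.02,
      trait_model = list(y = list(means = c(10, 11, 12), sd = 1,
                                  block_sd = 0.5, causal = TRUE)),
      causal_marker = list(locus = 42, effect = 1), seed = 700 + s
    )
    sim <- simulate_genotypes(sp)
    y <- genotype_means(simulate_phenotypes(sim), "y")
    scan <- mixed_model_scan(sim$geno, y, ibs_matrix(sim$geno))
    scan$locus_id[which.min(scan$p_value)]
  }, character(1))
  expect_gte(sum(top == "TP0042"), 9)
})

test_that("forward selection finds independent causal markers", {
  sp <- sim_spec(
    n_pops = 2, samples_per_pop = 90, n_loci = 300, differentiation = 0.2,
    n_admixed = 0, duplicate_groups = list(), missing_rate = 0.02,
    trait_model = list(y = list(means = c(0, 1), sd = 1, block_sd = 0.5,
                                causal = TRUE)),
    causal_marker = list(locus = 42, effect = 1.2), seed = 74
  )
  sim <- simulate_genotypes(sp)
  ph <- simulate_phenotypes(sim)
  y <- genotype_means(ph, "y")
  # add a second, independent large-effect marker by hand
  y <- y + 1.2 * ifelse(is.na(sim$geno$calls[names(y), 200]), 1,
                        sim$geno$calls[names(y), 200])
  res <- mlmm_forward(sim$geno, y, ibs_matrix(sim$geno))
  expect_true(all(c("TP0042", "TP0200") %in% res$cofactors$locus_id))

  # pure-noise trait selects nothing
  set.seed(75)
  y0 <- stats::setNames(stats::rnorm(n_samples(sim$geno)),
                        sample_ids(sim$geno))
  res0 <- mlmm_forward(sim$geno, y0, ibs_matrix(sim$geno))
  expect_equal(nrow(res0$cofactors), 0L)
  expect_error(mlmm_forward(sim$geno, y0, ibs_matrix(sim$geno),
                            max_steps = 0), "max_steps")
})

test_that("one shared marker drives all correlated seed-size traits", {
  sp <- sim_spec(
    n_pops = 2, samples_per_pop = 90, n_loci = 300, differentiation = 0.2,
    n_admixed = 0, duplicate_groups = list(), missing_rate = 0.02,
    causal_marker = list(locus = 42, effect = 1), seed = 76
  )
  sim <- simulate_genotypes(sp)
  ph <- simulate_phenotypes(sim)
  kin <- ibs_matrix(sim$geno)
  tops <- vapply(c("seed_area", "seed_perimeter", "seed_diameter"),
                 function(tr) {
    scan <- mixed_model_scan(sim$geno, genotype_means(ph, tr), kin)
    scan$locus_id[which.min(scan$p_value)]
  }, character(1))
  expect_equal(unname(tops), rep("TP0042", 3))
  # the three traits are genuinely correlated
  cors <- stats::cor(cbind(genotype_means(ph, "seed_area"),
                           genotype_means(ph, "seed_perimeter"),
                           genotype_means(ph, "seed_diameter")))
  expect_true(all(cors[upper.tri(cors)] > 0.3))
})

test_that("REML recovers the simulated variance ratio", {
  ratios <- vapply(1:20, function(s) {
    sim <- small_sim(n_pops = 2, n_per_pop = 100, n_loci = 1000, f = 0.2,
                     seed = 770 + s)
    K <- ibs_matrix(sim$geno)$values
    ids <- rownames(K)
    ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
    set.seed(880 + s)
    sg2 <- 2; se2 <- 1
    u <- ev$vectors %*% (sqrt(pmax(ev$values, 0) * sg2) *
                           stats::rnorm(length(ids)))
    y <- stats::setNames(drop(u) + stats::rnorm(length(ids), 0, sqrt(se2)),
                         ids)
    scan <- mixed_model_scan(sim$geno, y, K)
    vc <- attr(scan, "varcomp")
    vc$sigma2_g / vc$sigma2_e
  }, numeric(1))
  # the per-seed ratio is right-skewed, so summarise centrally
  expect_equal(stats::median(ratios), 2, tolerance = 0.25)
})
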