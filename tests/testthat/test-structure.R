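test_that("cluster scan is deterministic and anchored at k = 1", {
  sim <- small_sim(n_per_pop = 25, n_loci = 200, seed = 41)
  a <- find_clusters(sim$geno, k_max = 6, seed = 9)
  b <- find_clusters(sim$geno, k_max = 6, seed = 9)
  expect_identical(a$scan, b$scan)
  expect_identical(a$assignments, b$assignments)
  # k = 1: WSS equals the total sum of squares of the PC scores
  total_ss <- sum(scale(a$pc_scores, scale = FALSE)^2)
  expect_equal(a$scan$wss[1], total_ss)
  expect_true(all(diff(a$scan$wss) <= 1e-6))
  expect_warning(find_clusters(sim$geno, k_max = 100, seed = 1),
                 "k_max")
})

test_that("BIC selects the planted number of populations", {
  sim <- small_sim(n_pops = 3, n_per_pop = 25, n_loci = 400, f = 0.3,
                   missing = 0.05, seed = 42)
  sc <- find_clusters(sim$geno, k_max = 8, seed = 1)
  expect_equal(sc$k_selected, 3L)
  expect_gte(adjusted_rand_index(cluster_labels(sc), sim$truth$pop), 0.95)
})

test_that("cross-validated DAPC separates well-differentiated groups", {
  sim <- small_sim(n_pops = 5, n_per_pop = 12, n_loci = 300, f = 0.4,
                   seed = 43)
  fit <- dapc(sim$geno, sim$truth$pop, pc_grid = c(5, 10, 20), seed = 2)
  # number of axes bounded by groups - 1
  expect_equal(ncol(fit$scores), 4L)
  expect_equal(min(fit$xval$mean_error), 0)
  # centroids pairwise distances exceed within-group spread on 3 axes
  cent <- fit$centroids[, 1:3]
  spread <- max(vapply(levels(fit$groups), function(g) {
    sc <- fit$scores[fit$groups == g, 1:3, drop = FALSE]
    mean(sqrt(rowSums(sweep(sc, 2, colMeans(sc))^2)))
  }, numeric(1)))
  dmin <- min(stats::dist(cent))
  expect_gt(dmin, spread)
})

test_that("K = 1 admixture fit equals the closed-form allele frequencies", {
  sim <- small_sim(n_per_pop = 15, n_loci = 100, missing = 0.05, seed = 44)
  fit <- admixture_em(sim$geno, K = 1, n_runs = 2, seed = 3)
  expect_equal(unname(fit$q[, 1]), rep(1, n_samples(sim$geno)))
  p_hat <- colMeans(sim$geno$calls, na.rm = TRUE) / 2
  expect_equal(unname(fit$f[1, ]), unname(p_hat), tolerance = 1e-4)
  # log-likelihood equals the binomial log-likelihood at the MLE
  g <- sim$geno$calls
  ll <- sum(g * log(rep(p_hat, each = nrow(g))) +
              (2 - g) * log(rep(1 - p_hat, each = nrow(g))), na.rm = TRUE)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-2)
})

test_that("EM log-likelihood is monotone and q rows stay normalized", {
  sim <- small_sim(n_per_pop = 20, n_loci = 150, missing = 0.05, seed = 45)
  fit <- admixture_em(sim$geno, K = 3, n_runs = 3, seed = 4)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_true(all(abs(rowSums(fit$q) - 1) < 1e-6))
  expect_true(all(fit$f > 0 & fit$f < 1))
  expect_error(admixture_em(sim$geno, K = 100), "exceeds")
})

test_that("admixture recovers two clean populations", {
  sim <- small_sim(n_pops = 2, n_per_pop = 25, n_loci = 2000, f = 0.3,
                   seed = 46)
  fit <- admixture_em(sim$geno, K = 2, n_runs = 3, seed = 5)
  expect_true(all(apply(fit$q, 1, max) > 0.95))
  memb <- assign_membership(fit)
  expect_gte(adjusted_rand_index(memb$cluster, sim$truth$pop), 1)
})

test_that("k-means and admixture assignments agree on separated data", {
  sim <- small_sim(n_pops = 3, n_per_pop = 20, n_loci = 300, f = 0.35,
                   seed = 47)
  km <- cluster_labels(find_clusters(sim$geno, k_max = 6, seed = 6))
  fit <- admixture_em(sim$geno, K = 3, n_runs = 3, seed = 6)
  memb <- assign_membership(fit)
  non_adm <- memb$cluster != "admixed"
  expect_gte(adjusted_rand_index(km[non_adm], memb$cluster[non_adm]), 0.95)
})

test_that("Evanno delta-K reproduces hand-computed second differences", {
  mean_l <- c(-1000, -800, -790, -788)
  offs <- c(1, -1) / sqrt(2) # per-run offsets giving sd exactly 1
  runs <- do.call(rbind, lapply(1:2, function(r) {
    tibble::tibble(K = 1:4, run = r, log_likelihood = mean_l + offs[r])
  }))
  dk <- evanno_delta_k(runs)
  expect_equal(dk$sd_l, rep(1, 4))
  expect_equal(dk$delta_k, c(NA, 190, 8, NA))
  expect_equal(attr(dk, "k_selected"), 2L)
  expect_equal(dk$defined, c(FALSE, TRUE, TRUE, FALSE))

  # flat likelihoods: delta-K identically zero
  flat <- do.call(rbind, lapply(1:2, function(r) {
    tibble::tibble(K = 1:4, run = r, log_likelihood = -500 + offs[r])
  }))
  dkf <- evanno_delta_k(flat)
  expect_equal(dkf$delta_k[2:3], c(0, 0))

  # zero run-to-run SD: undefined, flagged
  zero <- do.call(rbind, lapply(1:2, function(r) {
    tibble::tibble(K = 1:3, run = r, log_likelihood = mean_l[1:3])
  }))
  dkz <- evanno_delta_k(zero)
  expect_true(all(is.na(dkz$delta_k)))
  expect_error(evanno_delta_k(runs[runs$K < 3, ]), "length >= 3")
})

test_that("membership rule is strict at the 0.6 boundary", {
  fit <- structure(list(
    K = 3,
    q = rbind(s1 = c(0.7, 0.2, 0.1), s2 = c(0.5, 0.3, 0.2),
              s3 = c(0.6, 0.4, 0.0)),
    runs = tibble::tibble()), class = "admixture_fit")
  colnames(fit$q) <- paste0("Q", 1:3)
  m <- assign_membership(fit)
  expect_equal(m$cluster, c("Q1", "admixed", "admixed"))
})
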