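test_that("balanced RCBD sums of squares decompose exactly", {
  set.seed(61)
  p <- tidyr::expand_grid(genotype_id = paste0("G", 1:12),
                          block_id = c("1", "2"))
  p$y <- stats::rnorm(nrow(p), 10, 2)
  a <- rcbd_anova(p, "y")
  total <- sum((p$y - mean(p$y))^2)
  expect_equal(sum(a$sumsq), total, tolerance = 1e-9)
  expect_equal(sum(a$df), nrow(p) - 1)
  ms <- a$meansq
  expect_equal(a$statistic[1], ms[1] / ms[3])
})

test_that("degenerate and missing phenotype inputs are handled", {
  p <- tidyr::expand_grid(genotype_id = paste0("G", 1:4),
                          block_id = c("1", "2"))
  p$y <- 5
  a <- rcbd_anova(p, "y")
  expect_equal(a$sumsq, rep(0, 3))
  expect_true(is.na(a$statistic[1]))

  p2 <- p
  p2$y <- stats::rnorm(8)
  p2$y[p2$genotype_id == "G1" & p2$block_id == "2"] <- NA
  expect_warning(rcbd_anova(p2, "y"), "fewer blocks")
})

test_that("heritability follows the entry-mean plug-in formula", {
  fake <- structure(
    tibble::tibble(term = c("genotype", "block", "residual"),
                   df = c(9, 1, 9), sumsq = c(90, 2, 18),
                   meansq = c(10, 2, 2), statistic = c(5, 1, NA),
                   p_value = c(0.01, 0.5, NA)),
    trait = "y", n_replicates = 2L,
    class = c("rcbd_anova", class(tibble::tibble())))
  h <- heritability(fake)
  expect_equal(h$sigma2_g, 4) # (10 - 2) / 2
  expect_equal(h$h2, 4 / (4 + 2 / 2)) # 0.8

  fake$meansq <- c(2, 2, 2)
  expect_equal(heritability(fake)$h2, 0)
  fake$meansq <- c(1, 2, 2)
  expect_warning(h3 <- heritability(fake), "clamped")
  expect_equal(h3$h2, 0)
})

test_that("null genotype effects give uniform p-values", {
  pvals <- vapply(1:200, function(s) {
    set.seed(600 + s)
    p <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:40),
                            block_id = c("1", "2"))
    p$y <- stats::rnorm(nrow(p))
    rcbd_anova(p, "y")$p_value[1]
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey comparisons produce consistent compact letters", {
  # equal means, tiny noise: one shared letter
  set.seed(62)
  p <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:20),
                          block_id = c("1", "2"))
  p$y <- stats::rnorm(nrow(p), 10, 1)
  labs <- stats::setNames(rep(c("c1", "c2"), 10), sprintf("G%02d", 1:20))
  tk <- cluster_tukey(p, labs, "y")
  expect_false(any(tk$pairs$significant))
  expect_equal(unique(tk$summary$letters), "a")

  # diameter-like separation: 3.8 vs 5.6 with SD 0.3 -> distinct letters
  p2 <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:40),
                           block_id = c("1", "2"))
  mu <- rep(c(3.8, 5.6), each = 40)
  p2$y <- stats::rnorm(nrow(p2), mu, 0.3)
  labs2 <- stats::setNames(rep(c("small", "large"), each = 20),
                           sprintf("G%02d", 1:40))
  tk2 <- cluster_tukey(p2, labs2, "y")
  expect_true(all(tk2$pairs$significant))
  expect_equal(sort(tk2$summary$letters), c("a", "b"))

  # letters consistent with the pairwise table on a 3-group case
  p3 <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:30),
                           block_id = c("1", "2"))
  mu3 <- rep(c(0, 0.4, 3), each = 20)
  set.seed(63)
  p3$y <- stats::rnorm(nrow(p3), mu3, 0.8)
  labs3 <- stats::setNames(rep(c("a", "b", "c"), each = 10),
                           sprintf("G%02d", 1:30))
  tk3 <- cluster_tukey(p3, labs3, "y")
  lt <- stats::setNames(tk3$summary$letters, tk3$summary$cluster)
  for (i in seq_len(nrow(tk3$pairs))) {
    shares <- any(strsplit(lt[tk3$pairs$cluster_a[i]], "")[[1]] %in%
                    strsplit(lt[tk3$pairs$cluster_b[i]], "")[[1]])
    expect_equal(shares, unname(!tk3$pairs$significant[i]))
  }
})

test_that("Tukey-Kramer p-values match a permutation oracle", {
  set.seed(64)
  vals <- list(a = stats::rnorm(6, 0), b = stats::rnorm(6, 1.2),
               c = stats::rnorm(6, 0.3))
  gm <- tibble::tibble(
    genotype_id = sprintf("G%02d", 1:18),
    block_id = "1",
    y = unlist(vals)
  )
  labs <- stats::setNames(rep(c("a", "b", "c"), each = 6), gm$genotype_id)
  tk <- cluster_tukey(gm, labs, "y")

  # permutation distribution of the maximum studentized-range statistic
  y <- gm$y
  grp <- rep(c("a", "b", "c"), each = 6)
  q_of <- function(y, grp) {
    m <- tapply(y, grp, mean)
    n <- tapply(y, grp, length)
    mse <- sum((y - ave(y, grp))^2) / (length(y) - 3)
    outer_q <- abs(outer(m, m, "-")) /
      sqrt(mse / 2 * outer(1 / n, 1 / n, "+"))
    outer_q
  }
  obs <- q_of(y, grp)
  set.seed(65)
  n_perm <- 4000
  exceed <- matrix(0, 3, 3)
  for (b in seq_len(n_perm)) {
    qp <- max(q_of(sample(y), grp))
    exceed <- exceed + (qp >= obs)
  }
  perm_p <- exceed / n_perm
  for (i in seq_len(nrow(tk$pairs))) {
    pa <- tk$pairs$cluster_a[i]; pb <- tk$pairs$cluster_b[i]
    expect_lt(abs(unname(tk$pairs$p_value[i]) - perm_p[pa, pb]), 0.05)
  }
})

test_that("family-wise error stays controlled under the global null", {
  ids <- sprintf("G%02d", 1:20)
  labs <- stats::setNames(rep(letters[1:5], each = 4), ids)
  rejections <- vapply(1:500, function(s) {
    set.seed(6000 + s)
    p <- tibble::tibble(genotype_id = ids, block_id = "1",
                        y = stats::rnorm(20))
    any(cluster_tukey(p, labs, "y")$pairs$significant)
  }, logical(1))
  # binomial slack around the nominal 0.05 (about 3 Sd)
  expect_lte(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})
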