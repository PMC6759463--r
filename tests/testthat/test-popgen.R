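test_that("fixed alternative alleles give theta exactly 1", {
  calls <- rbind(matrix(2L, 20, 5), matrix(0L, 20, 5))
  g <- make_geno(calls)
  labels <- rep(c("focal", "rest"), each = 20)
  rep_theta <- wc_fst_one_vs_rest(g, labels)
  expect_true(all(rep_theta$theta == 1))
  expect_true(all(rep_theta$above_0_95))
  # variance components at the limit: a = 0.5, b = c = 0
  comp <- gbspop:::wc_components(calls, factor(labels))
  expect_equal(comp$a, rep(0.5, 5))
  expect_equal(comp$b, rep(0, 5))
  expect_equal(comp$c, rep(0, 5))
  pair <- wc_fst_pairwise(g, labels)
  expect_equal(pair$values["focal", "rest"], 1)
})

test_that("copied identical groups never show positive differentiation", {
  # with identical groups the among-population variance s2 is exactly zero;
  # the finite-sample correction then makes the per-locus estimate weakly
  # negative, never positive
  sim <- small_sim(n_pops = 1, n_per_pop = 15, n_loci = 50, seed = 51)
  calls <- rbind(sim$geno$calls, sim$geno$calls)
  rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  g <- make_geno(calls)
  labels <- rep(c("g1", "g2"), each = 15)
  rep_theta <- wc_fst_one_vs_rest(g, labels)
  informative <- !is.na(rep_theta$theta)
  expect_true(all(rep_theta$theta[informative] <= 0))
  expect_false(any(rep_theta$above_0_8))
})

test_that("theta is near zero for split samples of one population", {
  sim <- small_sim(n_pops = 1, n_per_pop = 200, n_loci = 2000, f = 0.3,
                   seed = 52)
  labels <- rep(c("a", "b"), 100)
  theta <- wc_fst_pairwise(sim$geno, labels)$values[1, 2]
  expect_lt(abs(theta), 0.02)
})

test_that("nearly private alleles are flagged above 0.8", {
  hits <- vapply(1:10, function(s) {
    set.seed(520 + s)
    # focal cluster near fixation (p = 0.98) vs rest (p = 0.02), selfing
    focal <- 2L * stats::rbinom(40, 1, 0.98)
    rest <- 2L * stats::rbinom(160, 1, 0.02)
    g <- make_geno(cbind(c(focal, rest)))
    labels <- rep(c("f", "r"), c(40, 160))
    rep_theta <- wc_fst_one_vs_rest(g, labels)
    rep_theta$above_0_8[rep_theta$cluster == "f"]
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("identical-frequency groups are never flagged", {
  sim <- small_sim(n_pops = 1, n_per_pop = 60, n_loci = 300, seed = 53)
  labels <- rep(c("a", "b"), 30)
  rep_theta <- wc_fst_one_vs_rest(sim$geno, labels)
  expect_false(any(rep_theta$above_0_8))
})

test_that("Nei distance matches hand arithmetic and its limits", {
  # identical frequency vectors -> D = 0
  g <- make_geno(rbind(c(0L, 2L), c(2L, 0L), c(0L, 2L), c(2L, 0L)))
  expect_equal(nei_distance(g, c("x", "x", "y", "y"))["x", "y"], 0)

  # one locus, frequencies 0.9 vs 0.1: D = -ln(0.18 / 0.82)
  x <- c(rep(2L, 9), 0L)
  y <- c(rep(0L, 9), 2L)
  g2 <- make_geno(cbind(c(x, y)))
  d2 <- nei_distance(g2, rep(c("x", "y"), each = 10))
  expect_equal(d2["x", "y"], -log(0.18 / 0.82), tolerance = 1e-12)

  # disjoint fixed alleles -> infinite, flagged
  g3 <- make_geno(cbind(c(2L, 2L, 0L, 0L)))
  expect_warning(d3 <- nei_distance(g3, c("x", "x", "y", "y")), "infinite")
  expect_equal(d3["x", "y"], Inf)
})

test_that("neighbour joining recovers additive trees exactly", {
  # known 4-taxon additive tree: ((A:2,B:3):1,(C:4,D:5):1)
  ref <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):2);")
  d <- ape::cophenetic.phylo(ref)
  tree <- nj_tree(d)
  expect_equal(sort(tree$tip.label), c("A", "B", "C", "D"))
  # tree distances reproduce the input matrix exactly (additivity)
  back <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(back, d, tolerance = 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(ref), tree), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa|symmetric")
})

test_that("NJ agrees with the exhaustive topology oracle on 5 taxa", {
  set.seed(54)
  for (rep in 1:3) {
    ref <- ape::rtree(5, rooted = FALSE)
    ref$edge.length <- stats::runif(nrow(ref$edge), 0.5, 3)
    d <- ape::cophenetic.phylo(ref)
    tree <- nj_tree(d)
    all_topo <- phangorn::allTrees(5, rooted = FALSE)
    for (t in all_topo) t$tip.label <- paste0("t", 1:5)
    rss <- vapply(all_topo, function(t) {
      t$tip.label <- rownames(d)
      ls_fit_topology(t, d)
    }, numeric(1))
    best <- all_topo[[which.min(rss)]]
    best$tip.label <- rownames(d)
    expect_lt(min(rss), 1e-12)
    expect_equal(ape::dist.topo(best, tree), setNames(0, "PH85"),
                 ignore_attr = TRUE)
  }
})

# Nested two-level island model: two super-groups, each split into
# subpopulations, drawn with fully homozygous individuals. Exchangeable
# single-level populations are equidistant (a star tree with no internal
# signal), so resolved bipartitions need hierarchy planted explicitly.
hierarchical_geno <- function(n_loci = 800, n_per = 12, seed = 55) {
  set.seed(seed)
  p_anc <- stats::runif(n_loci, 0.2, 0.8)
  bn <- function(p, f) stats::rbeta(length(p), p * (1 - f) / f,
                                    (1 - p) * (1 - f) / f)
  super_a <- bn(p_anc, 0.3)
  super_b <- bn(p_anc, 0.3)
  subpops <- list(A1 = bn(super_a, 0.05), A2 = bn(super_a, 0.05),
                  B1 = bn(super_b, 0.05), B2 = bn(super_b, 0.05),
                  B3 = bn(super_b, 0.05))
  calls <- do.call(rbind, lapply(subpops, function(p) {
    t(replicate(n_per, 2L * stats::rbinom(n_loci, 1, p)))
  }))
  rownames(calls) <- paste0(rep(names(subpops), each = n_per), "_",
                            seq_len(n_per))
  list(geno = make_geno(calls, sample_ids = rownames(calls)),
       labels = rep(names(subpops), each = n_per))
}

test_that("bootstrap supports are percentages and saturate with hierarchy", {
  h <- hierarchical_geno()
  tree <- bootstrap_support(h$geno, h$labels, n_boot = 100, seed = 1)
  expect_true(all(tree$node.label >= 0 & tree$node.label <= 100))
  # the planted split (A1,A2) vs (B1,B2,B3) must be recovered with full
  # support: the bipartition's node has support >= 95
  internal <- tree$node.label[-1] # first node is the trivial root count
  expect_true(any(internal >= 95))
  expect_gte(mean(internal >= 95), 0.5)
  one <- bootstrap_support(h$geno, h$labels, n_boot = 1, seed = 2)
  expect_true(all(one$node.label %in% c(0L, 100L)))
})

test_that("allele-sharing Ward dendrogram mirrors IBS and planted groups", {
  g <- make_geno(rbind(c(0L, 2L, 0L), c(0L, 2L, 0L), c(2L, 0L, 2L)))
  w <- allele_sharing_ward(g)
  expect_equal(w$hclust$height[1], 0)
  expect_equal(as.matrix(w$dist), 1 - ibs_matrix(g)$values,
               ignore_attr = TRUE)
  expect_equal(w$linkage, "ward.D2")

  sim <- small_sim(n_pops = 5, n_per_pop = 12, n_loci = 400, f = 0.35,
                   seed = 56)
  w2 <- allele_sharing_ward(sim$geno)
  cut <- stats::cutree(w2$hclust, k = 5)
  expect_gte(adjusted_rand_index(cut, sim$truth$pop), 0.95)
})
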