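#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining on a square symmetric distance matrix.
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero with the (absolute) difference moved to the adjacent
#' branches through the same node, preserving path lengths through that
#' node as closely as possible. Additive input is recovered exactly.
#'
#' @param d Square symmetric numeric matrix with at least 3 taxa (row and
#'   column names are the taxon labels).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    w <- tree$edge.length[e]
    child <- tree$edge[e, 2]
    adjacent <- which(tree$edge[, 1] == child)
    tree$edge.length[e] <- 0
    if (length(adjacent)) {
      tree$edge.length[adjacent] <- tree$edge.length[adjacent] + abs(w)
    }
  }
  tree
}

#' Bootstrap support for a cluster tree
#'
#' Builds the Nei-distance neighbour-joining tree over cluster labels, then
#' resamples loci with replacement `n_boot` times (the standard phylogenetic
#' bootstrap over characters), recomputes distance and tree per replicate,
#' and annotates every internal edge of the full-data tree with the
#' percentage of replicates containing that bipartition.
#'
#' @param g A [geno_matrix()].
#' @param labels Group label per sample (at least 4 groups for non-trivial
#'   bipartitions).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree whose `node.label` holds integer bootstrap
#'   percentages in \[0, 100\].
#' @export
bootstrap_support <- function(g, labels, n_boot = 100, seed = 1L) {
  full <- nj_tree(nei_distance(g, labels))
  set.seed(seed)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_loci(g), n_loci(g), replace = TRUE)
    calls <- g$calls[, idx, drop = FALSE]
    colnames(calls) <- make.unique(colnames(calls))
    rep_g <- geno_matrix(calls, alleles = g$alleles[idx, , drop = FALSE])
    boots[[b]] <- nj_tree(nei_distance(rep_g, labels))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.integer(round(100 * counts / n_boot))
  full
}

#' Allele-sharing Ward dendrogram of individual accessions
#'
#' Individual-level hierarchical clustering: the allele-sharing distance is
#' `1 - IBS` (see [ibs_matrix()]) and agglomeration uses Ward's
#' increase-in-variance criterion on squared distances (the `ward.D2`
#' convention, recorded in the result). Identical samples merge at height
#' zero. Undefined IBS pairs are an error directing the caller to upstream
#' quality control.
#'
#' @param g A [geno_matrix()] with at least 2 samples.
#' @return List with `hclust` (the merge tree), `phylo` (the same tree as
#'   [ape::phylo]), `dist` (the allele-sharing distance matrix) and
#'   `linkage` (`"ward.D2"`).
#' @export
allele_sharing_ward <- function(g) {
  sim <- ibs_matrix(g)
  if (nrow(sim$undefined_pairs) > 0) {
    stop("undefined IBS pairs; filter loci/samples upstream", call. = FALSE)
  }
  d <- 1 - sim$values
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  list(hclust = hc, phylo = ape::as.phylo(hc), dist = d,
       linkage = "ward.D2")
}
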