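#' Identity-by-state similarity matrix
#'
#' For each pair of samples, the per-locus IBS score is the shared-allele
#' fraction `1 - |a - b| / 2` (identical genotypes 1, heterozygote versus
#' homozygote 0.5, opposite homozygotes 0), and the pair value is the mean
#' over loci where both calls are present. Pairs with zero shared non-missing
#' loci are `NA` and listed in `undefined_pairs`. Replicated genotypes of an
#' inbred line score near 1, which makes the matrix the calibration substrate
#' for redundancy detection and the kinship matrix for association analysis.
#'
#' @param g A [geno_matrix()] with at least 2 samples.
#' @return An object of class `ibs_matrix`: list with `values` (symmetric
#'   matrix in \[0, 1\], unit diagonal), `n_loci_used` (per-pair count of
#'   shared non-missing loci) and `undefined_pairs` (tibble, possibly empty).
#' @export
ibs_matrix <- function(g) {
  stopifnot(n_samples(g) >= 2)
  calls <- g$calls
  ind <- function(v) {
    m <- calls == v
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  }
  a0 <- ind(0L); a1 <- ind(1L); a2 <- ind(2L)
  called <- a0 + a1 + a2
  n_shared <- tcrossprod(called)
  absdiff <- tcrossprod(a0, a1) + tcrossprod(a1, a0) +
    tcrossprod(a1, a2) + tcrossprod(a2, a1) +
    2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0))
  values <- 1 - absdiff / (2 * n_shared)
  values[n_shared == 0] <- NA
  diag(values)[rowSums(called) > 0] <- 1
  dimnames(values) <- list(sample_ids(g), sample_ids(g))
  dimnames(n_shared) <- dimnames(values)

  und <- which(is.na(values) & upper.tri(values), arr.ind = TRUE)
  undefined_pairs <- tibble::tibble(
    sample_a = rownames(values)[und[, 1]],
    sample_b = colnames(values)[und[, 2]]
  )
  structure(list(values = values, n_loci_used = n_shared,
                 undefined_pairs = undefined_pairs),
            class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  cat(sprintf("<ibs_matrix> %d samples; off-diagonal IBS range %.3f-%.3f\n",
              nrow(x$values),
              min(x$values[upper.tri(x$values)], na.rm = TRUE),
              max(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' Pairwise IBS values as a tibble
#'
#' @param x An `ibs_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `ibs`, `n_loci`.
#' @method tidy ibs_matrix
#' @export
tidy.ibs_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(x$values)[ut[, 1]],
    sample_b = colnames(x$values)[ut[, 2]],
    ibs = x$values[ut],
    n_loci = x$n_loci_used[ut]
  )
}

#' Calibrate the redundancy threshold from biological replicates
#'
#' Takes all pairwise IBS values among the named replicate samples (e.g.
#' repeated individuals of a pure-line cultivar) and sets the redundancy
#' threshold to `mean - 3 * sd` of those values. Two genotypes at or above
#' the threshold are declared redundant. With a single replicate pair the SD
#' is zero and the threshold equals that pair's IBS (a warning is raised).
#'
#' @param sim An `ibs_matrix` from [ibs_matrix()].
#' @param replicate_ids Character vector (length >= 2) of replicate sample
#'   ids present in the matrix.
#' @return Tibble with one row: `threshold`, `mean_ibs`, `sd_ibs`, `n_pairs`.
#' @export
calibrate_threshold <- function(sim, replicate_ids) {
  stopifnot(inherits(sim, "ibs_matrix"))
  replicate_ids <- as.character(replicate_ids)
  if (length(replicate_ids) < 2) {
    stop("need at least 2 replicate samples", call. = FALSE)
  }
  missing_ids <- setdiff(replicate_ids, rownames(sim$values))
  if (length(missing_ids)) {
    stop("replicate ids not in similarity matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  sub <- sim$values[replicate_ids, replicate_ids]
  vals <- sub[upper.tri(sub)]
  if (anyNA(vals)) stop("undefined IBS among replicates", call. = FALSE)
  m <- mean(vals)
  s <- if (length(vals) > 1) stats::sd(vals) else 0
  if (length(vals) == 1) {
    warning("single replicate pair: sd = 0, threshold equals its IBS",
            call. = FALSE)
  }
  tibble::tibble(threshold = m - 3 * s, mean_ibs = m, sd_ibs = s,
                 n_pairs = length(vals))
}

#' Collapse redundant accessions
#'
#' Builds a graph with an edge for every sample pair whose IBS is at or
#' above `threshold`; redundancy groups are the connected components of size
#' at least 2 (near-identical-genotype semantics: transitive closure, not
#' cliques). Within each group the sample with the highest call rate is
#' retained (ties broken by sample-id order) and the other members are
#' removed.
#'
#' @param g A [geno_matrix()].
#' @param sim The matching `ibs_matrix`.
#' @param threshold Redundancy threshold in (0, 1\], typically from
#'   [calibrate_threshold()].
#' @return List with `geno` (pruned matrix), `groups` (tibble: `group`,
#'   `sample_id`, `call_rate`, `representative`), `threshold`.
#' @export
collapse_redundant <- function(g, sim, threshold) {
  stopifnot(inherits(sim, "ibs_matrix"), threshold > 0, threshold <= 1)
  ids <- sample_ids(g)
  stopifnot(identical(ids, rownames(sim$values)))
  v <- sim$values
  adj <- !is.na(v) & v >= threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  cr <- rowMeans(!is.na(g$calls))

  groups <- tibble::tibble(group = integer(), sample_id = character(),
                           call_rate = numeric(), representative = logical())
  remove <- character(0)
  gid <- 0L
  for (cid in seq_len(comp$no)) {
    members <- ids[comp$membership == cid]
    if (length(members) < 2) next
    gid <- gid + 1L
    ord <- order(-cr[members], members)
    members <- members[ord]
    groups <- dplyr::bind_rows(groups, tibble::tibble(
      group = gid, sample_id = members, call_rate = unname(cr[members]),
      representative = seq_along(members) == 1
    ))
    remove <- c(remove, members[-1])
  }
  keep <- !(ids %in% remove)
  list(geno = subset_geno(g, samples = keep), groups = groups,
       threshold = threshold)
}
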