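# Weir-Cockerham variance components per locus.
#
# For r groups with per-locus group sizes n_i (non-missing individuals),
# alternate-allele frequencies p_i and observed heterozygote frequencies h_i:
#   nbar = mean n_i;  n_c = (r*nbar - sum(n_i^2)/(r*nbar)) / (r - 1)
#   pbar = weighted mean of p_i;  s2 = sum n_i (p_i - pbar)^2 / ((r-1) nbar)
#   hbar = weighted mean of h_i
#   a = (nbar/n_c) [s2 - (pbar(1-pbar) - ((r-1)/r) s2 - hbar/4) / (nbar - 1)]
#   b = (nbar/(nbar-1)) [pbar(1-pbar) - ((r-1)/r) s2 - ((2nbar-1)/(4nbar)) hbar]
#   c = hbar/2
# Heterozygote frequencies enter as observed (no HWE assumption), which is
# what a selfing crop requires. Loci where any group has no calls, or with
# nbar <= 1, get NA components and are skipped by the ratio-of-sums.
wc_components <- function(calls, group) {
  group <- factor(group)
  r <- nlevels(group)
  L <- ncol(calls)
  n_i <- matrix(0, nrow = r, ncol = L)
  p_i <- matrix(0, nrow = r, ncol = L)
  h_i <- matrix(0, nrow = r, ncol = L)
  for (k in seq_len(r)) {
    sub <- calls[group == levels(group)[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(sub))
    p_i[k, ] <- colMeans(sub, na.rm = TRUE) / 2
    h_i[k, ] <- colMeans(sub == 1L, na.rm = TRUE)
  }
  ok <- colSums(n_i >= 1) == r
  nbar <- colMeans(n_i)
  ok <- ok & nbar > 1
  n_c <- (r * nbar - colSums(n_i^2) / (r * nbar)) / (r - 1)
  ok <- ok & n_c > 0
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  pq <- pbar * (1 - pbar)
  a <- (nbar / n_c) *
    (s2 - (pq - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  list(a = a, b = b, c = cc, p = p_i, n = n_i)
}

#' Pairwise multi-locus Weir-Cockerham F_ST
#'
#' Estimates the fixation index theta between every pair of labeled groups.
#' The multi-locus estimate is the ratio of summed variance components
#' `sum(a) / sum(a + b + c)` over loci with defined components — not the
#' mean of per-locus ratios. Heterozygote frequencies are used as observed
#' (no Hardy-Weinberg assumption).
#'
#' @param g A [geno_matrix()].
#' @param labels Group label per sample (at least 2 groups, each with at
#'   least 2 samples).
#' @return An object of class `fst_matrix`: list with `values` (symmetric
#'   matrix of theta, zero diagonal) and `n_loci_used` (per-pair count of
#'   loci with defined components).
#' @export
wc_fst_pairwise <- function(g, labels) {
  labels <- factor(labels)
  stopifnot(length(labels) == n_samples(g))
  if (nlevels(labels) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  lev <- levels(labels)
  m <- matrix(0, nlevels(labels), nlevels(labels),
              dimnames = list(lev, lev))
  nl <- matrix(n_loci(g), nlevels(labels), nlevels(labels),
               dimnames = list(lev, lev))
  for (i in seq_along(lev)[-1]) {
    for (j in seq_len(i - 1)) {
      sel <- labels %in% lev[c(i, j)]
      comp <- wc_components(g$calls[sel, , drop = FALSE],
                            droplevels(labels[sel]))
      use <- !is.na(comp$a)
      if (!any(use)) {
        stop("no usable loci between groups ", lev[i], " and ", lev[j],
             call. = FALSE)
      }
      theta <- sum(comp$a[use]) /
        sum(comp$a[use] + comp$b[use] + comp$c[use])
      m[i, j] <- m[j, i] <- theta
      nl[i, j] <- nl[j, i] <- sum(use)
    }
  }
  structure(list(values = m, n_loci_used = nl), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> pairwise Weir-Cockerham theta\n")
  print(round(x$values, 3))
  invisible(x)
}

#' @method tidy fst_matrix
#' @export
tidy.fst_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    group_a = rownames(x$values)[ut[, 1]],
    group_b = colnames(x$values)[ut[, 2]],
    fst = x$values[ut],
    n_loci = x$n_loci_used[ut]
  )
}

#' Per-locus one-vs-rest Weir-Cockerham F_ST
#'
#' Screens for distinctive alleles: for each cluster, every locus gets a
#' two-group theta comparing that cluster with the pooled remainder. Theta
#' reaches its upper limit of 1 exactly when the two groups fix different
#' alleles; values are reported unclamped (sampling noise can make them
#' negative), and loci exceeding 0.8 ("distinctive") and 0.95 ("nearly
#' private") are flagged together with the allele enriched in the focal
#' cluster. Monomorphic loci have undefined theta and are never flagged.
#'
#' @inheritParams wc_fst_pairwise
#' @return Tibble with `locus_id`, `cluster`, `theta`, `p_focal`, `p_rest`,
#'   `enriched_allele`, `above_0_8`, `above_0_95`.
#' @export
wc_fst_one_vs_rest <- function(g, labels) {
  labels <- factor(labels)
  stopifnot(length(labels) == n_samples(g))
  if (nlevels(labels) < 2) stop("need at least 2 groups", call. = FALSE)
  out <- vector("list", nlevels(labels))
  for (i in seq_along(levels(labels))) {
    lev <- levels(labels)[i]
    two <- factor(ifelse(labels == lev, "focal", "rest"),
                  levels = c("focal", "rest"))
    comp <- wc_components(g$calls, two)
    theta <- comp$a / (comp$a + comp$b + comp$c)
    theta[(comp$a + comp$b + comp$c) == 0] <- NA # monomorphic
    p_focal <- comp$p[1, ]
    p_rest <- comp$p[2, ]
    enriched <- ifelse(p_focal >= p_rest, g$alleles[, "alt"],
                       g$alleles[, "ref"])
    out[[i]] <- tibble::tibble(
      locus_id = locus_ids(g), cluster = lev, theta = theta,
      p_focal = p_focal, p_rest = p_rest, enriched_allele = enriched,
      above_0_8 = !is.na(theta) & theta > 0.8,
      above_0_95 = !is.na(theta) & theta > 0.95
    )
  }
  dplyr::bind_rows(out)
}

#' Nei's (1972) standard genetic distance between groups
#'
#' From group allele frequencies x and y at each biallelic locus:
#' `J_X = mean(x^2 + (1-x)^2)`, `J_Y` likewise,
#' `J_XY = mean(x y + (1-x)(1-y))`, and `D = -ln(J_XY / sqrt(J_X J_Y))`.
#' Loci lacking calls in either group are skipped pairwise. Disjoint fixed
#' alleles at every locus give infinite distance (flagged with a warning).
#'
#' @inheritParams wc_fst_pairwise
#' @return Symmetric matrix of distances (zero diagonal).
#' @export
nei_distance <- function(g, labels) {
  labels <- factor(labels)
  stopifnot(length(labels) == n_samples(g))
  if (nlevels(labels) < 2) stop("need at least 2 groups", call. = FALSE)
  lev <- levels(labels)
  freq <- matrix(NA_real_, nrow = length(lev), ncol = n_loci(g),
                 dimnames = list(lev, locus_ids(g)))
  for (k in seq_along(lev)) {
    sub <- g$calls[labels == lev[k], , drop = FALSE]
    called <- colSums(!is.na(sub)) > 0
    freq[k, called] <- colMeans(sub[, called, drop = FALSE],
                                na.rm = TRUE) / 2
  }
  d <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-1]) {
    for (j in seq_len(i - 1)) {
      x <- freq[i, ]; y <- freq[j, ]
      use <- !is.na(x) & !is.na(y)
      jx <- mean(x[use]^2 + (1 - x[use])^2)
      jy <- mean(y[use]^2 + (1 - y[use])^2)
      jxy <- mean(x[use] * y[use] + (1 - x[use]) * (1 - y[use]))
      if (jxy == 0) {
        warning("infinite Nei distance between ", lev[i], " and ", lev[j],
                call. = FALSE)
        d[i, j] <- d[j, i] <- Inf
      } else {
        d[i, j] <- d[j, i] <- -log(jxy / sqrt(jx * jy))
      }
    }
  }
  d
}
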