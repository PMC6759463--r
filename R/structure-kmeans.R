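#' k-means cluster scan with BIC model selection
#'
#' Nonparametric inference of the number of genetic clusters. Loci are
#' mean-imputed (PCA step only), centered and scaled, and projected onto the
#' smallest set of principal components explaining at least `pc_variance` of
#' the variance. k-means (multiple random restarts, best within-cluster sum
#' of squares kept) is run on the PC scores for each k in `1..k_max`, and
#' `BIC(k) = n * ln(WSS_k / n) + k * ln(n)` is minimised. Input loci should
#' be LD-pruned upstream so that clustering is not driven by autocorrelated
#' loci.
#'
#' @param g A [geno_matrix()].
#' @param k_max Largest k scanned (default 40; truncated with a warning when
#'   it is not below the sample count).
#' @param pc_variance Fraction of variance the retained PCs must explain
#'   (default 0.95).
#' @param n_starts Random restarts per k (default 10).
#' @param seed Integer seed.
#' @return An object of class `cluster_scan`: list with `scan` (tibble: `k`,
#'   `wss`, `bic`), `assignments` (matrix, samples x k values),
#'   `k_selected`, `n_pcs`, `pc_scores`, and `shallow_minimum` (TRUE when
#'   the BIC minimum improves on its neighbours by less than 1, an elbow
#'   diagnostic).
#' @export
find_clusters <- function(g, k_max = 40, pc_variance = 0.95, n_starts = 10,
                          seed = 1L) {
  n <- n_samples(g)
  if (k_max >= n) {
    warning("k_max reduced to n_samples - 1", call. = FALSE)
    k_max <- n - 1L
  }
  x <- scale_loci(impute_mean(g$calls))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pcs <- which(varfrac >= pc_variance)[1]
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]

  set.seed(seed)
  total_ss <- sum(scale(scores, scale = FALSE)^2)
  wss <- numeric(k_max)
  bic <- numeric(k_max)
  assignments <- matrix(1L, nrow = n, ncol = k_max,
                        dimnames = list(sample_ids(g), paste0("k", 1:k_max)))
  for (k in seq_len(k_max)) {
    if (k == 1) {
      wss[k] <- total_ss
    } else {
      km <- stats::kmeans(scores, centers = k, nstart = n_starts,
                          iter.max = 100)
      wss[k] <- km$tot.withinss
      assignments[, k] <- km$cluster
    }
    bic[k] <- n * log(wss[k] / n) + k * log(n)
  }
  k_sel <- which.min(bic)
  neigh <- c(if (k_sel > 1) bic[k_sel - 1], if (k_sel < k_max) bic[k_sel + 1])
  structure(list(
    scan = tibble::tibble(k = seq_len(k_max), wss = wss, bic = bic),
    assignments = assignments, k_selected = k_sel, n_pcs = n_pcs,
    pc_scores = scores,
    shallow_minimum = length(neigh) > 0 && min(neigh) - bic[k_sel] < 1
  ), class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("<cluster_scan> k = 1..%d on %d PCs; BIC-selected k = %d%s\n",
              nrow(x$scan), x$n_pcs, x$k_selected,
              if (x$shallow_minimum) " (shallow minimum)" else ""))
  invisible(x)
}

#' Cluster labels at the selected (or any) k
#'
#' @param scan A `cluster_scan`.
#' @param k Number of clusters (defaults to the BIC-selected k).
#' @return Named integer vector of cluster labels in `1..k`.
#' @export
cluster_labels <- function(scan, k = scan$k_selected) {
  stats::setNames(scan$assignments[, k], rownames(scan$assignments))
}

#' @method tidy cluster_scan
#' @export
tidy.cluster_scan <- function(x, ...) x$scan

#' @method glance cluster_scan
#' @export
glance.cluster_scan <- function(x, ...) {
  tibble::tibble(k_selected = x$k_selected, n_pcs = x$n_pcs,
                 bic_min = min(x$scan$bic),
                 shallow_minimum = x$shallow_minimum)
}

#' BIC curve of a cluster scan
#'
#' @param object A `cluster_scan`.
#' @param ... Unused.
#' @return A ggplot: BIC against k with the selected k marked.
#' @method autoplot cluster_scan
#' @export
autoplot.cluster_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = 2) +
    ggplot2::labs(x = "number of clusters (k)", y = "BIC") +
    ggplot2::theme_minimal()
}
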