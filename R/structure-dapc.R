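#' Discriminant analysis of principal components
#'
#' Fits linear discriminant axes on PCA-reduced genotypes to maximise
#' between-group over within-group variation, with the number of retained
#' principal components chosen by stratified cross-validation: for each
#' candidate PC count, linear discriminant functions are trained on the
#' training folds and the held-out assignment error is recorded; the PC
#' count with the lowest mean held-out error wins (ties to fewer PCs), and
#' the final model is refitted on all samples.
#'
#' @param g A [geno_matrix()].
#' @param groups Factor-like vector of group labels, one per sample (e.g.
#'   [cluster_labels()] output).
#' @param xval_folds Number of cross-validation folds (default 5; reduced
#'   with a warning when a group has fewer members than folds).
#' @param pc_grid Integer vector of candidate PC counts; defaults to an
#'   8-point grid from 2 to the largest usable count.
#' @param seed Integer seed for fold assignment.
#' @return An object of class `dapc_model`: list with `n_pcs`, `xval`
#'   (tibble: `n_pcs`, `mean_error`), `scores` (samples x axes), `centroids`
#'   (groups x axes), `loadings_pcs`, `loadings_loci`, `groups`, `lda`
#'   (the underlying fit).
#' @export
dapc <- function(g, groups, xval_folds = 5, pc_grid = NULL, seed = 1L) {
  groups <- factor(groups)
  stopifnot(length(groups) == n_samples(g), nlevels(groups) >= 2)
  n <- n_samples(g)
  x <- scale_loci(impute_mean(g$calls))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  positive <- sum(pc$sdev > 1e-8)
  # keep training-fold fits well-posed: fewer PCs than training samples
  # minus groups
  max_pc <- min(positive,
                floor(n * (1 - 1 / xval_folds)) - nlevels(groups) - 1)
  if (is.null(pc_grid)) {
    pc_grid <- unique(pmax(2, round(seq(2, max_pc, length.out = 8))))
  }
  pc_grid <- sort(unique(pmin(pc_grid, max_pc)))

  min_group <- min(table(groups))
  if (min_group < xval_folds) {
    warning("folds reduced to smallest group size (", min_group, ")",
            call. = FALSE)
    xval_folds <- max(2, min_group)
  }

  set.seed(seed)
  fold <- integer(n)
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    fold[idx] <- sample(rep_len(seq_len(xval_folds), length(idx)))
  }

  err <- vapply(pc_grid, function(npc) {
    scores <- pc$x[, seq_len(npc), drop = FALSE]
    fold_err <- vapply(seq_len(xval_folds), function(f) {
      tr <- fold != f
      fit <- suppressWarnings(
        MASS::lda(scores[tr, , drop = FALSE], grouping = groups[tr]))
      pred <- stats::predict(fit, scores[!tr, , drop = FALSE])$class
      mean(pred != groups[!tr])
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  n_pcs <- pc_grid[which.min(err)]

  scores_pc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- suppressWarnings(MASS::lda(scores_pc, grouping = groups))
  disc <- stats::predict(fit, scores_pc)$x
  centroids <- apply(disc, 2, function(col) tapply(col, groups, mean))
  centroids <- matrix(centroids, nrow = nlevels(groups),
                      dimnames = list(levels(groups), colnames(disc)))
  loadings_loci <- pc$rotation[, seq_len(n_pcs), drop = FALSE] %*% fit$scaling

  structure(list(
    n_pcs = n_pcs,
    xval = tibble::tibble(n_pcs = pc_grid, mean_error = err),
    scores = disc, centroids = centroids,
    loadings_pcs = fit$scaling, loadings_loci = loadings_loci,
    groups = groups, lda = fit
  ), class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf(
    "<dapc_model> %d groups, %d PCs retained (xval), %d discriminant axes\n",
    nlevels(x$groups), x$n_pcs, ncol(x$scores)))
  invisible(x)
}

#' Per-sample discriminant scores
#'
#' @param x A `dapc_model`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `group` and one column per discriminant
#'   axis (`LD1`, `LD2`, ...).
#' @method tidy dapc_model
#' @export
tidy.dapc_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(x$scores),
                   group = as.character(x$groups)),
    tibble::as_tibble(x$scores)
  )
}

#' @method glance dapc_model
#' @export
glance.dapc_model <- function(x, ...) {
  tibble::tibble(n_groups = nlevels(x$groups), n_pcs = x$n_pcs,
                 n_axes = ncol(x$scores),
                 xval_error = min(x$xval$mean_error))
}

#' Scatter of the first two discriminant axes
#'
#' @param object A `dapc_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dapc_model
#' @export
autoplot.dapc_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$LD1,
                                  y = if (ncol(object$scores) > 1)
                                    .data$LD2 else 0,
                                  colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "LD1", y = "LD2", colour = "cluster") +
    ggplot2::theme_minimal()
}
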