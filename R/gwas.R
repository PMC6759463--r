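#' Genotype means over blocks
#'
#' Collapses plot-level phenotypes to one value per genotype (the analysis
#' unit for association mapping of bulked or replicated traits).
#'
#' @param p Phenotype tibble (`genotype_id`, `block_id`, traits).
#' @param trait Trait column name.
#' @return Named numeric vector of genotype means.
#' @export
genotype_means <- function(p, trait) {
  stopifnot(trait %in% names(p))
  out <- tapply(p[[trait]], p$genotype_id, mean, na.rm = TRUE)
  stats::setNames(as.numeric(out), names(out))
}

# REML estimation of the variance ratio lambda = sigma2_g / sigma2_e for
# y = X b + u + e with u ~ N(0, sigma2_g K), via the spectral decomposition
# of K (one-dimensional search over log lambda).
reml_lambda <- function(y_star, x_star, d) {
  n <- length(y_star)
  p <- ncol(x_star)
  neg_reml <- function(log_lambda) {
    lambda <- exp(log_lambda)
    w <- lambda * d + 1
    sw <- 1 / sqrt(w)
    zx <- x_star * sw
    zy <- y_star * sw
    fit <- stats::lm.fit(zx, zy)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    xtx <- crossprod(zx)
    0.5 * ((n - p) * log(sigma2) + sum(log(w)) +
             determinant(xtx, logarithm = TRUE)$modulus[1] + (n - p))
  }
  grid <- seq(-10, 10, length.out = 21)
  vals <- vapply(grid, neg_reml, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(neg_reml, c(lo, hi))
  lambda <- exp(opt$minimum)
  w <- lambda * d + 1
  sw <- 1 / sqrt(w)
  fit <- stats::lm.fit(x_star * sw, y_star * sw)
  sigma2_e <- sum(fit$residuals^2) / (n - p)
  list(lambda = lambda, sigma2_e = sigma2_e,
       sigma2_g = lambda * sigma2_e)
}

#' Single-marker kinship mixed-model scan
#'
#' Tests every marker for association with a trait under the mixed model
#' `y = mu + cofactors + marker + u + e`, `u ~ N(0, sigma2_g K)` with K the
#' IBS kinship matrix. Variance components are estimated once per cofactor
#' set by REML through the spectral decomposition of K (a one-dimensional
#' search over the variance ratio), then each marker is tested by
#' generalised least squares with the fitted covariance (Wald test).
#' Markers collinear with the cofactors are skipped (`NA`, with a message).
#' With `K = I` the procedure reduces exactly to ordinary least squares.
#'
#' @param g A [geno_matrix()] (markers mean-imputed for testing).
#' @param y Named numeric vector of trait values (one per genotype; see
#'   [genotype_means()]). Names must match sample ids; the intersection is
#'   analysed.
#' @param kinship An [ibs_matrix()] or plain symmetric matrix over (at
#'   least) the analysed samples. Non-positive-semidefinite input is
#'   jittered (with a message).
#' @param cofactors Character vector of locus ids fitted as fixed cofactors.
#' @return Tibble with `locus_id`, `beta`, `se`, `statistic`, `p_value`;
#'   attributes `varcomp` (tibble: `sigma2_g`, `sigma2_e`, `lambda`) and
#'   `n` (samples used).
#' @export
mixed_model_scan <- function(g, y, kinship, cofactors = character(0)) {
  K <- if (inherits(kinship, "ibs_matrix")) kinship$values else as.matrix(kinship)
  ids <- intersect(sample_ids(g), names(y))
  ids <- intersect(ids, rownames(K))
  if (length(ids) < 10) stop("fewer than 10 aligned samples", call. = FALSE)
  y <- y[ids]
  keep <- !is.na(y)
  ids <- ids[keep]; y <- y[keep]
  M <- impute_mean(g$calls[ids, , drop = FALSE])
  K <- K[ids, ids]
  K <- (K + t(K)) / 2

  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    message("kinship not positive semidefinite; adding jitter")
    K <- K + diag(2 * abs(min(eig$values)), nrow(K))
    eig <- eigen(K, symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors

  stopifnot(all(cofactors %in% colnames(M)))
  X0 <- cbind(intercept = 1, M[, cofactors, drop = FALSE])
  y_star <- drop(crossprod(U, y))
  X0_star <- crossprod(U, X0)
  vc <- reml_lambda(y_star, X0_star, d)

  sw <- 1 / sqrt(vc$lambda * d + 1)
  Z0 <- X0_star * sw
  zy <- y_star * sw
  ZM <- crossprod(U, M) * sw

  q0 <- qr(Z0)
  ry <- qr.resid(q0, zy)
  RM <- qr.resid(q0, ZM)
  ssm <- colSums(RM^2)
  sym <- colSums(RM * ry)
  df <- length(ids) - ncol(X0) - 1

  beta <- sym / ssm
  rss <- sum(ry^2) - sym^2 / ssm
  se <- sqrt(rss / df / ssm)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)

  degenerate <- ssm < 1e-10 * length(ids)
  if (any(degenerate)) {
    message(sum(degenerate), " marker(s) collinear with cofactors skipped")
    beta[degenerate] <- NA; se[degenerate] <- NA
    tt[degenerate] <- NA; p[degenerate] <- NA
  }
  out <- tibble::tibble(locus_id = colnames(M), beta = unname(beta),
                        se = unname(se), statistic = unname(tt),
                        p_value = unname(p))
  attr(out, "varcomp") <- tibble::tibble(sigma2_g = vc$sigma2_g,
                                         sigma2_e = vc$sigma2_e,
                                         lambda = vc$lambda)
  attr(out, "n") <- length(ids)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotonised q-values).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Multi-locus mixed-model association scan
#'
#' Forward-selection association mapping: scan all markers with
#' [mixed_model_scan()], adjust p-values by Benjamini-Hochberg, and if the
#' best marker's q-value is below `fdr`, add it as a fixed cofactor,
#' re-estimate variance components, and rescan. Stops when no marker passes
#' or after `max_steps` cofactors. The result carries the final scan (with
#' q-values) and the cofactor path.
#'
#' @inheritParams mixed_model_scan
#' @param max_steps Maximum number of cofactors to include (default 10).
#' @param fdr FDR threshold for declaring a marker significant (default
#'   0.05).
#' @return An object of class `gwas_result`: list with `scan` (final
#'   per-marker tibble incl. `q_value`), `cofactors` (tibble: `step`,
#'   `locus_id`, `p_value`, `q_value` at selection), `varcomp` (per-step
#'   variance components), `n`.
#' @export
mlmm_forward <- function(g, y, kinship, max_steps = 10, fdr = 0.05) {
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  cof <- character(0)
  path <- tibble::tibble(step = integer(), locus_id = character(),
                         p_value = numeric(), q_value = numeric())
  vcs <- list()
  step <- 0L
  repeat {
    scan <- mixed_model_scan(g, y, kinship, cofactors = cof)
    scan$q_value <- bh_fdr(scan$p_value)
    vcs[[length(vcs) + 1]] <- dplyr::mutate(attr(scan, "varcomp"),
                                            step = step, .before = 1)
    candidates <- scan[!is.na(scan$q_value) & !(scan$locus_id %in% cof), ]
    if (!nrow(candidates)) break
    best <- candidates[which.min(candidates$p_value), ]
    if (best$q_value >= fdr || step >= max_steps) break
    step <- step + 1L
    cof <- c(cof, best$locus_id)
    path <- dplyr::bind_rows(path, tibble::tibble(
      step = step, locus_id = best$locus_id,
      p_value = best$p_value, q_value = best$q_value))
  }
  structure(list(scan = scan, cofactors = path,
                 varcomp = dplyr::bind_rows(vcs), n = attr(scan, "n")),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("<gwas_result> %d markers, n = %d; %d cofactor(s) selected\n",
              nrow(x$scan), x$n, nrow(x$cofactors)))
  if (nrow(x$cofactors)) print(x$cofactors)
  invisible(x)
}

#' @method tidy gwas_result
#' @export
tidy.gwas_result <- function(x, ...) x$scan

#' @method glance gwas_result
#' @export
glance.gwas_result <- function(x, ...) {
  tibble::tibble(n_markers = nrow(x$scan), n = x$n,
                 n_cofactors = nrow(x$cofactors),
                 min_q = min(x$scan$q_value, na.rm = TRUE))
}

#' Association plot over marker index
#'
#' @param object A `gwas_result`.
#' @param fdr Reference FDR level drawn as a horizontal line on the q-value
#'   scale (default 0.05).
#' @param ... Unused.
#' @return A ggplot of -log10(p) by marker index, selected cofactors
#'   highlighted.
#' @method autoplot gwas_result
#' @export
autoplot.gwas_result <- function(object, fdr = 0.05, ...) {
  d <- object$scan
  d$index <- seq_len(nrow(d))
  d$cofactor <- d$locus_id %in% object$cofactors$locus_id
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index,
                                  y = -log10(.data$p_value),
                                  colour = .data$cofactor)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "red")) +
    ggplot2::labs(x = "marker index", y = "-log10 p") +
    ggplot2::theme_minimal()
}
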