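#' Fit the admixture model by expectation-maximisation
#'
#' Maximum-likelihood analogue of the classical Bayesian admixture model of
#' population structure: each individual i has ancestry proportions q_i
#' (summing to 1 over K clusters) and each cluster k has per-locus
#' alternate-allele frequencies f_kl, and the two alleles of genotype g_il
#' are independent draws with alternate-allele probability
#' `sum_k q_ik f_kl`. The log-likelihood
#' `sum_il [ g_il log(sum_k q_ik f_kl) + (2 - g_il) log(sum_k q_ik (1 - f_kl)) ]`
#' (missing calls skipped exactly) is maximised by multiplicative EM updates,
#' which are monotone non-decreasing; f is clamped to `[1e-6, 1 - 1e-6]`.
#' Loci should be LD-pruned upstream to meet the model's independence
#' assumption. The best of `n_runs` random restarts is returned, with the
#' per-run log-likelihoods retained for Evanno-style model selection.
#'
#' @param g A [geno_matrix()].
#' @param K Number of ancestral clusters (at least 1, at most the sample
#'   count).
#' @param n_runs Independent random restarts (default 10).
#' @param max_iter Maximum EM iterations per run (default 2000).
#' @param tol Convergence threshold on the log-likelihood improvement
#'   (default 1e-4).
#' @param seed Integer seed; restart r uses a seed derived from it.
#' @return An object of class `admixture_fit`: list with `K`, `q` (samples x
#'   K, rows sum to 1), `f` (K x loci), `log_likelihood`, `trace`
#'   (per-iteration log-likelihood of the best run), `run` (index of the
#'   best run), `runs` (tibble: `run`, `log_likelihood`, `iterations`,
#'   `converged`).
#' @export
admixture_em <- function(g, K, n_runs = 10, max_iter = 2000, tol = 1e-4,
                         seed = 1L) {
  n <- n_samples(g)
  L <- n_loci(g)
  if (K > n) stop("K exceeds the number of samples", call. = FALSE)
  stopifnot(K >= 1, n_runs >= 1)
  G <- g$calls
  miss <- is.na(G)
  G0 <- G; G0[miss] <- 0L
  G2 <- 2L - G; G2[miss] <- 0L
  storage.mode(G0) <- "double"; storage.mode(G2) <- "double"
  n_alleles <- rowSums(!miss) * 2
  eps <- 1e-6

  loglik_qf <- function(Q, F_) {
    A <- Q %*% F_
    B <- Q %*% (1 - F_)
    sum(G0 * log(A)) + sum(G2 * log(B))
  }

  seeds <- derive_seeds(seed, n_runs)
  best <- NULL
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    Q <- matrix(stats::rgamma(n * K, 1), nrow = n)
    Q <- Q / rowSums(Q)
    base_f <- allele_freq(G)
    F_ <- matrix(pmin(pmax(rep(base_f, each = K) +
                             stats::rnorm(K * L, 0, 0.1), eps), 1 - eps),
                 nrow = K)

    em_step <- function(Q, F_) {
      A <- Q %*% F_
      B <- Q %*% (1 - F_)
      RA <- G0 / A    # n x L
      RB <- G2 / B
      # expected allele counts attributed to each cluster
      Q_new <- Q * (RA %*% t(F_) + RB %*% t(1 - F_)) / n_alleles
      Q_new <- Q_new / rowSums(Q_new)
      num <- F_ * (t(Q) %*% RA)
      den <- num + (1 - F_) * (t(Q) %*% RB)
      F_new <- num / den
      F_new[den == 0] <- base_f[rep(seq_len(L), each = K)][den == 0]
      list(Q = Q_new, F_ = pmin(pmax(F_new, eps), 1 - eps))
    }
    project <- function(th) {
      th$Q <- pmax(th$Q, 1e-9)
      th$Q <- th$Q / rowSums(th$Q)
      th$F_ <- pmin(pmax(th$F_, eps), 1 - eps)
      th
    }

    # squared-extrapolation (SQUAREM-style) acceleration of the EM map,
    # safeguarded so the recorded log-likelihood stays monotone: the
    # extrapolated point is only accepted when it beats the plain double
    # EM step.
    ll_old <- loglik_qf(Q, F_)
    trace <- ll_old
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      th0 <- list(Q = Q, F_ = F_)
      th1 <- em_step(th0$Q, th0$F_)
      th2 <- em_step(th1$Q, th1$F_)
      it <- it + 2L
      rq <- th1$Q - th0$Q; rf <- th1$F_ - th0$F_
      vq <- th2$Q - th1$Q - rq; vf <- th2$F_ - th1$F_ - rf
      vnorm <- sqrt(sum(vq^2) + sum(vf^2))
      ll2 <- loglik_qf(th2$Q, th2$F_)
      accepted <- th2
      ll <- ll2
      if (vnorm > 0) {
        alpha <- -sqrt(sum(rq^2) + sum(rf^2)) / vnorm
        ext <- project(list(Q = th0$Q - 2 * alpha * rq + alpha^2 * vq,
                            F_ = th0$F_ - 2 * alpha * rf + alpha^2 * vf))
        ll_ext <- loglik_qf(ext$Q, ext$F_)
        if (is.finite(ll_ext) && ll_ext > ll2) {
          accepted <- ext
          ll <- ll_ext
        }
      }
      Q <- accepted$Q; F_ <- accepted$F_
      trace <- c(trace, ll)
      if (ll - ll_old < tol && it > 2) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    ll <- trace[length(trace)]
    runs[[r]] <- tibble::tibble(run = r, log_likelihood = ll,
                                iterations = it, converged = converged)
    if (is.null(best) || ll > best$log_likelihood) {
      rownames(Q) <- sample_ids(g)
      colnames(Q) <- paste0("Q", seq_len(K))
      colnames(F_) <- locus_ids(g)
      best <- list(K = K, q = Q, f = F_, log_likelihood = ll, trace = trace,
                   run = r)
    }
  }
  best$runs <- dplyr::bind_rows(runs)
  structure(best, class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d samples; logL = %.2f (best of %d runs)\n",
              x$K, nrow(x$q), x$log_likelihood, nrow(x$runs)))
  invisible(x)
}

#' Ancestry proportions as a long tibble
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `cluster`, `q`.
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::as_tibble(x$q, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cluster", values_to = "q")
}

#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, log_likelihood = x$log_likelihood,
                 iterations = length(x$trace) - 1,
                 n_runs = nrow(x$runs), best_run = x$run)
}

#' Ancestry bar plot
#'
#' The classical stacked-bar ancestry display: one bar per individual,
#' partitioned by estimated ancestry fractions.
#'
#' @param object An `admixture_fit`.
#' @param order_by Optional vector of labels used to sort the bars (e.g.
#'   assigned clusters).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, order_by = NULL, ...) {
  d <- tidy(object)
  lev <- rownames(object$q)
  if (!is.null(order_by)) lev <- lev[order(order_by)]
  d$sample_id <- factor(d$sample_id, levels = lev)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$q,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Scan K values with repeated admixture fits
#'
#' Runs [admixture_em()] for each K in `k_range`, keeping every restart's
#' log-likelihood for [evanno_delta_k()].
#'
#' @inheritParams admixture_em
#' @param k_range Integer vector of K values (contiguous for the Evanno
#'   statistic).
#' @return List with `fits` (named list of `admixture_fit`, best run per K)
#'   and `runs` (tibble: `K`, `run`, `log_likelihood`).
#' @export
admixture_scan <- function(g, k_range = 1:10, n_runs = 10, max_iter = 2000,
                           tol = 1e-4, seed = 1L) {
  seeds <- derive_seeds(seed, length(k_range), stream = 7L)
  fits <- list()
  runs <- list()
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fit <- admixture_em(g, K, n_runs = n_runs, max_iter = max_iter,
                        tol = tol, seed = seeds[i])
    fits[[as.character(K)]] <- fit
    runs[[i]] <- dplyr::mutate(fit$runs, K = K, .before = 1)
  }
  list(fits = fits, runs = dplyr::bind_rows(runs))
}

#' Evanno delta-K statistic
#'
#' Selects the number of clusters from repeated model fits across a
#' contiguous K range: per run, `L'(K) = L(K) - L(K-1)` and
#' `|L''(K)| = |L'(K+1) - L'(K)|`; then
#' `deltaK(K) = mean over runs |L''(K)| / sd over runs of L(K)`. The
#' statistic is defined only for interior K; boundary rows and rows where
#' the run SD is zero are `NA` and flagged.
#'
#' @param runs Tibble with columns `K`, `run`, `log_likelihood`, with the
#'   same number of runs for every K (as produced by [admixture_scan()]).
#' @return An object of class `delta_k`: tibble with `K`, `mean_l`, `sd_l`,
#'   `delta_k`, `defined`, plus attribute `k_selected` (the interior K
#'   maximising deltaK).
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "run", "log_likelihood") %in% names(runs)))
  kv <- sort(unique(runs$K))
  if (length(kv) < 3 || !all(diff(kv) == 1)) {
    stop("need a contiguous K range of length >= 3", call. = FALSE)
  }
  counts <- table(runs$K)
  if (length(unique(counts)) != 1 || counts[1] < 2) {
    stop("need the same number (>= 2) of runs for every K", call. = FALSE)
  }
  L <- matrix(NA_real_, nrow = counts[1], ncol = length(kv),
              dimnames = list(NULL, kv))
  for (i in seq_along(kv)) {
    sub <- runs[runs$K == kv[i], ]
    L[sub$run, i] <- sub$log_likelihood
  }
  mean_l <- colMeans(L)
  sd_l <- apply(L, 2, stats::sd)
  delta <- rep(NA_real_, length(kv))
  for (i in seq_along(kv)[-c(1, length(kv))]) {
    lpp <- abs(L[, i + 1] - 2 * L[, i] + L[, i - 1])
    delta[i] <- if (sd_l[i] > 0) mean(lpp) / sd_l[i] else NA_real_
  }
  out <- tibble::tibble(K = kv, mean_l = unname(mean_l),
                        sd_l = unname(sd_l),
                        delta_k = delta, defined = !is.na(delta))
  k_sel <- if (any(out$defined)) out$K[which.max(out$delta_k)] else NA_integer_
  structure(out, k_selected = k_sel, class = c("delta_k", class(out)))
}

#' Assign samples to clusters by membership coefficient
#'
#' A sample is assigned to the cluster with its largest ancestry proportion
#' when that proportion strictly exceeds `q_min`; otherwise it is classified
#' as `"admixed"`.
#'
#' @param fit An `admixture_fit`.
#' @param q_min Membership threshold (default 0.6).
#' @return Tibble with `sample_id`, `cluster` (e.g. `"Q2"` or `"admixed"`),
#'   `q_max`.
#' @export
assign_membership <- function(fit, q_min = 0.6) {
  stopifnot(inherits(fit, "admixture_fit"))
  qmax <- apply(fit$q, 1, max)
  best <- colnames(fit$q)[max.col(fit$q, ties.method = "first")]
  tibble::tibble(
    sample_id = rownames(fit$q),
    cluster = unname(ifelse(qmax > q_min, best, "admixed")),
    q_max = unname(qmax)
  )
}
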