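#' Per-locus quality-control statistics
#'
#' Computes, over non-missing calls only: minor allele frequency
#' (`maf = min(p, 1 - p)` with `p` the mean call divided by 2), call rate,
#' the per-locus inbreeding coefficient `F = 1 - H_obs / H_exp` with
#' `H_exp = 2 p (1 - p)` (undefined for monomorphic loci; can be negative
#' under heterozygote excess), and whether the allele pair is a transition
#' (`{A,G}` or `{C,T}`) or a transversion.
#'
#' @param g A [geno_matrix()].
#' @return Tibble with columns `locus_id`, `maf`, `call_rate`,
#'   `inbreeding_f`, `is_transition`.
#' @export
locus_stats <- function(g) {
  calls <- g$calls
  n_called <- colSums(!is.na(calls))
  p <- allele_freq(calls)
  p[n_called == 0] <- NA
  h_obs <- colMeans(calls == 1L, na.rm = TRUE)
  h_obs[n_called == 0] <- NA
  h_exp <- 2 * p * (1 - p)
  f <- ifelse(!is.na(h_exp) & h_exp > 0, 1 - h_obs / h_exp, NA)
  pair <- paste0(pmin(g$alleles[, 1], g$alleles[, 2]),
                 pmax(g$alleles[, 1], g$alleles[, 2]))
  tibble::tibble(
    locus_id = locus_ids(g),
    maf = unname(pmin(p, 1 - p)),
    call_rate = unname(n_called / n_samples(g)),
    inbreeding_f = unname(f),
    is_transition = unname(pair %in% c("AG", "CT"))
  )
}

#' Filter loci on MAF, call rate and inbreeding coefficient
#'
#' The successive SNP quality-control cascade for a selfing species: keep
#' loci with minor allele frequency strictly above `min_maf`, call rate
#' strictly above `min_call_rate`, and per-locus inbreeding coefficient
#' strictly above `min_inbreeding` (all strict inequalities). Filters are
#' applied in the order given by `order`, and the report records the
#' attrition per step. A locus with an undefined statistic fails the
#' corresponding filter.
#'
#' @param g A [geno_matrix()].
#' @param min_maf,min_call_rate,min_inbreeding Thresholds (defaults 0.05,
#'   0.80, 0.8).
#' @param order Character vector giving the filter application order, a
#'   permutation of `c("maf", "call_rate", "inbreeding")`.
#' @return List with `geno` (the filtered [geno_matrix()]) and `report`, a
#'   tibble with one row per step (`step`, `threshold`, `loci_in`,
#'   `loci_dropped`, `loci_out`).
#' @export
filter_loci <- function(g, min_maf = 0.05, min_call_rate = 0.80,
                        min_inbreeding = 0.8,
                        order = c("maf", "call_rate", "inbreeding")) {
  stopifnot(setequal(order, c("maf", "call_rate", "inbreeding")))
  thr <- c(maf = min_maf, call_rate = min_call_rate,
           inbreeding = min_inbreeding)
  report <- tibble::tibble(step = character(), threshold = numeric(),
                           loci_in = integer(), loci_dropped = integer(),
                           loci_out = integer())
  for (step in order) {
    st <- locus_stats(g)
    value <- switch(step, maf = st$maf, call_rate = st$call_rate,
                    inbreeding = st$inbreeding_f)
    keep <- !is.na(value) & value > thr[[step]]
    report <- dplyr::bind_rows(report, tibble::tibble(
      step = step, threshold = thr[[step]], loci_in = n_loci(g),
      loci_dropped = sum(!keep), loci_out = sum(keep)
    ))
    if (!any(keep)) {
      stop("all loci removed by the '", step, "' filter", call. = FALSE)
    }
    g <- subset_geno(g, loci = keep)
  }
  list(geno = g, report = report)
}

#' Exclude samples with low call rate
#'
#' Removes accessions whose call rate is below `min_call_rate` (i.e. more
#' than `1 - min_call_rate` missing data).
#'
#' @param g A [geno_matrix()].
#' @param min_call_rate Minimum sample call rate (default 0.80).
#' @return List with `geno` (samples retained) and `dropped` (character
#'   vector of removed sample ids).
#' @export
filter_samples <- function(g, min_call_rate = 0.80) {
  cr <- rowMeans(!is.na(g$calls))
  drop <- cr < min_call_rate
  if (all(drop)) stop("all samples removed by call-rate filter",
                      call. = FALSE)
  list(geno = subset_geno(g, samples = !drop),
       dropped = sample_ids(g)[drop])
}

#' Transition/transversion summary
#'
#' Counts loci whose allele pair is a transition (`{A,G}`, `{C,T}`) versus a
#' transversion and reports the Ts/Tv ratio. With zero transversions the
#' ratio is `NA` and flagged undefined.
#'
#' @param g A [geno_matrix()].
#' @return Tibble with one row: `transitions`, `transversions`, `ts_tv_ratio`
#'   (rounded to 2 decimals), `defined`.
#' @export
ts_tv <- function(g) {
  st <- locus_stats(g)
  ts <- sum(st$is_transition)
  tv <- sum(!st$is_transition)
  tibble::tibble(
    transitions = ts,
    transversions = tv,
    ts_tv_ratio = if (tv > 0) round(ts / tv, 2) else NA_real_,
    defined = tv > 0
  )
}

#' Greedy linkage-disequilibrium pruning
#'
#' Thins loci so that no kept pair is in strong LD. The r-squared between two
#' loci is the squared Pearson correlation of their 0/1/2 call vectors over
#' pairwise-complete samples (composite genotypic LD; no imputation). The
#' scan is greedy in locus (file) order: each locus is dropped if its
#' r-squared with any previously kept locus is `>= r2_max`, so ties keep the
#' earlier locus. Loci without variance over complete pairs correlate with
#' nothing (r-squared treated as 0). There is no genomic window: loci from
#' reference-free GBS pipelines carry no coordinates.
#'
#' @param g A [geno_matrix()] with at least 2 loci.
#' @param r2_max Exclusion threshold (a locus is removed at r-squared at or
#'   above this value); default 0.5.
#' @return List with `geno` (kept loci), `dropped` (locus ids),
#'   `n_pairs_evaluated`.
#' @export
ld_prune <- function(g, r2_max = 0.5) {
  stopifnot(n_loci(g) >= 2)
  calls <- g$calls
  kept <- integer(0)
  dropped <- integer(0)
  n_pairs <- 0
  for (l in seq_len(n_loci(g))) {
    if (!length(kept)) {
      kept <- l
      next
    }
    r <- suppressWarnings(
      stats::cor(calls[, l], calls[, kept, drop = FALSE],
                 use = "pairwise.complete.obs")
    )
    r[is.na(r)] <- 0 # zero variance over complete pairs
    n_pairs <- n_pairs + length(kept)
    if (any(r^2 >= r2_max)) dropped <- c(dropped, l) else kept <- c(kept, l)
  }
  list(geno = subset_geno(g, loci = kept),
       dropped = locus_ids(g)[dropped],
       n_pairs_evaluated = n_pairs)
}

#' Run the full quality-control cascade
#'
#' Convenience wrapper applying [filter_loci()], then [filter_samples()],
#' and computing the [ts_tv()] summary of the retained loci.
#'
#' @inheritParams filter_loci
#' @param sample_call_rate Minimum sample call rate (default 0.80).
#' @return List with `geno`, `locus_report`, `dropped_samples`, `ts_tv`.
#' @export
qc_cascade <- function(g, min_maf = 0.05, min_call_rate = 0.80,
                       min_inbreeding = 0.8, sample_call_rate = 0.80) {
  fl <- filter_loci(g, min_maf, min_call_rate, min_inbreeding)
  fs <- filter_samples(fl$geno, sample_call_rate)
  list(geno = fs$geno, locus_report = fl$report,
       dropped_samples = fs$dropped, ts_tv = ts_tv(fs$geno))
}
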