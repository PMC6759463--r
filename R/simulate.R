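#' Specify a synthetic GBS germplasm panel
#'
#' Parameters of the island-model generator used throughout the package's
#' tests and examples. Population allele frequencies follow the
#' Balding-Nichols model: for ancestral frequency p and differentiation F,
#' each population draws its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F),
#' so F is the expected fixation index of that population against the
#' ancestral pool. Individuals are inbred through `selfing_inbreeding`
#' (probability that the two alleles of an individual are copies of a single
#' draw), admixed individuals mix populations locus by locus according to a
#' Dirichlet ancestry vector truncated so that no component exceeds 0.6, and
#' duplicate groups plant near-identical copies of a source sample.
#'
#' The defaults emulate a Mediterranean lentil germplasm panel: 185
#' accessions in five differentiated subpopulations (pairwise fixation index
#' roughly 0.2-0.35) plus admixed individuals, a few thousand biallelic loci,
#' strong selfing, planted replicate groups and sparse missing data.
#'
#' @param n_pops Number of subpopulations (K).
#' @param samples_per_pop Integer vector of per-population sample counts
#'   (recycled to length `n_pops`).
#' @param n_loci Number of biallelic loci.
#' @param differentiation Balding-Nichols F per population, each in (0, 1)
#'   (recycled to length `n_pops`).
#' @param selfing_inbreeding Within-individual inbreeding coefficient F_IS in
#'   \[0, 1\]; 1 means complete selfing (no heterozygotes).
#' @param n_admixed Number of admixed individuals.
#' @param duplicate_groups List of lists with elements `source` (index of the
#'   sample to copy among the non-duplicate samples), `copies` (number of
#'   extra copies) and `error` (per-locus probability that a copy's call is
#'   replaced by one of the other two codes).
#' @param missing_rate Fraction of calls masked to missing, uniformly at
#'   random.
#' @param trait_model Named list of trait specifications, each a list with
#'   `means` (per-cluster trait means, length `n_pops`), `sd` (residual
#'   standard deviation among genotypes), `block_sd` (standard deviation of
#'   the common block effect) and `causal` (logical: does the causal marker
#'   act on this trait). See [simulate_phenotypes()].
#' @param causal_marker List with `locus` (column index) and `effect`
#'   (additive effect per alternate-allele copy, in units of the trait's
#'   residual SD). `NULL` disables the causal marker.
#' @param seed Integer seed; identical spec + seed reproduce identical
#'   datasets.
#'
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_pops = 5,
                     samples_per_pop = c(34, 34, 33, 33, 32),
                     n_loci = 3000,
                     differentiation = c(0.35, 0.30, 0.25, 0.22, 0.20),
                     selfing_inbreeding = 0.95,
                     n_admixed = 19,
                     duplicate_groups = list(
                       list(source = 1, copies = 3, error = 0.01),
                       list(source = 40, copies = 2, error = 0.01),
                       list(source = 80, copies = 1, error = 0.01)
                     ),
                     missing_rate = 0.05,
                     trait_model = default_trait_model(),
                     causal_marker = list(locus = 101, effect = 1),
                     seed = 1L) {
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  differentiation <- rep_len(differentiation, n_pops)
  stopifnot(
    n_pops >= 1, n_loci >= 1, all(samples_per_pop >= 1),
    all(differentiation > 0), all(differentiation < 1),
    selfing_inbreeding >= 0, selfing_inbreeding <= 1,
    n_admixed >= 0, missing_rate >= 0, missing_rate < 1
  )
  if (!is.null(causal_marker)) {
    stopifnot(causal_marker$locus >= 1, causal_marker$locus <= n_loci)
  }
  if (!is.null(trait_model)) {
    trait_model <- lapply(trait_model, function(t) {
      t$means <- rep_len(t$means, n_pops)
      t
    })
  }
  structure(list(
    n_pops = as.integer(n_pops), samples_per_pop = samples_per_pop,
    n_loci = as.integer(n_loci), differentiation = differentiation,
    selfing_inbreeding = selfing_inbreeding,
    n_admixed = as.integer(n_admixed), duplicate_groups = duplicate_groups,
    missing_rate = missing_rate, trait_model = trait_model,
    causal_marker = causal_marker, seed = as.integer(seed)
  ), class = "sim_spec")
}

#' Default trait model for the synthetic panel
#'
#' Six traits of a lentil field trial (flowering time in days, plant height
#' and first-flowering-node height in cm, seed area in mm^2, perimeter and
#' diameter in mm) with per-cluster means and spreads typical of a
#' Mediterranean panel. The three seed-size traits respond to the causal
#' marker, so they share a large-effect locus.
#'
#' @return Named list of per-trait specifications (see [sim_spec()]).
#' @export
default_trait_model <- function() {
  list(
    flowering_time = list(means = c(134, 132, 143, 146, 144), sd = 5.0,
                          block_sd = 2.0, causal = FALSE),
    plant_height = list(means = c(31, 36, 41, 44, 37), sd = 4.8,
                        block_sd = 2.0, causal = FALSE),
    node_height = list(means = c(13, 13, 18, 20, 17), sd = 3.4,
                       block_sd = 1.5, causal = FALSE),
    seed_area = list(means = c(11.9, 16.2, 25.6, 18.4, 17.2), sd = 4.5,
                     block_sd = 1.0, causal = TRUE),
    seed_perimeter = list(means = c(13.0, 15.7, 19.1, 16.2, 15.7), sd = 2.0,
                          block_sd = 0.5, causal = TRUE),
    seed_diameter = list(means = c(3.8, 4.5, 5.6, 4.7, 4.6), sd = 0.6,
                         block_sd = 0.1, causal = TRUE)
  )
}

#' Simulate a genotype panel from an island model
#'
#' Draws ancestral allele frequencies from Uniform(0.05, 0.95), population
#' frequencies from the Balding-Nichols Beta distribution, and individual
#' genotypes with within-individual inbreeding F_IS (with probability F_IS a
#' single allele draw is doubled, otherwise two alleles are drawn). Admixed
#' individuals draw a population of origin locus by locus from their ancestry
#' vector; duplicate copies perturb their source genotype at the stated error
#' rate; missing data is masked uniformly at random.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `geno_sim` with elements
#'   \describe{
#'     \item{geno}{the [geno_matrix()] (calls, alleles);}
#'     \item{truth}{tibble with `sample_id`, `pop` (cluster label or
#'       `"admixed"`), `duplicate_of` (source sample id or `NA`);}
#'     \item{ancestry}{matrix of true ancestry proportions (samples x K);}
#'     \item{spec}{the spec used.}
#'   }
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  K <- spec$n_pops
  L <- spec$n_loci
  fis <- spec$selfing_inbreeding

  p_anc <- stats::runif(L, 0.05, 0.95)
  pop_freq <- matrix(0, nrow = K, ncol = L)
  for (k in seq_len(K)) {
    f <- spec$differentiation[k]
    pop_freq[k, ] <- stats::rbeta(L, p_anc * (1 - f) / f,
                                  (1 - p_anc) * (1 - f) / f)
  }

  draw_calls <- function(p_row) {
    # p_row: per-locus allele frequency for this individual
    selfed <- stats::runif(L) < fis
    g <- stats::rbinom(L, 2L, p_row)
    g[selfed] <- 2L * stats::rbinom(sum(selfed), 1L, p_row[selfed])
    g
  }

  n_core <- sum(spec$samples_per_pop)
  ids <- character(0)
  pops <- character(0)
  calls <- matrix(NA_integer_, nrow = n_core + spec$n_admixed, ncol = L)
  row <- 0L
  for (k in seq_len(K)) {
    for (i in seq_len(spec$samples_per_pop[k])) {
      row <- row + 1L
      calls[row, ] <- draw_calls(pop_freq[k, ])
      ids <- c(ids, sprintf("P%d_%02d", k, i))
      pops <- c(pops, paste0("P", k))
    }
  }
  ancestry <- matrix(0, nrow = n_core + spec$n_admixed, ncol = K)
  ancestry[cbind(seq_len(n_core), rep(seq_len(K), spec$samples_per_pop))] <- 1

  # admixed: flat Dirichlet truncated so no component exceeds 0.6, which
  # guarantees they fail the q > 0.6 assignment rule by construction
  for (i in seq_len(spec$n_admixed)) {
    repeat {
      q <- stats::rgamma(K, 1)
      q <- q / sum(q)
      if (max(q) <= 0.6) break
    }
    row <- row + 1L
    origin <- sample.int(K, L, replace = TRUE, prob = q)
    p_row <- pop_freq[cbind(origin, seq_len(L))]
    calls[row, ] <- draw_calls(p_row)
    ids <- c(ids, sprintf("ADM_%02d", i))
    pops <- c(pops, "admixed")
    ancestry[row, ] <- q
  }

  dup_of <- rep(NA_character_, length(ids))
  for (grp in spec$duplicate_groups) {
    src <- grp$source
    stopifnot(src >= 1, src <= length(ids))
    for (j in seq_len(grp$copies)) {
      g <- calls[src, ]
      flip <- which(stats::runif(L) < grp$error)
      for (idx in flip) {
        g[idx] <- sample(setdiff(0:2, g[idx]), 1)
      }
      calls <- rbind(calls, g)
      ancestry <- rbind(ancestry, ancestry[src, ])
      ids <- c(ids, sprintf("%s_dup%d", ids[src], j))
      pops <- c(pops, pops[src])
      dup_of <- c(dup_of, ids[src])
    }
  }

  if (spec$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < spec$missing_rate
    calls[mask] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))

  rownames(calls) <- ids
  colnames(calls) <- sprintf("TP%04d", seq_len(L))
  rownames(ancestry) <- ids
  geno <- geno_matrix(calls, alleles = cbind(ref = ref, alt = unname(alt)))
  truth <- tibble::tibble(sample_id = ids, pop = pops, duplicate_of = dup_of)
  structure(list(geno = geno, truth = truth, ancestry = ancestry,
                 spec = spec), class = "geno_sim")
}

#' Simulate field-trial phenotypes for a synthetic panel
#'
#' Generates a randomised complete block design with `n_blocks` blocks. The
#' plot value of a trait is: cluster mean (ancestry-weighted for admixed
#' individuals) + a common block effect + the causal-marker additive effect
#' (`effect x residual SD` per alternate-allele copy, for traits flagged
#' `causal`) + a genotype-level residual + plot noise. Traits flagged
#' `causal` additionally share the genotype-level residual through a common
#' latent "seed size" deviate, so they are positively correlated, as seed
#' morphometrics measured on the same seed lot are.
#'
#' @param sim A `geno_sim` from [simulate_genotypes()].
#' @param n_blocks Number of blocks (replicates); the panel default is 2.
#' @param plot_sd Standard deviation of plot-level noise, as a fraction of
#'   each trait's residual SD.
#' @param seed Integer seed (defaults to the genotype spec seed + 1).
#' @return Tibble with `genotype_id`, `block_id` and one column per trait.
#' @export
simulate_phenotypes <- function(sim, n_blocks = 2, plot_sd = 0.25,
                                seed = NULL) {
  stopifnot(inherits(sim, "geno_sim"))
  spec <- sim$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  ids <- sample_ids(sim$geno)
  n <- length(ids)
  K <- spec$n_pops
  tm <- spec$trait_model
  stopifnot(all(vapply(tm, function(t) length(t$means), 1L) == K))

  causal_call <- rep(0, n)
  if (!is.null(spec$causal_marker)) {
    cc <- sim$geno$calls[, spec$causal_marker$locus]
    causal_call <- ifelse(is.na(cc), 0, cc)
  }
  latent <- stats::rnorm(n) # shared seed-size deviate (unit scale)

  out <- tibble::tibble(
    genotype_id = rep(ids, times = n_blocks),
    block_id = rep(seq_len(n_blocks), each = n)
  )
  for (tr in names(tm)) {
    t <- tm[[tr]]
    cluster_mean <- as.vector(sim$ancestry %*% t$means)
    g_effect <- if (isTRUE(t$causal) && !is.null(spec$causal_marker)) {
      spec$causal_marker$effect * t$sd * causal_call
    } else 0
    resid <- if (isTRUE(t$causal)) {
      t$sd * (sqrt(0.5) * latent + sqrt(0.5) * stats::rnorm(n))
    } else {
      t$sd * stats::rnorm(n)
    }
    geno_value <- cluster_mean + g_effect + resid
    block_eff <- stats::rnorm(n_blocks, 0, t$block_sd)
    out[[tr]] <- rep(geno_value, times = n_blocks) +
      block_eff[out$block_id] +
      stats::rnorm(n * n_blocks, 0, plot_sd * t$sd)
  }
  out$block_id <- as.character(out$block_id)
  out
}
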