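#' Pipeline configuration
#'
#' Bundles every stage threshold of the germplasm analysis pipeline with
#' the field-standard defaults: SNP filters MAF > 0.05, locus call rate >
#' 0.80, inbreeding coefficient > 0.8; sample call rate >= 0.80; LD pruning
#' at r-squared 0.5; membership threshold q > 0.6; k-means scan 1..40;
#' 10 admixture runs per K over K = 1..10; 100 tree bootstraps; per-locus
#' F_ST flags at 0.8/0.95; GWAS FDR 0.05. A master seed deterministically
#' derives per-stage seeds, so multi-run procedures get independent but
#' reproducible streams.
#'
#' @param min_maf,min_call_rate,min_inbreeding,sample_call_rate SNP/sample
#'   QC thresholds.
#' @param r2_max LD-pruning threshold.
#' @param ibs_threshold Redundancy threshold used when no replicate ids are
#'   supplied for calibration (`NULL` requires replicates).
#' @param q_min Membership-coefficient threshold.
#' @param k_max k-means scan upper bound.
#' @param admix_k Contiguous K range for the admixture scan.
#' @param n_runs Admixture restarts per K.
#' @param n_boot Tree bootstrap replicates.
#' @param fdr GWAS false-discovery-rate threshold.
#' @param max_steps Maximum GWAS cofactors.
#' @param seed Master seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_maf = 0.05, min_call_rate = 0.80,
                            min_inbreeding = 0.8, sample_call_rate = 0.80,
                            r2_max = 0.5, ibs_threshold = NULL, q_min = 0.6,
                            k_max = 40, admix_k = 1:10, n_runs = 10,
                            n_boot = 100, fdr = 0.05, max_steps = 10,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full germplasm analysis pipeline
#'
#' Executes the stages end to end on an in-memory genotype matrix:
#' SNP/sample QC, IBS redundancy collapse, LD pruning, k-means/BIC and DAPC
#' clustering, admixture scan with Evanno delta-K and membership assignment,
#' pairwise and per-locus F_ST, Nei/NJ bootstrap tree, allele-sharing Ward
#' dendrogram, per-trait RCBD statistics and kinship mixed-model GWAS.
#' Every stage is a pure function of (inputs, parameters, derived seed), so
#' rerunning with the same inputs and config reproduces all results.
#'
#' @param geno A [geno_matrix()].
#' @param pheno Optional phenotype tibble (plot level); enables the
#'   phenotype and GWAS stages.
#' @param replicate_ids Optional character vector of replicate sample ids
#'   used to calibrate the redundancy threshold; otherwise
#'   `config$ibs_threshold` must be set.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage tables, matrices,
#'   Newick trees and the Q-matrix are written there and listed in the
#'   manifest.
#' @return A list of class `pipeline_result` with one element per stage and
#'   a `manifest` tibble describing each artifact.
#' @export
run_pipeline <- function(geno, pheno = NULL, replicate_ids = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6, stream = 11L)
  manifest <- list()
  note <- function(name, stage, params) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      artifact = name, stage = stage, parameters = params)
  }

  qc <- qc_cascade(geno, config$min_maf, config$min_call_rate,
                   config$min_inbreeding, config$sample_call_rate)
  note("qc", "qc", sprintf("maf>%g, call_rate>%g, F>%g, sample_cr>=%g",
                           config$min_maf, config$min_call_rate,
                           config$min_inbreeding, config$sample_call_rate))

  sim <- ibs_matrix(qc$geno)
  if (!is.null(replicate_ids)) {
    replicate_ids <- intersect(replicate_ids, sample_ids(qc$geno))
    cal <- calibrate_threshold(sim, replicate_ids)
    threshold <- cal$threshold
  } else {
    if (is.null(config$ibs_threshold)) {
      stop("supply replicate_ids or config$ibs_threshold", call. = FALSE)
    }
    cal <- NULL
    threshold <- config$ibs_threshold
  }
  dedup <- collapse_redundant(qc$geno, sim, threshold)
  note("dedup", "dedup", sprintf("threshold=%.4f", threshold))

  pruned <- ld_prune(dedup$geno, config$r2_max)
  note("prune", "prune", sprintf("r2_max=%g", config$r2_max))

  scan <- find_clusters(pruned$geno, k_max = config$k_max,
                        seed = seeds[1])
  labels <- cluster_labels(scan)
  dapc_fit <- dapc(pruned$geno, labels, seed = seeds[2])
  admix <- admixture_scan(pruned$geno, k_range = config$admix_k,
                          n_runs = config$n_runs, seed = seeds[3])
  dk <- evanno_delta_k(admix$runs)
  k_admix <- attr(dk, "k_selected")
  best_fit <- admix$fits[[as.character(k_admix)]]
  membership <- assign_membership(best_fit, config$q_min)
  note("structure", "cluster/dapc/admix",
       sprintf("k_max=%d, admix_k=%d..%d, runs=%d, q_min=%g", config$k_max,
               min(config$admix_k), max(config$admix_k), config$n_runs,
               config$q_min))

  fst_pair <- wc_fst_pairwise(pruned$geno, labels)
  fst_locus <- wc_fst_one_vs_rest(dedup$geno, labels)
  nei <- nei_distance(pruned$geno, labels)
  tree <- if (nlevels(factor(labels)) >= 3) {
    bootstrap_support(pruned$geno, labels, n_boot = config$n_boot,
                      seed = seeds[4])
  } else NULL
  dendro <- allele_sharing_ward(pruned$geno)
  note("distance", "fst/tree/dendro",
       sprintf("flags 0.8/0.95, n_boot=%d", config$n_boot))

  pheno_stats <- NULL
  gwas <- NULL
  if (!is.null(pheno)) {
    traits <- setdiff(names(pheno), c("genotype_id", "block_id"))
    geno_clusters <- tibble::tibble(genotype_id = names(labels),
                                    cluster = as.character(labels))
    pheno_stats <- purrr::map(stats::setNames(traits, traits), function(tr) {
      a <- rcbd_anova(pheno, tr)
      list(anova = a, heritability = heritability(a),
           tukey = tryCatch(cluster_tukey(pheno, geno_clusters, tr),
                            error = function(e) NULL))
    })
    kin <- ibs_matrix(dedup$geno)
    gwas <- purrr::map(stats::setNames(traits, traits), function(tr) {
      mlmm_forward(dedup$geno, genotype_means(pheno, tr), kin,
                   max_steps = config$max_steps, fdr = config$fdr)
    })
    note("pheno", "pheno", "rcbd anova + H2 + tukey")
    note("gwas", "gwas", sprintf("fdr=%g, max_steps=%d", config$fdr,
                                 config$max_steps))
  }

  result <- list(
    qc = qc, ibs = sim, calibration = cal, dedup = dedup, prune = pruned,
    cluster_scan = scan, labels = labels, dapc = dapc_fit,
    admixture = admix, delta_k = dk, membership = membership,
    fst_pairwise = fst_pair, fst_locus = fst_locus, nei = nei,
    tree = tree, dendrogram = dendro, pheno = pheno_stats, gwas = gwas,
    config = config, manifest = dplyr::bind_rows(manifest)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_square_matrix(sim$values, file.path(out_dir, "ibs_matrix.tsv"))
    write_square_matrix(fst_pair$values, file.path(out_dir, "fst_matrix.tsv"))
    write_square_matrix(nei, file.path(out_dir, "nei_matrix.tsv"))
    utils::write.table(result$delta_k, file.path(out_dir, "delta_k.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_qmatrix(best_fit$q, file.path(out_dir, "qmatrix.tsv"))
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    write_newick(dendro$phylo, file.path(out_dir, "dendrogram.nwk"))
    utils::write.table(fst_locus, file.path(out_dir, "fst_per_locus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  QC: %d loci, %d samples kept (%d samples dropped)\n",
              n_loci(x$qc$geno), n_samples(x$qc$geno),
              length(x$qc$dropped_samples)))
  cat(sprintf("  dedup: %d redundancy group(s), %d samples kept\n",
              max(c(0, x$dedup$groups$group)), n_samples(x$dedup$geno)))
  cat(sprintf("  prune: %d loci kept\n", n_loci(x$prune$geno)))
  cat(sprintf("  k-means k = %d; admixture delta-K selects K = %s\n",
              x$cluster_scan$k_selected, attr(x$delta_k, "k_selected")))
  invisible(x)
}
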