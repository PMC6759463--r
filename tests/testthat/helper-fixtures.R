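# Shared fixture builders: everything is generated in code at test time.

# Minimal genotype matrix from a plain integer matrix.
make_geno <- function(calls, alleles = NULL, sample_ids = NULL,
                      locus_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(calls)))
  dimnames(calls) <- list(sample_ids, locus_ids)
  geno_matrix(calls, alleles = alleles)
}

# Small clean island-model panel (no admixture, no duplicates by default).
small_sim <- function(n_pops = 2, n_per_pop = 30, n_loci = 300, f = 0.3,
                      fis = 0.95, missing = 0, admixed = 0,
                      dups = list(), seed = 1) {
  simulate_genotypes(sim_spec(
    n_pops = n_pops, samples_per_pop = n_per_pop, n_loci = n_loci,
    differentiation = f, selfing_inbreeding = fis, n_admixed = admixed,
    duplicate_groups = dups, missing_rate = missing,
    causal_marker = NULL, seed = seed
  ))
}

# A tiny VCF written to a temp file; returns the path.
write_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t1|1",
    "1\t300\tsnp3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t400\tsnp4\tG\tC\t.\tPASS\t.\tGT\t1/0\t0/0\t0/0"
  )
  writeLines(lines, path)
  path
}

# HapMap table holding the same biallelic genotypes as the test VCF
# (snp1, snp2, snp4; the multiallelic snp3 has no HapMap counterpart).
write_test_hapmap <- function(path = tempfile(fileext = ".hmp.txt")) {
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    "S1", "S2", "S3"), collapse = "\t")
  rows <- c(
    paste(c("snp1", "A/G", "1", "100", "+", rep("NA", 6),
            "AA", "R", "GG"), collapse = "\t"),
    paste(c("snp2", "C/T", "1", "200", "+", rep("NA", 6),
            "NN", "CC", "TT"), collapse = "\t"),
    paste(c("snp4", "G/C", "1", "400", "+", rep("NA", 6),
            "GC", "GG", "GG"), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

# Least-squares residual sum of squares when fitting branch lengths of a
# fixed unrooted topology to a distance matrix; used by the exhaustive
# NJ topology oracle.
ls_fit_topology <- function(tree, d) {
  tips <- tree$tip.label
  pairs <- utils::combn(length(tips), 2)
  A <- matrix(0, ncol(pairs), nrow(tree$edge))
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    path <- ape::nodepath(tree, i, j)
    for (s in seq_len(length(path) - 1)) {
      e <- which((tree$edge[, 1] == path[s] & tree$edge[, 2] == path[s + 1]) |
                   (tree$edge[, 2] == path[s] & tree$edge[, 1] == path[s + 1]))
      A[p, e] <- 1
    }
    y[p] <- d[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

write_test_pheno <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "genotype_id,block_id,flowering_time,plant_height",
    "MG1,1,134,31",
    "MG1,2,136,33",
    "MG2,1,132,",
    "MG2,2,abc,35"
  ), path)
  path
}
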