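#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads a VCF (4.x) and recodes diploid GT fields to alternate-allele counts.
#' Only biallelic SNP records are kept; multiallelic records and records whose
#' REF/ALT are not single nucleotides are skipped with a message. Half-missing
#' or missing genotypes (`./.`, `.`) become `NA`. Sample and locus order is
#' preserved from the file, and CHROM/POS/ID are carried as per-locus metadata.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0 || ncol(v@gt) < 2) {
    stop("VCF has no GT data", call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  if (!any(keep)) stop("no biallelic SNP records in VCF", call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]
  ids <- fix[keep, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[no_id]

  # strip phase, count ALT alleles; anything containing "." is missing
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1", "1")] <- 2L
    out
  }
  calls <- t(apply(gt, 1, code))
  dimnames(calls) <- list(ids, colnames(gt))
  meta <- tibble::tibble(
    chrom = unname(fix[keep, "CHROM"]),
    pos = suppressWarnings(as.integer(fix[keep, "POS"]))
  )
  geno_matrix(t(calls), alleles = cbind(ref = ref, alt = alt), meta = meta)
}

.iupac <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            A = "AA", C = "CC", G = "GG", T = "TT", N = NA_character_)

#' Read genotypes from a HapMap-style table
#'
#' Reads the tab-separated HapMap dialect produced by TASSEL-style pipelines:
#' a `rs#` column, an `alleles` column like `"A/G"`, assorted metadata columns
#' and then one column per sample holding two-letter (`"AG"`) or single-letter
#' IUPAC (`"R"`) genotypes. Genotypes are recoded to alternate-allele counts
#' against the locus allele pair (first allele = reference); `"N"`/`"NN"` is
#' missing. A genotype letter outside the locus allele pair is an error naming
#' the locus and sample.
#'
#' @param path Path to a HapMap-style TSV.
#' @return A [geno_matrix()].
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("rs#", "alleles")
  if (!all(need %in% names(tab))) {
    stop("HapMap file must have 'rs#' and 'alleles' columns", call. = FALSE)
  }
  std <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
           "protLSID", "assayLSID", "panelLSID", "QCcode")
  sample_cols <- setdiff(names(tab), std)
  if (!length(sample_cols)) stop("no sample columns found", call. = FALSE)

  allele_pair <- strsplit(tab$alleles, "/", fixed = TRUE)
  if (any(lengths(allele_pair) != 2)) {
    stop("alleles column must be of the form 'X/Y'", call. = FALSE)
  }
  al <- do.call(rbind, allele_pair)

  calls <- matrix(NA_integer_, nrow = length(sample_cols), ncol = nrow(tab),
                  dimnames = list(sample_cols, tab[["rs#"]]))
  for (j in seq_len(nrow(tab))) {
    ref <- al[j, 1]; alt <- al[j, 2]
    gt <- toupper(unlist(tab[j, sample_cols], use.names = FALSE))
    one <- nchar(gt) == 1
    gt[one] <- .iupac[gt[one]]
    gt[gt %in% c("N", "NN", "", "--")] <- NA
    known <- !is.na(gt)
    letters2 <- cbind(substr(gt[known], 1, 1), substr(gt[known], 2, 2))
    bad <- !(letters2[, 1] %in% c(ref, alt)) | !(letters2[, 2] %in% c(ref, alt))
    if (any(bad)) {
      s <- sample_cols[known][which(bad)[1]]
      stop(sprintf("genotype '%s' at locus %s, sample %s not in alleles %s/%s",
                   gt[known][which(bad)[1]], tab[["rs#"]][j], s, ref, alt),
           call. = FALSE)
    }
    calls[known, j] <- (letters2[, 1] == alt) + (letters2[, 2] == alt)
  }
  geno_matrix(calls, alleles = cbind(ref = al[, 1], alt = al[, 2]))
}

#' Read and write the plain 0/1/2 genotype table
#'
#' The package's plain-text dialect: a TSV with samples as rows, loci as
#' columns, a leading `sample_id` column, and cells 0/1/2/NA. `write_geno_tsv`
#' then `read_geno_tsv` round-trips calls exactly. Allele pairs, which the
#' plain table does not carry, default to A/G on reading.
#'
#' @param path File path.
#' @param g A [geno_matrix()].
#' @return `read_geno_tsv` returns a [geno_matrix()]; `write_geno_tsv`
#'   invisibly returns `path`.
#' @export
read_geno_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1] != "sample_id") {
    stop("first column must be 'sample_id'", call. = FALSE)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample_id
  geno_matrix(m)
}

#' @rdname read_geno_tsv
#' @export
write_geno_tsv <- function(g, path) {
  tab <- data.frame(sample_id = sample_ids(g), g$calls, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
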