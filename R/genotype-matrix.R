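#' Construct a genotype matrix
#'
#' The central data container of the package: a samples x loci matrix of
#' alternate-allele counts (0, 1, 2 or `NA` for missing) together with the
#' two alleles segregating at each locus. Heterozygote phase is ignored
#' (unphased genotyping-by-sequencing data), and loci keep file order; no
#' genomic coordinates are required, although `read_vcf()` carries them as
#' optional metadata when present.
#'
#' @param calls Integer matrix, samples as rows and loci as columns, entries
#'   in `{0, 1, 2, NA}` (count of the alternate allele).
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the row names of `calls`.
#' @param locus_ids Character vector of unique locus identifiers; defaults to
#'   the column names of `calls`.
#' @param alleles Two-column character matrix (`ref`, `alt`) giving the two
#'   distinct nucleotides at each locus, one row per locus.
#' @param meta Optional tibble of per-locus metadata (e.g. chromosome and
#'   position from a VCF), with one row per locus.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, sample_ids = rownames(calls),
                        locus_ids = colnames(calls), alleles = NULL,
                        meta = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(calls)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids", call. = FALSE)
  if (anyDuplicated(locus_ids)) stop("duplicated locus ids", call. = FALSE)
  if (length(sample_ids) != nrow(calls) || length(locus_ids) != ncol(calls)) {
    stop("id lengths do not match call matrix dimensions", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(alleles)) {
    alleles <- matrix(rep(c("A", "G"), each = ncol(calls)), ncol = 2,
                      dimnames = list(NULL, c("ref", "alt")))
  }
  alleles <- as.matrix(alleles)
  colnames(alleles) <- c("ref", "alt")
  if (nrow(alleles) != ncol(calls)) {
    stop("alleles must have one row per locus", call. = FALSE)
  }
  if (any(alleles[, 1] == alleles[, 2])) {
    stop("each locus needs two distinct alleles", call. = FALSE)
  }
  dimnames(calls) <- list(sample_ids, locus_ids)
  structure(list(calls = calls, alleles = alleles, meta = meta),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d loci (%.1f%% missing)\n",
              n_samples(x), n_loci(x),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @export
as.matrix.geno_matrix <- function(x, ...) x$calls

#' Dimensions and identifiers of a genotype matrix
#'
#' @param g A `geno_matrix`.
#' @return `n_samples()`/`n_loci()` return counts; `sample_ids()`/`locus_ids()`
#'   return character vectors.
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$calls)

#' @rdname n_samples
#' @export
sample_ids <- function(g) rownames(g$calls)

#' @rdname n_samples
#' @export
locus_ids <- function(g) colnames(g$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g A `geno_matrix`.
#' @param samples,loci Index, logical or character vectors selecting rows
#'   (samples) and columns (loci). Defaults keep everything.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(g, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  li <- if (is.null(loci)) seq_len(n_loci(g)) else loci
  calls <- g$calls[si, li, drop = FALSE]
  if (is.character(li)) li <- match(li, locus_ids(g))
  if (is.logical(li)) li <- which(li)
  meta <- if (!is.null(g$meta)) g$meta[li, , drop = FALSE] else NULL
  al <- g$alleles[li, , drop = FALSE]
  geno_matrix(calls, alleles = al, meta = meta)
}

#' Turn a genotype matrix into a long tibble
#'
#' One row per (sample, locus) call; convenient for ad hoc dplyr summaries.
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `locus_id`, `call`.
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(sample_ids(x), times = n_loci(x)),
    locus_id = rep(locus_ids(x), each = n_samples(x)),
    call = as.integer(x$calls)
  )
}

#' One-line summary of a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return Tibble with sample/locus counts and the missing-call fraction.
#' @method glance geno_matrix
#' @export
glance.geno_matrix <- function(x, ...) {
  tibble::tibble(
    n_samples = n_samples(x),
    n_loci = n_loci(x),
    missing_rate = mean(is.na(x$calls))
  )
}
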