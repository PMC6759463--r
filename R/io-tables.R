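#' Read a phenotype table
#'
#' Reads a CSV with one row per (genotype, block) plot and one column per
#' trait, as recorded in a randomised complete block design. Mandatory columns
#' are `genotype_id` and `block_id` (any further columns are traits).
#' Non-numeric trait cells become `NA` with a warning; a duplicated
#' (genotype, block) combination is an error.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `genotype_id`, `block_id` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  need <- c("genotype_id", "block_id")
  if (!all(need %in% names(tab))) {
    stop("phenotype CSV must have 'genotype_id' and 'block_id' columns",
         call. = FALSE)
  }
  key <- paste(tab$genotype_id, tab$block_id)
  if (anyDuplicated(key)) {
    stop("duplicated (genotype_id, block_id) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  traits <- setdiff(names(tab), need)
  for (tr in traits) {
    raw <- tab[[tr]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & is.na(val)
    if (any(bad)) {
      warning(sum(bad), " non-numeric cell(s) in trait '", tr,
              "' set to NA", call. = FALSE)
    }
    tab[[tr]] <- val
  }
  tibble::as_tibble(tab)
}

#' Write a labeled square matrix
#'
#' Writes a symmetric similarity or distance matrix as a labeled TSV
#' (default) or in the PHYLIP square dialect. Asymmetric input is rejected.
#'
#' @param m Symmetric numeric matrix with row/column names.
#' @param path Output file path.
#' @param format `"tsv"` (labelled, with an `id` header column) or
#'   `"phylip"` (taxon count on the first line).
#' @return Invisibly, `path`.
#' @export
write_square_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8,
                                              check.attributes = FALSE))) {
    stop("matrix must be square and symmetric", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (format == "tsv") {
    tab <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                         format(m[i, ], digits = 6)), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] object (node labels, when present, are written
#'   as bootstrap support).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write an ancestry (Q) matrix
#'
#' One row per sample, K ancestry-proportion columns each summing to 1.
#'
#' @param q Numeric matrix or data frame of ancestry proportions with sample
#'   row names, or the tibble produced by [tidy.admixture_fit()] in wide form.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_qmatrix <- function(q, path) {
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 1e-6)) {
    stop("Q rows must sum to 1", call. = FALSE)
  }
  if (is.null(rownames(q))) rownames(q) <- paste0("S", seq_len(nrow(q)))
  tab <- data.frame(sample_id = rownames(q), q, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("sample_id",
                                   paste0("Q", seq_len(ncol(q)))))
  invisible(path)
}
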