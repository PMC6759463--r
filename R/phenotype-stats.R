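#' Randomised-complete-block ANOVA for a trait
#'
#' Two-way additive model `trait ~ genotype + block` on plot-level data.
#' Sums of squares are Type II (identical to the sequential decomposition
#' for balanced designs, and exact there: genotype + block + residual SS
#' add up to the total). The genotype effect is tested with
#' `F = MS_G / MS_E`.
#'
#' @param p Phenotype tibble with `genotype_id`, `block_id` and trait
#'   columns (see [read_phenotypes()] / [simulate_phenotypes()]).
#' @param trait Name of the trait column to analyse.
#' @return Tibble of class `rcbd_anova` with rows `genotype`, `block`,
#'   `residual` and columns `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p_value`, plus attribute `n_replicates` (number of blocks).
#' @export
rcbd_anova <- function(p, trait) {
  stopifnot(trait %in% names(p))
  d <- data.frame(
    y = p[[trait]],
    genotype = factor(p$genotype_id),
    block = factor(p$block_id)
  )
  d <- d[!is.na(d$y), ]
  if (nlevels(droplevels(d$genotype)) < 2 || nlevels(droplevels(d$block)) < 2) {
    stop("need at least 2 genotypes and 2 blocks", call. = FALSE)
  }
  d$genotype <- droplevels(d$genotype)
  d$block <- droplevels(d$block)
  per_block <- table(d$genotype)
  if (any(per_block < nlevels(d$block))) {
    warning(sum(per_block < nlevels(d$block)),
            " genotype(s) observed in fewer blocks than the design;",
            " retained under Type-II SS", call. = FALSE)
  }
  fit <- stats::lm(y ~ genotype + block, data = d)
  if (stats::sd(d$y) == 0) {
    out <- tibble::tibble(
      term = c("genotype", "block", "residual"),
      df = c(nlevels(d$genotype) - 1L, nlevels(d$block) - 1L,
             fit$df.residual),
      sumsq = 0, meansq = 0, statistic = c(NA, NA, NA),
      p_value = c(NA, NA, NA)
    )
  } else {
    a2 <- car::Anova(fit, type = 2)
    ms <- a2$`Sum Sq` / a2$Df
    out <- tibble::tibble(
      term = c("genotype", "block", "residual"),
      df = a2$Df,
      sumsq = a2$`Sum Sq`,
      meansq = ms,
      statistic = c(ms[1] / ms[3], ms[2] / ms[3], NA),
      p_value = c(a2$`Pr(>F)`[1:2], NA)
    )
  }
  structure(out, trait = trait, n_replicates = nlevels(d$block),
            class = c("rcbd_anova", class(out)))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' From the RCBD expected mean squares, the genotypic variance component is
#' `sigma2_g = (MS_G - MS_E) / r` and broad-sense heritability on an
#' entry-mean basis is `H2 = sigma2_g / (sigma2_g + sigma2_e / r)`, with r
#' the number of replicates. A negative variance-component estimate is
#' clamped to zero with a warning; `MS_E = 0` gives the degenerate `H2 = 1`
#' (flagged).
#'
#' @param a An [rcbd_anova()] table.
#' @param r Number of replicates; defaults to the block count recorded in
#'   `a`.
#' @return Tibble with `trait`, `sigma2_g`, `sigma2_e`, `h2`, `degenerate`.
#' @export
heritability <- function(a, r = attr(a, "n_replicates")) {
  stopifnot(inherits(a, "rcbd_anova"), r >= 2)
  ms_g <- a$meansq[a$term == "genotype"]
  ms_e <- a$meansq[a$term == "residual"]
  s2g <- (ms_g - ms_e) / r
  if (!is.na(s2g) && s2g < 0) {
    warning("negative genotypic variance clamped to 0", call. = FALSE)
    s2g <- 0
  }
  degenerate <- !is.na(ms_e) && ms_e == 0
  h2 <- if (degenerate) 1 else s2g / (s2g + ms_e / r)
  tibble::tibble(trait = attr(a, "trait"), sigma2_g = s2g, sigma2_e = ms_e,
                 h2 = h2, degenerate = degenerate)
}

# Insert-and-absorb compact letter display from the set of significantly
# different pairs. Returns a character vector of letter strings per level.
letter_display <- function(levels_ordered, sig_pairs) {
  sets <- list(levels_ordered)
  for (i in seq_len(nrow(sig_pairs))) {
    pa <- sig_pairs$a[i]; pb <- sig_pairs$b[i]
    new_sets <- list()
    for (s in sets) {
      if (pa %in% s && pb %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, pa)), list(setdiff(s, pb)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]])) {
          if (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v) {
            keep[u] <- FALSE
          }
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  sets <- sets[order(vapply(sets, function(s)
    min(match(s, levels_ordered)), numeric(1)))]
  out <- stats::setNames(rep("", length(levels_ordered)), levels_ordered)
  for (i in seq_along(sets)) {
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  }
  out
}

#' Tukey HSD comparison of clusters for a trait
#'
#' Compares genetic clusters on genotype means: plot values are first
#' averaged over blocks so each genotype contributes one value, then a
#' one-way ANOVA across clusters is followed by Tukey-Kramer
#' studentized-range comparisons (exact for unequal group sizes) and a
#' compact letter display assembled by insert-and-absorb from the
#' significant pairs — clusters sharing no letter differ at `alpha`.
#' Singleton clusters are excluded with a warning.
#'
#' @param p Phenotype tibble (plot level).
#' @param cluster_labels Named vector or two-column tibble
#'   (`genotype_id`, `cluster`) mapping genotypes to clusters.
#' @param trait Trait column name.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `tukey_result` with `summary` (tibble: `cluster`,
#'   `n`, `mean`, `sd`, `letters`) and `pairs` (tibble: `cluster_a`,
#'   `cluster_b`, `diff`, `p_value`, `significant`).
#' @export
cluster_tukey <- function(p, cluster_labels, trait, alpha = 0.05) {
  stopifnot(trait %in% names(p))
  if (is.data.frame(cluster_labels)) {
    lab <- stats::setNames(as.character(cluster_labels$cluster),
                           cluster_labels$genotype_id)
  } else {
    lab <- stats::setNames(as.character(cluster_labels),
                           names(cluster_labels))
  }
  gm <- stats::aggregate(p[[trait]], by = list(genotype_id = p$genotype_id),
                         FUN = mean, na.rm = TRUE)
  names(gm)[2] <- "value"
  gm$cluster <- lab[gm$genotype_id]
  gm <- gm[!is.na(gm$cluster) & !is.na(gm$value), ]
  sizes <- table(gm$cluster)
  if (any(sizes < 2)) {
    warning("singleton cluster(s) excluded: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    gm <- gm[gm$cluster %in% names(sizes)[sizes >= 2], ]
  }
  gm$cluster <- factor(gm$cluster)
  if (nlevels(gm$cluster) < 2) stop("need at least 2 clusters", call. = FALSE)

  fit <- stats::aov(value ~ cluster, data = gm)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cluster
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble::tibble(
    cluster_a = vapply(cmp, `[`, "", 1),
    cluster_b = vapply(cmp, `[`, "", 2),
    diff = unname(tk[, "diff"]),
    p_value = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
  means <- tapply(gm$value, gm$cluster, mean)
  ord <- names(sort(means, decreasing = TRUE))
  sig <- pairs[pairs$significant, c("cluster_a", "cluster_b")]
  names(sig) <- c("a", "b")
  letters_out <- letter_display(ord, sig)
  summary <- tibble::tibble(
    cluster = levels(gm$cluster),
    n = as.integer(table(gm$cluster)),
    mean = as.numeric(means[levels(gm$cluster)]),
    sd = as.numeric(tapply(gm$value, gm$cluster, stats::sd)),
    letters = unname(letters_out[levels(gm$cluster)])
  )
  structure(list(summary = summary, pairs = pairs, trait = trait,
                 alpha = alpha), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("<tukey_result> trait '%s' (alpha = %g)\n", x$trait, x$alpha))
  print(x$summary)
  invisible(x)
}

#' @method tidy tukey_result
#' @export
tidy.tukey_result <- function(x, ...) x$pairs

#' @method glance tukey_result
#' @export
glance.tukey_result <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_clusters = nrow(x$summary),
                 n_significant_pairs = sum(x$pairs$significant))
}
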