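# COG functional-category statistics: tallies at the general (0-4) or
# sub-group (25 letters) level, chi-square goodness of fit of the
# duplicate set against genome-wide proportions, divergence binning, and
# positional clusters of same-category duplicated genes.

#' Tally COG categories over a set of genes
#'
#' Multi-category genes contribute one count to EACH of their categories,
#' so the tally total can exceed the number of genes. Genes without any
#' category are counted in general group `0` (level "general") or category
#' `"0"` (level "subgroup").
#'
#' @param genes data.frame with a `cogs` column (concatenated letters,
#'   "" for none), e.g. the `genes` field of a [genome_bundle()].
#' @param level `"general"` (groups 0-4) or `"subgroup"` (25 letters plus
#'   "0" for unclassified).
#' @return A list of class `"cog_tally"`: `counts` (named integer vector),
#'   `total`, `level`.
#' @export
tally_cogs <- function(genes, level = c("general", "subgroup")) {
  level <- match.arg(level)
  letters_by_gene <- strsplit(genes$cogs, "")
  bad <- unique(unlist(letters_by_gene))
  bad <- setdiff(bad, COG_LETTERS)
  if (length(bad))
    stop("unknown COG letter(s): ", paste(bad, collapse = ", "))
  if (level == "general") {
    cats <- as.character(0:4)
    counts <- setNames(integer(5), cats)
    for (ls in letters_by_gene) {
      if (!length(ls)) counts[["0"]] <- counts[["0"]] + 1L
      else {
        # a gene annotated with several letters of the same general group
        # still counts once per category annotation
        for (grp in COG_GENERAL_GROUP[ls])
          counts[[as.character(grp)]] <- counts[[as.character(grp)]] + 1L
      }
    }
  } else {
    cats <- c("0", COG_LETTERS)
    counts <- setNames(integer(length(cats)), cats)
    for (ls in letters_by_gene) {
      if (!length(ls)) counts[["0"]] <- counts[["0"]] + 1L
      else for (l in ls) counts[[l]] <- counts[[l]] + 1L
    }
  }
  structure(list(counts = counts, total = sum(counts), level = level),
            class = "cog_tally")
}

#' Upper-tail chi-square probability
#'
#' Thin wrapper over the chi-square survival function: returns
#' P(X >= x) for X ~ chi-square with `df` degrees of freedom.
#'
#' @param x Non-negative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Probability in [0, 1].
#' @export
chi2_sf <- function(x, df) {
  stopifnot(x >= 0, df >= 1)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Chi-square goodness of fit of a tally against expected proportions
#'
#' Tests the null hypothesis that the observed category counts follow the
#' supplied proportions (e.g. that duplicated genes have the same COG
#' distribution as the full genome). Categories with zero expected
#' proportion and zero observed count are dropped; a zero proportion with
#' a positive count leaves the statistic undefined and is an error. No
#' continuity correction is applied. Degrees of freedom = (number of
#' categories with positive expectation) - 1.
#'
#' @param observed A `"cog_tally"` or named count vector.
#' @param expected_props Named proportions over the same categories,
#'   summing to 1 (tolerance 1e-9).
#' @return List of class `"gof_result"`: `chi2`, `df`, `p`, `expected`.
#' @export
chisq_gof <- function(observed, expected_props) {
  counts <- if (inherits(observed, "cog_tally")) observed$counts else observed
  stopifnot(!is.null(names(counts)), !is.null(names(expected_props)))
  expected_props <- expected_props[names(counts)]
  if (anyNA(expected_props))
    stop("expected_props must cover every observed category")
  if (abs(sum(expected_props) - 1) > 1e-9)
    stop("expected proportions must sum to 1")
  total <- sum(counts)
  stopifnot(total > 0)
  zero_p <- expected_props == 0
  if (any(zero_p & counts > 0))
    stop("zero expected proportion with positive observed count: ",
         paste(names(counts)[zero_p & counts > 0], collapse = ", "))
  counts <- counts[!zero_p]
  props <- expected_props[!zero_p]
  expected <- total * props
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  structure(list(chi2 = chi2, df = df, p = chi2_sf(chi2, df),
                 expected = expected),
            class = "gof_result")
}

#' Bin pairwise amino-acid divergences into decade bins
#'
#' Bins are [0,10), [10,20), ..., [80,90), [90,100]; the last bin is
#' closed above so a divergence of exactly 100 is counted.
#'
#' @param pairs data.frame with a `divergence` column (or numeric vector).
#' @param width Bin width in percent (default 10).
#' @return Named integer vector of bin counts, summing to the number of
#'   pairs.
#' @export
bin_divergence <- function(pairs, width = 10) {
  d <- if (is.data.frame(pairs)) pairs$divergence else pairs
  stopifnot(all(d >= 0 & d <= 100))
  breaks <- seq(0, 100, by = width)
  idx <- pmin(findInterval(d, breaks), length(breaks) - 1L)
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1],
                 c(rep(")", length(breaks) - 2L), "]"))
  counts <- setNames(integer(length(labs)), labs)
  for (i in idx) counts[i] <- counts[i] + 1L
  counts
}

#' Positional clusters of same-category duplicated genes
#'
#' Tiles each replicon with fixed non-overlapping windows starting at
#' coordinate 0 and reports every (window, general COG group) holding at
#' least `min_count` duplicated genes of that group. A multi-category gene
#' can appear under each of its groups.
#'
#' @param dup_genes data.frame of duplicated genes: `locus_tag`,
#'   `replicon_id`, `start`, `cogs`, and optionally `divergence`.
#' @param window Window width in nt (default 100 kb).
#' @param min_count Minimum genes per (window, group) (default 3).
#' @return data.frame: `replicon_id`, `window_start`, `window_end`,
#'   `group`, `n`, `loci`, `mean_divergence` (NA when divergences are not
#'   supplied).
#' @export
find_cog_clusters <- function(dup_genes, window = 1e5, min_count = 3) {
  rows <- list()
  for (i in seq_len(nrow(dup_genes))) {
    g <- dup_genes[i, ]
    groups <- if (nzchar(g$cogs))
      unique(COG_GENERAL_GROUP[strsplit(g$cogs, "")[[1]]]) else 0L
    win <- floor(g$start / window)
    for (grp in groups)
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = g$replicon_id, win = win, group = grp,
        locus_tag = g$locus_tag,
        divergence = if ("divergence" %in% names(dup_genes))
          g$divergence else NA_real_,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(replicon_id = character(0), window_start = numeric(0),
                      window_end = numeric(0), group = integer(0),
                      n = integer(0), loci = character(0),
                      mean_divergence = numeric(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(
    split(d, list(d$replicon_id, d$win, d$group), drop = TRUE),
    function(s) {
      if (nrow(s) < min_count) return(NULL)
      data.frame(replicon_id = s$replicon_id[1],
                 window_start = s$win[1] * window,
                 window_end = (s$win[1] + 1) * window,
                 group = s$group[1], n = nrow(s),
                 loci = paste(sort(s$locus_tag), collapse = ","),
                 mean_divergence = mean(s$divergence),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(out))
    return(data.frame(replicon_id = character(0), window_start = numeric(0),
                      window_end = numeric(0), group = integer(0),
                      n = integer(0), loci = character(0),
                      mean_divergence = numeric(0), stringsAsFactors = FALSE))
  out <- out[order(out$replicon_id, out$window_start, out$group), ]
  rownames(out) <- NULL
  out
}
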