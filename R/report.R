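# Report arithmetic: every percentage in the study's tables is
# 100 * count / denominator rounded half-up as the last step, so fixture
# counts reproduce printed values exactly. Also builds the tree-type by
# location by bootstrap-band matrix.

#' Percentage with half-up rounding
#'
#' `100 * count / denom`, rounded half-up at `decimals` places (rounding
#' is the last operation). Half-up (not banker's) rounding matches the
#' convention of printed report tables.
#'
#' @param count,denom Numerator and positive denominator.
#' @param decimals Decimal places (default 1).
#' @return Rounded percentage.
#' @export
pct <- function(count, denom, decimals = 1) {
  if (any(denom <= 0)) stop("denominator must be positive")
  x <- 100 * count / denom
  s <- 10^decimals
  floor(x * s + 0.5 + 1e-9) / s
}

#' Tree-type by location by bootstrap-band matrix
#'
#' Cross-tabulates classified duplicate pairs by location class, Type-A /
#' Type-B call, and bootstrap band. Bands: `>=90` is [90, 100],
#' `70-90` is [70, 90), `<70` is [0, 70), and `undefined` collects pairs
#' without a bootstrap value (e.g. unresolvable ortholog choices).
#'
#' @param results data.frame with columns `location_class`, `call`
#'   ("TypeA"/"TypeB"), `bootstrap_support` (integer or NA).
#' @return data.frame with one row per (location_class, call, band) cell
#'   plus `n`; cells sum to the number of classified pairs.
#' @export
tree_type_table <- function(results) {
  bands <- c(">=90", "70-90", "<70", "undefined")
  classes <- c("CI-CI", "CI-CII", "CII-CII", "C-P", "P-P")
  calls <- c("TypeA", "TypeB")
  band_of <- function(v) {
    ifelse(is.na(v), "undefined",
           ifelse(v >= 90, ">=90", ifelse(v >= 70, "70-90", "<70")))
  }
  grid <- expand.grid(location_class = classes, call = calls, band = bands,
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  if (nrow(results) > 0) {
    res <- results[!is.na(results$call) & results$call %in% calls, ,
                   drop = FALSE]
    if (nrow(res) > 0) {
      key <- paste(res$location_class, res$call, band_of(res$bootstrap_support))
      tab <- table(key)
      gk <- paste(grid$location_class, grid$call, grid$band)
      hit <- match(names(tab), gk)
      grid$n[hit[!is.na(hit)]] <- as.integer(tab[!is.na(hit)])
    }
  }
  grid
}
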