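# Codon-level functional-constraint analysis. Two estimators of Ka
# (nonsynonymous substitutions per nonsynonymous site) and Ks (synonymous
# substitutions per synonymous site) are provided: classic Nei-Gojobori
# counting (equal mutation weights, Jukes-Cantor correction), kept as an
# independent cross-check; and a kappa- and frequency-corrected
# approximate method in the Yang-Nielsen family, the headline estimator,
# which weights mutational opportunity by the transition/transversion
# ratio and position-specific nucleotide frequencies and corrects each
# substitution class with a two-parameter (transition/transversion)
# distance. Stop-codon-crossing mutational pathways are excluded and
# weights renormalized; saturation flags the estimate undefined rather
# than extrapolating.

.codon_cache <- new.env(parent = emptyenv())

codon_data <- function() {
  if (!is.null(.codon_cache$d)) return(.codon_cache$d)
  gc11 <- Biostrings::getGeneticCode("11")
  codons <- names(gc11)
  aa <- unname(gc11)
  nts <- c("A", "C", "G", "T")
  is_ts <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  # all single-nucleotide neighbours of every codon
  neigh <- list()
  for (cd in codons) {
    v <- strsplit(cd, "")[[1]]
    rows <- list()
    for (pos in 1:3) for (alt in setdiff(nts, v[pos])) {
      w <- v; w[pos] <- alt
      cd2 <- paste(w, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos, to = cd2, target_nt = alt,
        ts = is_ts(v[pos], alt),
        syn = gc11[[cd2]] == gc11[[cd]],
        stop = gc11[[cd2]] == "*", stringsAsFactors = FALSE)
    }
    neigh[[cd]] <- do.call(rbind, rows)
  }
  .codon_cache$d <- list(codons = codons, aa = setNames(aa, codons),
                         sense = codons[aa != "*"],
                         stops = codons[aa == "*"], neigh = neigh)
  .codon_cache$d
}

# Synonymous/nonsynonymous site counts for one codon under mutation
# weights w = kappa^ts * pi_pos(target). pi is a list of 3 length-4
# frequency vectors (named ACGT), or NULL for uniform.
.codon_sites <- function(codon, kappa = 1, pi = NULL, cd = codon_data()) {
  nb <- cd$neigh[[codon]]
  s <- 0
  for (pos in 1:3) {
    rows <- nb[nb$pos == pos & !nb$stop, , drop = FALSE]
    if (!nrow(rows)) next
    w <- ifelse(rows$ts, kappa, 1) *
      (if (is.null(pi)) 1 else pi[[pos]][rows$target_nt])
    tot <- sum(w)
    if (tot > 0) s <- s + sum(w[rows$syn]) / tot
  }
  c(S = s, N = 3 - s)
}

# Average synonymous/nonsynonymous (and transition/transversion) difference
# counts between two codons over all shortest mutational pathways; paths
# through stop codons are dropped and the remaining paths reweighted. If
# every path crosses a stop, all paths are used and stop-involving steps
# are classified by their amino-acid change.
.codon_diffs <- function(c1, c2, cd = codon_data()) {
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  out <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  if (!length(pos)) return(out)
  paths <- if (length(pos) == 1) list(pos) else {
    perms <- list()
    permute <- function(rem, acc) {
      if (!length(rem)) perms[[length(perms) + 1L]] <<- acc
      else for (i in seq_along(rem))
        permute(rem[-i], c(acc, rem[i]))
    }
    permute(pos, integer(0))
    perms
  }
  is_ts <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  walk <- function(order, allow_stop) {
    cur <- v1
    steps <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
    for (p in order) {
      aa_from <- cd$aa[[paste(cur, collapse = "")]]
      nxt <- cur; nxt[p] <- v2[p]
      key <- paste(nxt, collapse = "")
      aa_to <- cd$aa[[key]]
      if (aa_to == "*" && !allow_stop) return(NULL)
      ts <- is_ts(cur[p], v2[p])
      syn <- aa_to == aa_from
      slot <- paste0(if (syn) "sd" else "nd", "_", if (ts) "ts" else "tv")
      steps[slot] <- steps[slot] + 1
      cur <- nxt
    }
    steps
  }
  res <- lapply(paths, walk, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) res <- lapply(paths, walk, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

#' Build a validated two-row codon alignment
#'
#' @param a,b Nucleotide strings of equal length divisible by 3, gap-free,
#'   with no stop codons.
#' @return List of class `"codon_alignment"` with `a`, `b`, `n_codons`.
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0, nchar(a) > 0,
            !grepl("-", a, fixed = TRUE), !grepl("-", b, fixed = TRUE))
  cd <- codon_data()
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  if (any(split3(a) %in% cd$stops) || any(split3(b) %in% cd$stops))
    stop("stop codon inside codon alignment")
  structure(list(a = a, b = b, n_codons = nchar(a) / 3),
            class = "codon_alignment")
}

#' Back-translate an aligned protein pair onto its source CDSs
#'
#' Replaces each aligned residue by its source codon and drops every
#' column where either row is gapped, yielding a gap-free codon alignment
#' whose translation reproduces the (pairwise-ungapped) protein alignment.
#' A terminal stop codon on either CDS is tolerated and stripped.
#'
#' @param prot_aln Character vector of 2 aligned (gapped) protein rows.
#' @param cds_a,cds_b The original coding sequences.
#' @return A [codon_alignment()].
#' @export
backtranslate_pair <- function(prot_aln, cds_a, cds_b) {
  stopifnot(length(prot_aln) == 2, nchar(prot_aln[1]) == nchar(prot_aln[2]))
  strip_stop <- function(cds, prot_len) {
    if (nchar(cds) == 3 * (prot_len + 1)) substr(cds, 1, 3 * prot_len)
    else cds
  }
  r1 <- strsplit(prot_aln[1], "")[[1]]
  r2 <- strsplit(prot_aln[2], "")[[1]]
  ung1 <- paste(r1[r1 != "-"], collapse = "")
  ung2 <- paste(r2[r2 != "-"], collapse = "")
  cds_a <- strip_stop(toupper(cds_a), nchar(ung1))
  cds_b <- strip_stop(toupper(cds_b), nchar(ung2))
  for (side in 1:2) {
    cds <- c(cds_a, cds_b)[side]
    prot <- c(ung1, ung2)[side]
    tr <- translate_cds(cds)
    if (!identical(tr, prot)) {
      pos <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stop("CDS ", side, " does not translate to its aligned protein row ",
           "(first mismatch at residue ", pos, ")")
    }
  }
  codon_of <- function(cds) function(i) substr(cds, 3 * i - 2, 3 * i)
  ca <- codon_of(cds_a); cb <- codon_of(cds_b)
  ia <- ib <- 0L
  out_a <- out_b <- character(0)
  for (k in seq_along(r1)) {
    if (r1[k] != "-") ia <- ia + 1L
    if (r2[k] != "-") ib <- ib + 1L
    if (r1[k] != "-" && r2[k] != "-") {
      out_a <- c(out_a, ca(ia))
      out_b <- c(out_b, cb(ib))
    }
  }
  if (!length(out_a)) stop("no ungapped columns to back-translate")
  codon_alignment(paste(out_a, collapse = ""), paste(out_b, collapse = ""))
}

.kaks_result <- function(S, N, Sd, Nd, Ka, Ks, method, kappa_hat = NA_real_,
                         saturated = FALSE) {
  omega <- if (saturated || is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_
           else Ka / Ks
  structure(list(Ka = Ka, Ks = Ks, omega = omega, S = S, N = N,
                 Sd = Sd, Nd = Nd, kappa_hat = kappa_hat, method = method,
                 saturated = saturated,
                 label = classify_selection(omega)),
            class = "kaks_result")
}

.jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# two-parameter (K80-type) correction from transition/transversion
# proportions within one substitution class
.k80_correct <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) return(c(NA_real_, NA_real_))
  c(ts = 0.5 * log(1 / a) - 0.25 * log(1 / b),
    tv = 0.5 * log(1 / b))
}

.split_codons <- function(x) substring(x, seq(1, nchar(x), 3),
                                       seq(3, nchar(x), 3))

#' Nei-Gojobori Ka/Ks (equal-weight counting, Jukes-Cantor correction)
#'
#' Sites are counted per codon as the fraction of non-stop single-base
#' changes that are synonymous; differences are averaged over all shortest
#' mutational pathways (stop-crossing pathways excluded, weights
#' renormalized); proportions are corrected with the one-parameter
#' Jukes-Cantor formula d = -3/4 ln(1 - 4p/3). Proportions >= 3/4 flag
#' the estimate as saturated (value undefined).
#'
#' @param codon_aln A [codon_alignment()].
#' @return List of class `"kaks_result"`: `Ka`, `Ks`, `omega`, `S`, `N`,
#'   `Sd`, `Nd`, `kappa_hat` (NA here), `method`, `saturated`, `label`.
#' @export
kaks_ng86 <- function(codon_aln) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  cd <- codon_data()
  ca <- .split_codons(codon_aln$a)
  cb <- .split_codons(codon_aln$b)
  S <- (sum(vapply(ca, function(x) .codon_sites(x, cd = cd)[["S"]], numeric(1))) +
        sum(vapply(cb, function(x) .codon_sites(x, cd = cd)[["S"]], numeric(1)))) / 2
  N <- 3 * codon_aln$n_codons - S
  diffs <- Reduce(`+`, Map(function(x, y) .codon_diffs(x, y, cd), ca, cb))
  Sd <- diffs[["sd_ts"]] + diffs[["sd_tv"]]
  Nd <- diffs[["nd_ts"]] + diffs[["nd_tv"]]
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- .jc_correct(ps)
  Ka <- .jc_correct(pn)
  .kaks_result(S, N, Sd, Nd, Ka, Ks, "NG86",
               saturated = is.na(Ka) || is.na(Ks))
}

# Degeneracy class of each codon position: 4 if every nucleotide change
# at the position is synonymous, 0 if every change is nonsynonymous,
# 2 otherwise.
.position_degeneracy <- function(codon, cd = codon_data()) {
  nb <- cd$neigh[[codon]]
  vapply(1:3, function(pos) {
    rows <- nb[nb$pos == pos & !nb$stop, , drop = FALSE]
    if (!nrow(rows)) return(0L)
    if (all(rows$syn)) 4L else if (!any(rows$syn)) 0L else 2L
  }, integer(1))
}

# Mutational transition/transversion ratio estimated with the K80 formula
# at sites whose degeneracy class agrees between the two sequences:
# fourfold-degenerate sites see mutation without selection, nondegenerate
# sites see it filtered by a class-independent acceptance, so kappa is
# taken from the fourfold class when it is informative and from the
# nondegenerate class otherwise. Returns 1 when the pair carries no
# information; capped when transversions are absent.
.estimate_kappa <- function(a, b, cap = 15) {
  cd <- codon_data()
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  deg_a <- unlist(lapply(ca, .position_degeneracy, cd = cd))
  deg_b <- unlist(lapply(cb, .position_degeneracy, cd = cd))
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  purine <- function(x) x %in% c("A", "G")
  kappa_at <- function(mask) {
    n <- sum(mask)
    if (n < 10) return(NA_real_)
    diff <- mask & (va != vb)
    if (!any(diff)) return(NA_real_)
    ts <- diff & (purine(va) == purine(vb))
    d <- .k80_correct(sum(ts) / n, sum(diff & !ts) / n)
    if (anyNA(d)) return(cap)
    if (d[["tv"]] <= 0) return(cap)
    max(2 * d[["ts"]] / d[["tv"]], 0.1)
  }
  k4 <- kappa_at(deg_a == 4L & deg_b == 4L)
  if (!is.na(k4)) return(k4)
  k0 <- kappa_at(deg_a == 0L & deg_b == 0L)
  if (!is.na(k0)) return(k0)
  1
}

#' Kappa- and frequency-corrected Ka/Ks (Yang-Nielsen family)
#'
#' Estimates the transition/transversion ratio kappa from the aligned
#' nucleotides with the K80 formula, counts synonymous/nonsynonymous
#' mutational opportunity per codon weighting each possible change by
#' kappa^(transition) times the position-specific target-nucleotide
#' frequency, averages pathway differences with a transition/transversion
#' split, and corrects each class with the two-parameter K80 distance.
#' With kappa = 1 and uniform frequencies the counting collapses to
#' Nei-Gojobori (the correction differs only in its two-parameter form).
#'
#' @param codon_aln A [codon_alignment()].
#' @return A `"kaks_result"` (method `"MYN"`, with `kappa_hat`).
#' @export
kaks_myn <- function(codon_aln) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  cd <- codon_data()
  ca <- .split_codons(codon_aln$a)
  cb <- .split_codons(codon_aln$b)
  kappa <- .estimate_kappa(codon_aln$a, codon_aln$b)
  # position-specific nucleotide frequencies, pooled over the two rows
  nts <- c("A", "C", "G", "T")
  pi <- lapply(1:3, function(pos) {
    obs <- c(substring(ca, pos, pos), substring(cb, pos, pos))
    f <- table(factor(obs, levels = nts))
    p <- as.numeric(f) / sum(f)
    # damp empty cells so weights stay positive
    p <- (p + 1e-3) / sum(p + 1e-3)
    setNames(p, nts)
  })
  S <- (sum(vapply(ca, function(x)
          .codon_sites(x, kappa, pi, cd)[["S"]], numeric(1))) +
        sum(vapply(cb, function(x)
          .codon_sites(x, kappa, pi, cd)[["S"]], numeric(1)))) / 2
  N <- 3 * codon_aln$n_codons - S
  diffs <- Reduce(`+`, Map(function(x, y) .codon_diffs(x, y, cd), ca, cb))
  Sd <- diffs[["sd_ts"]] + diffs[["sd_tv"]]
  Nd <- diffs[["nd_ts"]] + diffs[["nd_tv"]]
  ks_parts <- if (S > 0) .k80_correct(diffs[["sd_ts"]] / S,
                                      diffs[["sd_tv"]] / S) else c(0, 0)
  ka_parts <- if (N > 0) .k80_correct(diffs[["nd_ts"]] / N,
                                      diffs[["nd_tv"]] / N) else c(0, 0)
  Ks <- sum(ks_parts)
  Ka <- sum(ka_parts)
  .kaks_result(S, N, Sd, Nd, Ka, Ks, "MYN", kappa_hat = kappa,
               saturated = anyNA(c(ks_parts, ka_parts)))
}

#' Label the selective regime of an omega value
#'
#' Reference marks omega = 0.3, 1, 3 delimit negative (purifying),
#' neutral, and positive selection: `"purifying"` when omega <= 0.3,
#' `"positive"` when omega >= 3, `"neutral_zone"` between, `"undefined"`
#' for NA (e.g. Ks = 0 or saturation). The marks are attached as an
#' attribute so downstream tables can echo them.
#'
#' @param omega Ka/Ks ratio (may be NA).
#' @return Label string with attribute `marks`.
#' @export
classify_selection <- function(omega) {
  marks <- c(purifying = 0.3, neutral = 1, positive = 3)
  lab <- if (is.null(omega) || length(omega) == 0 || is.na(omega)) "undefined"
         else if (omega <= marks[["purifying"]]) "purifying"
         else if (omega >= marks[["positive"]]) "positive"
         else "neutral_zone"
  structure(lab, marks = marks)
}

#' One-way ANOVA on omega values grouped by strain
#'
#' Standard between/within sum-of-squares decomposition with the upper
#' F tail for the p-value. Degenerate inputs where every observation is
#' identical give F = 0, p = 1 by convention.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations).
#' @return List of class `"anova_result"`: `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `group_sds`, `pooled_sd`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 2))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  pooled_sd <- sqrt(ssw / dfw)
  if (ssw == 0) {
    if (ssb <= 1e-300) {
      F <- 0; p <- 1
    } else {
      F <- Inf; p <- 0
    }
  } else {
    F <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(F, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(F = F, df_between = dfb, df_within = dfw, p = p,
                 group_means = means, group_sds = sds,
                 pooled_sd = pooled_sd),
            class = "anova_result")
}
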