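# GY94-style codon substitution process used by the genome simulator: the
# instantaneous rate from codon i to j is nonzero only for single-
# nucleotide changes and proportional to pi_j * kappa^(transition) *
# omega^(nonsynonymous); stop codons are inaccessible. The generator is
# normalized so branch lengths are expected substitutions per codon site.

.codon_pairs_cache <- new.env(parent = emptyenv())

# sense-codon single-nucleotide neighbour triplets (precomputed once)
.codon_pairs <- function() {
  if (!is.null(.codon_pairs_cache$p)) return(.codon_pairs_cache$p)
  cd <- codon_data()
  sense <- cd$sense
  idx <- setNames(seq_along(sense), sense)
  rows <- list()
  for (c1 in sense) {
    nb <- cd$neigh[[c1]]
    nb <- nb[!nb$stop, , drop = FALSE]
    rows[[c1]] <- data.frame(i = idx[[c1]], j = idx[nb$to],
                             ts = nb$ts, syn = nb$syn,
                             target_nt = nb$target_nt,
                             stringsAsFactors = FALSE)
  }
  .codon_pairs_cache$p <- do.call(rbind, rows)
  .codon_pairs_cache$p
}

#' Equilibrium codon frequencies with optional GC bias
#'
#' Codon frequencies proportional to the product of per-position
#' nucleotide frequencies with the given GC content, restricted and
#' renormalized over the 61 sense codons. `gc = 0.5` gives the uniform
#' default; higher values mimic high-GC genomes.
#'
#' @param gc GC content in (0, 1).
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
codon_freqs <- function(gc = 0.5) {
  stopifnot(gc > 0, gc < 1)
  cd <- codon_data()
  ntp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p <- vapply(cd$sense, function(cdn) {
    v <- strsplit(cdn, "")[[1]]
    prod(ntp[v])
  }, numeric(1))
  p / sum(p)
}

#' Build a normalized GY94-style codon rate model
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Sense-codon frequencies (default uniform); see
#'   [codon_freqs()].
#' @return List of class `"codon_model"`: `codons`, `pi`, `rates` (total
#'   leaving rate per codon), `jump_cum` (cumulative jump distribution per
#'   row), `Q` (61 x 61 generator, normalized to one expected
#'   substitution per codon site).
#' @export
codon_model <- function(kappa = 2, omega = 0.2, pi = NULL) {
  stopifnot(kappa > 0, omega >= 0)
  cd <- codon_data()
  n <- length(cd$sense)
  if (is.null(pi)) pi <- setNames(rep(1 / n, n), cd$sense)
  pi <- pi[cd$sense] / sum(pi)
  pr <- .codon_pairs()
  w <- pi[pr$j] * ifelse(pr$ts, kappa, 1) * ifelse(pr$syn, 1, omega)
  Q <- matrix(0, n, n, dimnames = list(cd$sense, cd$sense))
  Q[cbind(pr$i, pr$j)] <- w
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate codon model (no substitutions possible)")
  Q <- Q / mu
  rates <- -diag(Q)
  jump <- Q
  diag(jump) <- 0
  jump <- jump / ifelse(rates > 0, rates, 1)
  structure(list(codons = cd$sense, pi = pi, rates = rates,
                 jump_cum = t(apply(jump, 1, cumsum)), Q = Q),
            class = "codon_model")
}

#' Draw a random stop-free CDS from codon equilibrium frequencies
#'
#' @param n_codons Number of codons.
#' @param pi Sense-codon frequencies (default uniform).
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, pi = NULL) {
  cd <- codon_data()
  if (is.null(pi)) pi <- rep(1 / length(cd$sense), length(cd$sense))
  paste(sample(cd$sense, n_codons, replace = TRUE, prob = pi), collapse = "")
}

#' Evolve a CDS along a branch under the codon model
#'
#' Exact event-by-event (Gillespie) simulation per codon site:
#' exponential waiting times at the codon's total leaving rate, jumps
#' drawn from the embedded chain. The expected number of substitutions
#' per codon site over the branch equals `t` under the normalized
#' generator.
#'
#' @param seq Stop-free CDS (length divisible by 3).
#' @param t Branch length in expected substitutions per codon site (>= 0).
#' @param kappa,omega,pi Model parameters (ignored when `model` given).
#' @param seed Optional integer seed for reproducibility.
#' @param model Optional prebuilt [codon_model()].
#' @return The evolved CDS (same length).
#' @export
evolve_codon_seq <- function(seq, t, kappa = 2, omega = 0.2, pi = NULL,
                             seed = NULL, model = NULL) {
  stopifnot(t >= 0, nchar(seq) %% 3 == 0)
  if (!is.null(seed)) set.seed(seed)
  if (t == 0) return(seq)
  if (is.null(model)) model <- codon_model(kappa, omega, pi)
  codons <- .split_codons(toupper(seq))
  state <- match(codons, model$codons)
  if (anyNA(state)) stop("sequence contains stop or invalid codon(s)")
  state <- evolve_states(state, model$rates, model$jump_cum, t)
  paste(model$codons[state], collapse = "")
}
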