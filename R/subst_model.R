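# Empirical amino-acid substitution model machinery. The rate matrix is
# built from symmetric exchangeabilities and stationary frequencies
# (general time-reversible form), normalized to one expected substitution
# per site, and diagonalized once through the pi^(1/2) symmetrization so
# transition probability matrices are cheap to evaluate at any branch
# length.

#' Build the WAG amino-acid substitution model
#'
#' Constructs the reversible rate matrix Q with Q_ij = s_ij * pi_j from
#' the published WAG exchangeabilities and frequencies, scales it to one
#' expected substitution per site, and precomputes its eigensystem.
#'
#' @param freqs Optional stationary frequencies (named by residue in
#'   ARNDCQEGHILKMFPSTWYV order); defaults to the WAG frequencies.
#' @return Object of class `"subst_model"` with fields `states`, `pi`,
#'   `Q`, and the eigendecomposition used by [prob_matrix()].
#' @export
wag_model <- function(freqs = NULL) {
  states <- WAG_ORDER
  pi <- if (is.null(freqs)) WAG_FREQS else unname(freqs[states])
  pi <- pi / sum(pi)
  S <- matrix(0, 20, 20, dimnames = list(states, states))
  S[lower.tri(S)] <- WAG_EXCH_LOWER
  S <- S + t(S)
  Q <- S * rep(pi, each = 20)      # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))         # expected substitutions per site
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * Q       # symmetric under reversibility
  B <- (B + t(B)) / 2              # clean numerical asymmetry
  eig <- eigen(B, symmetric = TRUE)
  structure(list(states = states, pi = pi, Q = Q,
                 values = eig$values,
                 V1 = (1 / sq) * eig$vectors,       # diag(1/sq) %*% U
                 V2 = t(eig$vectors * sq)),         # t(U) %*% diag(sq)
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [wag_model()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 20 x 20 probability matrix (rows sum to 1).
#' @export
prob_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$V1 %*% (exp(model$values * t) * model$V2)
  P[P < 0] <- 0                    # clip tiny negative round-off
  P
}
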