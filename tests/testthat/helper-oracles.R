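# Independent oracles and fixture builders shared across the test files.
# Each oracle deliberately uses a different algorithm than the package
# implementation it checks.

# ---- brute-force global affine alignment score ----
# Enumerates every global alignment as a sequence of columns (match,
# gap-in-b consuming a, gap-in-a consuming b) and scores it directly,
# with a gap run of length k costing open + k * ext. No memoization: the
# recursion explores the full alignment tree, so it is only usable for
# short sequences.
enum_align_score <- function(a, b, submat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      recurse(i + 1, j + 1, score + submat[av[i], bv[j]], "m")
    if (i <= length(av)) {
      cost <- gap_ext + if (last == "x") 0 else gap_open
      recurse(i + 1, j, score - cost, "x")
    }
    if (j <= length(bv)) {
      cost <- gap_ext + if (last == "y") 0 else gap_open
      recurse(i, j + 1, score - cost, "y")
    }
  }
  recurse(1L, 1L, 0, "none")
  best
}

# ---- brute-force quartet likelihood ----
# Sums the joint probability over the two internal nodes' 400 state
# pairs per site. Transition matrices come from a truncated series for
# exp(Qt), independent of the eigendecomposition in the package.
series_pmat <- function(Q, t, terms = 120) {
  Q <- unname(Q)
  n <- nrow(Q)
  P <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% (Q * t) / k
    P <- P + term
  }
  unname(P)
}

brute_quartet_loglik <- function(msa, topology, bl, model,
                                 root = 1L) {
  top <- genedup:::QUARTET_TOPOLOGIES[[topology]]
  states <- model$states
  enc <- lapply(strsplit(msa, ""), function(v) match(v, states))
  n_sites <- length(enc[[1]])
  P <- lapply(bl, function(t) series_pmat(model$Q, t))
  leaf_lik <- function(leaf, x, s) {
    obs <- enc[[leaf]][s]
    if (is.na(obs)) 1 else P[[leaf]][x, obs]
  }
  ll <- 0
  for (s in seq_len(n_sites)) {
    if (all(is.na(c(enc[[1]][s], enc[[2]][s], enc[[3]][s], enc[[4]][s]))))
      next
    tot <- 0
    for (x in 1:20) for (y in 1:20) {
      l1 <- leaf_lik(top$pair1[1], x, s) * leaf_lik(top$pair1[2], x, s)
      l2 <- leaf_lik(top$pair2[1], y, s) * leaf_lik(top$pair2[2], y, s)
      # root at internal node 1 or 2; the pulley principle makes both equal
      pr <- if (root == 1L) unname(model$pi[x]) * P[[5]][x, y]
            else unname(model$pi[y]) * P[[5]][y, x]
      tot <- tot + pr * l1 * l2
    }
    ll <- ll + log(tot)
  }
  ll
}

# ---- regularized upper incomplete gamma (chi-square tail) ----
# Series for the lower regularized gamma when x < a + 1, continued
# fraction for the upper otherwise (Numerical-Recipes style).
gamma_upper_reg <- function(x, a, tol = 1e-14, itmax = 500) {
  if (x <= 0) return(1)
  if (x < a + 1) {
    ap <- a
    s <- 1 / a
    del <- s
    for (i in seq_len(itmax)) {
      ap <- ap + 1
      del <- del * x / ap
      s <- s + del
      if (abs(del) < abs(s) * tol) break
    }
    return(1 - s * exp(-x + a * log(x) - lgamma(a)))
  }
  b <- x + 1 - a
  c <- 1e300
  d <- 1 / b
  h <- d
  for (i in seq_len(itmax)) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b
    if (abs(d) < 1e-300) d <- 1e-300
    c <- b + an / c
    if (abs(c) < 1e-300) c <- 1e-300
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < tol) break
  }
  exp(-x + a * log(x) - lgamma(a)) * h
}

chi2_sf_oracle <- function(x, df) gamma_upper_reg(x / 2, df / 2)

# ---- fixture builders ----
random_protein <- function(n, alphabet = genedup:::WAG_ORDER)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# hand-built multi-replicon bundle with valid CDS/protein records
make_test_bundle <- function(strain = "test",
                             cds = c(g1 = "ATGGCTAAA", g2 = "ATGGCTAAA",
                                     g3 = "ATGTGTTGT"),
                             replicon = c("CI", "CII", "pA"),
                             replicon_class = c("chromosome", "chromosome",
                                                "plasmid"),
                             cogs = c("C", "CG", "")) {
  n <- length(cds)
  genes <- data.frame(
    locus_tag = names(cds), strain = strain,
    replicon_id = replicon[seq_len(n)],
    replicon_class = replicon_class[seq_len(n)],
    start = rep(101L, n), end = 100L + nchar(cds),
    strand = rep("+", n), cogs = cogs[seq_len(n)],
    protein_seq = vapply(cds, genedup::translate_cds, character(1),
                         USE.NAMES = FALSE),
    cds_seq = unname(cds), stringsAsFactors = FALSE)
  reps <- data.frame(replicon_id = c("CI", "CII", "pA"),
                     class = c("chromosome", "chromosome", "plasmid"),
                     length = c(20000L, 10000L, 5000L),
                     stringsAsFactors = FALSE)
  genome_bundle(strain, reps, genes)
}

# bundle holding families with prescribed copy numbers, built from
# near-identical sequence copies so every within-family pair is a
# reciprocal hit and across-family pairs are unrelated
make_family_bundle <- function(copy_numbers, n_codons = 120, seed = 1) {
  set.seed(seed)
  cds <- character(0)
  fam_of <- character(0)
  for (f in seq_along(copy_numbers)) {
    anc <- random_cds(n_codons)
    for (k in seq_len(copy_numbers[f])) {
      nm <- sprintf("f%02dc%d", f, k)
      cds[nm] <- evolve_codon_seq(anc, 0.02, kappa = 2, omega = 0.5)
      fam_of[nm] <- sprintf("f%02d", f)
    }
  }
  n <- length(cds)
  genes <- data.frame(
    locus_tag = names(cds), strain = "fams", replicon_id = "CI",
    replicon_class = "chromosome",
    start = seq(1L, by = 1000L, length.out = n),
    end = seq(1L, by = 1000L, length.out = n) + nchar(cds) - 1L,
    strand = "+", cogs = "",
    protein_seq = vapply(cds, genedup::translate_cds, character(1),
                         USE.NAMES = FALSE),
    cds_seq = unname(cds), stringsAsFactors = FALSE)
  reps <- data.frame(replicon_id = "CI", class = "chromosome",
                     length = max(genes$end) + 1000L,
                     stringsAsFactors = FALSE)
  list(bundle = genome_bundle("fams", reps, genes), family = fam_of)
}

# simulate the four sequences of a quartet with known age class, using
# the same event times as the cohort simulator defaults
sim_quartet_seqs <- function(type, n_codons = 300, omega = 0.13,
                             kappa = 2) {
  ev <- function(s, t) evolve_codon_seq(s, t, kappa = kappa, omega = omega)
  anc <- random_cds(n_codons)
  if (type == "A") {
    c1 <- ev(anc, 0.1); c2 <- ev(anc, 0.1)
    c1 <- ev(c1, 0.2); c2 <- ev(c2, 0.2)
    seqs <- c(P1 = ev(c1, 0.3), P2 = ev(c2, 0.3),
              O1 = ev(c1, 0.3), O2 = ev(c2, 0.3))
  } else {
    b <- ev(anc, 0.2)
    o1 <- ev(b, 0.3)
    o2 <- ev(anc, 0.5)
    c0 <- ev(b, 0.15)
    seqs <- c(P1 = ev(c0, 0.15), P2 = ev(c0, 0.15), O1 = o1, O2 = o2)
  }
  vapply(seqs, genedup::translate_cds, character(1))
}

# simulate one codon-aligned pair at total divergence t and given omega
sim_codon_pair <- function(omega, t = 0.4, kappa = 2, n_codons = 300) {
  anc <- random_cds(n_codons)
  a <- evolve_codon_seq(anc, t / 2, kappa = kappa, omega = omega)
  b <- evolve_codon_seq(anc, t / 2, kappa = kappa, omega = omega)
  codon_alignment(a, b)
}
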