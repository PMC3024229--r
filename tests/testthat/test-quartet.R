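test_that("the WAG model is a valid normalized reversible generator", {
  m <- wag_model()
  expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji
  flux <- m$pi * m$Q
  expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-12)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  P <- prob_matrix(m, 0.7)
  expect_equal(range(rowSums(P)), c(1, 1), tolerance = 1e-10)
  expect_true(all(P >= 0))
  # P(t) converges to the stationary distribution
  expect_equal(unname(prob_matrix(m, 500)[1, ]), unname(m$pi),
               tolerance = 1e-8)
})

test_that("quartet likelihood matches degenerate limits and brute force", {
  m <- wag_model()
  # identical sequences, zero branch lengths: logL = sum log pi(state)
  s <- "ARNDC"
  msa <- rep(s, 4)
  ll <- quartet_loglik(msa, "TB", rep(0, 5), m)
  expect_equal(ll, sum(log(m$pi[1:5])), tolerance = 1e-9)

  set.seed(21)
  for (i in 1:5) {
    msa2 <- vapply(1:4, function(k) random_protein(2), character(1))
    bl <- runif(5, 0.05, 1.5)
    for (tp in c("TA1", "TA2", "TB")) {
      ll_fast <- quartet_loglik(msa2, tp, bl, m)
      expect_equal(ll_fast, brute_quartet_loglik(msa2, tp, bl, m),
                   tolerance = 1e-8)
      # pulley principle: rooting at the other internal node is identical
      expect_equal(ll_fast,
                   brute_quartet_loglik(msa2, tp, bl, m, root = 2L),
                   tolerance = 1e-8)
    }
  }
})

test_that("gap columns are treated as missing data", {
  m <- wag_model()
  msa <- c("AR-", "AR-", "ARA", "ARC")
  expect_silent(ll <- quartet_loglik(msa, "TB", rep(0.1, 5), m))
  # marginalizing the gap leaves cannot beat observing them
  expect_true(is.finite(ll))
  expect_warning(quartet_loglik(c("A-", "A-", "A-", "A-"), "TB",
                                rep(0.1, 5), m), "all-gap")
})

test_that("fitting recovers simulated topologies and breaks ties deterministically", {
  m <- wag_model()
  set.seed(77)
  msa_a <- align_quartet(sim_quartet_seqs("A"))
  fit_a <- fit_quartet(msa_a, m)
  expect_identical(fit_a$call, "TypeA")
  # reported topology is the likelihood winner
  expect_true(all(fit_a$logL >= fit_a$logL_all - 1e-6))
  # optimized branch lengths are at a local maximum
  for (br in 1:5) {
    for (eps in c(-1e-3, 1e-3)) {
      bl <- fit_a$branch_lengths
      bl[br] <- min(max(bl[br] + eps, 1e-8), 10)
      expect_lte(quartet_loglik(msa_a, fit_a$topology, bl, m),
                 fit_a$logL + 1e-6)
    }
  }

  msa_b <- align_quartet(sim_quartet_seqs("B"))
  fit_b <- fit_quartet(msa_b, m)
  expect_identical(fit_b$call, "TypeB")
  expect_identical(classify_topology(fit_b), "TypeB")

  # four identical sequences: all topologies tie; the deterministic
  # preference order reports a Type-A topology and flags the tie
  tied <- fit_quartet(rep(strrep("ARNDCQEGHI", 3), 4), m)
  expect_true(tied$tie)
  expect_identical(tied$topology, "TA1")
  expect_identical(tied$call, "TypeA")
})

test_that("bootstrap support is reproducible and sensible", {
  m <- wag_model()
  set.seed(13)
  msa <- align_quartet(sim_quartet_seqs("B"))
  fit <- fit_quartet(msa, m)
  s1 <- bootstrap_support(msa, m, n = 10, seed = 5, full_fit = fit)
  s2 <- bootstrap_support(msa, m, n = 10, seed = 5, full_fit = fit)
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 <= 100)
  s_one <- bootstrap_support(msa, m, n = 1, seed = 9, full_fit = fit)
  expect_true(s_one %in% c(0L, 100L))
})

test_that("a strongly divergent quartet gets near-unanimous support", {
  m <- wag_model()
  set.seed(2024)
  # long internal branch: deep pre-speciation duplication
  ev <- function(s, t) evolve_codon_seq(s, t, kappa = 2, omega = 0.5)
  anc <- random_cds(300)
  c1 <- ev(anc, 0.5); c2 <- ev(anc, 0.5)
  seqs <- vapply(c(P1 = ev(c1, 0.15), P2 = ev(c2, 0.15),
                   O1 = ev(c1, 0.15), O2 = ev(c2, 0.15)),
                 translate_cds, character(1))
  msa <- align_quartet(seqs)
  fit <- fit_quartet(msa, m)
  expect_identical(fit$call, "TypeA")
  expect_gte(bootstrap_support(msa, m, n = 100, seed = 3, full_fit = fit),
             95)
})

test_that("ortholog selection applies the shared-best tie-break", {
  set.seed(55)
  co <- simulate_cohort(sim_config(n_families = 8, seed = 55))
  truth <- co$truth[co$truth$duplicated, ]
  pairs <- data.frame(gene_a = truth$locus_a, gene_b = truth$locus_b,
                      stringsAsFactors = FALSE)
  a_rows <- truth$type == "A"
  chA <- select_orthologs(pairs[which(a_rows)[1], ], co$focal,
                          co$ortholog_db)
  expect_identical(chA$status, "ok")
  # pre-speciation families have distinct per-copy orthologs in X
  expect_false(chA$same_best_resolved)
  expect_true(chA$ortholog_a$id != chA$ortholog_b$id)

  if (any(!a_rows)) {
    chB <- select_orthologs(pairs[which(!a_rows)[1], ], co$focal,
                            co$ortholog_db)
    expect_identical(chB$status, "ok")
    # post-speciation paralogs share their best match in species X, so
    # the weaker one must take the next-best distinct ortholog
    expect_true(chB$same_best_resolved)
    expect_true(chB$ortholog_a$id != chB$ortholog_b$id)
    expect_setequal(c(chB$ortholog_a$species, chB$ortholog_b$species),
                    c("X", "Y"))
  }

  # an empty database is unresolvable, not an error
  empty_db <- co$ortholog_db
  empty_db$genes <- empty_db$genes[0, ]
  expect_identical(select_orthologs(pairs[1, ], co$focal, empty_db)$status,
                   "unresolvable")
  # thresholds nothing can meet are likewise unresolvable
  expect_identical(
    select_orthologs(pairs[1, ], co$focal, co$ortholog_db,
                     homology_thresholds(id_min = 101))$status,
    "unresolvable")
})

test_that("progressive quartet alignment round-trips its inputs", {
  set.seed(66)
  s <- random_protein(40)
  msa_id <- align_quartet(setNames(rep(s, 4), paste0("s", 1:4)))
  expect_false(any(grepl("-", msa_id, fixed = TRUE)))

  # substitution+truncation inputs: rows ungap back to the inputs and
  # columns cover the longest input
  seqs <- c(a = random_protein(30), b = random_protein(34),
            c = random_protein(28), d = random_protein(31))
  msa <- align_quartet(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_gte(nchar(msa[1]), max(nchar(seqs)))
  for (k in 1:4)
    expect_identical(unname(gsub("-", "", msa[k], fixed = TRUE)),
                     unname(seqs[k]))
})

test_that("progressive alignment is no worse than random gap placements", {
  # sum-of-pairs score with affine gaps, scored column-wise per row pair
  sp_score <- function(msa, scheme = align_scheme()) {
    B <- scheme$matrix
    rows <- strsplit(msa, "")
    total <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      a <- rows[[i]]; b <- rows[[j]]
      keep <- !(a == "-" & b == "-")
      a <- a[keep]; b <- b[keep]
      run <- "none"
      for (k in seq_along(a)) {
        if (a[k] == "-" || b[k] == "-") {
          gap_side <- if (a[k] == "-") "a" else "b"
          total <- total - scheme$gap_ext -
            (if (run == gap_side) 0 else scheme$gap_open)
          run <- gap_side
        } else {
          total <- total + B[a[k], b[k]]
          run <- "none"
        }
      }
    }
    total
  }
  random_msa <- function(seqs, width) {
    vapply(seqs, function(s) {
      v <- strsplit(s, "")[[1]]
      slots <- sort(sample(width, length(v)))
      out <- rep("-", width)
      out[slots] <- v
      paste(out, collapse = "")
    }, character(1))
  }
  set.seed(31)
  for (rep in 1:3) {
    seqs <- vapply(sample(5:8, 4, replace = TRUE), random_protein,
                   character(1))
    msa <- align_quartet(seqs)
    ours <- sp_score(msa)
    width <- max(nchar(seqs)) + 2
    rand_best <- max(vapply(1:50, function(i)
      sp_score(random_msa(seqs, width)), numeric(1)))
    expect_gte(ours, rand_best)
  }
})

test_that("topology labels map onto the Type-A/Type-B calls", {
  for (tp in c("TA1", "TA2")) {
    r <- structure(list(topology = tp), class = "quartet_result")
    expect_identical(classify_topology(r), "TypeA")
  }
  r <- structure(list(topology = "TB"), class = "quartet_result")
  expect_identical(classify_topology(r), "TypeB")
})

test_that("newick output carries the fitted branch lengths", {
  r <- structure(list(topology = "TB",
                      branch_lengths = c(0.1, 0.2, 0.3, 0.4, 0.5)),
                 class = "quartet_result")
  nwk <- quartet_newick(r, c("p1", "p2", "o1", "o2"))
  expect_match(nwk, "^\\(\\(p1:0.100000,p2:0.200000\\):0.500000,")
  expect_match(nwk, "o1:0.300000")
  expect_match(nwk, ";$")
})
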