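test_that("the codon model is a valid normalized generator", {
  m <- codon_model(kappa = 2, omega = 0.2)
  expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  # stationarity of the equilibrium frequencies
  expect_equal(max(abs(m$pi %*% m$Q)), 0, tolerance = 1e-12)
  # stop codons are absent from the state space
  expect_false(any(c("TAA", "TAG", "TGA") %in% m$codons))
  expect_equal(length(m$codons), 61L)

  # GC bias shifts codon frequencies as requested
  f <- codon_freqs(0.7)
  expect_equal(sum(f), 1)
  expect_gt(f[["GGG"]], f[["AAA"]])
})

test_that("codon evolution respects its degenerate limits", {
  set.seed(12)
  s <- random_cds(100)
  expect_identical(evolve_codon_seq(s, 0), s)

  # omega = 0: no accepted change is nonsynonymous
  s2 <- evolve_codon_seq(s, 2, kappa = 2, omega = 0, seed = 4)
  expect_false(identical(s2, s))   # synonymous changes did occur
  expect_identical(translate_cds(s2), translate_cds(s))

  # same seed, same trajectory
  expect_identical(evolve_codon_seq(s, 0.5, seed = 11),
                   evolve_codon_seq(s, 0.5, seed = 11))

  # expected substitutions per codon site ~ t under the normalized
  # generator: estimate total divergence with the counting method
  set.seed(8)
  m <- codon_model(2, 1)   # neutral: realized changes trace the clock
  anc <- random_cds(500)
  der <- evolve_codon_seq(anc, 0.3, model = m)
  r <- kaks_ng86(codon_alignment(anc, der))
  d_tot <- (r$Ka * r$N + r$Ks * r$S) / (r$N + r$S) * 3  # per codon
  expect_lt(abs(d_tot - 0.3), 0.08)
})

test_that("cohorts are reproducible and structurally consistent", {
  cfg <- sim_config(n_families = 8, seed = 17)
  co <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co, co2)

  # truth loci exist in the focal bundle
  truth <- co$truth
  expect_true(all(truth$locus_a %in% co$focal$genes$locus_tag))
  dup <- truth[truth$duplicated, ]
  expect_true(all(dup$locus_b %in% co$focal$genes$locus_tag))
  # per-strain retention counts match the strain bundles
  for (i in seq_len(nrow(dup))) {
    fam_loci <- c(dup$locus_a[i], dup$locus_b[i])
    for (s in c("strainA", "strainB", "strainC")) {
      tag <- sub("strain", "S", s)  # SA/SB/SC locus prefixes
      retained <- dup[[paste0(s, "_retained")]][i]
      present <- sum(sub("^F_", "", fam_loci) %in%
                       sub(paste0("^", substr(tag, 1, 2), "_"), "",
                           co$strains[[s]]$genes$locus_tag))
      expect_equal(present, retained)
    }
  }
  # written cohorts round-trip and are byte-stable
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co2, d2)
  expect_identical(readLines(file.path(d1, "focal", "genes.tsv")),
                   readLines(file.path(d2, "focal", "genes.tsv")))
  focal2 <- read_bundle(file.path(d1, "focal"))
  expect_identical(focal2$genes$cds_seq, co$focal$genes$cds_seq)
})

test_that("age-class structure follows the configuration", {
  co_a <- simulate_cohort(sim_config(n_families = 10, p_pre = 1,
                                     seed = 3))
  expect_true(all(co_a$truth$type[co_a$truth$duplicated] == "A"))

  co_b <- simulate_cohort(sim_config(n_families = 10, p_pre = 0,
                                     seed = 3))
  expect_true(all(co_b$truth$type[co_b$truth$duplicated] == "B"))

  # no copy loss: every strain retains both copies of every pair
  co_k <- simulate_cohort(sim_config(n_families = 10, p_loss = 0,
                                     seed = 9))
  dup <- co_k$truth[co_k$truth$duplicated, ]
  expect_true(all(dup$strainA_retained == 2 & dup$strainB_retained == 2 &
                    dup$strainC_retained == 2))
})
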