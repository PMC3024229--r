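test_that("back-translation maps aligned residues onto source codons", {
  # gap-free identical proteins: full-length codon alignment
  cds <- "ATGGCTAAACCG"
  aln <- backtranslate_pair(c("MAKP", "MAKP"), cds, cds)
  expect_equal(aln$n_codons, 4)
  expect_identical(aln$a, cds)

  # one gap column drops one codon from each row
  aln2 <- backtranslate_pair(c("MAKP", "MA-P"), "ATGGCTAAACCG",
                             "ATGGCTCCG")
  expect_equal(aln2$n_codons, 3)
  expect_identical(aln2$a, "ATGGCTCCG")
  expect_identical(aln2$b, "ATGGCTCCG")

  # a terminal stop codon on the CDS is tolerated
  aln3 <- backtranslate_pair(c("MA", "MA"), "ATGGCTTAA", "ATGGCT")
  expect_equal(aln3$n_codons, 2)

  # a CDS that does not translate to its row is an error naming the
  # position
  expect_error(backtranslate_pair(c("MAKP", "MAKP"), "ATGGCTAAACCG",
                                  "ATGGCTCGGCCG"), "mismatch at residue 3")
})

test_that("Nei-Gojobori counting matches hand-checked codon cases", {
  # identical sequences
  r0 <- kaks_ng86(codon_alignment("ATGGCT", "ATGGCT"))
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$omega))
  expect_identical(as.character(r0$label), "undefined")
  expect_equal(r0$S + r0$N, 6)  # 3 sites per codon

  # TTA -> TTG: both leucine, purely synonymous. One difference over
  # well under one synonymous site exceeds the correctable range, so Ks
  # is flagged saturated on this single-codon toy
  r1 <- kaks_ng86(codon_alignment("TTA", "TTG"))
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$Ka, 0)
  expect_true(r1$saturated)

  # over a longer synonymous-only alignment Ks is finite and Ka stays 0
  ca <- rep(c("TTA", "GGC"), 15)
  cb <- ca
  cb[c(1, 5, 9)] <- "TTG"
  r1b <- kaks_ng86(codon_alignment(paste(ca, collapse = ""),
                                   paste(cb, collapse = "")))
  expect_equal(r1b$Sd, 3)
  expect_equal(r1b$Nd, 0)
  expect_equal(r1b$Ka, 0)
  expect_gt(r1b$Ks, 0)

  # AAA -> AGA: Lys -> Arg, purely nonsynonymous; omega undefined at
  # Ks = 0
  r2 <- kaks_ng86(codon_alignment("AAA", "AGA"))
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  expect_equal(r2$Ks, 0)
  expect_gt(r2$Ka, 0)
  expect_true(is.na(r2$omega))
})

test_that("pathway averaging conserves the number of differences", {
  cd <- genedup:::codon_data()
  set.seed(17)
  sense <- cd$sense
  for (i in 1:40) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    d <- genedup:::.codon_diffs(c1, c2, cd)
    ndiff <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(sum(d), ndiff, tolerance = 1e-12)
  }
})

test_that("saturation is flagged undefined rather than extrapolated", {
  # force an extreme proportion with a tiny alignment of repeated
  # synonymous differences: p >= 3/4 is unreachable for Ks here, so use
  # the correction directly
  expect_true(is.na(genedup:::.jc_correct(0.75)))
  expect_true(is.na(genedup:::.jc_correct(0.9)))
  expect_equal(genedup:::.jc_correct(0), 0)
})

test_that("the kappa-corrected method collapses to Nei-Gojobori at kappa 1", {
  set.seed(23)
  rel_err <- function(x, y) abs(x - y) / pmax(abs(y), 1e-12)
  ka_err <- ks_err <- numeric(0)
  for (i in 1:15) {
    aln <- sim_codon_pair(omega = 0.3, t = 0.4, kappa = 1)
    ng <- kaks_ng86(aln)
    my <- kaks_myn(aln)
    ka_err <- c(ka_err, rel_err(my$Ka, ng$Ka))
    ks_err <- c(ks_err, rel_err(my$Ks, ng$Ks))
  }
  expect_lt(mean(ka_err), 0.05)
  expect_lt(mean(ks_err), 0.05)
})

test_that("kappa-corrected estimates recover a purifying omega", {
  set.seed(29)
  om <- vapply(1:30, function(i) kaks_myn(sim_codon_pair(0.13))$omega,
               numeric(1))
  expect_lt(abs(mean(om, na.rm = TRUE) - 0.13), 0.04)
  kap <- kaks_myn(sim_codon_pair(0.13))$kappa_hat
  expect_gt(kap, 1)
})

test_that("selection labels use the omega = 0.3 / 1 / 3 reference marks", {
  expect_identical(as.character(classify_selection(0.13)), "purifying")
  expect_identical(as.character(classify_selection(0.3)), "purifying")
  expect_identical(as.character(classify_selection(1)), "neutral_zone")
  expect_identical(as.character(classify_selection(2.99)), "neutral_zone")
  expect_identical(as.character(classify_selection(3)), "positive")
  expect_identical(as.character(classify_selection(5)), "positive")
  expect_identical(as.character(classify_selection(NA)), "undefined")
  expect_equal(unname(attr(classify_selection(0.5), "marks")),
               c(0.3, 1, 3))
})

test_that("one-way ANOVA matches its closed-form identities", {
  # identical groups: no between-group variance at all
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- anova_oneway(g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  # two groups: F equals the square of the pooled-variance t statistic
  x <- c(0.10, 0.15, 0.12)
  y <- c(0.13, 0.18, 0.16, 0.20)
  r2 <- anova_oneway(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  # agreement with the standard fit
  ow <- stats::oneway.test(v ~ g,
                           data = data.frame(v = c(x, y),
                                             g = rep(c("x", "y"),
                                                     c(3, 4))),
                           var.equal = TRUE)
  expect_equal(r2$F, unname(ow$statistic), tolerance = 1e-12)

  # invariance to adding a constant
  r3 <- anova_oneway(list(x = x + 7, y = y + 7))
  expect_equal(r3$F, r2$F, tolerance = 1e-10)
  expect_equal(r3$p, r2$p, tolerance = 1e-10)

  # group summaries
  expect_equal(unname(r2$group_means), c(mean(x), mean(y)))
  expect_equal(r2$pooled_sd,
               sqrt((2 * var(x) + 3 * var(y)) / 5), tolerance = 1e-12)
  expect_error(anova_oneway(list(a = 1:3)))
  expect_error(anova_oneway(list(a = 1:3, b = 2)))
})
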