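test_that("all-vs-all search keeps exact duplicates and drops noise", {
  set.seed(3)
  dup <- random_cds(150)
  fb <- make_family_bundle(c(2))
  hits <- all_vs_all(fb$bundle)
  # both directed hits present for the planted near-identical pair
  expect_setequal(paste(hits$query, hits$subject),
                  c("f01c1 f01c2", "f01c2 f01c1"))
  expect_true(all(hits$percent_identity > 90))

  # unrelated random proteins yield nothing
  set.seed(4)
  cds <- setNames(replicate(3, random_cds(120)), c("a", "b", "c"))
  b <- make_test_bundle(cds = cds, replicon = rep("CI", 3),
                        replicon_class = rep("chromosome", 3),
                        cogs = rep("", 3))
  expect_equal(nrow(all_vs_all(b)), 0)

  # an unsatisfiable identity threshold empties the hit list
  expect_equal(nrow(all_vs_all(fb$bundle,
                               homology_thresholds(id_min = 101))), 0)
})

test_that("families are connected components of the reciprocal graph", {
  hits2 <- data.frame(query = c("a", "b"), subject = c("b", "a"),
                      score = 1, aligned_cols = 1L, identities = 1L,
                      percent_identity = 100, evalue = 0,
                      query_len = 1L, subject_len = 1L)
  f <- build_families(hits2)
  expect_length(f$families, 1)
  expect_identical(f$families[[1]], c("a", "b"))
  expect_identical(f$histogram,
                   c(`2` = 1L, `3` = 0L, `4` = 0L, `5+` = 0L))

  # a chain a<->b, b<->c merges into one 3-member component even though
  # a and c are not directly reciprocal
  chain <- do.call(rbind, lapply(list(c("a", "b"), c("b", "a"),
                                      c("b", "c"), c("c", "b")),
                                 function(p) data.frame(
    query = p[1], subject = p[2], score = 1, aligned_cols = 1L,
    identities = 1L, percent_identity = 100, evalue = 0,
    query_len = 1L, subject_len = 1L)))
  f3 <- build_families(chain)
  expect_length(f3$families, 1)
  expect_identical(f3$families[[1]], c("a", "b", "c"))

  # a one-directional hit contributes no edge
  oneway <- chain[1, ]
  expect_length(build_families(oneway)$families, 0)
})

test_that("planted copy-number classes are recovered exactly", {
  fb <- make_family_bundle(c(rep(2, 10), 3, 3, 5), seed = 8)
  hits <- all_vs_all(fb$bundle)
  f <- build_families(hits)
  expect_identical(f$histogram,
                   c(`2` = 10L, `3` = 2L, `4` = 0L, `5+` = 1L))
  # histogram masses sum to the genes placed in families
  expect_equal(sum(lengths(f$families)), 10 * 2 + 2 * 3 + 5)
  # recovered memberships match the planted families
  got <- lapply(f$families, sort)
  want <- lapply(split(names(fb$family), fb$family), sort)
  expect_setequal(got, unname(want))
})

test_that("duplicate pairs carry divergence and location classes", {
  b <- make_test_bundle()  # g1 CI, g2 CII identical CDS, g3 plasmid
  fams <- list(c("g1", "g2"))
  pairs <- call_duplicate_pairs(fams, b)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$location_class, "CI-CII")
  expect_equal(pairs$percent_identity, 100)
  expect_equal(pairs$divergence, 0)
  expect_equal(pairs$divergence, 100 - pairs$percent_identity)

  expect_identical(location_class(b, "g1", "g1"), "CI-CI")
  expect_identical(location_class(b, "g1", "g3"), "C-P")
  expect_identical(location_class(b, "g3", "g3"), "P-P")

  # forced pairs are appended; unknown loci are an error
  forced <- data.frame(gene_a = "g1", gene_b = "g3")
  p2 <- call_duplicate_pairs(list(), b, forced_pairs = forced)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$location_class, "C-P")
  expect_error(call_duplicate_pairs(list(), b,
                                    data.frame(gene_a = "g1",
                                               gene_b = "nope")),
               "nope")
  expect_equal(nrow(call_duplicate_pairs(list(), b)), 0)
})

test_that("pair recall and precision are perfect on a simulated cohort", {
  co <- simulate_cohort(sim_config(n_families = 20, seed = 31))
  hits <- all_vs_all(co$focal)
  pairs <- call_duplicate_pairs(build_families(hits), co$focal)
  truth <- co$truth[co$truth$duplicated, ]
  want <- apply(truth[, c("locus_a", "locus_b")], 1,
                function(r) paste(sort(r), collapse = "|"))
  got <- apply(pairs[, c("gene_a", "gene_b")], 1,
               function(r) paste(sort(r), collapse = "|"))
  expect_setequal(got, unname(want))   # recall and precision both 1
})
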