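test_that("COG tallies count one per category annotation", {
  g <- data.frame(cogs = c("CG", "", "J"))
  t_gen <- tally_cogs(g, "general")
  # C and G are both metabolism, so the multi-COG gene adds two counts
  # to group 3; the unannotated gene lands in group 0
  expect_equal(unname(t_gen$counts), c(1L, 1L, 0L, 2L, 0L))
  expect_equal(t_gen$total, 4L)

  t_sub <- tally_cogs(g, "subgroup")
  expect_equal(t_sub$counts[["C"]], 1L)
  expect_equal(t_sub$counts[["G"]], 1L)
  expect_equal(t_sub$counts[["0"]], 1L)
  expect_equal(t_sub$total, 4L)

  none <- data.frame(cogs = rep("", 5))
  expect_equal(tally_cogs(none, "general")$counts[["0"]], 5L)

  ten <- data.frame(cogs = rep("E", 10))
  expect_equal(tally_cogs(ten, "subgroup")$total, 10L)

  expect_error(tally_cogs(data.frame(cogs = "X"), "general"), "unknown")
})

test_that("chi-square goodness of fit matches hand computation", {
  # observed exactly proportional to expected
  obs <- c(a = 10L, b = 30L)
  r0 <- chisq_gof(obs, c(a = 0.25, b = 0.75))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # (10-20)^2/20 + (30-20)^2/20 = 10
  r <- chisq_gof(obs, c(a = 0.5, b = 0.5))
  expect_equal(r$chi2, 10)
  expect_equal(r$df, 1L)
  expect_equal(r$p, chi2_sf(10, 1))

  # impossible categories are dropped from df; impossible-but-observed
  # is an error
  r2 <- chisq_gof(c(a = 10L, b = 30L, c = 0L),
                  c(a = 0.5, b = 0.5, c = 0))
  expect_equal(r2$df, 1L)
  expect_equal(r2$chi2, 10)
  expect_error(chisq_gof(c(a = 10L, b = 30L, c = 1L),
                         c(a = 0.5, b = 0.5, c = 0)), "zero expected")
  expect_error(chisq_gof(obs, c(a = 0.5, b = 0.6)), "sum to 1")
})

test_that("chi-square statistic is relabeling-invariant and scales linearly", {
  set.seed(10)
  props <- c(w = 0.1, x = 0.2, y = 0.3, z = 0.4)
  obs <- c(w = 12L, x = 18L, y = 35L, z = 35L)
  r <- chisq_gof(obs, props)
  perm <- c("z", "w", "y", "x")
  expect_equal(chisq_gof(obs[perm], props[perm])$chi2, r$chi2)
  expect_equal(chisq_gof(obs * 3L, props)$chi2, 3 * r$chi2)
})

test_that("the chi-square tail matches an independent gamma evaluation", {
  expect_equal(chi2_sf(0, 4), 1)
  # closed form at two degrees of freedom
  expect_equal(chi2_sf(2, 2), exp(-1), tolerance = 1e-12)
  for (x in c(0.5, 3.2, 9.585, 20)) {
    for (df in c(1, 2, 4, 10)) {
      expect_equal(chi2_sf(x, df), chi2_sf_oracle(x, df),
                   tolerance = 1e-10)
    }
    expect_true(chi2_sf(x + 0.5, 4) < chi2_sf(x, 4))
  }
  # Monte-Carlo tail frequency within 3 standard errors
  set.seed(1)
  n_draws <- 2e6
  draws <- stats::rchisq(n_draws, df = 4)
  p_hat <- mean(draws >= 9.585)
  p <- chi2_sf(9.585, 4)
  se <- sqrt(p * (1 - p) / n_draws)
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("divergence binning uses decade bins closed at 100", {
  expect_equal(unname(bin_divergence(c(21))[3]), 1L)
  names(bin_divergence(21))[3] == "[20,30)"
  expect_equal(unname(bin_divergence(100)[10]), 1L)
  expect_equal(unname(bin_divergence(0)[1]), 1L)
  set.seed(5)
  d <- runif(57, 0, 100)
  expect_equal(sum(bin_divergence(d)), 57L)
  # planted divergences land in their exact expected bins
  planted <- c(5, 15, 15, 95, 100)
  expect_equal(unname(bin_divergence(planted)),
               c(1L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L))
})

test_that("same-COG positional clusters are found in fixed windows", {
  g <- data.frame(locus_tag = c("a", "b", "c", "d"),
                  replicon_id = "CII",
                  start = c(310000, 350000, 390000, 650000),
                  cogs = c("C", "G", "E", "C"),
                  divergence = c(10, 20, 30, 40))
  # three metabolism genes between 0.3 and 0.4 Mb form one cluster
  cl <- find_cog_clusters(g, window = 1e5, min_count = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$window_start, 3e5)
  expect_equal(cl$window_end, 4e5)
  expect_equal(cl$group, 3L)
  expect_equal(cl$n, 3L)
  expect_equal(cl$mean_divergence, 20)

  # spread one per window: nothing
  g2 <- g; g2$start <- c(1e5, 3e5, 5e5, 7e5) + 10
  expect_equal(nrow(find_cog_clusters(g2, min_count = 3)), 0)
  # min_count 1 reports every (gene, group)
  expect_equal(sum(find_cog_clusters(g2, min_count = 1)$n), 4L)
})
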