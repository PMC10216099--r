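# Bayesian and frequentist inference: dual-oracle checks for the BF
# quadrature, evidence categories, summary-statistic ANOVA and chi-squared.

test_that("JZS quadrature matches the g-representation and Monte-Carlo oracles", {
  cases <- list(c(t = 2.1, n1 = 12, n2 = 14, w = 0.707),
                c(t = 5.445878, n1 = 16, n2 = 16, w = 0.707),
                c(t = -1.3, n1 = 8, n2 = 8, w = 0.5),
                c(t = 4.696548, n1 = 16, n2 = 16, w = 1.0))
  for (cs in cases) {
    bf <- eegnets:::.jzsBF(cs["t"], cs["n1"], cs["n2"], cs["w"], "two_sided")
    expect_equal(bf, oracleJzsG(cs["t"], cs["n1"], cs["n2"], cs["w"]),
                 tolerance = 1e-4, ignore_attr = TRUE)
    mc <- oracleJzsMC(cs["t"], cs["n1"], cs["n2"], cs["w"])
    expect_lt(abs(bf - mc$bf), 4 * mc$se + 1e-8)
  }
})

test_that("null data support the null; BF increases with |t|", {
  bf0 <- jzsTtestBF(m1 = 1, sd1 = 1, n1 = 16, m2 = 1, sd2 = 1, n2 = 16)
  expect_lt(bf10(bf0), 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t) eegnets:::.jzsBF(t, 16, 16, 0.707,
                                                 "two_sided"), 0)
  expect_true(all(diff(bfs) > 0))
})

test_that("a directional prior in the data's direction at least doubles nothing away", {
  two <- jzsTtestBF(m1 = 0, sd1 = 1, n1 = 16, m2 = 1.2, sd2 = 1, n2 = 16,
                    side = "two_sided")
  onUp <- jzsTtestBF(m1 = 0, sd1 = 1, n1 = 16, m2 = 1.2, sd2 = 1, n2 = 16,
                     side = "greater")
  onDown <- jzsTtestBF(m1 = 0, sd1 = 1, n1 = 16, m2 = 1.2, sd2 = 1, n2 = 16,
                       side = "less")
  expect_gte(bf10(onUp), bf10(two))
  expect_lt(bf10(onDown), bf10(two))
})

test_that("raw-sample and summary modes agree exactly", {
  set.seed(50)
  x <- rnorm(10, 0, 1.2); y <- rnorm(14, 0.8, 0.9)
  a <- jzsTtestBF(x = x, y = y, width = 0.6)
  b <- jzsTtestBF(m1 = mean(x), sd1 = sd(x), n1 = 10,
                  m2 = mean(y), sd2 = sd(y), n2 = 14, width = 0.6)
  expect_equal(bf10(a), bf10(b), tolerance = 1e-12)
  expect_equal(a@statistic$t, b@statistic$t)
})

test_that("correlation BF matches an independent exact implementation", {
  # frozen values from an exact reference implementation of the
  # stretched-beta Pearson-correlation Bayes factor (two-sided)
  frozen <- rbind(c(r = 0.89, n = 16, w = 0.5, bf = 2137.0981),
                  c(r = 0.84, n = 16, w = 0.5, bf = 342.4911),
                  c(r = 0.55, n = 16, w = 0.5, bf = 3.2493),
                  c(r = 0.55, n = 16, w = 1.0, bf = 2.9031),
                  c(r = 0.89, n = 16, w = 1.0, bf = 4849.0956))
  for (i in seq_len(nrow(frozen))) {
    f <- frozen[i, ]
    expect_equal(bf10(bayesCorrelationBF(f["r"], f["n"], width = f["w"])),
                 unname(f["bf"]), tolerance = 1e-3)
  }
  expect_lt(bf10(bayesCorrelationBF(0, 16)), 1)
  one <- bayesCorrelationBF(0.55, 16, side = "greater")
  expect_gt(bf10(one), bf10(bayesCorrelationBF(0.55, 16)))
  expect_error(bayesCorrelationBF(1, 16), "infinite evidence")
  expect_error(bayesCorrelationBF(0.5, 2), "n >= 3")
})

test_that("evidence categories honor the printed boundaries exactly", {
  expect_equal(evidenceCategory(2.999999), "anecdotal")
  expect_equal(evidenceCategory(3), "moderate")
  expect_equal(evidenceCategory(10), "strong")
  expect_equal(evidenceCategory(30), "very_strong")
  expect_equal(evidenceCategory(100), "extreme")
  expect_equal(evidenceCategory(0.02), "anecdotal")
})

test_that("robustness curves reproduce the single-call BF at its width", {
  bf <- jzsTtestBF(m1 = -2.52, sd1 = 1.15, n1 = 16, m2 = -0.56, sd2 = 1.21,
                   n2 = 16)
  rob <- bfRobustness(bf, widths = c(0.25, 0.5, 1))
  at <- rob@robustness$bf10[abs(rob@robustness$width - bf@prior$width) < 1e-12]
  expect_equal(at, bf10(bf), tolerance = 1e-9)
  # null data stay unconvincing across the whole grid
  null <- bfRobustness(jzsTtestBF(m1 = 0, sd1 = 1, n1 = 16, m2 = 0, sd2 = 1,
                                  n2 = 16), widths = seq(0.1, 2, by = 0.25))
  expect_true(all(null@robustness$bf10 < 1))
  cr <- bfRobustness(bayesCorrelationBF(0.84, 16), widths = c(0.25, 0.5, 2))
  at2 <- cr@robustness$bf10[abs(cr@robustness$width - 0.5) < 1e-12]
  expect_equal(at2, bf10(bayesCorrelationBF(0.84, 16)), tolerance = 1e-9)
})

test_that("summary-statistic ANOVA reproduces the published F tests", {
  copy <- anovaFromSummary(-4.93, 2.69, 16, -0.88, 1.27, 16)
  expect_equal(copy$F, 29.67, tolerance = 0.01)
  expect_equal(copy$etaPSquared, 0.497, tolerance = 0.005 / 0.497)
  recall <- anovaFromSummary(-2.52, 1.15, 16, -0.56, 1.21, 16)
  expect_equal(recall$F, 22.19, tolerance = 0.01)
  expect_equal(recall$etaPSquared, 0.425, tolerance = 0.005 / 0.425)
  age <- anovaFromSummary(157.19, 21.78, 16, 155.44, 23.09, 16)
  expect_lt(abs(age$F - 0.049), 0.002)
  same <- anovaFromSummary(1, 1, 10, 1, 1, 10)
  expect_equal(same$F, 0)
  expect_equal(same$etaPSquared, 0)
  expect_error(anovaFromSummary(1, 0, 10, 1, 0, 10), "pooled variance")
})

test_that("2x2 chi-squared equals a direct expected-count computation", {
  tab <- matrix(c(12, 14, 4, 2), 2)
  res <- chisq2x2(tab)
  # brute-force oracle
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$chi2Corrected,
               sum((abs(tab - E) - 0.5)^2 / E), tolerance = 1e-12)
  expect_equal(res$chi2, 0.8205128, tolerance = 1e-6)
  expect_equal(chisq2x2(matrix(c(5, 5, 3, 3), 2))$chi2, 0)
  expect_error(chisq2x2(matrix(c(0, 0, 3, 3), 2)), "marginal")
  expect_error(chisq2x2(matrix(c(1.5, 2, 3, 3), 2)), "integer")
})

test_that("group comparison tables flag effects with the figure tiers", {
  set.seed(51)
  mkTab <- function(shift) {
    nodal <- expand.grid(subjectID = sprintf("S%02d", 1:20),
                         network = "DAN", band = "gamma",
                         node = c("n1", "n2"), role = "IPS",
                         measure = "degree", stringsAsFactors = FALSE)
    nodal$group <- ifelse(as.integer(sub("S", "", nodal$subjectID)) <= 10,
                          "NVLD", "TD")
    nodal$value <- rnorm(nrow(nodal)) +
      ifelse(nodal$group == "NVLD" & nodal$node == "n1", shift, 0)
    global <- data.frame(subjectID = nodal$subjectID[1:20],
                         group = nodal$group[1:20], network = "DAN",
                         hemisphere = "L", band = "gamma",
                         measure = "global_efficiency", value = rnorm(20))
    list(global = global, nodal = nodal)
  }
  out <- compareGroupsGraphMetrics(mkTab(3))
  n1 <- out$nodal[out$nodal$node == "n1", ]
  expect_gt(n1$bf10, 10)
  expect_equal(n1$tier, "red")
  expect_equal(n1$direction, "NVLD>TD")
  n2 <- out$nodal[out$nodal$node == "n2", ]
  expect_lt(n2$bf10, 3)
  expect_equal(n2$tier, "blue")
  # identical group distributions at large n support the null
  flat <- mkTab(0)
  flat$nodal$value <- rep(rnorm(40), each = 1)
  out2 <- compareGroupsGraphMetrics(flat)
  expect_true(all(out2$global$bf10 < 1))
  onegrp <- mkTab(0)
  onegrp$nodal <- onegrp$nodal[onegrp$nodal$group == "NVLD", ]
  expect_error(compareGroupsGraphMetrics(onegrp), "group")
})
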