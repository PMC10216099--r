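# Synthetic cohort generator: determinism, seed substreams, variance
# contract, behavior linkage, and the published-summary score draws.

shortCfg <- function(seed = 3, ...) {
  cohortConfig(nPerGroup = 2, durationS = 10, seed = seed, ...)
}

test_that("identical config and seed give byte-identical series; seeds differ", {
  a <- generateCohort(shortCfg(seed = 5))
  b <- generateCohort(shortCfg(seed = 5))
  expect_identical(a$recordings[["NVLD01"]]@series,
                   b$recordings[["NVLD01"]]@series)
  expect_identical(a$scores, b$scores)
  c <- generateCohort(shortCfg(seed = 6))
  expect_false(identical(a$recordings[["NVLD01"]]@series,
                         c$recordings[["NVLD01"]]@series))
})

test_that("per-subject substreams: enlarging the cohort keeps old subjects", {
  small <- generateCohort(cohortConfig(nPerGroup = 2, durationS = 10, seed = 4))
  large <- generateCohort(cohortConfig(nPerGroup = 3, durationS = 10, seed = 4))
  for (id in c("NVLD01", "NVLD02", "TD01", "TD02"))
    expect_identical(small$recordings[[id]]@series,
                     large$recordings[[id]]@series)
})

test_that("ROI series variance sits near the per-band unit-variance target", {
  coh <- generateCohort(cohortConfig(nPerGroup = 2, durationS = 240, seed = 8))
  v <- apply(coh$recordings[["TD01"]]@series, 2, var)
  target <- coh$truth$varianceTarget
  expect_true(all(abs(v - target) / target < 0.10))
})

test_that("behavior is an exact affine function of the true coupling statistic", {
  cfg <- cohortConfig(nPerGroup = 3, durationS = 10, seed = 2,
                      couplings = couplingSpec("NVLD", "DAN", "R", "delta",
                                               0.5, jitterSD = 0.2),
                      behaviorBeta = 7, behaviorNoiseSD = 0)
  coh <- generateCohort(cfg)
  expect_equal(coh$scores$composite, 7 * coh$truth$behaviorStat$stat,
               tolerance = 1e-12)
  # composite is the copy/recall average by construction
  expect_equal(coh$scores$composite,
               (coh$scores$copyZ + coh$scores$recallZ) / 2)
  # jitter actually varies the statistic across NVLD subjects
  nv <- coh$truth$behaviorStat$stat[coh$truth$behaviorStat$group == "NVLD"]
  expect_gt(stats::sd(nv), 0)
  # TD carries no coupling, so its statistic is exactly zero
  expect_equal(coh$truth$behaviorStat$stat[coh$truth$behaviorStat$group == "TD"],
               rep(0, 3))
})

test_that("group effects enter through couplings only, not amplitude", {
  cfg <- cohortConfig(nPerGroup = 2, durationS = 60, seed = 9,
                      couplings = couplingSpec("NVLD", "DAN", "both", "gamma",
                                               0.7))
  coh <- generateCohort(cfg)
  vN <- mean(apply(coh$recordings[["NVLD01"]]@series, 2, var))
  vT <- mean(apply(coh$recordings[["TD01"]]@series, 2, var))
  expect_equal(vN, vT, tolerance = 0.05)
})

test_that("config validation rejects the documented error cases", {
  expect_error(cohortConfig(nPerGroup = 1), "nPerGroup")
  expect_error(cohortConfig(durationS = -2), "positive")
  expect_error(cohortConfig(durationS = 4), "Welch")
  expect_error(couplingSpec("NVLD", "DAN", "both", "gamma", 1.0), "\\[0, 1\\)")
  expect_error(cohortConfig(couplings = data.frame(
    group = "NVLD", network = "DAN", hemisphere = "both", band = "sigma",
    role = "all", a = 0.5, jitterSD = 0)), "invalid band")
})

test_that("published-summary score draws recover the printed means", {
  big <- generateRocftScores(1e5, seed = 42)
  s <- rocftSummaries()
  for (g in c("NVLD", "TD")) {
    expect_lt(abs(mean(big$copyZ[big$group == g]) -
                    s$mean[s$trial == "copy" & s$group == g]), 0.02)
    expect_lt(abs(mean(big$recallZ[big$group == g]) -
                    s$mean[s$trial == "recall" & s$group == g]), 0.02)
  }
  expect_identical(generateRocftScores(2, seed = 7),
                   generateRocftScores(2, seed = 7))
  degenerate <- rocftSummaries()
  degenerate$sd <- 0
  z <- generateRocftScores(5, seed = 1, summaries = degenerate)
  expect_equal(unique(z$copyZ[z$group == "NVLD"]), -4.93)
  expect_error(generateRocftScores(1), ">= 2")
})
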