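test_that("configuration errors name the offending field", {
  expect_error(simulationConfig(nPatients = 0), "nPatients")
  expect_error(simulationConfig(carrierFreq = 1.5), "carrierFreq")
  expect_error(simulationConfig(baselineHazard = -1), "baselineHazard")
  expect_error(simulationConfig(competingFractions = c(relapse = 1)),
               "competingFractions")
  expect_error(
    simulationConfig(subgroupSpec = list(
      list(regions = "TP53", prevalence = 0.7, logHR = 1),
      list(regions = "TET2", prevalence = 0.6, logHR = 1))),
    "prevalences")
})

test_that("a fixed seed reproduces every table exactly", {
  cfg <- simulationConfig(nPatients = 80L, nGenes = 30L, nWindows = 10L,
                          seed = 11L)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_identical(s1$truth$geneAll, s2$truth$geneAll)
  expect_identical(as.data.frame(s1$variants), as.data.frame(s2$variants))
})

test_that("neutral region carrier fractions stay within 3 binomial SDs", {
  cfg <- simulationConfig(nPatients = 500L, nGenes = 60L, nWindows = 0L,
                          carrierFreq = 0.1, subgroupSpec = list(),
                          plantedEffects = data.frame(), seed = 7L)
  sim <- simulateCohort(cfg)
  frac <- colMeans(sim$truth$geneAll)
  sd3 <- 3 * sqrt(0.1 * 0.9 / 500)
  expect_true(all(abs(frac - 0.1) <= sd3))
})

test_that("outcome tables satisfy the structural invariants", {
  sim <- simulateCohort(simulationConfig(nPatients = 300L, nGenes = 20L,
                                         nWindows = 5L, seed = 3L))
  oc <- sim$outcomes
  expect_true(all(oc$os_time > 0))
  expect_true(all(oc$dfs_time <= oc$os_time + 1e-12))
  expect_true(all(oc$first_event_code %in% 0:2))
  expect_identical(oc$dfs_event == 1L, oc$first_event_code != 0L)
  ## admin censoring bounds follow-up
  expect_true(all(oc$os_time <= 120))
})

test_that("competing-risk generation respects degenerate causes", {
  cfg <- simulationConfig(nPatients = 400L, nGenes = 5L, nWindows = 0L,
                          competingFractions = c(relapse = 0, trm = 1),
                          subgroupSpec = list(), seed = 5L)
  oc <- simulateCohort(cfg)$outcomes
  expect_true(all(oc$first_event_code %in% c(0L, 2L)))

  expect_error(
    simulationConfig(nPatients = 10L,
                     competingFractions = c(relapse = 0, trm = 0)),
    "zero")
  cfgOk <- simulationConfig(nPatients = 10L, seed = 1L)
  cfgBad <- cfgOk
  cfgBad@competingFractions[] <- 0
  expect_error(simulateCompetingRisks(rep(0, 10), rep(0, 10), cfgBad),
               "no events possible")
})

test_that("equal cause-specific hazards split events about 50/50", {
  cfg <- simulationConfig(nPatients = 4000L, nGenes = 5L, nWindows = 0L,
                          competingFractions = c(relapse = 0.5, trm = 0.5),
                          postRelapseHazard = 0.05,
                          subgroupSpec = list(), plantedEffects = data.frame(),
                          clinicalEffects = c(ipssr = 0, mds_eb = 0, hma = 0,
                                              chemo = 0, ric = 0),
                          seed = 13L)
  oc <- simulateCohort(cfg)$outcomes
  ev <- oc$first_event_code[oc$first_event_code != 0L]
  fracRelapse <- mean(ev == 1L)
  se <- sqrt(0.25 / length(ev))
  expect_lt(abs(fracRelapse - 0.5), 4 * se)
})

test_that("heavy censoring censors everything at early times", {
  cfg <- simulationConfig(nPatients = 200L, nGenes = 5L, nWindows = 0L,
                          censoringRate = 1000, subgroupSpec = list(),
                          seed = 9L)
  oc <- simulateCohort(cfg)$outcomes
  expect_lt(mean(oc$os_event), 0.02)
  expect_lt(median(oc$os_time), 0.01)
})

test_that("null-config simulated OS matches the exponential survivor curve", {
  h <- 0.02
  cfg <- simulationConfig(nPatients = 2000L, nGenes = 5L, nWindows = 0L,
                          baselineHazard = h, censoringRate = 0,
                          adminCensorTime = 1000,
                          postRelapseHazard = 1e6,  # death at first event
                          subgroupSpec = list(), plantedEffects = data.frame(),
                          clinicalEffects = c(ipssr = 0, mds_eb = 0, hma = 0,
                                              chemo = 0, ric = 0),
                          seed = 17L)
  oc <- simulateCohort(cfg)$outcomes
  ## distributional identity with the closed form
  expect_gt(stats::ks.test(oc$dfs_time, "pexp", h)$p.value, 0.01)
  ## and the survivor curve tracks it within the pointwise 95% bands for
  ## most of the time grid (whole-curve drift makes joint coverage < 95%)
  km <- survival::survfit(survival::Surv(oc$dfs_time, oc$dfs_event) ~ 1,
                          conf.int = 0.95)
  grid <- seq(10, 90, 10)
  idx <- findInterval(grid, km$time)
  inside <- exp(-h * grid) >= km$lower[idx] & exp(-h * grid) <= km$upper[idx]
  expect_gte(mean(inside), 0.5)
})

test_that("planted log hazard ratios are recoverable within 3 SE", {
  cfg <- simulationConfig(nPatients = 1000L, nGenes = 30L, nWindows = 0L,
                          carrierFreq = 0.2,
                          plantedEffects = data.frame(region_id = "HCN2",
                                                      logHR = 0.6,
                                                      endpoint = "all"),
                          subgroupSpec = list(),
                          clinicalEffects = c(ipssr = 0, mds_eb = 0, hma = 0,
                                              chemo = 0, ric = 0),
                          seed = 19L)
  sim <- simulateCohort(cfg)
  oc <- sim$outcomes
  fit <- coxRegionTest(sim$truth$geneAll[, "HCN2"], oc$dfs_time, oc$dfs_event)
  expect_lt(abs(fit$beta - 0.6) / fit$se, 3)
})

test_that("subgroup signatures imprint the expected block pattern", {
  cfg <- simulationConfig(nPatients = 600L, nGenes = 30L, nWindows = 0L,
                          seed = 23L)
  sim <- simulateCohort(cfg)
  sub <- sim$truth$subgroup
  g <- sim$truth$geneAll
  ## signature genes enriched within their own subgroup
  expect_gt(mean(g[sub == 1, "DNMT3A"]), 0.8)
  expect_gt(mean(g[sub == 2, "TET2"]), 0.8)
  expect_gt(mean(g[sub == 3, "RUNX1"]), 0.8)
  expect_gt(mean(g[sub == 4, "TP53"]), 0.8)
  expect_gt(mean(sim$truth$del5q[sub == 4]), 0.8)
  ## and near baseline outside it
  expect_lt(mean(g[sub != 2, "TET2"]), 0.2)
  rf <- recurrentFeatureMatrix(sim)
  expect_true(all(rf %in% 0:1))
  expect_true("del5q" %in% colnames(rf))
})
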