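test_that("concordance matches exhaustive pair enumeration, ties included", {
  set.seed(31)
  for (i in 1:20) {
    n <- 50
    time <- rpois(n, 20) + 1          # discrete -> tied times
    event <- rbinom(n, 1, 0.7)
    risk <- sample(seq(0, 1, 0.2), n, replace = TRUE)  # tied risks
    got <- concordanceIndex(risk, time, event, B = 0)$c
    expect_equal(got, cindexOracle(risk, time, event)$c, tolerance = 1e-12)
  }
})

test_that("concordance limits: perfect ranking and constant risk", {
  time <- c(3, 7, 1, 9, 5); event <- rep(1L, 5)
  expect_equal(concordanceIndex(-time, time, event, B = 0)$c, 1.0)
  expect_equal(concordanceIndex(rep(2, 5), time, event, B = 0)$c, 0.5)
  expect_error(concordanceIndex(1:3, 1:3, rep(0L, 3), B = 0), "pairs")
  ci <- concordanceIndex(-time, time, event, B = 50, seed = 2)
  expect_true(ci$lower <= ci$c && ci$c <= ci$upper)
})

test_that("uncensored Brier score has its closed forms", {
  set.seed(32)
  n <- 40
  time <- rexp(n, 0.1); event <- rep(1L, n)
  evalTimes <- quantile(time, c(0.25, 0.5, 0.75), names = FALSE)
  ## constant 1/2 prediction: Brier = 1/4 at every time
  b <- brierScore(matrix(0.5, n, 3), time, event, evalTimes)
  expect_equal(b$curve$brier, rep(0.25, 3), tolerance = 1e-12)
  expect_equal(b$integrated, 0.25, tolerance = 1e-12)
  ## plain MSE of the survival indicator when weights are 1
  S <- matrix(runif(n * 3), n, 3)
  b2 <- brierScore(S, time, event, evalTimes)
  mse <- vapply(1:3, function(j)
    mean(((time > evalTimes[j]) - S[, j])^2), numeric(1))
  expect_equal(b2$curve$brier, mse, tolerance = 1e-12)
  ## the survival indicator itself scores identically zero
  S3 <- vapply(evalTimes, function(t0) as.numeric(time > t0), numeric(n))
  b3 <- brierScore(S3, time, event, evalTimes)
  expect_equal(b3$curve$brier, rep(0, 3), tolerance = 1e-15)
  expect_error(brierScore(S, time, event, max(time) + 1), "beyond")
})

test_that("censored Brier matches the worked 8-patient IPCW fixture", {
  ## fixture: times, events and predictions fixed; weights derive from the
  ## Kaplan-Meier of the censoring distribution, G
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  S <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  t0 <- 4.5
  ## censoring KM: drops at the censoring times 2, 5, 7
  ## G(t) = 6/7 on [2,5), = 6/7 * 3/4 on [5,7), = 6/7 * 3/4 * 1/2 on [7,8)
  G2 <- 6 / 7
  ## subjects 1,3,4 died before t0: weight 1/G(T-); G(1-)=G(3-)=G(4-)=...
  ## G(1-)=1, G(3-)=G2, G(4-)=G2
  ## subjects 5..8 alive at t0: weight 1/G(t0) with G(4.5)=G2
  expected <- (1 / 1 * (0 - S[1])^2 +
               1 / G2 * (0 - S[3])^2 +
               1 / G2 * (0 - S[4])^2 +
               1 / G2 * ((1 - S[5])^2 + (1 - S[6])^2 +
                         (1 - S[7])^2 + (1 - S[8])^2)) / 8
  got <- brierScore(matrix(S, ncol = 1), time, event, t0)
  expect_equal(got$curve$brier, expected, tolerance = 1e-10)
})

test_that("forests are deterministic under a fixed seed", {
  set.seed(33)
  n <- 150
  x <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
  d <- makeSurvData(n, lp = 0.8 * x$b)
  f1 <- fitRsf(x, d$time, d$event, numTrees = 80, seed = 4)
  f2 <- fitRsf(x, d$time, d$event, numTrees = 80, seed = 4)
  expect_identical(f1$oobMortality, f2$oobMortality)
  expect_identical(f1$importance, f2$importance)
})

test_that("a perfect predictor drives OOB concordance towards 1", {
  set.seed(34)
  n <- 200
  time <- rexp(n, 0.05)
  x <- data.frame(risk = -time)  # orders event times exactly
  f <- fitRsf(x, time, rep(1L, n), numTrees = 300, seed = 5)
  expect_gt(f$oobConcordance, 0.95)
})

test_that("pure-noise features give chance-level OOB concordance", {
  set.seed(35)
  n <- 300
  x <- data.frame(matrix(rnorm(n * 4), n))
  d <- makeSurvData(n)
  f <- fitRsf(x, d$time, d$event, numTrees = 300, seed = 6)
  ## MC band for null OOB concordance (see also the ladder null band)
  expect_gt(f$oobConcordance, 0.38)
  expect_lt(f$oobConcordance, 0.58)
})

test_that("importance singles out the only predictive feature", {
  set.seed(36)
  n <- 300
  x <- data.frame(signal = rbinom(n, 1, 0.5), n1 = rnorm(n),
                  n2 = rbinom(n, 1, 0.3), flat = rep(1, n))
  d <- makeSurvData(n, lp = 1.2 * x$signal)
  f <- suppressWarnings(fitRsf(x, d$time, d$event, numTrees = 300, seed = 7))
  vi <- permutationImportance(f)
  expect_identical(names(vi)[1], "signal")
  ## a constant feature is never split on: VIMP exactly zero
  expect_identical(unname(vi["flat"]), 0)
  fNone <- fitRsf(x["signal"], d$time, d$event, numTrees = 20, seed = 8,
                  importance = "none")
  expect_error(permutationImportance(fNone), "importance")
  expect_error(fitRsf(x, d$time, rep(0L, n)), "event")
})

test_that("ladder features are nested and exclude outcomes", {
  sim <- simulateCohort(simulationConfig(nPatients = 60L, nGenes = 15L,
                                         nWindows = 0L, seed = 41L))
  mc <- rpois(60, 2)
  sup <- sample(1:3, 60, TRUE); uns <- sample(1:4, 60, TRUE)
  fb <- ladderFeatures("base", sim$clinical)
  fc <- ladderFeatures("clinical", sim$clinical)
  fg <- ladderFeatures("genomic", sim$clinical, mc, sup, uns)
  ff <- ladderFeatures("full", sim$clinical, mc, sup, uns)
  expect_true(all(colnames(fb) %in% colnames(fc)))
  expect_true(all(colnames(fc) %in% colnames(ff)))
  expect_true(all(colnames(fg) %in% colnames(ff)))
  expect_false(any(grepl("time|event", colnames(ff))))
  expect_error(ladderFeatures("genomic", sim$clinical, mc), "subgroup")
})

test_that("ladder evaluation fills the model-by-endpoint grid", {
  set.seed(43)
  sim <- simulateCohort(simulationConfig(nPatients = 250L, nGenes = 40L,
                                         nWindows = 0L, seed = 47L))
  mc <- mutationalCount(CarrierExperiment(t(sim$truth$geneAll),
                                          scheme = "gene_all"),
                        c("TP53", "HCN2"))
  sup <- sample(1:3, 250, TRUE); uns <- sample(1:4, 250, TRUE)
  lad <- evaluateLadder(sim$clinical, sim$outcomes, mc, sup, uns,
                        endpoints = c("os", "relapse"),
                        strata = "conditioning_regimen",
                        numTrees = 60, bootB = 30, seed = 3)
  tab <- lad$table
  expect_setequal(unique(tab$model),
                  c("base", "clinical", "genomic", "full"))
  expect_setequal(unique(tab$stratum),
                  c("all", "myeloablative", "reduced intensity"))
  expect_true(all(tab$c >= 0 & tab$c <= 1, na.rm = TRUE))
  expect_true(all(tab$lower <= tab$c + 1e-9 & tab$c <= tab$upper + 1e-9,
                  na.rm = TRUE))
  expect_true(all(lad$brier$brier >= 0 & lad$brier$brier <= 1))
  grid <- ladderGrid(lad)
  expect_equal(nrow(grid), 4 * 3)  # 4 models x 3 strata rows
  expect_true(all(c("os", "relapse") %in% colnames(grid)))
  ## unknown stratum column is an error
  expect_error(
    evaluateLadder(sim$clinical, sim$outcomes, mc, sup, uns,
                   endpoints = "os", strata = "nope", numTrees = 10,
                   bootB = 0, seed = 1),
    "stratum")
})
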