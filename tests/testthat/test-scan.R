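test_that("cox burden fit matches grid maximisation of the Efron likelihood", {
  ## 6-patient worked fixture: distinct times 1..6, all events, two carriers
  ## (failing 2nd and 5th so the maximiser is finite)
  time <- 1:6
  event <- rep(1L, 6)
  carrier <- c(0, 1, 0, 0, 1, 0)
  fit <- coxRegionTest(carrier, time, event)
  oracle <- efronOracleBeta(carrier, time, event)
  expect_lt(abs(fit$beta - oracle), 1e-8)

  ## and with ties, where the Efron correction actually matters
  time2 <- c(1, 1, 2, 2, 3, 4, 5, 5)
  event2 <- c(1, 1, 1, 0, 1, 1, 1, 1)
  carrier2 <- c(1, 0, 1, 1, 0, 0, 1, 0)
  fit2 <- coxRegionTest(carrier2, time2, event2)
  oracle2 <- efronOracleBeta(carrier2, time2, event2)
  expect_lt(abs(fit2$beta - oracle2), 1e-8)
})

test_that("degenerate carrier vectors are rejected", {
  expect_error(coxRegionTest(rep(0, 6), 1:6, rep(1, 6)), "carrier")
  expect_error(coxRegionTest(rep(1, 6), 1:6, rep(1, 6)), "carrier")
  expect_error(coxRegionTest(c(1, 0, 1), 1:3, rep(0, 3)), "event")
  expect_error(coxRegionTest(c(2, 0, 1), 1:3, rep(1, 3)), "binary")
})

test_that("estimates are invariant to patient order and time rescaling", {
  set.seed(42)
  n <- 120
  carrier <- rbinom(n, 1, 0.3)
  d <- makeSurvData(n, lp = 0.5 * carrier)
  f0 <- coxRegionTest(carrier, d$time, d$event)
  perm <- sample(n)
  f1 <- coxRegionTest(carrier[perm], d$time[perm], d$event[perm])
  expect_equal(f0$beta, f1$beta, tolerance = 1e-10)
  f2 <- coxRegionTest(carrier, d$time * 365.25, d$event)
  expect_equal(f0$beta, f2$beta, tolerance = 1e-10)
})

test_that("score statistic equals the log-rank statistic without censoring", {
  set.seed(7)
  n <- 80
  carrier <- rbinom(n, 1, 0.4)
  time <- rexp(n, 0.1 * exp(0.4 * carrier))
  event <- rep(1L, n)
  sc <- summary(survival::coxph(survival::Surv(time, event) ~ carrier))$sctest
  lr <- survival::survdiff(survival::Surv(time, event) ~ carrier)$chisq
  expect_lt(abs(sc[["test"]] - lr), 1e-8)
  ## the package's vectorised scorer reproduces the same statistic
  z <- coxScoreZ(matrix(carrier, ncol = 1), time, event)
  expect_lt(abs(z^2 - lr), 1e-8)
})

test_that("null permutations give uniform p-values", {
  set.seed(13)
  n <- 100
  carrier <- rbinom(n, 1, 0.3)
  d <- makeSurvData(n, censRate = 0.01)
  ps <- replicate(400, {
    perm <- sample(n)
    coxRegionTest(carrier, d$time[perm], d$event[perm])$p_raw
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("monotone likelihood is flagged rather than raised", {
  ## carrier perfectly predicts the earliest events -> divergent beta
  time <- c(1, 2, 3, 10, 11, 12, 13, 14)
  event <- rep(1L, 8)
  carrier <- c(1, 1, 1, 0, 0, 0, 0, 0)
  fit <- suppressWarnings(coxRegionTest(carrier, time, event))
  expect_false(fit$converged)
})

test_that("genome scan orders by p, adjusts multiplicity and keeps flags", {
  set.seed(21)
  n <- 300; G <- 40
  m <- matrix(rbinom(n * G, 1, 0.15), n, G,
              dimnames = list(sprintf("P%03d", 1:n), sprintf("g%03d", 1:G)))
  lp <- 1.1 * m[, "g001"]
  d <- makeSurvData(n, lp = lp)
  ce <- CarrierExperiment(t(m), scheme = "gene_all")
  res <- genomeScan(ce, d$time, d$event)
  expect_identical(res$region_id[1], "g001")
  expect_false(is.unsorted(res$p_raw))
  expect_true(all(res$p_bonferroni >= res$p_raw - 1e-15))
  ## BH q-values are monotone in the raw p ordering
  expect_false(is.unsorted(res$q_bh))
  ## adjusted covariates keep the planted signal on top
  covs <- data.frame(ipss_r_risk = sample(1:5, n, replace = TRUE))
  resAdj <- genomeScan(ce, d$time, d$event, covariates = covs)
  expect_identical(resAdj$region_id[1], "g001")
  expect_error(genomeScan(ce[0, ], d$time, d$event), "empty")
})

test_that("a single tested region has Bonferroni equal to raw p", {
  set.seed(3)
  n <- 100
  m <- matrix(rbinom(n, 1, 0.3), n, 1,
              dimnames = list(sprintf("P%03d", 1:n), "only"))
  d <- makeSurvData(n)
  ce <- CarrierExperiment(t(m), scheme = "gene_all")
  res <- genomeScan(ce, d$time, d$event)
  expect_equal(res$p_bonferroni, res$p_raw)
  expect_equal(res$q_bh, res$p_raw)
})

test_that("fine-gray equals cause-specific cox without competing events", {
  set.seed(5)
  n <- 200
  carrier <- rbinom(n, 1, 0.3)
  t0 <- rexp(n, 0.05 * exp(0.6 * carrier))
  cens <- pmin(rexp(n, 0.03), 60)
  time <- pmin(t0, cens)
  code <- as.integer(t0 <= cens)  # only cause 1 or censoring
  fg <- fineGrayRegionTest(carrier, time, code, "relapse")
  cx <- coxRegionTest(carrier, time, as.integer(code == 1L))
  expect_lt(abs(fg$beta - cx$beta), 1e-6)
})

test_that("fine-gray agrees with the cmprsk estimator", {
  set.seed(6)
  n <- 500
  carrier <- rbinom(n, 1, 0.3)
  t1 <- rexp(n, 0.04 * exp(0.8 * carrier))
  t2 <- rexp(n, 0.03)
  cens <- pmin(rexp(n, 0.02), 60)
  time <- pmin(t1, t2, cens)
  code <- ifelse(pmin(t1, t2) > cens, 0L, ifelse(t1 < t2, 1L, 2L))
  fg <- fineGrayRegionTest(carrier, time, code, "relapse")
  crr <- cmprsk::crr(time, code, cbind(carrier), failcode = 1, cencode = 0)
  expect_lt(abs(fg$beta - crr$coef), 1e-4)
  expect_error(fineGrayRegionTest(carrier, time, rep(0L, n), "trm"), "trm")
})

test_that("volcano table is a monotone transform of the scan", {
  res <- S4Vectors::DataFrame(region_id = c("a", "b", "c"),
                              beta = c(1, -1, 0.5),
                              p_raw = c(0.01, 0.02, 1),
                              q_bh = c(0.03, 0.03, 1))
  v <- volcanoTable(res)
  expect_equal(nrow(v), 3)
  expect_equal(v$neglog10_p[3], 0)
  expect_equal(v$neglog10_p[1] - v$neglog10_p[2], log10(2), tolerance = 1e-12)
  expect_identical(v$label, c("a", "b", ""))
  expect_error(volcanoTable(res[0, ]), "empty")
})
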