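test_that("two perfectly separated blocks are recovered exactly", {
  x <- rbind(matrix(rep(c(1L, 1L, 0L, 0L), each = 20), 20),
             matrix(rep(c(0L, 0L, 1L, 1L), each = 25), 25))
  colnames(x) <- paste0("f", 1:4)
  r <- unsupervisedSubgroups(x, kRange = 2, seed = 1)
  expect_identical(r$k, 2L)
  truth <- rep(1:2, c(20, 25))
  expect_equal(mclust::adjustedRandIndex(r$assignment$subgroup, truth), 1)
})

test_that("partition is stable under patient reordering", {
  blocks <- makeSignatureBlocks(200, labelNoise = 0, seed = 4)
  r1 <- unsupervisedSubgroups(blocks$matrix, k = 4, seed = 2)
  perm <- sample(nrow(blocks$matrix))
  r2 <- unsupervisedSubgroups(blocks$matrix[perm, ], k = 4, seed = 2)
  ## same partition up to label names
  l1 <- r1$assignment$subgroup[match(r2$assignment$patient_id,
                                     r1$assignment$patient_id)]
  expect_equal(mclust::adjustedRandIndex(l1, r2$assignment$subgroup), 1)
})

test_that("degenerate feature matrices are rejected", {
  x <- matrix(1L, 10, 3, dimnames = list(paste0("P", 1:10), paste0("f", 1:3)))
  expect_error(unsupervisedSubgroups(x), "degenerate")
  expect_error(unsupervisedSubgroups(x[, 1, drop = FALSE]), "two features")
})

test_that("common/rare split partitions features by cohort frequency", {
  set.seed(8)
  x <- cbind(common1 = rbinom(1000, 1, 0.2),
             edge = rbinom(1000, 1, 0.05),
             rare1 = rbinom(1000, 1, 0.002))
  x[1, "rare1"] <- 1L  # ensure non-empty
  sp <- splitCommonRare(x, 0.01)
  expect_setequal(c(colnames(sp$common), colnames(sp$rare)), colnames(x))
  expect_true("rare1" %in% colnames(sp$rare))
  expect_true("common1" %in% colnames(sp$common))
  ## a feature at 0.9% frequency is rare under a 1% threshold
  y <- matrix(c(rep(1L, 9), rep(0L, 991)), 1000, 1,
              dimnames = list(NULL, "f9"))
  expect_identical(colnames(splitCommonRare(y, 0.01)$rare), "f9")
  ## raising the threshold never moves a feature from rare to common
  for (th in c(0.005, 0.01, 0.05, 0.1)) {
    loRare <- colnames(splitCommonRare(x, th)$rare)
    hiRare <- colnames(splitCommonRare(x, min(th * 2, 0.49))$rare)
    expect_true(all(loRare %in% hiRare))
  }
  expect_error(splitCommonRare(x, 0.6), "freqThreshold")
})

test_that("supervised CV recovers a planted survival-linked subgroup", {
  set.seed(42)
  n <- 600; p <- 1000
  sub <- rbinom(n, 1, 0.4)
  x <- matrix(rbinom(n * p, 1, 0.1), n, p,
              dimnames = list(sprintf("P%04d", 1:n), sprintf("f%04d", 1:p)))
  planted <- sprintf("f%04d", 1:10)
  for (f in planted) x[, f] <- rbinom(n, 1, ifelse(sub == 1, 0.9, 0.1))
  d <- makeSurvData(n, rate = 0.02, censRate = 0.01, lp = 1.0 * sub)
  r <- supervisedClusterCV(x, d$time, d$event,
                           supervisedConfig(kClusters = 2, nTopFeatures = 25,
                                            nFolds = 5, seed = 3))
  expect_lt(r$oofLogrankP, 0.01)
  expect_gte(sum(planted %in% r$selectedConsensus), 7)
  expect_true(all(!is.na(r$assignment$subgroup)))
})

test_that("feature scoring never sees held-out outcomes", {
  set.seed(9)
  n <- 120
  x <- matrix(rbinom(n * 50, 1, 0.2), n, 50,
              dimnames = list(sprintf("P%03d", 1:n), sprintf("f%02d", 1:50)))
  d <- makeSurvData(n)
  r <- supervisedClusterCV(x, d$time, d$event,
                           supervisedConfig(kClusters = 2, nTopFeatures = 10,
                                            nFolds = 4, seed = 5))
  for (f in r$folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
  }
  ## every patient is held out exactly once
  held <- unlist(lapply(r$folds, `[[`, "test_ids"))
  expect_setequal(held, rownames(x))
  expect_identical(anyDuplicated(held), 0L)
})

test_that("leave-one-out folds still label every patient", {
  set.seed(10)
  n <- 24
  x <- matrix(rbinom(n * 8, 1, 0.3), n, 8,
              dimnames = list(sprintf("P%02d", 1:n), sprintf("f%d", 1:8)))
  d <- makeSurvData(n, rate = 0.1, censRate = 0.01)
  r <- suppressWarnings(
    supervisedClusterCV(x, d$time, d$event,
                        supervisedConfig(kClusters = 2, nTopFeatures = 4,
                                         nFolds = n, seed = 6)))
  expect_true(all(!is.na(r$assignment$subgroup)))
})

test_that("subgroup evaluation recovers a planted subgroup hazard", {
  set.seed(11)
  n <- 800
  lab <- sample(1:2, n, replace = TRUE)
  d <- makeSurvData(n, rate = 0.02, censRate = 0.01,
                    lp = 1.0 * (lab == 2))
  assign <- data.frame(patient_id = sprintf("P%04d", 1:n), subgroup = lab)
  ev <- evaluateSubgroups(assign, d$time, d$event, reference = 1)
  expect_identical(ev$reference, 1)
  row <- ev$cox[ev$cox$subgroup == "2", ]
  expect_lt(abs(log(row$hr) - 1.0) / ((log(row$upper) - log(row$lower)) / 3.92), 3)
  expect_lt(ev$logrank_p, 1e-6)
})

test_that("exchangeable subgroups show no separation", {
  set.seed(12)
  n <- 400
  lab <- sample(1:2, n, replace = TRUE)  # independent of outcome
  d <- makeSurvData(n)
  ev <- evaluateSubgroups(data.frame(patient_id = seq_len(n), subgroup = lab),
                          d$time, d$event)
  row <- ev$cox[1, ]
  expect_gt(row$upper, 1)  # CI covers HR = 1
  expect_lt(row$lower, 1.5)
  expect_error(
    evaluateSubgroups(data.frame(patient_id = 1:n, subgroup = lab),
                      d$time, d$event, reference = 99),
    "reference")
})

test_that("KM estimate equals the empirical survivor function when uncensored", {
  set.seed(13)
  n <- 60
  time <- rexp(n, 0.1)
  assign <- data.frame(patient_id = 1:n, subgroup = rep(1:2, each = n / 2))
  ev <- evaluateSubgroups(assign, time, rep(1L, n))
  for (g in 1:2) {
    kg <- ev$km[ev$km$subgroup == as.character(g), ]
    tg <- time[assign$subgroup == g]
    emp <- vapply(kg$time, function(t0) mean(tg > t0), numeric(1))
    expect_equal(kg$survival, emp, tolerance = 1e-12)
    expect_false(is.unsorted(rev(kg$survival)))  # non-increasing
  }
})

test_that("the reference subgroup defaults to the best median survival", {
  set.seed(14)
  n <- 300
  lab <- sample(1:3, n, replace = TRUE)
  lp <- c(1.5, 0, 0.8)[lab]  # subgroup 2 has the best survival
  d <- makeSurvData(n, rate = 0.05, censRate = 0.005, lp = lp)
  ev <- evaluateSubgroups(data.frame(patient_id = 1:n, subgroup = lab),
                          d$time, d$event)
  expect_identical(ev$reference, 2L)
})
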