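## Random-survival-forest prognostic model ladder and its evaluation:
## Harrell's concordance with percentile-bootstrap confidence intervals on
## out-of-bag risk predictions, IPCW (Graf) Brier score curves with a
## trapezoid integrated score, and permutation variable importance.

#' Fit a random survival forest
#'
#' Ensemble of survival trees grown on bootstrap samples with the log-rank
#' splitting rule (via `ranger`); out-of-bag cumulative-hazard and survival
#' predictions are retained, and ensemble mortality (the row sum of the OOB
#' cumulative hazard) is the per-patient risk score. Evaluation downstream
#' uses these out-of-bag predictions only.
#'
#' @param features numeric `data.frame`/matrix of predictors (categoricals
#'   already encoded; see [ladderFeatures()]).
#' @param time,event endpoint vectors (>= 1 event required).
#' @param numTrees number of trees.
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param minNodeSize minimal terminal-node size.
#' @param seed integer seed; fixed seed reproduces the forest exactly
#'   (forests are grown single-threaded for determinism).
#' @param importance `"permutation"` (OOB C-index drop after permuting each
#'   feature, averaged over trees) or `"none"`.
#' @return Object of class `RsfModel`: the `ranger` forest plus OOB
#'   survival/CHF matrices (`oobSurvival`, `oobChf`, `times`), the OOB risk
#'   score (`oobMortality`), the OOB concordance and the permutation VIMP.
#' @export
fitRsf <- function(features, time, event, numTrees = 500L, mtry = NULL,
                   minNodeSize = 5L, seed = 1L,
                   importance = c("permutation", "none")) {
  importance <- match.arg(importance)
  features <- as.data.frame(features)
  colnames(features) <- make.names(colnames(features), unique = TRUE)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  const <- vapply(features, function(v) length(unique(v)) <= 1L, logical(1))
  if (any(const)) {
    warning("constant features retained: ",
            paste(names(features)[const], collapse = ", "))
  }
  d <- cbind(.time = time, .event = event, features)
  fit <- ranger::ranger(
    survival::Surv(.time, .event) ~ ., data = d,
    num.trees = numTrees,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(features)))),
    min.node.size = minNodeSize, splitrule = "logrank",
    importance = importance, seed = seed, num.threads = 1L,
    oob.error = TRUE)
  mortality <- rowSums(fit$chf)
  structure(list(forest = fit, oobChf = fit$chf,
                 oobSurvival = fit$survival,
                 times = fit$unique.death.times,
                 oobMortality = mortality,
                 oobConcordance = 1 - fit$prediction.error,
                 importance = if (importance == "permutation")
                   fit$variable.importance else NULL,
                 featureNames = colnames(features), seed = seed),
            class = "RsfModel")
}

#' @export
print.RsfModel <- function(x, ...) {
  cat("Random survival forest:", x$forest$num.trees, "trees,",
      length(x$featureNames), "features\n")
  cat("  OOB concordance:", round(x$oobConcordance, 3), "\n")
  invisible(x)
}

#' Harrell's concordance index with bootstrap confidence interval
#'
#' C over usable pairs — event/event pairs with distinct times and
#' event/censored-later pairs; ties in the risk score count 1/2 — with a
#' percentile bootstrap over patients for the confidence interval.
#'
#' @param risk risk scores (higher = earlier expected failure).
#' @param time,event endpoint vectors.
#' @param B bootstrap resamples for the CI (0 skips the CI).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return List with `c`, `lower`, `upper`, `n` and `nPairs`.
#' @export
concordanceIndex <- function(risk, time, event, B = 1000L, seed = 1L,
                             conf = 0.95) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cidx <- function(idx) {
    cf <- concordance(Surv(time[idx], event[idx]) ~ risk[idx],
                      reverse = TRUE)
    cf
  }
  full <- cidx(seq_along(risk))
  counts <- full$count
  nPairs <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (nPairs < 1) stop("no comparable pairs", call. = FALSE)
  lower <- upper <- NA_real_
  if (B > 0) {
    set.seed(deriveSeed(seed, "bootstrap"))
    bs <- vapply(seq_len(B), function(b) {
      idx <- sample(length(risk), replace = TRUE)
      tryCatch(cidx(idx)$concordance, error = function(e) NA_real_)
    }, numeric(1))
    qs <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    lower <- unname(qs[1L]); upper <- unname(qs[2L])
  }
  list(c = unname(full$concordance), lower = lower, upper = upper,
       n = length(risk), nPairs = unname(nPairs),
       counts = counts[c("concordant", "discordant", "tied.x")])
}

#' IPCW Brier score curve and integrated score
#'
#' Time-indexed mean squared error of predicted survival probabilities
#' against the observed survival status, weighted by the inverse probability
#' of censoring (Graf estimator; the censoring distribution is the
#' Kaplan-Meier of the censoring indicator). Without censoring the weights
#' are 1 and the score is the plain mean squared error of the survival
#' indicator. The integrated score is the trapezoid average over
#' `evalTimes`.
#'
#' @param survPred matrix of predicted survival probabilities, patients in
#'   rows and `evalTimes` in columns (a single column is recycled).
#' @param time,event endpoint vectors.
#' @param evalTimes evaluation times; must not exceed the last observed
#'   follow-up time.
#' @return List with `curve` (`data.frame(time, brier)`) and `integrated`.
#' @export
brierScore <- function(survPred, time, event, evalTimes) {
  n <- length(time)
  if (any(evalTimes > max(time))) {
    stop("evaluation times beyond the last observed follow-up time",
         call. = FALSE)
  }
  if (is.vector(survPred)) survPred <- matrix(survPred, ncol = 1L)
  if (ncol(survPred) == 1L && length(evalTimes) > 1L) {
    survPred <- survPred[, rep(1L, length(evalTimes)), drop = FALSE]
  }
  stopifnot(nrow(survPred) == n, ncol(survPred) == length(evalTimes))
  ## censoring distribution G by Kaplan-Meier; G(t-) via left limit
  Gfit <- survfit(Surv(time, 1 - event) ~ 1)
  Gfun <- stats::stepfun(Gfit$time, c(1, Gfit$surv), right = FALSE)
  GminusFun <- function(t) {
    ## left-continuous version: value just before t
    vapply(t, function(tt) {
      k <- Gfit$time < tt
      if (!any(k)) 1 else Gfit$surv[max(which(k))]
    }, numeric(1))
  }
  Gi <- GminusFun(time)  # G(T_i-)
  bs <- vapply(seq_along(evalTimes), function(j) {
    t0 <- evalTimes[j]
    S <- survPred[, j]
    w <- numeric(n)
    died <- time <= t0 & event == 1
    alive <- time > t0
    w[died] <- 1 / pmax(Gi[died], 1e-10)
    w[alive] <- 1 / pmax(Gfun(t0), 1e-10)
    err <- numeric(n)
    err[died] <- (0 - S[died])^2
    err[alive] <- (1 - S[alive])^2
    sum(w * err) / n
  }, numeric(1))
  curve <- data.frame(time = evalTimes, brier = bs)
  integrated <- if (length(evalTimes) > 1L) {
    dt <- diff(evalTimes)
    sum(dt * (bs[-1] + bs[-length(bs)]) / 2) / diff(range(evalTimes))
  } else {
    bs
  }
  list(curve = curve, integrated = integrated)
}

#' Permutation variable importance of a fitted forest
#'
#' VIMP of each feature: the drop in out-of-bag concordance when the
#' feature's values are permuted, averaged over the trees of the ensemble
#' (computed at fit time from the per-tree OOB samples, so it never touches
#' in-bag predictions). Constant features, which no tree splits on, have
#' VIMP exactly 0.
#'
#' @param model an `RsfModel` from [fitRsf()] (fitted with
#'   `importance = "permutation"`, the default).
#' @return Named numeric VIMP vector, decreasing.
#' @export
permutationImportance <- function(model) {
  if (is.null(model$importance)) {
    stop("model was fitted with importance = 'none'; refit with ",
         "importance = 'permutation'", call. = FALSE)
  }
  sort(model$importance, decreasing = TRUE)
}

## interpolate an OOB survival matrix onto arbitrary evaluation times
.survivalAt <- function(model, evalTimes) {
  S <- model$oobSurvival
  tt <- model$times
  out <- vapply(evalTimes, function(t0) {
    k <- findInterval(t0, tt)
    if (k == 0) rep(1, nrow(S)) else S[, k]
  }, numeric(nrow(S)))
  matrix(out, nrow = nrow(S))
}
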