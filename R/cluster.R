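## Genomic subgrouping: unsupervised K-means on recurrent mutations plus
## cytogenetics, and outcome-guided (supervised) clustering with k-fold
## cross-validation — per fold, features are scored by univariate Cox
## association on the training split only, the top features are retained,
## K-means is fitted on the training split and held-out patients are
## assigned to the nearest centroid, so feature selection never sees the
## held-out outcomes.

#' Vectorised univariate Cox score statistics
#'
#' Computes the partial-likelihood score test z-statistic of every feature
#' column against a right-censored endpoint in one pass (Breslow handling of
#' ties), the feature-screening engine of supervised clustering. Equivalent
#' to fitting `ncol(x)` univariate Cox models and taking their score tests,
#' but O(n p) overall.
#'
#' @param x numeric patients x features matrix.
#' @param time,event follow-up and event indicator.
#' @return Named numeric z-statistics; `NA` for features with zero score
#'   variance (e.g. constant columns).
#' @export
coxScoreZ <- function(x, time, event) {
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  ord <- order(time)
  xs <- x[ord, , drop = FALSE]
  ev <- event[ord] == 1
  ts <- time[ord]
  n <- nrow(xs)
  ## risk-set sums from the tail: S1[k, ] = sum_{i >= k} x_i
  S1 <- apply(xs[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  S2 <- apply((xs * xs)[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  S0 <- (n:1)
  ## ties: every event in a tied block uses the risk set at the block head
  head <- match(ts, ts)  # first index with the same time
  S1e <- S1[head, , drop = FALSE]
  S2e <- S2[head, , drop = FALSE]
  S0e <- S0[head]
  xb <- S1e / S0e
  U <- colSums((xs - xb)[ev, , drop = FALSE])
  V <- colSums((S2e / S0e - xb * xb)[ev, , drop = FALSE])
  z <- U / sqrt(V)
  z[V <= 0] <- NA_real_
  names(z) <- colnames(x)
  z
}

#' Split features by cohort carrier frequency
#'
#' @param x binary patients x features matrix.
#' @param freqThreshold frequency cut in (0, 0.5); features with frequency
#'   at or above it are common, below it rare.
#' @return List with binary matrices `common` and `rare` (a partition of the
#'   input features).
#' @export
splitCommonRare <- function(x, freqThreshold = 0.01) {
  if (freqThreshold <= 0 || freqThreshold >= 0.5) {
    stop("configuration error: 'freqThreshold' must lie in (0, 0.5)",
         call. = FALSE)
  }
  freq <- colMeans(x)
  list(common = x[, freq >= freqThreshold, drop = FALSE],
       rare = x[, freq < freqThreshold, drop = FALSE])
}

#' Unsupervised genomic subgroups by K-means
#'
#' K-means (Euclidean distance on the binary 0/1 values, multiple restarts)
#' on a recurrent-mutation + cytogenetics feature matrix. When `k` is not
#' given, it is chosen as the value in `kRange` maximising the mean
#' silhouette width.
#'
#' @param x binary patients x features matrix (row names = patient ids).
#' @param k fixed number of clusters; `NULL` selects by silhouette.
#' @param kRange candidate cluster numbers for silhouette selection.
#' @param seed integer seed (restarts are seed-derived, so a fixed seed
#'   gives a deterministic partition).
#' @param nstart number of K-means restarts; the best objective is kept.
#' @return List with `assignment` (`data.frame(patient_id, subgroup)`,
#'   labels contiguous and ordered by decreasing cluster size), `k`,
#'   `silhouette` (mean width per candidate k), `centers` and
#'   `withinss` (final K-means objective).
#' @export
unsupervisedSubgroups <- function(x, k = NULL, kRange = 2:6, seed = 1L,
                                  nstart = 20L) {
  if (ncol(x) < 2L) stop("at least two features are required", call. = FALSE)
  if (nrow(unique(x)) < 2L) {
    stop("degenerate feature matrix: all patients identical", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%04d", seq_len(nrow(x)))
  sil <- NULL
  if (is.null(k)) {
    kRange <- kRange[kRange >= 2 & kRange <= nrow(unique(x))]
    if (!length(kRange)) stop("no admissible k in 'kRange'", call. = FALSE)
    D <- dist(x)
    sil <- vapply(kRange, function(kk) {
      set.seed(deriveSeed(seed, "kmeans", kk))
      cl <- kmeans(x, centers = kk, nstart = nstart, iter.max = 50L)
      mean(cluster::silhouette(cl$cluster, D)[, "sil_width"])
    }, numeric(1))
    names(sil) <- kRange
    k <- kRange[which.max(sil)]
  }
  k <- as.integer(k)
  set.seed(deriveSeed(seed, "kmeans", k))
  cl <- kmeans(x, centers = k, nstart = nstart, iter.max = 50L)
  relabel <- order(tabulate(cl$cluster, k), decreasing = TRUE)
  newLab <- match(cl$cluster, relabel)
  list(assignment = data.frame(patient_id = rownames(x),
                               subgroup = newLab,
                               method = "unsupervised",
                               stringsAsFactors = FALSE),
       k = k, silhouette = sil,
       centers = cl$centers[relabel, , drop = FALSE],
       withinss = cl$tot.withinss)
}

#' Outcome-guided clustering with k-fold cross-validation
#'
#' For each fold: (1) every feature is scored on the training split only by
#' its univariate Cox score z against the endpoint, (2) the
#' `nTopFeatures` features with largest |z| are retained, (3) K-means is
#' fitted on the training split over the retained features, (4) held-out
#' patients are assigned to the nearest training centroid, (5) the held-out
#' survival separation is recorded by log-rank. Final subgroup labels are
#' the out-of-fold assignments; cluster labels are aligned across folds by
#' matching full-feature cluster mean profiles to the first completed fold.
#'
#' @param x binary patients x features matrix.
#' @param time,event endpoint aligned with the rows of `x`.
#' @param config a [supervisedConfig()].
#' @return List with `assignment` (`patient_id`, `subgroup`, `fold`),
#'   `folds` (per-fold diagnostics: selected features, training ids,
#'   held-out log-rank p), `oofLogrankP` (log-rank over all out-of-fold
#'   labels), `selectedConsensus` (features selected in at least half of the
#'   completed folds) and `config`.
#' @export
supervisedClusterCV <- function(x, time, event, config = supervisedConfig()) {
  validObject(config)
  n <- nrow(x)
  if (length(time) != n || length(event) != n) {
    stop("outcome vectors must align with the feature matrix", call. = FALSE)
  }
  if (config@nTopFeatures > ncol(x)) {
    stop("configuration error: 'nTopFeatures' exceeds the feature count",
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%04d", seq_len(n))
  k <- config@kClusters
  set.seed(deriveSeed(config@seed, "folds"))
  foldId <- sample(rep_len(seq_len(config@nFolds), n))
  labels <- rep(NA_integer_, n)
  foldOut <- list()
  refProfile <- NULL
  for (f in sort(unique(foldId))) {
    test <- which(foldId == f)
    train <- which(foldId != f)
    if (sum(event[train]) < 1) {
      warning("fold ", f, " skipped: no events in training split")
      next
    }
    z <- coxScoreZ(x[train, , drop = FALSE], time[train], event[train])
    z[is.na(z)] <- 0
    sel <- names(sort(abs(z), decreasing = TRUE))[seq_len(config@nTopFeatures)]
    set.seed(deriveSeed(config@seed, "kmeans", f))
    km <- kmeans(x[train, sel, drop = FALSE], centers = k, nstart = 20L,
                 iter.max = 50L)
    ## align labels across folds on full-feature cluster mean profiles
    profile <- t(vapply(seq_len(k), function(cc) {
      colMeans(x[train[km$cluster == cc], , drop = FALSE])
    }, numeric(ncol(x))))
    if (is.null(refProfile)) {
      refProfile <- profile
      mapping <- seq_len(k)
    } else {
      mapping <- .greedyMatch(profile, refProfile)
    }
    ## nearest-centroid assignment of held-out patients
    xt <- x[test, sel, drop = FALSE]
    d2 <- outer(rowSums(xt * xt), rowSums(km$centers^2), "+") -
      2 * xt %*% t(km$centers)
    assigned <- max.col(-d2, ties.method = "first")
    labels[test] <- mapping[assigned]
    lr <- .logrankP(time[test], event[test], mapping[assigned])
    foldOut[[length(foldOut) + 1L]] <- list(
      fold = f, train_ids = rownames(x)[train],
      test_ids = rownames(x)[test], selected = sel,
      logrank_p = lr, kmeans_objective = km$tot.withinss)
  }
  if (!length(foldOut)) {
    stop("all folds skipped: no usable training events", call. = FALSE)
  }
  done <- !is.na(labels)
  oof <- .logrankP(time[done], event[done], labels[done])
  selList <- lapply(foldOut, `[[`, "selected")
  tab <- table(unlist(selList))
  consensus <- names(tab)[tab >= length(selList) / 2]
  list(assignment = data.frame(patient_id = rownames(x),
                               subgroup = labels,
                               method = "supervised",
                               fold = foldId, stringsAsFactors = FALSE),
       folds = foldOut, oofLogrankP = oof,
       selectedConsensus = consensus, config = config)
}

## greedy one-to-one matching of cluster profiles to a reference
.greedyMatch <- function(profile, refProfile) {
  k <- nrow(profile)
  cost <- as.matrix(stats::dist(rbind(profile, refProfile)))[seq_len(k),
                                                             k + seq_len(k)]
  mapping <- integer(k)
  for (i in seq_len(k)) {
    idx <- which(cost == min(cost, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    mapping[idx[1L]] <- idx[2L]
    cost[idx[1L], ] <- NA
    cost[, idx[2L]] <- NA
  }
  mapping
}

.logrankP <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) < 2L || sum(event) < 1 || length(time) < 3L) {
    return(NA_real_)
  }
  sd <- tryCatch(survdiff(Surv(time, event) ~ g), error = function(e) NULL)
  if (is.null(sd)) return(NA_real_)
  pchisq(sd$chisq, df = nlevels(g) - 1L, lower.tail = FALSE)
}

#' Survival separation of genomic subgroups
#'
#' Kaplan-Meier curves per subgroup, the overall log-rank test, and a
#' multivariable Cox model with subgroup indicators against a reference
#' subgroup, adjusted for clinical covariates. The reference defaults to the
#' subgroup with the longest median OS.
#'
#' @param assignment `data.frame` with `patient_id` and `subgroup` (from
#'   [unsupervisedSubgroups()] or [supervisedClusterCV()]).
#' @param time,event endpoint aligned with `assignment` rows.
#' @param clinical optional adjustment covariate `data.frame`.
#' @param reference reference subgroup label; `NULL` picks the subgroup with
#'   the longest median survival.
#' @return List with `km` (per-subgroup life table: time, n.risk, survival),
#'   `logrank_p`, `cox` (`DataFrame` of per-subgroup HR, CI, p vs the
#'   reference) and `reference`.
#' @export
evaluateSubgroups <- function(assignment, time, event, clinical = NULL,
                              reference = NULL) {
  lab <- assignment$subgroup
  ok <- !is.na(lab)
  lab <- lab[ok]; time <- time[ok]; event <- event[ok]
  if (!is.null(clinical)) clinical <- clinical[ok, , drop = FALSE]
  groups <- sort(unique(lab))
  if (length(groups) < 2L) {
    stop("at least two subgroups with patients are required", call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% groups) {
    stop("reference subgroup '", reference, "' not present", call. = FALSE)
  }
  fitAll <- survfit(Surv(time, event) ~ lab)
  med <- summary(fitAll)$table
  med <- if (is.matrix(med)) med[, "median"] else med[["median"]]
  if (is.null(reference)) {
    medv <- as.numeric(med)
    medv[is.na(medv)] <- Inf  # median never reached = best survival
    reference <- groups[which.max(medv)]
  }
  g <- stats::relevel(factor(lab), ref = as.character(reference))
  Z <- .covariateDesign(clinical)
  G <- stats::model.matrix(~g)[, -1, drop = FALSE]
  colnames(G) <- paste0("subgroup", levels(g)[-1])
  fit <- .coxFitRaw(cbind(G, Z), time, event)
  idx <- seq_len(ncol(G))
  beta <- fit$coefficients[idx]
  se <- sqrt(diag(fit$var)[idx])
  cox <- DataFrame(subgroup = levels(g)[-1], hr = exp(beta),
                   lower = exp(beta - 1.96 * se),
                   upper = exp(beta + 1.96 * se),
                   p = 2 * pnorm(-abs(beta / se)))
  ## life table per subgroup
  smry <- summary(fitAll)
  kmGroup <- if (!is.null(smry$strata)) {
    sub("^lab=", "", as.character(smry$strata))
  } else {
    rep(as.character(groups[1L]), length(smry$time))
  }
  km <- data.frame(subgroup = kmGroup, time = smry$time,
                   n_risk = smry$n.risk, n_event = smry$n.event,
                   survival = smry$surv, stringsAsFactors = FALSE)
  list(km = km, logrank_p = .logrankP(time, event, lab), cox = cox,
       reference = reference)
}
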