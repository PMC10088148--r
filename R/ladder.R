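## The four-model prognostic ladder evaluated across OS, DFS, relapse and
## TRM: base (IPSS-R only), clinical (base + MDS type + HMA + chemotherapy),
## genomic (mutational count over association candidates + supervised and
## unsupervised subgroup labels), and full (clinical + genomic). Relapse and
## TRM are modelled as single-event endpoints with the competing first event
## censored at its time (primary mode) or with competing-event patients
## excluded (sensitivity mode).

#' Per-patient mutational count over association candidates
#'
#' @param ce a [CarrierExperiment-class].
#' @param candidateRegions region ids (e.g. significant regions of a
#'   [genomeScan()]); ids absent from the matrix are ignored.
#' @return Named integer vector: number of candidate regions carried.
#' @export
mutationalCount <- function(ce, candidateRegions) {
  keep <- intersect(candidateRegions, rownames(ce))
  m <- carrierMatrix(ce, transpose = TRUE)
  if (!length(keep)) {
    return(setNames(integer(ncol(ce)), colnames(ce)))
  }
  rowSums(m[, keep, drop = FALSE])
}

#' Select association candidates from scan results
#'
#' @param results `DataFrame` from [genomeScan()].
#' @param qThreshold BH q-value cutoff.
#' @param maxRegions cap on the number of candidates (smallest p first).
#' @return Character vector of region ids.
#' @export
selectCandidates <- function(results, qThreshold = 0.05, maxRegions = 25L) {
  ok <- !is.na(results$q_bh) & results$q_bh < qThreshold & results$converged
  ids <- results$region_id[ok]
  head(ids, maxRegions)
}

#' Assemble the feature matrix of one ladder model
#'
#' Encodings: IPSS-R ordinally (integer score), MDS type one-hot, binary
#' exposures as 0/1, subgroup labels one-hot. The feature sets are nested:
#' base is contained in clinical, clinical and genomic in full.
#'
#' @param model `"base"`, `"clinical"`, `"genomic"` or `"full"`.
#' @param clinical clinical covariate table ([readClinical()] layout).
#' @param mutationCount per-patient candidate mutation count
#'   ([mutationalCount()]); used by the genomic and full models.
#' @param supervised,unsupervised per-patient subgroup labels (vectors
#'   aligned with `clinical`).
#' @return Numeric `data.frame` of model features.
#' @export
ladderFeatures <- function(model = c("base", "clinical", "genomic", "full"),
                           clinical, mutationCount = NULL,
                           supervised = NULL, unsupervised = NULL) {
  model <- match.arg(model)
  oneHot <- function(v, prefix) {
    f <- factor(v)
    mm <- stats::model.matrix(~ f - 1)
    colnames(mm) <- paste0(prefix, "_", levels(f))
    as.data.frame(mm)
  }
  base <- data.frame(ipss_r = as.integer(factor(clinical$ipss_r_risk)))
  clin <- cbind(base, oneHot(clinical$mds_type, "mdstype"),
                hma = clinical$hma_exposure,
                chemo = clinical$chemo_exposure)
  gen <- NULL
  if (model %in% c("genomic", "full")) {
    if (is.null(supervised) || is.null(unsupervised)) {
      stop("genomic and full models need both subgroup label vectors",
           call. = FALSE)
    }
    gen <- cbind(
      data.frame(mutational_count = mutationCount %||%
                   rep(0L, nrow(clinical))),
      oneHot(supervised, "supgroup"), oneHot(unsupervised, "unsgroup"))
  }
  switch(model,
         base = base,
         clinical = clin,
         genomic = gen,
         full = cbind(clin, gen))
}

.endpointOutcome <- function(outcomes, endpoint,
                             competingMode = c("censor", "exclude")) {
  competingMode <- match.arg(competingMode)
  keep <- rep(TRUE, nrow(outcomes))
  switch(endpoint,
    os = list(time = outcomes$os_time, event = outcomes$os_event,
              keep = keep),
    dfs = list(time = outcomes$dfs_time, event = outcomes$dfs_event,
               keep = keep),
    relapse = {
      if (competingMode == "exclude") keep <- outcomes$first_event_code != 2L
      list(time = outcomes$dfs_time,
           event = as.integer(outcomes$first_event_code == 1L), keep = keep)
    },
    trm = {
      if (competingMode == "exclude") keep <- outcomes$first_event_code != 1L
      list(time = outcomes$dfs_time,
           event = as.integer(outcomes$first_event_code == 2L), keep = keep)
    },
    stop("unknown endpoint: ", endpoint, call. = FALSE))
}

#' Fit and evaluate the prognostic model ladder
#'
#' Fits the four nested random-survival-forest models for each requested
#' endpoint and evaluates them on out-of-bag predictions only: Harrell's C
#' with a percentile-bootstrap CI, the IPCW Brier curve and its integrated
#' value, and permutation feature importance. When `strata` names a clinical
#' column (e.g. `conditioning_regimen`), each model is additionally
#' evaluated within every stratum by restricting the OOB predictions to the
#' stratum's patients.
#'
#' @param clinical,outcomes cohort tables aligned on `patient_id`.
#' @param mutationCount per-patient candidate count ([mutationalCount()]).
#' @param supervised,unsupervised subgroup label vectors.
#' @param endpoints subset of `c("os","dfs","relapse","trm")`.
#' @param models subset of the four ladder models.
#' @param strata `NULL` (overall only) or the name of a clinical column to
#'   stratify the evaluation by.
#' @param numTrees,minNodeSize forest size and node size.
#' @param bootB bootstrap resamples for the concordance CI.
#' @param competingMode `"censor"` (default) or `"exclude"` for the
#'   relapse/TRM endpoints.
#' @param nEvalTimes number of Brier evaluation times (quantiles of the
#'   observed event times).
#' @param seed global seed; per-cell seeds are derived from it.
#' @return Object of class `LadderEvaluation`: `table` (one row per model x
#'   endpoint x stratum with C and CI), `brier` (long curve table), `vimp`
#'   (long importance table) and the call parameters.
#' @export
evaluateLadder <- function(clinical, outcomes, mutationCount,
                           supervised, unsupervised,
                           endpoints = c("os", "dfs", "relapse", "trm"),
                           models = c("base", "clinical", "genomic", "full"),
                           strata = NULL, numTrees = 500L, minNodeSize = 5L,
                           bootB = 1000L,
                           competingMode = c("censor", "exclude"),
                           nEvalTimes = 10L, seed = 1L) {
  competingMode <- match.arg(competingMode)
  stopifnot(identical(clinical$patient_id, outcomes$patient_id))
  strataLevels <- list(all = rep(TRUE, nrow(clinical)))
  if (!is.null(strata)) {
    if (!strata %in% colnames(clinical)) {
      stop("stratum column '", strata, "' absent from the clinical table",
           call. = FALSE)
    }
    for (lv in sort(unique(clinical[[strata]]))) {
      strataLevels[[lv]] <- clinical[[strata]] == lv
    }
  }
  rowsTab <- list(); rowsBrier <- list(); rowsVimp <- list()
  cell <- 0L
  for (ep in endpoints) {
    oc <- .endpointOutcome(outcomes, ep, competingMode)
    for (mod in models) {
      cell <- cell + 1L
      feats <- ladderFeatures(mod, clinical, mutationCount, supervised,
                              unsupervised)
      keep <- oc$keep
      fit <- fitRsf(feats[keep, , drop = FALSE], oc$time[keep],
                    oc$event[keep], numTrees = numTrees,
                    minNodeSize = minNodeSize,
                    seed = deriveSeed(seed, "model", cell))
      risk <- fit$oobMortality
      for (st in names(strataLevels)) {
        sel <- strataLevels[[st]][keep]
        if (sum(oc$event[keep][sel]) < 1) {
          rowsTab[[length(rowsTab) + 1L]] <- data.frame(
            model = mod, endpoint = ep, stratum = st, c = NA_real_,
            lower = NA_real_, upper = NA_real_, n = sum(sel),
            n_events = 0L, note = "not evaluable: no events",
            stringsAsFactors = FALSE)
          next
        }
        ci <- concordanceIndex(risk[sel], oc$time[keep][sel],
                               oc$event[keep][sel], B = bootB,
                               seed = deriveSeed(seed, "bootstrap", cell))
        rowsTab[[length(rowsTab) + 1L]] <- data.frame(
          model = mod, endpoint = ep, stratum = st, c = ci$c,
          lower = ci$lower, upper = ci$upper, n = ci$n,
          n_events = sum(oc$event[keep][sel]), note = "",
          stringsAsFactors = FALSE)
      }
      ## Brier on the overall cohort
      evTimes <- unique(quantile(oc$time[keep][oc$event[keep] == 1],
                                 probs = seq(0.1, 0.9,
                                             length.out = nEvalTimes),
                                 names = FALSE))
      S <- .survivalAt(fit, evTimes)
      br <- brierScore(S, oc$time[keep], oc$event[keep], evTimes)
      rowsBrier[[length(rowsBrier) + 1L]] <- cbind(
        data.frame(model = mod, endpoint = ep), br$curve,
        integrated = br$integrated)
      vi <- permutationImportance(fit)
      rowsVimp[[length(rowsVimp) + 1L]] <- data.frame(
        model = mod, endpoint = ep, feature = names(vi), vimp = unname(vi),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rowsTab),
                 brier = do.call(rbind, rowsBrier),
                 vimp = do.call(rbind, rowsVimp),
                 endpoints = endpoints, models = models,
                 competingMode = competingMode, seed = seed),
            class = "LadderEvaluation")
}

#' @export
print.LadderEvaluation <- function(x, ...) {
  cat("Prognostic model ladder evaluation (OOB)\n")
  print(ladderGrid(x), row.names = FALSE)
  invisible(x)
}

#' Concordance grid in the ladder layout
#'
#' One row per model (and per evaluation stratum), one column per endpoint,
#' entries formatted as `C (lower-upper)`.
#'
#' @param evaluation a `LadderEvaluation` from [evaluateLadder()].
#' @return `data.frame` grid.
#' @export
ladderGrid <- function(evaluation) {
  tab <- evaluation$table
  tab$rowlab <- ifelse(tab$stratum == "all", tab$model,
                       paste0(tab$model, " (", tab$stratum, ")"))
  fmt <- ifelse(is.na(tab$c), "NE",
                sprintf("%.2f (%.2f-%.2f)", tab$c, tab$lower, tab$upper))
  wide <- data.frame(model = unique(tab$rowlab), stringsAsFactors = FALSE)
  for (ep in evaluation$endpoints) {
    col <- fmt[tab$endpoint == ep][match(wide$model,
                                         tab$rowlab[tab$endpoint == ep])]
    wide[[ep]] <- col
  }
  wide
}
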