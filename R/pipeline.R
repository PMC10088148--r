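## End-to-end pipeline: simulate -> aggregate -> scan -> cluster -> model ->
## report, driven by one YAML/JSON config and one global seed, with a
## digest-based manifest for reproducibility and incremental re-runs. All
## tabular outputs are TSV; the manifest records an md5 digest per output
## file, so a stage whose outputs are intact (and whose upstream stages did
## not re-run) is skipped.

.PIPELINE_STAGES <- c("simulate", "aggregate", "scan", "cluster", "model",
                      "report")

.KNOWN_BLOCKS <- c("seed", "inputs", .PIPELINE_STAGES)

#' Write / read a carrier matrix as TSV
#'
#' Regions in rows (column `region_id` first), patients in columns.
#'
#' @param ce a [CarrierExperiment-class].
#' @param path output TSV path.
#' @return `writeCarrierMatrix`: the path, invisibly. `readCarrierMatrix`:
#'   a [CarrierExperiment-class] (ranges are not preserved by the TSV, only
#'   identities and the scheme).
#' @export
writeCarrierMatrix <- function(ce, path) {
  m <- carrierMatrix(ce)
  df <- cbind(data.frame(region_id = rownames(m), stringsAsFactors = FALSE),
              as.data.frame(m, check.names = FALSE))
  .writeTsv(df, path)
}

#' @rdname writeCarrierMatrix
#' @param scheme scheme label of the stored matrix.
#' @export
readCarrierMatrix <- function(path, scheme = "gene_all") {
  df <- .readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  storage.mode(m) <- "integer"
  CarrierExperiment(m, scheme = scheme)
}

.configError <- function(path, why) {
  stop("config error at ", path, ": ", why, call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks block names, stage parameters and input paths; unknown keys and
#' missing required entries raise an error naming the offending path into
#' the config. Defaults are filled in explicitly so the manifest records
#' the exact configuration that ran.
#'
#' @param config list (parsed YAML/JSON) or a path to a config file.
#' @return The validated config with defaults filled in.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  unknown <- setdiff(names(config), .KNOWN_BLOCKS)
  if (length(unknown)) .configError(unknown[1L], "unknown block")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$simulate) && is.null(config$inputs)) {
    .configError("inputs", paste0("either a 'simulate' block or an 'inputs'",
                                  " block with cohort file paths is required"))
  }
  if (is.null(config$simulate)) {
    for (f in c("vcf", "bed", "layout", "clinical", "outcomes")) {
      if (is.null(config$inputs[[f]])) {
        .configError(paste0("inputs.", f), "required path missing")
      }
    }
  } else {
    simKnown <- names(formals(simulationConfig))
    bad <- setdiff(names(config$simulate), simKnown)
    if (length(bad)) .configError(paste0("simulate.", bad[1L]), "unknown field")
  }
  agg <- config$aggregate %||% list()
  agg$minCarriers <- agg$minCarriers %||% 3L
  agg$windowSize <- agg$windowSize %||% 10000L
  agg$step <- agg$step %||% 5000L
  if (agg$step > agg$windowSize) {
    .configError("aggregate.step", "must not exceed aggregate.windowSize")
  }
  config$aggregate <- agg
  sc <- config$scan %||% list()
  sc$endpoint <- sc$endpoint %||% "os"
  if (!sc$endpoint %in% c("os", "dfs", "relapse", "trm")) {
    .configError("scan.endpoint", "must be one of os, dfs, relapse, trm")
  }
  sc$test <- sc$test %||%
    if (sc$endpoint %in% c("relapse", "trm")) "fine_gray" else "cox_wald"
  if (sc$test == "fine_gray" && !sc$endpoint %in% c("relapse", "trm")) {
    .configError("scan.test",
                 "fine_gray requires endpoint 'relapse' or 'trm'")
  }
  sc$adjust <- sc$adjust %||% c("ipss_r_risk", "hma_exposure")
  sc$schemes <- sc$schemes %||% c("gene_all", "gene_nonsyn", "window")
  config$scan <- sc
  cl <- config$cluster %||% list()
  cl$kRange <- cl$kRange %||% c(2L, 6L)
  cl$freqThreshold <- cl$freqThreshold %||% 0.01
  cl$kClusters <- cl$kClusters %||% 3L
  cl$nTopFeatures <- cl$nTopFeatures %||% 50L
  cl$nFolds <- cl$nFolds %||% 5L
  config$cluster <- cl
  mo <- config$model %||% list()
  mo$numTrees <- mo$numTrees %||% 500L
  mo$minNodeSize <- mo$minNodeSize %||% 5L
  mo$bootB <- mo$bootB %||% 1000L
  mo$endpoints <- mo$endpoints %||% c("os", "dfs", "relapse", "trm")
  mo$strata <- mo$strata %||% "conditioning_regimen"
  mo$competingMode <- mo$competingMode %||% "censor"
  config$model <- mo
  config
}

.md5 <- function(paths) {
  d <- tools::md5sum(paths)
  names(d) <- basename(names(d))
  d
}

.stageOutputs <- list(
  simulate = c("simulate/cohort.vcf", "simulate/clinical.tsv",
               "simulate/outcomes.tsv", "simulate/regions.bed",
               "simulate/layout.tsv", "simulate/truth.json"),
  aggregate = c("aggregate/matrix_gene_all.tsv",
                "aggregate/matrix_gene_nonsyn.tsv",
                "aggregate/matrix_window.tsv"),
  scan = NULL,     # depends on configured schemes
  cluster = c("cluster/unsupervised.tsv", "cluster/supervised.tsv",
              "cluster/diagnostics.json", "cluster/km.tsv"),
  model = c("model/table1.tsv", "model/brier.tsv", "model/vimp.tsv"),
  report = c("report/ladder_grid.tsv", "report/volcano.tsv",
             "report/km.tsv", "report/summary.json")
)

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing every output under
#' `outDir` and a `manifest.json` with per-file md5 digests, the config
#' hash and the global seed. A stage is skipped when a previous manifest
#' shows all its outputs intact on disk and nothing upstream re-ran.
#'
#' @param config config list or path (see [validatePipelineConfig()]).
#' @param outDir output directory.
#' @param seed optional override of the config seed.
#' @param force re-run every stage regardless of the manifest.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = NULL, force = FALSE) {
  config <- validatePipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- as.integer(config$seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfgHashFile <- tempfile(); writeLines(cfgJson, cfgHashFile)
  cfgHash <- unname(tools::md5sum(cfgHashFile)); unlink(cfgHashFile)

  prev <- NULL
  manifestPath <- file.path(outDir, "manifest.json")
  if (file.exists(manifestPath) && !force) {
    prev <- tryCatch(jsonlite::read_json(manifestPath, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) &&
        (!identical(unname(prev$config_hash), unname(cfgHash)) ||
         !identical(as.integer(prev$seed), seed))) {
      prev <- NULL  # config or seed changed: everything re-runs
    }
  }

  outputsOf <- .stageOutputs
  outputsOf$scan <- c(
    sprintf("scan/results_%s.tsv", config$scan$schemes),
    sprintf("scan/volcano_%s.tsv", config$scan$schemes))
  if (is.null(config$simulate)) outputsOf$simulate <- character()

  stageDigests <- list()
  upstreamReran <- FALSE
  ranStages <- character()

  canSkip <- function(stage) {
    if (upstreamReran || is.null(prev)) return(FALSE)
    rec <- prev$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    files <- file.path(outDir, outputsOf[[stage]])
    if (!all(file.exists(files))) return(FALSE)
    cur <- .md5(files)
    identical(unname(cur), unname(unlist(rec$outputs)))
  }
  finishStage <- function(stage) {
    files <- file.path(outDir, outputsOf[[stage]])
    stageDigests[[stage]] <<- as.list(.md5(files))
    ranStages <<- c(ranStages, stage)
  }

  env <- new.env(parent = emptyenv())

  ## ---- simulate ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    if (canSkip("simulate")) {
      message("pipeline: simulate up to date, skipping")
      stageDigests$simulate <- prev$stages$simulate$outputs
      env$paths <- setNames(
        file.path(outDir, outputsOf$simulate),
        c("vcf", "clinical", "outcomes", "bed", "layout", "truth"))
    } else {
      message("pipeline: simulate")
      args <- config$simulate
      args$seed <- deriveSeed(seed, "simulate")
      sim <- do.call(simulationConfig, args)
      env$paths <- writeCohort(simulateCohort(sim),
                               file.path(outDir, "simulate"))
      finishStage("simulate")
      upstreamReran <- TRUE
    }
  } else {
    env$paths <- unlist(config$inputs)
  }

  clinical <- readClinical(env$paths[["clinical"]])
  outcomes <- readOutcomes(env$paths[["outcomes"]])

  ## ---- aggregate -----------------------------------------------------------
  aggDir <- file.path(outDir, "aggregate")
  if (canSkip("aggregate")) {
    message("pipeline: aggregate up to date, skipping")
    stageDigests$aggregate <- prev$stages$aggregate$outputs
  } else {
    message("pipeline: aggregate")
    dir.create(aggDir, showWarnings = FALSE)
    variants <- readVcfVariants(env$paths[["vcf"]],
                                sampleSubset = clinical$patient_id)
    genes <- readGeneBed(env$paths[["bed"]])
    layout <- readGenomeLayout(env$paths[["layout"]])
    ceAll <- collapseByGene(variants, genes, "any",
                            patients = clinical$patient_id)
    ceNs <- collapseByGene(variants, genes, "nonsynonymous_coding",
                           patients = clinical$patient_id)
    wchrom <- layout[!layout$chrom %in%
                       as.character(unique(seqnames(genes))), , drop = FALSE]
    windows <- buildWindows(wchrom, config$aggregate$windowSize,
                            config$aggregate$step)
    ceW <- collapseByRegions(variants, windows,
                             patients = clinical$patient_id,
                             scheme = "window")
    writeCarrierMatrix(ceAll, file.path(aggDir, "matrix_gene_all.tsv"))
    writeCarrierMatrix(ceNs, file.path(aggDir, "matrix_gene_nonsyn.tsv"))
    writeCarrierMatrix(ceW, file.path(aggDir, "matrix_window.tsv"))
    finishStage("aggregate")
    upstreamReran <- TRUE
  }
  mats <- list(
    gene_all = readCarrierMatrix(file.path(aggDir, "matrix_gene_all.tsv"),
                                 "gene_all"),
    gene_nonsyn = readCarrierMatrix(
      file.path(aggDir, "matrix_gene_nonsyn.tsv"), "gene_nonsyn"),
    window = readCarrierMatrix(file.path(aggDir, "matrix_window.tsv"),
                               "window"))

  epOutcome <- .endpointOutcome(outcomes, config$scan$endpoint)
  scanEvent <- if (config$scan$test == "fine_gray") {
    outcomes$first_event_code
  } else {
    epOutcome$event
  }
  covars <- clinical[, intersect(config$scan$adjust, colnames(clinical)),
                     drop = FALSE]

  ## ---- scan ----------------------------------------------------------------
  scanDir <- file.path(outDir, "scan")
  if (canSkip("scan")) {
    message("pipeline: scan up to date, skipping")
    stageDigests$scan <- prev$stages$scan$outputs
  } else {
    message("pipeline: scan")
    dir.create(scanDir, showWarnings = FALSE)
    for (scheme in config$scan$schemes) {
      ce <- filterMinCarriers(mats[[scheme]], config$aggregate$minCarriers)
      res <- genomeScan(ce, epOutcome$time, scanEvent, covariates = covars,
                        test = config$scan$test,
                        cause = if (config$scan$endpoint %in%
                                      c("relapse", "trm"))
                          config$scan$endpoint else "relapse")
      .writeTsv(as.data.frame(res),
                file.path(scanDir, sprintf("results_%s.tsv", scheme)))
      .writeTsv(volcanoTable(res),
                file.path(scanDir, sprintf("volcano_%s.tsv", scheme)))
    }
    finishStage("scan")
    upstreamReran <- TRUE
  }

  ## ---- cluster -------------------------------------------------------------
  clDir <- file.path(outDir, "cluster")
  if (canSkip("cluster")) {
    message("pipeline: cluster up to date, skipping")
    stageDigests$cluster <- prev$stages$cluster$outputs
  } else {
    message("pipeline: cluster")
    dir.create(clDir, showWarnings = FALSE)
    recurrent <- .pipelineRecurrentFeatures(mats$gene_all, clinical)
    uns <- unsupervisedSubgroups(
      recurrent, k = NULL,
      kRange = seq(config$cluster$kRange[1], config$cluster$kRange[2]),
      seed = deriveSeed(seed, "cluster"))
    allFeat <- cbind(carrierMatrix(mats$gene_all, transpose = TRUE),
                     carrierMatrix(mats$window, transpose = TRUE))
    common <- splitCommonRare(allFeat, config$cluster$freqThreshold)$common
    sup <- supervisedClusterCV(
      common, outcomes$os_time, outcomes$os_event,
      supervisedConfig(kClusters = config$cluster$kClusters,
                       nTopFeatures = min(config$cluster$nTopFeatures,
                                          ncol(common)),
                       nFolds = config$cluster$nFolds,
                       seed = deriveSeed(seed, "cluster", 2L)))
    .writeTsv(uns$assignment, file.path(clDir, "unsupervised.tsv"))
    .writeTsv(sup$assignment, file.path(clDir, "supervised.tsv"))
    diag <- list(
      unsupervised = list(k = uns$k, silhouette = as.list(uns$silhouette)),
      supervised = list(
        oof_logrank_p = sup$oofLogrankP,
        consensus_features = sup$selectedConsensus,
        folds = lapply(sup$folds, function(f)
          f[c("fold", "logrank_p", "kmeans_objective")])))
    jsonlite::write_json(diag, file.path(clDir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ev <- evaluateSubgroups(uns$assignment, outcomes$os_time,
                            outcomes$os_event)
    .writeTsv(ev$km, file.path(clDir, "km.tsv"))
    finishStage("cluster")
    upstreamReran <- TRUE
  }
  unsLab <- .readTsv(file.path(clDir, "unsupervised.tsv"))$subgroup
  supLab <- .readTsv(file.path(clDir, "supervised.tsv"))$subgroup

  ## ---- model ---------------------------------------------------------------
  moDir <- file.path(outDir, "model")
  if (canSkip("model")) {
    message("pipeline: model up to date, skipping")
    stageDigests$model <- prev$stages$model$outputs
  } else {
    message("pipeline: model")
    dir.create(moDir, showWarnings = FALSE)
    scanRes <- .readTsv(file.path(scanDir, "results_gene_all.tsv"))
    cand <- selectCandidates(scanRes)
    mc <- mutationalCount(mats$gene_all, cand)
    strata <- config$model$strata
    if (!is.null(strata) && !strata %in% colnames(clinical)) strata <- NULL
    lad <- evaluateLadder(
      clinical, outcomes, mc, supLab, unsLab,
      endpoints = config$model$endpoints, strata = strata,
      numTrees = config$model$numTrees,
      minNodeSize = config$model$minNodeSize,
      bootB = config$model$bootB,
      competingMode = config$model$competingMode,
      seed = deriveSeed(seed, "model"))
    .writeTsv(lad$table, file.path(moDir, "table1.tsv"))
    .writeTsv(lad$brier, file.path(moDir, "brier.tsv"))
    .writeTsv(lad$vimp, file.path(moDir, "vimp.tsv"))
    finishStage("model")
    upstreamReran <- TRUE
  }

  ## ---- report --------------------------------------------------------------
  if (canSkip("report")) {
    message("pipeline: report up to date, skipping")
    stageDigests$report <- prev$stages$report$outputs
  } else {
    message("pipeline: report")
    renderReport(outDir, primaryScheme = config$scan$schemes[1L])
    finishStage("report")
  }

  manifest <- list(
    tool = "mdswgs", version = as.character(packageVersion("mdswgs")),
    seed = seed, config_hash = unname(cfgHash), config = config,
    stages = lapply(stageDigests, function(d) list(outputs = d)))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message("pipeline: done (", length(ranStages), " stage(s) executed: ",
          paste(ranStages, collapse = ", "), ")")
  invisible(manifest)
}

## recurrent-driver + cytogenetic feature matrix for the unsupervised path;
## falls back to the most frequent gene features when the canonical driver
## symbols are not in the region dictionary
.pipelineRecurrentFeatures <- function(ceGeneAll, clinical) {
  m <- carrierMatrix(ceGeneAll, transpose = TRUE)
  genes <- intersect(.RECURRENT_GENES, colnames(m))
  if (length(genes) < 2L) {
    genes <- names(sort(colSums(m), decreasing = TRUE))[seq_len(min(10L,
                                                                    ncol(m)))]
  }
  feats <- m[, genes, drop = FALSE]
  if ("del5q" %in% colnames(clinical)) {
    feats <- cbind(feats, del5q = clinical$del5q)
  }
  rownames(feats) <- clinical$patient_id
  feats
}

#' Assemble the consolidated report
#'
#' Collects whatever stage outputs are present under `outDir` into
#' machine-readable report tables: the ladder concordance grid, the volcano
#' table of the primary scan scheme, the subgroup Kaplan-Meier table and a
#' JSON summary. Missing stages are simply omitted.
#'
#' @param outDir pipeline output directory.
#' @param primaryScheme which scan scheme feeds `report/volcano.tsv`.
#' @return Invisibly, the paths written.
#' @export
renderReport <- function(outDir, primaryScheme = "gene_all") {
  repDir <- file.path(outDir, "report")
  dir.create(repDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  summary <- list()
  volc <- file.path(outDir, "scan",
                    sprintf("volcano_%s.tsv", primaryScheme))
  if (file.exists(volc)) {
    v <- .readTsv(volc)
    .writeTsv(v, file.path(repDir, "volcano.tsv"))
    written <- c(written, "volcano.tsv")
    summary$scan <- list(regions = nrow(v),
                         top = v$region_id[which.max(v$neglog10_p)])
  }
  km <- file.path(outDir, "cluster", "km.tsv")
  if (file.exists(km)) {
    .writeTsv(.readTsv(km), file.path(repDir, "km.tsv"))
    written <- c(written, "km.tsv")
  }
  tab1 <- file.path(outDir, "model", "table1.tsv")
  if (file.exists(tab1)) {
    t1 <- .readTsv(tab1)
    ev <- structure(list(table = t1, endpoints = unique(t1$endpoint)),
                    class = "LadderEvaluation")
    .writeTsv(ladderGrid(ev), file.path(repDir, "ladder_grid.tsv"))
    written <- c(written, "ladder_grid.tsv")
    summary$ladder <- list(models = unique(t1$model),
                           endpoints = unique(t1$endpoint))
  }
  if (!length(written)) {
    stop("no stage outputs found under ", outDir, call. = FALSE)
  }
  jsonlite::write_json(summary, file.path(repDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(repDir, c(written, "summary.json")))
}
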