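#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for synthetic transplant cohorts
#'
#' Holds every knob of the synthetic-cohort generator: cohort and genome
#' sizes, per-region somatic carrier frequency, planted region-level
#' log-hazard-ratio effects, genomic subgroup signatures, clinical covariate
#' effects, and the baseline/censoring/competing-risk hazards of the
#' proportional-hazards outcome model. Construct with [simulationConfig()].
#'
#' @slot nPatients,nGenes,nWindows cohort size and number of gene regions /
#'   sliding windows carrying somatic variants.
#' @slot carrierFreq baseline per-region carrier probability.
#' @slot signatureCarrierProb carrier probability of a signature gene within
#'   its own subgroup.
#' @slot plantedEffects `data.frame` with columns `region_id`, `logHR` and
#'   `endpoint` (`"all"`, `"relapse"` or `"trm"`).
#' @slot subgroupSpec list of subgroup signatures, each a list with elements
#'   `regions` (character), `prevalence` and `logHR`.
#' @slot clinicalEffects named numeric log-hazard ratios for clinical
#'   covariates.
#' @slot baselineHazard,weibullShape baseline event hazard (per month) and
#'   Weibull shape (1 = exponential).
#' @slot competingFractions named numeric multipliers splitting the baseline
#'   hazard into cause-specific relapse and TRM hazards.
#' @slot postRelapseHazard mortality hazard after relapse (per month).
#' @slot censoringRate,adminCensorTime independent exponential censoring rate
#'   (per month) and administrative cutoff (months).
#' @slot seed integer seed; a fixed seed reproduces all tables exactly.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nPatients = "integer",
  nGenes = "integer",
  nWindows = "integer",
  carrierFreq = "numeric",
  signatureCarrierProb = "numeric",
  plantedEffects = "data.frame",
  subgroupSpec = "list",
  clinicalEffects = "numeric",
  baselineHazard = "numeric",
  weibullShape = "numeric",
  competingFractions = "numeric",
  postRelapseHazard = "numeric",
  censoringRate = "numeric",
  adminCensorTime = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(expr, m) if (!isTRUE(expr)) msg <<- c(msg, m)
  chk(object@nPatients >= 1L, "'nPatients' must be a positive count")
  chk(object@nGenes >= 1L, "'nGenes' must be a positive count")
  chk(object@nWindows >= 0L, "'nWindows' must be a non-negative count")
  chk(object@carrierFreq >= 0 && object@carrierFreq <= 1,
      "'carrierFreq' must lie in [0, 1]")
  chk(object@signatureCarrierProb >= 0 && object@signatureCarrierProb <= 1,
      "'signatureCarrierProb' must lie in [0, 1]")
  if (nrow(object@plantedEffects)) {
    chk(all(c("region_id", "logHR", "endpoint") %in%
              colnames(object@plantedEffects)),
        "'plantedEffects' needs columns region_id, logHR, endpoint")
    chk(all(object@plantedEffects$endpoint %in% c("all", "relapse", "trm")),
        "'plantedEffects$endpoint' must be one of all, relapse, trm")
  }
  if (length(object@subgroupSpec)) {
    prev <- vapply(object@subgroupSpec, function(s) s$prevalence, numeric(1))
    chk(all(prev >= 0 & prev <= 1), "'subgroupSpec' prevalences must lie in [0, 1]")
    chk(sum(prev) <= 1 + 1e-12,
        "'subgroupSpec' prevalences must sum to at most 1")
  }
  chk(object@baselineHazard > 0, "'baselineHazard' must be positive")
  chk(object@weibullShape > 0, "'weibullShape' must be positive")
  chk(all(object@competingFractions >= 0),
      "'competingFractions' must be non-negative")
  chk(sum(object@competingFractions) > 0 || object@baselineHazard == 0,
      "'competingFractions' cannot be all zero (no events possible)")
  chk(object@censoringRate >= 0, "'censoringRate' must be non-negative")
  chk(object@adminCensorTime > 0, "'adminCensorTime' must be positive")
  if (length(msg)) paste("configuration error:", msg) else TRUE
})

## ---------------------------------------------------------------------------
## CarrierExperiment
## ---------------------------------------------------------------------------

#' Patients-by-regions somatic carrier matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose single assay
#' `"carrier"` is a binary regions x patients incidence matrix: entry
#' \eqn{(r, p)} is 1 when patient \eqn{p} carries at least one qualifying
#' somatic variant in region \eqn{r}. Row ranges carry the region scheme
#' (`gene_nonsyn`, `gene_all` or `window`) and region identifiers; rows are
#' regions (features) and columns are patients, following Bioconductor
#' convention. The per-patient x per-region orientation used in modelling is
#' obtained with `carrierMatrix(x, transpose = TRUE)`.
#'
#' @exportClass CarrierExperiment
setClass("CarrierExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("CarrierExperiment", function(object) {
  if (!"carrier" %in% names(assays(object)))
    return("assay 'carrier' is required")
  m <- assay(object, "carrier")
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    return("assay 'carrier' must be binary 0/1 without missing values")
  if (is.null(colnames(object)))
    return("patient identifiers (colnames) are required")
  if (anyDuplicated(rownames(object)))
    return("region identifiers must be unique")
  TRUE
})

#' Construct a CarrierExperiment
#'
#' @param carrier binary matrix, regions in rows and patients in columns
#'   (dimnames required).
#' @param regions `GRanges` parallel to the rows, with metadata columns
#'   `region_id` and `scheme`; optional.
#' @param scheme region scheme label recorded in the metadata.
#' @param ... further metadata entries.
#' @return A [CarrierExperiment-class] object.
#' @export
CarrierExperiment <- function(carrier, regions = NULL,
                              scheme = c("gene_all", "gene_nonsyn", "window"),
                              ...) {
  scheme <- match.arg(scheme)
  storage.mode(carrier) <- "integer"
  if (is.null(regions)) {
    regions <- GRanges(rep("unplaced", nrow(carrier)),
                       IRanges(seq_len(nrow(carrier)), width = 1L),
                       region_id = rownames(carrier), scheme = scheme)
    names(regions) <- rownames(carrier)
  }
  se <- SummarizedExperiment(
    assays = SimpleList(carrier = carrier),
    rowRanges = regions,
    metadata = list(scheme = scheme, ...)
  )
  rownames(se) <- rownames(carrier)
  colnames(se) <- colnames(carrier)
  new("CarrierExperiment", se)
}

#' @describeIn CarrierExperiment-class display a compact summary
#' @param object a `CarrierExperiment`.
#' @export
setMethod("show", "CarrierExperiment", function(object) {
  nc <- Matrix_rowSums(assay(object, "carrier"))
  cat("CarrierExperiment with", nrow(object), "regions x",
      ncol(object), "patients\n")
  cat("  scheme:", metadata(object)$scheme %||% "unknown", "\n")
  cat("  carriers per region: median", stats::median(nc),
      "[", min(nc), "-", max(nc), "]\n")
  invisible(NULL)
})

## plain rowSums, named to avoid accidental S4 dispatch surprises
Matrix_rowSums <- function(m) rowSums(m)

## ---------------------------------------------------------------------------
## SupervisedConfig
## ---------------------------------------------------------------------------

#' Configuration of outcome-guided (supervised) clustering
#'
#' @slot kClusters number of clusters fitted on the selected features.
#' @slot nTopFeatures number of features retained per fold by univariate Cox
#'   score ranking.
#' @slot nFolds number of cross-validation folds (>= 2).
#' @slot endpoint scoring endpoint, `"os"` or `"dfs"`.
#' @slot seed integer seed driving fold assignment and K-means restarts.
#' @exportClass SupervisedConfig
setClass("SupervisedConfig", representation(
  kClusters = "integer", nTopFeatures = "integer", nFolds = "integer",
  endpoint = "character", seed = "integer"
))

setValidity("SupervisedConfig", function(object) {
  msg <- character()
  if (object@kClusters < 2L) msg <- c(msg, "'kClusters' must be >= 2")
  if (object@nFolds < 2L) msg <- c(msg, "'nFolds' must be >= 2")
  if (object@nTopFeatures < 1L) msg <- c(msg, "'nTopFeatures' must be >= 1")
  if (!object@endpoint %in% c("os", "dfs"))
    msg <- c(msg, "'endpoint' must be 'os' or 'dfs'")
  if (length(msg)) paste("configuration error:", msg) else TRUE
})

#' @rdname SupervisedConfig-class
#' @param kClusters,nTopFeatures,nFolds,endpoint,seed see slot documentation.
#' @return A `SupervisedConfig` object.
#' @export
supervisedConfig <- function(kClusters = 3L, nTopFeatures = 50L, nFolds = 5L,
                             endpoint = "os", seed = 1L) {
  new("SupervisedConfig", kClusters = as.integer(kClusters),
      nTopFeatures = as.integer(nTopFeatures), nFolds = as.integer(nFolds),
      endpoint = endpoint, seed = as.integer(seed))
}
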