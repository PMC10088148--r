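#' @importFrom stats rexp rbinom runif rnorm setNames p.adjust pchisq pnorm
#'   quantile median complete.cases kmeans dist sd
#' @importFrom utils write.table read.delim packageVersion head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stage-keyed seed derivation: one global integer deterministically yields a
## distinct 32-bit seed per pipeline stage (and per fold / replicate where
## needed), so the whole pipeline is reproducible from a single integer.
.STAGE_OFFSETS <- c(
  simulate = 1L, aggregate = 2L, scan = 3L, cluster = 4L,
  model = 5L, report = 6L, kmeans = 7L, folds = 8L, bootstrap = 9L
)

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic derivation used throughout the pipeline so that one global
#' integer seed controls every source of randomness. The derived value is
#' always a valid 32-bit R integer.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (`"simulate"`, `"aggregate"`, `"scan"`,
#'   `"cluster"`, `"model"`, `"report"`, `"kmeans"`, `"folds"`,
#'   `"bootstrap"`) or an arbitrary integer offset.
#' @param index Optional extra index (e.g. fold or replicate number).
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, stage, index = 0L) {
  off <- if (is.character(stage)) {
    if (!stage %in% names(.STAGE_OFFSETS)) {
      stop("unknown stage name: ", stage)
    }
    .STAGE_OFFSETS[[stage]]
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) * 7919 + off * 104729 + index * 1299709) %%
               2147483629)
}

.assertProb <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("configuration error: '", field, "' must be a probability in [0, 1]",
         call. = FALSE)
  }
}

.assertCount <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x)) {
    stop("configuration error: '", field, "' must be a positive integer count",
         call. = FALSE)
  }
}

.assertRate <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop("configuration error: '", field, "' must be a non-negative rate",
         call. = FALSE)
  }
}

.assertBinary <- function(x, what = "carrier vector") {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop(what, " must be binary 0/1 without missing values", call. = FALSE)
  }
}

## write.table with fixed conventions so outputs are byte-stable
.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
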