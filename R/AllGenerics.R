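#' Extract the binary carrier matrix
#'
#' @param x a [CarrierExperiment-class].
#' @param transpose if `TRUE`, return patients x regions (the orientation
#'   used by the survival models); default is the stored regions x patients.
#' @return An integer 0/1 matrix.
#' @export
setGeneric("carrierMatrix", function(x, transpose = FALSE)
  standardGeneric("carrierMatrix"))

#' @rdname carrierMatrix
#' @export
setMethod("carrierMatrix", "CarrierExperiment", function(x, transpose = FALSE) {
  m <- assay(x, "carrier")
  if (transpose) t(m) else m
})

#' Number of carriers per region
#'
#' @param x a [CarrierExperiment-class].
#' @return Named integer vector of column sums of the patient incidence.
#' @export
setGeneric("nCarriers", function(x) standardGeneric("nCarriers"))

#' @rdname nCarriers
#' @export
setMethod("nCarriers", "CarrierExperiment", function(x) {
  n <- rowSums(assay(x, "carrier"))
  storage.mode(n) <- "integer"
  n
})

#' Region scheme of a carrier matrix
#'
#' @param x a [CarrierExperiment-class].
#' @return One of `"gene_nonsyn"`, `"gene_all"`, `"window"`.
#' @export
setGeneric("regionScheme", function(x) standardGeneric("regionScheme"))

#' @rdname regionScheme
#' @export
setMethod("regionScheme", "CarrierExperiment", function(x) {
  metadata(x)$scheme
})

#' Drop regions with too few (or too many) carriers
#'
#' Regions with fewer than `kMin` carriers, or with more than
#' `nPatients - kMin` carriers (near-monomorphic regions, which carry no
#' contrast), are removed before association testing. The removal is logged
#' and recorded in the object metadata.
#'
#' @param x a [CarrierExperiment-class].
#' @param kMin minimum number of carriers (and of non-carriers), >= 1.
#' @param verbose emit a message with the counts removed.
#' @return The filtered [CarrierExperiment-class].
#' @export
setGeneric("filterMinCarriers", function(x, kMin = 3L, verbose = TRUE)
  standardGeneric("filterMinCarriers"))
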