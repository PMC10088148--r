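## Collapse site-level somatic variants into per-patient, per-region binary
## carrier indicators under three schemes: gene-based nonsynonymous coding,
## gene-based all-variant, and genome-wide sliding windows.
##
## Coordinate convention: everything in memory is 1-based inclusive
## (GRanges). BED input is 0-based half-open and is converted on read by
## rtracklayer::import; VCF positions are already 1-based.

#' Read somatic variants from a multi-sample VCF
#'
#' One record per ALT allele per site (multi-allelic sites are split); a
#' sample is a carrier when its genotype contains at least one alternate
#' allele. Consequence annotation is taken from a VCF INFO tag (it is
#' produced upstream of this package), defaulting to `CSQ` with values
#' `nonsynonymous_coding` / `other`; sites without the tag are `other`.
#'
#' @param path path to a VCF 4.x file with a GT FORMAT field.
#' @param sampleSubset optional character vector restricting to these sample
#'   ids; ids missing from the header are an error.
#' @param consequenceKey INFO tag holding the consequence class.
#' @return A `GRanges` with metadata columns `ref`, `alt`, `consequence` and
#'   `carriers` (a `CharacterList` of carrier sample ids). Sites where no
#'   retained sample carries the allele are dropped.
#' @export
readVcfVariants <- function(path, sampleSubset = NULL,
                            consequenceKey = "CSQ") {
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% names(VariantAnnotation::geno(vcf))) {
    stop("VCF format error: no GT genotype field in ", path, call. = FALSE)
  }
  samples <- colnames(vcf)
  if (!is.null(sampleSubset)) {
    missing <- setdiff(sampleSubset, samples)
    if (length(missing)) {
      stop("samples absent from VCF header: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    vcf <- vcf[, sampleSubset]
    samples <- sampleSubset
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  gr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  csq <- if (consequenceKey %in% colnames(VariantAnnotation::info(vcf))) {
    as.character(VariantAnnotation::info(vcf)[[consequenceKey]])
  } else {
    rep("other", nrow(vcf))
  }
  csq[is.na(csq)] <- "other"
  ## split multi-allelic records manually: the ALT allele with (1-based)
  ## index k is carried by samples whose GT contains allele code k
  alleleCodes <- lapply(seq_len(nrow(gt)), function(i) {
    strsplit(gt[i, ], "[/|]")
  })
  recs <- list()
  for (i in seq_len(nrow(vcf))) {
    alts <- as.character(altList[[i]])
    for (k in seq_along(alts)) {
      carr <- samples[vapply(alleleCodes[[i]],
                             function(a) as.character(k) %in% a,
                             logical(1))]
      if (!length(carr) || alts[k] == refs[i]) next
      recs[[length(recs) + 1L]] <- list(
        chrom = as.character(seqnames(gr))[i], pos = start(gr)[i],
        ref = refs[i], alt = alts[k], csq = csq[i], carriers = carr)
    }
  }
  if (!length(recs)) {
    out <- GRanges()
    out$ref <- character(); out$alt <- character()
    out$consequence <- character()
    out$carriers <- IRanges::CharacterList()
    return(out)
  }
  out <- GRanges(vapply(recs, `[[`, "", "chrom"),
                 IRanges(vapply(recs, `[[`, 0L, "pos"), width = 1L))
  out$ref <- vapply(recs, `[[`, "", "ref")
  out$alt <- vapply(recs, `[[`, "", "alt")
  out$consequence <- vapply(recs, `[[`, "", "csq")
  out$carriers <- IRanges::CharacterList(lapply(recs, `[[`, "carriers"))
  out
}

#' Read gene regions from a BED file
#'
#' BED is 0-based half-open; `rtracklayer` converts to the 1-based inclusive
#' convention used throughout. The BED name column supplies the gene symbol.
#'
#' @param path BED file path.
#' @return `GRanges` with `region_id` (gene symbol) and `scheme` columns.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) {
    stop("BED gene file needs a name column with gene symbols", call. = FALSE)
  }
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 region_id = gr$name, scheme = "gene_all")
  names(out) <- make.unique(gr$name)
  out
}

#' Read a genome layout table
#'
#' @param path TSV with columns `chrom` and `length`.
#' @return The layout `data.frame`.
#' @export
readGenomeLayout <- function(path) {
  lay <- .readTsv(path)
  if (!all(c("chrom", "length") %in% colnames(lay))) {
    stop("genome layout needs columns 'chrom' and 'length'", call. = FALSE)
  }
  lay
}

#' Build sliding windows over a genome layout
#'
#' Windows of `windowSize` bp are tiled every `step` bp along each
#' chromosome (1-based inclusive); when the tiling does not reach the
#' chromosome end, a final clipped window covers the remainder. With
#' `step == windowSize` the windows partition each chromosome into
#' `ceiling(length / windowSize)` non-overlapping pieces.
#'
#' @param genomeLayout `data.frame` with columns `chrom`, `length`.
#' @param windowSize,step window width and offset in bp;
#'   `windowSize >= step >= 1` is required.
#' @return `GRanges` with deterministic `region_id`s
#'   (`<chrom>_w<index>`) and `scheme = "window"`.
#' @export
buildWindows <- function(genomeLayout, windowSize = 10000L, step = 5000L) {
  windowSize <- as.integer(windowSize)
  step <- as.integer(step)
  if (step < 1L || windowSize < 1L) {
    stop("configuration error: 'windowSize' and 'step' must be >= 1",
         call. = FALSE)
  }
  if (step > windowSize) {
    stop("configuration error: 'step' must not exceed 'windowSize' ",
         "(positions would be skipped)", call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(genomeLayout)), function(i) {
    chrom <- genomeLayout$chrom[i]
    L <- as.integer(genomeLayout$length[i])
    starts <- seq.int(1L, max(L - windowSize + 1L, 1L), by = step)
    ends <- pmin(starts + windowSize - 1L, L)
    if (ends[length(ends)] < L) {
      starts <- c(starts, starts[length(starts)] + step)
      ends <- c(ends, L)
    }
    GRanges(chrom, IRanges(starts, ends),
            region_id = sprintf("%s_w%05d", chrom, seq_along(starts)),
            scheme = "window")
  })
  out <- do.call(c, pieces)
  names(out) <- out$region_id
  out
}

#' Collapse variants onto regions as a binary carrier matrix
#'
#' A patient carries a region when they carry at least one variant whose
#' position overlaps the region and which passes the consequence filter.
#' Variants overlapping no region are tallied (not an error) and the count
#' recorded in the result metadata as `intergenic`.
#'
#' @param variants `GRanges` as produced by [readVcfVariants()].
#' @param regions `GRanges` with `region_id` metadata (gene intervals or
#'   windows). Intervals sharing a `region_id` are treated as one region.
#' @param patients character vector fixing patient order (typically from the
#'   clinical table); defaults to the sorted union of carriers.
#' @param consequenceFilter `"any"` or `"nonsynonymous_coding"`.
#' @param scheme scheme label stored in the result.
#' @return A [CarrierExperiment-class].
#' @export
collapseByRegions <- function(variants, regions, patients = NULL,
                              consequenceFilter = c("any",
                                                    "nonsynonymous_coding"),
                              scheme = "gene_all") {
  consequenceFilter <- match.arg(consequenceFilter)
  if (consequenceFilter != "any") {
    variants <- variants[variants$consequence == consequenceFilter]
  }
  if (is.null(patients)) {
    patients <- sort(unique(unlist(variants$carriers)))
  }
  ids <- unique(regions$region_id)
  m <- matrix(0L, nrow = length(ids), ncol = length(patients),
              dimnames = list(ids, patients))
  hits <- findOverlaps(variants, regions)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    rid <- regions$region_id[sh]
    carr <- variants$carriers[qh]
    for (i in seq_along(qh)) {
      pats <- intersect(unlist(carr[[i]]), patients)
      if (length(pats)) m[rid[i], pats] <- 1L
    }
  }
  intergenic <- sum(!(seq_along(variants) %in% qh))
  ## one representative range per region id (merged span)
  first <- match(ids, regions$region_id)
  repRegions <- GRanges(seqnames(regions)[first],
                        IRanges(start(regions)[first], end(regions)[first]),
                        region_id = ids, scheme = scheme)
  names(repRegions) <- ids
  CarrierExperiment(m, regions = repRegions, scheme = scheme,
                    intergenic = intergenic,
                    consequenceFilter = consequenceFilter)
}

#' Gene-based burden collapse
#'
#' Convenience wrapper around [collapseByRegions()] for the two gene-based
#' schemes: all somatic variants, or nonsynonymous coding variants only.
#' Intervals of the same gene are merged before overlap.
#'
#' @param variants `GRanges` from [readVcfVariants()].
#' @param geneRegions `GRanges` with `region_id` gene symbols (e.g. from
#'   [readGeneBed()]).
#' @param consequenceFilter `"any"` (scheme `gene_all`) or
#'   `"nonsynonymous_coding"` (scheme `gene_nonsyn`).
#' @param patients optional patient ordering.
#' @return A [CarrierExperiment-class].
#' @export
collapseByGene <- function(variants, geneRegions,
                           consequenceFilter = c("any",
                                                 "nonsynonymous_coding"),
                           patients = NULL) {
  consequenceFilter <- match.arg(consequenceFilter)
  scheme <- if (consequenceFilter == "any") "gene_all" else "gene_nonsyn"
  ## merge intervals per gene symbol
  spl <- S4Vectors::split(geneRegions, geneRegions$region_id)
  merged <- unlist(reduce(spl))
  merged$region_id <- names(merged)
  merged$scheme <- scheme
  merged <- merged[order(match(merged$region_id,
                               unique(geneRegions$region_id)))]
  collapseByRegions(variants, merged, patients = patients,
                    consequenceFilter = consequenceFilter, scheme = scheme)
}

#' @rdname filterMinCarriers
#' @export
setMethod("filterMinCarriers", "CarrierExperiment",
          function(x, kMin = 3L, verbose = TRUE) {
  kMin <- as.integer(kMin)
  if (kMin < 1L) {
    stop("configuration error: 'kMin' must be >= 1", call. = FALSE)
  }
  nc <- nCarriers(x)
  n <- ncol(x)
  keep <- nc >= kMin & nc <= n - kMin
  dropped <- sum(!keep)
  if (verbose) {
    message(sprintf(
      "filterMinCarriers: dropped %d/%d regions (carriers < %d or > %d)",
      dropped, length(keep), kMin, n - kMin))
  }
  out <- x[keep, ]
  metadata(out)$minCarriers <- kMin
  metadata(out)$droppedRegions <- dropped
  out
})
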