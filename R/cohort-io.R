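## Cohort serialization: multi-sample VCF (GT only) for variants, TSV for
## clinical and outcome tables, BED for gene regions, JSON for the planted
## truth used by recovery tests. Everything round-trips losslessly through
## the readers in the aggregation module.

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, multi-sample, GT field encodes carrier
#' status, coordinate-sorted), `clinical.tsv`, `outcomes.tsv`, `regions.bed`
#' (gene regions), `layout.tsv` (chromosome lengths) and `truth.json`
#' (planted effects and carrier truth for recovery tests). The VCF `fileDate`
#' header line is omitted so that re-running a seeded simulation reproduces
#' byte-identical files.
#'
#' @param sim an `MdsCohortSim` from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
writeCohort <- function(sim, dir) {
  if (!nrow(sim$clinical)) {
    stop("cannot write a cohort with zero patients", call. = FALSE)
  }
  if (!identical(sim$clinical$patient_id, sim$outcomes$patient_id)) {
    stop("clinical and outcome tables disagree on patient_id", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             clinical = file.path(dir, "clinical.tsv"),
             outcomes = file.path(dir, "outcomes.tsv"),
             bed = file.path(dir, "regions.bed"),
             layout = file.path(dir, "layout.tsv"),
             truth = file.path(dir, "truth.json"))

  .writeCohortVcf(sim$variants, sim$clinical$patient_id, sim$layout,
                  paths[["vcf"]])
  .writeTsv(sim$clinical, paths[["clinical"]])
  .writeTsv(sim$outcomes, paths[["outcomes"]])
  bed <- sim$geneRegions
  bed$name <- bed$region_id
  rtracklayer::export(bed, paths[["bed"]], format = "BED")
  .writeTsv(sim$layout, paths[["layout"]])

  asCarrierList <- function(m) {
    if (is.null(m)) return(NULL)
    lapply(as.data.frame(m, check.names = FALSE),
           function(col) rownames(m)[col == 1L])
  }
  truth <- list(
    patients = sim$clinical$patient_id,
    planted_effects = sim$truth$plantedEffects,
    subgroup = sim$truth$subgroup,
    del5q = sim$truth$del5q,
    carriers = list(gene_all = asCarrierList(sim$truth$geneAll),
                    gene_nonsyn = asCarrierList(sim$truth$geneNonsyn),
                    window = asCarrierList(sim$truth$window)),
    seed = sim$truth$seed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

.writeCohortVcf <- function(variants, patients, layout, path) {
  n <- length(patients)
  gt <- matrix("0/0", nrow = length(variants), ncol = n,
               dimnames = list(NULL, patients))
  carr <- variants$carriers
  for (i in seq_along(variants)) {
    ids <- intersect(unlist(carr[[i]]), patients)
    if (length(ids)) gt[i, ids] <- "0/1"
  }
  hdr <- VariantAnnotation::VCFHeader(samples = patients)
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String",
    Description = "Somatic consequence class", row.names = "CSQ")
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  gr <- GRanges(seqnames(variants), IRanges(start(variants), width = 1L))
  seqs <- unique(as.character(seqnames(variants)))
  lens <- layout$length[match(seqs, layout$chrom)]
  GenomeInfoDb::seqlevels(gr) <- seqs
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(seqs, lens)
  fx <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(variants$ref),
    ALT = Biostrings::DNAStringSetList(as.list(variants$alt)),
    QUAL = rep(NA_real_, length(variants)),
    FILTER = rep("PASS", length(variants)))
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(Samples = seq_len(n),
                                   row.names = patients),
    exptData = list(header = hdr), fixed = fx,
    info = S4Vectors::DataFrame(CSQ = variants$consequence),
    geno = S4Vectors::SimpleList(GT = gt))
  VariantAnnotation::writeVcf(vcf, path)
  ## drop the volatile fileDate line so seeded runs are byte-identical
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##fileDate")], path)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' @param path `clinical.tsv` as written by [writeCohort()].
#' @return `data.frame` with `ipss_r_risk` as an ordered-level factor.
#' @export
readClinical <- function(path) {
  cl <- .readTsv(path)
  req <- c("patient_id", "ipss_r_risk", "mds_type", "hma_exposure",
           "chemo_exposure", "conditioning_regimen")
  missing <- setdiff(req, colnames(cl))
  if (length(missing)) {
    stop("clinical table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lv <- c("Very Low", "Low", "Intermediate", "High", "Very High")
  if (all(cl$ipss_r_risk %in% lv)) {
    cl$ipss_r_risk <- factor(cl$ipss_r_risk, levels = lv)
  }
  cl
}

#' Read an outcome table
#'
#' @param path `outcomes.tsv` as written by [writeCohort()].
#' @return Validated `data.frame` of outcome records.
#' @export
readOutcomes <- function(path) {
  oc <- .readTsv(path)
  req <- c("patient_id", "os_time", "os_event", "dfs_time", "dfs_event",
           "first_event_code")
  missing <- setdiff(req, colnames(oc))
  if (length(missing)) {
    stop("outcome table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(oc$os_time <= 0) || any(oc$dfs_time <= 0)) {
    stop("outcome times must be positive", call. = FALSE)
  }
  if (any(oc$dfs_time > oc$os_time + 1e-8)) {
    stop("dfs_time must not exceed os_time", call. = FALSE)
  }
  oc
}

#' Read back the planted truth of a simulated cohort
#'
#' @param path `truth.json` as written by [writeCohort()].
#' @param scheme which carrier truth matrix to reconstruct.
#' @return List with the planted-effect table, subgroup labels and the
#'   requested binary truth matrix (patients x regions).
#' @export
readTruth <- function(path, scheme = c("gene_all", "gene_nonsyn", "window")) {
  scheme <- match.arg(scheme)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  carr <- truth$carriers[[scheme]]
  pats <- truth$patients
  m <- matrix(0L, nrow = length(pats), ncol = length(carr),
              dimnames = list(pats, names(carr)))
  for (r in names(carr)) {
    ids <- unlist(carr[[r]])
    if (length(ids)) m[ids, r] <- 1L
  }
  list(plantedEffects = truth$planted_effects, subgroup = truth$subgroup,
       del5q = truth$del5q, matrix = m, seed = truth$seed)
}
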