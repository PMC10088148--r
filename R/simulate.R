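## Synthetic transplant-cohort generator.
##
## The generator emulates the statistical structure of a WGS-profiled MDS
## alloHCT registry cohort: binary somatic carrier status per gene and per
## sliding window, recurrent-mutation and cytogenetic (del5q) flags that
## define genomic subgroups, modest clinical covariate effects, and
## right-censored OS/DFS with competing relapse/TRM first events generated
## from proportional-hazards models with planted log-hazard-ratio effects.

.RECURRENT_GENES <- c("TP53", "TET2", "DNMT3A", "ASXL1", "RUNX1", "STAG2",
                      "EZH2", "ETV6", "JAK2")
.SCAN_GENES <- c("HCN2", "DDX11")

.defaultSubgroupSpec <- function() {
  ## Four-signature structure: subgroup 1 DNMT3A/STAG2/ASXL1, subgroup 2
  ## TET2, subgroup 3 RUNX1, subgroup 4 TP53 + del5q (the high-risk one);
  ## remaining patients form the reference subgroup.
  list(
    list(regions = c("DNMT3A", "STAG2", "ASXL1"), prevalence = 0.20,
         logHR = 0.30),
    list(regions = "TET2", prevalence = 0.20, logHR = 0.10),
    list(regions = "RUNX1", prevalence = 0.15, logHR = 0.25),
    list(regions = c("TP53", "del5q"), prevalence = 0.15, logHR = 0.90)
  )
}

#' Build a simulation configuration
#'
#' Defaults describe a registry-scale MDS transplant cohort: 494 patients,
#' a post-transplant mortality hazard giving a median OS of roughly three
#' years, ten-year administrative follow-up truncation, competing relapse and
#' transplant-related mortality (TRM) first events, modest clinical effects
#' (|log HR| <= 0.3) and a strong TP53/del5q genomic subgroup effect.
#'
#' @param nPatients,nGenes,nWindows cohort size, number of gene regions and
#'   number of 10 kb sliding windows simulated.
#' @param carrierFreq baseline per-region somatic carrier probability.
#' @param signatureCarrierProb probability that a patient carries a signature
#'   gene of their own subgroup (recurrent driver mutations define the
#'   subgroup, so this is close to 1).
#' @param plantedEffects `data.frame(region_id, logHR, endpoint)` of planted
#'   region-level effects; `endpoint` is `"all"` (both causes), `"relapse"`
#'   or `"trm"`. `NULL` plants the default TP53 and HCN2 OS effects.
#' @param subgroupSpec list of subgroup signatures (see
#'   [SimulationConfig-class]); `NULL` gives the default four-signature
#'   structure; `list()` disables subgroups.
#' @param clinicalEffects named numeric log HRs: `ipssr` (per IPSS-R level
#'   above Very Low), `mds_eb` (excess-blast type), `hma`, `chemo`, `ric`
#'   (reduced-intensity conditioning).
#' @param baselineHazard,weibullShape baseline first-event hazard per month
#'   and Weibull shape (1 = exponential, the default).
#' @param competingFractions named multipliers splitting `baselineHazard`
#'   into cause-specific relapse and TRM hazards.
#' @param postRelapseHazard mortality hazard per month after relapse.
#' @param censoringRate,adminCensorTime independent exponential censoring
#'   hazard per month and administrative cutoff in months.
#' @param nonsynFraction probability that an emitted coding variant is
#'   nonsynonymous.
#' @param seed integer seed; fixed seed reproduces all tables exactly.
#' @return A validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nPatients = 494L, nGenes = 200L, nWindows = 100L,
                             carrierFreq = 0.05,
                             signatureCarrierProb = 0.90,
                             plantedEffects = NULL,
                             subgroupSpec = NULL,
                             clinicalEffects = c(ipssr = 0.15, mds_eb = 0.20,
                                                 hma = 0.10, chemo = 0.10,
                                                 ric = 0.10),
                             baselineHazard = 0.02, weibullShape = 1,
                             competingFractions = c(relapse = 0.55,
                                                    trm = 0.45),
                             postRelapseHazard = 0.08,
                             censoringRate = 0.01, adminCensorTime = 120,
                             nonsynFraction = 0.7,
                             seed = 1L) {
  if (is.null(plantedEffects)) {
    plantedEffects <- data.frame(
      region_id = c("TP53", "HCN2"), logHR = c(0.8, 0.7),
      endpoint = c("all", "all"), stringsAsFactors = FALSE)
    ## default effects only apply to genes that exist at this genome size
    plantedEffects <- plantedEffects[plantedEffects$region_id %in%
                                       .geneNames(nGenes), , drop = FALSE]
  }
  if (nrow(plantedEffects) && !"endpoint" %in% colnames(plantedEffects)) {
    plantedEffects$endpoint <- "all"
  }
  if (is.null(subgroupSpec)) subgroupSpec <- .defaultSubgroupSpec()
  .assertCount(nPatients, "nPatients")
  .assertCount(nGenes, "nGenes")
  if (nWindows != 0) .assertCount(nWindows, "nWindows")
  .assertProb(carrierFreq, "carrierFreq")
  .assertProb(signatureCarrierProb, "signatureCarrierProb")
  .assertProb(nonsynFraction, "nonsynFraction")
  .assertRate(baselineHazard, "baselineHazard")
  .assertRate(censoringRate, "censoringRate")
  .assertRate(postRelapseHazard, "postRelapseHazard")
  if (!all(c("relapse", "trm") %in% names(competingFractions))) {
    stop("configuration error: 'competingFractions' needs named entries ",
         "'relapse' and 'trm'", call. = FALSE)
  }
  cfg <- new("SimulationConfig",
             nPatients = as.integer(nPatients), nGenes = as.integer(nGenes),
             nWindows = as.integer(nWindows), carrierFreq = carrierFreq,
             signatureCarrierProb = signatureCarrierProb,
             plantedEffects = plantedEffects, subgroupSpec = subgroupSpec,
             clinicalEffects = clinicalEffects,
             baselineHazard = baselineHazard, weibullShape = weibullShape,
             competingFractions = competingFractions[c("relapse", "trm")],
             postRelapseHazard = postRelapseHazard,
             censoringRate = censoringRate,
             adminCensorTime = adminCensorTime, seed = as.integer(seed))
  attr(cfg, "nonsynFraction") <- nonsynFraction
  validObject(cfg)
  cfg
}

.geneNames <- function(nGenes) {
  named <- c(.RECURRENT_GENES, .SCAN_GENES)
  if (nGenes <= length(named)) return(named[seq_len(nGenes)])
  c(named, sprintf("GENE%04d", seq_len(nGenes - length(named))))
}

.geneRegions <- function(nGenes) {
  nm <- .geneNames(nGenes)
  gr <- GRanges("chrG",
                IRanges(start = (seq_len(nGenes) - 1L) * 5000L + 1L,
                        width = 3000L),
                region_id = nm, scheme = "gene_all")
  names(gr) <- nm
  gr
}

.genomeLayout <- function(nGenes, nWindows) {
  lay <- data.frame(chrom = "chrG", length = nGenes * 5000L,
                    stringsAsFactors = FALSE)
  if (nWindows > 0) {
    lay <- rbind(lay, data.frame(chrom = "chrW",
                                 length = (nWindows + 1L) * 5000L))
  }
  lay
}

#' Draw competing-risk outcome records from cause-specific hazards
#'
#' First-event times are the minimum of latent cause-specific exponential
#' (or Weibull) relapse and TRM times; overall survival continues after a
#' relapse with a constant post-relapse mortality hazard. Independent
#' exponential censoring plus an administrative cutoff is applied.
#'
#' @param lpRelapse,lpTrm per-patient log relative hazards for the relapse
#'   and TRM cause-specific hazards.
#' @param config a [SimulationConfig-class]; only the hazard, censoring and
#'   shape fields are used. Draws come from the current RNG state (callers
#'   wanting reproducibility set a seed first).
#' @return `data.frame` with columns `os_time`, `os_event`, `dfs_time`,
#'   `dfs_event`, `relapse_time` and `first_event_code`
#'   (0 censored / 1 relapse / 2 TRM).
#' @export
simulateCompetingRisks <- function(lpRelapse, lpTrm, config) {
  stopifnot(length(lpRelapse) == length(lpTrm))
  n <- length(lpRelapse)
  h0 <- config@baselineHazard
  fr <- config@competingFractions[["relapse"]]
  ft <- config@competingFractions[["trm"]]
  if (h0 * (fr + ft) <= 0) {
    stop("all cause-specific hazards are zero: no events possible",
         call. = FALSE)
  }
  shape <- config@weibullShape
  drawTime <- function(rate) {
    t <- rep(Inf, n)
    pos <- rate > 0
    if (any(pos)) t[pos] <- (rexp(sum(pos)) / rate[pos])^(1 / shape)
    t
  }
  tRel <- drawTime(h0 * fr * exp(lpRelapse))
  tTrm <- drawTime(h0 * ft * exp(lpTrm))
  ## post-relapse mortality: constant hazard after the relapse date
  postDeath <- if (config@postRelapseHazard > 0) {
    rexp(n, config@postRelapseHazard)
  } else {
    rep(Inf, n)
  }
  tDeath <- ifelse(tTrm <= tRel, tTrm, tRel + postDeath)
  tFirst <- pmin(tRel, tTrm)
  cens <- if (config@censoringRate > 0) {
    pmin(rexp(n, config@censoringRate), config@adminCensorTime)
  } else {
    rep(config@adminCensorTime, n)
  }
  dfsTime <- pmin(tFirst, cens)
  dfsEvent <- as.integer(tFirst <= cens)
  code <- ifelse(dfsEvent == 0L, 0L, ifelse(tRel <= tTrm, 1L, 2L))
  osTime <- pmin(tDeath, cens)
  osEvent <- as.integer(tDeath <= cens)
  data.frame(os_time = osTime, os_event = osEvent,
             dfs_time = dfsTime, dfs_event = dfsEvent,
             relapse_time = dfsTime,
             first_event_code = as.integer(code))
}

#' Simulate a full synthetic cohort
#'
#' Generates, in one reproducible pass: clinical covariates, subgroup
#' membership, gene and window carrier matrices with planted effects,
#' site-level somatic variants realising those carriers (for VCF emission),
#' and competing-risk outcome tables from the proportional-hazards model.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return An object of class `MdsCohortSim`: a list with elements
#'   `clinical`, `outcomes`, `variants` (a `GRanges` with `ref`, `alt`,
#'   `consequence` and `carriers` metadata), `geneRegions`, `windows`,
#'   `layout` and `truth` (planted carrier matrices, subgroup labels, linear
#'   predictors and the planted effect table).
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nPatients
  pid <- sprintf("P%04d", seq_len(n))

  ## ---- clinical covariates -------------------------------------------------
  ipssLevels <- c("Very Low", "Low", "Intermediate", "High", "Very High")
  ipss <- sample(seq_along(ipssLevels), n, replace = TRUE,
                 prob = c(0.08, 0.20, 0.30, 0.27, 0.15))
  mdsTypes <- c("MDS-SLD", "MDS-MLD", "MDS-RS", "MDS-EB")
  mdsType <- sample(mdsTypes, n, replace = TRUE,
                    prob = c(0.15, 0.30, 0.15, 0.40))
  hma <- rbinom(n, 1, 0.60)
  chemo <- rbinom(n, 1, 0.25)
  regimen <- ifelse(rbinom(n, 1, 0.45) == 1L, "myeloablative",
                    "reduced intensity")

  ## ---- subgroup membership -------------------------------------------------
  spec <- config@subgroupSpec
  prev <- vapply(spec, function(s) s$prevalence, numeric(1))
  probs <- c(prev, 1 - sum(prev))
  subgroup <- sample(seq_along(probs), n, replace = TRUE, prob = probs)
  subgroup[subgroup == length(probs)] <- 0L  # 0 = reference subgroup

  ## ---- gene carriers -------------------------------------------------------
  genes <- .geneRegions(config@nGenes)
  gnames <- names(genes)
  pCarr <- matrix(config@carrierFreq, nrow = n, ncol = config@nGenes,
                  dimnames = list(pid, gnames))
  del5qProb <- rep(0.05, n)
  for (k in seq_along(spec)) {
    member <- subgroup == k
    for (rg in spec[[k]]$regions) {
      if (rg == "del5q") {
        del5qProb[member] <- config@signatureCarrierProb
      } else if (rg %in% gnames) {
        pCarr[member, rg] <- config@signatureCarrierProb
      }
    }
  }
  geneCarrier <- matrix(rbinom(n * config@nGenes, 1, as.vector(pCarr)),
                        nrow = n, dimnames = dimnames(pCarr))
  del5q <- rbinom(n, 1, del5qProb)

  clinical <- data.frame(
    patient_id = pid,
    ipss_r_risk = factor(ipssLevels[ipss], levels = ipssLevels),
    mds_type = mdsType, hma_exposure = hma, chemo_exposure = chemo,
    conditioning_regimen = regimen, del5q = del5q,
    stringsAsFactors = FALSE)

  ## ---- site-level variants realising the gene carriers ---------------------
  nonsynFraction <- attr(config, "nonsynFraction") %||% 0.7
  vr <- .emitGeneVariants(geneCarrier, genes, nonsynFraction)
  geneNonsyn <- vr$nonsynTruth

  ## ---- window variants (noncoding, tiled chromosome) -----------------------
  windows <- GRanges()
  windowCarrier <- NULL
  wvariants <- GRanges()
  if (config@nWindows > 0) {
    lay <- data.frame(chrom = "chrW", length = (config@nWindows + 1L) * 5000L)
    windows <- buildWindows(lay, windowSize = 10000L, step = 5000L)
    wv <- .emitWindowVariants(pid, config)
    wvariants <- wv$variants
    windowCarrier <- .carrierFromVariants(wvariants, windows, pid)
  }

  variants <- suppressWarnings(c(vr$variants, wvariants))
  variants <- variants[order(as.factor(seqnames(variants)), start(variants))]

  ## ---- linear predictors ---------------------------------------------------
  eff <- config@clinicalEffects
  lpClin <- (ipss - 1) * (eff[["ipssr"]] %||% 0) +
    (mdsType == "MDS-EB") * (eff[["mds_eb"]] %||% 0) +
    hma * (eff[["hma"]] %||% 0) + chemo * (eff[["chemo"]] %||% 0) +
    (regimen == "reduced intensity") * (eff[["ric"]] %||% 0)
  lpSub <- numeric(n)
  for (k in seq_along(spec)) lpSub[subgroup == k] <- spec[[k]]$logHR

  lpPlant <- function(which) {
    pe <- config@plantedEffects
    pe <- pe[pe$endpoint %in% which, , drop = FALSE]
    out <- numeric(n)
    for (i in seq_len(nrow(pe))) {
      rid <- pe$region_id[i]
      if (rid %in% colnames(geneCarrier)) {
        out <- out + pe$logHR[i] * geneCarrier[, rid]
      } else if (!is.null(windowCarrier) && rid %in% colnames(windowCarrier)) {
        out <- out + pe$logHR[i] * windowCarrier[, rid]
      } else {
        stop("planted effect names unknown region_id: ", rid, call. = FALSE)
      }
    }
    out
  }
  lpBase <- lpClin + lpSub + lpPlant("all")
  lpRelapse <- lpBase + lpPlant("relapse")
  lpTrm <- lpBase + lpPlant("trm")

  ## ---- outcomes ------------------------------------------------------------
  outcomes <- cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
                    simulateCompetingRisks(lpRelapse, lpTrm, config))

  truth <- list(
    geneAll = geneCarrier, geneNonsyn = geneNonsyn, window = windowCarrier,
    subgroup = subgroup, del5q = del5q,
    lp = data.frame(base = lpBase, relapse = lpRelapse, trm = lpTrm),
    plantedEffects = config@plantedEffects, seed = config@seed)

  structure(list(clinical = clinical, outcomes = outcomes,
                 variants = variants, geneRegions = genes, windows = windows,
                 layout = .genomeLayout(config@nGenes, config@nWindows),
                 truth = truth, config = config),
            class = "MdsCohortSim")
}

#' @export
print.MdsCohortSim <- function(x, ...) {
  cat("Synthetic MDS transplant cohort\n")
  cat("  patients:", nrow(x$clinical), " gene regions:", length(x$geneRegions),
      " windows:", length(x$windows), "\n")
  cat("  variant records:", length(x$variants), "\n")
  cat("  OS events:", sum(x$outcomes$os_event),
      " relapse:", sum(x$outcomes$first_event_code == 1L),
      " TRM:", sum(x$outcomes$first_event_code == 2L), "\n")
  invisible(x)
}

## Emit per-gene site pools and assign carrier patients to sites. Each carrier
## holds 1-2 of the gene's sites; each site records its carrier set, so the
## gene-level "any variant" collapse reproduces the planted carrier matrix
## exactly. A site is nonsynonymous with probability nonsynFraction;
## occasionally a second ALT at an occupied position exercises the
## multi-allelic split in the reader.
.emitGeneVariants <- function(geneCarrier, genes, nonsynFraction) {
  bases <- c("A", "C", "G", "T")
  pid <- rownames(geneCarrier)
  n <- length(pid)
  recs <- vector("list", ncol(geneCarrier))
  nonsynTruth <- matrix(0L, nrow = n, ncol = ncol(geneCarrier),
                        dimnames = dimnames(geneCarrier))
  for (g in seq_len(ncol(geneCarrier))) {
    carriers <- which(geneCarrier[, g] == 1L)
    if (!length(carriers)) next
    nSites <- min(max(2L, stats::rpois(1, 3)), 6L)
    pos <- sort(sample(seq(start(genes)[g], end(genes)[g]), nSites))
    csq <- ifelse(runif(nSites) < nonsynFraction, "nonsynonymous_coding",
                  "other")
    ref <- sample(bases, nSites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    siteCarr <- vector("list", nSites)
    for (p in carriers) {
      k <- sample(nSites, min(nSites, sample(1:2, 1)))
      for (s in k) siteCarr[[s]] <- c(siteCarr[[s]], pid[p])
      if (any(csq[k] == "nonsynonymous_coding")) {
        nonsynTruth[p, g] <- 1L
      }
    }
    keep <- lengths(siteCarr) > 0
    if (!any(keep)) next
    recs[[g]] <- GRanges(
      as.character(seqnames(genes))[g],
      IRanges(pos[keep], width = 1L),
      ref = ref[keep], alt = alt[keep], consequence = csq[keep],
      carriers = IRanges::CharacterList(siteCarr[keep]))
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  variants <- if (length(recs)) do.call(c, unname(recs)) else GRanges()
  list(variants = variants, nonsynTruth = nonsynTruth)
}

## Window variants are placed on 5 kb tiles of chrW (each 10 kb window spans
## two adjacent tiles); per-tile carrier probability q is chosen so the
## per-window carrier frequency is approximately carrierFreq.
.emitWindowVariants <- function(pid, config) {
  n <- length(pid)
  nTiles <- config@nWindows + 1L
  q <- 1 - sqrt(1 - min(config@carrierFreq, 0.999))
  bases <- c("A", "C", "G", "T")
  recs <- list()
  for (tile in seq_len(nTiles)) {
    carr <- which(rbinom(n, 1, q) == 1L)
    if (!length(carr)) next
    lo <- (tile - 1L) * 5000L + 1L
    nSites <- max(1L, min(3L, stats::rpois(1, 1.5)))
    pos <- sort(sample(seq(lo, lo + 4999L), nSites))
    ref <- sample(bases, nSites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    siteCarr <- vector("list", nSites)
    for (p in carr) {
      s <- sample(nSites, 1)
      siteCarr[[s]] <- c(siteCarr[[s]], pid[p])
    }
    keep <- lengths(siteCarr) > 0
    recs[[length(recs) + 1L]] <- GRanges(
      "chrW", IRanges(pos[keep], width = 1L),
      ref = ref[keep], alt = alt[keep],
      consequence = rep("other", sum(keep)),
      carriers = IRanges::CharacterList(siteCarr[keep]))
  }
  variants <- if (length(recs)) do.call(c, unname(recs)) else GRanges()
  list(variants = variants)
}

## carrier matrix from in-memory variants by interval overlap
.carrierFromVariants <- function(variants, regions, pid) {
  m <- matrix(0L, nrow = length(pid), ncol = length(regions),
              dimnames = list(pid, regions$region_id))
  if (!length(variants)) return(m)
  hits <- findOverlaps(variants, regions)
  for (h in seq_along(hits)) {
    v <- S4Vectors::queryHits(hits)[h]
    r <- S4Vectors::subjectHits(hits)[h]
    m[unlist(variants$carriers[v]), r] <- 1L
  }
  m
}

#' Recurrent-mutation and cytogenetic feature matrix
#'
#' Binary patients x features matrix of the recurrent driver genes present in
#' the simulated genome plus the del5q cytogenetic flag — the feature set on
#' which unsupervised genomic subgrouping operates.
#'
#' @param sim an `MdsCohortSim` from [simulateCohort()].
#' @return Binary matrix with patient ids as row names.
#' @export
recurrentFeatureMatrix <- function(sim) {
  genes <- intersect(.RECURRENT_GENES, colnames(sim$truth$geneAll))
  m <- cbind(sim$truth$geneAll[, genes, drop = FALSE],
             del5q = sim$truth$del5q)
  storage.mode(m) <- "integer"
  m
}
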