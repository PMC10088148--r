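# mdswgs

Whole-genome somatic variant survival analysis for myelodysplastic
syndrome (MDS) cohorts undergoing allogeneic hematopoietic cell
transplantation (alloHCT). The package is aimed at biostatisticians and
computational biologists who have per-patient somatic calls (VCF), region
definitions (BED) and clinical/outcome tables, and want to go from variants
to prognosis in one reproducible pipeline:

* **Burden collapsing** — multi-sample VCFs become binary patients x
  regions carrier matrices under three schemes: gene-based nonsynonymous
  coding, gene-based all-variant, and genome-wide sliding windows.
* **Association scanning** — per region r with carrier indicator
  `x_r`, a covariate-adjusted proportional-hazards model
  `h(t | x) = h0(t) · exp(β_r x_r + γ'z)` is fitted by maximising the Efron
  partial likelihood (Wald or likelihood-ratio p), or a Fine–Gray
  subdistribution model for the competing first events relapse and
  transplant-related mortality; Bonferroni and Benjamini–Hochberg control
  the genome-wide multiplicity, with volcano-plot tables as output.
* **Genomic subgrouping** — unsupervised K-means over recurrent driver
  mutations and cytogenetics (TP53, TET2, DNMT3A, ASXL1, RUNX1, STAG2, …,
  del5q), and outcome-guided (supervised) clustering with k-fold
  cross-validation: per fold, features are ranked by univariate Cox score
  on the training split only, K-means runs on the selected features, and
  held-out patients are assigned to the nearest centroid.
* **Prognostic model ladder** — four nested random survival forests
  (base = IPSS-R; clinical = base + MDS type + HMA + chemotherapy;
  genomic = candidate mutational count + subgroup labels; full =
  clinical + genomic), evaluated out-of-bag by Harrell's C-index
  (percentile-bootstrap CI), IPCW Brier score curves, and permutation
  feature importance, optionally stratified by conditioning regimen.
* **Synthetic cohorts** — a seeded generator plants region effects,
  subgroup signatures, censoring and competing risks in
  proportional-hazards outcomes, so the whole pipeline is testable against
  known truth without access-restricted registry data.

## Worked example

```r
library(mdswgs)

cfg <- simulationConfig(nPatients = 300L, nGenes = 100L, nWindows = 40L,
                        seed = 42L)
sim <- simulateCohort(cfg)
print(sim)
#> Synthetic MDS transplant cohort
#>   patients: 300  gene regions: 100  windows: 40
#>   variant records: 389
#>   OS events: 234  relapse: 126  TRM: 122

out <- writeCohort(sim, "demo")                       # VCF + TSVs + truth
variants <- readVcfVariants(out[["vcf"]], sampleSubset = sim$clinical$patient_id)
genes    <- readGeneBed(out[["bed"]])
ce <- collapseByGene(variants, genes, "any", patients = sim$clinical$patient_id)
ce <- filterMinCarriers(ce, 3)

scan <- genomeScan(ce, sim$outcomes$os_time, sim$outcomes$os_event,
                   covariates = sim$clinical[, c("ipss_r_risk", "hma_exposure")])
head(as.data.frame(scan)[, c("region_id", "n_carriers", "hr", "p_raw", "q_bh")], 3)
#>   region_id n_carriers        hr        p_raw         q_bh
#> 1      TP53         53 3.3928023 5.546793e-13 5.546793e-11
#> 2  GENE0072         17 2.6073605 3.177724e-04 1.588862e-02
#> 3  GENE0076         12 0.3669845 1.032420e-02 2.265940e-01
```

The generator planted a TP53 effect and a high-risk TP53/del5q subgroup;
the scan recovers TP53 as the only genome-wide significant gene (hazard
ratio 3.4 for carriers, BH q = 5.5e-11), with the remaining regions at
chance levels. Subgrouping and survival separation:

```r
uns <- unsupervisedSubgroups(recurrentFeatureMatrix(sim), k = 4, seed = 1)
ev  <- evaluateSubgroups(uns$assignment, sim$outcomes$os_time, sim$outcomes$os_event)
ev$logrank_p                       # 1.3e-08 across the four subgroups
as.data.frame(ev$cox)
#>   subgroup   hr lower upper        p
#> 1        2 1.09 0.771  1.55 6.15e-01
#> 2        3 2.85 2.007  4.04 4.45e-09
#> 3        4 1.50 1.039  2.17 3.06e-02
```

Relative to the reference subgroup (best median survival), the cluster
carrying the TP53/del5q signature shows a 2.9-fold mortality hazard — the
planted high-risk group — while the TET2-like cluster is indistinguishable
from reference. `supervisedClusterCV()`, `evaluateLadder()` and
`ladderGrid()` continue the pipeline through outcome-guided clustering and
the four-model concordance grid; `runPipeline()` executes all stages from
one YAML/JSON config with a digest-based manifest (see
`inst/scripts/mdswgs.R` for a shell entry point).

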