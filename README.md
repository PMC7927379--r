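# breedPLS

Conservation genetics for multi-breed SNP panels: **which SNPs make each
breed unique?** breedPLS answers this with a one-vs-rest partial least
squares (PLS) scan. For every breed in turn, the 0/1 breed-membership
indicator *y* is regressed on all SNP dosages *X* (column-standardized)
at once; the first PLS component maximizes the covariance between scores
and the response, so its weight vector is the normalized cross-covariance

&nbsp;&nbsp;&nbsp;&nbsp;*w*₁ ∝ *X*ᵀ*y*꜀,

and the regression coefficients β = *W*(*P*ᵀ*W*)⁻¹*q* (NIPALS deflation
for further components) rank SNPs by how strongly they separate the
focal breed from all others. Per-SNP p-values come either from
genome-wide z-standardization of the coefficients with normal tails
(default) or from response permutations with add-one empirical p-values;
SNPs with p < 0.01 are the breed's *specific SNPs*.

Around the scan, the package provides the full analysis chain used in
breed-characterization studies:

* a **Balding–Nichols simulator** of multi-breed panels
  (per-breed frequencies Beta(p(1−F)/F, (1−p)(1−F)/F), so
  Var(p_b) = F·p(1−p)) with *planted* single-breed loci as ground truth;
* **VCF I/O and QC**: dosage loading, breed tables, breed-stratified
  imputation, inclusive MAF ≥ 0.05 filtering, 400-kb windowed SNP
  density;
* **population structure**: genetic-relationship-matrix PCA
  ((x−2p)/√(2p(1−p)) standardization) and classical PCoA (Gower double
  centering), with variance-explained fractions;
* **annotation and enrichment**: SNP→gene mapping against GFF3/BED gene
  models, hypergeometric right-tail (Fisher exact) term enrichment on
  GMT files, counts at p < 0.05 and p < 0.01;
* **network modules**: greedy seed-and-grow modules (≤ 35 genes) on a
  user-supplied gene-interaction graph, scored as −log₁₀ of the
  hypergeometric right-tail p of the focus-gene overlap, with per-breed
  module counts and ranking;
* a **pipeline** (`runPipeline()` / `breedpls` CLI) tying it together
  with YAML configuration, full determinism under a seed, and a JSON
  summary.

## Worked example

Simulate a six-breed panel with five planted breed-specific loci per
breed (allele-frequency shift 0.5 in the focal breed only), run QC, and
scan:

```r
library(breedPLS)

cfg <- SimulationConfig(nBreeds = 6, samplesPerBreed = rep(20L, 6),
                        nSnps = 3000, fst = 0.05, nPlantedPerBreed = 5L,
                        plantedDelta = 0.5, missingRate = 0.02, seed = 7)
sim <- simulateBreedPanel(cfg)
sim$panel
#> GenotypePanel: 3000 SNPs x 120 samples
#>   breeds (6): B01=20 B02=20 B03=20 B04=20 B05=20 B06=20
#>   missing dosages: 7095

panel <- filterMaf(computeMaf(imputeMissing(sim$panel)))
#> [breedPLS] 87 SNP(s) removed at MAF < 0.05; 2913 retained

round(100 * varianceFraction(runPCA(panel, k = 4)), 2)
#> [1] 2.68 2.60 2.55 2.46

scans <- scanAllBreeds(panel, alpha = 0.01)
scans[["B01"]]
#> BreedScanResult for breed B01
#>   2913 SNPs scanned (zscore, 1 component(s))
#>   30 significant at p < 0.01
scanSummary(scans)$perBreed
#>   breed n_snps n_significant
#> 1   B01   2913            30
#> 2   B02   2913            34
#> 3   B03   2913            37
#> 4   B04   2913            32
#> 5   B05   2913            29
#> 6   B06   2913            32
```

What the numbers mean: each breed gets ~1% of SNPs called at the strict
p < 0.01 threshold (the genome-wide z null is calibrated), and the calls
concentrate on the planted truth — here 25 of the 30 planted loci land
in their focal breed's significant set:

```r
hit <- mapply(function(id, b) id %in% significantSnps(scans[[b]]),
              sim$truth$snp_id, sim$truth$breed_code)
sum(hit)
#> [1] 25
```

The first four PCA axes each explain ~2.5% of variance because
Balding–Nichols breeds are exchangeable (no hierarchical split); a real
panel with a deep population split concentrates far more variance on
PC1. Downstream, `mapSnpsToGenes()`, `enrichTerms()` and
`scoreModules()` take each breed's significant set through gene mapping,
term enrichment and network-module scoring; `runPipeline()` runs the
whole chain and writes per-breed tables, Manhattan plots and a
`summary.json`.

Everything is also available from the shell:

```sh
inst/exec/breedpls simulate --out sim --n-breeds 6 --n-snps 3000 --seed 7
inst/exec/breedpls scan --vcf sim/panel.vcf --breeds sim/breeds.tsv --out scan
inst/exec/breedpls all --config run.yaml
```

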