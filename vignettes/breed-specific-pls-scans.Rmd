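---
title: "Breed-specific selection signatures by one-vs-rest PLS scans"
author: "breedPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-specific selection signatures by one-vs-rest PLS scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedPLS)
```

## The problem

A conservation program for a set of related populations — here, pig breeds
genotyped together on one SNP panel — needs to know what distinguishes
*each* breed from all the others, not merely whether the breeds differ.
breedPLS operationalizes "breed-specific" as a one-vs-rest regression
problem: for every breed in turn, a 0/1 breed-membership indicator is
regressed on all SNP dosages at once by partial least squares (PLS), and
SNPs whose regression coefficients are extreme genome-wide are called that
breed's specific SNPs. Downstream, those SNPs are mapped to genes, the
gene sets are tested for term enrichment with Fisher's exact
(hypergeometric right-tail) test, and gene-interaction modules around the
significant genes are built and scored the same way. The package wraps
the whole chain — simulation or VCF input, QC, population structure,
scan, annotation, enrichment, network scoring — into one reproducible
pipeline.

## The scan statistic

Let $X$ be the $n \times m$ matrix of alternate-allele dosages (0/1/2)
after imputation and MAF filtering, column z-scored so that weights are
comparable across allele frequencies, and let $y$ be the indicator of the
focal breed, centered. PLS1 with NIPALS deflation extracts latent
components that maximize covariance with the response; the
first-component weight vector is the normalized cross-covariance

$$ w_1 \propto X^\top y_c, $$

scores are $t = Xw$, and $X$ (and $y$) are deflated before further
components. Coefficients are mapped back to SNP space as
$\beta = W (P^\top W)^{-1} q$; for the default single component
$\beta \propto w_1$. One component is the default because a one-vs-rest
contrast targets a single discriminant direction; `nComponents` is
exposed for users who want to absorb additional structure, and the fit is
checked in the test suite against an independently coded NIPALS
implementation (mixOmics) to $10^{-8}$.

### Per-SNP significance

The per-SNP null distribution of a PLS coefficient has no closed form, so
two conventions are implemented and recorded in the output metadata:

* **`zscore`** (default): coefficients are standardized genome-wide,
  $z_j = (c_j - \bar c)/\mathrm{sd}(c)$, and converted to two-sided
  standard-normal tail probabilities. This treats the genome-wide
  coefficient distribution — which under multi-population drift is wide —
  as the empirical null, in the spirit of structured-population
  association scans, and self-calibrates across divergence levels.
* **`permutation`**: the response is permuted $B$ times, the model refit,
  and add-one empirical p-values
  $p_j = (1 + \#\{|c^{(b)}_j| \ge |c_j|\})/(B+1)$ reported. By default
  the coefficients are z-standardized *within each permutation* before
  comparison. This choice matters: the raw coefficient scale
  $\beta = X^\top y_c / \|t\|^2$ depends on how strongly the weight
  vector aligns with the leading variance directions of $X$, so observed
  and permuted coefficients live on systematically different scales in a
  structured panel and comparing them raw yields a strongly conservative
  test. Standardizing within each permutation removes the global scale
  and restores calibration; the raw comparison remains available via
  `standardize = FALSE`.

Significance calls use a strict threshold, `p < alpha` with
`alpha = 0.01` by default, and no multiple-testing correction — matching
the reporting convention the scan is designed around (per-breed
significant-SNP counts at p < 0.01). The per-breed counts are reported
both summed and as a union over breeds, since a SNP may be called in more
than one breed.

## The synthetic-data generator

The generator emulates the statistical structure the scan assumes: $B$
breeds of unequal sizes typed at many biallelic SNPs with
population-level allele-frequency divergence and a small set of planted
loci strongly differentiated in exactly one breed. Its default
configuration mirrors a 24-breed, 1069-animal panel (breed sizes 10–97)
at 62,822 SNPs on 18 autosomes.

* **Divergence model.** Per-SNP ancestral frequencies are uniform on
  `ancestralMafRange` (default 0.05–0.5); each breed's frequency is an
  independent Balding–Nichols draw,
  $p_b \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, so
  $\mathrm{Var}(p_b) = F\,p(1-p)$ with $F$ the `fst` parameter.
  Balding–Nichols was chosen because it is the standard single-parameter
  model of $F_{ST}$-like structure. The true divergence of the emulated
  panel is not published, so `fst` defaults to 0.15 and is exposed rather
  than fixed; `estimateFst()` recovers it from a frequency matrix by
  variance decomposition.
* **Planted signal.** For each breed, `nPlantedPerBreed` distinct SNPs
  are chosen and the focal breed's frequency is shifted by
  `plantedDelta` toward whichever boundary has more room (up when
  $p \le 0.5$), clipped to $[0.02, 0.98]$ so planted loci stay
  polymorphic and survive the MAF filter. A deterministic shift — not a
  sweep simulator — is used because it produces exactly the one-breed
  contrast the statistic tests, with a known effect size.
* **Genotypes** are Binomial(2, breed frequency) per individual, with
  independent missingness at `missingRate` (default 0.02). Positions are
  evenly spaced per chromosome; only density plotting and gene mapping
  consume them.

What the generator deliberately does **not** emulate: linkage
disequilibrium, recombination maps, demographic history, genotyping
error, or any real functional annotation (the `simulateAnnotation()`
companion produces random gene spans anchored on SNP positions, random
term sets and a random interaction graph — combinatorial structure only).
Passing tests on these panels therefore demonstrate the statistical
machinery, not performance on LD-structured real data.

### Detectability of the planted signal

A planted shift of $\delta$ competes against drift: the focal-vs-rest
frequency gap of an unplanted locus has standard deviation about
$\sqrt{F\,p(1-p)\,(1 + 1/(B-1))}$, roughly $0.15$ at $F = 0.1$ for
mid-range frequencies. A genome-wide standardized planted coefficient
therefore sits near $\delta/0.15 \approx 2.7$ SD for $\delta = 0.4$ —
right at the $\alpha = 0.01$ call threshold of $2.58$ — so recovery of a
$\delta = 0.4$ signal at $F = 0.1$ is partial by construction, while at
$F \le 0.05$ the same shift stands far clear of the drift distribution
and recovery is near-complete. The package's benchmarks report recovery
at both regimes rather than hiding the boundary case; this is a property
of any one-vs-rest frequency-contrast statistic at these sample sizes,
not of the implementation.

## QC choices

* **Imputation** replaces haplotype-based imputation with two simple
  breed-stratified rules — per-breed major dosage (default) or a binomial
  draw from the breed allele frequency — because the scan consumes
  dosages only and LD-aware imputation is out of scope. A SNP entirely
  missing within a breed falls back to the panel-wide rule, with a
  logged count.
* **MAF filtering** is inclusive (`maf >= 0.05` retained) and MAF is
  computed after imputation (missing entries are excluded from counts
  when present, so the order only matters at the margin; the choice is
  logged by the pipeline).
* **SNP density** uses 400-kb non-overlapping windows, window $k$
  covering 1-based positions $[kw+1, (k+1)w]$; counts always sum to the
  panel SNP count.
* Multiallelic and non-SNP VCF records are skipped (with a logged
  count), not split: the emulated panel is biallelic.

## Population structure

PCA follows the genetic-relationship-matrix convention: dosages are
standardized as $(x - 2p)/\sqrt{2p(1-p)}$, $G = ZZ^\top/m$ is
eigendecomposed, coordinates are eigenvectors scaled by
$\sqrt{\lambda}$, and variance fractions are eigenvalues over the sum of
positive eigenvalues. PCoA is classical metric MDS with Gower double
centering; negative eigenvalues are reported in the spectrum but excluded
from coordinates, the standard treatment. Because the distance choice
behind published PCoA plots is usually unstated, both Euclidean distance
on standardized dosages (default) and allele-sharing (1 − IBS) are
offered. On Euclidean distances of the standardized dosages, PCoA
coordinates equal $\sqrt{m}$ times the PCA coordinates up to axis sign
(because $B = ZZ^\top = mG$) — the module's primary cross-check, enforced
at $10^{-8}$ in the tests. A t-SNE view of the same panels is possible
with any established t-SNE implementation applied to the PCA
coordinates; it is a visualization aid only and no wrapper is shipped.

## Enrichment and network scoring

SNP-to-gene assignment includes a gene when any significant SNP lies
within `flankBp` (default 10 kb — an assignment-rule choice, logged and
configurable, since published SNP-to-gene windows are rarely stated) of
its span, strand ignored. The enrichment background defaults to the
genes reachable from the post-filter SNP panel, i.e. the universe the
scan could possibly hit, rather than the whole genome; it is
configurable. Enrichment p-values are exact hypergeometric right tails,
reported raw at p < 0.05 and p < 0.01.

Network modules are built by a deterministic greedy seed-and-grow
procedure: seed on the unassigned focus gene of highest degree, then
repeatedly absorb the unassigned neighbor adjacent to most module
members (ties: higher degree, then lexicographic id) up to 35 genes, the
conventional module size of commercial pathway-analysis reports; modules
with fewer than two focus genes are discarded. The generation algorithm
of the commercial tool this emulates is proprietary and unpublished, so
module *membership* is a documented stand-in — only the *score*,
$-\log_{10}$ of the hypergeometric right-tail p of the focus-gene
overlap (capped at 300), is exactly the published formula. Because a
score cut for "counting networks" is likewise unpublished, the ranking
reports both the raw module count and the count at score ≥ 2
(overlap p ≤ 0.01).

## Numerical and reproducibility choices

* Ties in imputation (equal dosage counts) go to the smaller dosage;
  ties in module growth are broken by degree then lexicographic id;
  eigenvector signs are fixed by making the largest-magnitude entry
  positive. Every tie-break is deterministic so identical inputs and
  seeds give byte-identical outputs, including the pipeline's
  `summary.json`.
* Permutation p-values use the add-one rule, so they are bounded below
  by $1/(B+1)$ and never zero.
* `plsFit` refuses constant responses, component counts beyond
  $\min(n-1, m)$, and vanishing residual cross-covariance; `runPCA`
  instructs the user to MAF-filter when monomorphic SNPs are present.
* All randomness flows from explicit integer seeds: the generator chain
  derives its three stages from `seed`, `seed + 1`, `seed + 2`; the scan
  gives breed $i$ the seed `seed + i`.

## Benchmark problem sizes

The test-suite benchmarks run on scaled-down panels chosen to exercise
the statistics with comfortable margins: calibration and power use
6 breeds × 30 samples at 5,000 SNPs (10 and 20 replicates respectively),
oracle comparisons use dozens of 30 × 100 matrices, and the end-to-end
determinism check uses 4 breeds × 20 samples at 2,000 SNPs. The
`scripts/acceptance.R` benchmark recomputes the same quantities from
scratch at the same sizes.

## Known limitations

* No LD modelling anywhere: simulated panels are exchangeable across
  loci, and the scan treats SNPs marginally (the PLS weight vector is a
  single discriminant direction, not a conditional model).
* The genome-wide z null assumes the coefficient distribution is
  approximately normal; heavy-tailed structure (e.g. a recently admixed
  breed) will shift calibration, which is why the permutation option
  exists.
* The enrichment stage does no GO-graph propagation or pathway topology;
  supply GMT content at the granularity you want tested.
* Module membership is not comparable to proprietary network tools, only
  module scores are.
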