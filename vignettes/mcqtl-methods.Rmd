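---
title: "Multiple-line cross QTL mapping: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-line cross QTL mapping: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcqtl)
```

This vignette documents the statistical model the package fits, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices made where the method left the design open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## 1. The mapping model

The response is a vector of per-line adjusted entry means (BLUEs) for N
doubled-haploid (DH) lines from P biparental families on a shared
consensus map. At each evaluated genome position the package fits, by
ordinary least squares,

$$Y = J M + X_q B_q + X_c B_c + \varepsilon,$$

with `J` the N×P family-membership indicator, `M` the family means,
`X_q` the N×P block of expected reference-parent allele counts at the
tested position (one column per family, zero off-family), `B_q` the
family-specific allele-substitution effects, and `X_c` the same
construction for each cofactor marker. Families in which the position is
(quasi-)monomorphic contribute no column, keeping the design full rank;
the within-family count variance of a genuinely segregating DH locus is
close to 1, so a column-inclusion threshold of 0.01 on that variance
distinguishes the two regimes with a wide margin.

**Expected counts.** For a DH line the genotype at an unobserved
position is 0 or 2 copies of the family's reference-parent allele. Its
conditional expectation given the flanking marker genotypes uses
Haldane's map function $r(d) = (1-e^{-2d/100})/2$ (no interference), e.g.
$2\,(1-r_1)(1-r_2)/(1-r_T)$ with $r_T = r_1 + r_2 - 2 r_1 r_2$ when both
flanks carry the reference allele. Missing flanks fall back to the
nearest non-missing marker on that side, then to the one-sided
conditional, then to the population expectation 1. Only flanking-marker
conditioning is used — no multipoint hidden-state smoothing — which keeps
the computation exactly checkable against a brute-force enumeration of
the eight flanking-haplotype outcomes (the test suite verifies agreement
to 1e-12). The same Haldane assumption drives the meiosis simulator, so
simulation and inference are internally consistent.

**Testing.** Each position is assessed by the likelihood-ratio test of
the full against the null (family means + cofactors) model, reported on
the LOD scale, $\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$. Where a
p-value is needed (the epistasis scan), the LR statistic is referred to
its exact finite-sample null distribution for Gaussian least squares —
the F distribution, of which the LR is a monotone transform — rather
than the chi-square asymptote, so per-test error rates are exact at any
sample size.

**Cofactors.** Forward selection over all markers, each entering as a
family-specific block on top of family means, with the Schwarz criterion
(BIC) as entry rule; ties go to the earlier map position and selection
stops at `max_cofactors` (default 20). BIC was chosen over AIC-type
rules for conservatism at N ≈ 650: on pure-noise traits the median
number of selected cofactors is 0–2 (verified in the suite). During the
scan, cofactors closer than 10 cM (`cofactor_window`) to the tested
marker interval — interpreted literally as the two markers flanking the
tested position — are dropped from both models at that position.

**Thresholds.** The genome-wide LOD threshold is the empirical
(1 − α) quantile (inverse-ECDF, so α = 1 returns the minimum) of the
max-LOD distribution over permutations of the phenotype *within family*
(default 2000, α = 0.10). Within-family permutation respects the family
mean term `J M`: it is the exchangeability structure of the model's
null. The test suite confirms that within-family permutations of one
draw and fresh exchangeable null draws give max-LOD distributions that
agree (KS test), and the acceptance script measures the realized
experiment-wise type I error on 100 independent null populations.

**Support intervals and peak hygiene.** A QTL's support interval extends
from its peak outward to the first grid positions at which the LOD has
dropped by 1.0 (`lod_falloff`), truncated at chromosome ends. Peaks
whose support intervals overlap, or whose peaks lie within 10 cM of each
other, are merged keeping the higher peak. The second clause is a
deliberate addition: the cofactor-exclusion boundary can notch a single
QTL's profile into twin peaks ~10 cM apart, and 10 cM is already the
package-wide resolution at which two signals count as one region. As a
final guard the identified list is trimmed by backward elimination
(`trim_qtl`): in the joint multi-QTL fit, any QTL whose conditional
(drop-one) LOD falls below the detection threshold is removed, weakest
first. Genuinely distinct QTL keep conditional support near their
marginal LOD; collinear duplicates of one signal do not. Without this
step the drop-one pG decomposition splits one QTL's variance over two
collinear records and becomes uninterpretable.

**Proportion of genotypic variance.** Overall
$p_G = 100\,R^2_{adj}/h^2$, where $R^2_{adj}$ is the adjusted
coefficient of determination of the QTL terms beyond family means in the
simultaneous multi-QTL fit (adjustment factor $(n-P)/(n-P-m)$ with m the
rank added by the QTL blocks). Per-QTL values are drop-one decrements of
$R^2_{adj}$; per-family values repeat the computation within each
family's subsample. Whether per-family values should use family-specific
heritabilities is not determinable from the method description this
package follows; the population h² is used as a proxy and the choice is
recorded in the result's metadata. All pG values are floored at 0.

## 2. Cross-validation

Fivefold cross-validation stratified by family (fold sizes within one
line of proportionality; verified as an invariant). Per fold, the whole
pipeline reruns from scratch on the estimation set — cofactor selection,
permutation threshold (200 permutations by default here, for
tractability; configurable to 2000), detection, trimming, joint effect
estimation. In the test set, the QTL-predicted values and the observed
values are centred within family and correlated; the test-set pG is
$100 \cdot \max(0, 1-(1-r^2)\frac{n-1}{n-2})/h^2$ for positive r, 0
otherwise (a negative predictive correlation means no transferable
signal), and 0 for folds whose estimation set yields no QTL. The
default is 20 runs × 5 folds; the relative bias of pG is
$100\,(p_{G,ES}-p_{G,TS})/p_{G,ES}$, undefined (NA, with a warning) when
$p_{G,ES} \le 0$.

## 3. Epistasis scan

All marker pairs on different chromosomes or ≥ 20 cM apart are tested by
extending the two-locus additive model with an interaction block whose
family-p column is the product of the two *within-family mean-centred*
counts — centring makes the interaction orthogonal to the main effects
in balanced DH families, where the locus correlation within a family is
0 for unlinked loci. The main-effect cofactors of the 1-D scan are not
carried into the pair model: the extended model is family means + locus
1 + locus 2 + interaction. Pairs are kept at
$p < \alpha / \binom{2C}{2}$ (α = 0.05, C chromosomes, two assumed
independent regions per chromosome; the region count is a parameter, not
hard-coded, since consensus maps can have more linkage groups than
chromosomes). Overlapping significant pairs collapse to the best pair
per region pair. Two caveats are documented deliberately: (i) the
region-based Bonferroni assumes the effective number of independent
tests equals the region-pair count, which a dense marker-pair grid can
exceed — the package's specificity checks therefore use pair grids whose
density matches the region count; (ii) rank-deficient interaction
blocks (perfectly correlated loci) are skipped and counted in the
result's metadata.

## 4. What the simulator emulates — and what it does not

`simulate_triticale()` generates the study conditions end to end:

* **Population**: four DH families of 131/120/200/196 lines from six
  parents (the first two families share one parent, the last two
  another; the pools are disjoint), 21 chromosomes (7 per subgenome
  A/B/R) of 120 cM carrying 40 markers by default. DH lines are doubled
  single F1 gametes — one Haldane meiosis, no interference, no
  segregation distortion.
* **Architecture**: per trait three major QTL (pG targets 14.1%, 12.5%,
  24.1% on the 5A/1B/5R analogues) and six minor QTL (2.5% each), with
  the 5A locus segregating only in the third family and the 5R locus in
  all but the third; effect sizes are derived from the targets and the
  realized family weights. The polygenic background is a normal draw
  calibrated per seed (made orthogonal to the QTL part and scaled) so
  the realized genotypic variance matches `var_g` exactly.
* **Traits**: winter hardiness (σ²G = 3.00, σ²G×L = 0.33, σ²e = 0.81,
  two locations, mean 3.9) and frost tolerance (2.36, —, 0.34, one
  location, mean 4.8) on the 1–9 scoring scale; scores are deliberately
  *not* clamped to [1, 9]. The printed phenotypic correlation of 0.88
  together with h² ≈ 0.87/0.91 implies a genetic correlation of
  0.88/√(0.87·0.91) ≈ 0.99, so the paired preset shares all QTL between
  the traits (effects scaled by √(2.36/3.00)) and correlates the
  polygenic backgrounds at 0.99 — a closed-form calibration, not a
  fitted one.
* **Trials**: partially replicated designs with a duplication fraction
  of 0.484 (960 plots per location for 647 entries implies ~313
  duplicated lines), giving a harmonic-mean replicate number of 1.32,
  which reproduces h² ≈ 0.86 and repeatability ≈ 0.90 from the variance
  components above. Location effects are N(0,1); within-location
  replicate (block) effects are zero by design, though the entry-mean
  stage estimates them regardless.
* **QTL positions lie at markers**: every simulated locus coincides
  with a map marker (anchor markers are inserted where needed), so true
  QTL genotypes come from the same meiosis as the markers rather than
  from a second, inconsistent sampling step.

Not emulated — hence not demonstrated by passing tests: segregation
distortion, dominance (DH lines have none), genotyping error, spatial
field trend and the exact alpha-design layout, genotype-by-environment
interaction at the QTL level (mapping uses across-location means only),
and real consensus-map artifacts such as locally wrong marker order.
Results on real data inherit whatever those features add.

## 5. Phenotype stage

The entry-mean stage is two-stage fixed-effects least squares: per
location, line + replicate effects jointly by least squares, each line
taken at the average replicate effect; then a plain average of the
location-wise estimates. This replaces the mixed-model/spatial BLUEs a
full trial analysis would use, because the true trial layout of the
emulated study is unavailable; on balanced synthetic data the two
coincide, and on the package's p-rep simulations the difference is the
(unmodelled) shrinkage of a random-line model. Check entries present in
the trial but absent from the family table are used for the adjustment
and excluded from the output. Variance components come from
expected-mean-squares ANOVA on the line × location table of adjusted
cell means (plot error from the pooled within-location residual mean
square), a deliberate closed-form simplification of REML; negative
solutions truncate to 0, and with one location the genotype-by-location
component is reported as NA and h² is the repeatability. The effective
replicate number is the harmonic mean of per-cell replicate counts.
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times L}/L + \sigma^2_e/(L\bar r))$.

## 6. Numerical choices, tie-breaks, degenerate inputs

* Least squares via base R's rank-revealing (pivoted) QR; permutation
  responses are swept through each position's decomposition in one pass,
  which is what makes 100-dataset × 200-permutation acceptance runs
  affordable on one CPU.
* A zero-variance response gives LOD ≡ 0 (not an error); a perfect fit
  (RSS₁ = 0) gives a large finite LOD via an RSS floor of RSS₀ · 1e-15.
* Cofactor-selection ties on BIC break toward the earlier (chromosome,
  position); QTL-merge ties on LOD break toward the lower position.
* The scan grid is every `scan_step` cM (default 1) plus every marker
  position; peaks are reported at grid resolution.
* Config files are flat `key=value` text; unknown keys are rejected
  rather than ignored.
* Derived seeds stay below 2³¹; every stochastic step (map, meiosis,
  polygenic draw, permutations, folds) takes an explicit seed and is
  reproducible from it.

## 7. Problem sizes used in the validation suite

The suite exercises reduced-scale versions of the study chosen to keep
the full validation run in the tens of minutes on one core while leaving
each check statistically meaningful: null populations of 4 × 50 lines on
5 chromosomes (200 permutations, 100 datasets) for the type-I-error
measurement; 50 replicates at ~5 cM marker spacing (the preset's
density regime) for localization and pG recovery of a 25%-pG QTL; 20
replicates of a sparse 10-locus design — whose pair count matches the
region-pair count of the Bonferroni assumption, see §3 — for epistasis
sensitivity and specificity; and the full 647-line preset with 10
markers per chromosome, a 5 cM grid and 100 permutations for the
cross-validation overfitting check (10 runs × 5 folds). Map expansion
and recombination-fraction invariants use 10,000-line families, where
binomial error is negligible.

## 8. Known limitations

* Flanking-marker conditioning (not multipoint) loses a little
  information when markers are missing in runs; with the preset's
  complete genotypes the two coincide.
* The region-based epistasis correction is optimistic on marker grids
  much denser than two regions per chromosome (§3).
* Per-family pG uses the population h²; family-specific heritabilities
  would need per-family trial data.
* The entry-mean stage is fixed-effects; no spatial or incomplete-block
  recovery, and no shrinkage.
* Detected-QTL pG is known to be optimistic on the data that detected
  it — that is the point of the cross-validation module, which measures
  the bias rather than pretending it away.
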