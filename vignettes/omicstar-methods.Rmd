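---
title: "Methods: multi-omics star-network signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics star-network signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicstar)
```

# Overview

`omicstar` integrates four omics layers measured on the same subjects — gut
bacterial genera, gut viral species, plasma metabolites, and plasma
cytokines/chemokines — across three cohorts (healthy controls, liver
cirrhosis, hepatocellular carcinoma). The pipeline screens features for
cohort differences, correlates the significant candidates across layers in
four subject subsets, extracts correlation star networks that span all four
layers, and classifies the star centers as common, disease-specific, or
disease-severity-associated signatures. This vignette records the
statistical machinery, its assumptions, the defaults and why they were
chosen, and the places where the design was genuinely open.

# Screening model

Each feature is tested independently across cohorts with the
**Kruskal–Wallis** rank test,

$$H = \frac{12}{N(N+1)} \sum_j n_j \left(\bar R_j - \frac{N+1}{2}\right)^2
  \bigg/ \left(1 - \frac{\sum_t (t^3 - t)}{N^3 - N}\right),$$

with a $\chi^2_{k-1}$ reference distribution. The $\chi^2$ approximation
(rather than exact enumeration) is the pragmatic choice at cohort sizes of
17/18/10, where enumeration is infeasible; the test suite checks the
approximation against a permutation oracle at moderate $N$ and its type-I
error calibration (0.05 ± 0.02 at $\alpha = 0.05$ over 1000 seeded null
features). When every observation is identical the tie correction is zero
and the statistic is undefined; we define $H = 0$, $p = 1$.

**Dunn's post hoc test** follows on the pooled ranking:

$$z_{jk} = \frac{\bar R_j - \bar R_k}
 {\sqrt{\left[\frac{N(N+1)}{12} - \frac{\sum_t(t^3-t)}{12(N-1)}\right]
  \left(\frac{1}{n_j} + \frac{1}{n_k}\right)}}.$$

The multiplicity adjustment over the (at most three) pairs defaults to
**Benjamini–Hochberg**; the upstream analyses this mirrors report only
"adjusted p" without naming a method, so BH was chosen as the common modern
default, with Bonferroni and Holm available by flag. A feature is
*significant* when its KW p-value and at least one adjusted Dunn pair fall
below $\alpha = 0.05$; its *enriched cohort* is the cohort with the maximal
group mean on the analyzed scale (medians by flag). Count layers are
screened on the relative-abundance scale, matching how abundance heatmaps
compare cohorts.

Features first pass a **prevalence filter**: mean relative abundance
strictly greater than $10^{-4}$ (0.01%). The strict inequality follows the
filter's usual wording. Whether the mean is taken across all samples or
within cohorts is ambiguous in such descriptions; the default averages
across all samples, and `scope = "any_cohort"` keeps a feature whose
within-cohort mean clears the threshold anywhere.

## Summary-statistics tests

Clinical characteristics tables print mean ± SD and $n$ per cohort;
`t_test_from_summary()` recomputes the pooled-variance two-sided Student
t-test from those summaries alone
($df = n_a + n_b - 2$). For 2×2 categorical tables `chi2_2x2()` wraps the
chi-square test; published tables are not always consistent about the Yates
continuity correction (we found one where different columns match the
corrected and uncorrected statistic), so the correction is a flag,
defaulting to on. `mann_whitney()` uses tie-aware full enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments when both sides have ≤ 8
observations (the two-sided p is the probability of a $U$ at least as far
from $n_1 n_2 / 2$ as observed) and the continuity-corrected,
tie-corrected normal approximation otherwise.

# Diversity estimators

Alpha diversity: Shannon $H = -\sum p_i \ln p_i$ in natural-log units and
the Gini–Simpson complement $1 - \sum p_i^2$ — the defaults of the common
amplicon toolchains — with the Simpson concentration variant by flag.
Richness estimators use singleton/doubleton counts: Chao1 in the
bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (no division by zero
at $F_2 = 0$; classic form by flag), and ACE with the rare/abundant cut at
10 reads,

$$S_{ACE} = S_{abund} + \frac{S_{rare}}{C} + \frac{F_1}{C}\gamma^2,
  \qquad C = 1 - F_1/N_{rare}.$$

Degenerate ACE inputs are handled explicitly: if all rare species are
singletons the coverage $C$ is zero and ACE falls back to Chao1 with a
warning; with $N_{rare} \le 1$ it returns observed richness. Both
estimators are cross-checked against `vegan::estimateR` in the tests.

No rarefaction is applied before alpha diversity (the emulated workflow
does not mention it); a `rarefy_counts()` utility exists but is never
called implicitly.

Beta diversity uses **Bray–Curtis** dissimilarity
($BC = \sum|x_i-y_i| / \sum(x_i+y_i)$, via `vegan::vegdist`), which is not
a metric — the package asserts symmetry, range and identity, not the
triangle inequality. **PCoA** Gower-centers $-d^2/2$ and eigendecomposes;
Bray–Curtis input routinely yields negative eigenvalues, which are retained
in the result but excluded from coordinates and explained fractions.
Ordination group separation is tested with **PERMANOVA** (999 permutations,
`vegan::adonis2`, $p = (1 + \#\{F^{perm} \ge F\})/(1 + n_{perm})$). The
workflow this emulates never names its ordination significance test;
PERMANOVA is this package's explicit stand-in choice.

Venn overlap counts a feature "present" in a cohort when it has ≥ 1 read in
≥ 1 of the cohort's samples, both thresholds configurable; the seven region
counts always sum to the union size (inclusion–exclusion is asserted in
tests).

# LEfSe-style effect sizes

The biomarker score mirrors the reference LEfSe procedure: a KW filter at
$\alpha = 0.05$, then 30 bootstrap rounds, each subsampling two thirds of
every class and fitting a linear discriminant (`MASS::lda`) on the
surviving features after per-sample total-sum scaling to $10^6$. The
per-round effect size of a feature is the average of (a) the absolute
difference of its class means and (b) its unit-normalised LDA coefficient
times the class separation of the projected means; the reported score is
the mean over rounds of $\log_{10}(1 + \mathrm{effect})$. The $10^6$
scaling puts scores on the familiar 2–6 range, making the conventional
biomarker threshold of 3 meaningful. This exact blend is a compatibility
choice mirroring the reference implementation rather than a derived
formula. A tiny relative jitter ($10^{-6}$ of each feature's SD) guards the
LDA fit against exact collinearity — the reference tool injects noise for
the same reason — and a degenerate fit falls back to the raw mean
difference term. With three classes the default is one-against-all (each
feature scored in its winning class versus the rest); all-against-all
averages the winning class's pairwise comparisons instead. The subclass
(within-class) stage of the reference tool is a structural no-op here
because the design has cohort labels only.

# Joint networks and star extraction

All significant candidates from the four layers are correlated pairwise
with Pearson's $r$ and the two-sided $t$ p-value
($t = r\sqrt{n-2}/\sqrt{1-r^2}$), in each of four subject subsets: all
subjects, Ctrl+LC, Ctrl+HCC, LC+HCC. Three defaults deserve a note, since
the analyses this mirrors leave them unstated:

- **Edge rule:** unadjusted $p < 0.05$ with no $|r|$ floor. No multiplicity
  correction is applied to edges by default (a BH option exists); the
  published analyses report none.
- **Scale:** correlations are computed on the analyzed scale (relative
  abundance / concentration) without log transform, since none is stated;
  a $\log_{10}(x + 10^{-6})$ option exists for abundance layers.
- **Gut-permeability markers** (LPS, zonulin, TMAO) are not network nodes:
  the four-layer composition rule concerns the four omics layers only.

A "network centered on X" is formalized as the **star (ego-graph of radius
1)** of X: published renderings of such networks draw exactly
center-plus-direct-neighbors graphs. A star is retained when the layers of
its members cover at least `min_layers = 4` layers, with the center's own
layer counting toward coverage (the centers of the emulated figures are
themselves members of one of the four datasets). Whether coverage should
instead require the *neighbors alone* to span the remaining layers is
ambiguous; the center-inclusive reading is the default and
`include_center = FALSE` gives the stricter one. Star extraction is
order-invariant and monotone (removing an edge never creates a retained
star), both property-tested against a brute-force recount.

Constant candidate columns (possible in subsets where a feature never
varies) are dropped with a warning; a constant vector's correlation is
reported as missing, never as zero.

# Signature classification

A center's membership across the four subset analyses maps to a label by
ordered rules:

1. Ctrl–LC **and** Ctrl–HCC → `Common` (the ALL flag is not required:
   no published row exercises that combination, and the permissive reading
   was chosen);
2. Ctrl–LC only → `LCSpecific`;
3. Ctrl–HCC only → `HCCSpecific`;
4. ALL only → `CommonAllOnly` when the control mean is *strictly* the
   extreme of the three cohort means with LC and HCC on the same side
   (i.e. the all-subject correlation is driven by a consistent shared
   direction of change in both diseases), else `Unclassified`. Ties are
   not strict extremes and fall through to `Unclassified`;
5. otherwise `Unclassified`.

Severity association is orthogonal: it is LC–HCC membership, so a center
can be simultaneously `Common` and severity-associated. `CommonAllOnly` is
kept as a distinct label (rendered "Common \*") rather than merged into
`Common`, because it rests on weaker evidence and the published table
annotates such rows differently. The rules are exhaustive over all 16 flag
combinations (truth-table tested), and the transcribed 39-row published
membership fixture reproduces its printed label and severity columns
row by row.

# The synthetic cohort generator

The generator's defaults are the study conditions the pipeline assumes:

- **Cohorts:** Ctrl/LC/HCC of 17/18/10 subjects.
- **Count layers** (bacteria, virus): per-sample Dirichlet-multinomial at
  depth 70,000 — the order of magnitude of cleaned reads per subject in
  the emulated study — with geometric-ladder base concentrations
  ($5 \cdot 0.9^i$, total 50) giving realistically skewed, strongly
  overdispersed compositions. Cohort effects multiply a feature's base
  concentration (1 = null).
- **Concentration layers** (metabolite, cytokine): truncated normal,
  truncated at zero rather than resampled because real plasma panels
  contain means near zero with large SDs; the truncation fraction is
  logged in the truth record. Cohort effects are additive in measurement
  units (0 = null).
- **Planted stars:** one latent Gaussian factor per star, per sample,
  entering count layers on the log scale
  ($a_i \mapsto a_i e^{\lambda_i z}$) and concentration layers linearly in
  SD units, with the center's loading fixed at $+1$ and neighbor loadings
  in $[-1, 1]$ controlling correlation signs.

All randomness flows through one seeded stream; the caller's RNG state is
restored on exit, and equal (spec, seed) gives byte-identical datasets on
disk.

For the recovery simulations, "2-SD planted effects" are sized against each
feature's *own* variability: a star member on a count layer carries a
latent log-scale factor of SD ≈ 1, so its 2-SD multiplicative shift is
$e^2 \approx 8$; a concentration member with loading $\lambda$ has total SD
$\sigma\sqrt{1+\lambda^2}$, so its additive shift is twice that. Shift
directions follow loading signs so that the cohort-shift and latent-factor
contributions to a planted correlation reinforce rather than cancel.
No effect-size ground truth exists for the real data (only printed
mean ± SD); these magnitudes are chosen to produce separations of the size
the printed tables show, not claimed to match the real generating process.

The generator emulates the *statistical* structure the pipeline consumes —
compositionality, overdispersion, group shifts, cross-layer dependence. It
does not emulate raw reads, phylogenies, assay-level noise (ELISA plates,
NMR spectra), covariate structure (age/sex/BMI confounding), or the
zero-inflation patterns of real viromes. Passing recovery tests therefore
demonstrate that the pipeline's inference machinery is correct and
calibrated under its own model, not that the model captures every feature
of real data.

# Problem sizes and numerical choices

The test and acceptance simulations use compact designs chosen to exercise
every code path at study-realistic sample sizes: 45 subjects (17/18/10)
throughout; 10–15 features per layer with one planted star for recovery
runs (50 seeds); 1000 features for null calibration. Round-trip IO
preserves 12+ significant digits (full-precision decimal text). Eigenvalues
below $\sqrt{\varepsilon} \cdot \max|\lambda|$ are treated as null in PCoA.
P-values are floored at the smallest positive double so reported values lie
in $(0, 1]$; a perfect correlation reports $p = 0$ exactly. Edge lists use
a canonical (layer, feature) ordering so undirected pairs are stored once
and outputs are order-invariant. Pipeline output directories are stamped
with a hash of the full configuration, so reruns with changed thresholds
never overwrite earlier results, and manifests omit wall-clock times to
keep reruns byte-identical.

# Known limitations

- Pearson correlation on compositional relative abundances is subject to
  spurious negative correlation (closure); the emulated workflow uses plain
  Pearson, so no compositional transform (CLR etc.) is applied. The worked
  example in the README shows the practical consequence: a strong shift in
  a dominant taxon drags every other relative abundance with it.
- Unadjusted edge p-values at $\alpha = 0.05$ imply a nontrivial
  false-edge rate in large candidate sets; the BH option is provided but
  not default, to match the emulated analysis.
- Star-center counts on real data depend on curation decisions the source
  text does not specify; the package reproduces the *rules*, and claims no
  reproduction of specific published network counts.
- UniFrac beta diversity and taxonomic cladograms are out of scope (no
  phylogeny is available at this interface).
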