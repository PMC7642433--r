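---
title: "Classifying tumour-immune phenotypes from CD8 topology and bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumour-immune phenotypes from CD8 topology and bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunophen)
```

## The problem

Solid tumours differ sharply in where their cytotoxic CD8+ T cells sit:
*infiltrated* tumours have T cells inside the malignant epithelium,
*excluded* tumours confine them to the surrounding stroma, and *desert*
tumours have few T cells anywhere. These phenotypes predict response to
immunotherapy, but calling them by eye from CD8 immunohistochemistry (IHC)
is subjective, and many cohorts have expression data without imaging.

`immunophen` implements a reproducible pipeline that (i) quantifies CD8
topology from two-channel IHC rasters, (ii) compresses it into two polar
metrics, (iii) discovers the genes that track those metrics, and (iv)
trains a portable expression-only classifier of the three phenotypes —
with a synthetic-data module that plants known ground truth so every stage
is testable offline.

## The polar metrics

With tumour-compartment CD8 density $t$ and stroma-compartment density $s$
(cells/mm²), the pipeline works with

$$R = \sqrt{t^2 + s^2}, \qquad \theta = \operatorname{atan}(s/t) \in [0, \pi/2].$$

$R$ encodes total CD8 quantity; $\theta$ encodes stroma skew ($\theta =
\pi/2$ means purely stromal, hence exclusion). The two-argument arctangent
handles $t = 0$ without special cases; it agrees with $\operatorname{atan}(s/t)$
everywhere the ratio is defined. At $t = s = 0$ the angle is genuinely
undefined: the convention is $\theta := 0$ with `degenerate_flag = TRUE`.
The flag travels with the sample — downstream models receive the flagged
$\theta$ as-is, because zero-CD8 tumours carry their information almost
entirely through $R$ (they are deserts regardless of angle).

```{r polar}
to_polar(3, 4)
```

## Digital pathology reconstruction

The original compartment-calling algorithm ran in discontinued commercial
software; this package reconstructs the described logic with every
threshold exposed:

1. **Nucleus segmentation** — threshold the haematoxylin channel, split
   touching objects by watershed on the Euclidean distance transform.
   Watershed markers come from a lightly smoothed distance transform: a
   convex nucleus then yields exactly one marker (the discrete distance
   ridge of an elongated nucleus is otherwise a broken plateau), while the
   saddle between two genuinely touching nuclei survives smoothing and
   keeps them separate.
2. **Compartment call** — a nucleus is tumour-class when it is large and
   round (`area >= 45` µm² and `eccentricity <= 0.7` by default; epithelial
   nuclei are larger and rounder than fibroblast nuclei). The tumour
   compartment is the union of disks of `dilation_radius_um` (default
   12 µm) around tumour-nucleus centroids — the "immediate region
   surrounding" the tumour cells; the remaining tissue is stroma; pixels
   outside the tissue envelope (morphological closing of the
   nuclei-or-DAB support) are background and never enter density
   denominators. The dilation radius and minimum CD8 blob size are not
   stated in the source material; they are configuration parameters with
   documented defaults, not claims about the original values.
3. **CD8 counting** — each connected DAB-positive component of at least
   `min_blob_area` (3 µm²) counts once, for the compartment under its
   centroid pixel (an unambiguous tie-break for boundary-straddling
   cells). Densities are counts over compartment areas in mm²; a zero-area
   compartment reports a missing density but keeps its count.

## Expression preparation

Counts are prepared exactly in the conventional bulk RNA-seq way: genes
with CPM < 0.25 in at least 10% of samples are removed (a fraction of
exactly 10% removes); TMM scale factors are computed with the canonical
trims (30% on M, 5% on A), inverse-asymptotic-variance weights, the
upper-quartile reference rule, and rescaling to geometric mean 1 (verified
against `edgeR::calcNormFactors` in the test suite); log2 CPM uses

$$\log_2\!\left(\frac{c + 0.5}{L \cdot f + 1} \cdot 10^6\right)$$

with prior 0.5 — the exact dialect is pinned in the provenance because it
is not uniquely determined by convention. Voom precision weights are *not*
computed: downstream clustering and classification consume values, not a
weighted linear model. Finally each sample's column is divided by that
sample's mean log2 CPM over four housekeeping genes (ACTB, ACTG1,
HSP90AB1, UBC — the generic identification rule, mean log2 CPM > 10 and
variance below the 25th percentile, is also provided; EEF1A1, a fifth
pan-cancer candidate, is conventionally dropped for low expression in
ovarian cohorts). This ratio normalization is what makes the classifier
portable across platforms. PCA outlier scores are reported as a
diagnostic only; no sample is excluded automatically, because no exclusion
rule is defined.

One deployment nuance discovered in testing: applying the low-expression
filter to a *new* cohort can remove a trained classifier's genes (genes
planted low in excluded tumours occasionally dip under the CPM cutoff).
`filter_low_expression(keep_genes = )` therefore exempts model genes at
classification time; training-time behaviour is unchanged.

## Gene selection by per-gene random forests

For every gene, a regression forest predicts its normalized expression
from $(R, \theta)$: patients are bootstrap-resampled per tree, and both
predictors are candidates at every split (no predictor subsampling — with
two predictors, `mtry` restriction would be meaningless). Importance is
permutation-based: the mean increase, over trees, of out-of-bag MSE when
one predictor's OOB values are permuted, expressed as a percentage of the
forest's aggregated OOB MSE. Defaults are 500 trees and minimum node size
5, the canonical regression-forest settings.

Selection then proceeds in two steps. Genes whose *average* permutation
importance falls in the bottom quartile are dropped as unassociated. (The
phrase "average MSE below the first quantile" admits a literal reading —
low OOB MSE — but low OOB error denotes *well-predicted* genes, the
opposite of unassociated; the intent fixes the direction. The literal
variant is available via `drop_rule = "oob_mse"`.) Among retained genes,
the third quartiles of the two importances are computed (inclusive
linear-interpolation quantiles, strict `>`; computed after the drop, on
retained genes) and genes are partitioned into `quantity_only`,
`distribution_only`, `both`, and `none`. The signature used downstream is
the union of the two *exclusive* sets, mirroring the published
103 + 56 = 159 construction in which shared genes are set aside as
redundant with the quantity axis.

A structural note: quantile thresholds select a fixed *fraction* of
retained genes, so loosening `select_quantile` grows the total selected
set monotonically, but the exclusive-union signature itself can shrink as
genes migrate into `both`. The tests assert the former (true) property.

## Consensus clustering and the phenotype merge

Samples are clustered on the signature genes with "Pearson distance +
k-means", made precise as k-means on per-sample profiles standardized to
zero mean and unit norm — squared Euclidean distance is then proportional
to $1 - r$ (Pearson). Each of 1,000 replicates subsamples 80% of patients
(100% of features), runs k-means (k = 6, k-means++ initialization, 10
restarts, 300-iteration cap, per-replicate seeds fanned out from the
master seed), and the consensus matrix entry for a pair is its co-cluster
count over its co-sample count. Final clusters come from average-linkage
hierarchical clustering of $1 - M$ cut at $k$. The exploratory $k = 4$
step of the original analysis is not reproduced; only $k = 6$ feeds the
pipeline.

The original six-to-three reduction was manual. Reproducibility demands a
rule, so the merge is an explicit, configurable surrogate — not a claim
about the original procedure: clusters whose mean $R$ falls below the
cohort's 40th percentile (motivated by the published ~41% desert share)
are desert; of the rest, clusters whose mean $\theta$ exceeds the median
$\theta$ of non-desert samples are excluded; the remainder are
infiltrated. The merge map records the statistics behind every
assignment, and a phenotype receiving no cluster is a warning with
diagnostics, not an error — the manual step it replaces offered no
guarantee either.

## Nearest shrunken centroids with a confidence gate

For gene $i$, class $k$: with overall mean $\bar x_i$, class centroid
$\bar x_{ik}$, pooled within-class standard deviation $s_i$, and fudge
$s_0 = \operatorname{median}(s_i)$,

$$d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k (s_i + s_0)}, \quad
  d'_{ik} = \operatorname{sign}(d_{ik})\max(|d_{ik}| - \Delta,\, 0),$$

with $m_k = \sqrt{1/n_k - 1/n}$ — the standard error of the centroid
offset, derivable from the covariance of a class mean with the overall
mean. (Some descriptions use $\sqrt{1/n_k + 1/n}$; that variant sits
behind `mk_convention = "plus"`.) Prediction uses the shrunken centroids
$\bar x'_{ik} = \bar x_i + m_k (s_i + s_0) d'_{ik}$ in the standardized
discriminant
$\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$,
with posteriors $\propto \exp(-\delta_k/2)$ and priors defaulting to
observed class frequencies. Genes fully shrunk for every class are inert —
the classifier selects genes implicitly as $\Delta$ grows.

$\Delta$ is chosen by stratified 10-fold cross-validation over a grid of
30 evenly spaced values from 0 to $\max|d_{ik}|$, minimizing
misclassification with ties broken toward the largest (most parsimonious)
$\Delta$. The confidence gate is applied at deployment, not inside CV: a
sample is assigned its top phenotype only when that posterior strictly
exceeds 0.7 *and* both others are strictly below 0.5 ("exceeded" /
"below" read as strict); otherwise it is `unclassified`.

Two calibration subtleties the tests respect: (1) each point of the CV
curve is an unbiased error estimate, but the curve *minimum* is
selection-biased low (about 1.3 curve-point standard deviations under a
null), so the permuted-label calibration checks curve means and bounds the
minimum separately; (2) at total shrinkage the posteriors reduce exactly
to the class priors, which the equal-prior symmetry test exploits.

## What the synthetic world does and does not establish

The generator plants: phenotype prevalences (0.30, 0.20, 0.41,
renormalized — the published test-set shares); latent $(R, \theta)$ from
truncated normals (deserts near $R \approx 25$ cells/mm², the others near
220, split by $\theta$ at $\pi/4$; 10% of deserts have exactly zero CD8,
exercising the degenerate flag); densities back-computed as
$(R\cos\theta, R\sin\theta)$ so the polar transform is exactly invertible
on truth; negative-binomial counts (dispersion 0.15; log-uniform library
sizes 0.8–2.5 M) over a gene panel of 2,000 with modules — 300 cytotoxic
genes tracking $R$ on the log2 scale, 150 TGF-β/stromal up and 150
antigen-presentation down only in excluded tumours, 100
metabolic/neuroendocrine genes up only in deserts, 40 housekeeping genes
(high mean, dispersion 0.005, ~15% of the library, so they satisfy the
selection rule they are meant to satisfy), 1,260 noise genes. The log2
effect size defaults to 2 — a strong but realistic immune-signature fold
change. Module sizes were fixed a priori from a structural property of
quantile selection: top-quartile thresholds select a fixed *count* of
genes, so planted modules must be commensurate with those slots for
sensitivity/false-positive criteria to be meaningful at the 2,000-gene
scale (the real study's 16,944-gene panel is ~8× larger).

A green suite therefore establishes: the formulas are implemented as
stated, planted truth is recovered through the *entire* inferential chain
(training labels come from consensus clustering, never from truth — truth
only scores the result), and everything is bit-reproducible under a master
seed. It does *not* establish clinical validity: no batch effects, FFPE
degradation, stain variability, compression artefacts, tumour-purity
variation, or survival endpoints are simulated, and the IHC cartoons
(elliptical nuclei, disk CD8 cells, two clean channels, no colour
deconvolution) isolate the algorithmic content rather than emulate optics.

## Numerical choices and degenerate inputs

* Quantiles everywhere use R's default inclusive linear interpolation
  (type 7), pinned because quantile dialects change set sizes.
* $\theta$ at $(0,0)$: flagged 0, see above; `from_polar` is exact on the
  non-degenerate domain to 1e-9 relative error (tested at $n = 10^4$).
* TMM: genes with a zero in either sample are excluded pair-wise; an
  all-zero overlap raises an error naming the sample; factors of exactly
  identical columns short-circuit to 1.
* Consensus: a pair never co-sampled raises an error advising more
  replicates; an all-ones consensus matrix cannot be cut into $k > 1$
  non-empty clusters and errors.
* NSC: a class with fewer than 2 samples errors; fold counts reduce with
  a warning when the smallest class is smaller than the requested folds;
  constant-gene degeneracy is guarded by $s_0$.
* Model JSON uses 17 significant digits so a serialized model predicts
  bit-identically after reload.
* Forest determinism: all randomness (bootstrap, permutations) draws from
  R's RNG in a single thread, so `set.seed` reproduces importance tables
  exactly; categories are invariant to positive rescaling of a predictor
  because midpoint splits commute with monotone scaling.

## Known limitations

* The ~5% upper bound on noise-gene selection is structural, not
  universal: with a much smaller signal fraction (as in a full
  transcriptome) quantile-based selection would necessarily admit more
  noise genes; the published analysis evidently relied on its larger gene
  panel's importance distribution.
* The 6→3 merge rule is a documented surrogate for a manual step.
* The IHC module reconstructs described logic with invented thresholds;
  it is not a re-implementation of the discontinued original software.
* Survival analysis, enrichment, molecular subtyping and methylation
  analyses of the source study are out of scope.
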