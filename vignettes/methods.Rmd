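---
title: "Measuring phylogenetic signal in binary chemotaxonomic traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetic signal in binary chemotaxonomic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmsignal)
```

## The question and the model

Chemotaxonomic surveys score a compound class (say, alkaloids) as present or
absent in each plant family and ask whether the presences cluster on the
phylogeny — which would suggest conserved biosynthetic machinery — or are
scattered, as expected under repeated independent origins and losses. For a
binary trait, continuous-trait measures (Pagel's λ, Blomberg's K, Moran's I)
do not apply; the D statistic of Fritz & Purvis (2010) does, and `phylo_d()`
implements it from first principles.

The raw statistic is d, the sum of sister-clade differences: tips carry
their 0/1 state, every internal node of a dichotomous tree is assigned the
unweighted mean of its two children, and d adds up |parent − child| over all
edges. D rescales d between the means of two nulls so that it is comparable
across trees and prevalences:

$$D = \frac{d_{obs} - \overline{d}_{Brownian}}{\overline{d}_{random} - \overline{d}_{Brownian}}$$

with D = 1 for a randomly arranged trait, D = 0 for a trait exactly as
clustered as a threshold-Brownian character, D < 0 for extreme clustering,
D > 1 for overdispersion. Each null is an empirical distribution of d:

- **random shuffle**: the observed multiset of tip states is permuted
  uniformly over the tips, so prevalence k is preserved exactly;
- **Brownian threshold**: a continuous liability evolves from the root by
  independent normal increments of variance equal to branch length, and the
  k highest-valued tips are marked present.

Both p-values are one-tailed empirical proportions: `p_random` is the
fraction of shuffle replicates with d at or below the observed value (small
means "more clustered than random"), `p_brownian` the fraction of Brownian
replicates with d at or above it (small means "more dispersed than
Brownian"). No +1 continuity correction is applied by default, so a p of 0
is possible at finite B; `plus_one = TRUE` switches to (r+1)/(B+1).

## Conventions that had to be chosen

The published description of the statistic leaves several details open; we
fixed each one, and the choices are safe because of a structural property:
**self-calibration**. Observed and null replicates run through the *same* d
operator, so any internally consistent convention yields E[D] ≈ 0 under
threshold-Brownian generation and E[D] ≈ 1 under shuffle generation. The
test suite asserts exactly this by simulation, which is the real correctness
surface; the individual conventions are:

- **Nodal estimation**: unweighted mean of the two children, branch lengths
  ignored. d is therefore purely topological; branch lengths enter only the
  Brownian simulation. Trees without branch lengths get unit lengths, with a
  warning, for the Brownian null only.
- **Polytomies**: resolved deterministically before computation
  (`binarize()`), nesting children left-to-right with zero-length internal
  edges. Zero-length edges contribute no Brownian variance, so the
  resolution does not perturb the threshold-Brownian null; root-to-tip path
  lengths are provably unchanged (tested).
- **Brownian root and scale**: root value 0, rate σ² = 1. Thresholding by
  rank makes both irrelevant (location/scale invariance of ranks).
- **Threshold ties**: continuous draws are almost surely tie-free, but
  zero-length pendant edges can create exact ties; these are broken by a
  seeded uniform draw per tip, keeping every replicate deterministic given
  its seed.
- **Degenerate inputs**: constant traits (k = 0 or k = n) are errors, not
  silent zeros; if the two null means coincide to within 1e-9 the
  normalization is refused rather than divided through.
- **Small trees**: the statistic has little power below 25 tips; `phylo_d()`
  warns, and `run_screen()` skips such clades by default (`min_tips = 25`).

## The screen and per-cell seeding

`run_screen()` evaluates every (clade, class) pair: extract the clade's
subtree, binarize, restrict the class column, estimate D. Cells that cannot
be estimated produce machine-readable skip rows (`clade_not_found`,
`min_tips`, `degenerate_prevalence`) rather than aborting the grid. Each
cell's null streams are seeded by a stable 31-bit string hash of
(master seed, clade name, class name), so the full table is bit-for-bit
reproducible and independent of the order in which cells are computed — a
property the tests check by shuffling the clade list.

No multiple-testing correction is applied across the grid, mirroring the
original analysis; the per-cell p-values are reported so any correction can
be applied downstream.

## The subsampling robustness experiment

Observed chemotaxonomic matrices undersample reality: absence often means
"not looked". The robustness experiment quantifies sensitivity to this by
demoting a random subset of present cells to unknown — keeping 50%, 70%,
80% and 95% of observed cases, the published design — and re-running the
screen. Retained counts follow round-half-up with a minimum of one;
subsampling is uniform over all present cells of the matrix (the stated
design does not stratify; a per-class stratified mode is available behind
`stratified = TRUE`). The inner screens reuse the master seed, so at
fraction 1.0 the experiment reproduces the plain screen exactly — an
identity the tests assert bit-for-bit — and reported summaries are the mean
|ΔD| and the significance-flip rate per cell.

## What the synthetic data emulate — and what they do not

`make_synthetic_study()` plays the role of the study's trait matrix and
published tree so the pipeline is fully testable offline.

- **Tree**: a forward pure-birth (Yule) simulation; lineages split at a
  constant rate, giving an ultrametric tree with expected depth
  (H_n − 1)/λ. Real family-level trees are not Yule — they carry extinction,
  rate variation and calibration error — but a Yule tree is the standard
  neutral scaffold for calibrating tree statistics, and nothing downstream
  assumes more than ultrametricity and branch lengths.
- **Regimes**, one per trait column, all honouring an exact prevalence
  contract (k = round(p·n) present tips):
  `brownian_threshold` shares its code path — draw for draw — with the
  Brownian null (a test asserts byte-identical output for equal seeds);
  `random` is a uniform k-subset; `clumped` fills the clade whose size is
  nearest k, trimming or topping up by topological distance with ties broken
  by label order; `overdispersed` places one presence per cherry, spreading
  the chosen cherries evenly across the tree (taking instead the first k
  cherries in traversal order concentrates presences in one region and
  weakens the overdispersion — a pitfall we hit and test against).
- **The "paperlike" preset**: 437 families and eight classes whose column
  sums reproduce the published prevalence counts (flavonoids 245, alkaloids
  221, terpenoids 206, tannins 175, phenolic acids 167, phenylpropanoids
  162, steroids 153, quinones 82) exactly, because the prevalences are
  target counts rather than probabilities. All eight columns use the
  threshold-Brownian regime: it is the only generating model under which
  "some clustering, short of perfect conservatism" — the qualitative
  published finding — arises naturally. The preset does **not** reproduce
  the published D values themselves (those depend on the real matrix and
  real tree), and a green test on synthetic data establishes only that the
  estimator and pipeline behave correctly, not that any biological claim is
  re-derived.

A genuine re-analysis of the original data requires the study's
supplementary matrix and the published family-level calibrated tree, neither
of which can be redistributed here; the acceptance suite contains a
full-reproduction block that activates when those files are placed under
`inst/extdata/`.

## Temporal mapping

`trait_lineages_through_time()` is a deliberately modest surrogate for
"when did carriers of this class diversify": at age t it counts branches
crossing t that lead to at least one present tip (a Dollo-style minimal
mapping). At t = 0 it equals the class prevalence; for an all-present class
it reduces to the plain lineages-through-time curve; it is non-increasing
in t and bounded by the total lineage count (both tested). It is **not** an
ancestral-state reconstruction — it never claims the ancestor possessed the
class, only that its descendants include a carrier — and curves from it
should not be read as reproducing any published diversification figure.
Age conventions: tips at age 0, ages increase rootward; at exactly a node's
age the edge above the node counts as crossing; the root lineage is counted
from the root age upward. Ultrametricity is required within a relative
tolerance of 1e-6 of tree depth, absorbing the rounding noise real
calibrated trees carry.

## Family collapsing

Species-level trees are reduced to one exemplar tip per family
(`collapse_to_families()`): the exemplar is the family's first tip in a
left-to-right depth-first traversal, a deterministic and documented choice
made because no published rule exists. Non-monophyletic families are
collapsed by the same rule with a warning naming them; for analyses at the
family level with family-level traits, which exemplar carries the label has
no effect on the trait values, only on the (slight) branch-length
differences among candidate exemplars.

## Known limitations

- D is estimated by Monte-Carlo; at B = 1000 the standard error of D for a
  437-tip tree is of order 0.01–0.03, so published six-decimal values are
  not reproducible in principle, only to within Monte-Carlo tolerance.
- The screen treats clades independently; nested clades (eudicots inside
  angiosperms) reuse the same data, and no attempt is made to decorrelate
  them — matching the original design.
- `unknown` and `absent` are stored distinctly but analysed identically
  (both 0), the same conflation the source data make; the storage keeps the
  door open for explicit missing-data models later.
- The Yule generator has no extinction and simulates no within-family
  structure; clumped and overdispersed regimes are deterministic given the
  tree, so their replicate-to-replicate variation comes from the null
  estimation alone.
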