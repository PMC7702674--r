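---
title: "Models and design choices in skullconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in skullconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`skullconv` tests whether a fossorial lifestyle drives convergent
evolution of skull-roof microanatomy and macroscopic skull shape in
lepidosaurs. This vignette explains the models behind each stage, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## Trait extraction from cross-section masks

Each specimen contributes eight binary transverse cross-sections (two per
roofing bone — premaxilla, nasal, frontal, parietal — at 1/3 and 2/3 of
the anteroposterior bone length), a table of section positions along the
cranial profile, and three linear skull dimensions (mm).

**Compactness** is the fraction of bone-tissue pixels among all pixels
inside the outer bone limits. "Inside" is defined by morphological hole
filling: background components not connected to the raster border count as
interior cavities (background 4-connectivity, foreground 8-connectivity,
via `EBImage::fillHull`). Compactness is stored as a fraction in [0, 1]
and reported in percent.

**Local thickness** follows the inscribed-disc construction: the thickness
at a pixel is the diameter of the largest disc that contains the pixel and
fits inside the (hole-filled) section. Discretely, the disc at centre q
has radius r(q) equal to the Euclidean distance transform, a pixel p is
covered when |p − q| < r(q), and thickness(p) is the maximum 2·r(q) over
covering centres. This convention reproduces the width of a rasterized bar
and the diameter of a rasterized disc exactly and is within one pixel on
corner-dominated shapes; the painting loop is implemented in C++ since it
is the only pixel-quadratic step. Mean thickness is the average over
foreground pixels times the pixel size.

**Thickness integral.** Absolute thickness is normalized by the skull
diameter to `d_rel` (percent) and integrated over the anterior half of the
cranial profile, `d = ∫₀^0.5 d_rel(s) ds`, with piecewise-linear
interpolation between sections. No section sits exactly at s = 0, so the
default extrapolates the first measured value as a constant back to the
anterior limit; truncating the integral at the first section is available
via `extrapolate = "truncate"`. The two options differ by the small area
`s₁·d_rel(s₁)` and barely affect class contrasts, but the constant
extrapolation respects the integral's stated limits.

**Overlap.** For an anterior bone A and posterior neighbour B,
`ovl = 100(2/3 − 2Δ/(L_A + L_B))` with Δ the *signed* distance from A's
posterior section to B's anterior section measured along the profile
(positive when the sections are in anatomical order). The sign convention
is fixed by two anchor configurations: coincident bone centres give 100%
and exactly abutting bones give 0%. Values are deliberately not clamped —
a gap yields a negative overlap, and strongly nested bones can exceed
100%. When converting normalized profile positions to mm the pipeline
estimates the profile length from the section geometry itself (sections of
one bone are L/3 apart), which is exact for internally consistent tables.

**Log-compactness.** Compactness aggregates between 95 and 100%, so
`c_log = −log₁₀((105 − c)/105)` spreads that interval. The 5% horizontal
dilation avoids an asymptote at 100%; the base (10) is a package constant
— any base is a monotone rescaling of the same axis.

## Lifestyle signal: λ-GLS whitening with RRPP permutations

For each trait the pipeline fits Pagel's λ by maximum likelihood under the
GLS model `trait ~ lifestyle`, profiling the multivariate-normal
likelihood over λ ∈ [0, 1]. λ multiplies the off-diagonal entries of the
Brownian-motion covariance (shared root-to-MRCA path lengths) and leaves
the diagonal untouched — the matrix form is exact for non-ultrametric
trees carrying fossil tips, which is why it is preferred over branch-length
rescaling. Estimates outside [0, 1] are clamped to the boundary and
flagged.

The ANOVA then whitens trait and design with the inverse Cholesky factor
of the λ-covariance and computes the usual F statistic. Significance comes
from residual randomization (RRPP): residuals of the reduced
(intercept-only) model are permuted, added back to the reduced fit, and
the F distribution is rebuilt; `p = (b + 1)/(n_perm + 1)`. Pairwise
contrasts use absolute distances between least-squares means in the
whitened space, with the same permutation scheme and Holm step-down
adjustment. With λ = 0 on a star phylogeny the whole construction
collapses to an ordinary permutation ANOVA (a property the tests check to
1e−8). Only the single-factor and single-covariate designs used by the
analysis are implemented.

## Ancestral lifestyle and clustering

The three lifestyle classes are binarized (fully fossorial vs the rest)
for history reconstruction. The Mk model is fitted by Felsenstein pruning
with bounded optimization; the default flavour is ER (for a binary
character SYM is identical), ARD is available. Stochastic character maps
are drawn exactly: conditional likelihoods upward, joint node states by
stochastic traceback, and branch histories conditioned on their endpoint
states by uniformization (jump chain `R = I + Q/Ω`, jump count sampled
from its conditional law, virtual jumps collapsed). Uniformization was
chosen over rejection sampling for bounded runtime on long branches. The
root prior defaults to the stationary distribution of Q and can be set to
uniform; both options are exposed because the choice is not dictated by
the data.

Branch-wise posterior profiles (default 20 grid points per branch) locate
"acquisition" branches where the posterior for the fully fossorial state
crosses 50%, and fully fossorial tips are grouped by their nearest
acquiring ancestor into disjoint focal clades. The Retention Index
`(g − s)/(g − m)` (Fitch steps s, minimum m = k − 1, maximum
g = n − max state frequency) and a two-block PLS between principal
coordinates of the patristic distance matrix (components covering 95% of
the positive eigenvalue mass) and one-hot lifestyle indicators quantify
phylogenetic clustering of the character. The PLS block construction is an
interpretation (only the method name is fixed by convention); both the
coordinate cutoff and the blocks are arguments.

## Convergence indices

**C1.** For every between-clade pair of focal tips,
`C1 = 1 − D_tip/D_max`: `D_tip` is the trait distance between the tips and
`D_max` the largest distance between any two of their ancestors, each
lineage traced from the tip back to and including the pair's MRCA (the
tips themselves included). Ancestral states come from maximum-likelihood
(joint GLS) reconstruction under Brownian motion, computed as a
precomputed linear operator on tip values so that simulation nulls reduce
to matrix products. Within-clade pairs are excluded from the average —
members of one fossorial clade share their history and are not independent
convergence events. C1 is invariant to affine trait rescaling.

**C5** counts lineages entering the focal morphospace: the closed interval
spanned by the focal tips (univariate) or the minimum-area enclosing
ellipse of the focal points (bivariate; Khachiyan's algorithm, with a 95%
covariance ellipse as an alternative and a padded bounding ellipse as the
degenerate fallback). Each branch is a linear segment between its
endpoint states; a branch counts once when its parent-side value lies
outside the region and the segment reaches it (pass-throughs count — the
lineage did enter), and a root inside the region counts as one entry at
the origin of the walk. These two conventions are documented choices where
the framework is silent.

**Significance.** The null estimates the BM rate σ² from the observed
trait by ML, simulates `n_sim` datasets on the same tree, re-derives
ancestral states and (for C5) the region per dataset, and reports
`p = (count ≥ observed + 1)/(n_sim + 1)`. C1 and C5 reuse one seed stream
so the two p-values are coupled reproducibly. Full-study defaults are
10,000 permutations, 10,000 maps and 30,000 simulations; reduced runs are
labelled in the report. Note that C5's p-values are lattice-valued (the
statistic is an integer count): they are valid but discrete, which matters
when checking calibration (see below).

## The synthetic-study generator

The generator plants a known truth at the scale of the empirical study:
99 tips on a pure-birth tree (birth rate 0.1/My, depth ≈ 45 My), a
three-state lifestyle (non/semi/fully fossorial) evolving under an Mk
process in which entry into the fully fossorial state is rare and nearly
irreversible — so acquisitions form a few deep clades — and per-trait
Ornstein–Uhlenbeck dynamics whose optimum switches with the lifestyle
regime active at that point of the branch. OU segments use the exact
Gaussian transition (not an Euler discretization), so α = 0 reduces to
Brownian motion exactly. Defaults: α = 0.5 per My (adaptation half-life
1.4 My, i.e. strong pull), fully fossorial optima c = 96%, d = 3.5%,
ovl = 60%, rfp = 0.7, elo = 3.0, dia = 5 mm against non-fossorial
80/2.2/35/1.2/2.1/9 with semi-fossorial intermediate, within-regime
stationary deviations of roughly 1–5% of the trait scale, plus one neutral
BM control trait carrying no lifestyle structure. Because a single Mk draw
on a random 99-tip tree frequently yields too few fossorial tips to embody
the planted design, lifestyle histories are redrawn (sub-seeded, hence
reproducible) until at least 3 independent acquisition clades and 10–45
fully fossorial tips are realized; this conditioning is part of the study
design, not of the inference.

Masks are solid bars whose pixel height encodes the planted thickness and
whose cavities are sampled from the eroded interior, so realized
compactness is exact bookkeeping and cavities can never touch the outer
boundary. Specimen tables (section positions, bone lengths, skull
dimensions) are constructed by inverting the trait definitions, so the
measurement stage recovers the planted `ovl`, `rfp`, `elo` and `dia`
exactly and `c` and `d` to within raster discretization (< 0.1% and < 2%
respectively).

What the generator does *not* emulate: real cross-section geometry
(bars instead of curved bone profiles), segmentation noise and thresholding
artefacts, fossil (non-ultrametric) tips, measurement error in section
placement, and correlated trait evolution beyond the shared lifestyle
regime. Passing the end-to-end tests therefore demonstrates that the
chain of estimators recovers a planted signal of realistic shape and size
— not that any particular empirical dataset will behave as cleanly.

## Numerical choices and degenerate inputs

- GLS likelihoods use Cholesky whitening; λ optimization is bounded 1-D
  (`optimize`, tol 1e−6), with boundary clamping detected by comparing
  boundary and near-boundary likelihoods.
- The ancestral-state operator solves the edge-weighted Laplacian system;
  zero-length branches receive a 1e−9 floor (hard polytomies behave as
  zero-variance steps). A constant trait makes C1 undefined (D_max = 0)
  and is rejected explicitly.
- Mk transition probabilities use the ER closed form when all off-diagonal
  rates are equal and an eigendecomposition otherwise; per-tree likelihood
  evaluations cache one matrix per unique branch length. Pruning rescales
  partials to avoid underflow.
- Uniformization caps the jump count at the 1 − 1e−12 Poisson quantile;
  an endpoint pair of zero probability (impossible under a fitted model)
  raises an error rather than looping.
- The minimum enclosing ellipse runs Khachiyan updates to a 1e−7
  simplex tolerance, then rescales so every focal point satisfies the
  quadratic form at 1 — containment is guaranteed despite finite
  iteration. Fewer than 3 non-collinear focal points trigger the padded
  bounding-ellipse fallback, flagged in the result.
- All permutation and simulation p-values use `(b + 1)/(n + 1)` with ties
  counted by `≥`, so p is never 0 and tests remain valid at any count.

## Validation design and known limitations

The test suite checks every computational core against an independent
oracle on small instances: hole-fill/thickness against per-pixel
brute-force disc coverage, the BM covariance against the patristic
identity `V_ij = (depth_i + depth_j − d_ij)/2`, pruning likelihoods and
Fitch steps against exhaustive enumeration, ancestral states against the
closed-form GLS expression through the full node covariance, C1/C5 against
explicit ancestor-pair and branch-walk oracles, simmap change counts
against rejection sampling, and λ against an independent GLS
implementation. Statistical calibration is checked on the scales the
budget allows (hundreds of null datasets with hundreds of permutations
each, rather than full-study counts); the calibration of C5's discrete
p-values is assessed through the standard randomized-p construction,
because raw lattice-valued p-values cannot be uniform on a continuum.

Limitations worth keeping in mind: the RRPP implementation covers only the
single-factor and single-covariate designs; C2–C4 and multivariate C1 are
out of scope; local thickness is 2-D per section, not a 3-D volume
measure; and with very few focal tips the C5 region degenerates and the
index loses discrimination — the package flags but cannot repair that.
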