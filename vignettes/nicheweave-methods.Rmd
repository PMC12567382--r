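---
title: "Methods: climate-gradient analysis of tick–host niche networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-gradient analysis of tick-host niche networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nicheweave` estimates how much of a tick's host spectrum is explained
by shared climate. The unit of analysis is the ecosystem: within each
ecosystem class, every tick and every host genus gets a realized
climatic niche, niches are compared pairwise, and the resulting
overlap-weighted bipartite networks are scored for structure. This
vignette records the models, the parameters that matter, the numerical
choices, and what the synthetic data generator does and does not
emulate.

## Climate predictors

Each climate variable (maximum temperature and minimum temperature in
°C, vapour pressure deficit in kPa) enters as a 12-value monthly
climatology per grid cell. `fit_harmonics()` fits the single annual
harmonic

$$y_m = a_0 + a_1\cos(2\pi m/12) + b_1\sin(2\pi m/12), \quad m = 1,\dots,12,$$

by least squares. Months sit at integer positions 1–12, so the basis is
exactly orthogonal over the year and the coefficients have closed
forms: $a_0$ is the monthly mean, $a_1 = \tfrac{1}{6}\sum y_m \cos$,
$b_1 = \tfrac{1}{6}\sum y_m \sin$. Three coefficients per variable give
the nine predictors used everywhere downstream. We deliberately stop at
the first harmonic: it is the minimal seasonal model yielding exactly
three coefficients per variable, and the annual cycle dominates the
within-year variance of all three variables. Because the basis is
orthogonal and the monthly design is balanced, fitting one regression
on the multi-year climatology is algebraically identical to averaging
per-year fits; we fit on the climatology. The integer month convention
makes two properties exact, and tested: adding a constant shifts only
$a_0$, and circularly shifting the series by $k$ months rotates
$(a_1, b_1)$ by $2\pi k/12$ while preserving the amplitude.

Cells with any missing monthly value are masked out of all nine layers
rather than imputed.

## Distribution models

Presence-only records are converted to a balanced classification
problem: one pseudo-absence cell per presence record, drawn uniformly
and without replacement from the cells holding no presence of that
taxon. Records are split 70/30 into training and test strata per label
(`train_fraction = 0.7`).

Three learners sit behind one contract — a fitted object mapping a
9-vector of predictors to a score in [0, 1]:

* `smooth_additive` — penalised additive logistic regression
  (`mgcv::gam`, thin-plate smooths with basis size `gam_k = 4`,
  convergence tolerance `1e-8`, up to 500 iterations);
* `adaptive_hinge` — lasso-penalised logistic regression on a basis of
  hinge functions `max(0, x - knot)` / `max(0, knot - x)` at three
  quantile knots per predictor, with the penalty chosen by 3-fold
  cross-validation (`glmnet`) — an adaptively selected
  piecewise-linear model;
* `kernel_margin` — radial-kernel support-vector machine (`e1071`)
  whose decision values are recalibrated to probability scale by a
  univariate logistic regression.

No claim is made that these reproduce any other implementation
coefficient-for-coefficient; the contract is validated by virtual-taxon
recovery instead (below). Members reaching Cohen's κ ≥ 0.4 on the
held-out test records (the conventional "moderate agreement" floor;
`retain_kappa`) enter the ensemble with weights proportional to κ. The
continuous ensemble surface is binarised at the threshold maximising
TSS = sensitivity + specificity − 1 over the midpoints of consecutive
sorted unique test scores, ties broken toward the lower threshold —
a prevalence-robust rule for presence/absence maps. Degenerate inputs
fail loudly: single-label training data, all-equal test scores, and
fully constant predictors are errors, not silent defaults.

*Abiotic suitability* of ecosystem $e$ for a tick is
$100 \times$ the mean continuous ensemble suitability over the cells of
$e$; values below 20 % are conventionally read as insufficient for
population persistence.

## Niche hulls and overlap

A single PCA (centred, unit variance) is fitted to the predictor table
of **all** grid cells, because cross-taxon overlap is only meaningful in
one shared space; taxa are projected into it. Axis signs follow the
convention that each axis's largest-magnitude loading is positive. Two
axes are kept for hull construction: a convex polygon is a planar
object, and overlap in more dimensions would require hypervolume
intersection, which is out of scope (`k_pcs` is configurable for the
PCA itself).

A taxon's niche in an ecosystem is the convex hull of the projected
predictor vectors of the cells that are predicted present *and* inside
the ecosystem. A switch to raw occupied occurrence cells is provided
(`occurrence_niche_points()`), since both conventions are in use.
Hulls with fewer than three distinct, non-collinear points are
*degenerate*: they score 0 overlap against any defined hull (an
unresolvable niche cannot share area), while a taxon with *no*
qualifying cell yields an undefined (`NA`) matrix cell that is excluded
from row means. Overlap is the Jaccard percentage
$100\,A_\cap/(A_1 + A_2 - A_\cap)$, with the intersection area from
Sutherland–Hodgman convex clipping (tolerance $10^{-12}$ on the
half-plane tests). *Biotic suitability* of a tick in an ecosystem is
the mean of its defined row entries.

Convex hulls are outlier-sensitive, so `trimmed_convex_hull()` can drop
points above the 97.5th percentile of squared Mahalanobis distance
before hull construction; trimming is off in the main pipeline and on
in the recovery experiment, where its population analogue is needed
(below).

## Host phylogenetics

Faith's PD of a tick's host set is the sum of branch lengths of the
spanning subtree rooted at the subset's most recent common ancestor;
the MRCA-to-root path is excluded by default so that PD is a pure
among-host diversity (single host → PD 0, PD monotone under adding
hosts). An `include_root = TRUE` switch covers the other convention.
The host set per tick × ecosystem comprises the hosts with defined
overlap cells in that ecosystem's matrix.

Pagel's λ scales the off-diagonal phylogenetic covariance (diagonal
preserved). The likelihood profiles the ancestral mean and Brownian
rate analytically, leaving a 1-D bounded maximisation over λ ∈ [0, 1]
(golden-section-based, tolerance `1e-6`, boundary values checked
explicitly). Constant traits and star trees are flagged as undefined
rather than forced to a number. λ is a phylogenetic-*signal* parameter;
it is reported alongside Faith's PD (computed on the tick's host
overlap profile by default in the pipeline) because both readings of
"phylogenetic diversity per region" occur in practice, and the choice
between them is left visible to the user rather than hidden.

## Networks and significance

Each ecosystem's overlap matrix becomes a directed tick→host network
with an edge wherever the defined overlap exceeds `edge_threshold`
(default 0) and the overlap as weight. Nestedness is reported twice:
binary NODF (paired-overlap of decreasing fills; equal fills contribute
zero; matrix pre-sorted, so the score is permutation-invariant) and a
weighted NODF in which a sparser line's cell qualifies only when it is
nonzero and *strictly smaller* than the denser line's weight — uniform
weights therefore score 0. On an all-connected network the binary
version is degenerate by construction (all fills equal), which is why
the weighted variant carries the directional comparisons.

Barber's bipartite modularity
$Q = \tfrac{1}{m}\sum_{ij}(A_{ij} - k_i d_j/m)\,\delta(g_i, h_j)$ is
maximised by greedy label moves over rows and columns in fixed order
(lowest label wins ties), restarted from one deterministic and
`n_restarts` seeded random initialisations — reproducibility is
preferred over global optimality, and the label-move optimum matches
exhaustive partition search on all ≤ 8-node test networks.

Significance of a network score uses a proportional null model: cell
fill probabilities $p_{ij} = (r_i/C + c_j/R)/2$ from the observed
margins, metric recomputed on each null draw, upper-tail p with the
add-one correction (p is never 0). For weighted metrics the observed
positive weights are resampled onto the null-filled cells. When the
generating probabilities are known (calibration studies), they can be
supplied directly; estimating them from each draw is conservative. A
true Mantel test (Pearson correlation of upper triangles, simultaneous
row/column permutation, two-sided by default, exhaustive enumeration
available for small n) is provided for matrix-vs-matrix questions. A
null-model z/p for a nestedness scalar and a Mantel test answer
different questions; both tools are exposed and labelled, and the
pipeline reports the null-model p for nestedness.

## Ordination

Each (tick, ecosystem) item carries its profile of Jaccard overlaps
over the union host set (undefined → 0; ticks absent from an ecosystem
drop out). The dissimilarity between items is the root-mean-square
difference of profiles, which is bounded on [0, 100] and maps identical
profiles to 0 and fully antipodal ones to 100. The literal reciprocal
transform `100/(1 + v)` is available as `distance_mode = "reciprocal"`,
but the complement-style distance is the default because the reciprocal
explodes as overlap approaches 0. Non-metric MDS (Kruskal stress-1 via
monotone regression) runs from a classical-scaling start plus seeded
random restarts (`nmds_starts = 8`, 300 iterations, stress floor
`1e-7`); stress below 0.05 (strict) is read as a reliable reduction. A
permutation test on mean between- minus within-ecosystem distance
(`group_separation_test()`, 999 permutations by default) asks whether
profiles are structured by ecosystem; it is this package's own generic
construction, not a reproduction of any published test.

## The synthetic generator

The generator emulates the study system with known truth:

* **Climate** — per-band harmonic triples per variable along a
  latitudinal gradient (defaults: a warm south band and a cold north
  band), plus a linear west–east "continentality" tilt on $a_0$;
  without the second gradient the predictor cloud collapses onto a
  curve and every niche hull would be degenerate. Additive i.i.d.
  Gaussian monthly noise defaults to 5 % of the mean seasonal
  amplitude — small enough that harmonic recovery is testable against
  closed-form standard errors ($\mathrm{SE}(a_0) = \sigma/\sqrt{12}$,
  $\mathrm{SE}(a_1) = \mathrm{SE}(b_1) = \sigma/\sqrt 6$).
* **Taxa** — Gaussian (bell-shaped) suitability
  $s(x) = p_{\max}\exp(-\tfrac12 d_M^2(x))$ with niche centers anchored
  at the predictor vectors of real grid cells (so niches lie on the
  realized climate manifold) and diagonal breadths proportional to the
  per-predictor spatial s.d. (`breadth_scale`, default 0.6 in the
  pipeline, 0.4 in the recovery experiment). The `"nested"` community
  places concentric host niches of geometrically growing breadth and
  progressively displaced ticks, making host ranges nested subsets by
  construction — the "extreme ecosystem" used in directional
  nestedness checks.
* **Occurrences** — cells drawn with replacement proportional to true
  suitability (repeat draws emulate repeated records at a locality).
* **Truth** — `true_pairwise_overlap` is the cell-set Jaccard between
  level sets of prevalence-normalised suitability at
  `level_set_tau = 0.05`: exactly 100 for identical (center, breadth),
  strictly decreasing in center separation, and independent of the
  hull machinery it validates.
* **Phylogeny/traits** — Yule trees via `ape`, tip traits multivariate
  normal with λ-scaled Brownian covariance.

What it does **not** emulate: real geography or projections, spatial
autocorrelation in sampling effort, observation bias, temporal
dynamics, or biotic interactions in the sampling process. Passing
recovery tests therefore demonstrates correctness of the estimators
under the stated generative model, not robustness to the biases of
real occurrence data.

## The overlap-recovery experiment

`overlap_recovery_experiment()` sweeps a virtual host's niche center
away from a virtual tick's (six separations, 0.07–0.42 predictor s.d.,
shared diagonal breadth 0.4 s.d.) on a 30 × 30 grid, pools eight seeded
samples of 500 records per taxon, and estimates overlap with trimmed
occurrence hulls in the common PCA plane. Choosing the comparison
target needs care: the raw hull of occupied cells is not a consistent
estimator of any fixed level set (its extent grows with sample size and
grid resolution), and cell-set Jaccard and hull-area Jaccard differ by
construction (hulls convexify). The estimator's exact population
analogue is `true_trimmed_hull()`: the suitability-weighted Mahalanobis
level set retaining the same 97.5 % mass that trimming retains — the
true-suitability level set at the same presence threshold. Against this
target the estimate is nearly unbiased, declines strictly with
separation, and stays within the ±10-point recovery band across seeds;
pooling replicates (rather than averaging per-replicate hulls) is what
removes the finite-sample hull-shrinkage bias.

## Reproducibility and problem sizes

One global seed expands to per-stage child seeds through the fixed rule
in `child_seed()` (`(seed · 1009 + offset) mod 2^31 − 1`, one documented
offset per stage), so any stage can be re-run in isolation. Identical
seeds give bit-identical climate grids, occurrence sets, model fits,
null distributions and reports; the pipeline's determinism is asserted
by running it twice in the test suite.

The shipped experiments use deliberately modest sizes — grids of
25–50 cells a side, 100–500 records per taxon, 99–199 null replicates
and permutations in the pipeline defaults, 500 simulations in the
type-I calibration — chosen so the full suite and the acceptance script
each run in minutes on a single core while keeping every tolerance
testable (Monte-Carlo standard errors are propagated into the
assertions). All sizes are parameters; nothing in the implementation
assumes them.

## Known limitations

* Hull-based niches ignore density within the hull; two taxa sharing a
  boundary region count as overlapping even if their cores differ.
  Kernel-density niche estimates are out of scope.
* Overlap is computed in two PCA dimensions; structure in higher
  components is invisible to the hulls.
* The learners are standard, not exhaustive: no spatial
  cross-validation, bias correction, or variable selection.
* The proportional null model conditions on observed margins only
  probabilistically; exact fixed-margin null spaces (swap algorithms)
  are not implemented.
* The Mantel test answers matrix-correlation questions; the
  significance of a single nestedness scalar is a null-model question,
  and the package keeps the two separate.
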