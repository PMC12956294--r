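---
title: "Estimating overlapping dynamic connectivity states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating overlapping dynamic connectivity states: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cddfip)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the synthetic-data tests do and
do not establish.

## The model

The pipeline assumes that a subject's demeaned windowed functional network
connectivity (FNC) — the `W x P` matrix of sliding-window Pearson
correlations among `M` network timecourses, `P = M(M-1)/2` unique pairs,
with each pair's temporal mean removed — is approximately a linear mixture
of a small number of *overlapping* connectivity states:

$$Y \approx A\,S, \qquad S \in \mathbb{R}^{K \times P},\; A \in \mathbb{R}^{W \times K},$$

where the rows of $S$ are connectivity templates (symmetric `M x M`
patterns, vectorized) and the columns of $A$ are their amplitude
timecourses. Unlike hard-clustering dFNC, several states can be active in
the same window; unlike plain group decompositions, $S$ is re-estimated per
subject under a closeness constraint to the group templates, and a final
calibration step restores the correlation units that ICA scaling destroys.

### Two-stage estimation

**Stage 1 (group).** All subjects' demeaned windows are stacked and the
group states are extracted by blind ICA: PCA-whitening of the stacked
matrix to `K` dimensions (thin SVD), then a symmetric fixed-point iteration
maximizing non-Gaussianity with the log-cosh contrast. We orient the ICA so
the *states* are the independent sources over the `P` connectivity features
(the spatial-ICA analogue); the mixing then lives over windows, which is
what "overlapping states with timecourses" means operationally. The
algorithm choice (symmetric fixed-point, log-cosh) is ours: it is
deterministic given a seed and has essentially no tuning knobs. Iteration
stops when the maximum row-angle change drops below `1e-6` or after 1000
sweeps; on noisy data the symmetric update can settle into a slow rotation
of a weakly non-Gaussian subspace, in which case the most stable rotation
encountered is kept and a warning is raised — the affected components are
exactly the ones whose orientation the data barely constrains. Each state
is normalized to unit L2 norm with its largest-magnitude element made
positive, fixing the sign/scale indeterminacy.

`K` can be fixed (15 is the conventional choice at full imaging scale, with
53 networks) or selected by the scree-elbow rule: the `k` whose cumulative
explained-variance point lies farthest (perpendicular chord distance) from
the line joining the curve's endpoints. Ties — including the degenerate
flat-curve case — resolve to the smallest `k`.

**Stage 2 (subject).** For each subject, dual regression initializes the
decomposition (timecourses = least-squares projection of the data on the
group states; subject states = least-squares projection on those
timecourses). With `refine_iters > 0`, each subject state then receives
fixed-point non-Gaussianity updates in the subject's own whitened feature
space; after every update the state is blended convexly toward its group
prior with the *minimal* weight that restores
$\mathrm{cor}(s_k, b_k) \ge \rho$. This correlation-threshold blend was
chosen over an augmented-Lagrangian constrained ICA because it is simple,
monotone in the constraint, and degenerates gracefully: `refine_iters = 0`
is plain dual regression, and `rho = 1` returns the priors themselves.
States stay matched to the basis by index, so no permutation matching is
ever needed downstream. Defaults `rho = 0.8`, 10 iterations.

### Calibration

ICA output is scale-free, but the dynamics metrics below compare amplitudes
across subjects, so units matter. The calibration regresses the subject's
entire dynamic profile (the flattened `W x P` demeaned FNC) jointly onto
the `K` predictors $R_k = a_k s_k^{\top}$ (timecourse `k` outer
subject-state `k`), one ordinary least squares fit for
$\beta \in \mathbb{R}^K$. Before the fit, states are unit-norm and
timecourses are standardized to zero mean and unit variance, so the betas
carry *all* of the scale; the calibrated mixing matrix is
$X = A\,\mathrm{diag}(\beta)$. In the noiseless case
$\sum_k \beta_k R_k$ reproduces the demeaned windows exactly, and adding
back the stored static FNC reproduces the raw windowed correlations — the
sense in which calibration is unit-preserving. Joint (rather than
per-state) OLS is our choice where the alternative was open; betas may be
negative, which simply records a sign flip of that state's expression in
the subject and is kept, not rectified. Near-collinear predictors
(condition number above `1e10`) fall back to the minimum-norm solution with
a warning.

## Dynamics metrics

All metrics operate on the calibrated mixing matrix `X` (`T` windows x `N`
states), because calibration is what makes amplitudes comparable across
subjects.

* **Occupancy.** Dominant state
  $C(t) = \arg\max_i |x_i(t)| / \sum_j |x_j(t)|$; since the denominator is
  common and positive this is the argmax of $|x_i(t)|$ (a property the test
  suite verifies on random matrices). Ties break to the lowest index.
  Counts convert to percentages that sum to exactly 100.
* **Convergence/divergence.** Pairwise distance
  $d_{ij}(t) = |x_i(t) - x_j(t)|$. The distance operands are the *scalar*
  amplitudes of the two states at the window — of the two readings the
  source equations admit, the scalar one is the only one that yields a
  per-pair `N x N` classification. A pair is converged at `t` when
  $d \le \epsilon$ and diverged when $d \ge \theta$; the band in between is
  deliberately unclassified, so the two per-pair fractions sum to at most
  1. No universal values of $\epsilon, \theta$ exist; the default takes the
  25th and 75th percentiles of the distances pooled across the cohort's
  subjects, windows, and pairs, which anchors the bands to the cohort's own
  dispersion. A degenerate pool (all distances equal) is an error, not a
  silent guess.
* **State dispersion profile.** The normalized histogram of all pooled
  pairwise distances of one subject, on bin edges shared across the cohort
  (default 50 equal-width bins spanning the pooled range) so group curves
  are directly comparable; out-of-range values are clipped into the end
  bins with a warning.
* **Dynamic state density.** A state is "strong" at `t` when
  $|x_i(t)| > thr$, strictly; `thr = 0.06` is the conventional default on
  the calibrated scale and is configurable. The per-window count
  $S_t \in \{0..N\}$ is summarized as a histogram over exactly those
  integers, normalized by `T`; group summaries are plain means of the
  per-subject histograms, which remain normalized by linearity.

## Group statistics

Cellwise two-sample t-tests compare the groups feature by feature
(pooled-variance Student form by default; Welch is a switch —
the sources that motivated this design say only "two-sample t-tests", and
pooled variance is the stricter reading of that phrase). Each comparison
matrix forms one Benjamini–Hochberg family over its unique upper-triangle
cells (per-matrix, not global, correction — matching how such matrices are
usually reported figure by figure). The rejection boundary is the step-up
rule's inclusive one, `q <= level`. Significance maps are
$-\log_{10}(p)\cdot\mathrm{sign}(t)$ with `p` floored at `1e-300`.
Zero-variance features are reported as `t = 0, p = 1` with a warning — they
occur legitimately, e.g. in empty density bins. Covariates (age, sex, site)
are regressed out of every derived feature across the cohort before
testing when present; residualization is idempotent and leaves the features
orthogonal to the design. Density histograms are additionally clustered
with Euclidean k-means (`stats::kmeans`, best of `restarts` random starts
under a fixed seed; default `k = 3`).

## The synthetic-data generator

The generator defines the conditions under which the pipeline's claims are
tested.

* **States** are block-structured: networks are partitioned into
  communities, each state loads on its own community-pair block with
  random-sign unit loadings plus dense Gaussian jitter (sd 0.1), then
  unit-normalized. Random signs keep every state zero-mean over features —
  without this, mutually exclusive all-positive blocks share a baseline and
  are *negatively dependent*, which no ICA can fully separate; with it, the
  states are sparse, near-orthogonal, and identifiable. Candidates are
  redrawn until all pairwise |correlations| are at most 0.3.
* **Windowed-FNC subjects** follow `Y = A S_subj + E`. Subject states are
  the ground truth plus a perturbation whose per-entry sd is
  `perturb_sd / sqrt(P)`, making `perturb_sd` the expected L2 distortion of
  a unit-norm state (so `perturb_sd = 0.2` means a state about 0.98
  correlated with the group truth). Mixing timecourses are moving-average
  filtered white noise (span `ceiling(W/10)`, minimum 2), standardized,
  matching the temporal autocorrelation a sliding window induces; the
  per-state amplitude profile is fixed and shared across subjects (unit
  scale by default) so that between-subject amplitude variance reflects
  dynamics and planted effects rather than arbitrary per-subject gain.
  Noise variance is `var(signal)/snr`, so the residual share of total
  variance is `1/(1+snr)`.
* **Timecourse subjects** are sampled from a slowly drifting covariance
  `C(t) = repair(I + sum_k a_k(t) devec(s_k))`, where `repair` shrinks
  toward the identity until the smallest eigenvalue reaches `1e-6` and
  rescales to a correlation matrix. This drifting-covariance process is our
  stand-in for a generative model the overlapping-state literature leaves
  unspecified; it exists to exercise the windowing stage end to end, and
  the stored ground truth (window-averaged `a_k`) is approximate by
  construction.
* **Cohorts** draw two labeled groups from one root seed with a
  deterministic per-subject split (bit-identical regeneration). Planted
  effects act on the patient group's mixing: an amplitude-variance shift
  multiplies the affected states' amplitudes by `sqrt(1 + magnitude)`
  (+50% variance at the default magnitude 0.5), an occupancy bias or
  density shift scales amplitudes by `1 + magnitude`. Covariates are
  independent draws, which keeps residualization testable under the null.

**What passing tests show — and don't.** The generator produces smooth,
low-rank, linearly mixed windows with Gaussian noise. Real windowed FNC has
bounded correlations, window-to-window dependence from overlapping windows,
motion and scanner artifacts, and states that need not be linearly mixed or
independent. Recovery numbers (e.g. mean matched |correlation| ≥ 0.95 at
`K = 5, M = 20, W = 100, snr = 5`) therefore validate the *estimator
chain*, not performance on any real dataset.

## Numerical choices and problem sizes

* Window-length conversion rounds seconds/TR to the nearest integer with
  exact halves rounded down (45 s at TR 2 s → 22 TRs).
* "Demeaning" is implemented as removing each pair's temporal mean (the
  subject's static FNC), not centering each window's matrix spatially; the
  stored mean makes the operation exactly invertible, and the
  reconstruction identity is tested.
* Windows with a constant column get their affected correlations set to 0
  with a warning, keeping the decomposition well-posed instead of
  propagating `NaN`.
* Indexing is 0-based half-open in the window definition; R surfaces use
  1-based state indices.
* The test suite and acceptance script run at reduced problem sizes chosen
  to make their statistical targets well-powered while staying quick on a
  single CPU: cohorts of 10–20 subjects per group with `K = 5, M = 20,
  W = 100`; 200-replicate null studies for error-rate checks; 100 simulated
  cohorts for planted-effect detection, tested one-sided on the divergence
  of the pairs involving the shifted state (the pairs that carry the
  planted signal — averaging over all pairs dilutes it roughly 2.5-fold at
  `K = 5`).
* Under a global null, the Benjamini–Hochberg procedure's expected
  false-discovery proportion equals the nominal level exactly (for
  independent continuous p-values), so empirical means over finitely many
  replicates scatter symmetrically around it; the suite's FDR check
  therefore allows the Monte Carlo standard error rather than demanding
  the empirical mean fall below the level, which a correct implementation
  would fail about half the time.

## Known limitations

* No tapered or adaptive windows, no time-frequency connectivity, no
  Fisher z-transform.
* The constrained refinement is a projection heuristic, not a constrained
  optimization with convergence guarantees; its value is tested empirically
  (it improves subject-state recovery over the group basis under
  perturbation).
* No transition/dwell-time Markov statistics, meta-state analyses,
  permutation tests, or site-harmonization models.
* Group comparisons assume independent subjects and (by default) equal
  variances; Welch's correction is available but mixed-effects structure is
  out of scope.
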