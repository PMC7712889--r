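---
title: "Reoccurring neural states at rest: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reoccurring neural states at rest: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostates)
```

## The problem

During wakeful rest the brain moves through temporally reoccurring patterns
of network activity. `neurostates` implements a complete analysis chain for
relating those patterns to self-reported experience: it segments
parcel-level resting-state BOLD time series into discrete states with a
hidden Markov model (HMM), summarises each subject's state dynamics as
dwell-times, fractional occupancies and switching rates, relates dwell-times
to rotated principal components of retrospective thought reports and
well-being questionnaires through a multivariate analysis of covariance, and
places the state activity maps in a three-dimensional space of cortical
connectivity gradients, calibrated against a permutation null.

Because the kind of dataset this analysis targets (resting fMRI with
end-of-scan experience sampling) is rarely publicly shareable, the package
ships a first-class synthetic-data module. Every downstream stage is
developed and tested against data whose generating process — and therefore
whose ground truth — is known exactly.

## The observation model

The concatenated group matrix stacks every retained subject's standardised
parcel time series: with $N$ subjects, $T$ volumes and $P$ parcels it is an
$(N \times T) \times P$ matrix (at the default geometry,
$(256 \times 180) \times 17$). Each hidden state $s$ is a multivariate
Gaussian over parcels with mean map $\mu_s$ and covariance $\Sigma_s$, and a
$K \times K$ row-stochastic matrix governs transitions between states.
Inference is at the group level: one set of $(\mu_s, \Sigma_s)$ and one
transition matrix are shared by all subjects, while the state time courses
are decoded per subject (the forward–backward recursions restart at each
subject boundary).

Parameters are estimated by expectation–maximisation (Baum–Welch) with
full-covariance Gaussians. The EM objective — the total log-likelihood — is
monotone over iterations, which makes the multi-restart protocol testable:
`fitGroupHmm()` runs `nRuns` independently initialised fits (k-means
centroids plus a seeded random perturbation) and keeps the run with the best
final objective, reporting every run's objective for stability inspection.
This mirrors the standard practice of running a sensitive unsupervised
inference several times and keeping the best solution; with well-separated
states all restarts agree (matched mean-map correlations above 0.99 in the
test suite).

Hard state assignment uses Viterbi decoding in log space. Ties are broken
toward the lowest state index so decoded paths are deterministic even for
exactly symmetric states.

### Dynamics summaries

From each subject's Viterbi path, `computeStateMetrics()` derives:

* **mean dwell-time** (TRs): the mean length of maximal runs of a state;
  truncated runs at the start or end of a scan count as visits, and a state
  a subject never enters is flagged missing (`NA`);
* **fractional occupancy**: the proportion of volumes in each state (rows
  sum to 1 exactly);
* **switching rate**: state changes per transition opportunity,
  $\#\{t: s_t \neq s_{t+1}\}/(T-1)$.

Before entering any regression, dwell-times are z-scored per state across
subjects and values beyond 2.5 standard deviations are substituted with the
mean (0). Never-visited states are mean-imputed first, which lands them at
0 after standardisation — the same substitution the outlier rule applies, so
one convention covers both cases.

## Experience reports and their decomposition

The 25 Likert items (1–4) are decomposed with `pcaVarimax()`:
correlation-matrix PCA (items standardised, since Likert items share no
natural scale), retention by the Kaiser criterion (eigenvalue strictly
greater than 1), varimax rotation of the retained loadings with Kaiser
row-normalisation, and least-squares component scores. The strict inequality
carries a `1e-8` floating-point guard so that an exactly uncorrelated item
set (all eigenvalues 1 up to rounding) retains nothing and raises an error
rather than retaining rounding noise. Each component is sign-flipped so its
largest-magnitude loading is positive. Well-being questionnaires go through
the identical operation.

Orthogonal rotation preserves communalities (tested to `1e-8`). One caveat
worth stating: least-squares scores of *rotated* components are exactly
uncorrelated only when the rotated components' variances are equal (as in a
balanced block structure); on general data small score correlations appear.
The test suite checks exact uncorrelatedness where it holds exactly and
leaves it at that.

## Dwell-times and experience: the MANCOVA

`fitMancova()` fits an ordinary least-squares multivariate regression of the
component scores on a design containing the intercept, the $K$ standardised
dwell-times and covariates of no interest (mean framewise displacement, age,
gender; motion and age z-scored, gender binary). Each dwell-time is tested
as a single-degree-of-freedom multivariate contrast with all other columns
retained:

$$\Lambda = \frac{\det E}{\det(E + H)},$$

with $E$ the residual SSCP matrix and $H$ the hypothesis SSCP of that
coefficient row. For single-df hypotheses the F transform
$F = \frac{1-\Lambda}{\Lambda}\cdot\frac{df_2}{df_1}$ with $df_1 = p$ and
$df_2 = n - \mathrm{rank}(X) - p + 1$ is exact, and partial
$\eta^2 = 1 - \Lambda$. With $n = 256$ subjects, $p = 8$ components and 11
design columns this yields $(df_1, df_2) = (8, 238)$; the well-being
analysis ($n = 168$, $p = 3$) yields $(3, 155)$. No multiplicity correction
is applied across the $K$ predictor tests; the result object records how
many were run. Entering all dwell-times simultaneously (rather than one at
a time) is what produces this df structure, so the package treats that as
the intended design.

The tested predictors' coefficients are mapped back to item space through
the transpose of the rotated loading matrix (`backProjectBetas()`), giving
per-state item maps suitable for word-cloud-style displays.

## Gradient-space projection and the permutation null

Each state's mean map is correlated with three orthogonal connectivity
gradients (unimodal–transmodal, visual–motor, task-positive–task-negative).
The Fisher-z transformed correlations are the state's coordinates;
correlations are clipped to $|r| \le 1 - 10^{-7}$ so degenerate toy inputs
stay finite. The set-level statistic is

$$\sum_{i=1}^{K} \sqrt{S_{iG1}^2 + S_{iG2}^2 + S_{iG3}^2}\cdot
  \max(S_{iG1}, S_{iG2}, S_{iG3}),$$

each state's distance from the origin weighted by its maximum coordinate.
The signed maximum follows the formula literally — a state with all-negative
coordinates contributes a negative term, and a state whose largest
coordinate is 0 contributes nothing. Because the signed reading is genuinely
ambiguous (weighting by the largest absolute coordinate is equally
defensible as a way to differentiate points on the same sphere),
`maxRule = "absolute"` exposes the alternative; the default implements the
formula as displayed.

The null distribution shuffles the $P$ parcel weights of each state map
independently (each state's weight multiset is conserved), projects the
synthetic set and records its weighted distance sum; 300 permutations of a
7-state solution give 2100 synthetic states. The exceedance p-value uses the
add-one permutation convention $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(B+1)$, so it is never exactly zero and is uniform under
exchangeability — a property the test suite verifies by simulation.

## The synthetic cohort

`simulationConfig()` encodes the study conditions as defaults: 256 subjects,
a 9-minute run at TR = 3 s (180 volumes), 17 parcels, 7 states, 10 HMM
restarts, 300 permutations, the 2.5σ outlier rule, and the motion exclusion
thresholds (mean FD > 0.3 mm, or more than 15% of volumes above the 0.5 mm
per-volume scrub threshold; both boundaries exclusive, so a subject at
exactly 0.3 mm or exactly 15% is retained). The per-volume definition of a
"motion-affected" volume is taken from the 0.5 mm scrubbing criterion used
in confound regression, the only in-data candidate for that threshold; it is
configurable.

Values the study conditions do not pin down were chosen once, on
plausibility grounds, and are not tuned:

* **Transition matrix**: self-transition 0.9, off-diagonal mass spread
  evenly — a mean dwell of 10 TRs (30 s), a typical fMRI network-state
  timescale.
* **State mean maps**: orthonormal cosine (DCT) rows scaled to 1.5 in
  standardised signal units, identity covariances — states that are
  distinguishable but overlap substantially at the single-volume level.
* **Report coupling**: latent component scores are standardised dwell-times
  times an effect size of 0.5 plus unit Gaussian noise (components 1 and 2
  driven by states 3 and 7 by default); items load 0.8 on one component each
  in a sparse round-robin pattern, with item noise SD 0.6, and are
  discretised at the quartile cut-points of each item's latent score so rank
  information is preserved. With 25 items over 8 components this reliably
  yields exactly 8 retained components (within-block correlations around
  0.6 put the block eigenvalues near 2.3), mirroring the 8-component
  experience decomposition; the 12-item/3-component well-being geometry
  yields 3.
* **Motion**: i.i.d. gamma framewise displacement (clean mean 0.15 mm) with
  a configurable probability of a volume drawn above the 0.5 mm threshold.
  Only the exclusion rule consumes FD, so temporal autocorrelation of
  motion is deliberately not modelled.
* **Initial state**: drawn from the chain's stationary distribution, so the
  simulated chains start in equilibrium and dwell statistics carry no
  burn-in artefact.
* **Demographics**: age $\mathcal{N}(20.7, 2.4^2)$ and a 169/256 female
  proportion, matching the cohort the geometry emulates.

One global seed expands into per-subject substreams, so a given subject's
data are bit-identical whether the cohort has 3 subjects or 256 — a property
the tests rely on.

What the generator does **not** emulate: haemodynamic convolution and
autocorrelated BOLD noise, spatially structured state maps with realistic
network topography, physiological confounds, non-stationary or
subject-specific transition structure, and item-level response styles.
Passing tests therefore demonstrate that the pipeline recovers the
structures it models — not that those structures exhaust real resting-state
data.

## Numerical choices

* Standardisation uses the population SD (divisor $n$), applied per subject
  and parcel *before* concatenation; concatenating never mixes subjects'
  means or variances. Zero-variance parcels are an error naming subject and
  parcel.
* EM convergence: relative log-likelihood change below $10^{-6}$, cap 500
  iterations (non-convergence returns best-so-far with a warning).
  Covariances receive a $10^{-6} I$ ridge after each M-step; the model is
  flagged if the floor is still active at convergence.
* Viterbi and the state-matching assignment are exact and deterministic
  (lowest-index tie-breaks; the assignment uses a bitmask dynamic program
  rather than a greedy heuristic).
* Degenerate inputs fail loudly: non-stochastic transition rows,
  non-positive-definite covariances (naming the offending state),
  constant items, constant state maps in the permutation null.

## Problem sizes used by the test suite

The suite exercises every operation at sizes chosen to make the properties
sharp while keeping a full run around a minute: exhaustive Viterbi
enumeration at $K = 2, T = 6$; transition recovery over 20 replicate cohorts
of 50 subjects × 180 volumes × 17 parcels at $K = 3$; 1000 null simulations
for the type-I calibration of the Wilks test; 500 replicates for the
uniformity of the exceedance p; and a 16-subject end-to-end determinism
check. The acceptance script runs the complete pipeline at the full default
geometry. The end-to-end power check for the planted dwell-time/report
association uses ground-truth state paths across 100 replicate cohorts — the
HMM-fit link in that chain is covered separately by the parameter-recovery
tests — plus a single full run through the fitted model.

## Limitations

* EM with full covariances stands in for variational Bayes; the contract is
  the multi-restart/best-objective protocol and the downstream summaries,
  not the inference flavour, and no free-energy-based model comparison
  across $K$ is provided beyond per-run objectives and split-half style
  state matching.
* The gradient maps are consumed at parcel resolution as an input; the
  package neither computes gradients from connectivity nor reduces
  voxel-resolution maps to parcels.
* The report-coupling model is a stand-in: its effect sizes are free
  parameters of the generator, not estimates of any real-data association.
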