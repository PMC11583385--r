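---
title: "Estimating dynamic MTL network flexibility: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic MTL network flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlflex)
```

## The problem

Resting-state functional connectivity of the medial temporal lobe (MTL)
is not static: the coupling among the perirhinal, parahippocampal and
entorhinal cortices and the hippocampal subfields reorganises on the
scale of tens of seconds. *Dynamic network flexibility* quantifies this
reorganisation as the propensity of each region to change its community
(module) allegiance across consecutive time windows. mtlflex implements
the full chain from ROI-averaged time series to that statistic, plus
the cognitive scores (acquired equivalence generalization, RAVLT) and
covariate-adjusted standardized regressions used to relate flexibility
to cognition and plasma biomarkers. Because no subject-level data are
distributed with the package, every stage is driven and validated by
synthetic generators with planted ground truth.

## From time series to coherence layers

A subject is a 7 × 812 matrix sampled at TR = 0.664 s. The first and
last six time points are discarded and the remaining 800 are cut into
L = 16 consecutive non-overlapping 50-point windows (33 s each). Within
each window, connectivity between ROIs i and j is the magnitude-squared
spectral coherence averaged over the band of interest:

$$C_{ijl} = \operatorname{mean}_{f \in [0.06, 0.12]}
  \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1].$$

Estimator settings (all exposed through `welchSettings()`):

* **Welch segments of 25 samples, Hann taper, 50 % overlap, linear
  detrend per segment.** Three segments are averaged inside a 50-point
  window. Averaging is essential: single-segment coherence is
  identically 1 at every frequency. At 25-sample segments the spectral
  resolution is 1/(25 × 0.664 s) ≈ 0.060 Hz, which places exactly one
  one-sided bin (0.0602 Hz) inside the closed band [0.06, 0.12] Hz.
* **Band-edge convention:** a bin belongs to the band when its center
  frequency f satisfies 0.06 ≤ f ≤ 0.12 (closed interval).
* **Windows that do not divide evenly** leave a trailing remainder that
  is dropped with a warning (the default geometry divides exactly:
  812 − 12 = 16 × 50).
* **Per-window demeaning** is applied before the estimator (and each
  Welch segment is additionally detrended).

Two numerical caveats are worth knowing. First, with only three
(overlapping, hence correlated) segments the estimator has a large
positive small-sample bias under independence — far from zero — so
coherence values must only ever be compared within the same
estimator settings, never against zero. The test suite pins this bias
against an independently written naive DFT implementation. Second,
zero-variance series make coherence undefined and raise an error rather
than returning a value.

A wavelet-coherence alternative was considered and deliberately not
implemented: the statistic computed here is the named Fourier
band-averaged magnitude-squared coherence, and the single in-band bin
at this window length means a wavelet variant would mostly re-weight
the same information.

## The multilayer network and its partition

The 16 coherence layers (diagonals zeroed, so self-coherence never
enters node strengths) are linked by *identity inter-layer coupling*:
each node is connected with weight ω to its own copies in the previous
and next window only — no all-to-all layer coupling. The quality of a
partition g of the 7 × 16 node-layer units is the multilayer
modularity

$$Q = \frac{1}{2\mu} \sum_{ijlr}\left[\left(A_{ijl} -
  \gamma\frac{k_{il}k_{jl}}{2m_l}\right)\delta_{lr} +
  \delta_{ij}\,\omega\,\mathbb{1}\{|l-r|=1\}\right]
  \delta(g_{il}, g_{jr}),$$

with per-layer strengths $k_{il}$, totals $2m_l$, and
$2\mu = \sum_l 2m_l + 2\omega N(L-1)$. A layer with zero total weight
contributes no null term. With a single layer and all nodes in one
community, Q = 0 exactly — a closed-form identity the tests rely on.

`louvainMultilayer()` optimizes Q with the standard two-phase greedy
scheme on the supra-modularity matrix: phase 1 sweeps node-layer units
in a seeded random permutation, moving each unit to the community with
the largest strictly positive gain (ties, within a numerical guard of
1e−12, keep the current community); phase 2 aggregates communities into
super-nodes, summing all intra- and inter-layer modularity terms, and
repeats until no aggregation reduces the unit count. Q is nondecreasing
across accepted moves and never ends below the all-singletons
partition. Community identity across layers is carried implicitly by
the shared labels of the multilayer partition — the coupling is what
makes labels comparable across time — with no post-hoc label matching.

On 4-node × 2-layer instances the optimizer's best-of-100-seeds result
equals the exhaustively enumerated maximum over all 4140 partitions of
the eight units, and the implementation's Q agrees with a direct
quadruple-sum evaluation to 1e−12.

**Flexibility.** For a partition with L layers, node i's flexibility is
$f_i = \#\{l : g_{il} \neq g_{i,l+1}\}/(L-1)$, and the network value is
the arithmetic mean over nodes. Flexibility is undefined (an error) for
a single layer. Because a single greedy run is sensitive to degenerate
optima, `flexibilityPipeline()` averages node and network flexibility
over `nRuns = 100` restarts by default (child seeds derived
deterministically from one master seed) and reports the dispersion
across runs.

## Choosing γ and ω

The resolution and coupling of the multilayer modularity are free
parameters, and their conventional values (γ = 1, ω = 1) come from
studies of much larger networks. On this 7-node network the coherence
layers are dense with weights roughly in 0.4–1.0, and calibration on
synthetic subjects with planted, window-boundary-aligned community
switches showed that ω = 1 *freezes* the partition: estimated
flexibility is essentially 0 even when every node genuinely switches
community four times (planted flexibility 0.267). Estimated flexibility
decreases monotonically in ω on fixed switching input — a property the
test suite enforces over ω ∈ {0.1, 0.5, 1, 2, 5} — so ω trades spurious
switching on static input (large at small ω) against missed true
switching (total at large ω).

The package default is **ω = 0.3, γ = 1**: small enough that true
reorganisation is detected with small bias, large enough that noise on
static input produces little spurious switching. Both parameters are
required arguments of the network constructor in the sense that they
are always recorded in every output manifest, and the ω-monotonicity of
flexibility (nonincreasing in ω) is enforced as a property test. No
claim is made that any particular (γ, ω) reproduces the absolute
flexibility scale of any empirical cohort; only relative and
recovery-based statements are tested.

## The synthetic subject generator

`simulateRoiTimeSeries()` emulates exactly what the connectivity stage
consumes: per segment, every community receives one shared narrowband
signal — Gaussian noise band-pass filtered to [0.06, 0.12] Hz by FFT
masking, unit variance — and each node's series is
`withinCoupling` (default 2) times its community's shared signal plus
independent standard Gaussian broadband noise. Narrowband *noise*
rather than sinusoids avoids degenerate single-frequency coherence.
Planted labels are defined per time point; `plantedFlexibility()` maps
them to windows by majority (a tie breaks to the earlier segment's
label) and counts label changes over L − 1 transitions.

`switchSchedule()` constructs recoverable switching: at successive
window boundaries one node from each of the two communities swaps
sides, chosen greedily (fewest changes so far, lowest index first), so
each community always keeps a persistent core — a switch that merely
relabels whole communities would be invisible in principle to any
community-tracking method. With 7 nodes, 16 windows and 4 changes per
node this plants flexibility of exactly 4/15 for every node.

What the generator does **not** emulate: hemodynamics, scanner noise
spectra and autocorrelation structure, motion artifacts, spatially
varying SNR, within-community coupling heterogeneity, or switches
misaligned with window boundaries (supported, but the recovery tests
use aligned ones). Passing recovery tests therefore show that the
estimator chain is correct and sensitive under its own model, not that
empirical fMRI flexibility values are unbiased.

## The acquired equivalence task and simulated agents

`aeTask()` generates the paradigm: four face antecedents and four fish
consequents randomly assigned to roles per seed; stage 1 trains A1→X1
and B1→Y1, stage 2 adds A2→X1 and B2→Y1 (different faces, same fish —
the acquired equivalence), stage 3 adds A1→X2 and B1→Y2; the transfer
phase interleaves 36 old-association trials with 12 new trials testing
the equivalence-implied pairings A2→X2 and B2→Y2. Acquisition proceeds
in randomized blocks of all active associations (earlier stages stay
interleaved), advancing on one error-free block and capped at 10 blocks
per stage with a truncation flag — a learning-to-criterion convention;
both knobs are arguments. Trial timing (1 s feedback, 1 s intertrial)
is recorded but computationally inert.

Scoring: average errors per presented acquisition trial (errors per
trial, not per block), transfer error proportion, the headline accuracy
percent = 100 × correct/total over the 48 transfer trials (a pooled
acquisition+transfer percentage is also emitted, since either
convention appears in practice; the transfer-only score is the
default), and separate retention (old) and generalization (new)
accuracies that recombine 36:12 to the overall transfer accuracy.

`simulateAgent()` lets tests dissociate intact learning from impaired
generalization: acquisition uses an incremental associative learner
(logistic soft choice on strength differences, delta-rule feedback
updates), transfer uses Bernoulli responses with separate retention and
generalization probabilities.

`ravltScores()` derives delayed recall and percent forgetting,
100 × (trial5 − delayed)/trial5, returning a flagged `NA` (not an
error, not 0) when trial 5 is zero.

## Regressions, screening and power

`fitAdjustedModel()` implements the reporting convention of
covariate-adjusted association studies: the outcome, focal predictor
and continuous covariates are z-scored, binary sex enters 0/1 unscaled,
and ordinary least squares yields the focal standardized β, its t and
two-sided p at the residual degrees of freedom, R², R = √R², and the
overall F with its dfs satisfying F = (R²/k)/((1−R²)/(n−k−1)) exactly.
Rows with any missing model variable are deleted listwise and the n
actually used is reported. No multiple-testing adjustment is applied
across the model suite; p-values are nominal.

`runModelSuite()` fits the eleven focal models — AE accuracy and RAVLT
delayed recall against network flexibility, and each of p-tau231,
p-tau181 and the Aβ42/Aβ40 ratio against AE accuracy, RAVLT and
flexibility — with age, sex and education as covariates everywhere and
the AE acquisition score as an additional covariate exactly in the
models involving AE accuracy.

Screening follows the 2×IQR rule with type-7 (linear-interpolation)
quartiles: flag x outside [Q1 − 2·IQR, Q3 + 2·IQR], report, never drop.
A constant variable has IQR 0, so any deviation from the constant is
flagged. Model-level screening flags standardized residuals (residual
divided by the residual SD) beyond ±2.

`sampleSizePointBiserial()` performs the exact power calculation for a
two-tailed point-biserial correlation: noncentrality
δ = √n·ρ/√(1−ρ²), df = n − 2, two-tailed critical value at α, scanning
n upward for the smallest integer reaching the target power. For
ρ = 0.40, α = 0.05 and power 0.95 the minimum is n = 71 (achieved power
0.952; n = 70 reaches only 0.949).

## The synthetic cohort generator

`simulateCohort()` draws age (70.88 ± 6.05 y), education
(13.90 ± 2.47 y) and sex (Bernoulli, 66.21 % female by default), plus
latent standard-normal scores for flexibility, AE accuracy, acquisition
score, RAVLT delayed recall, p-tau231 (20.39 ± 11.99 pg/mL), p-tau181
(18.68 ± 9.49 pg/mL) and the Aβ42/Aβ40 ratio (0.06 ± 0.01; the SD is
set to 0.01 so the column is non-degenerate, and the acquisition score
scale 0.25 ± 0.15 errors/trial is the generator's own choice). Planted
effects are specified as standardized coefficients per
(predictor, outcome) pair; each affected outcome is rebuilt as the
planted linear combination of its z-scored predictors plus Gaussian
noise with variance 1 − Σβ², so the planted standardized β is exact.
Latents are then mapped linearly to each variable's measurement scale;
biomarkers and the acquisition score are truncated at zero
(non-negativity), which slightly compresses their lower tails — the
other variables are left untruncated precisely so that planted-effect
recovery is unbiased. Values can therefore exceed physical ranges in
the tails (e.g. accuracy above 1); the generator targets statistical
fidelity of the planted effects, not marginal realism.

Under the null (no planted effects) all variables are independent and
the regression t-tests are exactly calibrated; the test suite verifies
the type-I error of every focal model over 2000 cohorts of n = 148 and
recovers a planted β = 0.28 within ±0.05 at n = 5000.

## Problem sizes, determinism and limitations

The test suite uses deliberately small Monte-Carlo designs chosen to
give comfortable statistical margins at desk scale: 20 synthetic
subjects × 20 optimizer restarts for flexibility recovery, 15–20 seeds
for coherence-contrast and ω-monotonicity properties, 2000 replicates
for regression calibration, 2000 agents for transfer-score
expectations. All randomness flows from explicit seeds through one
fan-out helper (`childSeeds()`), every public simulation function
restores the caller's RNG state, and the end-to-end pipeline is
bit-reproducible given its master seed.

Known limitations: flexibility estimates depend on (γ, ω) and on the
coherence estimator's bias, so absolute values are not comparable
across settings; the single in-band spectral bin at 50-point windows
makes band-averaging a one-bin mean; the Louvain optimizer is greedy
and stochastic, with optimality guaranteed only on the enumerable test
instances; and the synthetic generators validate the machinery, not the
biology — no claim about empirical effect sizes or the empirical
flexibility distribution follows from the tests passing. Layer-shuffled
null-model networks and additional dynamic metrics (promiscuity,
allegiance matrices) are out of scope by design.
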