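---
title: "Models, estimators and design choices in skpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in skpatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

skpatch packages the bespoke computational steps of a combined
electrophysiology / Patch-seq / imaging / behavior study of SK-channel
function in midbrain dopamine neurons.  This vignette explains the models
and estimators it implements, the parameters that matter, the synthetic
data used to validate them, and the choices made where the underlying
conventions were genuinely open.

## The pacemaker simulator

The simulator exists to give every downstream feature operator an input
with known ground truth whose physiology responds to an SK knob in the
right direction.  It is a deliberately minimal single-compartment
membrane model (capacitance 1 µF/cm², area 3000 µm² ≈ 30 pF):

$$C\,\dot V = -(I_\mathrm{Na} + I_\mathrm{K} + I_\mathrm{Ca}
 + I_\mathrm{SK} + I_\mathrm{A} + I_\mathrm{leak}) + I_\mathrm{inj} + I_\mathrm{OU}$$

* fast Na⁺ (instantaneous m∞³, dynamic inactivation h) and a delayed
  rectifier n⁴ generate the spike;
* a high-threshold Ca²⁺ current (activation midpoint −20 mV) loads a
  single calcium pool only during spikes:
  $\dot{[\mathrm{Ca}]} = -k_\mathrm{Ca} I_\mathrm{Ca} - ([\mathrm{Ca}]-\mathrm{Ca}_\mathrm{rest})/\tau_\mathrm{Ca}$
  with $k_\mathrm{Ca}=0.006$ µM·cm²/(ms·µA) and $\tau_\mathrm{Ca}=250$ ms;
* the SK current is calcium-gated with Hill activation,
  $I_\mathrm{SK} = g_\mathrm{SK}\,
  \frac{[\mathrm{Ca}]^{n}}{[\mathrm{Ca}]^{n}+K_\mathrm{eff}^{n}}(V-E_K)$,
  $n=4$, $K_{1/2}=0.5$ µM;
* an A-type K⁺ current (instantaneous a∞³, inactivation τ_b = 150 ms,
  inside the 30–300 ms VTA band) shapes the ramp to threshold and the
  rebound delay;
* an ohmic leak with reversal −30 mV supplies the depolarizing pacemaker
  drive;
* noise is an additive Ornstein–Uhlenbeck current (sd 40 pA, correlation
  time 5 ms).  White noise was rejected because its effect on CV_ISI
  depends on the integration step.

Two knobs map onto SK biology.  `g_sk` is the conductance a blocker such
as apamin removes.  `phi` ∈ [0, 1] is a calmodulin-phosphorylation
factor: CK2-phosphorylated SK-bound CaM has reduced apparent calcium
sensitivity, modeled as a right-shift of the activation curve,
$K_\mathrm{eff} = K_{1/2}(1 + 2\varphi)$.  A literal multiplication of
$K_{1/2}$ by a factor ≤ 1 would *left*-shift the curve (increase
sensitivity), so the $(1+2\varphi)$ form is used: φ = 0 is the
unphosphorylated baseline and increasing φ reduces sensitivity, which
keeps the firing rate monotonically non-decreasing in φ.

Defaults were calibrated once and frozen: spontaneous rate ≈ 2.7 Hz at
zero noise (inside the 0.5–4 Hz pacemaker band), spike full width at
half maximum ≈ 1.15 ms (the "wide spike" DA signature), apparent
threshold ≈ −45 mV.  The SK conductance operates in a *non-saturating*
activation regime (peak [Ca] ≈ 0.4 µM against $K_{1/2}=0.5$ µM): with a
saturated SK gate the afterhyperpolarization duration is set by calcium
clearance alone and `g_sk` stops mattering, which defeats the purpose of
the knob.  Calibration targeted qualitative contracts only — the rate
band, monotonicity of rate in `g_sk` (decreasing) and `phi` (increasing),
and the robustness of the paired-run directions (rate up, CV_ISI up,
mAHP depolarized when `g_sk` drops to 40%) across a 24-seed sweep — never
a published group statistic.

Integration is fixed-step explicit Euler at dt = 0.025 ms (upper bound
0.05 ms enforced); halving dt changes the apparent threshold by < 0.5 mV
and the deterministic rate by ~1%, which is the accuracy the feature
tests require.  Divergence (|V| > 200 mV) raises an error naming the
step.  The integrator is compiled (Rcpp) and uses R's RNG, so every run
is reproducible from `(params, seed)`.

What the generators do *not* emulate: multi-compartment morphology,
synaptic input, bursting, electrode artifacts, series-resistance errors,
and any quantitative fit to recorded traces.  A green mechanism suite
therefore shows that the *operators* recover planted structure with the
right directionality — not that the model reproduces any particular
neuron quantitatively.

## Spike features

Rate is the mean spike count per 10 ms bin divided by the bin length.
A coefficient of variation cannot be formed inside 10 ms bins, so CV_ISI
is computed from the ISIs whose onset falls within each analysis segment
(default 10 s, configurable through `cv_segment_s`; pass the recording
length to get the plain global CV) and averaged across segments — this
keeps slow rate drift from inflating the estimate.  With fewer than
three spikes the CV is flagged undefined rather than returned as 0.

ISI trajectories are resampled to exactly 1000 points by linear
interpolation on the half-open interval from one spike to the next (the
right endpoint belongs to the next ISI), so identical ISIs give identical
rows and a 1000-sample ISI round-trips within interpolation tolerance.
The minimum ISI voltage is the minimum of the per-cell average row; the
mAHP is the mean of that row from 10 to 100 ms after the minimum, with
point indices mapped to milliseconds through the cell's mean ISI.  ISIs
shorter than 110 ms truncate the window and set a flag.  Grand averages
across cells are plain means of per-cell averages, so averaging commutes
with row permutation.

The apparent threshold is read off the peak-aligned *average* waveform as
the voltage where dV/dt first reaches 10 mV/ms before the peak.  No
standard defines the width reference level for this measure; full width
at half maximum with the half level midway between threshold and peak is
adopted (configurable), and the Gaussian-spike test pins the convention
to its closed form (FWHM = 2.355 σ when the threshold sits near the
baseline).

Whole-cell voltage traces whose metadata lacks `ljp_corrected = TRUE` are
shifted by the configured junction potential before feature extraction,
mirroring offline correction practice; the flag prevents double
correction.

## Voltage-clamp metrics

Tail metrics average the sweeps, take the baseline as the mean over the
50 ms immediately pre-step, and integrate the baseline-subtracted current
from step offset by the trapezoidal rule — exact for piecewise-linear
input, within 0.1% of the closed forms for exponential and alpha-function
test signals.  No convention fixes the integration window for tail
charge; the package integrates to 1 s after offset or until the baseline
has been re-crossed for 50 consecutive ms, whichever comes first (both
configurable and echoed in reports).

The bi-exponential inactivation fit seeds Levenberg–Marquardt from a
two-segment log-linear regression (early quarter / late half of the
offset-subtracted log decay) and retries from a deterministic grid of
multiplicative jitters spanning [0.3, 3]; the best residual wins, time
constants are reported ordered, and near-mono-exponential solutions
(amplitude ratio < 1%, or τ₂/τ₁ < 1.2) carry a degeneracy flag instead of
pretending two resolvable components exist.

Cell classification applies the standard VTA DA / SNc DA / LC NE rule
sets.  "Fast" vs "slow" A-current inactivation is mapped to τ_A below /
above 100 ms — a repository convention, since the printed band (30–300
ms) is only stated for VTA cells.  A missing feature fails its rule
closed unless the anatomical region hint names that rule's region, in
which case the comparison is skipped; this is the only reading under
which a typical SNc recording lacking a τ_A measurement can still be
labelled SNc from its rate, width and I_H.  Every comparison lands in
the returned rule trace, so each decision is reproducible.

## Liquid junction potential

`compute_ljp()` implements two estimators with the sign convention
pipette-minus-bath (`V_corrected = V_measured + V_J`; a −54.9 mV nominal
command with V_J = −17.1 mV is a −72 mV holding potential):

* **Henderson** — the closed form under a linear mixing profile;
* **nernst_planck** — explicit relaxation of the one-dimensional
  electrodiffusion system (Nernst–Planck fluxes with the electric field
  set by the zero-net-current constraint) from a sharp interface to its
  stationary free-diffusion profile, then integrating the field.  It
  makes no profile assumption and agrees with Henderson well below 1 mV
  on patch-type junctions; grid 201 points, which is converged to
  < 0.01 mV against refinement.

The mobility table stores limiting molar conductivities at 25 °C from
standard tabulations.  The organic species carry documented effective
parameters: gluconate at the conventional 0.33 relative mobility vs K⁺;
HEPES speciated at the recipe pH (pKa 7.55, ~39% anionic at pH 7.35);
ATP/GTP as Mg complexes with effective valence −2 (millimolar Mg²⁺ is
present in the recipe); phosphate split at pKa₂ = 7.20.  Electroneutrality
is enforced to 1%, with an optional balancing counter-ion representing
the titration base (KOH for the internal).

With *all* printed species included, both estimators put the internal-vs-
aCSF junction at −14.2 to −14.4 mV.  Stationary Nernst–Planck calculators
of the LJPcalc family report −17.1 mV for this internal — a value this
package reproduces to 0.05 mV when the junction is reduced to its major
carriers only (≈140 K-gluconate vs ≈150 NaCl), but not with the full
recipes: the pipette's 15 mM Cl⁻ and the bath's 21 mM HCO₃⁻ each damp the
junction by 1–2 mV, and no literature-supported gluconate mobility closes
the gap (it would need λ ≈ 13 S·cm²/mol, half the accepted value).  The
package deliberately reports the full-recipe value; users who want to
match a major-ion calculation can pass reduced `solution_spec`s.
Temperature enters only through RT/F (< 3% between 25 and 33 °C).

## Patch-seq statistics

The QC filter keeps cells expressing all three DA markers (count ≥ 1)
and none of the four contamination markers (count ≤ 0 by default), and
logs attrition per criterion.  The expression filter keeps genes with
count ≥ 1 in ≥ 80% of the cells of at least one group; where different
phrasings of this rule circulate (">1 in >80%" vs "≥1 in at least 80%"),
the inclusive version is the default and both thresholds are
configurable.  The per-cell-counts reading is the only one compatible
with a per-cell fraction.

Size factors are median-of-ratios: per cell, the median over reference
genes (nonzero in every cell) of count over the gene's geometric mean,
rescaled to geometric mean one.  On a two-cell matrix where one cell is
exactly double the other this gives (1/√2, √2) by hand.  With no
all-nonzero gene the geometric means fall back to positive counts only,
with a warning.  `DESeq2::estimateSizeFactorsForMatrix` is used in the
test suite as an independent cross-check, not as the implementation.

Differential expression is a per-gene two-sample t test on normalized
counts — Welch by default, since nothing fixes the variance assumption
and unequal variances are the safer default; a pooled option exists.
Benjamini–Hochberg adjustment is implemented as the textbook step-up
(sort, scale by m/rank, cumulative minimum, unsort), tested for exact
equality against an independently coded brute force and against
`stats::p.adjust`.  The fold change is the ratio of normalized group
means with a pseudo-count of 0.5 (configurable, echoed in the manifest)
against division by zero; a gene is a DEG iff FDR < 0.1 *and* |FC| >
1.25, both strict.  Zero-variance genes get p = 1 and a flag.
Physiology correlations are Pearson on normalized expression — no log
transform by default, because the upstream convention does not state
one; a log2 option exists.

The synthetic Patch-seq generator draws negative-binomial counts (size 5,
log-normal gene means around 30, log-normal size factors sd 0.3 — typical
magnitudes for deeply sequenced Patch-seq libraries), plants marker
structure, DEGs at a stated fold change (half up, half down), and
covariate-tracking genes whose latent mean follows the planted Pearson r
against a tail-amplitude covariate; those genes are generated high-mean
and low-dispersion so counting noise attenuates the realized correlation
by only a few percent.  Under the global null the raw p-value fraction
below 0.05 is 0.050 ± 0.01 across 50 seeds, and planted 2-fold DEGs at
n = 30 + 30 are recovered at ≥ 90% with empirical FDR at or below the
nominal level.

## Imaging and behavior

Per-cell intensity quantification is a mean over mask pixels (labels are
arbitrary positive integers; 0 is background and never counted).  Mask
resizing is nearest-neighbour index mapping only — labels must never be
interpolated.  "Brightest slice" of a stack is the slice with the highest
*mean* intensity (the metric is not standardized; per-slice mean is
adopted).  Group comparison pools per-cell means across animals into one
empirical cumulative distribution per group and applies the two-sample
Kolmogorov–Smirnov test via `stats::ks.test`, with the brute-force ECDF
supremum as the test-suite oracle; per-animal summaries can be rebuilt
from the per-cell table for hierarchical reanalysis.

Behavioral metrics are pure functions of the event log: accuracy =
100 × correct/(correct + incorrect) pokes (pokes during reinforcement
timeouts count by default, since accuracy is defined over all pokes; a
flag excludes them); acquisition day = first day at or above 70%
("obtained 70%" is read inclusively), non-learner after day 14;
progressive-ratio breakpoint indexes the printed 24-step schedule by
pellets earned; the attentional index is the novel-minus-familiar mean
head-entry latency per 3-trial bin, bins with missing retrievals being
excluded with a flag; centre occupancy is the fraction of samples with
both coordinates in the middle 10 of 16 beams, with (10/16)² ≈ 39% as the
geometric reference.

## Problem sizes and runtime

The validation suite simulates 10 matched pairs of 40 s recordings for
the SK mechanism checks (the 1 s settle-in transient is cropped, CV taken
over the whole remaining recording), 20 seeds for bi-exponential recovery
at 5 pA noise, 20 seeds of 1000-gene / 60-cell DEG recovery, and 50 seeds
for the planted-correlation coverage check at n = 68 cells.  These sizes
were chosen so each stochastic check has enough replication for its
acceptance margin while the whole suite completes in a few minutes on a
single core.

## Known limitations

* The neuron model is a caricature built for directionality, not fit to
  any recorded cell; its mAHP sits deeper (≈ −84 mV) than typical DA
  recordings.
* The junction calculator ignores activity coefficients and space
  charge; speciation of the organic anions is the dominant uncertainty
  (±1–2 mV).
* The Patch-seq stage models neither gene–gene correlation nor dropout
  beyond NB sampling, so it validates the testing pipeline, not any
  normalization-vs-dropout trade-off.
* Segmentation is out of scope: masks are consumed, never produced.
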