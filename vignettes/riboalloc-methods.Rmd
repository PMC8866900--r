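---
title: "Methods: growth rates, promoter activity and proteome budgets in riboalloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth rates, promoter activity and proteome budgets in riboalloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

riboalloc analyses the quantitative readouts of bacterial
ribosome-allocation experiments: plate-reader growth curves with diauxic
(glucose-to-acetate) shifts, ribosomal-reporter fluorescence as a function
of growth rate, promoter-activity dynamics of adaptation genes, the
conversion of transcript abundances into proteome mass, and dual-reporter
isocost lines that measure a cell's total expression budget. This vignette
documents the models behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the packaged simulators do and do
not emulate.

## Growth-rate estimation from OD time series

The central estimator is a Gaussian-process (GP) regression on log OD. For
a well with readings $\mathrm{OD}(t_i)$ at times $t_i$ (hours), the model
is

$$ y_i = \log \mathrm{OD}(t_i) = m(t_i) + f(t_i) + \varepsilon_i, \qquad
   f \sim \mathcal{GP}\!\left(0,\; a^2
   e^{-(t-t')^2 / 2\ell^2}\right), $$

and the growth rate is the derivative of the posterior mean of
$m + f$: $\mu(t) = \mathrm{d}\log\mathrm{OD}/\mathrm{d}t$, evaluated
analytically (the derivative of a squared-exponential GP posterior is
available in closed form, together with the derivative-process variance
used as the pointwise uncertainty). Finite differences are never used on
the data.

Four estimator details matter in practice and are deliberate design
choices:

1. **Heteroscedastic noise.** Plate-reader OD noise is approximately
   additive with constant standard deviation, so on the log scale its
   variance is proportional to $1/\mathrm{OD}^2$. The GP noise term is
   $\sigma_n^2 w_i$ with $w_i \propto 1/\mathrm{OD}_i^2$ (normalized so
   $\sigma_n$ is the noise sd at the best-measured point). Without this,
   the scatter of early near-blank readings dominates the fit and the
   early derivative is badly inflated.
2. **Linear mean function.** A precision-weighted linear trend in $t$ is
   fitted first (GLS under the same weights) and the GP models the
   residuals; the trend slope is added back to the derivative. Log growth
   curves are dominated by a near-linear trend, and a zero-mean GP forced
   to carry that trend bows at the record edges, inflating the derivative
   exactly where $\mu_\max$ often sits. For exactly exponential data the
   residual vanishes and $\mu(t)$ is recovered to machine precision.
3. **Anchored noise level.** Hyperparameters $(a, \ell, \sigma_n)$ are
   chosen by maximizing the log marginal likelihood (L-BFGS-B, five
   restarts from seeded uniform draws in log-space; bounds
   $\ell \in [2\,\Delta t,\ \mathrm{span}]$,
   $\sigma_n \in [10^{-4}, 1]$ in log-OD units). With a few dozen points
   the marginal likelihood occasionally prefers a short length-scale that
   absorbs noise into signal; a weakly-informative lognormal prior (sd 0.5
   in log space) centres $\sigma_n$ on a robust estimate from standardized
   second differences, which is nearly signal-free for growth-scale
   trends. This is a MAP rather than a pure ML fit.
4. **Selection-bias-corrected maxima.** The maximum of a posterior-mean
   curve overstates the maximum of the underlying function when several
   local wiggles compete: the expected overshoot is approximately
   $E[\max_m N(0,1)] \cdot \mathrm{sd}$ for $m$ competing maxima. Phase
   maxima reported by `detect_growth_phases()` subtract this term, with
   $m$ counted as the local maxima within two posterior standard
   deviations of the phase peak. A broad wiggly plateau ($m \approx 3$-$4$)
   is corrected by about one standard deviation; a single sharp peak
   ($m = 1$) is left untouched.

`GrowthFit` reports $\mu(t)$ and its sd on the observation grid (with
$\mu_\max$ their maximum, per the container's contract) and also evaluates
the analytic derivative on a four-fold refined grid for phase detection.

## Diauxic-shift characterization

A diauxic shift is a growth *pause*: glucose runs out, growth stops, and
after a lag the culture resumes on the accumulated acetate at a lower rate.
`detect_growth_phases()` therefore gates detection on an interior valley of
$\mu(t)$ dropping below `valley_frac` $\times\ \mu_\max$ (default 0.3) and
takes the largest maxima on either side as $\mu_1$ and $\mu_2$, requiring
prominence of at least `prominence_frac` $\times\ \mu_\max$ (default 0.10)
above the valley floor and separation of at least `min_separation` (default
1 h). An alternative rule — rank all local maxima by height and keep the two
largest — was considered and rejected: on realistic noisy curves the GP
posterior wiggles on the glucose plateau by a few percent, and that rule
mistakes a plateau wiggle for a second growth phase in a large fraction of
single wells, whereas wiggles never dip near zero and so never pass the
pause gate. The shift time is the $\mu$ minimum between the two maxima; the
lag is the contiguous interval around it where $\mu$ stays below
`resumption_frac` $\times\ \mu_2$ (default 0.5). Calls whose flanking
prominence is below twice the threshold carry a `low_prominence` flag
rather than being silently trusted, since borderline curves are exactly
where manual curation and automation can disagree.

Replicate structure does real statistical work here. Single-well phase
estimates inherit the GP's plateau wiggle (roughly $\pm 5\%$ on $\mu_1$
under 0.01-OD noise); the study design this package emulates measures nine
replicate wells per condition, and replicate means bring all three phase
metrics within 5% of truth in essentially every simulated experiment.
`summarize_replicates()` reports mean, SD and $n$ per strain-by-medium
group and a Welch test at 95% confidence against a designated reference
strain.

## Reporter allocation

Normalized reporter signal is blank-corrected fluorescence per OD averaged
over the exponential window, defined as the times where
$\mu(t) \ge$ `window_frac` $\times\ \mu_\max$ (default 0.8). The
allocation line is an ordinary least-squares fit of that signal against
growth rate across media; slopes are compared between strains with a
two-sample $t$ statistic on the OLS slope standard errors with
Welch-Satterthwaite degrees of freedom, at 95% confidence and without
multiple-testing correction (comparisons are reported per strain pair).
Fluorescence units are treated as arbitrary throughout; rescaling the
channel rescales slope and intercept together and leaves every
significance flag unchanged.

## Promoter activity

Promoter activity is $PA(t) = (\mathrm{d}GFP/\mathrm{d}t)/OD$, with the
derivative taken by the same GP engine (noise weights proportional to the
squared signal rise above its minimum, since fluorescence noise is
predominantly multiplicative — using the rise rather than the raw signal
keeps $PA$ exactly invariant to a constant offset on GFP). A
Savitzky-Golay fallback (window 7, order 2) is provided for speed and
agrees with the GP within 5% on smooth, slowly varying signals; it is not
recommended near sharp activity peaks, which its fixed window attenuates.

The two-phase dynamics around the activity peak are summarized by OLS
slopes fitted on the 20-80% band of the peak on each side (`onset_frac`
= 0.2 sets the band): the rise slope where $PA$ climbs from 0.2 to 0.8 of
its peak, the fall slope where it descends through the same band, both on
the refined evaluation grid. The band convention — rather than fitting all
the way into the peak — keeps the smoother-rounded cap out of the fit;
including it biases both slopes toward zero by 10-30% on pulse-like
profiles. The exact endpoints of such slope segments are a reporting
convention, so results always carry the `onset_frac` used. Mutant-vs-WT
comparisons report the rise slope as percent of WT and the fall as a fold
change of magnitudes, with Welch tests when replicate profiles are
supplied.

## Proteome mass budget

The mass model converts transcript abundances to protein mass through
per-gene translation efficiencies anchored on a reference condition:

$$ s_i = \frac{C^{\mathrm{cell}}_i}{r_i^{\mathrm{WT}}}, \qquad
   P_i = \frac{r_i \, s_i \, MW_i}{N_A}, $$

with $r_i$ in FPKM, $C^{\mathrm{cell}}_i$ the reference protein copies per
cell, $MW_i$ in g/mol, $N_A = 6.02214076 \times 10^{23}$, and masses
reported in femtograms ($10^{15}$ fg/g). With WT transcripts the model
reduces exactly to $C^{\mathrm{cell}}_i MW_i / N_A$ — this self-consistency
holds to machine precision and is asserted in the tests. A gene's
contribution to the proteome change is $\Delta_i = P_i^{\mathrm{mut}} -
P_i^{\mathrm{WT}}$, linear in the transcript difference at fixed $s_i$.
Genes with reference copies but zero WT transcript have no defined
efficiency; they are excluded from mass computation and listed in an
exclusion report rather than imputed. Direction totals are reported both
as signed sums and as sums of $|\Delta_i|$ per DE-direction label (labels
are taken from the input table, never recalled here); the headline
up/down ratio uses the absolute sums. The Pareto summary ranks genes by
$|\Delta_i|$ (ties broken lexicographically by id) and reports the
cumulative percent of the total absolute change, defaulting to the top 20.
Transcript inputs are assumed to be on one comparable normalized scale;
the module does not re-normalize.

## Isocost budget lines

For the dual-reporter assay, expression is read per well at the first time
OD crosses `od_target` (default 0.2, linearly interpolated between
samples; tolerance 0.02 for wells that stop just short), giving one
(RFP/OD, GFP/OD) point per inducer level. The isocost line is the OLS fit
of GFP/OD on RFP/OD across levels; under a fixed expression budget its
slope is negative, and the GFP-axis intercept — the constitutive
reporter's output when the induced one takes nothing — is the budget
metric. The RFP-axis intercept is reported alongside; only ratios of
budgets between strains are compared (fluorescence units are arbitrary),
with a 95% CI from first-order error propagation on the intercept standard
errors and an `unstable` flag when the reference's own intercept CI spans
zero.

## The simulators and what they emulate

Every analysis stage has a generator with a machine-readable truth record;
the test suite reads truth only from those records.

- `simulate_diauxic_growth()` integrates a sequential two-substrate Monod
  model (deSolve, `lsodar` with a root stop at glucose exhaustion):
  glucose-phase growth at $\mu_1 G/(G + K_g)$ with acetate overflow at 0.3
  substrate units per OD formed, an explicit pause of `lag_duration`, then
  acetate growth at $\mu_2 A/(A + K_a)$. Defaults — $\mu_1 = 0.9$,
  $\mu_2 = 0.35\ \mathrm{h}^{-1}$, 1 h lag, inoculum 0.05 OD, glucose
  sized so exhaustion falls near 4 h, 20-minute sampling over 10 h,
  additive OD noise sd 0.01 — mirror a glucose-minimal-medium batch
  culture. The truth record carries the analytic $\mu(t)$ of the noiseless
  model, the per-phase Monod maxima (slightly below the nominal rates),
  and the shift time defined as the midpoint of the pause.
- `simulate_reporter_allocation()` places per-strain allocation lines
  $F/OD = a + b\mu$ over logistic growth at eleven growth rates spanning
  0.25-1.67 h$^{-1}$, with 3% multiplicative fluorescence noise;
  `simulate_allocation_points()` emits (μ, F/OD) pairs directly (5% noise)
  for regression-calibration studies.
- `simulate_promoter_reporter()` integrates a triangular activity pulse
  against the diauxic OD curve, $GFP(t) = GFP(0) + \int PA^*(\tau)
  OD(\tau)\, d\tau$, peaking before the growth shift, with background
  fluorescence kept small relative to the integrated signal (an induced
  promoter rising well above autofluorescence) and 1% multiplicative
  noise.
- `simulate_budget_tables()` draws lognormal copies, molecular weights and
  WT FPKMs, plants log2 fold changes on labelled fractions of genes, and
  can rescale the transcript differences so direction totals hit requested
  femtogram targets exactly (exact because $\Delta_i$ is linear in the
  transcript difference).
- `simulate_isocost()` puts per-OD reporter outputs on a planted line over
  the four-level induction design (0, 2.5, 5, 20 nM) with a saturating
  induction response and 3% multiplicative noise, wrapped in growth curves
  so the OD-matching step is exercised end to end.

What the simulators do *not* emulate: plate-reader drift and edge effects,
OD nonlinearity at high density, fluorophore maturation delays,
well-to-well cross-talk, condition-dependent translation efficiencies, and
biological replicate variance beyond measurement noise. Passing tests
demonstrate that the estimators recover known structure under the stated
noise models, not that real instruments behave this ideally.

## Numerical choices and degenerate inputs

- OD is clipped at a configurable floor (default 0.005, a typical
  detection limit) before the log transform; clipped wells are flagged,
  never dropped.
- Blank correction subtracts the per-time mean of wells whose strain is
  `"blank"` when such wells exist, and records whether it was applied;
  data without blank wells pass through unchanged.
- Constant or near-constant signals short-circuit the GP (the linear trend
  is the whole fit) and growth rates near zero are returned with a warning
  rather than an error; flat curves are called monophasic.
- All stochastic steps take explicit seeds (default 17) through a local
  RNG scope that restores the caller's random-number state.
- Exact-line inputs are legitimate in tests and yield zero-width residual
  bands; the OLS helpers tolerate them.
- Problem sizes used by the checks — 50 simulated diauxic experiments of
  nine wells, 20 promoter pulses, 100-seed calibration loops, 1000-gene
  budget tables — were chosen to hold Monte-Carlo error well below the
  tolerances they are compared against.

## Known limitations

The single squared-exponential length-scale must compromise between the
smooth growth phases and the kinked shift region; the derivative therefore
carries small systematic wiggle near phase boundaries, which is why phase
metrics are reported with the selection-bias correction and why replicate
averaging is recommended. On a pure exponential with additive noise, a few
percent of noise realizations admit an overfit hyperparameter optimum
essentially tied with the smooth one, and the estimated $\mu_\max$ can
then err by slightly more than 5%. The promoter fall slope over a
sub-hour band rests on roughly three samples at 20-minute resolution and
has irreducible per-well noise of several percent; across-replicate or
across-seed means are the reliable quantity. The mass model inherits the
assumptions of its reference proteome: efficiencies are fixed at their
reference-condition values, and genes absent from the reference are
excluded rather than imputed.
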