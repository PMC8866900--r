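# riboalloc

Quantitative analysis of bacterial ribosome-allocation experiments:
growth-rate estimation from plate-reader OD600 time series by
Gaussian-process regression, diauxic (glucose-to-acetate) shift
characterization, ribosome-reporter vs growth-rate regressions,
promoter-activity dynamics, transcript-to-proteome mass budgets, and
dual-reporter isocost budget lines. Every stage ships with a simulator
that emits known ground truth, so the whole pipeline is testable without
any external data.

## Who this is for

Microbial physiology and systems-biology labs analysing growth-law
experiments: strains whose rRNA operon copy number or RNA polymerase has
been perturbed, grown across media spanning a range of growth rates, with
OD and fluorescent-reporter channels read every 20 minutes. The package
turns those raw time series and gene-level tables into the field's
standard quantities.

## The models at the core

**Growth rate.** A squared-exponential Gaussian process is fitted to
log OD (heteroscedastic noise ∝ 1/OD² on the log scale, precision-weighted
linear mean, MAP hyperparameters with an anchored noise level), and
μ(t) = d log OD/dt is the analytic derivative of the posterior mean with
pointwise uncertainty from the derivative process. Diauxic shifts are
detected as an interior growth pause (μ dropping below 0.3·μmax) flanked
by two prominent maxima μ₁ and μ₂; the shift time is the μ minimum and the
lag the interval where μ stays below 0.5·μ₂.

**Allocation.** Normalized reporter signal F/OD over the exponential
window (μ ≥ 0.8·μmax) is regressed on μ by OLS; slopes are compared
between strains with a Welch t test on the slope standard errors.

**Promoter activity.** PA(t) = (dGFP/dt)/OD via the same GP engine; the
rise and fall of the activity pulse are OLS slopes on the 20–80% band on
each side of the peak.

**Proteome budget.** Translation efficiency s_i = C_cell,i / r_WT,i
converts transcripts to protein copies; P_i = r_i·s_i·MW_i/N_A gives mass
(reported in fg, N_A = 6.02214076×10²³). Per-gene deltas
Δ_i = P_mut,i − P_wt,i are totalled by DE direction and category and
Pareto-ranked by |Δ|.

**Isocost lines.** (RFP/OD, GFP/OD) read at a matched OD (default 0.2)
across inducer levels; OLS of GFP/OD on RFP/OD gives a negatively sloped
line whose GFP intercept is the strain's expression budget; budgets are
compared as ratios with error-propagated CIs.

See `vignettes/riboalloc-methods.Rmd` for assumptions, parameter defaults
and numerical choices.

## Worked example

The numbered drivers under `analysis/` run the full synthetic study — a
WT-like strain against a fast-growing mutant with reduced adaptation
capacity — and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # generate all datasets + truth records
Rscript analysis/02_growth_rates.R    # GP fits, diauxic metrics, replicate summaries
Rscript analysis/03_allocation.R      # reporter/OD vs growth-rate regressions
Rscript analysis/04_promoter.R        # PA dynamics and slope comparisons
Rscript analysis/05_proteome_budget.R # mass-budget totals and Pareto table
Rscript analysis/06_isocost.R         # isocost lines and budget ratios
```

Output from a run of steps 02–06:

```
WT: mu1 0.854 (true 0.876), mu2 0.339 (true 0.344), shift 4.80 h (true 4.85)
rrnDel: mu1 1.029 (true 0.944), mu2 0.243 (true 0.245), shift 4.80 h (true 4.83)
mutant vs WT mu_max: p = 1.89e-05 -> significantly faster in glucose; post-shift mu2 is 71% of WT

WT slope 3.30 [3.10, 3.49]; mutant slope 3.29 [3.24, 3.35]
slope difference -0.003 (p = 0.97): no significant difference between mutant and WT (95%)

WT: PA peaks at 3.67 h (1.13 h before the shift), rise +1.89, fall -5.23
mutant rise slope is 82% of WT; fall magnitude 0.94-fold of WT

upregulated mass 6.27 fg vs downregulated 2.09 fg (ratio 3.00)
top 20 genes carry 64.8% of the total mass change

WT: slope -2.02, budget (GFP intercept) 992 [920, 1063]
rrnDel: slope -1.84, budget (GFP intercept) 678 [638, 718]
mutant budget is 68% of WT [65%, 71%] - significantly reduced
```

Reading it: the mutant outgrows WT on glucose but reaches only ~71% of the
WT growth rate after the shift; ribosome-reporter allocation falls on the
same line for both strains (shared slope, p = 0.97); the mutant's
promoter-activity rise toward its peak is 82% of WT; the planted
transcriptome change costs 6.27 fg of upregulated protein mass against
2.09 fg downregulated (3.0×); and the mutant's expression budget is 68% of
WT — the simulated truth being 0.7.

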