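---
title: "Methods: test-retest reliability of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcreliab)
```

# The problem and the model

A functional connectome is the matrix of Pearson correlations between the
timecourses of brain regions in a resting-state fMRI scan. For a connectome
(or any feature derived from it) to serve as an individual-difference
measure, subjects must stay more like themselves than like each other across
repeated sessions. `fcreliab` quantifies that with the single-measure
consistency intraclass correlation, ICC(3,1): a two-way model with subjects
as random rows and sessions as fixed columns,

$$y_{is} = \mu + b_i + s_s + \varepsilon_{is}, \qquad
b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{is} \sim N(0, \sigma_w^2),$$

whose estimand is $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$. Because session
effects are fixed, a constant shift between sessions (e.g. a scanner
recalibration affecting everyone equally) does not lower the ICC —
*consistency*, not absolute agreement, is measured. From the ANOVA mean
squares the estimator is $(BMS - EMS) / (BMS + (k-1)\,EMS)$ with $k$ the
number of sessions (here $k = 2$). Confidence intervals use the standard
F-based construction for this estimator; the level defaults to 95%
($\alpha = 0.05$), the community default for reported reliability intervals.
Negative estimates (possible whenever $BMS < EMS$) are retained as computed:
clamping them to zero would bias summaries of large edge collections upward,
and bin assignment ("poor") is unaffected either way.

Edge-wise analysis applies this estimator independently to every
upper-triangle entry of the connectome, subjects × edges, one column per
edge. The implementation is vectorized but is required (and tested) to agree
with the scalar two-way ANOVA to 1e-10.

## Reliability bins

Two conventional labelings are provided. The four-class scheme: poor
(< 0.40), fair (0.40–0.60), good (0.60–0.75), excellent (> 0.75); the
five-class scheme: slight (< 0.20), fair (0.20–0.40), moderate (0.40–0.60),
substantial (0.60–0.80), perfect (> 0.80). Interval notation of this form is
ambiguous at the cutoffs, so one convention is fixed package-wide: intervals
are closed on the left (0.40 is "fair", 0.80 is "perfect"). Bin proportions
are computed over non-missing estimates only.

# Preprocessing chain

The per-run conditioning order is fixed, not configurable:

1. **Global signal regression** (optional): each region's series is replaced
   by its least-squares residual on an intercept plus the cross-region mean
   series. The regressor is the *raw* mean, computed before any filtering,
   so both branches of a GSR+/GSR− comparison see identical inputs
   otherwise.
2. **High-pass filter**: 4th-order Butterworth, 0.008 Hz cutoff (default),
   applied forward and backward for zero phase. The filter family and order
   are a design choice — Butterworth is the standard maximally flat choice,
   and zero-phase application avoids shifting signal relative to the motion
   trace. Because forward-backward IIR filtering is sensitive to edge
   transients, each series is demeaned and odd-extended around both
   endpoints (by three filter time constants) before filtering; a constant
   series maps exactly to zero, and the tested passband response is within
   2% at 0.05 Hz for TR = 0.72 s.
3. **Scrubbing**: frames whose relative RMS displacement strictly exceeds
   0.30 mm are deleted (a frame at exactly 0.30 survives). Subjects with
   more than 15% flagged frames in *any* run are excluded entirely — again a
   strict inequality, so exactly 15% passes. Motion flags depend only on the
   RMS trace, so the GSR+ and GSR− branches of an analysis always exclude
   the same subjects.
4. **Concatenation**: each run's columns are demeaned, then the session's
   runs are stacked in order. Demeaning is a deliberate choice: without it,
   baseline offsets between runs masquerade as shared variance and inflate
   every pooled correlation (this failure mode is exercised in the tests).

Pearson correlation of the concatenated session then yields one connectivity
matrix per subject and session, in raw r units throughout — thresholds, bin
cutoffs and strength averages are all defined on r, so no Fisher transform
is applied anywhere.

Edges are vectorized in row-major upper-triangle order, (1,2), (1,3), …,
(1,R), (2,3), …; all panels, masks and reassembled matrices share this
convention.

# Thresholding analyses

For each threshold in a 20-point grid (0.05 to 1.00 in steps of 0.05), each
subject's two session connectomes are thresholded *independently*, and two
questions are asked per edge:

- **Consistency of retention.** The consistency ratio of an edge is the
  number of subjects retaining it in both sessions divided by the number
  retaining it in at least one. Edges never retained by anyone are excluded
  (undefined ratio). Ratios are summarized with the same bin cutoffs as ICC,
  for convenience of comparison.
- **Reliability among consistent retainers.** ICC is recomputed per edge
  using only subjects who retained the edge in both sessions, so that a
  value zeroed by thresholding in one session never enters the estimate.
  Edges with fewer than `min_subjects` (default 10) such subjects are
  reported missing: an ICC on a handful of subjects is too unstable to
  summarize. The floor is configurable.

**Absolute mode** zeroes off-diagonal entries with value strictly below the
threshold. The comparison is on signed values: at any positive threshold all
negative correlations are removed.

**Relative (proportional) mode** ranks edges by signed value — "strongest"
is read as largest r, not largest magnitude, so negative edges are dropped
first — and the standalone operation `threshold_relative(m, p)` retains the
`ceiling(p·E)` top edges, ties at the cut broken by canonical edge order.

**Sweep direction.** In the threshold *sweep*, a larger grid value is more
stringent in both modes. For absolute mode this is automatic. For relative
mode the grid value `t` is interpreted as the proportion of weakest edges
removed, i.e. the sweep retains the strongest `1 − t` of edges at grid value
`t`. This is the only reading under which the sweep is a stringency axis:
had `t` been the retained proportion, `t = 1` would retain every edge in
both sessions and force a consistency ratio of exactly 1 — the maximum — at
the grid's endpoint, making a monotone decline impossible by construction.
The `t = 1.00` endpoint (nothing retained) yields no evaluable edges and is
reported as a missing summary, excluded from trend statistics. Trends are
Spearman rank correlations of the per-threshold median (of the consistency
ratio, and of the thresholded ICC) against the grid values; constant medians
yield an undefined trend rather than an error.

# Comparison tests and sample size

Atlas comparisons use the Kruskal–Wallis rank test (tie-corrected H,
chi-square p). The GSR+ vs GSR− comparison uses the Wilcoxon signed-rank
test on paired edge ICCs, reported as a signed Z from the tie-corrected,
continuity-corrected normal approximation — appropriate at connectome scale
where n is in the tens of thousands — with zero differences dropped.
Strength–reliability association uses Spearman's rho (Pearson on average
ranks) with the t-approximation p-value. All three are rank-based and hence
invariant under strictly monotone transformations of their inputs, which the
tests verify. p-values are reported as computed, never floored.

The sample-size utility answers "how many subjects does a reliability study
need to detect ICC $\rho_1$ against $\rho_0$": the Walter–Eliasziw–Donner
approximation with $\theta(\rho) = (1 + (k-1)\rho)/(1-\rho)$,
$C_0 = \theta(\rho_0)/\theta(\rho_1)$ and

$$n \;=\; 1 + \frac{2k\,(z_{1-\alpha} + z_{1-\beta})^2}{(k-1)\,(\ln C_0)^2},$$

rounded up. $\alpha$ is **one-sided** (default 0.05, power 0.80) — the
hypothesis is directional ($\rho_1 > \rho_0$), and this is the convention
under which the formula reproduces its published reference values (152
subjects for detecting ICC 0.20 with two sessions). A simulation test
confirms the returned n delivers empirical power close to the target.

# The synthetic cohort generator

Real two-session resting-state data cannot ship with a package, so every
downstream stage is validated against simulated cohorts with *known*
reliability structure, at two levels.

**Edge-level panels** (`generate_edge_panel`) draw
$y_{eis} = \mu_e + b_{ei} + \varepsilon_{eis}$ directly, with per-edge
between-subject SD $\sigma_b$ and within-subject SD $\sigma_w$, so the true
ICC of every edge is known exactly
($\sigma_b^2/(\sigma_b^2 + \sigma_w^2)$). These panels back the
parameter-recovery tests: estimator bias < 0.03 at n = 200, regression of
estimate on truth with slope in [0.9, 1.1], and 95% CI coverage within
[0.93, 0.97] at true ICC 0.5, n = 50.

**Timeseries cohorts** (`generate_timeseries_cohort`) emulate the
acquisition structure the pipeline expects: per subject, two sessions of
`n_runs_per_session` runs (default 2) of `n_timepoints_per_run` frames
(default 1,200) at TR 0.72 s. The generative hierarchy is:

- a **population correlation matrix** (default: regions grouped into
  blocks emulating resting-state networks, with block strengths and smooth
  edge-level variation drawn once from a fixed structure seed, so edge
  strengths form a continuum as empirical FC distributions do);
- a **subject matrix**: population matrix plus symmetric Gaussian
  perturbation (SD `subject_dev_sd`, default 0.10), projected back to a
  valid correlation matrix — this is the between-subject, trait-like
  variance;
- a **session matrix**: subject matrix perturbed again (SD
  `session_dev_sd`, default 0.08) — the within-subject, state-like variance.
  Without this level the only within-subject variability would be sampling
  error, which at 2,400 frames per session would make nearly every edge's
  ICC ≈ 0.95, nothing like empirical connectomes; the 0.10/0.08 split puts
  the median edge ICC near 0.55, in the realistic range for two sessions on
  consecutive days;
- **runs**: zero-mean Gaussian draws with the session correlation, plus a
  shared **global component** — a random walk low-passed below 0.05 Hz,
  standardized, added equally to all regions with per-subject amplitude
  drawn from N(`global_amp_mean` = 1, `global_amp_sd` = 0.5) in units of
  regional signal SD. Because the amplitude is a stable subject trait, it
  contributes *reliable* shared variance; regressing it out (GSR) therefore
  lowers edge ICC in this model, the directional behavior the GSR
  comparison tests exercise;
- **motion spikes**: each frame independently spikes with probability
  `spike_rate` (default 0.02); spiked frames receive large-amplitude
  corruption in all regions and an RMS trace value of `spike_rms`
  (default 0.5 mm, necessarily above the 0.30 scrubbing threshold);
  clean frames draw RMS below 0.25 mm, and the first frame of each run is 0
  by the relative-displacement convention.

All randomness flows from one cohort seed through per-subject substreams, so
identical specs regenerate identical cohorts bit for bit, and a subject's
data do not depend on how many subjects follow them.

The projection step (`nearest_valid_correlation`) clips eigenvalues at a
small positive floor, reconstructs, and rescales to unit diagonal; inputs
already valid are returned unchanged, making the operation idempotent.
Congruence preserves positive definiteness, so a single pass suffices.

**What the generator does not emulate:** hemodynamics, spatial structure
within regions, temporally autocorrelated noise beyond the global component,
distance-dependent artifacts, heavy-tailed motion, or any empirically
calibrated between-subject FC dispersion (no public reference distribution
exists for the latter; the defaults are chosen for realism of the resulting
ICC distribution, not fitted to any dataset). Passing tests on these cohorts
therefore demonstrates correctness of the estimators and pipeline plumbing,
and directional fidelity of the GSR and thresholding phenomena — not that
real-data effect sizes will match.

# Numerical and degenerate-input choices

- Zero-variance regions get NA correlations (with a warning) and propagate
  as missing; they are excluded pairwise, never imputed.
- All-identical ICC tables (BMS = EMS = 0) are undefined and reported
  missing; zero EMS with positive BMS yields ICC exactly 1 with a degenerate
  [1, 1] interval.
- Relative-threshold ties at the cut resolve toward earlier canonical edge
  order, making thresholded outputs reproducible to the byte.
- An all-constant run under GSR falls back to intercept-only residuals with
  a logged warning; an all-flagged run is an error, not an empty output.
- Region order is taken from the timeseries header and must be identical
  across runs and subjects; mismatches are errors, never reconciled.

# Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to make every property measurable with comfortable
margins: edge-panel checks use up to 200 subjects × 1,000–2,000 edges; the
pipeline smoke tests use 12–20 subjects at 10–16 regions; the threshold-sweep
and GSR analyses use 50–100 subjects at 30–40 regions with the full
4 × 1,200-frame session structure. The sweep trend on a 100-subject cohort
reproduces a rank correlation of −1 between relative-threshold stringency
and median consistency ratio.

# Known limitations

- Only ICC(3,1) is provided — no ICC(1,1), ICC(2,1) or average-measure
  variants, and no mixed-model estimation (which would differ only by
  clamping negative estimates).
- The pipeline assumes exactly two sessions for edge-wise reliability and
  sweeps; `icc_c1` itself accepts any k ≥ 2.
- No nuisance regression beyond the global mean (no motion parameters,
  derivatives, or component-based denoising): the package expects its input
  timeseries to be already denoised upstream.
- The CLI is a thin wrapper over the exported functions; orchestration
  beyond one cohort per call (e.g. multi-atlas batch runs) is left to the
  caller.
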