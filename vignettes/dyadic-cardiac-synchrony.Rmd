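---
title: "Measuring interpersonal cardiac synchrony: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interpersonal cardiac synchrony: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two people coordinate their actions, their autonomic nervous systems can
transiently couple: beat-to-beat heart-rate fluctuations of one partner
co-vary, within a window of a few seconds, with those of the other. This
package measures that coupling from two-person ECG and asks what makes it
stronger or weaker — task structure, novelty, behavioral coordination, and
stable traits such as social anxiety or perspective taking.

The central statistic is block-level **physiological synchrony**: the mean of
the lagged cross-correlations (±3 s) between the two partners' *prewhitened*
inter-beat-interval (IBI) series, Fisher-Z transformed. Prewhitening matters
because IBI series are autocorrelated, trending and quasi-periodic;
cross-correlating them directly produces large spurious correlations between
people who never interacted. The package therefore also builds the matching
negative control: a **pseudo-dyad** distribution obtained by re-pairing each
subject with partners from *other* dyads performing the same condition, which
quantifies how much synchrony the shared task context alone produces.

## Pipeline

1. **ECG to IBI** (`bandpass_filter`, `detect_rpeaks`, `compute_ibi`,
   `clean_ibi`, `resample_ibi`). Zero-phase second-order Butterworth filters
   at 0.6 Hz (high-pass) and 20 Hz (low-pass); R-peaks as local maxima above
   an adaptive threshold (half the rolling 95th percentile over 2 s windows,
   floored at 30% of the global near-maximum so beat-free edge windows cannot
   drop the threshold to the noise floor) with a 250 ms refractory period;
   intervals in ms between consecutive peaks; artifact correction by an
   absolute range (300–2000 ms) plus an 11-beat rolling-median rule (25%
   relative tolerance) with natural-cubic-spline replacement over beat time;
   finally spline interpolation onto a uniform 4 Hz grid. The filter type and
   order are implementation choices — only the cutoffs are prescribed by the
   measurement convention — and zero-phase filtering is used so peak times are
   not biased. Artifact review is deterministic here (no manual editing); the
   per-block replacement fraction is reported in a QC table so unusable
   blocks (>25% flagged) fail loudly.

2. **Prewhitening** (`boxcox_lambda`, `fit_auto_arima`, `ljung_box`). Each
   4 Hz series is Box-Cox transformed with the lambda minimizing the Guerrero
   coefficient-of-variation criterion (grid over [−1, 2], subseries of 8
   samples), then fit by an exhaustive — not stepwise — search over
   ARIMA(p, 1, q) models, p, q ≤ 5 by default, by maximum likelihood. With a
   seasonal period `m > 1` the search extends to (P, 1, Q) seasonal terms;
   because no seasonal period is prescribed anywhere, `m` defaults to 1 and
   seasonal differencing is disabled rather than inventing a period silently
   — the first difference plus ARMA terms absorb the quasi-periodic
   respiratory component in practice (the validation suite verifies ≥90%
   Ljung-Box whiteness on realistic series). AICc is the single selection
   criterion: it is the small-sample-safe member of the usual trio (AICc,
   AIC, BIC are all reported), ties break toward fewer parameters and then a
   lower MA order. Candidates that fail to converge are skipped; if none
   converges the differenced series is returned flagged `converged = FALSE`.
   Residuals stay on the Box-Cox scale — only their cross-correlation is used,
   and a monotone back-transform would not change its interpretation.

3. **Synchrony** (`cross_correlation`, `lag_group_means`, `average_ccf`,
   `fisher_z`, `dyad_block_synchrony`). The two residual series are aligned
   on their common 4 Hz lattice (grids are anchored to multiples of 0.25 s
   from the block start) and cross-correlated at lags −12…+12 (±3 s), sliding
   subject 2 over subject 1 so a positive lag means subject 1 leads. Each lag
   uses the biased, full-length-normalized estimator — products summed over
   the overlap, divided by n·sd₁·sd₂ with full-series moments — which keeps
   every value in [−1, 1] and avoids the variance blow-up of
   shrinking-window normalization at the largest lags. The 25 signed values
   are averaged into one synchrony value per block (signs retained to keep
   in-phase and antiphase coupling distinguishable), Fisher-Z transformed,
   and ×100 for reporting. Lag-group summaries use the unique non-overlapping
   partition with a −4…+4 central band: negative −12…−5, zero −4…+4,
   positive +5…+12 (8 + 9 + 8 lags).

4. **Surrogates** (`enumerate_pseudo_pairs`, `pseudo_synchrony_distribution`,
   `welch_test`). Within each condition cell — block type × movement ×
   ordinal position of the block within its condition, baseline forming its
   own cell — subject 1 of one dyad is paired with subject 2 of every other
   dyad (one pairing per unordered dyad pair, subject 1 from the
   lower-numbered dyad; only S1×S2 pairings, preserving the task's
   table-side asymmetry). Exhaustive enumeration gives
   (N_b² − N_b)/2 · N_c pairings — 13,260 at 40 dyads × 17 cells — and a
   seeded per-cell subsample supports desk-scale runs. Per-subject ARIMA
   fits are computed once and reused across all pairings. REAL and PSEUDO
   distributions are compared with Welch's unequal-variances t-test on the
   unscaled Fisher-Z values, separately for task and baseline.

5. **HRV and behavior** (`rmssd`, `hrv_change`, `trial_differences`,
   `tukey_filter`, `block_average`). rMSSD is computed on the cleaned
   *beat-domain* intervals — resampling would distort successive differences
   — and each task block is referenced to the resting baseline
   (change = block − baseline). Behavioral synchrony is the per-trial
   absolute difference in the two subjects' grasp-contact and
   start-release times; Tukey 1.5·IQR outlier filtering is applied per
   measure across the study's whole trial pool (a single global retained
   range per measure; per-block filtering is available via `scope`), then
   averaged to one value per block.

6. **Dyad-level models** (`build_dyad_design`, `fit_mixed_model`,
   `saturated_then_trim`, `fdr_adjust`, `lag_group_contrast`). Synchrony is a
   between-dyad outcome, so within-dyad variables (social anxiety,
   perspective taking, HRV change) enter as the dyad SUM and the absolute
   difference ABSDIFF of the two members' scores. The saturated model holds
   both; if no ABSDIFF term reaches α = 0.05 (raw p) they are dropped and the
   trimmed SUM-only model is reported. Fixed effects come from a Gaussian
   linear mixed model (REML, Satterthwaite p-values, by-dyad random
   intercept, optional random slopes with an automatic fallback ladder when
   the fit is singular), with Benjamini-Hochberg adjustment within the
   reported coefficient family, Wald intervals by default and a parametric
   bootstrap behind `ci_method = "boot"`, a likelihood-ratio comparison
   against the random-intercept-only null, and variance-partition marginal /
   conditional R². Block novelty is coded old = 1 / new = 0 (`novelty_old`),
   so higher synchrony in novel blocks appears as a negative coefficient;
   the factor is also kept so either coding can be used.

## The synthetic study generator

`generate_dyad_ibi` draws each subject's IBI fluctuation as AR(1) noise
(stationary SD `ibi_sd_ms`, lag-1 coefficient `ar_coefficient`), a linear
trend, a quasi-periodic respiratory-like oscillation (sinusoid with a random
phase walk), and `coupling_gain` times a **shared driver**: unit-SD Gaussian
noise low-pass filtered at `driver_bandwidth_hz`, delayed into subject 2 by
`coupling_lag_samples`. The driver models slow autonomic co-fluctuation;
0.1 Hz matches the multi-second scale at which the ±3 s CCF operates. No
published estimate pins the spectral content of the observed coupling, so the
bandwidth is a modelling choice, stated here once.

Defaults describe a seated adult at rest: mean RR 850/820 ms, fluctuation SD
45 ms, lag-1 autocorrelation 0.8 at 4 Hz, drift 5 ms/min, a 4 s respiratory
period with 20 ms amplitude. Series are generated directly in the 4 Hz
domain (the resampled representation every downstream stage consumes), with
`uniform_to_beats` inverting the tachogram into beat times for the
beat-domain consumers (rMSSD, ECG synthesis via `generate_ecg_from_rpeaks`).
This decouples validation of the prewhitening/CCF chain from R-peak
detection, which is exercised separately through the synthetic ECG path.

`generate_study` assembles dyads of a baseline block plus 16 task blocks —
four counterbalanced runs of four blocks in the conditions free/same,
free/opposite, leader-follower/same, leader-follower/opposite, leaders
switching mid-run, 20 trials per block. A block is **novel** when its block
type × movement × leader combination differs from the preceding block's; this
is the minimal operationalization of task switching, and it marks six of the
sixteen blocks (each run's first block plus the mid-run leader switches).
Trial times share a dyad-level "sloppiness" factor so grasp-time and
start-time differences correlate across dyads, with occasional distraction
delays to exercise the Tukey filter; questionnaire scores are truncated
normals (social anxiety mean 38.2, SD 20.7; perspective taking mean 27.8,
SD 3.8).

The per-block coupling gain is

```
gain = gain_task + gain_novelty_delta · [new] + gain_anxiety_slope · z(anxiety sum)
```

clamped at zero, with the baseline always uncoupled. The default
`gain_task = 0.25` was calibrated once, by Monte-Carlo over the canonical
prewhitening path (exhaustive ARIMA search), so the task-level averaged CCF
sits at the magnitude reported for real dyads (≈0.004, i.e. 0.4 on the
×100 scale); `gain_novelty_delta = 0.05` then reproduces an old/new
contrast of roughly 0.35 vs 0.55 (×100), and `gain_anxiety_slope = -0.05`
a standardized anxiety-sum coefficient near −0.2. These constants are the
generator's definition of "realistic effect sizes" and are not revisited per
analysis. One subtlety: the residual cross-correlation left after
prewhitening depends on the whitening filters. The minimal reduced-order
search used by the Monte-Carlo loops attenuates the slow shared driver more
strongly than the full ARIMA search, so the *equivalent* gain under the
reduced search is larger (≈0.5 for the same ≈0.005 averaged CCF); the
simulation suites state which convention they use.

**What the generator does not emulate.** Real ECG morphology beyond what peak
detection needs (no P waves, no arrhythmia, no electrode artifacts);
nonstationary coupling within a block; respiratory sinus arrhythmia coupling
between partners; floor/ceiling effects in questionnaires; missing data.
Passing the validation suite therefore shows the *estimator chain* behaves
correctly under known ground truth — it does not certify performance on any
particular real recording.

## Validation scales and numerical choices

The test suite validates the statistical guarantees at desk scale, with sizes
chosen by a-priori power analysis:

- **Null calibration**: 500 uncoupled studies of 8 dyads × 4 task blocks
  (45 s), surrogates subsampled to 10 pairings per cell; the REAL-vs-PSEUDO
  Welch test must reject at 5% ± 2%. Because pseudo pairings reuse the same
  residual series as the real dyads, the two means are positively correlated
  and the test runs slightly conservative (measured ≈4%) — an intrinsic
  property of participant shuffling, shared with the original design.
- **Power**: at the calibrated paper-magnitude gain (averaged CCF
  0.004–0.006 under the reduced-search convention, gain 0.5), 10 dyads ×
  4 blocks give >80% power for REAL > PSEUDO at α = 0.05 across 200
  replicates.
- **Recovery**: 100 studies of 40 dyads × 16 task blocks (45 s) with a
  planted novelty increment (+0.2 gain) and anxiety-sum slope (−0.15
  gain/SD) must yield FDR-significant, sign-correct coefficients in ≥80% of
  runs. The plants are set near the middle of the gain-response curve so the
  experiment tests the estimator, not the edge of detectability.
- Monte-Carlo loops use a reduced prewhitening search (ARIMA(0/1, 1, 0),
  no Box-Cox) — on the generator's short blocks the first difference plus one
  AR term is sufficient for whiteness, and it keeps tens of thousands of fits
  affordable; single-series analyses and the whiteness criterion use the full
  default grid.

Numerical details worth knowing: the biased CCF denominator uses population
SDs of the trimmed common series; Fisher Z is `atanh` and requires |r| < 1
(an averaged CCF of ±1 only occurs for degenerate inputs, which error
earlier); Box-Cox requires strictly positive values (IBIs are, by
construction and by the cleaning range); zero-phase filtering uses
odd-reflection end padding to suppress `filtfilt` edge transients; constant
series return lambda 1 by convention and take the flagged ARIMA fallback;
`stats::arima` residuals are Kalman-filter innovations of full input length,
so no samples are lost to differencing; all generators accept a `seed` and
restore the caller's RNG state.

## Limitations

- The synchrony estimate is stationary within a block; time-varying or
  directional coupling (windowed CCF, wavelet coherence, Granger-style
  measures) is out of scope.
- Frequency-domain HRV (HF/LF power) is not computed; only rMSSD.
- The ordinal (cumulative-link) analysis of closeness ratings and
  parametric-bootstrap p-values at the scale of thousands of replicates are
  exposed only through the design-table builders and the `ci_method = "boot"`
  contract, not re-implemented in full.
- The Welch comparison treats synchrony values as exchangeable within group;
  the residual-sharing dependence described above makes it mildly
  conservative at small dyad counts.
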