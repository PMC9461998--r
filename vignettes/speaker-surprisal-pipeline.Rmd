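---
title: "Modelling N400 attunement to speaker-specific surprisal: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling N400 attunement to speaker-specific surprisal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surpn400)
```

## The scientific problem

When listeners process speech, the N400 — a negative centro-parietal ERP
deflection roughly 300–500 ms after a word's onset — scales with how
unexpected the word is: in information-theoretic terms, with its *surprisal*,
the negative log probability of the word given its context. `surpn400`
implements an analysis pipeline for a specific question about this signal:
do listeners' predictive models *adapt to an individual speaker's
statistics* over the course of an experiment, and do resting-state
individual-difference measures (the aperiodic 1/f slope of the EEG spectrum,
the individual alpha frequency, idea density) moderate that adaptation?

The experimental paradigm manipulates the order of prenominal adjectives in
two-adjective noun phrases ("a huge gray elephant"). English has a
conventional ordering (value > size > dimension > physical property >
color); orders following it are *canonical* (C), reversed orders
*non-canonical* (N). Two speakers produce the materials with opposite
habits: a "canonical speaker" (C:N = 69%:31%) and a "non-canonical speaker"
(31%:69%). If listeners track each speaker's statistics, the N400 at the
second adjective should increasingly follow a *speaker-specific* surprisal
measure as exposure accumulates — a surprisal × exposure interaction.

The package provides every stage as tested, reusable code: the
cluster-based language model, the counterbalanced designs, resting-EEG
metrics, single-trial ERP features, a variance-components linear mixed
model (LMM) with partial-effect extraction, and a synthetic-data generator
with known ground truth that lets all of it be validated by parameter
recovery.

## The cluster-based surprisal model

Estimating bigram probabilities for specific adjective pairs is hopeless —
individual pairs are too rare, and an experiment's worth of exposure far
too small. The model therefore works at the level of *adjective clusters*:

1. Word embeddings (300-dimensional by convention) are reduced to 5
   principal components (`reduce_embeddings()`). Columns are centred but
   not scaled, since embedding dimensions share a scale. Loadings are
   sign-fixed (largest-magnitude entry positive) so results are
   reproducible across platforms.
2. k-means on the component scores yields k = 6 clusters
   (`fit_clusters()`). We use `stats::kmeans` (Hartigan–Wong) with 25
   random restarts under a caller-supplied seed; best-of-restarts makes
   the result deterministic given the seed. `select_k()` reports the full
   within-cluster sum-of-squares curve for the conventional visual
   inspection and automates the elbow as the k maximising the discrete
   second difference of the curve; on well-separated synthetic clusters
   this lands on the generating k.
3. Word-level unigram and bigram corpus counts are summed within clusters
   (`aggregate_cluster_counts()`).
4. Surprisal of the second adjective's cluster given the first's is
   `-log(bigram[c1, c2] / unigram[c1])` (`cluster_surprisal()`). Computed
   from corpus counts this is *global surprisal*.

*Speaker-based surprisal* (`speaker_surprisal_trajectory()`) applies the
same formula to counts accumulated incrementally within the experiment,
separately per speaker: trial t is scored from that speaker's trials
strictly before t — the listener's prior exposure — then added to the
running counts. An `include_current` toggle exists for sensitivity
analyses.

### Numerical choices

- **Log base**: natural log by default (base 2 available). Surprisal in
  nats; the choice only rescales coefficients.
- **Zero counts**: the raw ratio is undefined at first exposure, so we use
  add-alpha smoothing with alpha = 0.5 and denominator `unigram + alpha*k`:
  the first trial of a context scores `log(k)`, the maximum-uncertainty
  value, and smoothed next-cluster probabilities sum to one. `alpha = 0`
  reproduces the literal ratio, returning a flagged `+Inf` for unseen
  bigrams rather than an error.
- **Out-of-vocabulary words** in count aggregation: strict error by
  default; optionally dropped or assigned to the nearest centroid.
- **Frequency covariate**: `word_log_frequency()` returns the natural log
  of the raw count, with add-one smoothing for zero counts.

## Experiment designs

`build_design_exp1()` reproduces the 90-critical-passage design exactly:
two material versions assign passages 1–45 / 46–90 to the two speakers
with within-passage order patterns (NC / CN / NN / CC) arranged so the
canonical speaker utters 62 canonical tokens of 90 (69% after rounding)
and the non-canonical speaker the mirror image. Sixty filler passages
complete the 150-passage session. `build_design_exp2()` builds the blocked
variant: 150 passages, all critical, in five 30-passage blocks with
speaker order C, N, N, C, C. The source design states the token ratios
only as "approximately 70%:30%"; we realise them exactly as 126:54
canonical tokens for the canonical speaker (70% of its 180 tokens) and
36:84 for the non-canonical speaker, with pattern types interleaved across
each block so no block is a solid run of one pattern.

`pseudo_randomize()` permutes passages — fillers interspersed, blocks kept
intact — under the constraint that no more than three consecutive passages
share a uniform canonicity (mixed-order passages and fillers break runs),
then reassigns the *epoch index*, the presentation position of each
critical NP, which serves as the exposure proxy in the models.
`validate_design()` checks every invariant and rejects hand-edited
designs.

## Resting-state individual-difference metrics

`welch_psd()` is a standard Hann-windowed averaged periodogram (50%
overlap, one-sided density scaling, Parseval-consistent); no pre-installed
R package provides one, so it is implemented here and tested against
Parseval's identity and sinusoid oracles.

**Aperiodic 1/f slope** (`irasa()`): irregular-resampling auto-spectral
analysis separates the power-law background from oscillations. For each
factor h in 1.1–1.9 (step 0.05) the signal is resampled by h and 1/h
(polyphase FIR via `signal::resample`; factors expressed as rationals over
20); the geometric mean of the two PSDs leaves a power law invariant while
displacing oscillatory peaks to f/h and f·h, and the median across the
factor set suppresses them. The aperiodic slope and intercept come from
ordinary least squares on log power versus log frequency over 2–25 Hz — a
range that avoids the 0.1 Hz high-pass knee and the 30 Hz low-pass edge of
the task pipeline. The slope is reported as a positive exponent β for
1/f^β decay, with the raw (negative) regression coefficient stored
alongside.

**Individual alpha frequency** (`estimate_iaf()`): the peak alpha
frequency (PAF) is found on the background-corrected spectrum — a log-log
line fitted outside the 7–13 Hz window is subtracted, the in-window
residual is Savitzky–Golay smoothed (window 11 bins, order 5), and the
highest interior local maximum exceeding 0.15 log10 units over background
is taken. A purely aperiodic spectrum therefore yields a *missing* PAF
with a quality flag — missingness is data, not an error. The centre of
gravity (COG) is the power-weighted mean frequency over the window, so PAF
and COG can differ when the peak is asymmetric. PAF is the covariate used
in the moderation models.

**Sessions and electrodes**: metrics are computed per session and combined
by `combine_sessions()` — the mean of pre- and post-task estimates, the
available one if a session yields no estimate, and an exclusion flag if
both are missing. Multichannel input is averaged at the PSD level before
estimation; `iaf_electrodes()` and `slope_electrodes()` give the
conventional posterior and fronto-centro-parietal sets, but the choice is
an argument, not a constant.

## Single-trial ERP features

`preprocess_eeg()` applies an average reference, resampling to 500 Hz, and
a zero-phase band-pass (2nd-order 0.1 Hz high-pass cascaded with a
4th-order 30 Hz low-pass, each run forward–backward). `epoch_features()`
extracts per-trial means over the prestimulus (−200–0 ms) and N400
(300–500 ms) windows for the centro-parietal region of interest
(`cp_roi()`). Windows are half-open `[start, end)` in sample space with
the onset sample belonging to post-stimulus time — boundary conventions
the source description leaves open, fixed here and tested against
brute-force sample means. There is *no* baseline subtraction: the
prestimulus mean enters the model as a covariate instead, which avoids
baseline-induced distortions. Trials whose epoch leaves the recording are
dropped and counted, never silently. Ocular-artifact correction is out of
scope: the synthetic data contain no ocular activity, and users with real
recordings should correct artifacts upstream.

By default features are emitted per trial × channel (long format) so that
channel can enter the model as a random effect; `pool_roi = TRUE` averages
the ROI first.

## The variance-components linear mixed model

`build_model_frame()` applies the standard encodings: sum contrasts for
canonicity (canonical = +1, so the intercept is the grand mean), z-scores
for continuous predictors computed once over the analysis set (per-subject
scaling is available), and orthogonal polynomial columns for terms
modelled with higher-order trends (conventionally prestimulus amplitude to
2nd order, speaker-based surprisal to 3rd). Transform constants are stored
and re-applicable to new data.

`fit_vc_lmm()` fits LMMs with crossed random effects in which every
random-effect column is an independent *variance component* — all
random-effect correlations are structurally zero. This diagonal structure
mirrors the parsimonious models used in this literature (correlation
parameters are typically non-significant and constrained to zero) and is
what makes a transparent from-scratch fitter tractable. The implementation
profiles the deviance over the ratios θ = sd(component)/sd(residual): for
fixed θ the fixed effects, conditional modes and residual variance have
closed forms via a blocked Cholesky factorisation of the penalised normal
equations, and the profiled REML (default) or ML criterion is minimised on
the log-θ scale. We use derivative-free search (golden-section for one
component, Nelder–Mead with one restart otherwise; relative tolerance
1e-12) because quasi-Newton line searches proved fragile on the flat
profiles near component boundaries; components estimated below 2e-6 of the
residual sd are reported as exactly zero. The fitter is validated against
closed-form ANOVA/REML estimators on balanced one-way layouts, against
ordinary least squares when all components vanish, and against an
independent mixed-model implementation (lme4) to deviance agreement better
than 1e-3 on crossed designs.

Model comparison (`compare_models()`) reports dof, deviance, AIC, AICc and
BIC, with likelihood-ratio tests between successive nested ML fits — REML
is for variance reporting, ML for comparison. `re_pca()` reports each
grouping factor's component standard deviations and cumulative variance
shares, the overparameterisation diagnostic used during random-effects
selection; the stepwise selection itself is a scripted recipe for the
analyst, not an automated black box. `partial_effects()` removes the
fitted contributions of nuisance fixed terms and random components from
the observed response (keep-all returns the data bit-for-bit), which is
how effects of interest are visualised adjusted for prestimulus amplitude
and other covariates.

## The synthetic-data generator

Every generator is a pure function of its parameters and a seed, and every
latent draw is recorded, so the whole pipeline can be checked by parameter
recovery.

- `gen_embeddings()`: k Gaussian blobs with controllable
  separation/within-sd ratio; at ratio 20 clustering recovers the labels
  perfectly (adjusted Rand index 1), at ratio 0 it performs at chance.
- `gen_corpus_counts()`: bigram tokens drawn from a cluster transition
  matrix with uniform word choice within cluster; aggregated counts
  converge to the transition probabilities.
- `gen_resting_signal()`: Gaussian noise shaped in the frequency domain to
  an exact 1/f^β power law, plus narrowband alpha — white noise under a
  Gaussian spectral envelope (default FWHM 2 Hz, a realistic peak width)
  — at a controllable amplitude. Amplitude 0.3 of the broadband sd puts
  the peak roughly 1.5 log10 units over the background, a strong
  eyes-closed alpha. These signals drive the IRASA and IAF recovery tests
  (median |slope error| < 0.15 over β ∈ {0.5, 1, 1.5, 2}; PAF within
  0.25 Hz).
- `gen_participants()`: per-subject IAF (10 ± 1 Hz), aperiodic slope
  (1.3 ± 0.3) and idea density (0.5 ± 0.05 ideas/word).
- `simulate_trial_amplitudes()`: single-trial N400 amplitudes from a
  linear model with z-scored speaker-based surprisal, epoch, their
  interaction, sum-coded canonicity, optional covariate moderation of the
  interaction, crossed Gaussian random intercepts for subject, item and
  channel, a prestimulus coupling, and Gaussian noise. The surprisal
  coefficient is negative by default — larger prediction error, more
  negative amplitude. Channels are exchangeable labels; there is no scalp
  geometry, volume conduction or artifact structure, so passing tests
  validate the *statistical* pipeline, not biophysical realism.

Default effect magnitudes (intercept 1, surprisal −1.5, epoch 0.5,
surprisal × epoch −0.5, canonicity 0.5 µV; subject/item/channel sds
2/0.5/0.5 µV; residual 5 µV) are arbitrary in the sense that no empirical
coefficients are being reproduced; they were chosen once to be of
realistic ERP magnitude and to make recovery studies informative.

## Calibration of the end-to-end pipeline

`recovery_study()` repeats simulate → fit → test at a scaled-down study
size (20 subjects × 60 items × 1 pooled channel; 60 items = 30 passages of
the full design, keeping the randomised order and the incremental
surprisal computation). At 200 replicates the surprisal × epoch
coefficient shows type-I error compatible with 0.05 under a null truth,
negligible bias, and Wald CI coverage near nominal (REML standard errors).

One property of these study conditions deserves emphasis. Incremental
surprisal is heteroskedastic by construction: smoothing pins early trials
near log k, and the spread grows as each speaker's counts differentiate
(empirically the within-session variance roughly triples). The
surprisal × epoch product therefore correlates around 0.4 with the
surprisal main effect, inflating the interaction coefficient's sampling
variance by a factor of about 1.5 relative to an orthogonal design. At the
scaled size this caps achievable power for a −0.5 µV/sd interaction at
roughly 0.8 *in the best case* (zero random-effect variance, exact
standard errors); realised power in our calibration runs fluctuates
between about 0.6 and 0.8 across design realisations. This is a property
of the measure, not a defect of the fitter — the same fits are correctly
calibrated under the null and cover the truth at nominal rates — and it
disappears at the full design size. Analysts planning scaled-down
pilots should expect it.

## Known limitations

- The LMM fitter supports diagonal variance-component structures only; no
  correlated slopes, GLMMs or Bayesian estimation.
- Synthetic EEG omits ocular artifacts, volume conduction and
  non-stationarity; preprocessing is validated on its filtering/epoching
  contracts, not on artifact handling.
- The word-level language model is deliberately limited to the unigram
  frequency covariate; all n-gram structure lives at the cluster level.
- Elbow selection automates what is conventionally a visual judgement;
  k = 6 remains the default for the adjective materials, and the curve is
  always returned for inspection.
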