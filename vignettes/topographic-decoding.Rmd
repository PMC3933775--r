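---
title: "Decoding auditory categories from single-trial voltage topographies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding auditory categories from single-trial voltage topographies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the generative model
behind the decoder, the statistics wrapped around it, the synthetic data
the test suite runs on, and the numerical and design choices that a reader
should know before trusting (or modifying) a result.

## 1. Why topographies

Clinical auditory-evoked-potential work classically asks whether a specific
waveform (the N100) appears at a pre-selected electrode and latency. In
pathological recordings — early coma being the motivating case — evoked
responses are frequently present but atypical: shifted latencies,
non-prototypical scalp distributions, low amplitudes. Every analysis in
this package therefore operates on the *whole voltage topography*, the
vector of all electrode values at one instant, which is reference-free
after average referencing and requires no prior choice of electrode or
latency. Two consequences follow:

- presence of *any* reproducible response can be tested by asking whether
  the trial-average topography is more structured than electrode-shuffled
  surrogates (the topographic consistency test, section 5);
- a *difference* between two stimulus categories can be detected wherever
  and whenever their topographies differ, by modeling each category's
  topography distribution and comparing likelihoods (sections 2–4).

## 2. The condition model

For one recording and one condition, all average-referenced topographies
$x_i(t)\in\mathbb{R}^{d}$ ($d$ electrodes; all trials $i$, all latencies
$t$ pooled) are treated as draws from a $K$-component Gaussian mixture.
The component means are the condition's *template maps* — recurring scalp
patterns — and the mixture weights how often they occur.

Fitting choices (`fit_condition_gmm()`):

- **Diagonal covariances** by default. The pooled sample is large (tens of
  thousands of topographies) but the purpose of the model is density
  *comparison*, not generative realism; diagonal components keep the fit
  fast, stable, and well-conditioned at $d = 19$. Average referencing
  makes the data rank-deficient by one dimension, which a full covariance
  would have to regularize away.
- **EM with k-means initialization**, 5 restarts (each restart runs a
  short EM of 20 iterations from a fresh k-means solution on a subsample
  of at most 3000 topographies; the best restart continues to
  convergence). Convergence is declared when the relative log-likelihood
  change falls below `tol = 1e-4`, with a cap of 300 iterations.
- **Covariance floor** of $10^{-6}\times$ the pooled per-channel variance:
  components cannot collapse onto single points; a component whose
  responsibility mass still vanishes triggers a re-seeded restart, and
  after five such failures the fit errors rather than returning a
  degenerate model.
- $K = 1$ is computed in closed form (the grand mean and per-channel
  variances), which also pins the EM implementation down in tests.

## 3. Discriminative periods and classification

With mixtures $p(x\mid A)$ and $p(x\mid B)$ fitted on the training trials,
each trial yields a log-likelihood-ratio trace
$\mathrm{LLR}_i(t) = \log p(x_i(t)\mid A) - \log p(x_i(t)\mid B)$, and

$$D(t) = \overline{\mathrm{LLR}(t)}^{A} - \overline{\mathrm{LLR}(t)}^{B}$$

is non-negative in expectation wherever the two sets of template maps
differ. The discriminative periods $H$ (`select_periods()`) are the
maximal runs of consecutive latencies with $D(t)$ at or above its 0.9
quantile, keeping runs of at least 20 ms. Both numbers are tunable and
logged; the quantile sets how selective $H$ is (0.9 keeps roughly the top
decile of latencies), and the minimum duration suppresses single-sample
flickers that carry no physiologically plausible signal. Two degenerate
cases are defined explicitly: if no run is long enough, or if $D$ is
constant (a top quantile is then meaningless), $H$ falls back to the
single minimum-duration window centred on the earliest maximum of $D$.
Ties break toward the earliest latency, and the selected-$K$ tie in
cross-validation breaks toward the smallest $K$ — both choices are
deterministic and documented rather than RNG-dependent.

A held-out trial is scored by $\sum_{t\in H}\mathrm{LLR}(t)$; positive
scores favour condition A (the alphabetically first label). Decoding
performance is the AUC in its Mann–Whitney form (ties count one half), so
it is invariant under any monotone transformation of the scores.

`cross_validate()` selects $K$ over a grid (default $1\ldots8$) by 6-fold
stratified cross-validation on the CV set — non-overlapping test folds
whose per-condition sizes differ by at most one — maximizing the mean
test-fold AUC, then refits the mixtures and $H$ on the full CV set.

**Decimation.** Epochs are decimated by a factor of 4 (1024 Hz to 256 Hz)
before fitting, classification and permutation, identically in every
branch. The data are low-pass filtered at 40 Hz upstream, far below the
decimated Nyquist of 128 Hz, so this loses essentially nothing while
cutting the pooled sample fourfold.

## 4. Significance of a decoding result

`permutation_validate()` implements the full-pipeline null: the CV labels
are permuted, *both* mixtures are refitted and $H$ is re-estimated per
permutation (the conservative choice — the null model gets every chance
the true model had), and the same validation trials are rescored. $K$ is
*not* re-selected per permutation: it is treated as a fixed structural
parameter so the null is comparable and the cost linear in `n_perm`
(default 200).

The decision rule compares the observed AUC against the permutation AUCs
with a one-sided Wilcoxon signed-rank test on the differences
$\mathrm{AUC}_{\mathrm{true}} - \mathrm{AUC}_{\mathrm{perm},m}$ (one-sided
because only out-performing the null counts as decoding). The p-value is
exact for up to 25 non-zero differences (sign-flip enumeration via a
rank-sum recursion, valid under midranks), and a tie-corrected normal
approximation with continuity correction beyond.

**Calibration caveat.** All $n$ differences share the single observed AUC,
so they are strongly dependent, while the signed-rank null assumes
independent signs. Under label exchangeability (no effect), the observed
AUC is exchangeable with the permutation AUCs, and the signed-rank
decision then fires far more often than its nominal level — simulation
puts the per-recording rate near 0.3–0.4 at $\alpha = 0.05$ with 50
permutations. This is a property of the decision rule itself, not of the
implementation. The package therefore also reports the empirical
permutation p-value
$p_{\mathrm{perm}} = (1 + \#\{\mathrm{AUC}_{\mathrm{perm}} \ge
\mathrm{AUC}_{\mathrm{true}}\})/(n_{\mathrm{perm}}+1)$, which *is*
calibrated as a per-recording test, and the acceptance script reports the
null firing rates of both rules side by side. The `significant` flag
follows the signed-rank rule for fidelity to the established procedure;
anyone using these results for inference should prefer `p_perm` or treat
the flag's per-event rate as an empirical quantity — which is exactly what
the group-level binomial test does.

**Group level.** `min_significant_count(n, p_event, alpha_group)` returns
the smallest $k$ with $P(X \ge k \mid n, p_{\mathrm{event}}) \le
\alpha_{\mathrm{group}}$ by exact binomial tails ($\le$, the conventional
“significant at level $\alpha$” rule, which also makes the boundary
$\alpha_{\mathrm{group}} = 1 \Rightarrow k_{\min} = 0$ behave). The
per-event probability $p_{\mathrm{event}}$ is a *required* input: it is
the empirical chance rate of the per-recording decision, not a nominal
$\alpha$, for the reason above. A practical default is the median across
recordings of the empirical fraction of permutation AUCs at or above the
true AUC. With $n = 35$ and $p_{\mathrm{event}} = 0.2$, $k_{\min} = 12$.
`group_decode()` additionally implements pooled-subject decoding: fixed
per-subject quotas (defaults 20 CV + 4 V trials per condition per subject)
are drawn and pooled, one mixture pair is fitted across subjects, and the
standard validation runs on the pooled sets — 10 subjects give 200 CV and
40 V trials per condition.

## 5. Topographic consistency test

`run_tct()` asks, per latency, whether the trial-average topography has
more spatial structure (global field power, the spatial standard
deviation) than expected if electrode assignment were arbitrary: each
trial's channel values are shuffled across electrodes (independently per
trial and per randomization), the shuffled trials are averaged, and the
GFP of that average forms the null. The add-one estimate
$p(t) = (1 + \#\{\mathrm{GFP}_{\mathrm{null}} \ge
\mathrm{GFP}_{\mathrm{obs}}\})/(n_{\mathrm{rand}}+1)$ avoids $p = 0$;
`n_rand` defaults to 1000 and at least 100 is enforced (a coarser null
cannot resolve useful significance levels). Multiplicity across latencies
is handled by Benjamini–Hochberg FDR (`fdr_mask()`, default $q = 0.05$); a
separate *display* mask at $1-p > 0.999$ reproduces the conventional
strict-threshold view and needs $n_{\mathrm{rand}} \ge 999$ to be
attainable. The shuffling is within-trial across electrodes only —
shuffling across trials as well would also destroy per-trial amplitude
structure and test a different null. A convenience summary flags whether
any FDR-significant run intersects 100 ± 50 ms, the classical N100 band.

## 6. Stimulus acoustic controls

`spectrogram()` uses non-overlapping rectangular windows (5 ms default)
zero-padded to $\mathrm{round}(\mathrm{rate}/\mathrm{bin_{Hz}})$ samples,
one-sided power normalized so each time bin's total equals the window
energy. The frequency bin width defaults to 74 Hz; 160 Hz — an alternative
binning in circulation for the same analysis — is available by argument,
and nothing downstream depends on the choice. `bootstrap_bin_test()`
compares two groups of spectrograms bin-wise: the observed difference of
group means (a Welch $t$ per bin is available via `statistic = "t"`; the
mean difference is the default because the bootstrap already supplies the
null spread) against `n_boot` (default 5000) resamples drawn with
replacement from the *pooled* group — the exchangeability null, chosen
because the groups are fixed stimulus sets, not samples from known
populations. Two-tailed add-one p-values feed a 3 × 3 spatial criterion
(`spatial_threshold()`): a bin counts only if all eight neighbours are
also sub-threshold, so isolated bins and all border bins are excluded. The
same machinery applies to time-averaged power spectra (1-D), with a
3-neighbour line criterion. `hnr()` summarizes periodicity as the
framewise (30 ms / 10 ms) maximum normalized autocorrelation $r$ over lags
corresponding to 50–500 Hz, mapped to $10\log_{10}(r/(1-r))$ dB: harmonic
vocal-like sounds land above 30 dB, white noise near −8 dB, an equal-power
mix near 0 dB.

## 7. The synthetic session generator

The generator (`stimulus_design()`, `make_schedule()`, `sim_eeg_config()`,
`simulate_epochs()`, `inject_artifacts()`, `synth_sound()`) emulates the
study design so every stage above can be tested against known ground
truth:

- **Protocol.** 4 blocks; 12 animal + 8 human + 20 man-made exemplars,
  each twice per block (80 trials/block; 96/64/160 trials per category);
  500 ms sounds at 22,500 Hz; ISI 2 ± 0.2 s. Pseudo-randomization is a
  uniform shuffle of the per-block exemplar multiset — the simplest
  reproducible choice, with no constraint on immediate repeats — and the
  ISI jitter is uniform on ±0.2 s.
- **Epochs.** One epoch per event on $[-0.1, 0.8)$ s, half-open in
  continuous time with half-away-from-zero index rounding: 922 samples at
  1024 Hz (indices −102…819). Each epoch is the sum of (i) a common
  evoked component — a fronto-central negativity with Gaussian time
  course, peak −5 µV at 100 ms, width 15 ms, the N100 idealization;
  (ii) an optional condition effect: zero-mean unit-norm left/right
  temporal patterns, confined to a window (default 0.30–0.40 s) under a
  cosine-ramped boxcar envelope (10 ms ramps — band-limited, so filtering
  artifacts cannot masquerade as effects; an exact boxcar is available
  for identity tests); and (iii) spatially correlated Gaussian noise,
  correlation $\exp(-d/0.4)$ over schematic 10–20 electrode positions
  (head-radius units), per-channel SD 10 µV. `separation_to_amplitude()`
  converts a desired class-mean separation in noise-SD units into the
  effect amplitude. A *coma mode* scales the common component to 30% and
  delays it by 80 ms, a fixture convention for atypical patient responses.
- **Artifacts.** Each trial is hit with probability `rate` by a 100 ms
  single-channel square pulse of ±`amplitude` (default 150 µV, chosen to
  trip the ±100 µV rejection); the selected trials are recorded so
  rejection can be checked exactly.
- **Sounds.** Harmonic complexes (jittered harmonics, 1/k roll-off) and
  noise bursts, RMS-normalized like the experimental stimuli — enough
  spectral contrast to exercise the acoustic controls, with no pretension
  to formant-level realism.

What the generator deliberately does **not** emulate: physiological
artifact taxonomy (blinks, EMG, electrode drift), non-Gaussian and
non-stationary background EEG, volume-conducted source structure beyond
the exponential spatial correlation, and any acoustic realism beyond
harmonicity. Green tests therefore certify the *statistical machinery* —
calibration, power under a known effect, determinism, arithmetic — not
performance on real patient EEG.

## 8. Preprocessing choices

- **Filtering** (`bandpass_notch()`): channels are demeaned, then pass a
  0.1–40 Hz band-pass realized as cascaded 2nd-order Butterworth high- and
  low-pass sections plus a Q = 35 biquad notch at 50 Hz, every section
  applied forward–backward (zero phase, magnitude order doubled). The
  cascade realization is numerically robust at the extreme normalized
  corner of 0.1 Hz / 512 Hz, where a direct high-order band-pass
  polynomial is ill-conditioned. Zero-phase filtering is the analysis
  choice here (no causal latency shifts); demeaning first removes the DC
  pedestal that would otherwise leak through filter edge transients.
- **Epoching** (`extract_epochs()`): no baseline correction; events
  without full window support are skipped with a warning and logged.
- **Rejection** (`reject_artifacts()`): a single exceedance of ±100 µV on
  any channel at any sample drops the whole trial — per-trial rejection is
  what per-condition rejection percentages refer to. Rejection is monotone
  in the threshold.
- **Splitting** (`split_cv_validation()`): exactly 60 CV trials per
  condition drawn uniformly without replacement (randomness decouples the
  split from slow drifts along the session); the remainder is the
  validation set, with a hard floor of 1 and a warning below 20 per
  condition; fewer than 61 accepted trials in either condition excludes
  the recording, mirroring the clinical exclusion rule. The living vs.
  man-made comparison reuses the same accepted pool and the same
  $n_{\mathrm{cv}} = 60$.

## 9. Problem sizes used by the tests and acceptance script

Simulated decoding experiments use 20 independent recordings per
condition-of-interest, each with 90 trials per decoding condition (60 CV +
30 V), 19 channels at 1024 Hz decimated to 256 Hz, $K$ grid 1–3, 6 folds,
and 50 permutations — a geometry that keeps a full run in minutes on one
core while preserving the study's per-condition CV size. TCT and acoustic
calibrations use 10 seeds at reduced grid sizes with `n_rand = 150` and
`n_boot = 500`. These sizes are stated here as the package's chosen
experimental conditions; all of them are arguments, and nothing in the
implementation depends on them.

## 10. Known limitations

- The signed-rank significance flag is anticonservative as a per-recording
  test (section 4); `p_perm` is the calibrated alternative and both are
  always reported.
- Diagonal mixture covariances ignore within-component channel
  correlations; they bias the model toward more components rather than
  corrupting the comparison, but full-covariance fitting (available via
  the internal EM's structure) would need shrinkage at $d = 19$.
- The TCT's electrode-shuffling null treats channels as exchangeable under
  the null; strong channel-variance heterogeneity (e.g. one noisy
  electrode) makes it liberal, which matters for real recordings and is
  invisible in the homogeneous simulations.
- Group pooling assumes a shared discriminative topography across
  subjects; inter-subject topographic variability dilutes it by design.
- The EDF reader covers standard 16-bit continuous recordings with a
  uniform sampling rate; EDF+ annotations are skipped, discontinuous
  files are not supported.
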