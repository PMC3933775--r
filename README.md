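# topodecode

Single-trial EEG decoding of auditory stimulus categories from scalp voltage
topographies, with the complete statistical machinery needed to call a
discrimination real: label-permutation null models, a signed-rank decision, a
group-level binomial test, the topographic consistency test, and
acoustic-control statistics for the stimuli themselves. A synthetic-session
generator with known ground truth makes every stage testable end to end
without any patient data.

## The problem

Whether the brain still discriminates categories of environmental sounds
(human vs. animal vocalizations, living vs. man-made sources) when the
subject is unconscious is a question that clinical EEG can address: present
sounds at the bedside, record a 19-channel 10--20 EEG, and ask whether the
single-trial responses to the two categories are statistically
distinguishable *within each patient*. Comatose patients' evoked responses
often lack the prototypical N100 waveform, so the analysis must not
presuppose canonical components, latencies or electrodes. Working on whole
voltage topographies does exactly that:

- **Model.** For each condition $c$, the instantaneous topographies
  $x_i(t) \in \mathbb{R}^{19}$ (average-referenced; all trials, all
  latencies pooled) are modeled by a Gaussian mixture
  $p(x \mid c) = \sum_{k=1}^{K} w_k \, \mathcal{N}(x;\ \mu_k^{(c)}, \Sigma_k^{(c)})$,
  whose component means $\mu_k^{(c)}$ are the condition's *template maps*
  (diagonal $\Sigma$, EM with k-means initialization and restarts).
- **Discriminative periods.** The per-latency score
  $D(t) = \langle \mathrm{LLR}_i(t) \rangle_{i \in A} - \langle \mathrm{LLR}_i(t) \rangle_{i \in B}$,
  with $\mathrm{LLR}_i(t) = \log p(x_i(t)\mid A) - \log p(x_i(t)\mid B)$,
  is thresholded at its 0.9 quantile; maximal runs of at least 20 ms form
  the discriminative periods $H$.
- **Classification.** A held-out trial's score is
  $\sum_{t \in H} \mathrm{LLR}(t)$; performance is the AUC
  (Mann--Whitney). $K$ is chosen by 6-fold cross-validation on a CV set of
  60 trials per condition; the remaining trials form an untouched
  validation set.
- **Significance.** The CV labels are permuted 200 times, both mixtures and
  $H$ are refitted per permutation, and the same validation trials are
  rescored; the observed AUC is compared against the permutation AUCs with
  a one-sided Wilcoxon signed-rank test, and the mean permutation AUC is
  reported as the chance level. Across recordings, a binomial test on the
  number of significant comparisons gives the group-level decision.
- **Evoked-response presence.** The topographic consistency test (TCT)
  compares the global field power (GFP) of the trial-average map at each
  latency with a null obtained by shuffling each trial's values across
  electrodes, with Benjamini--Hochberg FDR correction.
- **Stimulus controls.** Binned spectrograms (5 ms x 74 Hz, rectangular
  windows, zero-padded FFT), bootstrap bin-wise tests with a 3 x 3 spatial
  threshold, and harmonics-to-noise ratios verify that category membership
  is not trivially explained by acoustics.

## Worked example

A fully synthetic session: the default stimulation protocol (4 blocks x 80
trials; 12 animal + 8 human + 20 man-made exemplars, twice per block, ISI
2 +/- 0.2 s), an N100-like evoked component, and a planted animal-vs-human
topographic effect in 0.30--0.40 s at 2-sigma single-trial separation.

```r
library(topodecode)

cfg <- sim_eeg_config(effect = default_effect(window = c(0.3, 0.4)))
cfg$effect$amplitude <- separation_to_amplitude(cfg, 2)
sched  <- make_schedule(stimulus_design(), eeg_rate = 1024, seed = 1)
epochs <- simulate_epochs(sched, cfg, seed = 2)
epochs
#> epoch_set: 320 trials x 19 channels x 922 samples @ 1024 Hz, t in [-0.100, 0.800] s
#>   labels: animal (96), human (64), manmade (160)

acc <- reject_artifacts(inject_artifacts(epochs, rate = 0.05,
                                         amplitude = 150, seed = 3))
acc$report
#>         condition n_total n_rejected   fraction
#> animal     animal      96          8 0.08333333
#> human       human      64          2 0.03125000
#> manmade   manmade     160          2 0.01250000

sp  <- split_cv_validation(acc$epochs, list(animal = "animal", human = "human"),
                           n_cv = 60, seed = 4)
dec <- cross_validate(sp$cv, K_grid = 1:3, n_folds = 6, seed = 5)
dec
#> trained_decoder: animal vs human, K = 1 (grid 1-3), CV AUC = 1.000, 1 H window(s) @ 256 Hz

res <- permutation_validate(sp$cv, sp$v, dec$K_selected, n_perm = 200, seed = 6)
res
#> decoding_result: animal vs human
#>   AUC = 1.000 (chance 0.469 over 200 permutations)
#>   signed-rank p = 3.24e-34 (significant at alpha = 0.001); empirical p_perm = 0.0249

tct <- run_tct(subset_trials(acc$epochs, acc$epochs$labels == "manmade"),
               n_rand = 1000, seed = 7)
tct
#> tct_result: 28/922 timepoints FDR-significant (q = 0.05, 1000 randomizations); consistency within 100 +/- 50 ms
```

The planted effect is recovered (validation AUC 1.0 against a chance level
near 0.5, with the discriminative period inside the true window), and the
TCT detects the simulated evoked response in the classical N100 band even
though no electrode or latency was pre-selected. For real data, ingest a
recording with `read_edf()`, filter with `bandpass_notch()` (0.1--40 Hz
band-pass, 50 Hz notch), epoch with `extract_epochs()` (-100--800 ms, no
baseline correction) and reject at +/- 100 uV before the same steps.

## Vignette

`vignettes/topographic-decoding.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, the numerical choices
(tie-breaks, floors, fallbacks), and known limitations — including the
calibration caveat of the signed-rank significance decision.
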