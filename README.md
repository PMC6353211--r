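# tfdwell

Single-molecule kinetics and target-gene activity of nuclear
transcription factors, in one tested R package.

Live-cell single-molecule tracking (SMT) of a labelled DNA-binding
protein — an NF-kB subunit such as p65 is the motivating case — yields
trajectories from which one wants the protein's chromatin residence
times, its bound fraction, and ultimately how those kinetics relate to
the transcriptional output of its target genes. Getting there requires a
chain of corrections and fits, each easy to get subtly wrong: linking
localizations into tracks, filtering bound molecules with spatial and
temporal thresholds, correcting apparent dwell times for photobleaching
against an immobile histone control, selecting between one- and
two-exponential dwell models, and decomposing displacement histograms
into diffusive components. `tfdwell` implements this chain, the matching
FRAP recovery analysis, and the downstream classification of
transcription-factor variants from expression data — plus seeded
simulators for trajectories, FRAP curves and count matrices so every
estimator is validated by parameter recovery against known ground truth.

## The models in brief

**Residence times.** Bound durations follow a two-class exponential
mixture. The survival (1-CDF) curve of apparent durations is corrected by
pointwise division with the survival curve of an immobile control imaged
identically,

    S_corrected(t) = S_target(t) / S_control(t),

which cancels photobleaching, then fitted with
`y = A1 exp(-t/t_fast) + A2 exp(-t/t_slow)`; an F-test on the residual
sums of squares decides whether the second class is supported.

**Bound fraction.** Single-step displacements at a 20 ms interval are fit
with a Rayleigh mixture

    p(r) = r * sum_i  f_i / (2 D_i dt) * exp(-r^2 / (4 D_i dt)),

and the weight of the slowest component — when its diffusivity matches
the chromatin reference ~0.04 um^2/s — is the bound fraction BF, from
which `k_on* = k_off * BF / (1 - BF)`.

**FRAP.** Double-normalized recovery curves are fitted with
`FRAP(t) = I1 (1 - exp(-t/tau1)) + I2 (1 - exp(-t/tau2))`, and the global
half-time solves `I1 (0.5 - exp(-t/tau1)) + I2 (0.5 - exp(-t/tau2)) = 0`
numerically.

**Variant classification.** Genes with a ChIP peak in the strand-aware
promoter+gene window (2 kb upstream pad) are kept; per-gene log2 fold
changes versus the non-transfected reference are compared between mutant
and wild type, and the median per-gene difference (the "logFC ratio")
calls each variant a gain or loss of function.

## A worked example

Simulate a wild-type-like slow-movie acquisition together with an
immobile control, then run the residence analysis:

```r
library(tfdwell)

cfg <- smt_sim_config(n_molecules = 20000, frac_bound = 1,
                      t_fast = 0.53, t_slow = 4.13, frac_slow_bound = 0.043,
                      p_bleach = 0.01, p_blink = 0.02, seed = 42)
tracks <- tracks_from_truth(simulate_tracks(cfg)$localizations)

ctl <- smt_sim_config(n_molecules = 15000, frac_bound = 1,
                      t_fast = Inf, t_slow = Inf,
                      p_bleach = 0.01, p_blink = 0.02, seed = 43)
control <- tracks_from_truth(simulate_tracks(ctl)$localizations)

ks <- estimate_binding_times(tracks, control)
cat(sprintf("model %d | t_fast %.2f s | t_slow %.2f s | slow fraction %.1f%%\n",
            ks$chosen_model, ks$t_fast, ks$t_slow, 100 * ks$frac_slow))
#> model 2 | t_fast 0.54 s | t_slow 3.70 s | slow fraction 4.0%
```

The F-test selects the two-component model and the fit returns the
short- and long-lived dwells (truth: 0.53 s and 4.13 s) and the
long-lived share of binding events (truth: 4.3%). At this deliberately
small example size (~4,000 filtered events) the long dwell carries a
~10% sampling spread; the acceptance script below runs the same
experiment at three times the size, where the spread tightens to a few
percent. The same pattern works for the displacement analysis:

```r
fast <- smt_sim_config(n_molecules = 700, frac_bound = 0.30,
                       frac_slow = 0.35, frac_free = 0.35,
                       D_bound = 0.04, D_slow = 0.5, D_free = 5,
                       t_fast = Inf, t_slow = Inf, p_bleach = 0.01,
                       p_blink = 0, sigma_loc = 0, t_gap = 0.015, seed = 44)
ssd <- single_step_displacements(
  tracks_from_truth(simulate_tracks(fast)$localizations), dt = 0.02)
fit <- fit_diffusion_components(ssd, n_components = 3)
round(100 * bound_fraction(fit), 1)
#> [1] 28
```

`run_smt()` / `run_all()` wire the stages together from a single seeded
configuration and write CSV/JSON reports plus a manifest.

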