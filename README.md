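# neostress

Bradycardia-based stress classification for neonatal multichannel
physiology.

## The problem

Preterm infants in the NICU experience bradycardias — transient heart-rate
drops, here defined as RR-interval elongations above 1.5× the record-mean RR
lasting at least 4 s — that typically co-occur with SpO₂ desaturations.
Accumulated procedural pain ("stress load", any non-zero pain-scale score
the day before a recording) appears to change the physiology of these
hypoxic events: deeper desaturations, more regular (discontinuous) EEG, and
stronger brain–heart coupling.  `neostress` turns that contrast into an
event-based classifier for researchers working on neonatal stress and
network physiology:

1. **Detect** bradycardias and desaturations (thresholds 3/5/10 % below a
   running-median baseline), pair them into hypoxic events, and cut 6-min
   windows with pre/during/post epochs around each bradycardia peak.
2. **Extract** per-event features: temporal and wavelet-spectral HRV and
   SpO₂ statistics (HF = (0.2–4] Hz, LF = (0.08–0.2] Hz), Poincaré
   descriptors (SD₁, SD₂, centroids), phase-rectified signal averaging
   slopes (T ∈ {1, 5, 10, 20, 50, 100} s), EEG delta-band power statistics,
   wavelet-leader multifractal log-cumulants (c₁, c₂), and topology indices
   (path length, efficiency, clustering, eccentricity, number of
   superfluous connections n_sup) of a 10-node coupling graph built from
   surrogate-validated imaginary wavelet coherence between the 8 EEG
   delta-power envelopes, the RR series and SpO₂ (19 AAFT surrogates,
   α = 0.05; VLF band (0.033–0.08] Hz for the youngest monitoring group,
   LF for the others).
3. **Classify** each event as belonging to a stressed vs non-stressed
   patient with a subspace-LDA ensemble (random feature subsets of size
   ⌊n/10⌋, stratified bagging, fold-internal F-score ranking, 90 %
   correlation cap and PMA age correction), evaluated with
   leave-one-patient-out cross-validation; pooled test scores give the AUC
   and Cohen's κ per monitoring group and desaturation threshold.

Clinical recordings of this kind are not publicly available, so the package
includes a synthetic-cohort generator (`generate_cohort()`) with
independently controllable stress effect sizes; every stage, including the
end-to-end classifier, is tested against that ground truth.  See the
methods vignette (`vignettes/neostress-methods.Rmd`) for the full model
description and all numerical choices.

## Worked example

```r
library(neostress)

config <- pipeline_config(rng_seed = 7)
cohort <- cohort_spec(n_subjects = 6, groups = "34weeks",
                      record_duration_s = 1500, events_mean = 3,
                      rng_seed = 7)

report <- run_pipeline(cohort, config, thresholds = c(3, 10))
report
#> <stress_report> leave-one-patient-out stress classification
#>    group threshold       auc     kappa n_events n_subjects flag
#>  34weeks         3 0.9898990 0.9000000       20          6
#>  34weeks        10 0.7857143 0.1818182        9          5
```

Each row is one monitoring-group × desaturation-threshold cell: events
paired at a deeper threshold are fewer (here 9 of 20 survive the 10 %
threshold, and one subject loses all its events), and the pooled
leave-one-patient-out AUC (≈ 0.99 at the 3 % threshold on this small cohort
with the default stress effect sizes) measures how well the per-event
features separate events of stressed subjects from controls; κ is the
chance-corrected agreement of the hard labels at a posterior of 0.5 and is
much noisier at small event counts.  On a null cohort
(`espec = null_effects()`) the AUC falls to chance level.

Lower-level entry points: `detect_events()` (one record's paired events),
`assemble_features()` (the per-event feature table; columns are documented
by `feature_registry()`), `lopo_evaluate()` (classification of an existing
table), `log_cumulants()`, `wavelet_coherence()`, `build_coupling_graph()`.
A thin command-line wrapper lives at `inst/scripts/neostress.R`.

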