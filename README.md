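# sersflow

Event detection and peptide classification for flow-through single-molecule
SERS.

## The problem

In flow-through surface-enhanced Raman spectroscopy (SERS), peptides are
driven electrophoretically through sub-2 nm plasmonic nanopores and read out
one molecule at a time: each translocation produces a burst of roughly 120
Raman photons, recorded by a single-photon avalanche diode (SPAD) camera as
a stream of 100 µs photon-count spectra over the 1000–1600 cm⁻¹
fingerprint window. The analytical challenge is that two clinically relevant
peptide hormones — oxytocin (OT) and vasopressin (VP), nine residues each,
differing only at positions 3 and 8 — have nearly identical fingerprints,
and single-event spectra fluctuate strongly. `sersflow` implements the full
analysis chain for this experiment, driven by a calibrated synthetic
generator so every stage is testable without instrument data:

1. **Synthesis** — Poisson photon background with slow sinusoidal drift,
   translocation events as a Poisson process with Poisson(Λ = 120) photons
   per event allocated by a per-event Dirichlet-perturbed emission
   fingerprint, dead/stuck detector channels, ground-truth event logs.
2. **Preprocessing** — removal of faulty detector channels; per-frame
   adaptive Wiener smoothing along the spectral axis.
3. **Event detection** — photon time trace by summing channels per frame;
   segmented local-median baseline subtraction; thresholding at
   *k* × robust scale (1.4826 × MAD); single-event spectra summed from the
   raw (unsmoothed) counts.
4. **Classification** — Yeo–Johnson power transform and 10-component PCA
   fitted on the training fold only, random forest (200 trees), repeated
   stratified 70/30 evaluation with accuracy, precision, recall and F1
   computed from TP/TN/FP/FN; N-event averaging curves plus the exact
   binomial majority-vote oracle
   P(correct) = Σ_{k>N/2} C(N,k) p^k (1−p)^{N−k} (+ ½ tie term).
5. **Mixture composition** — three-class protocol (OT, VP, MIX): mixture
   test spectra redistributed into the pure classes give a VP:OT ratio per
   random split; the histogram mode over 300 splits estimates the
   concentration ratio, with an exact hypergeometric
   sampling-without-replacement reference for its spread.

The one free parameter of the generator — the template separation δ at the
two discriminating residues — is frozen by `calibrate_separation()` so that
the single-event protocol operates at ~70.5 % held-out accuracy, the
regime where averaging ~40 events pushes discrimination past 99 %.

## Worked example

```r
library(sersflow)

# simulate 2 s of acquisition (20,000 frames, ~200 events) and detect events
sim <- generate_frame_stream(generator_config(n_frames = 20000, seed = 3))
det <- run_event_detection(sim$stream)
match_events(det$intervals, sim$events)
#>   n_detected n_truth n_matched precision recall    f1
#> 1        211     213       210     0.995  0.986 0.991
glance(photon_statistics(det$spectra))
#>       n  mean median    sd
#> 1   211  118.    117  18.5

# 400 spectra per class at the calibrated separation; 10x stratified 70/30
d  <- generate_event_spectra(800, generator_config(seed = 211),
                             composition = c(OT = 0.5, VP = 0.5), exact = TRUE)
ev <- evaluate_multirun(d, protocol_config(seed = 211))
glance(ev)
#>   mean_accuracy sd_accuracy n_runs macro_precision macro_recall macro_f1
#> 1         0.692      0.0267     10           0.692        0.692    0.692
majority_vote_tail(glance(ev)$mean_accuracy, 40)
#> [1] 0.9940
```

The detector finds essentially every simulated translocation (precision
0.995, recall 0.986) and detected events average ~118 photons, matching the
Λ = 120 photon budget once edge-frame losses and in-window background
cancel. Single events are classified at ~69 % on this dataset draw
(dataset-to-dataset spread is about ±2.5 points around the 70.5 %
operating point), and the exact majority-vote bound shows that 40 such
events identify the peptide with ~99.4 % reliability. `autoplot()` methods
produce the time-trace, accuracy-curve and ratio-histogram figures;
`tidy()`/`glance()` return per-run and one-row summaries.

## Scope and caveats

The generator reproduces the statistical structure of the experiment, not
its physics: no plasmonic field simulation, no electrophoretic transport,
no detector dead-time. Event information content is homogeneous by design
(every event carries ~Poisson(120) photons), which makes the
mixture-redistribution ratio estimator compress strongly unbalanced
compositions toward 1 — see the methods vignette
(`vignettes/sersflow-methods.Rmd`) for the analysis and for all numerical
design choices.
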