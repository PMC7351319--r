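# flimpipe

Fluorescence lifetime imaging (FLIm) analysis for intraoperative tissue
discrimination, with a full synthetic instrument simulator so every stage
is verifiable without clinical data.

## The problem

Point-scanning FLIm instruments excite tissue autofluorescence with a
pulsed UV laser and record, for every scanned point, a single digitized
voltage trace containing four time-multiplexed spectral channel responses
(CH1 390 ± 20 nm, CH2 470 ± 14 nm, CH3 542 ± 25 nm, CH4 629 ± 26.5 nm,
sampled at 80 ps).  During robotic head-and-neck surgery such measurements
can flag neoplastic mucosa that neither white light nor (absent) tactile
feedback reveals.  Turning raw traces into a decision aid requires:

1. **Deconvolution** — each measured channel decay is the instrument
   response function (IRF) convolved with the fluorescence impulse
   response h(t).  We expand h on L orthonormal discrete-time Laguerre
   functions and solve the constrained least squares problem

       min_c || y − (IRF ⊛ Φ) c ||²   s.t.   Φc ≥ 0,  diff(Φc) ≤ 0

   (a nonnegative, non-increasing decay), exactly, through the dual
   nonnegative least-squares problem.  The **average lifetime** is the
   first moment τ_avg = Σ t·h(t) / Σ h(t); the **intensity ratio** of a
   channel is its decay integral over the summed integrals (CH4 is
   excluded from analysis, leaving 6 parameters: τ and ratio for CH1–3).
2. **Localization** — a blue-violet aiming beam marks the fiber position
   in 1280 × 720 white-light frames; it is segmented by HSV thresholding,
   morphological opening/closing, and an intensity-weighted centroid.
3. **Coregistration & filtering** — histology annotations are grayscale
   images (codes for healthy epithelium, cancer, tumor bed, …).  Points
   are labeled within a 10 px radius, excluded near heterogeneous tissue,
   filtered at 30 dB SNR on all channels, and MAD-filtered per patient
   (|x − median| ≤ 2.5·MAD).
4. **Discrimination** — per patient and imaging context (in vivo
   pre-resection, ex vivo specimen, in vivo tumor bed): Wilcoxon rank-sum
   p-values, ROC-AUC, average precision per parameter, Cohen's d between
   contexts, and a six-parameter Fisher LDA score min-max scaled to [0, 1].
5. **Visualization** — SNR-weighted Shepard (inverse-distance)
   interpolation renders parameter and LDA heat maps over the white-light
   frame.

## Worked example

```r
library(flimpipe)
model <- flim_instrument()          # 80 ps sampling, 4 channel windows
proc  <- flim_processor(model)      # precomputed CLS deconvolvers

set.seed(42)
truth <- default_tissue_classes()$cancer
wv <- generate_waveform(truth$lifetimes_ns, truth$weights,
                        generate_irf(model), model, target_snr_db = 40)
process_record(wv$record, proc)
```

prints (abridged)

```
  lifetime_ch1 lifetime_ch2 lifetime_ch3 intratio_ch1 intratio_ch2 intratio_ch3
1        3.773        3.839        3.102        0.377        0.347        0.275
```

against ground truth lifetimes (3.70, 3.75, 3.10) ns and intensity ratios
(0.380, 0.348, 0.272): the six FLIm parameters are recovered to a few
percent at 40 dB SNR.  A full synthetic cohort run —

```r
cfg <- flim_config(seed = 3, cohort = list(n_patients = 3L))
res <- run_pipeline(cfg, "run_dir")
read.csv(res$summary_file)
```

— writes per-scan measurement/labeled tables, per-patient discrimination
reports, heat maps, and a cohort summary in which the LDA variable beats
the best single parameter's AUC by ~0.06–0.09 per context, with the CH3
intensity ratio the strongest single parameter.

The command-line interface mirrors the stages:

```sh
Rscript inst/cli/flimpipe.R all --out run_dir --seed 3
Rscript inst/cli/flimpipe.R discriminate --out run_dir   # re-run one stage
```

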