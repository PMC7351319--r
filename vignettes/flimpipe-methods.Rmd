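---
title: "flimpipe: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flimpipe: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the science and the engineering decisions behind
flimpipe: what is modeled, which constants matter, what the synthetic
cohort does and does not emulate, and where the genuinely open design
choices were settled.

## 1. Measurement model

A point measurement is one digitized voltage trace containing four
time-multiplexed spectral channel responses.  The simulated record is

    r[n] = B + Σ_k  s_k[n] + ε[n],
    s_k  = (IRF ⊛ a_k e^{-t/τ_k}) placed in channel window k,

with constant background B, a Gaussian IRF, mono-exponential channel
decays, and white Gaussian noise.  Defaults and rationale:

* **Sampling 80 ps**, four equal channel windows; the default window is
  768 samples (61.4 ns), long enough that the slowest lifetime analyzed
  (8 ns) loses under 5% of its area to truncation.  The record carries a
  64-sample signal-free baseline segment before CH1 (background
  estimation) and each window has 3.2 ns of pre-onset dead time (noise
  estimation).
* **IRF**: Gaussian, FWHM 600 ps (pulsed-laser width dominates the 45 ps
  detector response).  Gaussian was chosen because it is standard and
  analytically checkable (peak position, area, measured FWHM).
* **Channel energy**: the noiseless integral of channel k equals
  `amplitude × w_k`, so spectral weights are exactly the ground-truth
  intensity ratios — the energy-split invariant the tests verify.
* **Noise**: per-channel σ_k = peak_k · 10^(−SNR/20), which makes the
  generator's SNR knob self-consistent with `estimate_snr()`
  (20·log10(peak/σ), σ taken from the pre-onset window).  An SNR target
  is drawn per point from N(40, 5) dB, floored at 20: with the 30 dB
  threshold three sigma below the mean, a few percent of points fail the
  SNR filter, as in intraoperative practice.
* **Decay model**: mono-exponential per channel.  Real autofluorescence
  is multi-exponential; since only the *average* lifetime is analyzed,
  ground truth stores the intensity-weighted mean lifetime and a
  mono-exponential with that mean is the simplest world in which the
  estimator's target is unambiguous.

## 2. Deconvolution

`deconvolve_cls()` minimizes ‖y − (IRF ⊛ Φ)c‖² subject to h = Φc ≥ 0 and
h non-increasing, where Φ holds L orthonormal discrete-time Laguerre
functions (pole-form recurrence φ₀(n) = √(1−α²)·αⁿ).  The quadratic
program is solved exactly via its dual, a nonnegative least-squares
problem handled by a Lawson–Hanson active-set solver; dual optimality
implies primal feasibility, and the tests verify h ≥ −1e−9 and
diff(h) ≤ 1e−6·max(h) on every accepted fit.  An independent
interior-point (log-barrier) solver with exact KKT refinement serves as
the test oracle; the two agree to 1e−6 on random small instances.

**Order and scale.**  L = 12 throughout.  No single Laguerre scale α can
represent both a 0.5 ns and an 8 ns decay on an 80 ps grid: a basis slow
enough for τ = 8 ns is not orthonormal on the window, and a basis fast
enough to be orthonormal underfits the tail (its first moment biases
low).  The processor therefore holds a ladder of precomputed deconvolvers
(α ∈ {0.70, 0.80, 0.86, 0.90, 0.93, 0.95}), runs a pilot fit at α = 0.90,
and refits with the smallest α whose slowest basis function covers about
7× the pilot lifetime.  Only the basis scale adapts; the optimization
problem never changes.  This keeps the pooled median lifetime error ≈ 3%
at 30 dB and ≈ 1% at 50 dB across τ ∈ [0.5, 8] ns.

**Estimand.**  The average lifetime is the first moment of the fitted h
*on the observation window*.  Its target is therefore the truncated
moment of the true decay (for τ = 8 ns on a 61 ns window the truncated
moment is ≈ 2% below τ).  Recovery tests compare against this closed-form
truncated moment; comparing a windowed moment estimator against the
untruncated τ would conflate estimator error with window physics.

**Intensity ratios** are computed from the background-subtracted measured
channel curves (not the fitted reconvolutions) — the raw integral is
unbiased under zero-mean noise and independent of fit quality.  The
denominator spans CH1–3 by default because CH4 is excluded from analysis;
`ratio_denominator = "all"` restores the all-channel denominator.

## 3. Localization

The aiming beam is segmented in HSV space: hue in [200°, 280°]
(blue-violet), saturation ≥ 0.4, value ≥ 0.08, followed by a 3×3
morphological opening (removes speckle) and closing, largest 8-connected
component (ties to higher total intensity), intensity-weighted centroid.
The synthetic background is low-saturation pink (saturation ≈ 0.3), so
the margin to the 0.4 threshold is realistic but solvable.  Sub-pixel
centroiding was chosen over a bounding-box center because it is testable
against the rendered ground truth (< 1 px clean, < 2 px RMS with
speckle).  Clinical frames defeat any fixed threshold ~35% of the time;
the artifact only claims accuracy on synthetic frames and reports
`not_found` / low confidence rather than guessing.

## 4. Coregistration and filtering

* Labels: a point on an annotated pixel takes that condition; otherwise
  the nearest annotated pixel within 10 px (Euclidean distance on pixel
  centers, inclusive bound).  Nearest-pixel labeling and heterogeneity
  exclusion are deliberately orthogonal rules: a point between two
  disparate tissues first gets its nearest label, then the exclusion rule
  decides retention.
* Heterogeneity: a disc containing ≥ 2 *binary-disparate* conditions
  excludes the point; thin/thick epithelium (and benign dysplasia or
  ulceration) all group to healthy and never exclude each other.
* SNR: inclusive 30 dB bound on all of CH1–3.
* MAD: raw median absolute deviation, no 1.4826 normal-consistency
  factor, cutoff 2.5, applied per parameter × patient × context.  Note
  the consequence: for near-Gaussian data 2.5 raw MADs ≈ 1.69σ, so ~9% of
  points are trimmed per parameter (symmetrically, so discrimination is
  essentially unaffected), versus ~0.5% had the scaled MAD been used.
  Univariate statistics use each parameter's own mask; the LDA uses the
  intersection of all six.
* All-equal values give MAD 0 and are kept (degenerate rule).

## 5. Discrimination

* **Wilcoxon rank-sum**: exact enumeration when min(n₁, n₂) ≤ 8 without
  ties, midrank normal approximation with continuity correction
  otherwise.  No multiple-testing correction is applied; reported
  p-values are raw.
* **AUC/AP orientation**: reports carry both the raw AUC/AP (parameter
  value as score, cancer positive — a parameter that is lower in cancer
  scores below 0.5) and an oriented version (sign flipped so AUC ≥ 0.5).
  Cross-parameter comparisons ("LDA beats the best single parameter") use
  the oriented scale, which is the conservative choice; null-calibration
  checks use the raw scale, where chance is exactly 0.5 in expectation.
* **LDA**: pure Fisher direction w ∝ S_w⁻¹(μ_cancer − μ_healthy), solved
  by SVD, no class priors (the per-scan min-max scaled score is not a
  probability and the paper-level analysis needs only a ranking).  The
  three intensity ratios sum to 1, so the within-class scatter is always
  rank-deficient by one; the ridge path (ε = 1e−6 · trace) is the normal
  route, not an anomaly.  Sign is fixed so cancer scores higher; scores
  are min-max scaled per scan.
* **Cohen's d** with pooled SD replaces p-values for large-n context
  comparisons.

## 6. Heat maps

Shepard inverse-distance interpolation with SNR weighting:
w_i = s(snr_i)/d^p with p = 2, support radius 30 px, and s the *linear
amplitude ratio* 10^(dB/20) (dB weighting is available; linear was chosen
as the default because weights then scale like signal amplitude, and the
map is invariant to any uniform rescaling of the weights).  A pixel
coinciding with a measurement takes its value exactly (no division by
zero); pixels with no measurement in range stay outside the support mask.
Interpolated values never leave the range of contributing measurements.

## 7. The synthetic world, and what a green test establishes

Class parameter means are **assumptions, not literature values** — no
absolute per-class lifetimes exist for these spectral bands in
oropharyngeal tissue.  Defaults: healthy epithelium τ = (4.0, 3.3, 2.8)
ns, weights (0.42, 0.32, 0.19, 0.07); cancer shifts of (−0.30, +0.45,
+0.30) ns and weight shifts making the CH3 intensity ratio the strongest
single discriminator (per-point Cohen's d ≈ 1–1.6, matching the observed
intraoperative AUC range of roughly 0.6–0.9); tumor bed with a markedly
shorter CH1 lifetime (cauterized collagen) and nearly unchanged CH2/CH3.
A per-patient lifetime offset (SD 0.12 ns) makes contrast intrapatient,
the regime the per-patient analysis is designed for.  `contrast = 0`
yields an exact null cohort.

Default cohort scale is 10 patients × 3 contexts × 120 points/scan —
clinical scans carry ~1700 coregistered points each; the simulator is
scaled down ~10× so the full suite runs in minutes on one CPU.

A green suite establishes that the *algorithms* are correct on data
obeying the stated model: Gaussian IRF and noise, mono-exponential
decays, rectangular annotations, clean spot rendering.  It does not
establish clinical performance: real tissue has multi-exponential
mixtures, cautery smoke and blood artifacts, annotation
slice-to-surface extrapolation error, 3-D geometry, and inter-patient
variability far beyond a scalar lifetime offset.

## 8. Numerical choices and degenerate inputs

* Laguerre bases are rejected if the Gram matrix deviates from identity
  by more than 1e−6 (raise the window length or lower α).
* Cholesky of the normal matrix falls back to a 1e−12·trace jitter.
* Zero waveforms return flagged empty fits; zero decay integrals flag the
  lifetime undefined; all-zero channel integrals drop the point with a
  log entry; σ = 0 caps the SNR at 120 dB, flagged.
* Ties in peak location take the first maximum; label-distance ties are
  broken deterministically by offset-table order.
* Storage formats are plain text throughout (CSV, ASCII PGM/PPM): the
  annotation containers are lossless, as required, and inspectable.

## 9. Known limitations

* CH4 (porphyrin band) is simulated as a small spectral weight but never
  analyzed, matching its exclusion from the analysis contract.
* The adaptive-α ladder tops out at α = 0.95 on the default window;
  lifetimes well above 8 ns would bias low.
* The aiming-beam tracker assumes one frame per measurement and no
  motion between them; video-rate tracking and 3-D coregistration are out
  of scope.
* The LDA is per patient and per context by design; no generalized
  inter-patient classifier is trained or implied.
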