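#' Tissue class model for the synthetic cohort generator
#'
#' Holds the per-channel ground-truth distribution a tissue condition draws
#' its decay parameters from: mean average lifetime and spectral weight per
#' spectral channel (CH1-CH4) plus their point-to-point standard deviations.
#' Spectral weights are fractions of total collected fluorescence energy and
#' sum to 1.
#'
#' No absolute per-class lifetime values are established for oropharyngeal
#' tissue at these bands; the shipped defaults (see
#' [default_tissue_classes()]) are plausible assumptions chosen for the
#' simulator, not literature values.
#'
#' @param label Condition name.
#' @param lifetimes_ns Length-4 vector of mean average lifetimes, ns.
#' @param lifetime_sd_ns Point-to-point lifetime SD (scalar or length 4).
#' @param weights Length-4 spectral weights, nonnegative, will be
#'   normalized to sum to 1.
#' @param weight_sd Point-to-point SD of each weight before renormalization.
#' @return Object of class `tissue_class`.
#' @export
tissue_class <- function(label, lifetimes_ns, lifetime_sd_ns = 0.25,
                         weights, weight_sd = 0.03) {
  stopifnot(length(lifetimes_ns) == 4, all(lifetimes_ns > 0),
            length(weights) == 4, all(weights >= 0), sum(weights) > 0)
  structure(list(label = label,
                 lifetimes_ns = as.numeric(lifetimes_ns),
                 lifetime_sd_ns = rep_len(lifetime_sd_ns, 4),
                 weights = weights / sum(weights),
                 weight_sd = rep_len(weight_sd, 4)),
            class = "tissue_class")
}

#' Default tissue classes with tunable cancer-vs-healthy contrast
#'
#' Three conditions: healthy epithelium, cancer, and tumor bed
#' (electrocauterized submucosa).  `contrast` linearly scales the
#' cancer-minus-healthy difference of every parameter mean: 1 gives the
#' default separation (per-point Cohen's d of roughly 1 to 1.6, strongest
#' on the CH3 intensity ratio, matching the single-parameter AUC range
#' observed intraoperatively); 0 gives a null cohort in which cancer and
#' healthy draws are identically distributed.  The tumor-bed condition has
#' a markedly shorter CH1 lifetime than healthy epithelium (cauterized
#' collagen) and nearly unchanged CH2/CH3 lifetimes.
#'
#' @param contrast Scale factor applied to the cancer-vs-healthy mean
#'   differences.
#' @param lifetime_sd_ns,weight_sd Point-to-point spreads shared by all
#'   classes.
#' @return Named list of [tissue_class()] objects
#'   (`healthy_epithelium`, `cancer`, `tumor_bed`).
#' @export
default_tissue_classes <- function(contrast = 1, lifetime_sd_ns = 0.25,
                                   weight_sd = 0.04) {
  healthy_tau <- c(4.0, 3.3, 2.8, 2.0)
  healthy_w <- c(0.42, 0.32, 0.19, 0.07)
  d_tau <- c(-0.30, 0.45, 0.30, 0.0)
  d_w <- c(-0.07, 0.00, 0.06, 0.01)
  cancer_tau <- healthy_tau + contrast * d_tau
  cancer_w <- pmax(healthy_w + contrast * d_w, 0.01)
  list(
    healthy_epithelium = tissue_class("healthy_epithelium", healthy_tau,
                                      lifetime_sd_ns, healthy_w, weight_sd),
    cancer = tissue_class("cancer", cancer_tau, lifetime_sd_ns, cancer_w,
                          weight_sd),
    # cauterized submucosa: shorter CH1 lifetime, CH2/CH3 nearly unchanged
    tumor_bed = tissue_class("tumor_bed", c(3.6, 3.26, 2.72, 1.9),
                             lifetime_sd_ns, c(0.47, 0.30, 0.16, 0.07),
                             weight_sd)
  )
}

#' Default additive context shifts
#'
#' Imaging context (in vivo pre-resection, ex vivo specimen, in vivo tumor
#' bed) shifts tissue fluorescence through resection-induced metabolic
#' change.  Shifts are added to the class parameter means for scans taken in
#' that context.
#'
#' @return Named list per context with `lifetimes_ns` and `weights`
#'   length-4 additive offsets.
#' @export
default_context_shifts <- function() {
  list(
    in_vivo_pre = list(lifetimes_ns = rep(0, 4), weights = rep(0, 4)),
    ex_vivo = list(lifetimes_ns = c(-0.30, 0.10, 0.03, 0),
                   weights = c(0.04, -0.03, -0.01, 0)),
    tumor_bed = list(lifetimes_ns = rep(0, 4), weights = rep(0, 4))
  )
}

# Draw one point's ground-truth decay parameters from a class model.
sample_point_params <- function(class_model, context_shift = NULL,
                                patient_tau_offset = 0) {
  mu_tau <- class_model$lifetimes_ns + patient_tau_offset
  mu_w <- class_model$weights
  if (!is.null(context_shift)) {
    mu_tau <- mu_tau + context_shift$lifetimes_ns
    mu_w <- mu_w + context_shift$weights
  }
  tau <- pmax(stats::rnorm(4, mu_tau, class_model$lifetime_sd_ns), 0.2)
  w <- pmax(stats::rnorm(4, mu_w, class_model$weight_sd), 0.005)
  list(lifetimes_ns = tau, weights = w / sum(w))
}

#' Simulate one digitized multi-channel fluorescence record
#'
#' Builds the record the digitizer would produce for one scan point: a
#' constant background level, four IRF-convolved mono-exponential channel
#' decays placed in their time-multiplexed windows with per-channel energy
#' proportional to the spectral weights, and additive white Gaussian noise
#' scaled so each channel's realized SNR (peak over noise sigma, as
#' [estimate_snr()] measures it) matches `target_snr_db`.
#'
#' @param lifetimes_ns Length-4 true average lifetime per channel, ns.
#' @param weights Length-4 spectral weights; must sum to 1.
#' @param irf Sampled IRF on the channel grid (defaults to the model IRF).
#' @param model A [flim_instrument()].
#' @param target_snr_db Per-channel SNR target in dB; `Inf` for noiseless.
#' @param amplitude Total signal area across channels, volt-samples.  The
#'   default gives peak amplitudes of a few hundred mV.
#' @return List with `record` (numeric vector of `model$record_length`),
#'   and `truth`: the input parameters, per-channel noise sigma, and a
#'   logical `truncation_flag` per channel set when the decay tail at the
#'   window end exceeds 1% of its peak (truncation-bias warning).
#' @export
generate_waveform <- function(lifetimes_ns, weights, irf = NULL, model,
                              target_snr_db = Inf, amplitude = 25) {
  stopifnot(inherits(model, "flim_instrument"),
            length(lifetimes_ns) == 4, all(lifetimes_ns > 0),
            length(weights) == 4, all(weights >= 0))
  # all-zero weights are the degenerate signal-free case (background +
  # noise only); otherwise the weights must be proper fractions
  if (sum(weights) > 0 && abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1")
  }
  if (is.null(irf)) irf <- generate_irf(model)
  N <- model$samples_per_channel
  tg <- channel_time_grid(model)
  record <- numeric(model$record_length)
  sigma <- numeric(4)
  trunc_flag <- logical(4)
  for (k in 1:4) {
    w <- weights[k]
    idx <- (model$window_starts[k] + 1):(model$window_starts[k] + N)
    if (w > 0) {
      decay <- exp(-tg / lifetimes_ns[k])
      curve <- stats::convolve(irf, rev(decay), type = "open")[seq_len(N)]
      curve <- curve * (amplitude * w / sum(curve))
      record[idx] <- record[idx] + curve
      peak <- max(curve)
      trunc_flag[k] <- exp(-(max(tg) - model$onset_ns) / lifetimes_ns[k]) > 0.01
      sigma[k] <- if (is.finite(target_snr_db)) peak / 10^(target_snr_db / 20) else 0
    } else {
      sigma[k] <- if (is.finite(target_snr_db)) model$noise_sigma else 0
    }
    if (sigma[k] > 0) record[idx] <- record[idx] + stats::rnorm(N, 0, sigma[k])
  }
  if (is.finite(target_snr_db)) {
    bl <- seq_len(model$baseline_samples)
    record[bl] <- record[bl] + stats::rnorm(length(bl), 0, model$noise_sigma)
  }
  record <- record + model$background_level
  list(record = record,
       truth = list(lifetimes_ns = lifetimes_ns, weights = weights,
                    noise_sigma = sigma, truncation_flag = trunc_flag,
                    target_snr_db = target_snr_db))
}

#' Generate one synthetic patient scan
#'
#' Samples scan-point positions inside the annotated regions of `map`,
#' draws ground-truth decay parameters from the per-condition class models
#' (with context shift and patient offset applied), and synthesizes the raw
#' record of every point.  Per-point SNR targets are drawn from a normal
#' distribution so that a small fraction of points falls below the 30 dB
#' analysis threshold, as seen in clinical runs.
#'
#' @param map An annotation map (see [generate_annotation_map()]).
#' @param classes Named list of [tissue_class()] models keyed by condition.
#' @param context One of `"in_vivo_pre"`, `"ex_vivo"`, `"tumor_bed"`.
#' @param n_points Number of scan points, split evenly across the map's
#'   annotated conditions.
#' @param model A [flim_instrument()].
#' @param irf Sampled IRF.
#' @param context_shifts See [default_context_shifts()].
#' @param patient_tau_offset Patient-level additive lifetime offset, ns.
#' @param snr_mean_db,snr_sd_db Per-point SNR target distribution.
#' @param margin_px Minimum distance of sampled points from region borders.
#' @return List of class `flim_scan`: `records` (list), `truth`
#'   (data.frame: point_index, x, y, condition, true lifetimes/ratios per
#'   CH1-3, target SNR), `map`, `context`.
#' @export
generate_scan <- function(map, classes, context, n_points, model,
                          irf = generate_irf(model),
                          context_shifts = default_context_shifts(),
                          patient_tau_offset = 0,
                          snr_mean_db = 40, snr_sd_db = 5,
                          margin_px = 15) {
  regions <- attr(map, "regions")
  stopifnot(!is.null(regions), n_points >= length(regions))
  shift <- context_shifts[[context]]
  n_per <- diff(round(seq(0, n_points, length.out = length(regions) + 1)))
  pts <- list(); k <- 0L
  for (ri in seq_along(regions)) {
    r <- regions[[ri]]
    for (i in seq_len(n_per[ri])) {
      k <- k + 1L
      x <- stats::runif(1, r$x0 + margin_px, r$x1 - margin_px)
      y <- stats::runif(1, r$y0 + margin_px, r$y1 - margin_px)
      pts[[k]] <- list(x = x, y = y, condition = r$condition)
    }
  }
  ord <- sample.int(length(pts))   # interleave regions along the scan path
  pts <- pts[ord]
  records <- vector("list", length(pts))
  truth <- vector("list", length(pts))
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    cls <- classes[[p$condition]]
    if (is.null(cls)) stop("no tissue class model for condition ", p$condition)
    par <- sample_point_params(cls, shift, patient_tau_offset)
    snr <- max(stats::rnorm(1, snr_mean_db, snr_sd_db), 20)
    wv <- generate_waveform(par$lifetimes_ns, par$weights, irf, model, snr)
    records[[i]] <- wv$record
    rr <- par$weights[1:3] / sum(par$weights[1:3])
    truth[[i]] <- data.frame(point_index = i, x = p$x, y = p$y,
                             condition = p$condition,
                             true_lifetime_ch1 = par$lifetimes_ns[1],
                             true_lifetime_ch2 = par$lifetimes_ns[2],
                             true_lifetime_ch3 = par$lifetimes_ns[3],
                             true_intratio_ch1 = rr[1],
                             true_intratio_ch2 = rr[2],
                             true_intratio_ch3 = rr[3],
                             target_snr_db = snr)
  }
  structure(list(records = records, truth = do.call(rbind, truth),
                 map = map, context = context), class = "flim_scan")
}

#' Default scan geometry for one synthetic patient
#'
#' In vivo pre-resection and ex vivo scans carry a central cancer region
#' flanked by healthy epithelium; the tumor-bed scan is a single
#' electrocauterized-submucosa region with no residual cancer, mirroring a
#' cohort in which no patient had residual disease.
#'
#' @param model A [flim_instrument()] (frame size source).
#' @return Named list of region lists per context, each usable with
#'   [generate_annotation_map()].
#' @export
default_scan_regions <- function(model = flim_instrument()) {
  epithelial <- list(
    list(condition = "healthy_epithelium", x0 = 200, x1 = 420, y0 = 240, y1 = 480),
    list(condition = "cancer",             x0 = 530, x1 = 750, y0 = 240, y1 = 480),
    list(condition = "healthy_epithelium", x0 = 860, x1 = 1080, y0 = 240, y1 = 480))
  list(in_vivo_pre = epithelial,
       ex_vivo = epithelial,
       tumor_bed = list(
         list(condition = "tumor_bed", x0 = 440, x1 = 840, y0 = 220, y1 = 500)))
}

#' Generate a synthetic multi-patient cohort
#'
#' Produces, per patient, one scan per requested context with annotation
#' maps and full ground truth, reproducibly from `seed`.  Patients receive
#' a patient-level lifetime offset so intrapatient contrast, not a global
#' decision boundary, is what downstream discrimination must exploit.
#'
#' @param n_patients Number of patients.
#' @param classes Named list of [tissue_class()] models.
#' @param contexts Character vector of contexts to simulate per patient.
#' @param n_points Scan points per scan.
#' @param model A [flim_instrument()].
#' @param seed Integer seed; fully determines the cohort.
#' @param patient_tau_sd SD of the patient-level lifetime offset, ns.
#' @param snr_mean_db,snr_sd_db Per-point SNR target distribution.
#' @return List of class `flim_cohort`: per patient a list with `patient`,
#'   `tau_offset`, and `scans` (named by context).
#' @export
generate_cohort <- function(n_patients = 10,
                            classes = default_tissue_classes(),
                            contexts = c("in_vivo_pre", "ex_vivo", "tumor_bed"),
                            n_points = 120, model = flim_instrument(),
                            seed = 1, patient_tau_sd = 0.12,
                            snr_mean_db = 40, snr_sd_db = 5) {
  stopifnot(n_patients >= 1)
  set.seed(as.integer(seed))
  irf <- generate_irf(model)
  regions <- default_scan_regions(model)
  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    tau_off <- stats::rnorm(1, 0, patient_tau_sd)
    scans <- list()
    for (ctx in contexts) {
      map <- generate_annotation_map(regions[[ctx]], model)
      scans[[ctx]] <- generate_scan(map, classes, ctx, n_points, model, irf,
                                    patient_tau_offset = tau_off,
                                    snr_mean_db = snr_mean_db,
                                    snr_sd_db = snr_sd_db)
    }
    patients[[p]] <- list(patient = p, tau_offset = tau_off, scans = scans)
  }
  structure(list(patients = patients, model = model, seed = seed,
                 contexts = contexts), class = "flim_cohort")
}
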