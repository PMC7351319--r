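#' Pipeline run configuration
#'
#' Collects every tunable of the simulate - process - localize - coregister
#' - discriminate - visualize chain in one validated, JSON-serializable
#' object.  All fixed analysis constants (30 dB SNR threshold, 2.5 MAD
#' cutoff, 10 px coregistration radius, CH4 exclusion) live here.
#'
#' @param seed Integer seed driving every random stage.
#' @param instrument Named list of [flim_instrument()] arguments.
#' @param laguerre Named list: `order`, `alphas`, `pilot_alpha`,
#'   `coverage`.
#' @param thresholds Named list: `snr_db`, `mad_k`, `radius_px`.
#' @param interpolation Named list: `power`, `support_radius`,
#'   `snr_weighting`.
#' @param cohort Named list: `n_patients`, `n_points`, `contexts`,
#'   `contrast`, `snr_mean_db`, `snr_sd_db`, `patient_tau_sd`.
#' @param localization Named list: `use_frames`, `spot_radius`,
#'   `hue_band`, `sat_min`, `min_area`.
#' @param visualization Named list: `enabled`, `alpha`, `parameters`.
#' @param ratio_denominator `"ch1_3"` or `"all"`.
#' @return Validated list of class `flim_config`.
#' @export
flim_config <- function(seed = 1,
                        instrument = list(),
                        laguerre = list(),
                        thresholds = list(),
                        interpolation = list(),
                        cohort = list(),
                        localization = list(),
                        visualization = list(),
                        ratio_denominator = "ch1_3") {
  merge_defaults <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    instrument = merge_defaults(instrument, list(
      sampling_ns = 0.08, samples_per_channel = 768L, baseline_samples = 64L,
      irf_fwhm_ns = 0.6, onset_ns = 3.2, noise_window_samples = 24L,
      noise_sigma = 0.002, background_level = 0.05,
      frame_width = 1280L, frame_height = 720L)),
    laguerre = merge_defaults(laguerre, list(
      order = 12L, alphas = c(0.70, 0.80, 0.86, 0.90, 0.93, 0.95),
      pilot_alpha = 0.90, coverage = 7)),
    thresholds = merge_defaults(thresholds, list(
      snr_db = 30, mad_k = 2.5, radius_px = 10)),
    interpolation = merge_defaults(interpolation, list(
      power = 2, support_radius = 30, snr_weighting = "linear")),
    cohort = merge_defaults(cohort, list(
      n_patients = 10L, n_points = 120L,
      contexts = c("in_vivo_pre", "ex_vivo", "tumor_bed"),
      contrast = 1, snr_mean_db = 40, snr_sd_db = 5, patient_tau_sd = 0.12)),
    localization = merge_defaults(localization, list(
      use_frames = FALSE, spot_radius = 12, hue_band = c(200, 280),
      sat_min = 0.4, min_area = 20)),
    visualization = merge_defaults(visualization, list(
      enabled = FALSE, alpha = 0.5,
      parameters = c("lifetime_ch1", "intratio_ch3", "lda"))),
    ratio_denominator = ratio_denominator)
  validate_config(cfg)
  structure(cfg, class = "flim_config")
}

#' @rdname flim_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed",
      "must be a single integer")
  chk(config$instrument$sampling_ns > 0, "instrument.sampling_ns", "must be > 0")
  chk(config$laguerre$order >= 1, "laguerre.order", "must be >= 1")
  chk(all(config$laguerre$alphas > 0 & config$laguerre$alphas < 1),
      "laguerre.alphas", "must lie in (0, 1)")
  chk(config$thresholds$snr_db > 0, "thresholds.snr_db", "must be > 0")
  chk(config$thresholds$mad_k > 0, "thresholds.mad_k", "must be > 0")
  chk(config$thresholds$radius_px > 0, "thresholds.radius_px", "must be > 0")
  chk(config$interpolation$power > 0, "interpolation.power", "must be > 0")
  chk(config$interpolation$support_radius > 0,
      "interpolation.support_radius", "must be > 0")
  chk(config$cohort$n_patients >= 1, "cohort.n_patients", "must be >= 1")
  chk(all(config$cohort$contexts %in%
            c("in_vivo_pre", "ex_vivo", "tumor_bed")),
      "cohort.contexts", "unknown context name")
  chk(config$ratio_denominator %in% c("ch1_3", "all"),
      "ratio_denominator", "must be 'ch1_3' or 'all'")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A [flim_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(flim_config, raw[setdiff(names(raw), character(0))])
}

scan_tag <- function(patient, context) sprintf("p%02d_%s", patient, context)

config_instrument <- function(config) do.call(flim_instrument, config$instrument)

config_processor <- function(config, model = config_instrument(config)) {
  flim_processor(model, order = config$laguerre$order,
                 alphas = config$laguerre$alphas,
                 pilot_alpha = config$laguerre$pilot_alpha,
                 coverage = config$laguerre$coverage)
}

#' Pipeline stage: simulate the synthetic cohort to disk
#'
#' Writes, per patient scan: the raw waveform matrix (one row per point),
#' the ground-truth table, and the annotation map; plus the sampled IRF and
#' the resolved configuration echo.  All outputs are plain text (CSV / PGM).
#'
#' @param config A [flim_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, the manifest data.frame of files written.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(file.path(out_dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  model <- config_instrument(config)
  classes <- default_tissue_classes(config$cohort$contrast)
  cohort <- generate_cohort(
    n_patients = config$cohort$n_patients, classes = classes,
    contexts = config$cohort$contexts, n_points = config$cohort$n_points,
    model = model, seed = config$seed,
    patient_tau_sd = config$cohort$patient_tau_sd,
    snr_mean_db = config$cohort$snr_mean_db,
    snr_sd_db = config$cohort$snr_sd_db)
  write_config(config, file.path(out_dir, "config.json"))
  utils::write.csv(data.frame(irf = generate_irf(model)),
                   file.path(out_dir, "irf.csv"), row.names = FALSE)
  files <- c("config.json", "irf.csv")
  for (pat in cohort$patients) {
    for (ctx in names(pat$scans)) {
      scan <- pat$scans[[ctx]]
      tag <- scan_tag(pat$patient, ctx)
      wf <- do.call(rbind, scan$records)
      data.table::fwrite(data.table::as.data.table(wf),
                         file.path(out_dir, "scans", paste0(tag, "_waveforms.csv")))
      data.table::fwrite(scan$truth,
                         file.path(out_dir, "scans", paste0(tag, "_truth.csv")))
      write_pgm(scan$map, file.path(out_dir, "scans", paste0(tag, "_annotation.pgm")))
      files <- c(files, paste0("scans/", tag,
                               c("_waveforms.csv", "_truth.csv", "_annotation.pgm")))
    }
  }
  manifest <- data.frame(file = files)
  utils::write.csv(manifest, file.path(out_dir, "manifest_simulate.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

run_scan_tags <- function(out_dir) {
  wf <- list.files(file.path(out_dir, "scans"), pattern = "_waveforms\\.csv$")
  sub("_waveforms\\.csv$", "", wf)
}

#' Pipeline stage: deconvolve all simulated scans
#'
#' Reads the waveform matrices written by [pipeline_simulate()] and writes a
#' measurement table per scan.
#'
#' @param out_dir Run directory containing `config.json` and `scans/`.
#' @return Invisibly, the vector of measurement files written.
#' @export
pipeline_process <- function(out_dir) {
  config <- read_config(file.path(out_dir, "config.json"))
  model <- config_instrument(config)
  proc <- config_processor(config, model)
  dir.create(file.path(out_dir, "measurements"), showWarnings = FALSE)
  tags <- run_scan_tags(out_dir)
  if (length(tags) == 0) stop("no simulated scans under ", out_dir,
                              ": run pipeline_simulate first")
  written <- character(0)
  for (tag in tags) {
    wf <- as.matrix(data.table::fread(
      file.path(out_dir, "scans", paste0(tag, "_waveforms.csv"))))
    records <- lapply(seq_len(nrow(wf)), function(i) as.numeric(wf[i, ]))
    meas <- process_scan(records, proc,
                         ratio_denominator = config$ratio_denominator)
    f <- file.path(out_dir, "measurements", paste0(tag, "_measurements.csv"))
    data.table::fwrite(meas, f)
    written <- c(written, f)
  }
  invisible(written)
}

#' Pipeline stage: localize points and attach histology labels
#'
#' Attaches (x, y) positions to each measurement -- through aiming-beam
#' rendering plus HSV segmentation when `localization$use_frames` is TRUE,
#' otherwise from the simulator's ground-truth path -- then assigns
#' annotation-map labels and applies the heterogeneity, SNR, and MAD filter
#' chain.  Writes one labeled table per scan and a cohort-wide filter
#' accounting log.
#'
#' @param out_dir Run directory after [pipeline_process()].
#' @return Invisibly, the filter-accounting data.frame.
#' @export
pipeline_coregister <- function(out_dir) {
  config <- read_config(file.path(out_dir, "config.json"))
  model <- config_instrument(config)
  dir.create(file.path(out_dir, "labeled"), showWarnings = FALSE)
  tags <- run_scan_tags(out_dir)
  log <- list()
  for (tag in tags) {
    meas <- as.data.frame(data.table::fread(
      file.path(out_dir, "measurements", paste0(tag, "_measurements.csv"))))
    truth <- as.data.frame(data.table::fread(
      file.path(out_dir, "scans", paste0(tag, "_truth.csv"))))
    map <- read_pgm(file.path(out_dir, "scans", paste0(tag, "_annotation.pgm")))
    attr(map, "codes") <- annotation_codes(fine = TRUE)
    if (isTRUE(config$localization$use_frames)) {
      dets <- vector("list", nrow(truth))
      for (i in seq_len(nrow(truth))) {
        set.seed((config$seed * 7919L + i * 13L +
                    sum(utf8ToInt(tag))) %% 2147483647L)
        frame <- render_aiming_beam_frame(
          model, center = c(truth$x[i], truth$y[i]),
          radius = config$localization$spot_radius)
        dets[[i]] <- segment_aiming_beam(
          frame, hue_band = config$localization$hue_band,
          sat_min = config$localization$sat_min,
          min_area = config$localization$min_area,
          expected_radius = config$localization$spot_radius)
      }
      pos <- track_scan(dets)
      meas$x <- pos$x; meas$y <- pos$y
    } else {
      meas$x <- truth$x; meas$y <- truth$y
    }
    labeled <- assign_labels(meas, map, radius = config$thresholds$radius_px)
    labeled <- exclude_heterogeneous(labeled, map,
                                     radius = config$thresholds$radius_px)
    labeled <- apply_filters(labeled, snr_db = config$thresholds$snr_db,
                             mad_k = config$thresholds$mad_k)
    data.table::fwrite(labeled,
                       file.path(out_dir, "labeled", paste0(tag, "_labeled.csv")))
    log[[tag]] <- data.frame(scan = tag,
                             t(attr(labeled, "filter_counts")))
  }
  log <- do.call(rbind, log)
  utils::write.csv(log, file.path(out_dir, "filter_log.csv"), row.names = FALSE)
  invisible(log)
}

#' Pipeline stage: per-patient discrimination reports and cohort summary
#'
#' @param out_dir Run directory after [pipeline_coregister()].
#' @return Invisibly, the list of per-scan reports.
#' @export
pipeline_discriminate <- function(out_dir) {
  dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
  tags <- run_scan_tags(out_dir)
  reports <- list()
  pooled <- list()
  for (tag in tags) {
    labeled <- as.data.frame(data.table::fread(
      file.path(out_dir, "labeled", paste0(tag, "_labeled.csv"))))
    patient <- as.integer(sub("^p(\\d+)_.*$", "\\1", tag))
    context <- sub("^p\\d+_", "", tag)
    rep <- patient_report(labeled, context = context, patient = patient)
    data.table::fwrite(as.data.frame(rep),
                       file.path(out_dir, "reports", paste0(tag, "_report.csv")))
    reports[[tag]] <- rep
    keep <- labeled$analysis_ready
    if (any(keep)) {
      d <- labeled[keep, c(flim_parameters(), "group"), drop = FALSE]
      d$context <- context
      pooled[[tag]] <- d
    }
  }
  summary <- cohort_summary(reports)
  utils::write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  pooled <- do.call(rbind, pooled)
  es <- context_effect_sizes(pooled)
  if (!is.null(es)) {
    utils::write.csv(es, file.path(out_dir, "context_effect_sizes.csv"),
                     row.names = FALSE)
  }
  invisible(reports)
}

#' Pipeline stage: render heat-map overlays
#'
#' Renders the configured parameters (plus the scaled LDA score when
#' requested) as SNR-weighted inverse-distance heat maps overlaid on a
#' synthetic white-light frame, one PPM per scan and parameter, for the
#' first patient.
#'
#' @param out_dir Run directory after [pipeline_discriminate()].
#' @return Invisibly, the vector of files written.
#' @export
pipeline_visualize <- function(out_dir) {
  config <- read_config(file.path(out_dir, "config.json"))
  model <- config_instrument(config)
  dir.create(file.path(out_dir, "heatmaps"), showWarnings = FALSE)
  tags <- grep("^p01_", run_scan_tags(out_dir), value = TRUE)
  written <- character(0)
  for (tag in tags) {
    labeled <- as.data.frame(data.table::fread(
      file.path(out_dir, "labeled", paste0(tag, "_labeled.csv"))))
    keep <- labeled$analysis_ready
    if (!any(keep)) next
    d <- labeled[keep, , drop = FALSE]
    set.seed(config$seed)
    frame <- render_aiming_beam_frame(model, spot = FALSE)
    for (param in config$visualization$parameters) {
      if (param == "lda") {
        pos <- d$group == "cancer"
        if (sum(pos) == 0 || sum(!pos) == 0) next
        feats <- as.matrix(d[, flim_parameters()])
        vals <- lda_scores(feats, suppressWarnings(fit_lda(feats, pos)))
      } else {
        vals <- d[[param]]
      }
      pts <- data.frame(x = d$x, y = d$y, value = vals,
                        snr_db = pmin(d$snr_ch1, d$snr_ch2, d$snr_ch3))
      hm <- interpolate_heatmap(pts, model$frame_width, model$frame_height,
                                power = config$interpolation$power,
                                support_radius = config$interpolation$support_radius,
                                snr_weighting = config$interpolation$snr_weighting)
      img <- overlay_heatmap(frame, hm, alpha = config$visualization$alpha)
      f <- file.path(out_dir, "heatmaps", paste0(tag, "_", param, ".ppm"))
      write_ppm(img, f)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Run the full pipeline
#'
#' simulate - process - localize/coregister - discriminate (- visualize,
#' when enabled), writing every intermediate to `out_dir`.  Fully
#' deterministic for a fixed configuration: re-running with the same seed
#' reproduces byte-identical tabular outputs.
#'
#' @param config A [flim_config()].
#' @param out_dir Run directory.
#' @return Invisibly, a list with the filter log, reports and summary paths.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  pipeline_simulate(config, out_dir)
  pipeline_process(out_dir)
  log <- pipeline_coregister(out_dir)
  reports <- pipeline_discriminate(out_dir)
  if (isTRUE(config$visualization$enabled)) pipeline_visualize(out_dir)
  invisible(list(filter_log = log, reports = reports,
                 summary_file = file.path(out_dir, "cohort_summary.csv")))
}
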