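test_that("noiseless single-channel record reproduces the closed-form decay", {
  model <- fx_model()
  # discrete delta IRF: the channel curve must be exactly the scaled
  # exponential from the impulse position onward
  delta <- numeric(model$samples_per_channel)
  delta[1] <- 1
  wv <- generate_waveform(c(4, 4, 4, 4), c(1, 0, 0, 0), irf = delta,
                          model = model, target_snr_db = Inf)
  ch <- demultiplex(wv$record - model$background_level, model)
  tg <- channel_time_grid(model)
  expected <- exp(-tg / 4)
  expected <- expected * (25 / sum(expected))
  expect_equal(ch[[1]], expected, tolerance = 1e-9)
  expect_true(all(abs(ch[[2]]) < 1e-12))
})

test_that("all-zero weights give background plus noise only", {
  model <- fx_model()
  wv <- generate_waveform(rep(1, 4), rep(0, 4), model = model,
                          target_snr_db = Inf)
  expect_true(all(wv$record == model$background_level))
  set.seed(11)
  noisy <- generate_waveform(rep(1, 4), rep(0, 4), model = model,
                             target_snr_db = 30)
  resid <- noisy$record - model$background_level
  expect_gt(stats::sd(resid), 0)
  expect_lt(max(abs(resid)), 6 * model$noise_sigma)
  # noiseless channels with zero weight are exactly flat background
  wv1 <- generate_waveform(rep(1, 4), c(1, 0, 0, 0), model = model,
                           target_snr_db = Inf)
  ch4 <- wv1$record[(model$window_starts[4] + 1):model$record_length]
  expect_true(all(ch4 == model$background_level))
})

test_that("noiseless channel integrals are proportional to spectral weights", {
  model <- fx_model()
  w <- c(0.4, 0.3, 0.2, 0.1)
  wv <- generate_waveform(c(3, 4, 2, 1), w, model = model,
                          target_snr_db = Inf)
  ch <- demultiplex(wv$record - model$background_level, model)
  ints <- vapply(ch, sum, numeric(1))
  expect_equal(ints / sum(ints), w, tolerance = 1e-6)
})

test_that("realized per-channel SNR matches the target over realizations", {
  model <- fx_model()
  irf <- fx_irf()
  set.seed(42)
  snrs <- replicate(200, {
    wv <- generate_waveform(c(4, 3, 2.5, 2), c(0.4, 0.3, 0.2, 0.1), irf,
                            model, target_snr_db = 30)
    rec <- subtract_background(wv$record, model)
    ch <- demultiplex(rec, model)
    estimate_snr(ch[[1]], seq_len(model$noise_window_samples))
  })
  expect_lt(abs(mean(snrs) - 30), 1)
})

test_that("slow decays raise the truncation flag, fast ones do not", {
  model <- fx_model()
  wv <- generate_waveform(c(40, 2, 2, 2), c(0.5, 0.3, 0.1, 0.1),
                          model = model, target_snr_db = Inf)
  expect_true(wv$truth$truncation_flag[1])
  expect_false(any(wv$truth$truncation_flag[2:4]))
})

test_that("scan generation is deterministic in the seed", {
  model <- fx_model()
  classes <- default_tissue_classes()
  map <- generate_annotation_map(default_scan_regions(model)$in_vivo_pre,
                                 model)
  mk <- function() {
    set.seed(99)
    generate_scan(map, classes, "in_vivo_pre", 6, model, fx_irf())
  }
  s1 <- mk(); s2 <- mk()
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
})

test_that("cohort structure and reproducibility", {
  model <- fx_model()
  co <- generate_cohort(n_patients = 2, n_points = 6, model = model,
                        seed = 7)
  expect_length(co$patients, 2)
  expect_named(co$patients[[1]]$scans,
               c("in_vivo_pre", "ex_vivo", "tumor_bed"))
  co2 <- generate_cohort(n_patients = 2, n_points = 6, model = model,
                         seed = 7)
  expect_identical(co$patients[[1]]$scans$ex_vivo$truth,
                   co2$patients[[1]]$scans$ex_vivo$truth)
  # ground-truth intensity ratios sum to 1
  tr <- co$patients[[1]]$scans$in_vivo_pre$truth
  expect_equal(tr$true_intratio_ch1 + tr$true_intratio_ch2 +
                 tr$true_intratio_ch3, rep(1, nrow(tr)), tolerance = 1e-12)
})

test_that("annotation maps carry exactly the configured codes", {
  m <- generate_annotation_map(
    list(list(condition = "cancer", x0 = 10, x1 = 20, y0 = 10, y1 = 20)),
    width = 50, height = 40)
  expect_setequal(unique(as.vector(m)), c(0L, 170L))
  empty <- generate_annotation_map(list(), width = 30, height = 30)
  expect_true(all(empty == 0L))
  # adjacent rectangles keep their own codes, no blending
  adj <- generate_annotation_map(
    list(list(condition = "cancer", x0 = 1, x1 = 10, y0 = 1, y1 = 30),
         list(condition = "healthy_epithelium", x0 = 11, x1 = 20,
              y0 = 1, y1 = 30)),
    width = 30, height = 30)
  expect_setequal(unique(as.vector(adj)), c(0L, 170L, 85L))
  expect_true(all(adj[1:30, 10] == 170L))
  expect_true(all(adj[1:30, 11] == 85L))
})

test_that("overlapping regions with different labels are rejected", {
  expect_error(generate_annotation_map(
    list(list(condition = "cancer", x0 = 1, x1 = 20, y0 = 1, y1 = 20),
         list(condition = "healthy_epithelium", x0 = 15, x1 = 30,
              y0 = 15, y1 = 30)),
    width = 40, height = 40), "overlapping")
})

test_that("aiming-beam frames are deterministic and spot-accurate", {
  model <- fx_model()
  mk <- function(spot = TRUE) {
    set.seed(5)
    render_aiming_beam_frame(model, center = c(640, 360), radius = 10,
                             spot = spot)
  }
  expect_identical(mk(), mk())                      # same seed, bit-identical
  expect_identical(mk(spot = FALSE), mk(spot = FALSE))
  # disabled spot leaves the background untouched
  set.seed(5)
  bg <- render_aiming_beam_frame(model, spot = FALSE)
  set.seed(5)
  with_spot <- render_aiming_beam_frame(model, center = c(640, 360),
                                        radius = 10)
  expect_identical(render_aiming_beam_frame(model, background = bg,
                                            spot = FALSE), bg)
  # intensity-weighted centroid of the painted difference is the center
  dmask <- abs(with_spot[, , 3] - bg[, , 3])
  idx <- which(dmask > 1e-3, arr.ind = TRUE)
  wgt <- dmask[idx]
  cx <- sum(idx[, 2] * wgt) / sum(wgt)
  cy <- sum(idx[, 1] * wgt) / sum(wgt)
  expect_lt(abs(cx - 640), 0.5)
  expect_lt(abs(cy - 360), 0.5)
  expect_error(render_aiming_beam_frame(model, center = c(10, 10),
                                        radius = 0), "radius")
})
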