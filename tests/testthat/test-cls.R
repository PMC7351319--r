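test_that("noiseless mono-exponential is recovered within 2%", {
  model <- fx_model()
  tg <- channel_time_grid(model)
  fit <- flimpipe:::fit_channel(fx_processor(), mono_waveform(4))
  tau_hat <- average_lifetime(fit$fit, model$sampling_ns)
  expect_lt(abs(tau_hat - truncated_moment(4, tg)) / truncated_moment(4, tg),
            0.02)
  expect_lt(abs(tau_hat - 4) / 4, 0.02)
})

test_that("zero waveform yields a flagged empty fit", {
  proc <- fx_processor()
  fit <- deconvolve_cls(numeric(fx_model()$samples_per_channel),
                        proc$decons[[1]])
  expect_true(fit$empty)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$integral, 0)
})

test_that("fits satisfy the decay constraints and recover noisy lifetimes", {
  model <- fx_model()
  proc <- fx_processor()
  tg <- channel_time_grid(model)
  set.seed(31)
  for (tau in c(1, 3, 6)) {
    wf0 <- mono_waveform(tau)
    sig <- max(wf0) / 10^(30 / 20)
    errs <- replicate(15, {
      ff <- flimpipe:::fit_channel(proc, wf0 + rnorm(length(wf0), 0, sig))
      h <- ff$fit$fitted_firf
      expect_gte(min(h), -1e-9)
      expect_lte(max(diff(h)), 1e-6 * max(h))
      tt <- truncated_moment(tau, tg)
      abs(average_lifetime(ff$fit, model$sampling_ns) - tt) / tt
    })
    expect_lt(median(errs), 0.05)
  }
})

test_that("CLS matches the interior-point oracle on small instances", {
  set.seed(17)
  for (i in 1:8) {
    N <- sample(48:64, 1)
    L <- sample(2:4, 1)
    alpha <- runif(1, 0.4, 0.6)
    basis <- laguerre_basis(L, alpha, N)
    irf <- exp(-0.5 * ((seq_len(N) - 5) / 2)^2)
    irf <- irf / sum(irf)
    tau <- runif(1, 3, 15)
    y <- stats::convolve(irf, rev(exp(-seq_len(N) / tau)),
                         type = "open")[seq_len(N)] + rnorm(N, 0, 0.02)
    decon <- cls_deconvolver(irf, basis)
    fit <- deconvolve_cls(y, decon)
    oracle <- qp_oracle(decon$V, y, basis$basis)
    expect_lt(max(abs(fit$fitted_firf - oracle$fitted)),
              1e-6 * max(1, max(abs(oracle$fitted))))
  }
})

test_that("average lifetime matches the analytic truncated moment", {
  dt <- 0.08
  tg <- seq(0, 25 - dt, by = dt)
  h <- exp(-tg / 4)
  expect_lt(abs(average_lifetime(h, dt) - truncated_moment(4, tg)) /
              truncated_moment(4, tg), 1e-12)
  # mass at t = 0 only
  h0 <- c(1, numeric(99))
  expect_equal(average_lifetime(h0, dt), 0)
  # scale invariance
  expect_equal(average_lifetime(h * 7.3, dt), average_lifetime(h, dt))
  # zero integral is undefined and flagged
  und <- average_lifetime(numeric(10), dt)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("intensity ratios follow their definition and normalize", {
  expect_equal(intensity_ratio(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(intensity_ratio(c(5, 0, 0)), c(1, 0, 0))
  set.seed(4)
  for (i in 1:1000) {
    r <- intensity_ratio(runif(3, 0, 10))
    expect_lt(abs(sum(r) - 1), 1e-12)
  }
  und <- intensity_ratio(c(0, 0, 0))
  expect_true(all(is.na(und)))
  expect_true(attr(und, "undefined"))
})

test_that("nnls solves random nonnegative least-squares problems", {
  set.seed(12)
  for (i in 1:20) {
    A <- matrix(rnorm(8 * 30), 8, 30)
    b <- rnorm(8)
    sol <- nnls(A, b)
    expect_true(all(sol$x >= 0))
    # KKT: gradient nonnegative... <= 0 for zero coords, ~0 for active
    grad <- as.numeric(crossprod(A, b - A %*% sol$x))
    expect_lt(max(grad[sol$x == 0]), 1e-6)
    expect_lt(max(abs(grad[sol$x > 0])), 1e-6)
  }
})
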