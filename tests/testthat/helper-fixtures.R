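# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- flim_instrument()
  .fx$model
}

fx_irf <- function() {
  if (is.null(.fx$irf)) .fx$irf <- generate_irf(fx_model())
  .fx$irf
}

fx_processor <- function() {
  if (is.null(.fx$proc)) .fx$proc <- flim_processor(fx_model())
  .fx$proc
}

# Noiseless IRF-convolved mono-exponential channel waveform on the model
# grid (computed directly, not via generate_waveform).
mono_waveform <- function(tau, model = fx_model(), irf = fx_irf()) {
  tg <- channel_time_grid(model)
  stats::convolve(irf, rev(exp(-tg / tau)), type = "open")[seq_along(tg)]
}

# Small toy annotation map used by coregistration tests: two rectangles
# (cancer, healthy) on a 200 x 200 canvas.
toy_map <- function() {
  generate_annotation_map(
    list(list(condition = "cancer", x0 = 40, x1 = 80, y0 = 40, y1 = 160),
         list(condition = "healthy_epithelium",
              x0 = 120, x1 = 160, y0 = 40, y1 = 160)),
    width = 200, height = 200)
}
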