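#' Render a synthetic white-light frame with an aiming-beam spot
#'
#' Composites a blue-violet Gaussian-profile aiming-beam spot onto a
#' tissue-like background (low-saturation pink with per-pixel texture
#' noise).  The spot's hue and saturation separate it from the background in
#' HSV space, which is what the localization stage exploits.
#'
#' @param model A [flim_instrument()] (frame size).
#' @param center Spot center `c(x, y)` in pixels; may be fractional.
#' @param radius Gaussian sigma of the spot profile, pixels; must be > 0.
#' @param background Optional pre-rendered H x W x 3 background array in
#'   [0, 1]; generated (using the current RNG state) when NULL.
#' @param spot If FALSE the background is returned untouched.
#' @param spot_color RGB of the beam at full opacity.
#' @param peak_alpha Peak opacity of the spot profile.
#' @return H x W x 3 array in [0, 1].
#' @export
render_aiming_beam_frame <- function(model, center = NULL, radius = 12,
                                     background = NULL, spot = TRUE,
                                     spot_color = c(0.30, 0.25, 1.0),
                                     peak_alpha = 0.95) {
  h <- model$frame_height; w <- model$frame_width
  if (is.null(background)) {
    base <- c(0.78, 0.56, 0.55)
    background <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      background[, , ch] <- pmin(pmax(
        base[ch] + matrix(stats::runif(h * w, -0.06, 0.06), h, w), 0), 1)
    }
  }
  if (!spot) return(background)
  stopifnot(!is.null(center), length(center) == 2)
  if (radius <= 0) stop("spot radius must be > 0")
  cx <- center[1]; cy <- center[2]
  if (cx < 1 || cx > w || cy < 1 || cy > h) stop("spot center outside frame")
  half <- ceiling(4 * radius)
  xs <- max(1, floor(cx - half)):min(w, ceiling(cx + half))
  ys <- max(1, floor(cy - half)):min(h, ceiling(cy + half))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  a <- peak_alpha * exp(-d2 / (2 * radius^2))
  img <- background
  for (ch in 1:3) {
    img[ys, xs, ch] <- img[ys, xs, ch] * (1 - a) + spot_color[ch] * a
  }
  img
}
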