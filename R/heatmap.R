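#' SNR-weighted inverse-distance heat-map interpolation
#'
#' Shepard inverse-distance-weighted interpolation combined with SNR
#' weighting: the value at pixel q is
#' `sum_i w_i v_i / sum_i w_i` with `w_i = s(snr_i) / d(q, i)^p` over the
#' measurements within `support_radius` of q, so that nearby, high-SNR
#' measurements dominate.  `s` converts the SNR from dB to a linear
#' amplitude ratio by default.  A pixel coinciding with a measurement takes
#' that measurement's value exactly; pixels with no measurement in range
#' are outside the support mask (NA).
#'
#' @param points data.frame with `x`, `y`, `value`, and `snr_db` columns.
#' @param width,height Output size in pixels.
#' @param power Shepard distance exponent p (> 0).
#' @param support_radius Influence radius R in pixels (> 0).
#' @param snr_weighting `"linear"` (amplitude ratio `10^(dB/20)`) or
#'   `"db"` (the raw dB value, floored at 0).
#' @return `height x width` numeric matrix of class `flim_heatmap`; NA
#'   outside the support mask.
#' @export
interpolate_heatmap <- function(points, width, height, power = 2,
                                support_radius = 30,
                                snr_weighting = c("linear", "db")) {
  snr_weighting <- match.arg(snr_weighting)
  stopifnot(nrow(points) >= 1, power > 0, support_radius > 0)
  sw <- switch(snr_weighting,
               linear = 10^(points$snr_db / 20),
               db = pmax(points$snr_db, 0))
  num <- matrix(0, height, width)
  den <- matrix(0, height, width)
  exact <- list()
  r <- ceiling(support_radius)
  for (i in seq_len(nrow(points))) {
    x <- points$x[i]; y <- points$y[i]
    if (is.na(x) || is.na(y)) next
    xs <- max(1, floor(x - r)):min(width, ceiling(x + r))
    ys <- max(1, floor(y - r)):min(height, ceiling(y + r))
    d2 <- outer((ys - y)^2, (xs - x)^2, "+")
    hit <- d2 < 1e-18
    if (any(hit)) {
      hidx <- which(hit, arr.ind = TRUE)
      exact[[length(exact) + 1L]] <-
        cbind(ys[hidx[, 1]], xs[hidx[, 2]], points$value[i])
    }
    inr <- d2 <= support_radius^2 & !hit
    w <- matrix(0, length(ys), length(xs))
    w[inr] <- sw[i] / sqrt(d2[inr])^power
    num[ys, xs] <- num[ys, xs] + w * points$value[i]
    den[ys, xs] <- den[ys, xs] + w
  }
  out <- num / den
  out[den == 0] <- NA_real_
  for (e in exact) out[cbind(e[, 1], e[, 2])] <- e[, 3]
  structure(out, class = c("flim_heatmap", "matrix"))
}

#' Overlay a heat map on a white-light frame
#'
#' Alpha-blends the color-mapped heat-map values onto the frame inside the
#' support mask; pixels outside the mask are returned bit-identical to the
#' input frame.
#'
#' @param frame H x W x 3 RGB array in [0, 1].
#' @param heatmap Matrix from [interpolate_heatmap()] (same H x W).
#' @param alpha Blend factor in [0, 1] (0 = frame only, 1 = pure colormap).
#' @param colors Colormap as a vector of R colors, low to high.
#' @param value_range Values mapped to the colormap ends; defaults to the
#'   finite range of the heat map (per-scan min-max).
#' @return H x W x 3 RGB array.
#' @export
overlay_heatmap <- function(frame, heatmap, alpha = 0.5,
                            colors = grDevices::hcl.colors(256, "viridis"),
                            value_range = NULL) {
  stopifnot(length(dim(frame)) == 3,
            all(dim(frame)[1:2] == dim(heatmap)))
  if (is.null(value_range)) {
    value_range <- range(heatmap, finite = TRUE)
    if (!all(is.finite(value_range))) return(frame)
  }
  mask <- is.finite(unclass(heatmap))
  if (!any(mask)) return(frame)
  v <- (heatmap[mask] - value_range[1]) /
    max(value_range[2] - value_range[1], .Machine$double.eps)
  v <- pmin(pmax(v, 0), 1)
  ramp <- grDevices::colorRamp(colors)(v) / 255
  out <- frame
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * ramp[, ch]
    out[, , ch] <- plane
  }
  out
}
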