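# Binary morphology on logical matrices, 3x3 square structuring element,
# implemented with padded shifts (FALSE outside the frame).

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

binary_erode <- function(m, size = 3L) {
  r <- (size - 1L) %/% 2L
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- out & shift_mat(m, dy, dx)
  }
  out
}

binary_dilate <- function(m, size = 3L) {
  r <- (size - 1L) %/% 2L
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- out | shift_mat(m, dy, dx)
  }
  out
}

binary_open <- function(m, size = 3L) binary_dilate(binary_erode(m, size), size)
binary_close <- function(m, size = 3L) binary_erode(binary_dilate(m, size), size)

# 8-connected component labels for the TRUE pixels of a logical matrix.
# Returns an integer vector of component ids aligned with which(mask).
label_components <- function(mask) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) return(integer(0))
  h <- nrow(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((idx - 1L) %% h) + 1L
  offsets <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(-1L, -1L),
                  c(1L, -1L), c(0L, 1L), c(-1L, 1L), c(1L, 1L))
  for (off in offsets) {
    nbr <- idx + off[1] + off[2] * h
    ok <- rows + off[1] >= 1L & rows + off[1] <= h &
      nbr >= 1L & nbr <= length(mask)
    ok[ok] <- pos[nbr[ok]] > 0L
    for (i in which(ok)) {
      a <- find(i); b <- find(pos[nbr[i]])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Segment the aiming-beam spot in a white-light frame
#'
#' Converts the frame to HSV, keeps pixels inside the configured blue-violet
#' hue band with saturation and value above threshold, applies a
#' morphological opening (removes speckle) followed by closing (fills the
#' spot core), and takes the largest 8-connected component (ties broken by
#' total intensity).  The detection center is the intensity-weighted
#' (HSV value) centroid of that component.
#'
#' @param frame H x W x 3 RGB array in [0, 1].
#' @param hue_band Hue interval in degrees (0-360) kept as beam-colored.
#' @param sat_min,val_min Minimum saturation / value.
#' @param struct_size Structuring element edge length, pixels.
#' @param min_area Minimum component area (pixels) for a detection.
#' @param expected_radius Nominal beam radius used for the confidence
#'   estimate (`confidence = area / (pi * expected_radius^2)`, capped at 1).
#' @return List of class `beam_detection`: `status` (`"found"` /
#'   `"not_found"`), `center` (x, y; NA when not found), `area`,
#'   `confidence`.
#' @export
segment_aiming_beam <- function(frame, hue_band = c(200, 280),
                                sat_min = 0.4, val_min = 0.08,
                                struct_size = 3L, min_area = 20,
                                expected_radius = 12) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rgb <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
               as.vector(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  mask <- matrix(hue >= hue_band[1] & hue <= hue_band[2] &
                   hsv[2, ] >= sat_min & hsv[3, ] >= val_min, h, w)
  not_found <- list(status = "not_found", center = c(NA_real_, NA_real_),
                    area = 0L, confidence = 0)
  class(not_found) <- "beam_detection"
  if (!any(mask)) return(not_found)
  mask <- binary_close(binary_open(mask, struct_size), struct_size)
  if (!any(mask)) return(not_found)
  labels <- label_components(mask)
  idx <- which(mask)
  val <- matrix(hsv[3, ], h, w)[idx]
  area <- tabulate(match(labels, unique(labels)))
  comp_ids <- unique(labels)
  best_area <- max(area)
  cand <- comp_ids[area == best_area]
  if (length(cand) > 1) {  # tie: higher total intensity wins
    tot <- vapply(cand, function(cid) sum(val[labels == cid]), numeric(1))
    cand <- cand[which.max(tot)]
  }
  keep <- labels == cand[1]
  if (best_area < min_area) return(not_found)
  px <- ((idx[keep] - 1L) %/% h) + 1L   # column = x
  py <- ((idx[keep] - 1L) %% h) + 1L    # row = y
  wgt <- val[keep]
  center <- c(sum(px * wgt), sum(py * wgt)) / sum(wgt)
  structure(list(status = "found", center = center, area = best_area,
                 confidence = min(1, best_area / (pi * expected_radius^2))),
            class = "beam_detection")
}

#' Associate per-frame beam detections with scan points
#'
#' One frame per measurement: detection i is assigned to point i.  Points
#' whose frame yields no detection get NA positions and are excluded from
#' coregistration downstream (logged via the `n_not_found` attribute).
#'
#' @param detections List of `beam_detection` objects, one per scan point.
#' @param n_points Expected number of measurements.
#' @return data.frame `point_index`, `x`, `y`, `status`, `confidence`;
#'   attribute `n_not_found`.
#' @export
track_scan <- function(detections, n_points = length(detections)) {
  if (length(detections) != n_points) {
    stop("have ", length(detections), " detections for ", n_points,
         " measurements")
  }
  out <- data.frame(
    point_index = seq_len(n_points),
    x = vapply(detections, function(d) d$center[1], numeric(1)),
    y = vapply(detections, function(d) d$center[2], numeric(1)),
    status = vapply(detections, function(d) d$status, character(1)),
    confidence = vapply(detections, function(d) d$confidence, numeric(1)))
  attr(out, "n_not_found") <- sum(out$status != "found")
  out
}
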