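# Disc lookup helper: integer pixel offsets within Euclidean distance
# `radius` of the origin, ordered by increasing distance.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d <- sqrt(g$dx^2 + g$dy^2)
  keep <- d <= radius
  g <- g[keep, ]
  g[order(d[keep]), ]
}

#' Assign histology conditions to positioned measurements
#'
#' A point lying on an annotated pixel takes that pixel's condition.
#' Otherwise it takes the condition of the nearest annotated pixel within
#' Euclidean distance `radius` of its (possibly subpixel) position (ties
#' broken deterministically by scan order of the offset table); with no
#' annotated pixel in range the point is left unlabeled.
#'
#' @param points data.frame with `x`, `y` columns (pixel coordinates).
#' @param map An `annotation_map` matrix.
#' @param radius Coregistration radius, pixels (inclusive bound).
#' @return `points` with added `condition` (NA when unlabeled), `group`
#'   (binary class), and `unlabeled` flag columns.
#' @export
assign_labels <- function(points, map, radius = 10) {
  codes <- attr(map, "codes")
  if (is.null(codes)) codes <- annotation_codes(fine = TRUE)
  h <- nrow(map); w <- ncol(map)
  n <- nrow(points)
  cond <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    x <- points$x[i]; y <- points$y[i]
    if (is.na(x) || is.na(y)) next
    xr <- round(x); yr <- round(y)
    if (xr >= 1 && xr <= w && yr >= 1 && yr <= h && map[yr, xr] != 0L) {
      cond[i] <- condition_of(map[yr, xr], codes)
      next
    }
    best_d <- Inf; best_code <- NA_integer_
    for (dy in -ceiling(radius):ceiling(radius)) {
      py <- yr + dy
      if (py < 1 || py > h) next
      for (dx in -ceiling(radius):ceiling(radius)) {
        px <- xr + dx
        if (px < 1 || px > w) next
        code <- map[py, px]
        if (code == 0L) next
        d <- sqrt((px - x)^2 + (py - y)^2)
        if (d <= radius && d < best_d) {
          best_d <- d; best_code <- code
        }
      }
    }
    if (!is.na(best_code)) cond[i] <- condition_of(best_code, codes)
  }
  points$condition <- cond
  points$group <- ifelse(is.na(cond), NA_character_,
                         codes$group[match(cond, codes$condition)])
  points$unlabeled <- is.na(cond)
  points
}

#' Flag measurements near heterogeneous tissue conditions
#'
#' A labeled point whose radius-`radius` disc contains annotated pixels of
#' two or more *binary-disparate* conditions (e.g. cancer and any
#' healthy-group condition) sits on a tissue boundary and is flagged
#' `heterogeneity_excluded`.  Pixels of different conditions that group to
#' the same binary class (thin and thick epithelium, say) do not trigger
#' exclusion.
#'
#' @param points data.frame as returned by [assign_labels()].
#' @param map An `annotation_map`.
#' @param radius Exclusion radius, pixels (inclusive).
#' @return `points` with a `heterogeneity_excluded` flag column.
#' @export
exclude_heterogeneous <- function(points, map, radius = 10) {
  codes <- attr(map, "codes")
  if (is.null(codes)) codes <- annotation_codes(fine = TRUE)
  h <- nrow(map); w <- ncol(map)
  n <- nrow(points)
  flag <- rep(FALSE, n)
  r <- ceiling(radius)
  for (i in seq_len(n)) {
    x <- points$x[i]; y <- points$y[i]
    if (is.na(x) || is.na(y) || isTRUE(points$unlabeled[i])) next
    groups <- character(0)
    for (dy in -r:r) {
      py <- round(y) + dy
      if (py < 1 || py > h) next
      for (dx in -r:r) {
        px <- round(x) + dx
        if (px < 1 || px > w) next
        code <- map[py, px]
        if (code == 0L) next
        if (sqrt((px - x)^2 + (py - y)^2) <= radius) {
          groups <- c(groups, codes$group[match(code, codes$value)])
        }
      }
    }
    flag[i] <- length(unique(groups)) >= 2
  }
  points$heterogeneity_excluded <- flag
  points
}

#' SNR filter across spectral channels 1-3
#'
#' A point passes only if its SNR meets the threshold on every analyzed
#' channel (inclusive bound).  Missing SNR values fail.
#'
#' @param points data.frame with `snr_ch1..3` columns.
#' @param threshold_db SNR threshold, dB.
#' @return `points` with an `snr_pass` flag column.
#' @export
filter_snr <- function(points, threshold_db = 30) {
  snr <- as.matrix(points[, c("snr_ch1", "snr_ch2", "snr_ch3")])
  pass <- rowSums(is.na(snr) | snr < threshold_db) == 0
  points$snr_pass <- pass
  points
}

#' Median-absolute-deviation outlier mask
#'
#' Keeps x iff `|x - median(x)| <= k * MAD` with the raw (unscaled)
#' `MAD = median(|x - median(x)|)`.  When all values are equal the MAD is 0
#' and only values equal to the median survive, which then keeps
#' everything.
#'
#' @param values Numeric vector.
#' @param k Cutoff in MADs.
#' @return Logical keep mask.
#' @export
mad_filter <- function(values, k = 2.5) {
  stopifnot(length(values) >= 1)
  med <- stats::median(values, na.rm = TRUE)
  mad_raw <- stats::median(abs(values - med), na.rm = TRUE)
  keep <- abs(values - med) <= k * mad_raw
  keep & !is.na(values)
}

flim_parameters <- function() {
  c("lifetime_ch1", "lifetime_ch2", "lifetime_ch3",
    "intratio_ch1", "intratio_ch2", "intratio_ch3")
}

#' Apply the full preprocessing filter chain to one patient scan
#'
#' Chains the analysis inclusion rules: histology label present, not
#' heterogeneity-excluded, SNR >= threshold on CH1-3, and per-parameter MAD
#' outlier masks (computed within this scan, i.e. per patient and context,
#' over the points that pass the preceding rules).  Univariate analyses use
#' each parameter's own MAD mask (`mad_pass_<parameter>`); `mad_pass_all`
#' marks points kept by every mask (used for LDA).  `analysis_ready` means
#' label + heterogeneity + SNR passed.
#'
#' @param points Labeled measurement data.frame ([assign_labels()] +
#'   [exclude_heterogeneous()] output with measurement columns).
#' @param snr_db SNR threshold, dB.
#' @param mad_k MAD cutoff.
#' @return Filtered data.frame with flag columns; attribute `filter_counts`
#'   tallies removals per rule.
#' @export
apply_filters <- function(points, snr_db = 30, mad_k = 2.5) {
  points <- filter_snr(points, snr_db)
  n <- nrow(points)
  dropped <- isTRUE_vec(points$dropped)
  base_pass <- !points$unlabeled & !points$heterogeneity_excluded &
    points$snr_pass & !dropped
  params <- flim_parameters()
  mad_all <- rep(TRUE, n)
  for (p in params) {
    keep <- rep(NA, n)
    if (any(base_pass)) keep[base_pass] <- mad_filter(points[[p]][base_pass], mad_k)
    points[[paste0("mad_pass_", p)]] <- keep
    mad_all <- mad_all & (!base_pass | (!is.na(keep) & keep))
  }
  points$mad_pass_all <- base_pass & mad_all
  points$analysis_ready <- base_pass
  attr(points, "filter_counts") <- c(
    total = n,
    dropped_processing = sum(dropped),
    unlabeled = sum(points$unlabeled & !dropped),
    heterogeneity = sum(points$heterogeneity_excluded & !points$unlabeled & !dropped),
    low_snr = sum(!points$snr_pass & !points$unlabeled &
                    !points$heterogeneity_excluded & !dropped),
    mad_any = sum(base_pass & !points$mad_pass_all),
    analysis_ready = sum(base_pass))
  points
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x
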