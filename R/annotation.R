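#' Annotation code table
#'
#' Pixel values of the grayscale histology annotation image and their
#' mapping to tissue conditions and to the binary (healthy vs cancer)
#' grouping used for discrimination.  Four coarse codes cover the study
#' conditions; optional fine codes (thin/thick epithelium, benign dysplasia,
#' benign ulceration) all group to healthy for the binary analysis.
#'
#' @param fine Include the fine-grained condition codes.
#' @return data.frame with columns `value`, `condition`, `group`
#'   (`"none"`, `"healthy"`, or `"cancer"`).
#' @export
annotation_codes <- function(fine = FALSE) {
  coarse <- data.frame(
    value = c(0L, 85L, 170L, 255L),
    condition = c("none", "healthy_epithelium", "cancer", "tumor_bed"),
    group = c("none", "healthy", "cancer", "healthy"))
  if (!fine) return(coarse)
  rbind(coarse, data.frame(
    value = c(60L, 110L, 140L, 200L),
    condition = c("thin_epithelium", "thick_epithelium", "dysplasia",
                  "ulceration"),
    group = c("healthy", "healthy", "healthy", "healthy")))
}

#' Rasterize labeled regions into a grayscale annotation map
#'
#' @param regions List of axis-aligned rectangles: each a list with
#'   `condition` and pixel bounds `x0`, `x1`, `y0`, `y1` (inclusive).
#' @param model A [flim_instrument()] (frame size), or NULL with explicit
#'   `width`/`height`.
#' @param width,height Frame size override, pixels.
#' @param codes Code table, see [annotation_codes()].
#' @return Integer matrix `height x width` (row = y, column = x) of pixel
#'   codes, class `annotation_map`, with the region list and code table as
#'   attributes.  Overlapping regions with different conditions are
#'   rejected (ambiguous ground truth).
#' @export
generate_annotation_map <- function(regions, model = NULL,
                                    width = NULL, height = NULL,
                                    codes = annotation_codes(fine = TRUE)) {
  if (!is.null(model)) {
    width <- model$frame_width; height <- model$frame_height
  }
  stopifnot(!is.null(width), !is.null(height))
  img <- matrix(0L, nrow = height, ncol = width)
  for (r in regions) {
    code <- codes$value[match(r$condition, codes$condition)]
    if (is.na(code)) stop("unknown condition: ", r$condition)
    xs <- max(1, round(r$x0)):min(width, round(r$x1))
    ys <- max(1, round(r$y0)):min(height, round(r$y1))
    patch <- img[ys, xs]
    if (any(patch != 0L & patch != code)) {
      stop("overlapping regions with different conditions at [",
           r$x0, ",", r$x1, "] x [", r$y0, ",", r$y1, "]")
    }
    img[ys, xs] <- code
  }
  structure(img, class = c("annotation_map", "matrix"),
            regions = regions, codes = codes)
}

#' Look up conditions / binary groups for pixel code values
#'
#' @param values Integer pixel values.
#' @param codes Code table.
#' @return Character vector of conditions (`condition_of`) or groups
#'   (`group_of`).
#' @export
condition_of <- function(values, codes = annotation_codes(fine = TRUE)) {
  codes$condition[match(values, codes$value)]
}

#' @rdname condition_of
#' @export
group_of <- function(values, codes = annotation_codes(fine = TRUE)) {
  codes$group[match(values, codes$value)]
}
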