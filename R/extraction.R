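# ---- crop boxes ------------------------------------------------------------

#' Crop window for a detected blob
#'
#' The ideal window is the axis-aligned square whose corners are
#' `(x - r', y - r')`, `(x + r', y - r')`, `(x - r', y + r')`,
#' `(x + r', y + r')` with `r' = scale_factor * radius` -- the corner matrix
#' built from the blob's center and size. It is rasterized by flooring the
#' minima and ceiling the maxima, then clipped to the image bounds
#' (0-based, half-open on the max side: pixels `x_min .. x_max - 1`).
#'
#' @param blob A single-row blob data frame (or list) with `x`, `y`,
#'   `radius`.
#' @param scale_factor Multiplier on the blob radius (> 0); enlarge to
#'   capture surrounding cytoplasm, shrink for tighter nuclear crops.
#' @param image_size `c(height, width)` of the source image.
#' @param min_area_frac Boxes whose clipped area falls below this fraction
#'   of the ideal area are rejected (returns `NULL`); default 0.25.
#' @return A `crop_box` list with `x_min`, `y_min`, `x_max`, `y_max` and the
#'   ideal (unclipped, unrasterized) corners, or `NULL` for a rejected box.
#' @export
crop_box <- function(blob, scale_factor = 1.0, image_size,
                     min_area_frac = 0.25) {
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be > 0", call. = FALSE)
  }
  h <- image_size[1]; w <- image_size[2]
  rp <- scale_factor * blob$radius
  ix_min <- blob$x - rp; ix_max <- blob$x + rp
  iy_min <- blob$y - rp; iy_max <- blob$y + rp

  x_min <- max(0, floor(ix_min)); x_max <- min(w, ceiling(ix_max))
  y_min <- max(0, floor(iy_min)); y_max <- min(h, ceiling(iy_max))
  if (x_min >= x_max || y_min >= y_max) return(NULL)

  ideal_area <- (ceiling(ix_max) - floor(ix_min)) *
                (ceiling(iy_max) - floor(iy_min))
  if ((x_max - x_min) * (y_max - y_min) < min_area_frac * ideal_area) {
    return(NULL)
  }
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 ideal = c(x_min = ix_min, y_min = iy_min,
                           x_max = ix_max, y_max = iy_max),
                 scale_factor = scale_factor, blob = blob),
            class = "crop_box")
}

#' Extract cell segments from an image
#'
#' Crops one sub-image per blob whose crop window survives clipping, from
#' the original image (color, if available) -- detection runs on grayscale
#' but segments keep the stain colors. Blobs whose window is rejected (near
#' frame edges) are skipped; the returned list carries a `dropped` attribute
#' with their indices.
#'
#' @param image Matrix (grayscale) or height x width x 3 array.
#' @param blobs Blob data frame.
#' @param scale_factor Multiplier on each blob radius (see [crop_box()]).
#' @param min_area_frac Passed to [crop_box()].
#' @return A list of `segment` objects (`pixels`, `box`, `blob_index`), in
#'   blob order.
#' @export
extract_segments <- function(image, blobs, scale_factor = 1.0,
                             min_area_frac = 0.25) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  segs <- list()
  dropped <- integer(0)
  for (i in seq_len(nrow(blobs))) {
    box <- crop_box(blobs[i, , drop = FALSE], scale_factor, c(h, w),
                    min_area_frac)
    if (is.null(box)) { dropped <- c(dropped, i); next }
    rows <- (box$y_min + 1L):box$y_max
    cols <- (box$x_min + 1L):box$x_max
    px <- if (length(d) == 3L) image[rows, cols, , drop = FALSE]
          else image[rows, cols, drop = FALSE]
    segs[[length(segs) + 1L]] <- structure(
      list(pixels = px, box = box, blob_index = i), class = "segment")
  }
  attr(segs, "dropped") <- dropped
  segs
}
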