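# ---- configuration ---------------------------------------------------------

#' Detection configuration
#'
#' @param threshold_rel Keep extrema whose response is at least this fraction
#'   of the volume's maximum response; in (0, 1]. Default 0.1.
#' @param threshold_abs Optional absolute response floor (default `NULL`,
#'   none).
#' @param overlap_max Maximum allowed pairwise disc-overlap fraction (of the
#'   smaller disc's area) during non-maximum suppression; in \[0, 1).
#'   Default 0.5.
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold_rel = 0.1, threshold_abs = NULL,
                             overlap_max = 0.5) {
  if (!is.numeric(threshold_rel) || threshold_rel <= 0 || threshold_rel > 1) {
    stop("threshold_rel must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(threshold_abs) && (!is.numeric(threshold_abs) ||
                                  length(threshold_abs) != 1L)) {
    stop("threshold_abs must be NULL or a single number", call. = FALSE)
  }
  if (!is.numeric(overlap_max) || overlap_max < 0 || overlap_max >= 1) {
    stop("overlap_max must lie in [0, 1)", call. = FALSE)
  }
  structure(list(threshold_rel = threshold_rel, threshold_abs = threshold_abs,
                 overlap_max = overlap_max),
            class = "detection_config")
}

empty_blobs <- function(polarity = "dark") {
  data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
             radius = numeric(0), response = numeric(0),
             polarity = character(0), stringsAsFactors = FALSE)
}

# ---- scale-space extremum selection ----------------------------------------

#' Find simultaneous space-scale extrema of a scale-space volume
#'
#' A voxel is selected when its response is strictly greater than all 26
#' neighbors of its 3x3x3 scale-space neighborhood. Only interior scale
#' layers are eligible (an extremum over scale needs a neighbor on both
#' sides) and a spatial border of width 1 is excluded. Surviving voxels
#' become blobs with `sigma` = the layer's scale and `radius = sqrt(2) *
#' sigma`, ordered by descending response (ties broken by y, then x, then
#' sigma).
#'
#' @param volume A `scale_space` from [build_scale_space()].
#' @param config A [detection_config()].
#' @return A data frame of blobs: columns `x`, `y` (0-based pixel centers;
#'   x = column, y = row), `sigma`, `radius`, `response`, `polarity`.
#' @export
find_scale_space_extrema <- function(volume, config = detection_config()) {
  if (!inherits(volume, "scale_space")) {
    stop("volume must be a scale_space object", call. = FALSE)
  }
  vol <- volume$responses
  d <- dim(vol)
  h <- d[1]; w <- d[2]; ns <- d[3]
  if (ns < 3L) stop("need at least 3 scale layers", call. = FALSE)
  if (h < 3L || w < 3L) stop("image too small for extremum search", call. = FALSE)

  # strict maximum over the 26-neighborhood, computed on the interior
  iy <- 2:(h - 1L); ix <- 2:(w - 1L); is <- 2:(ns - 1L)
  center <- vol[iy, ix, is, drop = FALSE]
  nbmax <- array(-Inf, dim = dim(center))
  for (ds in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (ds == 0L && dx == 0L && dy == 0L) next
    nbmax <- pmax(nbmax, vol[iy + dy, ix + dx, is + ds, drop = FALSE])
  }
  keep <- center > nbmax

  thr <- config$threshold_rel * max(vol)
  if (!is.null(config$threshold_abs)) thr <- max(thr, config$threshold_abs)
  keep <- keep & (center >= thr)

  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_blobs(volume$polarity))

  y <- iy[idx[, 1L]] - 1L            # 0-based row
  x <- ix[idx[, 2L]] - 1L            # 0-based column
  s <- volume$sigmas[is[idx[, 3L]]]
  resp <- center[keep]
  blobs <- data.frame(x = as.numeric(x), y = as.numeric(y), sigma = s,
                      radius = sqrt(2) * s, response = resp,
                      polarity = volume$polarity, stringsAsFactors = FALSE)
  ord <- order(-blobs$response, blobs$y, blobs$x, blobs$sigma)
  blobs <- blobs[ord, , drop = FALSE]
  rownames(blobs) <- NULL
  blobs
}

# ---- non-maximum suppression -----------------------------------------------

# area of intersection of two discs
circle_overlap_area <- function(x1, y1, r1, x2, y2, r2) {
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  tri <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                              (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}

#' Greedy non-maximum suppression of overlapping blobs
#'
#' Blobs are visited in descending response order (ties broken by y, x,
#' sigma). A blob is kept unless its disc overlaps an already-kept disc by
#' more than `overlap_max` of the smaller disc's area. Deterministic and
#' stable.
#'
#' @param blobs Blob data frame as returned by [find_scale_space_extrema()].
#' @param overlap_max Maximum tolerated overlap fraction in \[0, 1).
#' @return The surviving subset, same ordering.
#' @export
prune_overlaps <- function(blobs, overlap_max = 0.5) {
  if (nrow(blobs) <= 1L) return(blobs)
  ord <- order(-blobs$response, blobs$y, blobs$x, blobs$sigma)
  blobs <- blobs[ord, , drop = FALSE]
  n <- nrow(blobs)
  kept <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in which(kept)) {
      inter <- circle_overlap_area(blobs$x[i], blobs$y[i], blobs$radius[i],
                                   blobs$x[j], blobs$y[j], blobs$radius[j])
      small <- pi * min(blobs$radius[i], blobs$radius[j])^2
      if (inter > overlap_max * small) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  out <- blobs[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- end-to-end detection --------------------------------------------------

#' Detect blobs in an image
#'
#' Composition of [build_scale_space()], [find_scale_space_extrema()] and
#' [prune_overlaps()]: the end-to-end multiscale nucleus detector.
#' Deterministic for fixed inputs.
#'
#' @inheritParams build_scale_space
#' @param config A [detection_config()].
#' @return Blob data frame (see [find_scale_space_extrema()]).
#' @export
detect_blobs <- function(image, schedule = sigma_schedule(),
                         config = detection_config(),
                         polarity = c("dark", "bright"), truncate = 4) {
  polarity <- match.arg(polarity)
  ss <- build_scale_space(image, schedule, polarity, truncate)
  blobs <- find_scale_space_extrema(ss, config)
  prune_overlaps(blobs, config$overlap_max)
}
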