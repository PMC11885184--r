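# ---- image files -----------------------------------------------------------

#' Read an image file into the package's row/column convention
#'
#' Reads PNG/TIFF/JPEG (8- or 16-bit) and returns either a matrix
#' (grayscale) or a height x width x 3 array, values in \[0, 1\], with
#' rows = image rows. Alpha channels are dropped.
#'
#' @param path Image file path.
#' @return Matrix or 3D array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) return(t(a))
  if (d[3] >= 4L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  if (d[3] == 2L) a <- a[, , 1L, drop = TRUE]     # gray+alpha
  if (length(dim(a)) == 2L) return(t(a))
  aperm(a, c(2L, 1L, 3L))
}

#' Write an image (matrix or RGB array) to PNG/TIFF/JPEG
#'
#' @param image Matrix or height x width x 3 array in \[0, 1\].
#' @param path Output path; format from the extension.
#' @export
write_image <- function(image, path) {
  image[] <- pmin(1, pmax(0, image))   # clamp in place, keep dims
  obj <- if (length(dim(image)) == 3L) {
    EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    EBImage::Image(t(image))
  }
  EBImage::writeImage(obj, path)
  invisible(path)
}

# ---- tables ----------------------------------------------------------------

blob_csv_header <- c("frame", "x", "y", "sigma", "radius", "response",
                     "polarity")

#' Write a blob table to CSV
#'
#' Columns `frame,x,y,sigma,radius,response,polarity`; coordinates are
#' 0-based pixel centers, x = column, y = row.
#'
#' @param blobs Blob data frame; a `frame` column is added (0) if missing.
#' @param path Output CSV path.
#' @export
write_blobs <- function(blobs, path) {
  if (!"frame" %in% names(blobs)) blobs$frame <- rep(0L, nrow(blobs))
  blobs <- blobs[, blob_csv_header, drop = FALSE]
  utils::write.csv(blobs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a blob table written by [write_blobs()]
#' @param path CSV path.
#' @return Blob data frame.
#' @export
read_blobs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(blob_csv_header, names(df))
  if (length(missing) > 0) {
    stop("blob CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a ground-truth annotation table (`frame,x,y,radius`)
#' @param truth Data frame with `x`, `y`, `radius` (and optionally `frame`).
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  if (!"frame" %in% names(truth)) truth$frame <- rep(0L, nrow(truth))
  utils::write.csv(truth[, c("frame", "x", "y", "radius")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("x", "y"), names(df))
  if (length(missing) > 0) {
    stop("truth CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"frame" %in% names(df)) df$frame <- rep(0L, nrow(df))
  df
}

#' Serialize an evaluation report to JSON
#'
#' Percentages are additionally provided rounded half-even to 2 decimals;
#' undefined metrics appear as `null`.
#'
#' @param report An `eval_report` from [compute_metrics()].
#' @param path Output JSON path.
#' @export
write_eval_report <- function(report, path) {
  pct <- function(v) if (is.na(v)) NA else round(100 * v, 2)
  out <- list(
    tp = report$tp, fp = report$fp, fn = report$fn,
    precision = report$precision, recall = report$recall,
    f_measure = report$f_measure, accuracy = report$accuracy,
    precision_pct = pct(report$precision), recall_pct = pct(report$recall),
    f_measure_pct = pct(report$f_measure), accuracy_pct = pct(report$accuracy)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles every tunable of the detection/extraction pipeline; serializes
#' losslessly to YAML (see [write_run_config()]).
#'
#' @param sigma_min,sigma_max,n_sigmas,spacing Scale schedule (see
#'   [sigma_schedule()]).
#' @param polarity `"dark"` or `"bright"`.
#' @param threshold_rel,threshold_abs,overlap_max See [detection_config()].
#' @param crop_scale_factor Multiplier on blob radii for crops.
#' @param stride Process every `stride`-th frame of a sequence.
#' @param output_dir Run directory for artifacts.
#' @param seed RNG seed (synthetic generation only).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(sigma_min = 2, sigma_max = 8, n_sigmas = 10,
                       spacing = "log", polarity = "dark",
                       threshold_rel = 0.1, threshold_abs = NULL,
                       overlap_max = 0.5, crop_scale_factor = 1.0,
                       stride = 1L, output_dir = "cytoblob_run",
                       seed = 1L, log_level = "info") {
  sched <- sigma_schedule(sigma_min, sigma_max, n_sigmas, spacing)  # validates
  cfg <- detection_config(threshold_rel, threshold_abs, overlap_max)
  stopifnot(polarity %in% c("dark", "bright"), stride >= 1,
            crop_scale_factor > 0, log_level %in% c("info", "quiet"))
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 n_sigmas = as.integer(n_sigmas), spacing = spacing,
                 polarity = polarity, threshold_rel = threshold_rel,
                 threshold_abs = threshold_abs, overlap_max = overlap_max,
                 crop_scale_factor = crop_scale_factor,
                 stride = as.integer(stride), output_dir = output_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Save / load a run configuration as YAML (lossless round trip)
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v[!vapply(v, is.null, logical(1))])
}

schedule_from_config <- function(config) {
  sigma_schedule(config$sigma_min, config$sigma_max, config$n_sigmas,
                 config$spacing)
}

detconfig_from_config <- function(config) {
  detection_config(config$threshold_rel, config$threshold_abs,
                   config$overlap_max)
}

# ---- annotated previews ----------------------------------------------------

#' Draw detected blobs onto an image as circles
#'
#' Each blob is drawn as a circle of its radius centered at (x, y), in green
#' -- the visual check that detections sit on nuclei.
#'
#' @param image Matrix or RGB array in \[0, 1\].
#' @param blobs Blob data frame.
#' @param color Length-3 RGB vector for the outlines.
#' @return An RGB array with circles burned in.
#' @export
annotate_blobs <- function(image, blobs, color = c(0, 1, 0)) {
  if (length(dim(image)) == 2L) {
    rgb <- array(rep(image, 3L), dim = c(dim(image), 3L))
  } else rgb <- image
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  for (i in seq_len(nrow(blobs))) {
    r <- blobs$radius[i]
    theta <- seq(0, 2 * pi, length.out = max(16L, ceiling(4 * pi * r)))
    px <- round(blobs$x[i] + r * cos(theta))
    py <- round(blobs$y[i] + r * sin(theta))
    ok <- px >= 0 & px < w & py >= 0 & py < h
    for (c in 1:3) {
      rgb[cbind(py[ok] + 1L, px[ok] + 1L, c)] <- color[c]
    }
  }
  rgb
}
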