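# ---- frame sources ---------------------------------------------------------

#' Define a source of video frames
#'
#' Frames come from a directory of numbered image files (PNG/TIFF/JPEG),
#' sorted by filename -- the layout produced by exporting a slide-sweep
#' video frame by frame. Frame indices are 0-based positions in the sorted
#' listing; `stride` processes every stride-th frame.
#'
#' @param path Directory containing frame images.
#' @param stride Process every `stride`-th frame (>= 1).
#' @param pattern Filename regexp for frames.
#' @return A `frame_source` list with resolved file paths and indices.
#' @export
frame_source <- function(path, stride = 1L,
                         pattern = "\\.(png|tif|tiff|jpg|jpeg)$") {
  if (!dir.exists(path)) stop("not a directory: ", path, call. = FALSE)
  stopifnot(stride >= 1)
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) {
    warning("no frame images found in ", path, call. = FALSE)
  }
  all_idx <- seq_along(files) - 1L
  take <- which(all_idx %% stride == 0L)
  structure(list(origin = "image_directory", path = path,
                 files = files[take], frame_indices = all_idx[take],
                 stride = as.integer(stride)),
            class = "frame_source")
}

#' Decode the frames of a source, in order
#'
#' @param source A [frame_source()].
#' @return List of records `list(frame_index, image)`, stride applied, in
#'   filename order.
#' @export
iterate_frames <- function(source) {
  stopifnot(inherits(source, "frame_source"))
  lapply(seq_along(source$files), function(i) {
    img <- tryCatch(read_image(source$files[i]),
                    error = function(e) stop("failed to decode frame ",
                                             source$files[i], ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    list(frame_index = source$frame_indices[i], image = img)
  })
}

# ---- sequence processing ---------------------------------------------------

run_log <- function(config, path, msg) {
  if (!is.null(path) && !identical(config$log_level, "quiet")) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = path, append = TRUE)
  }
}

#' Run detection and extraction over a frame sequence
#'
#' For each frame: grayscale conversion, multiscale blob detection, segment
#' extraction, and bookkeeping. Per-frame outputs are a pure function of the
#' frame and the configuration (no cross-frame state), so identical inputs
#' produce identical outputs. Failing frames are logged and skipped; the run
#' errors only if every frame fails.
#'
#' Artifacts written under `config$output_dir`: `blobs.csv` (all frames),
#' `counts.csv` (frame_index, n_cells, n_segments), segment PNGs named
#' `frame{F}_blob{B}.png` with `segments.csv` manifest (when
#' `write_segments`), a `run_config.yaml` snapshot and `run.log`.
#'
#' @param source A [frame_source()].
#' @param config A [run_config()].
#' @param write_segments Write each crop as a PNG (default TRUE).
#' @return Invisibly, a list with `blobs` (all frames), `counts` (per-frame
#'   data frame) and `summary` (totals, mean blobs/frame, wall time).
#' @export
process_sequence <- function(source, config = run_config(),
                             write_segments = TRUE) {
  t0 <- Sys.time()
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  run_log(config, log_path,
          sprintf("start: %d frames, stride %d", length(source$files),
                  source$stride))

  schedule <- schedule_from_config(config)
  dcfg <- detconfig_from_config(config)
  all_blobs <- list()
  frame_results <- list()
  manifest <- list()
  n_failed <- 0L

  for (i in seq_along(source$files)) {
    fidx <- source$frame_indices[i]
    res <- tryCatch({
      rgb <- read_image(source$files[i])
      gray <- as_cyto_image(rgb)
      blobs <- detect_blobs(gray, schedule, dcfg, config$polarity)
      segs <- extract_segments(rgb, blobs, config$crop_scale_factor)
      list(blobs = blobs, segs = segs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      run_log(config, log_path,
              sprintf("frame %d FAILED: %s", fidx, conditionMessage(res)))
      next
    }
    blobs <- res$blobs
    if (nrow(blobs) > 0) blobs$frame <- fidx
    all_blobs[[length(all_blobs) + 1L]] <- blobs
    if (write_segments) {
      for (b in seq_along(res$segs)) {
        seg <- res$segs[[b]]
        fn <- sprintf("frame%05d_blob%04d.png", fidx, seg$blob_index - 1L)
        write_image(seg$pixels, file.path(out_dir, fn))
        manifest[[length(manifest) + 1L]] <- data.frame(
          file = fn, frame = fidx,
          x = seg$box$blob$x, y = seg$box$blob$y,
          sigma = seg$box$blob$sigma, radius = seg$box$blob$radius)
      }
    }
    frame_results[[length(frame_results) + 1L]] <-
      list(frame_index = fidx, n_cells = nrow(blobs),
           n_segments = length(res$segs))
    run_log(config, log_path,
            sprintf("frame %d: %d cells, %d segments", fidx, nrow(blobs),
                    length(res$segs)))
  }

  if (length(source$files) > 0L && n_failed == length(source$files)) {
    stop("all frames failed to process", call. = FALSE)
  }

  blobs_df <- if (length(all_blobs) > 0) {
    do.call(rbind, all_blobs)
  } else empty_blobs()
  counts <- if (length(frame_results) > 0) {
    per_frame_counts(frame_results)
  } else {
    data.frame(frame_index = integer(0), n_cells = integer(0),
               n_segments = integer(0))
  }
  write_blobs(blobs_df, file.path(out_dir, "blobs.csv"))
  utils::write.csv(counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE, quote = FALSE)
  if (write_segments && length(manifest) > 0) {
    utils::write.csv(do.call(rbind, manifest),
                     file.path(out_dir, "segments.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary <- list(n_frames = nrow(counts), n_failed = n_failed,
                  total_blobs = sum(counts$n_cells),
                  mean_blobs_per_frame = if (nrow(counts) > 0)
                    mean(counts$n_cells) else NA_real_,
                  wall_time_s = wall)
  run_log(config, log_path,
          sprintf("done: %d frames, %d blobs, %.2fs", summary$n_frames,
                  summary$total_blobs, wall))
  invisible(list(blobs = blobs_df, counts = counts, summary = summary))
}
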