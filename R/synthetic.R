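# ---- reproducible RNG ------------------------------------------------------

# pin the generator algorithm so seeds reproduce across platforms and across
# R sessions regardless of the caller's RNG settings
with_pinned_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(seed)
  force(code)
}

# ---- scene specification ---------------------------------------------------

#' Specification of a synthetic cytology field
#'
#' Describes a stained-cytology-like scene: a bright cytoplasm/background
#' field with a smooth multiplicative stain gradient, dark roughly-circular
#' nuclei rendered as isotropic 2D Gaussians of varying size and darkness,
#' and additive pixel noise. Ground truth (center and radius per nucleus) is
#' exact by construction, with the truth radius following the detector's
#' radius law `r = sqrt(2) * sigma`.
#'
#' @param height,width Field size in pixels.
#' @param n_cells Number of nuclei.
#' @param nucleus_sigma_range `c(min, max)` Gaussian scale of nuclei
#'   (pixels).
#' @param nucleus_darkness_range `c(min, max)` nuclear contrast as a
#'   fraction of local background intensity.
#' @param background_level Mean background intensity in \[0, 1\].
#' @param stain_gradient Amplitude of the smooth multiplicative staining
#'   field (0 = perfectly uniform stain).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param min_separation Minimum center distance between two nuclei, as a
#'   multiple of the sum of their truth radii (ignored when
#'   `allow_overlap = TRUE`).
#' @param allow_overlap Permit overlapping nuclei.
#' @param seed RNG seed; the scene is fully reproducible from it.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 256, width = 256, n_cells = 20,
                       nucleus_sigma_range = c(3, 6),
                       nucleus_darkness_range = c(0.3, 0.6),
                       background_level = 0.85, stain_gradient = 0.1,
                       noise_sd = 0.02, min_separation = 1.2,
                       allow_overlap = FALSE, seed = 1) {
  stopifnot(height >= 3, width >= 3, n_cells >= 0, noise_sd >= 0,
            length(nucleus_sigma_range) == 2,
            nucleus_sigma_range[1] > 0,
            nucleus_sigma_range[2] >= nucleus_sigma_range[1],
            length(nucleus_darkness_range) == 2,
            nucleus_darkness_range[1] > 0,
            nucleus_darkness_range[2] >= nucleus_darkness_range[1],
            background_level > 0, background_level <= 1,
            stain_gradient >= 0, min_separation >= 0)
  structure(list(height = height, width = width, n_cells = n_cells,
                 nucleus_sigma_range = nucleus_sigma_range,
                 nucleus_darkness_range = nucleus_darkness_range,
                 background_level = background_level,
                 stain_gradient = stain_gradient, noise_sd = noise_sd,
                 min_separation = min_separation,
                 allow_overlap = allow_overlap, seed = seed),
            class = "scene_spec")
}

# hematoxylin-eosin-like tint: background eosin pink, fixed and documented
# so the color-to-gray conversion path is exercised by every RGB scene
he_tint <- c(r = 1.00, g = 0.72, b = 0.88)

# smooth multiplicative stain field: low-frequency cosine drift
stain_field <- function(h, w, amplitude, phase) {
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  1 + amplitude * (0.6 * cos(2 * pi * (0.7 * xx + phase[1])) +
                   0.4 * cos(2 * pi * (0.9 * yy + phase[2])))
}

place_nuclei <- function(spec, sigmas) {
  n <- spec$n_cells
  radii <- sqrt(2) * sigmas
  margin <- ceiling(2.5 * sigmas)      # keep nuclei fully inside the field
  xs <- numeric(0); ys <- numeric(0)
  max_tries <- 200L * max(1L, n)
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(paste0("could not place %d nuclei at min_separation ",
                            "%.2f in a %d x %d field"),
                     n, spec$min_separation, spec$height, spec$width),
             call. = FALSE)
      }
      x <- runif(1, margin[i], spec$width - 1 - margin[i])
      y <- runif(1, margin[i], spec$height - 1 - margin[i])
      if (spec$allow_overlap || i == 1L) break
      d <- sqrt((xs - x)^2 + (ys - y)^2)
      need <- spec$min_separation * (radii[seq_len(i - 1L)] + radii[i])
      if (all(d >= need)) break
    }
    xs <- c(xs, x); ys <- c(ys, y)
  }
  data.frame(x = xs, y = ys, sigma = sigmas, radius = radii)
}

#' Generate a synthetic cytology field with exact ground truth
#'
#' Renders the scene described by a [scene_spec()]: multiplicative stain
#' gradient over a bright background, `n_cells` dark Gaussian nuclei at
#' rejection-sampled positions respecting the separation constraint,
#' additive Gaussian noise, clipping to \[0, 1\], and an
#' eosin-pink RGB tint. Bit-reproducible from `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return List with `rgb` (height x width x 3 array), `gray` (the luma the
#'   detector sees), and `truth` (data frame `x`, `y`, `sigma`, `radius`,
#'   0-based pixel-center coordinates).
#' @export
generate_scene <- function(spec = scene_spec()) {
  with_pinned_rng(spec$seed, {
    h <- spec$height; w <- spec$width
    phase <- runif(2)
    bg <- spec$background_level * stain_field(h, w, spec$stain_gradient, phase)

    sig <- runif(spec$n_cells, spec$nucleus_sigma_range[1],
                 spec$nucleus_sigma_range[2])
    dark <- runif(spec$n_cells, spec$nucleus_darkness_range[1],
                  spec$nucleus_darkness_range[2])
    truth <- place_nuclei(spec, sig)

    # nuclei attenuate the local background multiplicatively
    atten <- matrix(0, h, w)
    if (spec$n_cells > 0) {
      yy <- matrix(0:(h - 1), h, w)
      xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
      for (i in seq_len(spec$n_cells)) {
        r2 <- (xx - truth$x[i])^2 + (yy - truth$y[i])^2
        atten <- atten + dark[i] * exp(-r2 / (2 * truth$sigma[i]^2))
      }
    }
    gray_clean <- bg * pmax(0, 1 - atten)
    noisy <- gray_clean + rnorm(h * w, sd = spec$noise_sd)
    intensity <- pmin(1, pmax(0, noisy))

    rgb <- array(0, dim = c(h, w, 3))
    rgb[, , 1] <- intensity * he_tint["r"]
    rgb[, , 2] <- intensity * he_tint["g"]
    rgb[, , 3] <- intensity * he_tint["b"]

    list(rgb = rgb, gray = to_grayscale(rgb), truth = truth, spec = spec)
  })
}

#' Generate a synthetic frame sequence with drift
#'
#' The scene is rendered once and translated by `drift_px_per_frame`
#' (a `c(dx, dy)` vector, pixels per frame, wrap-around) to emulate a slide
#' sweep. Per-frame truth coordinates follow the same translation modulo the
#' field size.
#'
#' @param spec A [scene_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param drift_px_per_frame `c(dx, dy)` integer drift per frame.
#' @return List with `frames` (list of RGB arrays) and `truth` (data frame
#'   `frame`, `x`, `y`, `radius`, frame indices 0-based).
#' @export
generate_sequence <- function(spec = scene_spec(), n_frames = 10,
                              drift_px_per_frame = c(2, 0)) {
  stopifnot(n_frames >= 1)
  drift <- round(drift_px_per_frame)
  scene <- generate_scene(spec)
  h <- spec$height; w <- spec$width
  frames <- vector("list", n_frames)
  truth_list <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    dx <- (f * drift[1]) %% w
    dy <- (f * drift[2]) %% h
    rows <- ((seq_len(h) - 1L - dy) %% h) + 1L
    cols <- ((seq_len(w) - 1L - dx) %% w) + 1L
    frames[[f + 1L]] <- scene$rgb[rows, cols, , drop = FALSE]
    truth_list[[f + 1L]] <- data.frame(
      frame = f,
      x = (scene$truth$x + dx) %% w,
      y = (scene$truth$y + dy) %% h,
      radius = scene$truth$radius
    )
  }
  list(frames = frames, truth = do.call(rbind, truth_list), spec = spec,
       drift = drift)
}
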