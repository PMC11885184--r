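# ---- image container -------------------------------------------------------

#' Coerce to the detector's working image representation
#'
#' The pipeline operates on a plain numeric matrix with rows = image rows (y)
#' and columns = image columns (x), intensities in \[0, 1\]. Integer-valued
#' input in 0--255 is rescaled by 1/255; 3-channel arrays are converted to
#' luma first (see [to_grayscale()]).
#'
#' @param x A numeric matrix (grayscale) or a height x width x 3 array (RGB).
#' @return A numeric matrix with values in \[0, 1\].
#' @export
as_cyto_image <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    return(to_grayscale(x))
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("image must be a numeric matrix or a height x width x 3 array",
         call. = FALSE)
  }
  x <- rescale_intensity(x)
  validate_image(x)
  x
}

rescale_intensity <- function(x) {
  if (any(!is.finite(x))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  mx <- max(x)
  if (mx > 1) {
    # assume an 8- or 16-bit container dtype and map linearly to [0,1]
    denom <- if (mx <= 255) 255 else 65535
    x <- x / denom
  }
  if (min(x) < 0) stop("image intensities must be non-negative", call. = FALSE)
  x
}

validate_image <- function(x) {
  if (nrow(x) < 3L || ncol(x) < 3L) {
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  }
  invisible(x)
}

#' Convert an RGB image to grayscale (Rec. 601 luma)
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114). A single-channel
#' input passes through unchanged (after intensity rescaling).
#'
#' @param rgb A height x width x 3 numeric array, or a matrix (returned as-is
#'   up to rescaling). Values in \[0, 1\] or integers 0--255 (auto-rescaled).
#' @return A numeric matrix of luma values in \[0, 1\].
#' @export
to_grayscale <- function(rgb) {
  if (is.matrix(rgb)) {
    return(as_cyto_image(rgb))
  }
  d <- dim(rgb)
  if (length(d) == 3L && d[3] == 1L) {
    return(as_cyto_image(rgb[, , 1L]))
  }
  if (length(d) != 3L || d[3] != 3L) {
    stop("expected 1 or 3 channels, got shape: ",
         paste(d, collapse = " x "), call. = FALSE)
  }
  rgb <- rescale_intensity(rgb)
  g <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  validate_image(g)
  g
}

# ---- sigma schedule --------------------------------------------------------

#' Build a schedule of Gaussian scales
#'
#' The schedule lists the standard deviations sigma (in pixels) at which the
#' scale-normalized Laplacian is evaluated. Internally the normalization
#' variable is the variance t = sigma^2; all interfaces expose sigma.
#'
#' @param sigma_min,sigma_max Smallest / largest standard deviation (pixels).
#' @param n Number of scales (at least 3: extremum selection needs interior
#'   scale layers).
#' @param spacing `"log"` (geometric, the default: relative scale resolution
#'   is constant) or `"linear"`.
#' @return A `sigma_schedule` object: numeric vector of sigmas with a
#'   `spacing` attribute.
#' @export
sigma_schedule <- function(sigma_min = 2, sigma_max = 8, n = 10,
                           spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(sigma_min) || !is.numeric(sigma_max) ||
      sigma_min <= 0 || sigma_max <= sigma_min) {
    stop("need 0 < sigma_min < sigma_max", call. = FALSE)
  }
  if (n < 3L) stop("schedule needs at least 3 scales", call. = FALSE)
  s <- switch(spacing,
    log    = exp(seq(log(sigma_min), log(sigma_max), length.out = n)),
    linear = seq(sigma_min, sigma_max, length.out = n)
  )
  structure(s, spacing = spacing, class = c("sigma_schedule", "numeric"))
}

as_sigma_schedule <- function(sigmas, spacing = "custom") {
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) < 3L) stop("schedule needs at least 3 scales", call. = FALSE)
  if (any(sigmas <= 0) || any(diff(sigmas) <= 0)) {
    stop("sigmas must be strictly increasing and positive", call. = FALSE)
  }
  structure(sigmas, spacing = spacing, class = c("sigma_schedule", "numeric"))
}

# ---- separable convolution with reflection padding -------------------------

# 1D convolution along rows (vertical) of a matrix, symmetric (reflect)
# padding so constants are preserved exactly at the borders.
conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m)
  if (r >= 1L) {
    top <- pmin(r:1, h)              # symmetric: edge pixel duplicated
    bot <- h + 1L - pmin(seq_len(r), h)
    idx <- c(top, seq_len(h), bot)
  } else idx <- seq_len(h)
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, h, ncol(m))
  for (t in seq_along(k)) {
    out <- out + k[t] * p[t:(t + h - 1L), , drop = FALSE]
  }
  out
}

conv_sep <- function(m, ky, kx) {
  t(conv_rows(t(conv_rows(m, ky)), kx))
}

gauss_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# sampled analytic second derivative of a unit-mass 1D Gaussian;
# zero-sum corrected so constant images are annihilated exactly
gauss_d2_kernel <- function(sigma, truncate = 4) {
  r <- max(2L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

# ---- operators -------------------------------------------------------------

#' Gaussian smoothing
#'
#' Convolves the image with a normalized 2D Gaussian kernel of standard
#' deviation `sigma`, truncated at `truncate * sigma`, with reflection
#' (symmetric) border padding. Satisfies the semigroup property
#' `smooth(smooth(I, s1), s2) ~= smooth(I, sqrt(s1^2 + s2^2))`.
#'
#' @param image A numeric matrix (see [as_cyto_image()]).
#' @param sigma Standard deviation in pixels, > 0.
#' @param truncate Kernel support radius in units of sigma (default 4; the
#'   truncated mass is below 1e-4).
#' @return A matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma, truncate = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  image <- as_cyto_image(image)
  k <- gauss_kernel(sigma, truncate)
  conv_sep(image, k, k)
}

#' Scale-normalized Laplacian-of-Gaussian response
#'
#' Computes `sigma^2 * (Lxx + Lyy)` where `L` is the image smoothed at scale
#' `sigma`; the normalization factor is the variance t = sigma^2, which makes
#' peak responses comparable across scales. Second derivatives are taken by
#' convolution with sampled analytic Gaussian-derivative kernels (separable:
#' d2-Gaussian along one axis, Gaussian along the other). The sign convention
#' gives a positive response for a dark region of size ~sigma on a brighter
#' background.
#'
#' @inheritParams gaussian_smooth
#' @return A matrix of the same shape as `image`.
#' @export
normalized_log_response <- function(image, sigma, truncate = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  image <- as_cyto_image(image)
  g  <- gauss_kernel(sigma, truncate)
  d2 <- gauss_d2_kernel(sigma, truncate)
  lyy <- conv_sep(image, d2, g)
  lxx <- conv_sep(image, g, d2)
  sigma^2 * (lxx + lyy)
}

#' Build the scale-normalized LoG scale-space volume
#'
#' Stacks one normalized-LoG response layer per scale in the schedule. For
#' `polarity = "bright"` every layer is negated, so that downstream extremum
#' search always looks for maxima: with the default `"dark"` polarity the
#' volume responds positively to dark nuclei on a brighter background.
#'
#' @param image A numeric matrix or RGB array (converted via
#'   [as_cyto_image()]).
#' @param schedule A [sigma_schedule()] (or strictly increasing positive
#'   numeric vector of length >= 3).
#' @param polarity `"dark"` (default; stained nuclei) or `"bright"`.
#' @param truncate Kernel truncation radius in sigmas.
#' @return A `scale_space` object: list with `responses` (height x width x
#'   n_scales array), `sigmas`, and `polarity`.
#' @export
build_scale_space <- function(image, schedule = sigma_schedule(),
                              polarity = c("dark", "bright"), truncate = 4) {
  polarity <- match.arg(polarity)
  image <- as_cyto_image(image)
  if (!inherits(schedule, "sigma_schedule")) {
    schedule <- as_sigma_schedule(schedule)
  }
  sgn <- if (polarity == "dark") 1 else -1
  vol <- array(0, dim = c(nrow(image), ncol(image), length(schedule)))
  for (i in seq_along(schedule)) {
    vol[, , i] <- sgn * normalized_log_response(image, schedule[i], truncate)
  }
  structure(
    list(responses = vol, sigmas = as.numeric(schedule), polarity = polarity),
    class = "scale_space"
  )
}

#' @export
print.scale_space <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("scale_space: %d x %d px, %d scales (sigma %.3g..%.3g), polarity=%s\n",
              d[1], d[2], d[3], min(x$sigmas), max(x$sigmas), x$polarity))
  invisible(x)
}
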