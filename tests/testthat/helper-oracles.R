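# Independent oracles used across the suite.

# Brute-force strict 26-neighbor scale-space extremum scan (triple loop over
# interior voxels); returns 0-based (x, y, scale_index) sorted rows.
brute_force_extrema <- function(vol) {
  d <- dim(vol)
  hits <- list()
  for (s in 2:(d[3] - 1L)) for (j in 2:(d[2] - 1L)) for (i in 2:(d[1] - 1L)) {
    v <- vol[i, j, s]
    nb <- vol[(i - 1):(i + 1), (j - 1):(j + 1), (s - 1):(s + 1)]
    if (sum(v > nb) == 26L) {     # strictly greater than all 26 neighbors
      hits[[length(hits) + 1L]] <- c(x = j - 1L, y = i - 1L, s = s - 1L)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(x = integer(0), y = integer(0), s = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, hits))
  out[order(out$x, out$y, out$s), , drop = FALSE]
}

# Disc-disc intersection area by grid quadrature (independent of the
# closed-form lens area used in the package).
grid_circle_overlap <- function(x1, y1, r1, x2, y2, r2, step = 0.02) {
  gx <- seq(min(x1 - r1, x2 - r2), max(x1 + r1, x2 + r2), by = step)
  gy <- seq(min(y1 - r1, y2 - r2), max(y1 + r1, y2 + r2), by = step)
  xx <- rep(gx, times = length(gy))
  yy <- rep(gy, each = length(gx))
  inside <- ((xx - x1)^2 + (yy - y1)^2 <= r1^2) &
            ((xx - x2)^2 + (yy - y2)^2 <= r2^2)
  sum(inside) * step^2
}

# Render a dark Gaussian spot on a constant bright background.
render_spot <- function(size, cx, cy, sigma, bg = 0.9, depth = 0.5) {
  yy <- matrix(0:(size - 1), size, size)
  xx <- t(yy)
  bg - depth * exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sigma^2))
}

# Nearest schedule index for a sigma value (log distance).
schedule_index <- function(schedule, sigma) {
  which.min(abs(log(as.numeric(schedule)) - log(sigma)))
}

# 2x nearest-neighbor upsampling of a matrix.
upsample2 <- function(m) {
  m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L)]
}

# Independent greedy nearest-first one-to-one matcher written as an explicit
# pair-removal loop (no vectorized shortcuts), for cross-checking
# match_detections on small inputs.
greedy_match_loop <- function(bx, by, tx, ty, lim) {
  nb <- length(bx); nt <- length(tx)
  b_free <- rep(TRUE, nb); t_free <- rep(TRUE, nt)
  tp <- 0L
  repeat {
    best <- Inf; bi <- 0L; ti <- 0L
    for (i in seq_len(nb)) for (j in seq_len(nt)) {
      if (b_free[i] && t_free[j]) {
        d <- sqrt((bx[i] - tx[j])^2 + (by[i] - ty[j])^2)
        if (d <= lim && d < best) { best <- d; bi <- i; ti <- j }
      }
    }
    if (bi == 0L) break
    b_free[bi] <- FALSE; t_free[ti] <- FALSE; tp <- tp + 1L
  }
  list(tp = tp, fp = sum(b_free), fn = sum(t_free))
}
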