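#' Render a movie from terminal traces
#'
#' Renders each terminal as an isotropic 2-D Gaussian spot (peak amplitude
#' equal to its trace value that frame, `psf_sigma` pixels wide) over a
#' diffuse background level plus camera offset, adds read/shot noise, and
#' quantizes to 16-bit counts. Deterministic given the RNG state.
#'
#' @param positions numeric matrix with columns `x`, `y` (pixel
#'   coordinates, 1-based continuous).
#' @param traces frames-by-terminals numeric matrix.
#' @param geometry list with `width`, `height`, `psf_sigma`,
#'   `min_separation`, `background`, `offset`.
#' @param noise list with `read_sd`, `shot_scale`; omit or zero for a
#'   noiseless render.
#' @return integer array `[height, width, frames]` of class `frame_stack`
#'   with attributes `geometry`.
#' @export
render_movie <- function(positions, traces, geometry,
                         noise = list(read_sd = 0, shot_scale = 0)) {
  w <- geometry$width; h <- geometry$height
  n_term <- nrow(positions)
  if (n_term != ncol(traces))
    stop("render_movie: positions/traces terminal count mismatch")
  if (n_term > 0) {
    if (any(positions[, "x"] < 1 | positions[, "x"] > w |
            positions[, "y"] < 1 | positions[, "y"] > h))
      stop("render_movie: terminal position out of image bounds")
    if (n_term > 1) {
      d2 <- as.matrix(stats::dist(positions))
      diag(d2) <- Inf
      if (min(d2) < geometry$min_separation * 0.5)
        stop("render_movie: terminal positions closer than separation tolerance")
    }
  }
  n_frames <- nrow(traces)
  half <- ceiling(3 * geometry$psf_sigma)
  # per-terminal pixel footprint (linear indices into a h x w frame) and
  # unit-peak kernel weights
  foot <- vector("list", n_term)
  for (ti in seq_len(n_term)) {
    cx <- positions[ti, "x"]; cy <- positions[ti, "y"]
    xs <- max(1, floor(cx - half)):min(w, ceiling(cx + half))
    ys <- max(1, floor(cy - half)):min(h, ceiling(cy + half))
    gx <- exp(-(xs - cx)^2 / (2 * geometry$psf_sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * geometry$psf_sigma^2))
    k <- outer(gy, gx)                       # rows = y, cols = x
    idx <- outer(ys, (xs - 1L) * h, `+`)
    foot[[ti]] <- list(idx = as.vector(idx), k = as.vector(k))
  }
  base <- geometry$offset + geometry$background
  stack <- array(0L, dim = c(h, w, n_frames))
  read_sd <- if (is.null(noise$read_sd)) 0 else noise$read_sd
  shot <- if (is.null(noise$shot_scale)) 0 else noise$shot_scale
  for (fi in seq_len(n_frames)) {
    frame <- matrix(base, h, w)
    for (ti in seq_len(n_term)) {
      ft <- foot[[ti]]
      frame[ft$idx] <- frame[ft$idx] + traces[fi, ti] * ft$k
    }
    if (read_sd > 0 || shot > 0)
      frame <- frame + stats::rnorm(h * w, 0,
                                    sqrt(read_sd^2 + shot * pmax(frame, 0)))
    stack[, , fi] <- as.integer(pmin(pmax(round(frame), 0), 65535))
  }
  structure(stack, geometry = geometry, class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d x %d px, %d frames, range [%d, %d]\n",
              d[2], d[1], d[3], min(x), max(x)))
  invisible(x)
}
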