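#' Separable Gaussian blur with reflective padding
#' @param img numeric matrix.
#' @param sigma kernel SD, pixels.
#' @return blurred matrix, same dimensions.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_idx <- function(n) {
    idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
    pmin(pmax(idx, 1L), n)
  }
  conv1 <- function(m) {  # along rows (dimension 1)
    n <- nrow(m)
    pad <- m[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Circular region of interest
#' @param roi_id label.
#' @param x,y center, pixels.
#' @param radius pixels.
#' @param kind `"terminal"` or `"background"`.
#' @param partner background partner id (terminal ROIs only).
#' @return a `roi` object.
#' @export
roi <- function(roi_id, x, y, radius = 3, kind = c("terminal", "background"),
                partner = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(radius > 0)
  structure(list(roi_id = roi_id, x = x, y = y, radius = radius,
                 kind = kind, partner = partner), class = "roi")
}

#' Detect bouton puncta in a reference image
#'
#' Difference-of-Gaussians blob detection: local maxima of
#' `blur(sigma_small) - blur(sigma_large)` above `threshold`, accepted
#' greedily in descending DoG intensity (ties broken row-major) subject to
#' a minimum pairwise separation. Returns fixed-radius circular ROIs whose
#' circles lie fully inside the image.
#'
#' @param image 2-D numeric matrix (e.g. the mean baseline-epoch frame).
#' @param sigma_small,sigma_large DoG scales, px.
#' @param threshold DoG intensity threshold; `NULL` uses a robust
#'   data-driven default, `median(dog) + 8 * mad(dog)`.
#' @param min_separation minimum center distance between accepted ROIs, px.
#' @param radius ROI radius, px.
#' @return list of terminal [roi()]s (possibly empty).
#' @export
detect_puncta <- function(image, sigma_small = 1, sigma_large = 3,
                          threshold = NULL, min_separation = 4, radius = 3) {
  if (!is.matrix(image) || length(image) == 0)
    stop("detect_puncta: image must be a non-empty matrix")
  stopifnot(sigma_small > 0, sigma_large > sigma_small, min_separation > 0,
            radius > 0)
  dog <- gaussian_blur(image, sigma_small) - gaussian_blur(image, sigma_large)
  if (is.null(threshold))
    threshold <- stats::median(dog) + 8 * stats::mad(dog)
  h <- nrow(dog); w <- ncol(dog)
  if (h < 3 || w < 3) return(list())
  # strict 8-neighbour local maxima (interior pixels only)
  ctr <- dog[2:(h - 1), 2:(w - 1)]
  is_max <- ctr > threshold &
    ctr >= dog[1:(h - 2), 2:(w - 1)] & ctr >= dog[3:h, 2:(w - 1)] &
    ctr >= dog[2:(h - 1), 1:(w - 2)] & ctr >= dog[2:(h - 1), 3:w] &
    ctr > dog[1:(h - 2), 1:(w - 2)] & ctr > dog[1:(h - 2), 3:w] &
    ctr > dog[3:h, 1:(w - 2)] & ctr > dog[3:h, 3:w]
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(list())
  ys <- hits[, 1] + 1L; xs <- hits[, 2] + 1L
  vals <- dog[cbind(ys, xs)]
  ord <- order(-vals, ys, xs)   # descending intensity, ties row-major
  ys <- ys[ord]; xs <- xs[ord]
  acc_x <- numeric(0); acc_y <- numeric(0)
  for (i in seq_along(xs)) {
    if (xs[i] - radius < 1 || xs[i] + radius > w ||
        ys[i] - radius < 1 || ys[i] + radius > h) next
    if (length(acc_x) &&
        min((acc_x - xs[i])^2 + (acc_y - ys[i])^2) < min_separation^2) next
    acc_x <- c(acc_x, xs[i]); acc_y <- c(acc_y, ys[i])
  }
  lapply(seq_along(acc_x), function(i)
    roi(sprintf("roi%04d", i), acc_x[i], acc_y[i], radius, "terminal"))
}

#' Place adjacent non-synaptic background ROIs
#'
#' For each terminal ROI, searches a ring of candidate positions (8 angles
#' at increasing radial offsets) for the nearest same-radius circle that
#' lies within bounds and overlaps no terminal ROI and no already-placed
#' background ROI. Deterministic given ROI order. Terminals with no valid
#' position within `max_offset` are dropped and reported.
#'
#' @param rois list of terminal [roi()]s.
#' @param image_dim `c(height, width)` of the image.
#' @param max_offset maximum search offset from the terminal center, px.
#' @return list with `rois` (terminal ROIs with `partner` set, followed by
#'   background ROIs) and `excluded` (character vector of dropped ids).
#' @export
place_background_rois <- function(rois, image_dim, max_offset = 30) {
  h <- image_dim[1]; w <- image_dim[2]
  term_x <- vapply(rois, `[[`, 0, "x")
  term_y <- vapply(rois, `[[`, 0, "y")
  bg <- list(); excluded <- character(0)
  angles <- (0:7) * pi / 4
  for (i in seq_along(rois)) {
    r <- rois[[i]]$radius
    offsets <- seq(2 * r + 1, max_offset)
    placed <- FALSE
    for (d in offsets) {
      for (a in angles) {
        cx <- rois[[i]]$x + d * cos(a)
        cy <- rois[[i]]$y + d * sin(a)
        if (cx - r < 1 || cx + r > w || cy - r < 1 || cy + r > h) next
        min_d2_term <- min((term_x - cx)^2 + (term_y - cy)^2)
        if (min_d2_term < (2 * r)^2) next
        if (length(bg)) {
          bx <- vapply(bg, `[[`, 0, "x"); by <- vapply(bg, `[[`, 0, "y")
          if (min((bx - cx)^2 + (by - cy)^2) < (2 * r)^2) next
        }
        bid <- paste0(rois[[i]]$roi_id, "_bg")
        bg[[length(bg) + 1]] <- roi(bid, cx, cy, r, "background")
        rois[[i]]$partner <- bid
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed) excluded <- c(excluded, rois[[i]]$roi_id)
  }
  keep <- vapply(rois, function(r) !is.na(r$partner), TRUE)
  list(rois = c(rois[keep], bg), excluded = excluded)
}

#' Extract the per-frame mean trace of a circular ROI
#'
#' Pixel membership is center-in-circle, fixed once per ROI.
#'
#' @param stack a `frame_stack` (`[height, width, frames]`).
#' @param roi a [roi()].
#' @param frame_rate Hz, attached to the returned trace.
#' @return a `trace` object: list with `values`, `frame_rate`, `roi_id`,
#'   `corrected`.
#' @export
extract_trace <- function(stack, roi, frame_rate = NA_real_) {
  d <- dim(stack)
  if (roi$x - roi$radius < 1 || roi$x + roi$radius > d[2] ||
      roi$y - roi$radius < 1 || roi$y + roi$radius > d[1])
    stop("extract_trace: ROI out of bounds: ", roi$roi_id)
  xs <- floor(roi$x - roi$radius):ceiling(roi$x + roi$radius)
  ys <- floor(roi$y - roi$radius):ceiling(roi$y + roi$radius)
  grid <- expand.grid(y = ys, x = xs)
  inside <- (grid$x - roi$x)^2 + (grid$y - roi$y)^2 <= roi$radius^2
  grid <- grid[inside, ]
  n_frames <- d[3]
  flat <- matrix(as.numeric(stack), d[1] * d[2], n_frames)
  idx <- grid$y + (grid$x - 1) * d[1]
  values <- colMeans(flat[idx, , drop = FALSE])
  structure(list(values = values, frame_rate = frame_rate,
                 roi_id = roi$roi_id, corrected = FALSE), class = "trace")
}

#' Background-correct a terminal trace
#'
#' Frame-wise subtraction of the paired background-ROI trace.
#'
#' @param terminal_trace,background_trace `trace` objects of equal length
#'   and frame rate.
#' @return corrected `trace`.
#' @export
background_correct <- function(terminal_trace, background_trace) {
  if (length(terminal_trace$values) != length(background_trace$values))
    stop("background_correct: trace length mismatch")
  if (!isTRUE(all.equal(terminal_trace$frame_rate,
                        background_trace$frame_rate)))
    stop("background_correct: frame rate mismatch")
  out <- terminal_trace
  out$values <- terminal_trace$values - background_trace$values
  out$corrected <- TRUE
  out
}

#' Average aligned single-AP trials
#'
#' Frame-wise mean across trials sharing a stimulus alignment.
#'
#' @param traces list of `trace` objects (or numeric vectors) of equal
#'   length and frame rate.
#' @return averaged `trace`.
#' @export
average_trials <- function(traces) {
  if (length(traces) == 0) stop("average_trials: empty trial list")
  vals <- lapply(traces, function(tr)
    if (inherits(tr, "trace")) tr$values else as.numeric(tr))
  lens <- vapply(vals, length, 0L)
  if (length(unique(lens)) != 1)
    stop("average_trials: mismatched trial lengths")
  out <- if (inherits(traces[[1]], "trace")) traces[[1]] else
    structure(list(values = NULL, frame_rate = NA_real_, roi_id = NA,
                   corrected = FALSE), class = "trace")
  out$values <- Reduce(`+`, vals) / length(vals)
  out
}

#' Split a multi-trial recording into per-trial blocks
#' @param values full-recording numeric vector.
#' @param protocol a [stimulus_protocol()].
#' @return list of per-trial numeric vectors (length `trial_frames` each).
#' @export
split_trials <- function(values, protocol) {
  lapply(seq_len(protocol$n_trials), function(tr) {
    i0 <- (tr - 1L) * protocol$trial_frames
    values[i0 + seq_len(protocol$trial_frames)]
  })
}

#' Write/read an ROI table as CSV
#' @param rois list of [roi()]s.
#' @param path CSV file.
#' @export
write_roi_table <- function(rois, path) {
  dt <- data.table::rbindlist(lapply(rois, function(r)
    data.table::data.table(roi_id = r$roi_id, kind = r$kind, x = r$x,
                           y = r$y, radius = r$radius, partner = r$partner)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  dt <- data.table::fread(path)
  lapply(seq_len(nrow(dt)), function(i)
    roi(dt$roi_id[i], dt$x[i], dt$y[i], dt$radius[i], dt$kind[i],
        as.character(dt$partner[i])))
}
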