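test_that("detection returns nothing on a structureless image", {
  expect_equal(detect_puncta(matrix(100, 64, 64), threshold = 1), list())
  expect_error(detect_puncta(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("well-separated spots are recovered at their centers", {
  pos <- cbind(x = c(12, 30, 50, 20, 45), y = c(15, 40, 12, 52, 50))
  img <- spot_image(pos, amplitudes = c(80, 120, 100, 90, 110))
  rois <- detect_puncta(img, threshold = 5)
  expect_length(rois, 5)
  found <- cbind(vapply(rois, `[[`, 0, "x"), vapply(rois, `[[`, 0, "y"))
  for (i in seq_len(nrow(pos))) {
    d <- sqrt((found[, 1] - pos[i, "x"])^2 + (found[, 2] - pos[i, "y"])^2)
    expect_lte(min(d), 1)
  }
  # deterministic order: descending intensity
  expect_equal(rois[[1]]$x, 30)
})

test_that("greedy suppression keeps the brighter of two close spots", {
  pos <- cbind(x = c(30, 32), y = c(30, 31))
  img <- spot_image(pos, amplitudes = c(60, 140))
  rois <- detect_puncta(img, threshold = 5, min_separation = 6)
  expect_length(rois, 1)
  expect_lte(sqrt((rois[[1]]$x - 32)^2 + (rois[[1]]$y - 31)^2), 1)
})

test_that("background ROIs land on the first unobstructed candidate", {
  r <- list(roi("t1", 30, 30, 3, "terminal"))
  placed <- place_background_rois(r, c(64, 64))
  expect_length(placed$excluded, 0)
  bg <- placed$rois[[2]]
  # first enumeration point: offset 2*radius + 1 at angle 0
  expect_equal(c(bg$x, bg$y), c(37, 30))
  expect_equal(placed$rois[[1]]$partner, "t1_bg")
})

test_that("background placement respects bounds and non-overlap", {
  rs <- list(roi("t1", 61, 32, 3, "terminal"),
             roi("t2", 54, 32, 3, "terminal"))
  placed <- place_background_rois(rs, c(64, 64))
  term <- Filter(function(r) r$kind == "terminal", placed$rois)
  bg <- Filter(function(r) r$kind == "background", placed$rois)
  for (b in bg) {
    expect_true(b$x - b$radius >= 1 && b$x + b$radius <= 64)
    expect_true(b$y - b$radius >= 1 && b$y + b$radius <= 64)
    for (t in term)
      expect_gte(sqrt((t$x - b$x)^2 + (t$y - b$y)^2), 2 * b$radius)
  }
  d_bg <- sqrt((bg[[1]]$x - bg[[2]]$x)^2 + (bg[[1]]$y - bg[[2]]$y)^2)
  expect_gte(d_bg, 2 * bg[[1]]$radius)
})

test_that("crowded terminals with no background slot are flagged", {
  # a dense grid leaves no room within a tiny search radius
  xs <- rep(seq(8, 56, by = 7), times = 8)
  ys <- rep(seq(8, 56, by = 7), each = 8)
  rs <- lapply(seq_along(xs), function(i)
    roi(sprintf("t%02d", i), xs[i], ys[i], 3, "terminal"))
  placed <- place_background_rois(rs, c(64, 64), max_offset = 7)
  expect_gt(length(placed$excluded), 0)
})

test_that("extract_trace is the in-circle pixel mean", {
  stack <- array(7, dim = c(32, 32, 4))
  tr <- extract_trace(stack, roi("a", 16, 16, 3), frame_rate = 50)
  expect_equal(tr$values, rep(7, 4))
  # linearity: trace(A + B) = trace(A) + trace(B)
  a <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  b <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  r <- roi("a", 10, 20, 3)
  expect_equal(extract_trace(a + b, r)$values,
               extract_trace(a, r)$values + extract_trace(b, r)$values)
  expect_error(extract_trace(stack, roi("e", 31, 16, 3)), "out of bounds")
})

test_that("background correction subtracts frame-wise", {
  t1 <- structure(list(values = c(5, 6, 7), frame_rate = 50, roi_id = "a",
                       corrected = FALSE), class = "trace")
  t2 <- t1
  expect_equal(background_correct(t1, t2)$values, c(0, 0, 0))
  zero <- t1; zero$values <- c(0, 0, 0)
  out <- background_correct(t1, zero)
  expect_equal(out$values, t1$values)
  expect_true(out$corrected)
  # a shared additive offset cancels
  off1 <- t1; off1$values <- t1$values + 100
  off2 <- zero; off2$values <- zero$values + 100
  expect_equal(background_correct(off1, off2)$values, t1$values)
  short <- t1; short$values <- c(1, 2)
  expect_error(background_correct(t1, short), "length mismatch")
})

test_that("trial averaging is the frame-wise mean with 1/sqrt(n) noise law", {
  tr <- structure(list(values = sin(1:40), frame_rate = 100, roi_id = "a",
                       corrected = TRUE), class = "trace")
  expect_equal(average_trials(list(tr, tr, tr))$values, tr$values)
  expect_equal(average_trials(list(tr))$values, tr$values)
  set.seed(8)
  sigma <- 2
  resid_sd <- replicate(200, {
    trials <- lapply(1:15, function(i) sin(1:40) + rnorm(40, 0, sigma))
    stats::sd(average_trials(trials)$values - sin(1:40))
  })
  expect_equal(mean(resid_sd), sigma / sqrt(15), tolerance = 0.05)
  expect_error(average_trials(list()), "empty")
  expect_error(average_trials(list(tr, 1:3)), "mismatched")
})

test_that("noiseless movies round-trip traces through extraction", {
  cfg <- small_config(n_neurons = 1, n_terminals = 10, conditions = 2,
                      noise = noiseless, traces_only = FALSE,
                      geometry = list(width = 96, height = 96,
                                      psf_sigma = 1.5, min_separation = 6,
                                      background = 10, offset = 100))
  ds <- generate_dataset(cfg)
  rec <- ds$recordings$neuron01[["2"]]
  q <- quantify_stack(rec$movie, cfg$protocol)
  expect_gte(ncol(q$traces), 9)
  # match each detected ROI to its generating terminal and check
  # proportionality of the corrected deflection to the true trace
  term <- Filter(function(r) r$kind == "terminal", q$rois)
  for (i in seq_along(term)) {
    d <- sqrt((rec$positions[, "x"] - term[[i]]$x)^2 +
              (rec$positions[, "y"] - term[[i]]$y)^2)
    j <- which.min(d)
    expect_lte(d[j], 1.5)
    true_dev <- rec$noiseless[, j] - rec$noiseless[1, j]
    meas_dev <- q$traces[, i] - q$traces[1, i]
    if (stats::sd(true_dev) > 0)
      expect_gt(stats::cor(true_dev, meas_dev)^2, 0.999)
  }
})

test_that("detection on default-noise movies has high recall, low FDR", {
  cfg <- small_config(n_neurons = 1, n_terminals = 30, conditions = 2,
                      seed = 21, traces_only = FALSE,
                      geometry = list(width = 128, height = 128,
                                      psf_sigma = 1.5, min_separation = 5,
                                      background = 20, offset = 100))
  ds <- generate_dataset(cfg)
  rec <- ds$recordings$neuron01[["2"]]
  ref <- apply(rec$movie[, , 1:49], c(1, 2), mean)
  rois <- detect_puncta(ref)
  found <- cbind(vapply(rois, `[[`, 0, "x"), vapply(rois, `[[`, 0, "y"))
  hit <- vapply(seq_len(30), function(i)
    min(sqrt((found[, 1] - rec$positions[i, "x"])^2 +
             (found[, 2] - rec$positions[i, "y"])^2)) <= 2, TRUE)
  matched <- vapply(seq_len(nrow(found)), function(k)
    min(sqrt((rec$positions[, "x"] - found[k, 1])^2 +
             (rec$positions[, "y"] - found[k, 2])^2)) <= 2, TRUE)
  expect_gte(mean(hit), 0.95)            # recall
  expect_lte(mean(!matched), 0.05)       # false discovery
})

test_that("ROI tables round-trip through CSV", {
  rs <- list(roi("t1", 10, 12, 3, "terminal", "t1_bg"),
             roi("t1_bg", 17, 12, 3, "background"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(rs, path)
  back <- read_roi_table(path)
  expect_equal(back[[1]]$x, 10)
  expect_equal(back[[1]]$partner, "t1_bg")
  expect_equal(back[[2]]$kind, "background")
})
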