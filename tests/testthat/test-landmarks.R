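test_that("nasion estimate combines eye and nose boxes", {
  er <- bounding_box(top = 50, left = 10, width = 20, height = 12)
  el <- bounding_box(top = 50, left = 70, width = 20, height = 12)
  nose <- bounding_box(top = 70, left = 45, width = 10, height = 10)
  n <- nasion_intrinsic(er, el, nose)
  expect_equal(n$row, 56)   # mean vertical center of the eye boxes
  expect_equal(n$col, 50)   # mean of eye-pair midpoint and nose center

  # mirror-symmetric configuration about column c: estimate lands on c
  c0 <- 83.5
  er2 <- bounding_box(40, c0 - 30, 14, 10)
  el2 <- bounding_box(40, c0 + 30 - 14, 14, 10)
  nose2 <- bounding_box(60, c0 - 6, 12, 9)
  expect_equal(nasion_intrinsic(er2, el2, nose2)$col, c0)

  # both eyes at identical vertical center v: row is v
  expect_equal(nasion_intrinsic(
    bounding_box(30, 10, 10, 20), bounding_box(35, 60, 10, 10),
    nose)$row, 40)

  expect_error(nasion_intrinsic(el, er, nose), "left of")
})

test_that("nasion lies inside the span of its source boxes", {
  set.seed(42)
  for (i in 1:50) {
    er <- bounding_box(runif(1, 20, 60), runif(1, 5, 40),
                       runif(1, 5, 25), runif(1, 5, 20))
    el <- bounding_box(runif(1, 20, 60), er$left + er$width + runif(1, 5, 40),
                       runif(1, 5, 25), runif(1, 5, 20))
    nose <- bounding_box(runif(1, 50, 80),
                         (er$left + el$left) / 2 + runif(1, -10, 10),
                         runif(1, 5, 20), runif(1, 5, 20))
    n <- nasion_intrinsic(er, el, nose)
    vc <- c(er$top + er$height / 2, el$top + el$height / 2)
    expect_gte(n$row, min(vc)); expect_lte(n$row, max(vc))
    cols <- c(er$left, el$left + el$width, nose$left, nose$left + nose$width)
    expect_gte(n$col, min(cols)); expect_lte(n$col, max(cols))
  }
})

test_that("ear closest points sit mid-edge and corrections pull inward", {
  box <- bounding_box(top = 200, left = 100, width = 50, height = 60)
  rcp <- right_cp(box); lcp <- left_cp(box)
  expect_equal(c(rcp$col, rcp$row), c(150, 230))
  expect_equal(c(lcp$col, lcp$row), c(100, 230))

  rpp <- right_pp(box); lpp <- left_pp(box)
  expect_equal(c(rpp$col, rpp$row), c(140, 221.6))
  expect_equal(c(lpp$col, lpp$row), c(110, 221.6))

  # the correction shrinks the horizontal coordinate by 20% of the width
  # and the vertical by 14% of the height, both sides
  expect_equal(rcp$col - rpp$col, 0.2 * box$width)
  expect_equal(rcp$row - rpp$row, 0.14 * box$height)
  expect_equal(lpp$col - lcp$col, 0.2 * box$width)
  expect_equal(lcp$row - lpp$row, 0.14 * box$height)

  # corrected points lie strictly inside any box
  set.seed(9)
  for (i in 1:25) {
    b <- bounding_box(runif(1, 1, 100), runif(1, 1, 100),
                      runif(1, 1, 80), runif(1, 1, 80))
    for (p in list(right_pp(b), left_pp(b))) {
      expect_gt(p$col, b$left); expect_lt(p$col, b$left + b$width)
      expect_gt(p$row, b$top); expect_lt(p$row, b$top + b$height)
    }
  }

  expect_error(bounding_box(1, 1, 0, 10), "positive")
})

test_that("grid search recovers the correction fractions", {
  set.seed(11)
  gen <- function(a, b, n, noise = 0) {
    # balanced +/- noise signs; box sides >= 40 px so the L1 optimum stays
    # within 1/40 = 0.025 of the generating fractions
    sgn <- rep(c(-1, 1), length.out = n)
    lapply(seq_len(n), function(i) {
      box <- bounding_box(runif(1, 10, 120), runif(1, 10, 120),
                          runif(1, 40, 70), runif(1, 40, 80))
      list(box = box,
           col = box$left + a * box$width + noise * sgn[i],
           row = box$top + b * box$height - noise * sgn[i])
    })
  }
  # exact samples, step 0.01: exact recovery (zero-loss optimum)
  fit <- calibrate_pp_correction(gen(0.8, 0.36, 12), grid_step = 0.01)
  expect_equal(as.numeric(fit), c(0.80, 0.36))
  expect_equal(attr(fit, "loss"), 0, tolerance = 1e-9)

  # symmetric +/-1 px perturbations: matches the exhaustive joint-grid
  # oracle and stays within the L1 breakpoint band of the true fractions
  noisy <- gen(0.8, 0.36, 40, noise = 1)
  fit2 <- calibrate_pp_correction(noisy, grid_step = 0.01)
  expect_equal(as.numeric(fit2), brute_calibrate(noisy, 0.01),
               tolerance = 1e-12)
  expect_lte(abs(fit2[["a_col"]] - 0.8), 0.03)
  expect_lte(abs(fit2[["b_row"]] - 0.36), 0.03)

  # coarse grid snaps to the nearest grid point
  fit3 <- calibrate_pp_correction(gen(0.8, 0.36, 12), grid_step = 0.5)
  expect_equal(as.numeric(fit3), c(1.0, 0.5))

  expect_error(calibrate_pp_correction(list()), "no calibration samples")
})

test_that("find_arcs extracts circular success runs", {
  mk_table <- function(flags, step = 1)
    structure(list(azimuths = seq(0, by = step, length.out = length(flags)),
                   success = flags, step = step,
                   detections = vector("list", length(flags))),
              class = "detection_table")
  f <- rep(FALSE, 360); f[101:141] <- TRUE; f[201:206] <- TRUE
  arcs <- find_arcs(mk_table(f))
  expect_length(arcs, 2L)
  expect_equal(c(arcs[[1]]$start_deg, arcs[[1]]$end_deg,
                 arcs[[1]]$length_deg), c(100, 140, 41))
  expect_equal(c(arcs[[2]]$start_deg, arcs[[2]]$end_deg,
                 arcs[[2]]$length_deg), c(200, 205, 6))

  # wraparound: 350..359 and 0..10 merge into one arc of 21 degrees
  f2 <- rep(FALSE, 360); f2[c(351:360, 1:11)] <- TRUE
  arcs2 <- find_arcs(mk_table(f2))
  expect_length(arcs2, 1L)
  expect_equal(c(arcs2[[1]]$start_deg, arcs2[[1]]$end_deg,
                 arcs2[[1]]$length_deg), c(350, 10, 21))

  expect_length(find_arcs(mk_table(rep(FALSE, 360))), 0L)
  expect_equal(find_arcs(mk_table(rep(TRUE, 72), step = 5))[[1]]$length_deg,
               360)
})

test_that("best view maximizes eye area weighted by symmetry", {
  mk_det <- function(al, ar) list(
    eye_left = fd_detection("eye_left", bounding_box(10, 60, al, 1)),
    eye_right = fd_detection("eye_right", bounding_box(10, 10, ar, 1)),
    face = fd_detection("face", bounding_box(5, 5, 90, 90)),
    nose = fd_detection("nose", bounding_box(40, 45, 10, 10)))
  tab <- structure(list(
    azimuths = 0:9, step = 1,
    success = rep(TRUE, 10),
    detections = lapply(1:10, function(i) mk_det(10 + i, 20 - i))),
    class = "detection_table")
  arcs <- find_arcs(tab)
  best <- select_best_view(tab, arcs)
  # brute-force the score over the arc
  scores <- sapply(tab$detections, function(d) {
    al <- d$eye_left$box$width * d$eye_left$box$height
    ar <- d$eye_right$box$width * d$eye_right$box$height
    (al + ar) * (1 - abs(al - ar) / (al + ar))
  })
  expect_equal(best, tab$azimuths[which.max(scores)])

  # exact tie goes to the smaller azimuth
  tab2 <- tab
  tab2$detections <- lapply(1:10, function(i) mk_det(12, 12))
  expect_equal(select_best_view(tab2, find_arcs(tab2)), 0)

  expect_error(select_best_view(tab, list()), "no detection arc")
})

test_that("azimuth scan flags success where both eyes are visible", {
  h <- fixture_head()
  od <- make_oracle_detectors(h$truth)
  tab <- scan_face_elements(h$mesh, od$detectors, step = 5)
  expect_length(tab$azimuths, 72L)

  # independent visibility oracle straight from fresh depth buffers
  vis <- sapply(tab$azimuths, function(a) {
    v <- render_view(h$mesh, view_spec(h$mesh, a))
    landmark_visible(v, h$truth$eye_left, tol = 6) &&
      landmark_visible(v, h$truth$eye_right, tol = 6)
  })
  expect_equal(tab$success, unname(vis))

  # detectors that always fail produce an all-false table
  dud <- fd_detector(function(view, el) list(),
                     c("face", "eye_left", "eye_right", "nose", "mouth"),
                     name = "dud")
  tab2 <- scan_face_elements(h$mesh, list(face = dud), step = 90)
  expect_length(tab2$azimuths, 4L)
  expect_false(any(tab2$success))
})
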