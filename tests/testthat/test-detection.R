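test_that("cascade arithmetic follows f^s and t^s", {
  expect_equal(cascade_total_far(cascade_spec(0.3, 11)), 0.000002,
               tolerance = 1e-6 / 0.000002)
  expect_equal(cascade_total_far(cascade_spec(0.3, 8)), 0.000066,
               tolerance = 1e-6 / 0.000066)
  expect_identical(cascade_total_far(cascade_spec(0.42, 1)), 0.42)

  expect_equal(cascade_total_tpr(cascade_spec(0.3, 11, t = 1)), 1)
  expect_equal(cascade_total_tpr(cascade_spec(0.5, 11, t = 0.99)),
               0.99^11)
  expect_equal(round(0.99^11, 4), 0.8953)  # frozen from direct exponentiation

  expect_error(cascade_spec(1.2, 5), "FAR")
  expect_error(cascade_spec(0.5, 0), "stage count")
  expect_error(cascade_spec(0.5, 5, t = 0), "TPR")
})

test_that("total FAR is monotone in stages and per-stage rate", {
  for (f in seq(0.1, 0.9, by = 0.2)) {
    fars <- sapply(1:30, function(s) cascade_total_far(cascade_spec(f, s)))
    expect_true(all(diff(fars) < 0))
    tprs <- sapply(1:30, function(s)
      cascade_total_tpr(cascade_spec(f, s, t = 0.97)))
    expect_true(all(diff(tprs) < 0))
  }
  for (s in c(1L, 5L, 20L)) {
    fars <- sapply(seq(0.05, 0.95, by = 0.05), function(f)
      cascade_total_far(cascade_spec(f, s)))
    expect_true(all(diff(fars) > 0))
  }
})

test_that("oracle detectors box the projected landmarks, only when visible", {
  h <- fixture_head()
  od <- make_oracle_detectors(h$truth)
  frontal <- render_view(h$mesh, view_spec(h$mesh, h$truth$yaw_deg))

  for (el in c("eye_left", "eye_right")) {
    hits <- detect(frontal, el, od$detectors[[el]])
    expect_length(hits, 1L)
    p <- project_points(h$truth[[el]], frontal$spec)
    b <- hits[[1]]$box
    expect_gte(p$col, b$left); expect_lte(p$col, b$left + b$width)
    expect_gte(p$row, b$top); expect_lte(p$row, b$top + b$height)
  }

  # landmark back-facing: empty result
  back <- render_view(h$mesh, view_spec(h$mesh, h$truth$yaw_deg + 180))
  expect_length(detect(back, "eye_left", od$detectors$eye_left), 0L)
  lat_r <- render_view(h$mesh, view_spec(h$mesh, h$truth$yaw_deg - 87))
  expect_length(detect(lat_r, "ear_left",
                       od$ear_ladders$left$detectors[[1]]), 0L)

  expect_error(detect(frontal, "ear_left", od$detectors$face),
               "does not support")
})

test_that("detector ladder orders by total FAR and short-circuits", {
  h <- fixture_head()
  lat <- h$truth$yaw_deg + 87
  views <- lapply(lat + (-5:5), function(a)
    render_view(h$mesh, view_spec(h$mesh, a %% 360)))

  box_at <- function(top, left) bounding_box(top, left, 20, 30)
  mk <- function(name, far_f, far_s, fn)
    fd_detector(fn, c("ear_left", "ear_right"), name = name,
                cascade = cascade_spec(far_f, far_s))

  # strict detector finds one box: looser detectors must never run
  called <- character()
  d_strict <- mk("strict", 0.3, 11, function(view, el) {
    called <<- c(called, "strict")
    list(fd_detection(el, box_at(40, 40)))
  })
  d_loose <- mk("loose", 0.9, 2, function(view, el) {
    called <<- c(called, "loose")
    list(fd_detection(el, box_at(10, 10)))
  })
  ladder <- detector_ladder(list(d_loose, d_strict))  # order in, FAR out
  expect_equal(vapply(ladder$detectors, function(d) d$name, ""),
               c("strict", "loose"))
  hit <- ear_ladder_detect(views, "left", ladder)
  expect_equal(attr(hit, "detector"), "strict")
  expect_false("loose" %in% called)

  # first detector always empty, second hits only at the window edge view
  edge_az <- views[[1]]$spec$azimuth_deg
  d_empty <- mk("empty", 0.3, 11, function(view, el) list())
  d_edge <- mk("edge", 0.8, 3, function(view, el) {
    if (isTRUE(all.equal(view$spec$azimuth_deg, edge_az)))
      list(fd_detection(el, box_at(77, 33))) else list()
  })
  hit2 <- ear_ladder_detect(views, "left", detector_ladder(
    list(d_edge, d_empty)))
  expect_equal(attr(hit2, "detector"), "edge")
  expect_equal(hit2$box$top, 77)

  # multi-box views are failures for that detector; a clean single-box
  # detector further down the ladder wins
  d_multi <- mk("multi", 0.3, 11, function(view, el)
    list(fd_detection(el, box_at(10, 10)), fd_detection(el, box_at(50, 50))))
  hit3 <- ear_ladder_detect(views, "left",
                            detector_ladder(list(d_multi, d_loose)))
  expect_equal(attr(hit3, "detector"), "loose")

  # exhausted ladder errors with diagnostics
  err <- tryCatch(
    ear_ladder_detect(views, "left", detector_ladder(list(d_empty))),
    error = identity)
  expect_match(conditionMessage(err), "ear not found")
  expect_equal(err$diagnostics$empty[["empty_views"]], 11L)
})

test_that("detectors returning out-of-frame boxes are rejected", {
  h <- fixture_head()
  v <- render_view(h$mesh, view_spec(h$mesh, 0, image_size = c(64L, 64L)))
  bad <- fd_detector(function(view, el)
    list(fd_detection(el, bounding_box(60, 60, 20, 20))),
    "face", name = "bad")
  expect_error(detect(v, "face", bad), "outside the image")
})
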