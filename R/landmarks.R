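#' Scan face-element detections around the head
#'
#' Renders the head at every azimuth on a regular grid over `[0, 360)` and
#' runs the face, eye, nose and mouth detectors on each view. When a
#' detector returns several boxes for one element in one view, the
#' largest-area box is kept (eyes detected in oblique views cover fewer
#' pixels than in frontal views, so area tracks frontality). An azimuth is
#' flagged successful when face, both eyes and the nose are all present;
#' the mouth is recorded but not required.
#'
#' @param mesh a [head_mesh()] (already gravity-corrected).
#' @param detectors named list of [fd_detector()] with entries `face`,
#'   `eye_left`, `eye_right`, `nose` and optionally `mouth` (one detector
#'   may serve several elements).
#' @param step azimuth step in degrees (default 1).
#' @param image_size,scale forwarded to [view_spec()].
#' @return An object of class `detection_table`: `azimuths` (numeric
#'   vector), `detections` (list per azimuth of named [fd_detection()]
#'   lists), `success` (logical vector), `step`, and the view parameters.
#' @export
scan_face_elements <- function(mesh, detectors, step = 1,
                               image_size = c(240L, 240L), scale = NULL) {
  stopifnot(inherits(mesh, "head_mesh"), step > 0)
  azimuths <- seq(0, 360 - step, by = step)
  required <- c("face", "eye_left", "eye_right", "nose")
  elements <- intersect(FD_ELEMENTS[1:5], Reduce(
    union, lapply(detectors, `[[`, "elements")))
  dets <- vector("list", length(azimuths))
  success <- logical(length(azimuths))
  for (i in seq_along(azimuths)) {
    spec <- view_spec(mesh, azimuths[i], image_size = image_size,
                      scale = scale)
    view <- render_view(mesh, spec)
    found <- list()
    for (el in elements) {
      det <- detector_for(detectors, el)
      if (is.null(det)) next
      hits <- detect(view, el, det)
      if (length(hits) > 1L) {     # keep the largest-area box per element
        areas <- vapply(hits, function(h) box_area(h$box), numeric(1))
        hits <- hits[which.max(areas)]
      }
      if (length(hits) == 1L) found[[el]] <- hits[[1]]
    }
    dets[[i]] <- found
    success[i] <- all(required %in% names(found))
  }
  structure(list(azimuths = azimuths, detections = dets, success = success,
                 step = step, image_size = as.integer(image_size),
                 scale = scale),
            class = "detection_table")
}

detector_for <- function(detectors, element) {
  if (!is.null(detectors[[element]])) return(detectors[[element]])
  for (d in detectors) if (element %in% d$elements) return(d)
  NULL
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("detection_table: %d azimuths (step %g deg), %d successful\n",
              length(x$azimuths), x$step, sum(x$success)))
  invisible(x)
}

#' Detection arcs: maximal contiguous runs of successful azimuths
#'
#' Finds the maximal circularly-contiguous runs of azimuths on which all
#' required face elements were detected; a run wrapping through 360/0 is a
#' single arc. Arcs are returned sorted by descending angular length.
#'
#' @param table a `detection_table` from [scan_face_elements()].
#' @return List of `arc` objects, each with `start_deg`, `end_deg`
#'   (inclusive, circular) and `length_deg`; empty list when no azimuth
#'   succeeded.
#' @export
find_arcs <- function(table) {
  flags <- table$success
  n <- length(flags)
  if (!any(flags)) return(list())
  step <- table$step
  if (all(flags)) {
    return(list(structure(list(start_deg = table$azimuths[1],
                               end_deg = table$azimuths[n],
                               length_deg = n * step,
                               idx = seq_len(n)), class = "arc")))
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(which(r$values), function(k) starts[k]:ends[k])
  # circular merge: a run touching index n joins a run starting at index 1
  if (flags[1] && flags[n] && length(runs) > 1L) {
    last <- length(runs)
    runs[[1]] <- c(runs[[last]], runs[[1]])
    runs[[last]] <- NULL
  }
  arcs <- lapply(runs, function(ix) {
    structure(list(start_deg = table$azimuths[ix[1]],
                   end_deg = table$azimuths[ix[length(ix)]],
                   length_deg = length(ix) * step,
                   idx = ix), class = "arc")
  })
  arcs[order(vapply(arcs, `[[`, numeric(1), "length_deg"),
             decreasing = TRUE)]
}

#' @export
print.arc <- function(x, ...) {
  cat(sprintf("arc: %g..%g deg (length %g deg)\n",
              x$start_deg, x$end_deg, x$length_deg))
  invisible(x)
}

# Best-view score of one azimuth entry: eye-box area times symmetry.
best_view_score <- function(det) {
  al <- box_area(det$eye_left$box)
  ar <- box_area(det$eye_right$box)
  (al + ar) * (1 - abs(al - ar) / (al + ar))
}

#' Select the best frontal view inside the detection arc
#'
#' Within the longest arc, picks the azimuth maximizing
#' `(A_L + A_R) * (1 - |A_L - A_R| / (A_L + A_R))` where `A_L`, `A_R` are
#' the eye bounding-box areas: frontal views both enlarge the eye boxes and
#' balance them, so the score peaks at the most frontal, most symmetric
#' pose. Exact ties go to the smallest azimuth. When several arcs tie for
#' longest, the one containing the globally highest-scoring azimuth wins.
#'
#' @param table a `detection_table`.
#' @param arcs output of [find_arcs()] on the same table.
#' @return The selected azimuth in degrees.
#' @export
select_best_view <- function(table, arcs) {
  if (length(arcs) == 0L) fd_stop("no detection arc", "select_best_view")
  maxlen <- arcs[[1]]$length_deg
  cand <- Filter(function(a) a$length_deg == maxlen, arcs)
  best_az <- NA_real_; best_sc <- -Inf
  for (a in cand) {
    for (i in a$idx) {
      sc <- best_view_score(table$detections[[i]])
      az <- table$azimuths[i]
      if (sc > best_sc || (sc == best_sc && az < best_az)) {
        best_sc <- sc; best_az <- az
      }
    }
  }
  best_az
}

#' 2D fiducial (intrinsic pixel coordinates)
#'
#' @param label fiducial name.
#' @param row,col fractional intrinsic pixel coordinates.
#' @param azimuth_deg azimuth of the source view.
#' @return An object of class `fiducial2d`.
#' @export
fiducial2d <- function(label, row, col, azimuth_deg = NA_real_) {
  structure(list(label = label, row = row, col = col,
                 azimuth_deg = azimuth_deg),
            class = "fiducial2d")
}

#' Nasion pixel coordinates from the eye and nose boxes
#'
#' The nasion sits in the depression between the eyes just above the nose
#' bridge, so its pixel position is estimated from detector box geometry in
#' the best frontal view: the row is the mean vertical center of the two eye
#' boxes, `(top_R + top_L)/2 + (h_R + h_L)/4`; the column is the mean of the
#' eye-pair horizontal midpoint `(left_R + left_L + w_L)/2` (midpoint of the
#' right eye's left edge and the left eye's right edge) and the nose-box
#' horizontal center `left_N + w_N/2`. For a mirror-symmetric configuration
#' the column falls exactly on the symmetry axis.
#'
#' Note on image left/right: in a frontal view the subject's right eye
#' appears on the image left, so `eye_right` is the box with the smaller
#' `left`.
#'
#' @param eye_right,eye_left,nose [bounding_box()]es from one view
#'   (`eye_right$left < eye_left$left`).
#' @param azimuth_deg azimuth of the source view, carried into the result.
#' @return A [fiducial2d()] labelled `"nasion"`.
#' @export
nasion_intrinsic <- function(eye_right, eye_left, nose,
                             azimuth_deg = NA_real_) {
  for (b in list(eye_right, eye_left, nose))
    stopifnot(inherits(b, "bounding_box"))
  if (!(eye_right$left < eye_left$left))
    fd_stop("eye_right must lie left of eye_left in the image",
            "nasion_intrinsic")
  row <- (eye_right$top + eye_left$top) / 2 +
    (eye_right$height + eye_left$height) / 4
  eye_mid <- (eye_right$left + eye_left$left + eye_left$width) / 2
  nose_mid <- nose$left + nose$width / 2
  fiducial2d("nasion", row = row, col = (eye_mid + nose_mid) / 2,
             azimuth_deg = azimuth_deg)
}

#' Closest point on the ear box to the preauricular point
#'
#' The preauricular point lies just anterior to the tragus, so the nearest
#' point on the detected ear bounding box is the midpoint of the box edge
#' facing the face: the right edge for the right ear (nose on the image
#' right in a right-lateral view) and the left edge for the left ear.
#'
#' @param box the detected ear [bounding_box()].
#' @param azimuth_deg azimuth of the source view.
#' @return A [fiducial2d()] labelled `"rpa_cp"` / `"lpa_cp"`.
#' @name ear_cp
#' @export
right_cp <- function(box, azimuth_deg = NA_real_) {
  stopifnot(inherits(box, "bounding_box"))
  fiducial2d("rpa_cp", row = box$top + box$height / 2,
             col = box$left + box$width, azimuth_deg = azimuth_deg)
}

#' @rdname ear_cp
#' @export
left_cp <- function(box, azimuth_deg = NA_real_) {
  stopifnot(inherits(box, "bounding_box"))
  fiducial2d("lpa_cp", row = box$top + box$height / 2,
             col = box$left, azimuth_deg = azimuth_deg)
}

#' Corrected preauricular point inside the ear box
#'
#' The box-edge closest point systematically overshoots the anatomical
#' preauricular point; the calibrated correction pulls it inside the box:
#' column at `left + 8/10 * width` (right ear) or `left + width/5` (left
#' ear), row at `top + 0.36 * height` for both sides. Relative to the
#' closest point this shrinks the horizontal position by 20% of the box
#' width and raises the vertical position by 14% of the box height. The
#' default fractions are the calibrated constants; pass `a_col`/`b_row` to
#' use constants recalibrated with [calibrate_pp_correction()].
#'
#' @param box the detected ear [bounding_box()].
#' @param azimuth_deg azimuth of the source view.
#' @param a_col column fraction of the box width (default 8/10 right,
#'   1/5 left).
#' @param b_row row fraction of the box height (default 0.36).
#' @return A [fiducial2d()] labelled `"rpa"` / `"lpa"`.
#' @name ear_pp
#' @export
right_pp <- function(box, azimuth_deg = NA_real_, a_col = 8 / 10,
                     b_row = 0.36) {
  stopifnot(inherits(box, "bounding_box"))
  fiducial2d("rpa", row = box$top + b_row * box$height,
             col = box$left + a_col * box$width, azimuth_deg = azimuth_deg)
}

#' @rdname ear_pp
#' @export
left_pp <- function(box, azimuth_deg = NA_real_, a_col = 1 / 5,
                    b_row = 0.36) {
  stopifnot(inherits(box, "bounding_box"))
  fiducial2d("lpa", row = box$top + b_row * box$height,
             col = box$left + a_col * box$width, azimuth_deg = azimuth_deg)
}

#' Calibrate the preauricular correction fractions
#'
#' Exhaustive grid search for the box fractions `(a, b)` such that the
#' predicted preauricular pixel `(col, row) = (left + a*width,
#' top + b*height)` minimizes the summed L1 error against annotated
#' preauricular pixels. Column and row residuals are summed into one loss;
#' ties resolve to the smallest `(a, b)` lexicographically.
#'
#' @param samples list of `list(box = bounding_box, row = , col = )`
#'   annotated examples for one ear side.
#' @param grid_step grid resolution on `[0, 1]` for both fractions
#'   (default 0.01).
#' @return Named numeric `c(a_col, b_row)` with attribute `"loss"`.
#' @export
calibrate_pp_correction <- function(samples, grid_step = 0.01) {
  if (length(samples) == 0L) fd_stop("no calibration samples", "calibrate")
  left <- vapply(samples, function(s) s$box$left, numeric(1))
  top <- vapply(samples, function(s) s$box$top, numeric(1))
  w <- vapply(samples, function(s) s$box$width, numeric(1))
  h <- vapply(samples, function(s) s$box$height, numeric(1))
  col <- vapply(samples, function(s) s$col, numeric(1))
  row <- vapply(samples, function(s) s$row, numeric(1))
  grid <- seq(0, 1, by = grid_step)
  # The joint L1 loss separates as loss(a, b) = loss_a(a) + loss_b(b), so
  # evaluating each margin over the full grid covers every (a, b) pair; the
  # lexicographic tie rule reduces to first-index ties per margin.
  loss_a <- vapply(grid, function(a) sum(abs(left + a * w - col)), numeric(1))
  loss_b <- vapply(grid, function(b) sum(abs(top + b * h - row)), numeric(1))
  ia <- which.min(loss_a)  # which.min takes the first (smallest a) on ties
  ib <- which.min(loss_b)
  out <- c(a_col = grid[ia], b_row = grid[ib])
  attr(out, "loss") <- loss_a[ia] + loss_b[ib]
  out
}
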