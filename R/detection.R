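#' Detector bounding box (intrinsic pixels)
#'
#' Axis-aligned box in intrinsic image coordinates. `top`/`left` are the
#' (row, col) of the upper-left corner; `width` counts columns and `height`
#' counts rows. Fractional values are allowed (boxes derived from projected
#' geometry are sub-pixel).
#'
#' @param top,left upper-left corner (row, col).
#' @param width,height box extent in columns / rows; both must be `> 0`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(top, left, width, height) {
  if (!all(is.finite(c(top, left, width, height))))
    fd_stop("bounding box fields must be finite", "detection")
  if (width <= 0 || height <= 0)
    fd_stop("bounding box must have positive width and height", "detection")
  structure(list(top = top, left = left, width = width, height = height),
            class = "bounding_box")
}

box_area <- function(box) box$width * box$height

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding_box: top %.1f left %.1f  %.1f x %.1f\n",
              x$top, x$left, x$width, x$height))
  invisible(x)
}

FD_ELEMENTS <- c("face", "eye_left", "eye_right", "nose", "mouth",
                 "ear_left", "ear_right")

#' A single detector hit
#'
#' @param element one of `face`, `eye_left`, `eye_right`, `nose`, `mouth`,
#'   `ear_left`, `ear_right`.
#' @param box a [bounding_box()].
#' @param azimuth_deg azimuth of the source view.
#' @param score optional detector confidence.
#' @return An object of class `fd_detection`.
#' @export
fd_detection <- function(element, box, azimuth_deg = NA_real_, score = NA_real_) {
  element <- match.arg(element, FD_ELEMENTS)
  stopifnot(inherits(box, "bounding_box"))
  structure(list(element = element, box = box, azimuth_deg = azimuth_deg,
                 score = score),
            class = "fd_detection")
}

#' Cascade-classifier stage design
#'
#' A boosted cascade rejects a window as soon as any stage rejects it, so
#' with per-stage false-alarm rate `f` and per-stage true-positive rate `t`
#' over `s` stages, the whole cascade has false-alarm rate `f^s` and
#' true-positive rate `t^s`.
#'
#' @param f per-stage false alarm rate, in `(0, 1)`.
#' @param s number of stages, positive integer.
#' @param t per-stage true positive rate, in `(0, 1]` (default 1).
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(f, s, t = 1) {
  if (!is.finite(f) || f <= 0 || f >= 1)
    fd_stop("per-stage FAR f must lie in (0, 1)", "detection")
  if (!is.finite(t) || t <= 0 || t > 1)
    fd_stop("per-stage TPR t must lie in (0, 1]", "detection")
  s <- as.integer(s)
  if (is.na(s) || s < 1L) fd_stop("stage count s must be >= 1", "detection")
  structure(list(f = f, s = s, t = t), class = "cascade_spec")
}

#' Total false-alarm rate of a cascade
#'
#' @param spec a [cascade_spec()].
#' @return `f^s`.
#' @export
cascade_total_far <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  spec$f^spec$s
}

#' Total true-positive rate of a cascade
#'
#' @param spec a [cascade_spec()].
#' @return `t^s`.
#' @export
cascade_total_tpr <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  spec$t^spec$s
}

#' Published ear-detector cascade designs
#'
#' The per-stage FAR / stage-count pairs of the sixteen HOG ear-cascade
#' trainings (eight per side) that the dynamic detector ladder draws from,
#' together with the total FAR each training reported.
#'
#' @return Data frame with columns `side`, `f` (per-stage FAR), `s` (stages)
#'   and `total_far_reported`.
#' @export
ear_detector_design <- function() {
  data.frame(
    side = rep(c("left", "right"), each = 8L),
    f = rep(c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.85, 0.9), 2L),
    s = c(11L, 14L, 17L, 19L, 25L, 33L, 35L, 41L,
          8L, 12L, 14L, 15L, 19L, 21L, 24L, 25L),
    total_far_reported = c(
      0.000002, 0.000003, 0.000008, 0.000061,
      0.000134, 0.000634, 0.003386, 0.013303,
      0.000066, 0.000017, 0.000061, 0.000470,
      0.001139, 0.009223, 0.020233, 0.071789)
  )
}

#' Pluggable detector handle
#'
#' A detector is a function `fn(view, element)` returning a list of
#' [fd_detection()] for one element on one [render_view()] output, wrapped
#' with the elements it supports and an optional cascade design. Oracle
#' detectors (driven by synthetic ground truth), scripted mocks, and
#' runtime cascade models all share this contract; `detect()` and the
#' ladder never look inside.
#'
#' @param fn `function(view, element) -> list of fd_detection`.
#' @param elements character vector of supported elements.
#' @param name label used in diagnostics.
#' @param cascade optional [cascade_spec()] describing the detector design.
#' @return An object of class `fd_detector`.
#' @export
fd_detector <- function(fn, elements, name = "detector", cascade = NULL) {
  stopifnot(is.function(fn))
  elements <- match.arg(elements, FD_ELEMENTS, several.ok = TRUE)
  structure(list(fn = fn, elements = elements, name = name,
                 cascade = cascade),
            class = "fd_detector")
}

#' Run a detector on one view
#'
#' Pure function of `(view, detector)`: returns the detector's boxes for one
#' element, each validated to lie inside the image.
#'
#' @param view a [render_view()] result.
#' @param element element name, see [fd_detection()].
#' @param detector an [fd_detector()].
#' @return List of [fd_detection()] (possibly empty).
#' @export
detect <- function(view, element, detector) {
  stopifnot(inherits(view, "rendered_view"), inherits(detector, "fd_detector"))
  element <- match.arg(element, FD_ELEMENTS)
  if (!element %in% detector$elements)
    fd_stop(sprintf("detector '%s' does not support element '%s'",
                    detector$name, element), "detection")
  hits <- detector$fn(view, element)
  if (length(hits) == 0L) return(list())
  nr <- view$spec$image_size[1]; nc <- view$spec$image_size[2]
  lapply(hits, function(h) {
    stopifnot(inherits(h, "fd_detection"))
    b <- h$box
    if (b$top < 0.5 || b$left < 0.5 ||
        b$top + b$height > nr + 0.5 || b$left + b$width > nc + 0.5)
      fd_stop(sprintf("detector '%s' returned a box outside the image",
                      detector$name), "detection")
    h$azimuth_deg <- view$spec$azimuth_deg
    h
  })
}

#' FAR-ordered detector ladder
#'
#' Orders a set of detectors for one ear by ascending total cascade FAR, the
#' order in which the dynamic search tries them: the strictest detector
#' (fewest false alarms) gets the first chance, looser ones are fallbacks.
#'
#' @param detectors list of [fd_detector()], each carrying a
#'   [cascade_spec()] (or an explicit `total_far` attribute).
#' @return An object of class `detector_ladder`; entries sorted ascending by
#'   total FAR.
#' @export
detector_ladder <- function(detectors) {
  stopifnot(length(detectors) >= 1L)
  fars <- vapply(detectors, function(d) {
    if (!is.null(d$cascade)) cascade_total_far(d$cascade)
    else attr(d, "total_far") %||%
        fd_stop(sprintf("detector '%s' has no cascade design", d$name),
                "detection")
  }, numeric(1))
  ord <- order(fars)
  structure(list(detectors = detectors[ord], total_far = fars[ord]),
            class = "detector_ladder")
}

#' @export
print.detector_ladder <- function(x, ...) {
  cat("detector_ladder:\n")
  for (i in seq_along(x$detectors))
    cat(sprintf("  %d. %-20s total FAR %.3g\n", i, x$detectors[[i]]$name,
                x$total_far[i]))
  invisible(x)
}

#' Dynamic ear search over a lateral view window
#'
#' Runs the FAR-ordered ladder over a window of lateral views: detectors are
#' tried in ascending total-FAR order, and each detector scans every view
#' (center view first, then alternating outward) before the next, looser
#' detector is consulted. The first view on which the current detector
#' returns exactly one box yields the result. A view with more than one box
#' is a failure for that detector/view (the goal is a single confident true
#' positive) and the scan continues. If the ladder is exhausted an
#' "ear not found" error is raised carrying per-detector diagnostics.
#'
#' @param views list of [render_view()] results covering the lateral angle
#'   plus/minus half the search window at 1 degree steps.
#' @param side `"left"` or `"right"` (the subject's ear).
#' @param ladder a [detector_ladder()].
#' @return The winning [fd_detection()], with attribute `"detector"` naming
#'   the detector that produced it.
#' @export
ear_ladder_detect <- function(views, side = c("left", "right"), ladder) {
  side <- match.arg(side)
  stopifnot(inherits(ladder, "detector_ladder"), length(views) >= 1L)
  element <- paste0("ear_", side)
  # center-outward view order: the nominal lateral angle is the middle view
  n <- length(views)
  mid <- ceiling(n / 2)
  off <- c(0, as.vector(rbind(seq_len(n), -seq_len(n))))
  idx <- unique(mid + off[abs(off) <= n])
  idx <- idx[idx >= 1L & idx <= n]
  diag <- list()
  for (k in seq_along(ladder$detectors)) {
    det <- ladder$detectors[[k]]
    n_empty <- 0L; n_multi <- 0L
    for (i in idx) {
      hits <- detect(views[[i]], element, det)
      if (length(hits) == 1L) {
        out <- hits[[1]]
        attr(out, "detector") <- det$name
        return(out)
      }
      if (length(hits) > 1L) n_multi <- n_multi + 1L else n_empty <- n_empty + 1L
    }
    diag[[det$name]] <- c(empty_views = n_empty, multi_box_views = n_multi)
  }
  fd_stop(sprintf("%s ear not found in any of %d views by %d detectors",
                  side, n, length(ladder$detectors)),
          "ear_ladder_detect", diagnostics = diag)
}
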