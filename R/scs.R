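#' Rigid world-to-SCS transform
#'
#' A rigid map `p_scs = rotation %*% p + translation` from mesh/world
#' coordinates into the subject coordinate system. The rotation must be
#' orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation 3-vector.
#' @param convention coordinate-convention tag, default `"CTF"`.
#' @return An object of class `scs_transform`.
#' @export
scs_transform <- function(rotation, translation, convention = "CTF") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9)
    fd_stop("rotation is not orthonormal", "scs")
  if (det(rotation) < 0)
    fd_stop("rotation must be proper (det +1)", "scs")
  structure(list(rotation = rotation, translation = translation,
                 convention = convention),
            class = "scs_transform")
}

#' @export
print.scs_transform <- function(x, ...) {
  cat(sprintf("scs_transform (%s):\n", x$convention))
  m <- cbind(x$rotation, x$translation)
  colnames(m) <- c("r1", "r2", "r3", "t")
  print(round(m, 6))
  invisible(x)
}

#' Reproject a pixel onto the mesh surface
#'
#' Casts the orthographic ray through a (possibly fractional) pixel of a
#' rendered view and intersects it with every mesh triangle (watertight
#' edge handling: a hit on a shared edge counts once), returning the
#' intersection nearest the camera. The pixel must have been rasterized:
#' the depth buffer is checked at the nearest integer pixel and a
#' background pixel raises a "pixel off surface" error.
#'
#' @param mesh the [head_mesh()] that produced the view.
#' @param view a [render_view()] result.
#' @param pixel numeric `(row, col)`, fractional allowed.
#' @return 3D surface point (numeric length 3) with attributes `"face"`
#'   (1-based triangle index) and `"bary"` (barycentric coordinates).
#' @export
pixel_to_surface <- function(mesh, view, pixel) {
  stopifnot(inherits(mesh, "head_mesh"), inherits(view, "rendered_view"))
  pr <- min(max(round(pixel[1]), 1L), view$spec$image_size[1])
  pc <- min(max(round(pixel[2]), 1L), view$spec$image_size[2])
  if (!is.finite(view$depth[pr, pc]))
    fd_stop(sprintf("pixel (%.2f, %.2f) off surface", pixel[1], pixel[2]),
            "pixel_to_surface")
  ray <- pixel_to_ray(view, pixel)
  hit <- cpp_ray_cast(mesh$vertices, mesh$faces - 1L, ray$origin,
                      ray$direction)
  if (hit$face == 0L)
    fd_stop(sprintf("ray through pixel (%.2f, %.2f) misses the mesh",
                    pixel[1], pixel[2]), "pixel_to_surface")
  structure(as.numeric(hit$point), face = hit$face,
            bary = as.numeric(hit$bary))
}

#' Build the CTF subject coordinate system from the three fiducials
#'
#' CTF convention: origin midway between the preauricular points; +x from
#' the origin toward the nasion; +z perpendicular to the fiducial plane,
#' disambiguated to point along the (gravity-corrected) upward mesh axis;
#' +y = z cross x, pointing toward the left preauricular point. Returns the
#' world-to-SCS rigid map.
#'
#' @param nasion,lpa,rpa 3D points in mesh coordinates (non-collinear).
#' @param up world direction used only to disambiguate the +z sign
#'   (default `c(0, 0, 1)`, the gravity-corrected vertical).
#' @return An [scs_transform()].
#' @export
build_ctf_transform <- function(nasion, lpa, rpa, up = c(0, 0, 1)) {
  nasion <- as.numeric(nasion); lpa <- as.numeric(lpa); rpa <- as.numeric(rpa)
  origin <- (lpa + rpa) / 2
  xax <- nasion - origin
  ee <- lpa - rpa
  zax <- cross3(xax, ee)
  scale <- sqrt(sum(xax^2)) * sqrt(sum(ee^2))
  if (scale == 0 || sqrt(sum(zax^2)) < 1e-12 * scale)
    fd_stop("fiducials are collinear", "build_ctf_transform")
  xax <- xax / sqrt(sum(xax^2))
  zax <- zax / sqrt(sum(zax^2))
  if (sum(zax * up) < 0) zax <- -zax
  yax <- cross3(zax, xax)
  # columns of M are the SCS axes in world coordinates; world -> SCS is M^T
  M <- cbind(xax, yax, zax)
  scs_transform(t(M), -t(M) %*% origin)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Apply / invert a rigid transform
#'
#' @param points `n x 3` matrix or 3-vector.
#' @param t an [scs_transform()].
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(points, t) {
  stopifnot(inherits(t, "scs_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  out <- sweep(p %*% t(t$rotation), 2, t$translation, `+`)
  if (vec) as.numeric(out) else out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "scs_transform"))
  scs_transform(t(t$rotation), -t(t$rotation) %*% t$translation,
                convention = t$convention)
}

#' Locate the three fiducials on a head scan
#'
#' Runs the full localization pipeline:
#' 1. gravity-flip correction of the scanner orientation;
#' 2. azimuth scan over `[0, 360)` with face/eye/nose/mouth detectors;
#' 3. detection-arc extraction and best frontal view selection;
#' 4. nasion pixel estimate from eye/nose box geometry ([nasion_intrinsic()]);
#' 5. lateral views at the best view plus/minus `lateral_offset` degrees;
#' 6. dynamic FAR-ordered ear-ladder search over a `window`-degree range
#'    per side and preauricular correction ([right_pp()], [left_pp()]);
#' 7. reprojection of all three pixels onto the surface
#'    ([pixel_to_surface()]);
#' 8. CTF subject-coordinate-system construction
#'    ([build_ctf_transform()]).
#'
#' With the azimuth convention used here (counterclockwise from above),
#' `best_view + lateral_offset` shows the subject's left ear and
#' `best_view - lateral_offset` the right ear.
#'
#' The run report collects every intermediate result; on failure the error
#' carries the stage name and the partial report (and the partial report is
#' still written when `report_path` is given).
#'
#' @param mesh a [head_mesh()] as emitted by the scanner.
#' @param detectors named list of [fd_detector()] for the facial elements
#'   (see [scan_face_elements()]).
#' @param ear_ladders named list with `left` and `right`
#'   [detector_ladder()]s.
#' @param config list of pipeline settings; recognized entries (defaults):
#'   `flip` (TRUE) apply the gravity-flip; `step` (1) azimuth scan step in
#'   degrees; `lateral_offset` (87) degrees from best view to the lateral
#'   ear views; `window` (10) ear search window in degrees;
#'   `image_size` (`c(240, 240)`); `scale` (NULL = auto).
#' @param report_path optional path: the JSON run report is written here,
#'   also on failure.
#' @return List with `fiducials` (three [fiducial3d()] with both mesh and
#'   SCS coordinates), `transform` (the [scs_transform()]) and `report`.
#' @export
locate_fiducials <- function(mesh, detectors, ear_ladders,
                             config = list(), report_path = NULL) {
  cfg <- utils::modifyList(list(flip = TRUE, step = 1, lateral_offset = 87,
                                window = 10, image_size = c(240L, 240L),
                                scale = NULL), config)
  report <- list(config = cfg[order(names(cfg))], stages = character())
  finish <- function() {
    if (!is.null(report_path)) write_run_report(report, report_path)
  }
  stage <- function(name, expr) {
    report$stages <<- c(report$stages, name)
    tryCatch(expr, error = function(e) {
      report$error <<- list(stage = e$stage %||% name,
                            message = conditionMessage(e))
      finish()
      fd_stop(conditionMessage(e), name)
    })
  }

  if (isTRUE(cfg$flip)) mesh <- stage("gravity_flip", gravity_flip(mesh))
  report$flip_applied <- isTRUE(cfg$flip)

  table <- stage("scan_face_elements",
                 scan_face_elements(mesh, detectors, step = cfg$step,
                                    image_size = cfg$image_size,
                                    scale = cfg$scale))
  report$n_success_azimuths <- sum(table$success)

  arcs <- stage("find_arcs", {
    a <- find_arcs(table)
    if (length(a) == 0L) fd_stop("no detection arc", "find_arcs")
    a
  })
  report$arcs <- lapply(arcs, function(a)
    list(start_deg = a$start_deg, end_deg = a$end_deg,
         length_deg = a$length_deg))

  best <- stage("select_best_view", select_best_view(table, arcs))
  report$best_view_deg <- best

  ti <- which(table$azimuths == best)
  dets <- table$detections[[ti]]
  report$best_view_boxes <- lapply(
    dets, function(d) unclass(d$box)[c("top", "left", "width", "height")])

  nas2d <- stage("nasion_intrinsic", {
    # subject's right eye appears on the image left in a frontal view
    boxes <- list(dets$eye_right$box, dets$eye_left$box)
    lefts <- c(boxes[[1]]$left, boxes[[2]]$left)
    eye_img_left <- boxes[[order(lefts)[1]]]
    eye_img_right <- boxes[[order(lefts)[2]]]
    nasion_intrinsic(eye_img_left, eye_img_right, dets$nose$box,
                     azimuth_deg = best)
  })
  report$nasion_2d <- unclass(nas2d)[c("row", "col", "azimuth_deg")]

  best_spec <- view_spec(mesh, best, image_size = cfg$image_size,
                         scale = cfg$scale)
  best_view <- render_view(mesh, best_spec)

  lat <- list(left = (best + cfg$lateral_offset) %% 360,
              right = (best - cfg$lateral_offset) %% 360)
  report$lateral_angles_deg <- lat

  half <- cfg$window / 2
  ear2d <- list()
  ear_views <- list()
  for (side in c("left", "right")) {
    hit <- stage(paste0("ear_ladder_detect_", side), {
      angles <- lat[[side]] + seq(-half, half, by = 1)
      views <- lapply(angles, function(a)
        render_view(mesh, view_spec(mesh, a %% 360,
                                    image_size = cfg$image_size,
                                    scale = cfg$scale)))
      ear_ladder_detect(views, side, ear_ladders[[side]])
    })
    ear_views[[side]] <- render_view(
      mesh, view_spec(mesh, hit$azimuth_deg, image_size = cfg$image_size,
                      scale = cfg$scale))
    pp <- if (side == "right") right_pp(hit$box, hit$azimuth_deg)
          else left_pp(hit$box, hit$azimuth_deg)
    cp <- if (side == "right") right_cp(hit$box, hit$azimuth_deg)
          else left_cp(hit$box, hit$azimuth_deg)
    ear2d[[side]] <- pp
    report[[paste0("ear_", side)]] <- list(
      detector = attr(hit, "detector"),
      azimuth_deg = hit$azimuth_deg,
      box = unclass(hit$box)[c("top", "left", "width", "height")],
      cp = unclass(cp)[c("row", "col")],
      pp = unclass(pp)[c("row", "col")])
  }

  p3 <- stage("pixel_to_surface", list(
    nasion = pixel_to_surface(mesh, best_view, c(nas2d$row, nas2d$col)),
    lpa = pixel_to_surface(mesh, ear_views$left,
                           c(ear2d$left$row, ear2d$left$col)),
    rpa = pixel_to_surface(mesh, ear_views$right,
                           c(ear2d$right$row, ear2d$right$col))))

  transform <- stage("build_ctf_transform",
                     build_ctf_transform(p3$nasion, p3$lpa, p3$rpa))

  fids <- lapply(c("nasion", "lpa", "rpa"), function(lab)
    fiducial3d(lab, p3[[lab]],
               position_scs = apply_transform(as.numeric(p3[[lab]]),
                                              transform)))
  names(fids) <- c("nasion", "lpa", "rpa")

  report$fiducials_mesh <- lapply(fids, function(f) as.numeric(f$position))
  report$fiducials_scs <- lapply(fids, function(f) f$position_scs)
  report$transform <- list(rotation = unname(transform$rotation),
                           translation = transform$translation,
                           convention = transform$convention)
  finish()
  list(fiducials = fids, transform = transform, report = report)
}

#' Serialize a run report to canonical JSON
#'
#' Deterministic, full-precision JSON so that identical runs produce
#' byte-identical reports.
#'
#' @param report the `report` element of a [locate_fiducials()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
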