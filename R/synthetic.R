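#' Specification of a synthetic head fixture
#'
#' Parameters of the deterministic head-like test mesh: an ellipsoid
#' (semi-axes in mm: anterior-posterior, left-right, vertical) with a nose
#' protrusion and ear bumps, triangulated on a latitude/longitude grid whose
#' nodes carry the ground-truth landmarks, so every landmark is exactly a
#' mesh vertex. A per-spec seed draws mild anatomical variation (semi-axis
#' scaling in a plus/minus 8% band, bump sizes) and a random yaw (a whole
#' multiple of the longitude step) so different seeds face different
#' directions. The defaults are adult-head dimensions.
#'
#' @param seed integer; the only source of randomness.
#' @param radii semi-axes `(x, y, z)` in mm before seed variation.
#' @param nose_protrusion nose bump height in mm.
#' @param ear_bump ear bump height in mm.
#' @param n_lat number of latitude intervals pole-to-pole (even; the
#'   landmark latitudes are multiples of `180 / n_lat`).
#' @param n_lon number of longitude steps (multiple of 12).
#' @param texture_size side of the square RGB texture in texels.
#' @param style texture style tag (free text, recorded only).
#' @return An object of class `synthetic_head_spec`.
#' @export
synthetic_head_spec <- function(seed = 1L, radii = c(95, 75, 110),
                                nose_protrusion = 22, ear_bump = 7,
                                n_lat = 30L, n_lon = 60L,
                                texture_size = 256L, style = "flat") {
  if (any(radii <= 0)) fd_stop("radii must be positive", "synthetic")
  if (n_lon %% 12L != 0L || n_lat %% 2L != 0L)
    fd_stop("need n_lon a multiple of 12 and n_lat even", "synthetic")
  structure(list(seed = as.integer(seed), radii = radii,
                 nose_protrusion = nose_protrusion, ear_bump = ear_bump,
                 n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 texture_size = as.integer(texture_size), style = style),
            class = "synthetic_head_spec")
}

# Evaluate an expression with a private, restored RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic head with known fiducial ground truth
#'
#' Builds the textured mesh described by a [synthetic_head_spec()]. The
#' head faces its yaw direction (+X before yaw); the subject's left is +Y
#' and +Z is up ("upright" orientation). Because head scanners align Z
#' with gravity, the element `scanned` holds the same head in scanner
#' orientation, i.e. `gravity_flip(mesh)`; feeding `scanned` to the
#' pipeline with its default flip reproduces `mesh` exactly.
#'
#' Ground-truth landmarks (eye centers, nose tip, mouth center, nasion and
#' both preauricular points) are tagged grid vertices: each ground-truth
#' position is exactly on the surface. The nasion vertex lies on the
#' midline between and slightly below the eye centers; the preauricular
#' vertices sit on the side of the head just anterior to the ear bumps.
#'
#' @param spec a [synthetic_head_spec()] (or a bare seed).
#' @return List with `mesh` (upright [head_mesh()]), `scanned` (gravity
#'   orientation), `truth` (named list of 3D landmark positions in the
#'   upright frame, plus `vertex_id`, `yaw_deg`, `head_size` and
#'   `mean_edge`), and `spec`.
#' @export
make_synthetic_head <- function(spec = synthetic_head_spec()) {
  if (is.numeric(spec)) spec <- synthetic_head_spec(seed = spec)
  stopifnot(inherits(spec, "synthetic_head_spec"))
  draws <- with_local_seed(spec$seed, list(
    rscale = runif(3, 0.92, 1.08),
    nose = spec$nose_protrusion * runif(1, 0.85, 1.15),
    ear = spec$ear_bump * runif(1, 0.8, 1.2),
    yaw_step = sample.int(spec$n_lon, 1) - 1L,
    tex_seed = sample.int(1e6, 1)))
  radii <- spec$radii * draws$rscale
  nlat <- spec$n_lat; nlon <- spec$n_lon
  dlat <- 180 / nlat; dlon <- 360 / nlon

  # grid: rings j = 1..nlat-1 at latitude -90 + j*dlat, lon i = 0..nlon-1;
  # vertex index helper (1-based; poles appended last)
  vid <- function(i, j) (j - 1L) * nlon + (i %% nlon) + 1L
  nring <- (nlat - 1L) * nlon
  south <- nring + 1L; north <- nring + 2L

  lat <- rep(-90 + dlat * seq_len(nlat - 1L), each = nlon)
  lon <- rep(dlon * (seq_len(nlon) - 1L), nlat - 1L)
  latr <- c(lat, -90, 90) * pi / 180
  lonr <- c(lon, 0, 0) * pi / 180
  dirs <- cbind(cos(latr) * cos(lonr), cos(latr) * sin(lonr), sin(latr))

  # landmarks as (lon, lat) grid nodes, head facing lon 0 before yaw
  lm_deg <- list(eye_left = c(30, 18), eye_right = c(-30, 18),
                 nasion = c(0, 12), nose_tip = c(0, 0), mouth = c(0, -24),
                 lpa = c(90, 0), rpa = c(-90, 0))
  lm_id <- vapply(lm_deg, function(p)
    vid(as.integer(round(p[1] / dlon)),
        as.integer(round((p[2] + 90) / dlat))), integer(1))

  # radial bump displacement with cosine-squared falloff (angular radius in
  # degrees on the parameter sphere)
  bump <- function(center_deg, height, radius_deg) {
    cd <- center_deg * pi / 180
    cdir <- c(cos(cd[2]) * cos(cd[1]), cos(cd[2]) * sin(cd[1]), sin(cd[2]))
    ang <- acos(pmin(1, pmax(-1, dirs %*% cdir))) * 180 / pi
    height * ifelse(ang < radius_deg,
                    cos(pi / 2 * ang / radius_deg)^2, 0)
  }
  disp <- bump(c(0, 0), draws$nose, 18) +
    bump(c(96, 0), draws$ear, 14) + bump(c(-96, 0), draws$ear, 14)

  V <- sweep(dirs, 2, radii, `*`) + as.numeric(disp) * dirs

  # faces: quad strips between rings + pole fans; CCW seen from outside
  F <- matrix(0L, 0L, 3L)
  quads <- vector("list", nlat - 2L)
  for (j in seq_len(nlat - 2L)) {
    i <- 0:(nlon - 1L)
    a <- vid(i, j); b <- vid(i + 1L, j)
    cc <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    quads[[j]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  i <- 0:(nlon - 1L)
  F <- rbind(do.call(rbind, quads),
             cbind(south, vid(i + 1L, 1L), vid(i, 1L)),
             cbind(north, vid(i, nlat - 1L), vid(i + 1L, nlat - 1L)))
  dimnames(F) <- NULL

  # yaw the whole head by a multiple of the longitude step
  yaw <- draws$yaw_step * dlon
  cy <- cos(yaw * pi / 180); sy <- sin(yaw * pi / 180)
  Rz <- rbind(c(cy, -sy, 0), c(sy, cy, 0), c(0, 0, 1))
  V <- V %*% t(Rz)

  uv <- cbind((c(lon, 0, 0) %% 360) / 360, (c(lat, -90, 90) + 90) / 180)
  tex <- synthetic_face_texture(spec$texture_size, lm_deg, draws$tex_seed)

  mesh <- head_mesh(V, F, uv = uv, texture = tex,
                    units_hint = "mm (synthetic)")
  truth <- lapply(lm_id, function(k) as.numeric(V[k, ]))
  e1 <- V[F[, 1], ] - V[F[, 2], ]
  truth$vertex_id <- lm_id
  truth$yaw_deg <- yaw
  truth$head_size <- 2 * mean(radii)
  truth$mean_edge <- mean(sqrt(rowSums(e1^2)))
  list(mesh = mesh, scanned = gravity_flip(mesh), truth = truth, spec = spec)
}

# Face-like texture in the head's UV chart: skin base, dark eye/brow/mouth
# patches, plus seeded speckle so no two heads share a texture.
synthetic_face_texture <- function(size, lm_deg, seed) {
  tex <- array(0, c(size, size, 3))
  tex[, , 1] <- 0.85; tex[, , 2] <- 0.71; tex[, , 3] <- 0.60
  uv_px <- function(p) {   # (lon,lat) deg -> (row, col) texel
    c(round((1 - (p[2] + 90) / 180) * (size - 1)) + 1,
      round(((p[1] %% 360) / 360) * (size - 1)) + 1)
  }
  patch <- function(tex, center, rr, rc, col) {
    px <- uv_px(center)
    rows <- pmax(1, px[1] - rr):pmin(size, px[1] + rr)
    cols <- pmax(1, px[2] - rc):pmin(size, px[2] + rc)
    for (k in 1:3) tex[rows, cols, k] <- col[k]
    tex
  }
  tex <- patch(tex, lm_deg$eye_left, size %/% 48, size %/% 24, c(.15, .12, .10))
  tex <- patch(tex, lm_deg$eye_right, size %/% 48, size %/% 24, c(.15, .12, .10))
  tex <- patch(tex, lm_deg$mouth, size %/% 48, size %/% 18, c(.65, .25, .25))
  tex <- patch(tex, lm_deg$nose_tip, size %/% 36, size %/% 36, c(.78, .58, .48))
  speck <- with_local_seed(seed,
                           matrix(runif(size * size, -0.03, 0.03), size))
  for (k in 1:3) tex[, , k] <- pmin(1, pmax(0, tex[, , k] + speck))
  tex
}

#' Depth-buffer visibility of a mesh point in a view
#'
#' A landmark is treated as visible when its projection falls inside the
#' image and the rendered depth at the nearest pixel agrees with the
#' landmark's own depth within `tol` mesh units (an occluding surface in
#' front of a back-facing landmark produces a much smaller rendered depth).
#'
#' @param view a [render_view()] result.
#' @param point 3D mesh-space point.
#' @param tol depth agreement tolerance in mesh units.
#' @return Logical.
#' @export
landmark_visible <- function(view, point, tol = 6) {
  p <- project_points(point, view$spec)
  pr <- round(p$row); pc <- round(p$col)
  if (pr < 1 || pc < 1 || pr > view$spec$image_size[1] ||
      pc > view$spec$image_size[2]) return(FALSE)
  d <- view$depth[pr, pc]
  is.finite(d) && abs(d - p$depth) <= tol
}

#' Oracle detectors driven by synthetic ground truth
#'
#' Builds the full detector set for a synthetic head: face, eyes, nose and
#' mouth detectors plus per-side ear-detector ladders. Each detector
#' projects its ground-truth landmark into the view, checks depth-buffer
#' visibility, and returns one bounding box placed so that the downstream
#' estimator inverts it exactly at zero jitter:
#' * eye boxes are centered on the projected eye centers, with a common
#'   vertical offset making their mean vertical center equal the projected
#'   nasion row, and the nose-box center is chosen so the nasion column
#'   estimate equals the projected nasion column;
#' * ear boxes are placed so the preauricular correction
#'   ([right_pp()]/[left_pp()]) returns the projected preauricular point.
#' Eye and ear boxes foreshorten (width shrinks with the cosine of the
#' angle between the view azimuth and the landmark's outward direction),
#' which is what makes frontal views score highest in
#' [select_best_view()]. With `jitter_px > 0`, box corners receive
#' deterministic pseudo-random offsets derived from `(seed, azimuth,
#' element)`, so each detector stays a pure function of the view.
#'
#' The ear ladders carry the published cascade designs
#' ([ear_detector_design()]), one oracle detector per design, ordered by
#' total FAR.
#'
#' @param truth the `truth` element of [make_synthetic_head()].
#' @param jitter_px standard deviation of box-placement jitter in pixels.
#' @param seed base seed for the jitter stream.
#' @param vis_tol depth visibility tolerance in mesh units.
#' @return List with `detectors` (named list for
#'   [scan_face_elements()]) and `ear_ladders` (named list of
#'   [detector_ladder()]).
#' @export
make_oracle_detectors <- function(truth, jitter_px = 0, seed = 1L,
                                  vis_tol = 6) {
  yaw <- truth$yaw_deg
  out_lon <- c(face = yaw, eye_left = yaw + 30, eye_right = yaw - 30,
               nose = yaw, mouth = yaw, ear_left = yaw + 90,
               ear_right = yaw - 90)

  jit <- function(view, element, n) {
    if (jitter_px <= 0) return(numeric(n))
    s <- (seed * 7919L +
            as.integer(round(view$spec$azimuth_deg * 8)) * 131L +
            match(element, FD_ELEMENTS) * 100003L) %% .Machine$integer.max
    with_local_seed(s, rnorm(n, 0, jitter_px))
  }
  # apparent width factor: boxes narrow as the landmark turns away from the
  # camera (visibility itself is decided by the depth test, not this)
  foreshort <- function(view, element) {
    d <- ((view$spec$azimuth_deg - out_lon[[element]] + 180) %% 360) - 180
    max(0.12, cos(d * pi / 180))
  }
  fit_box <- function(view, top, left, width, height) {
    nr <- view$spec$image_size[1]; nc <- view$spec$image_size[2]
    if (top < 0.5 || left < 0.5 || top + height > nr + 0.5 ||
        left + width > nc + 0.5) return(NULL)   # would leave the frame
    bounding_box(top, left, width, height)
  }

  face_fn <- function(view, element) {
    H <- view$spec$scale * truth$head_size * 0.5
    eL <- project_points(truth$eye_left, view$spec)
    eR <- project_points(truth$eye_right, view$spec)
    if (!landmark_visible(view, truth$eye_left, vis_tol) ||
        !landmark_visible(view, truth$eye_right, vis_tol)) return(list())
    nas <- project_points(truth$nasion, view$spec)
    box <- switch(element,
      face = {
        m <- project_points(truth$mouth, view$spec)
        w <- 1.3 * H; h <- 1.7 * H
        cc <- (eL$col + eR$col) / 2
        cr <- (min(eL$row, eR$row) + m$row) / 2
        fit_box(view, cr - h / 2, cc - w / 2, w, h)
      },
      eye_left = , eye_right = {
        fs <- foreshort(view, element)
        e <- if (element == "eye_left") eL else eR
        # tall enough that the vertical re-centering toward the nasion row
        # below still keeps the eye center inside the box
        w <- 0.32 * H * fs; h <- 0.30 * H
        dr <- nas$row - (eL$row + eR$row) / 2   # common vertical shift
        j <- jit(view, element, 2)
        fit_box(view, e$row + dr - h / 2 + j[1], e$col - w / 2 + j[2], w, h)
      },
      nose = {
        n <- project_points(truth$nose_tip, view$spec)
        w <- 0.28 * H; h <- 0.32 * H
        cc <- 2 * nas$col - (eL$col + eR$col) / 2
        j <- jit(view, element, 2)
        fit_box(view, n$row - h / 2 + j[1], cc - w / 2 + j[2], w, h)
      },
      mouth = {
        m <- project_points(truth$mouth, view$spec)
        w <- 0.44 * H; h <- 0.20 * H
        fit_box(view, m$row - h / 2, m$col - w / 2, w, h)
      })
    if (is.null(box)) list() else list(fd_detection(element, box))
  }

  ear_fn <- function(view, element) {
    fs <- foreshort(view, element)
    pp3 <- if (element == "ear_left") truth$lpa else truth$rpa
    if (!landmark_visible(view, pp3, vis_tol)) return(list())
    H <- view$spec$scale * truth$head_size * 0.5
    p <- project_points(pp3, view$spec)
    w <- 0.28 * H * fs; h <- 0.44 * H
    a <- if (element == "ear_left") 0.2 else 0.8
    j <- jit(view, element, 2)
    box <- fit_box(view, p$row - 0.36 * h + j[1], p$col - a * w + j[2], w, h)
    if (is.null(box)) list() else list(fd_detection(element, box))
  }

  face_det <- fd_detector(face_fn, c("face", "eye_left", "eye_right",
                                     "nose", "mouth"), name = "oracle_face")
  design <- ear_detector_design()
  ladders <- lapply(c(left = "left", right = "right"), function(side) {
    rows <- design[design$side == side, ]
    detector_ladder(lapply(seq_len(nrow(rows)), function(i)
      fd_detector(ear_fn, paste0("ear_", side),
                  name = sprintf("oracle_ear_%s_f%g", side, rows$f[i]),
                  cascade = cascade_spec(rows$f[i], rows$s[i]))))
  })
  list(detectors = list(face = face_det, eye_left = face_det,
                        eye_right = face_det, nose = face_det,
                        mouth = face_det),
       ear_ladders = ladders)
}

#' Degrade a head mesh the way imperfect scans do
#'
#' Two deterministic degradation hooks for robustness testing:
#' `pixelate` block-averages the texture (emulating the aliased, pixelated
#' texture that fine clothing patterns produce during scanning) and
#' `holes` deletes random faces (emulating scan holes). Both are driven by
#' the explicit seed, so a fixed seed always yields the identical degraded
#' mesh.
#'
#' @param mesh a [head_mesh()].
#' @param pixelate integer block size in texels (1 = no change).
#' @param holes number of faces to delete.
#' @param seed seed for the hole positions.
#' @return The degraded [head_mesh()].
#' @export
degrade_head <- function(mesh, pixelate = 1L, holes = 0L, seed = 1L) {
  stopifnot(inherits(mesh, "head_mesh"))
  tex <- mesh$texture
  if (!is.null(tex) && pixelate > 1L) {
    k <- as.integer(pixelate)
    d <- dim(tex)
    bi <- (seq_len(d[1]) - 1L) %/% k
    bj <- (seq_len(d[2]) - 1L) %/% k
    for (ch in 1:3) {
      m <- tex[, , ch]
      sums <- rowsum(t(rowsum(m, bi)), bj)
      cnt <- rowsum(t(rowsum(matrix(1, d[1], d[2]), bi)), bj)
      avg <- t(sums / cnt)
      tex[, , ch] <- avg[bi + 1L, bj + 1L]
    }
  }
  faces <- mesh$faces
  if (holes > 0L && nrow(faces) > holes) {
    drop <- with_local_seed(seed, sample.int(nrow(faces), holes))
    faces <- faces[-drop, , drop = FALSE]
  }
  head_mesh(mesh$vertices, faces, uv = mesh$uv, texture = tex,
            units_hint = mesh$units_hint)
}

#' Write a synthetic head fixture to disk
#'
#' Writes the scanner-orientation mesh as OBJ + MTL + PNG next to `path`
#' and the ground truth (upright frame) as JSON.
#'
#' @param head result of [make_synthetic_head()].
#' @param path output `.obj` path.
#' @param truth_path output JSON path for the ground truth (default:
#'   `path` with `_truth.json`).
#' @return `path`, invisibly.
#' @export
write_synthetic_head <- function(head, path, truth_path = NULL) {
  write_obj(head$scanned, path)
  if (is.null(truth_path))
    truth_path <- paste0(sub("\\.obj$", "", path), "_truth.json")
  jsonlite::write_json(head$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
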