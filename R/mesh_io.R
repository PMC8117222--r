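#' Head-surface mesh container
#'
#' A `head_mesh` bundles the triangulated scan surface: an `n x 3` vertex
#' matrix, an `m x 3` face index matrix (1-based), optional per-vertex UV
#' texture coordinates in `[0, 1]^2`, and an optional RGB texture raster
#' (numeric array `h x w x 3`, values in `[0, 1]`). Coordinates are treated
#' as millimetres but never rescaled; `units_hint` merely records what the
#' caller believes the units are.
#'
#' @param vertices numeric matrix, one 3D point per row.
#' @param faces integer matrix, one triangle of 1-based vertex indices per row.
#' @param uv optional numeric matrix of per-vertex texture coordinates
#'   (same number of rows as `vertices`).
#' @param texture optional numeric array `h x w x 3` in `[0, 1]`.
#' @param units_hint free-text units annotation (default "mm").
#' @return An object of class `head_mesh`.
#' @export
head_mesh <- function(vertices, faces, uv = NULL, texture = NULL,
                      units_hint = "mm") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) fd_stop("vertices must be n x 3", "mesh_io")
  if (nrow(vertices) == 0L) fd_stop("mesh has no vertices", "mesh_io")
  if (ncol(faces) != 3L) fd_stop("faces must be m x 3 triangles", "mesh_io")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    fd_stop("face index out of range", "mesh_io")
  if (!is.null(uv)) {
    uv <- as.matrix(uv)
    storage.mode(uv) <- "double"
    if (nrow(uv) != nrow(vertices) || ncol(uv) != 2L)
      fd_stop("uv must be one (u,v) row per vertex", "mesh_io")
  }
  if (!is.null(texture)) {
    texture <- as_texture_array(texture)
    if (dim(texture)[1] < 1L || dim(texture)[2] < 1L)
      fd_stop("texture must be at least 1 x 1", "mesh_io")
  }
  structure(list(vertices = vertices, faces = faces, uv = uv,
                 texture = texture, units_hint = units_hint),
            class = "head_mesh")
}

as_texture_array <- function(x) {
  x <- unclass(x)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) != 3L) fd_stop("texture must be h x w x {1,3,4}", "mesh_io")
  storage.mode(x) <- "double"
  x
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("head_mesh: %d vertices, %d faces, %s, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$texture)) "untextured"
              else sprintf("texture %dx%d", dim(x$texture)[1], dim(x$texture)[2]),
              paste0("units_hint=", x$units_hint)))
  invisible(x)
}

#' Load a Wavefront OBJ head scan
#'
#' Parses the OBJ dialect that head scanners emit: `v`, `vt` and `f` records,
#' with `f v`, `f v/vt` and `f v/vt/vn` index forms (1-based; negative indices
#' resolved from the end). Polygonal faces are fan-triangulated. Normals and
#' all material properties except the diffuse texture map are ignored. The
#' texture is located through `mtllib`/`map_Kd` or, failing that, a same-name
#' `.png`/`.jpg` next to the OBJ; an unreadable texture degrades to an
#' untextured mesh with a warning.
#'
#' OBJ allows per-corner texture indices; this reader keeps one UV per vertex
#' (last assignment wins), which is exact for the seam-free per-vertex
#' parameterizations produced here and an adequate approximation otherwise.
#'
#' @param path path to the `.obj` file.
#' @param units_hint free-text units annotation stored on the mesh.
#' @return A [head_mesh()].
#' @export
load_obj_model <- function(path, units_hint = "mm") {
  if (!file.exists(path)) fd_stop(paste("no such file:", path), "mesh_io")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tag <- sub("[ \t].*$", "", lines)

  vlines <- lines[tag == "v"]
  if (length(vlines) == 0L) fd_stop("OBJ contains no vertices", "mesh_io")
  V <- do.call(rbind, lapply(strsplit(vlines, "[ \t]+"), function(p)
    as.numeric(p[2:4])))

  vt <- NULL
  vtlines <- lines[tag == "vt"]
  if (length(vtlines) > 0L)
    vt <- do.call(rbind, lapply(strsplit(vtlines, "[ \t]+"), function(p)
      as.numeric(p[2:3])))

  # faces: fan-triangulate, collect vertex and vt indices per corner
  fidx <- list(); ftidx <- list()
  for (ln in lines[tag == "f"]) {
    parts <- strsplit(ln, "[ \t]+")[[1]][-1]
    comp <- strsplit(parts, "/", fixed = TRUE)
    vi <- vapply(comp, function(p) as.integer(p[1]), integer(1))
    ti <- vapply(comp, function(p)
      if (length(p) >= 2L && nzchar(p[2])) as.integer(p[2]) else NA_integer_,
      integer(1))
    vi <- ifelse(vi < 0L, nrow(V) + vi + 1L, vi)
    if (!is.null(vt)) ti <- ifelse(!is.na(ti) & ti < 0L, nrow(vt) + ti + 1L, ti)
    if (any(vi < 1L | vi > nrow(V)))
      fd_stop("face index out of range", "mesh_io")
    if (length(vi) < 3L) next
    for (k in 2:(length(vi) - 1L)) {
      fidx[[length(fidx) + 1L]] <- vi[c(1L, k, k + 1L)]
      ftidx[[length(ftidx) + 1L]] <- ti[c(1L, k, k + 1L)]
    }
  }
  F <- if (length(fidx)) do.call(rbind, fidx) else matrix(integer(), 0, 3)

  uv <- NULL
  if (!is.null(vt) && length(ftidx)) {
    uv <- matrix(NA_real_, nrow(V), 2L)
    FT <- do.call(rbind, ftidx)
    ok <- !is.na(FT)
    uv[F[ok], ] <- vt[FT[ok], , drop = FALSE]
    if (anyNA(uv)) uv[is.na(uv)] <- 0
  }

  texture <- read_obj_texture(path, lines, tag)
  head_mesh(V, F, uv = uv, texture = texture, units_hint = units_hint)
}

# Resolve and read the diffuse texture referenced from an OBJ (via its MTL),
# falling back to a same-name image. Returns NULL (with a warning if a
# reference existed but could not be read).
read_obj_texture <- function(obj_path, lines, tag) {
  dir <- dirname(obj_path)
  candidates <- character()
  mtl <- sub("^mtllib[ \t]+", "", lines[tag == "mtllib"])
  for (m in mtl) {
    mp <- file.path(dir, m)
    if (file.exists(mp)) {
      ml <- trimws(readLines(mp, warn = FALSE))
      maps <- sub("^map_Kd[ \t]+", "", ml[grepl("^map_Kd[ \t]", ml)])
      candidates <- c(candidates, file.path(dir, maps))
    }
  }
  base <- sub("\\.obj$", "", obj_path, ignore.case = TRUE)
  candidates <- c(candidates, paste0(base, c(".png", ".jpg", ".jpeg")))
  candidates <- candidates[file.exists(candidates)]
  if (length(candidates) == 0L) return(NULL)
  for (tex in candidates) {
    img <- try(read_texture_image(tex), silent = TRUE)
    if (!inherits(img, "try-error") && !is.null(img)) return(img)
  }
  warning(sprintf("texture '%s' could not be read; mesh left untextured",
                  candidates[1]))
  NULL
}

read_texture_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE))
    return(as_texture_array(png::readPNG(path)))
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE) &&
      requireNamespace("EBImage", quietly = TRUE))
    return(as_texture_array(aperm(EBImage::imageData(
      EBImage::readImage(path)), c(2, 1, 3))))
  NULL
}

#' Write a mesh as Wavefront OBJ (+ MTL + PNG texture)
#'
#' Writes `v`/`vt`/`f` records; when the mesh is textured an MTL file and a
#' PNG texture are written next to the OBJ and referenced via
#' `mtllib`/`map_Kd`, so the output round-trips through [load_obj_model()].
#'
#' @param mesh a [head_mesh()].
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "head_mesh"))
  base <- sub("\\.obj$", "", path, ignore.case = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(mesh$texture)) {
    mtl <- paste0(base, ".mtl")
    tex <- paste0(base, ".png")
    png::writePNG(mesh$texture, tex)
    writeLines(c("newmtl scanned", paste("map_Kd", basename(tex))), mtl)
    writeLines(paste("mtllib", basename(mtl)), con)
  }
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  if (!is.null(mesh$uv)) {
    writeLines(sprintf("vt %.9g %.9g", mesh$uv[, 1], mesh$uv[, 2]), con)
    writeLines(sprintf("f %d/%d %d/%d %d/%d",
                       mesh$faces[, 1], mesh$faces[, 1],
                       mesh$faces[, 2], mesh$faces[, 2],
                       mesh$faces[, 3], mesh$faces[, 3]), con)
  } else {
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  }
  invisible(path)
}

#' Correct the gravity-aligned vertical flip of scanner output
#'
#' Structured-light head scanners orient their Z axis along gravity, so the
#' exported model appears upside down. This reflects the mesh about the
#' horizontal plane through its vertex centroid (`z -> 2*cz - z`) and
#' reverses face winding so outward normals stay outward. The operation is
#' its own inverse.
#'
#' @param mesh a [head_mesh()].
#' @return The flipped [head_mesh()].
#' @export
gravity_flip <- function(mesh) {
  stopifnot(inherits(mesh, "head_mesh"))
  cz <- mean(mesh$vertices[, 3])
  v <- mesh$vertices
  v[, 3] <- 2 * cz - v[, 3]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  head_mesh(v, f, uv = mesh$uv, texture = mesh$texture,
            units_hint = mesh$units_hint)
}

#' 3D fiducial landmark
#'
#' @param label one of `"nasion"`, `"lpa"`, `"rpa"`.
#' @param position 3D point in mesh coordinates.
#' @param position_scs optional 3D point in CTF head coordinates.
#' @return An object of class `fiducial3d`.
#' @export
fiducial3d <- function(label, position, position_scs = NULL) {
  label <- match.arg(label, c("nasion", "lpa", "rpa"))
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position)))
    fd_stop("position must be a finite 3-vector", "mesh_io")
  structure(list(label = label, position = position,
                 position_scs = if (!is.null(position_scs))
                   as.numeric(position_scs)),
            class = "fiducial3d")
}

#' Write localized fiducials to disk
#'
#' Writes a JSON document holding, per fiducial, both the mesh-space and the
#' CTF/SCS-space coordinates, plus the 4x4 rigid world-to-SCS matrix.
#' Optionally also writes an electrode-style plain-text export with one
#' `label x y z` line per fiducial (SCS coordinates).
#'
#' @param fids list of three [fiducial3d()] objects labelled nasion/lpa/rpa.
#' @param transform an [scs_transform()].
#' @param path output JSON path.
#' @param electrode_path optional path for the plain-text export.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fids, transform, path, electrode_path = NULL) {
  labs <- vapply(fids, function(f) f$label, character(1))
  for (need in c("nasion", "lpa", "rpa"))
    if (!need %in% labs)
      fd_stop(paste("missing fiducial:", need), "mesh_io")
  fids <- fids[match(c("nasion", "lpa", "rpa"), labs)]
  scs_pts <- apply_transform(
    do.call(rbind, lapply(fids, `[[`, "position")), transform)
  m4 <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  doc <- list(
    fiducials = lapply(seq_along(fids), function(i) list(
      label = fids[[i]]$label,
      position_mesh = as.numeric(fids[[i]]$position),
      position_scs = as.numeric(scs_pts[i, ]))),
    transform = list(convention = transform$convention,
                     matrix = unname(m4))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(electrode_path))
    writeLines(sprintf("%s\t%.9g\t%.9g\t%.9g",
                       c("nasion", "lpa", "rpa"),
                       scs_pts[, 1], scs_pts[, 2], scs_pts[, 3]),
               electrode_path)
  invisible(path)
}

#' Read fiducials written by [write_fiducials()]
#'
#' @param path JSON path.
#' @return List with elements `fiducials` (list of [fiducial3d()]) and
#'   `transform` (an [scs_transform()]).
#' @export
read_fiducials <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m4 <- as.matrix(doc$transform$matrix)
  tr <- scs_transform(m4[1:3, 1:3], m4[1:3, 4],
                      convention = doc$transform$convention)
  fids <- lapply(seq_len(nrow(doc$fiducials)), function(i)
    fiducial3d(doc$fiducials$label[i],
               unlist(doc$fiducials$position_mesh[i]),
               unlist(doc$fiducials$position_scs[i])))
  list(fiducials = fids, transform = tr)
}
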