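#' Orthographic view specification
#'
#' Defines one 2D projection of the head: an orthographic camera on the
#' horizontal circle of azimuth `azimuth_deg` about the mesh vertex centroid,
#' looking at the centroid, with image "up" = +Z. Azimuth increases
#' counterclockwise when viewed from above; azimuth 0 places the camera on
#' the +X axis.
#'
#' All pixel coordinates in this package are intrinsic and 1-based:
#' `(row = 1, col = 1)` is the top-left pixel, rows increase downward, and
#' pixel centers sit at integer coordinates. Public APIs take and return
#' `(row, col)` in that order.
#'
#' The depth buffer stores distance from a camera plane placed
#' `depth_offset` mesh units in front of the centroid along the camera
#' direction, so a surface point `p` has depth
#' `depth_offset - dot(p - center, camdir)`; smaller is closer.
#'
#' @param mesh the [head_mesh()] the view will frame (used for centroid and
#'   default scale).
#' @param azimuth_deg camera azimuth in degrees, any real (reduced mod 360).
#' @param image_size integer `(rows, cols)`.
#' @param scale pixels per mesh unit; default fits the mesh bounding sphere
#'   to 90% of the smaller image dimension.
#' @return An object of class `view_spec` with the camera basis
#'   (`camdir`, `rightv`, `upv`), `center`, `scale` and `depth_offset`.
#' @export
view_spec <- function(mesh, azimuth_deg, image_size = c(240L, 240L),
                      scale = NULL) {
  stopifnot(inherits(mesh, "head_mesh"))
  image_size <- as.integer(image_size)
  if (any(image_size < 1L)) fd_stop("image_size must be positive", "projection")
  center <- colMeans(mesh$vertices)
  rel <- sweep(mesh$vertices, 2, center)
  radius <- sqrt(max(rowSums(rel^2)))
  if (radius == 0) radius <- 1
  if (is.null(scale)) scale <- 0.45 * min(image_size) / radius
  if (scale <= 0) fd_stop("scale must be > 0", "projection")
  th <- (azimuth_deg %% 360) * pi / 180
  camdir <- c(cos(th), sin(th), 0)          # centroid -> camera
  upv <- c(0, 0, 1)
  rightv <- c(-sin(th), cos(th), 0)         # cross(-camdir, upv)
  structure(list(azimuth_deg = azimuth_deg %% 360,
                 image_size = image_size, scale = scale,
                 center = center, camdir = camdir, rightv = rightv,
                 upv = upv, depth_offset = radius),
            class = "view_spec")
}

#' Render one orthographic view of the mesh
#'
#' Z-buffered orthographic rasterization with per-pixel barycentric UV
#' texture lookup (nearest texel). Untextured meshes get flat Lambertian
#' shading from the camera direction. Background pixels hold the constant
#' `bg` color, depth `Inf`, and face id 0. Depth ties at shared edges go to
#' the smaller face index. Triangles degenerate in projection are skipped.
#'
#' @param mesh a [head_mesh()].
#' @param spec a [view_spec()] built for this mesh.
#' @param bg background RGB, values in `[0, 1]`.
#' @return An object of class `rendered_view`: `image` (`rows x cols x 3`
#'   array), `depth` (matrix, `Inf` at background), `faceid` (integer
#'   matrix, 0 at background) and `spec`.
#' @export
render_view <- function(mesh, spec, bg = c(0.08, 0.08, 0.1)) {
  stopifnot(inherits(mesh, "head_mesh"), inherits(spec, "view_spec"))
  textured <- !is.null(mesh$texture) && !is.null(mesh$uv)
  uv <- if (textured) mesh$uv else matrix(numeric(), 0, 2)
  tex <- if (textured) as.numeric(mesh$texture) else numeric()
  texdim <- if (textured) dim(mesh$texture)[1:2] else integer()
  out <- cpp_render(mesh$vertices, mesh$faces - 1L, uv, tex,
                    as.integer(texdim),
                    spec$center, spec$camdir, spec$rightv, spec$upv,
                    spec$image_size[1], spec$image_size[2],
                    spec$scale, spec$depth_offset, as.numeric(bg))
  img <- array(c(out$r, out$g, out$b),
               c(spec$image_size[1], spec$image_size[2], 3L))
  structure(list(image = img, depth = out$depth, faceid = out$faceid,
                 spec = spec),
            class = "rendered_view")
}

#' @export
print.rendered_view <- function(x, ...) {
  cat(sprintf("rendered_view: %dx%d @ azimuth %.1f deg, %d foreground px\n",
              x$spec$image_size[1], x$spec$image_size[2],
              x$spec$azimuth_deg, sum(is.finite(x$depth))))
  invisible(x)
}

#' Project mesh-space points into a view
#'
#' @param points numeric `n x 3` matrix (or 3-vector) of mesh coordinates.
#' @param spec a [view_spec()].
#' @return Data frame with fractional intrinsic `row`, `col` and `depth`
#'   (same depth convention as the view's depth buffer).
#' @export
project_points <- function(points, spec) {
  stopifnot(inherits(spec, "view_spec"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  rel <- sweep(as.matrix(points), 2, spec$center)
  r0 <- (spec$image_size[1] + 1) / 2
  c0 <- (spec$image_size[2] + 1) / 2
  data.frame(
    row = r0 - spec$scale * as.numeric(rel %*% spec$upv),
    col = c0 + spec$scale * as.numeric(rel %*% spec$rightv),
    depth = spec$depth_offset - as.numeric(rel %*% spec$camdir))
}

#' Orthographic ray through a pixel
#'
#' Inverts the camera of a rendered view: returns the ray that produced a
#' given (possibly fractional) pixel, in mesh coordinates. The origin lies on
#' the camera plane and the unit direction points toward the mesh, so a
#' surface point hit at ray parameter `t` has depth-buffer value `t`.
#'
#' @param view a [rendered_view()] (a bare [view_spec()] is also accepted).
#' @param pixel numeric `(row, col)`, inside the image bounds.
#' @return List with `origin` and `direction` (unit 3-vectors).
#' @export
pixel_to_ray <- function(view, pixel) {
  spec <- if (inherits(view, "view_spec")) view else view$spec
  pixel <- as.numeric(pixel)
  if (pixel[1] < 0.5 || pixel[1] > spec$image_size[1] + 0.5 ||
      pixel[2] < 0.5 || pixel[2] > spec$image_size[2] + 0.5)
    fd_stop(sprintf("pixel (%.2f, %.2f) outside %dx%d image",
                    pixel[1], pixel[2],
                    spec$image_size[1], spec$image_size[2]), "projection")
  r0 <- (spec$image_size[1] + 1) / 2
  c0 <- (spec$image_size[2] + 1) / 2
  origin <- spec$center + spec$depth_offset * spec$camdir +
    ((pixel[2] - c0) / spec$scale) * spec$rightv +
    ((r0 - pixel[1]) / spec$scale) * spec$upv
  list(origin = origin, direction = -spec$camdir)
}

#' Dump a rendered view (or its depth) as PNG
#'
#' @param view a [rendered_view()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_view_png <- function(view, path) {
  png::writePNG(view$image, path)
  invisible(path)
}
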