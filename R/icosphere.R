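#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected onto the unit sphere, the standard
#' near-uniform sphere triangulation; used as a geometric fixture for
#' rendering and ray-casting checks (silhouette radius, nearest-hit
#' reprojection).
#'
#' @param subdivisions number of 4-to-1 subdivision passes (0 = bare
#'   icosahedron, 20 faces; each pass multiplies the face count by 4).
#' @param radius sphere radius.
#' @param center 3-vector center.
#' @return A [head_mesh()] (untextured).
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- V[a, ] + V[b, ]
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      mid_cache[[key]] <- nv + length(newV)
      nv + length(newV)
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; cc <- F[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4L * i - 3L, ] <- c(a, ab, ca)
      newF[4L * i - 2L, ] <- c(b, bc, ab)
      newF[4L * i - 1L, ] <- c(cc, ca, bc)
      newF[4L * i, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  head_mesh(sweep(V * radius, 2, center, `+`), F, units_hint = "unit sphere")
}
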