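# Independent oracles and tiny fixtures. Everything here is deliberately
# naive/brute-force and shares no code with the package internals it checks.

# --- tiny meshes -----------------------------------------------------------

one_triangle_mesh <- function(v1 = c(0, -1, -1), v2 = c(0, 1, -1),
                              v3 = c(0, 0, 1)) {
  head_mesh(rbind(v1, v2, v3), matrix(1:3, 1))
}

# two parallel triangles stacked along +X (camera at azimuth 0 sees `near`
# first)
stacked_triangles_mesh <- function(gap = 1) {
  near <- rbind(c(gap, -1, -1), c(gap, 1, -1), c(gap, 0, 1))
  far <- rbind(c(-gap, -1, -1), c(-gap, 1, -1), c(-gap, 0, 1))
  head_mesh(rbind(near, far), rbind(1:3, 4:6))
}

write_mini_obj <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
  path <- file.path(dir, "mini.obj")
  writeLines(lines, path)
  path
}

# --- naive circular run finder (oracle for find_arcs) ----------------------

naive_runs <- function(flags) {
  n <- length(flags)
  if (!any(flags)) return(list())
  if (all(flags)) return(list(seq_len(n)))
  runs <- list()
  i <- 1L
  # start scanning just after a FALSE so wraparound runs stay whole
  start0 <- which(!flags)[1]
  order_idx <- ((start0 + seq_len(n) - 1L - 1L) %% n) + 1L
  cur <- integer()
  for (i in order_idx) {
    if (flags[i]) cur <- c(cur, i)
    else if (length(cur)) { runs[[length(runs) + 1L]] <- cur; cur <- integer() }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs[order(vapply(runs, length, integer(1)), decreasing = TRUE)]
}

# --- brute-force ray casting (oracle for pixel_to_surface) -----------------

# straightforward per-triangle plane/edge test, no shared code with the
# compiled Moller-Trumbore path
brute_ray_mesh <- function(mesh, origin, dir) {
  best_t <- Inf; best_f <- 0L
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    denom <- sum(nrm * dir)
    if (abs(denom) < 1e-14) next
    t <- sum(nrm * (tri[1, ] - origin)) / denom
    if (t <= 1e-12 || t >= best_t) next
    p <- origin + t * dir
    # solve barycentric via least squares on the triangle plane
    A <- cbind(e1, e2)
    uv <- solve(crossprod(A), crossprod(A, p - tri[1, ]))
    if (uv[1] >= -1e-9 && uv[2] >= -1e-9 && sum(uv) <= 1 + 1e-9) {
      best_t <- t; best_f <- f
    }
  }
  list(face = best_f, t = best_t)
}

# --- misc ------------------------------------------------------------------

# exhaustive joint-grid L1 calibration (oracle for calibrate_pp_correction):
# literal double loop over every (a, b) pair, lexicographic tie-break
brute_calibrate <- function(samples, step) {
  grid <- seq(0, 1, by = step)
  best <- c(NA, NA); best_loss <- Inf
  for (a in grid) for (b in grid) {
    loss <- 0
    for (s in samples)
      loss <- loss + abs(s$box$left + a * s$box$width - s$col) +
        abs(s$box$top + b * s$box$height - s$row)
    if (loss < best_loss - 1e-12) { best_loss <- loss; best <- c(a, b) }
  }
  best
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random rigid motion (proper rotation + translation)
random_rigid <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 50))
}

# edge audit: TRUE when every undirected edge is shared by exactly 2 faces
is_watertight <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# shared synthetic fixture for the cheap tests (built once per test run)
fixture_head <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_synthetic_head(synthetic_head_spec(seed = 101))
    cache
  }
})
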