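test_that("pixel_to_surface returns exact hits on simple geometry", {
  # single triangle: the ray through its projected centroid hits the
  # barycentric centroid
  m <- one_triangle_mesh()
  spec <- view_spec(m, 0, image_size = c(64L, 64L))
  v <- render_view(m, spec)
  centroid <- colMeans(m$vertices)
  p <- project_points(centroid, spec)
  hit <- pixel_to_surface(m, v, c(p$row, p$col))
  expect_equal(as.numeric(hit), centroid, tolerance = 1e-9)
  expect_equal(attr(hit, "face"), 1L)

  # two stacked parallel triangles: the nearer one wins
  m2 <- stacked_triangles_mesh()
  v2 <- render_view(m2, view_spec(m2, 0, image_size = c(64L, 64L)))
  ctr <- c((64 + 1) / 2, (64 + 1) / 2)
  hit2 <- pixel_to_surface(m2, v2, ctr)
  expect_equal(attr(hit2, "face"), 1L)
  expect_equal(hit2[1], 1)  # near plane is x = +gap

  # background pixel errors
  expect_error(pixel_to_surface(m, v, c(2, 2)), "off surface")
})

test_that("pixel_to_surface agrees with a brute-force intersection oracle", {
  sph <- make_icosphere(3, radius = 90)  # 1280 faces
  spec <- view_spec(sph, 40, image_size = c(96L, 96L))
  v <- render_view(sph, spec)
  fg <- which(is.finite(v$depth), arr.ind = TRUE)
  set.seed(5)
  pick <- fg[sample(nrow(fg), 40), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    px <- c(pick[k, 1], pick[k, 2])
    hit <- pixel_to_surface(sph, v, px)
    ray <- pixel_to_ray(v, px)
    oracle <- brute_ray_mesh(sph, ray$origin, ray$direction)
    expect_equal(attr(hit, "face"), oracle$face)
    expect_equal(sqrt(sum((as.numeric(hit) -
                           (ray$origin + oracle$t * ray$direction))^2)), 0,
                 tolerance = 1e-8)
  }

  # the center pixel of a sphere view hits within a facet of the nearest
  # sphere point to the camera
  ctr <- c((96 + 1) / 2, (96 + 1) / 2)
  hit <- pixel_to_surface(sph, v, ctr)
  nearest <- spec$center + 90 * spec$camdir
  expect_lt(sqrt(sum((as.numeric(hit) - nearest)^2)), 12)  # facet size
})

test_that("CTF construction places the fiducials canonically", {
  # already in CTF pose: identity
  tr <- build_ctf_transform(c(10, 0, 0), c(0, 8, 0), c(0, -8, 0))
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply_transform(c(10, 0, 0), tr), c(10, 0, 0))

  set.seed(21)
  for (i in 1:100) {
    nas <- rnorm(3, sd = 40); lpa <- rnorm(3, sd = 40); rpa <- rnorm(3, sd = 40)
    area2 <- sum(cross3_test(lpa - nas, rpa - nas)^2)
    if (area2 < 1e-4) next
    # a head whose vertical agrees with its anatomy: up on the side of the
    # fiducial plane that the right-handed nasion/left-ear frame implies
    up <- cross3_test(nas - (lpa + rpa) / 2, lpa - rpa)
    tr <- build_ctf_transform(nas, lpa, rpa, up = up)
    tn <- apply_transform(nas, tr)
    tl <- apply_transform(lpa, tr)
    trp <- apply_transform(rpa, tr)
    # nasion on +x axis
    expect_equal(tn[2], 0, tolerance = 1e-9)
    expect_equal(tn[3], 0, tolerance = 1e-9)
    expect_gt(tn[1], 0)
    # preauricular points symmetric about the origin, in the z = 0 plane
    expect_equal(tl, -trp, tolerance = 1e-9)
    expect_equal(tl[3], 0, tolerance = 1e-9)
    # y axis points toward the left preauricular point
    expect_gt(tl[2], 0)
    # tilting the scan upside down flips z (and with it the y side)
    tr_dn <- build_ctf_transform(nas, lpa, rpa, up = -up)
    expect_lt(apply_transform(lpa, tr_dn)[2], 0)
    # rigidity
    d0 <- dist(rbind(nas, lpa, rpa))
    d1 <- dist(rbind(tn, tl, trp))
    expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  }

  expect_error(build_ctf_transform(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "collinear")
})

test_that("CTF construction is equivariant under rigid motions", {
  set.seed(33)
  for (i in 1:100) {
    nas <- rnorm(3, sd = 40); lpa <- rnorm(3, sd = 40); rpa <- rnorm(3, sd = 40)
    if (sum(cross3_test(lpa - nas, rpa - nas)^2) < 1e-4) next
    g <- random_rigid()
    mv <- function(p) as.numeric(g$R %*% p + g$t)
    t1 <- build_ctf_transform(nas, lpa, rpa, up = c(0, 0, 1))
    t2 <- build_ctf_transform(mv(nas), mv(lpa), mv(rpa),
                              up = as.numeric(g$R %*% c(0, 0, 1)))
    for (p in list(nas, lpa, rpa, rnorm(3, sd = 30))) {
      expect_equal(apply_transform(mv(p), t2), apply_transform(p, t1),
                   tolerance = 1e-7)
    }
  }
})

test_that("rigid transforms apply, invert and compose correctly", {
  tr <- build_ctf_transform(c(9, 2, 1), c(-1, 7, 2), c(1, -8, -1))
  set.seed(2)
  P <- matrix(rnorm(30, sd = 20), 10, 3)
  Q <- apply_transform(P, tr)
  expect_equal(as.numeric(dist(Q)), as.numeric(dist(P)), tolerance = 1e-9)
  back <- apply_transform(Q, invert_transform(tr))
  expect_equal(back, P, tolerance = 1e-9)

  ident <- scs_transform(diag(3), c(0, 0, 0))
  expect_equal(apply_transform(P, ident), P)

  expect_error(scs_transform(matrix(rnorm(9), 3), c(0, 0, 0)),
               "orthonormal")
})
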