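test_that("STL and PLY round trips preserve geometry and reject bad input", {
  m <- tetrahedron_mesh()
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  stlb <- tempfile(fileext = ".stl")
  write_mesh(m, stl)
  write_mesh(m, ply)
  write_mesh(m, stlb, binary = TRUE)

  m_stl <- read_mesh(stl)
  m_ply <- read_mesh(ply)
  m_stlb <- read_mesh(stlb)
  expect_equal(nrow(m_stl$vertices), 4)
  expect_equal(nrow(m_stl$faces), 4)

  sort_rows <- function(v) v[do.call(order, as.data.frame(v)), ]
  expect_equal(sort_rows(m_stl$vertices), sort_rows(m_ply$vertices),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sort_rows(m_stlb$vertices), sort_rows(m$vertices),
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(triangle_mesh(m$vertices, rbind(c(1, 2, 10))),
               "out of range")
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
})

test_that("mesh validation drops degenerate faces and flags watertightness", {
  m <- tetrahedron_mesh()
  expect_true(is_watertight(m))
  # add a zero-area face: validation must remove it
  m2 <- triangle_mesh(m$vertices, rbind(m$faces, c(1, 1, 2)))
  expect_equal(nrow(m2$faces), 4)
  expect_error(triangle_mesh(m$vertices, rbind(c(1, 1, 2))), "degenerate")
  # open surface is not watertight
  open_cyl <- cylinder_mesh(capped = FALSE)
  expect_false(is_watertight(open_cyl))
})

test_that("nearest vertex distance matches hand computation and brute force", {
  m <- triangle_mesh(rbind(c(0, 0, 1), c(3, 0, 0), c(0, 4, 0)),
                     rbind(c(1, 2, 3)))
  r <- nearest_vertex_distance(c(0, 0, 5), m)
  expect_equal(r$distance, 4.0)
  expect_equal(r$index, 1L)
  expect_equal(nearest_vertex_distance(c(3, 0, 0), m)$distance, 0.0)

  # grid-accelerated search must equal the exhaustive scan exactly,
  # including the lowest-index tie break
  set.seed(42)
  verts <- matrix(rnorm(500 * 3, sd = 30), ncol = 3)
  verts[250, ] <- verts[10, ]  # duplicated vertex forces distance ties
  mesh <- triangle_mesh(verts, rbind(c(1, 2, 3)))
  pts <- rbind(matrix(rnorm(50 * 3, sd = 40), ncol = 3),
               verts[10, , drop = FALSE])
  g <- nearest_vertex_distance(pts, mesh, method = "grid")
  e <- nearest_vertex_distance(pts, mesh, method = "exhaustive")
  expect_identical(g$distance, e$distance)
  expect_identical(g$index, e$index)
  for (k in c(1, 17, 51)) {
    b <- brute_nearest_vertex(pts[k, ], verts)
    expect_identical(g$distance[k], b$distance)
    expect_identical(g$index[k], b$index)
  }
  expect_error(nearest_vertex_distance(c(0, 0, 0),
                                       list(vertices = matrix(0, 0, 3))),
               "empty")
})

test_that("point containment agrees with the analytic sphere", {
  s <- uv_sphere_mesh(radius = 1)
  expect_true(point_inside_surface(c(0, 0, 0), s))
  expect_false(point_inside_surface(c(2, 0, 0), s))

  set.seed(7)
  pts <- matrix(rnorm(100 * 3, sd = 0.8), ncol = 3)
  r <- sqrt(rowSums(pts^2))
  # stay clear of the chordal band near the surface where the faceted
  # sphere and the analytic sphere legitimately disagree
  keep <- abs(r - 1) > 0.05
  inside <- point_inside_surface(pts[keep, ], s)
  expect_equal(inside, r[keep] < 1)

  expect_error(point_inside_surface(c(0, 0, 0), cylinder_mesh(capped = FALSE)),
               "watertight")
})

test_that("containment is complementary under reflection through the centre", {
  s <- uv_sphere_mesh(radius = 1.5, centre = c(2, -1, 3))
  set.seed(11)
  pts <- sweep(matrix(rnorm(60 * 3, sd = 1.0), ncol = 3), 2, c(2, -1, 3), "+")
  r <- sqrt(rowSums(sweep(pts, 2, c(2, -1, 3))^2))
  keep <- abs(r - 1.5) > 0.08
  pts <- pts[keep, , drop = FALSE]
  refl <- sweep(-sweep(pts, 2, c(2, -1, 3)), 2, c(2, -1, 3), "+")
  expect_equal(point_inside_surface(pts, s), point_inside_surface(refl, s))
})

test_that("plane sections of a cylinder give a loop at the right radius", {
  cyl <- cylinder_mesh(radius = 10, height = 40)
  sec <- section_mesh(cyl, c(0, 0, 17.3), c(0, 0, 1))
  expect_s3_class(sec, "plane_section")
  expect_equal(sum(sec$closed), 1)
  loop <- sec$loops[[which(sec$closed)[1]]]
  radii <- sqrt(loop[, 1]^2 + loop[, 2]^2)
  # chordal tolerance of a 64-gon
  expect_true(all(radii <= 10 + 1e-9 & radii >= 10 * cos(pi / 64) - 1e-9))
  expect_error(section_mesh(cyl, c(0, 0, 100), c(0, 0, 1)), "empty section")
})

test_that("section centroids recover analytic centres", {
  cyl <- cylinder_mesh(radius = 10, height = 40)
  sec <- section_mesh(cyl, c(0, 0, 20.1), c(0, 0, 1))
  expect_equal(section_centroid(sec), c(0, 0, 20.1), tolerance = 1e-6)

  # square loop in a plane: centroid (1, 1)
  sq <- structure(list(
    point = c(0, 0, 0), normal = c(0, 0, 1),
    loops = list(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))),
    closed = TRUE), class = "plane_section")
  expect_equal(section_centroid(sq), c(1, 1, 0), tolerance = 1e-9)

  # ellipse loop: centroid at the ellipse centre regardless of the
  # (non-uniform) parameter sampling and of point ordering rotation
  set.seed(3)
  t <- sort(runif(180) * 2 * pi)
  ell <- cbind(5 + 3 * cos(t), -2 + 1.5 * sin(t), 1)
  mk <- function(pts) structure(list(point = c(0, 0, 1), normal = c(0, 0, 1),
                                     loops = list(pts), closed = TRUE),
                                class = "plane_section")
  c1 <- section_centroid(mk(ell))
  expect_equal(c1, c(5, -2, 1), tolerance = 5e-3)
  rot <- rbind(ell[61:180, ], ell[1:60, ])
  expect_equal(section_centroid(mk(rot)), c1, tolerance = 1e-12)

  # open loop is rejected
  open_sec <- structure(list(point = c(0, 0, 0), normal = c(0, 0, 1),
                             loops = list(ell[1:50, ]), closed = FALSE),
                        class = "plane_section")
  expect_error(section_centroid(open_sec), "closed")
})

test_that("sectioning an annular pair keeps inner and outer walls separate", {
  # inner and outer cortex stand-ins: coaxial capped cylinders
  outer <- cylinder_mesh(radius = 12, height = 40)
  inner <- cylinder_mesh(radius = 6, height = 40)
  si <- section_mesh(inner, c(0, 0, 20), c(0, 0, 1))
  expect_equal(sum(si$closed), 1)
  loop <- si$loops[[which(si$closed)[1]]]
  expect_true(all(abs(sqrt(loop[, 1]^2 + loop[, 2]^2) - 6) < 0.1))
  so <- section_mesh(outer, c(0, 0, 20), c(0, 0, 1))
  ro <- sqrt(so$loops[[which(so$closed)[1]]][, 1]^2 +
             so$loops[[which(so$closed)[1]]][, 2]^2)
  expect_true(all(abs(ro - 12) < 0.2))
})

test_that("landmark sidecars round trip through JSON", {
  lm <- list(lesser_trochanter_base = c(1.5, -2, 395),
             fossa = rbind(c(0, 1, 2), c(3, 4, 5)))
  path <- tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$lesser_trochanter_base, lm$lesser_trochanter_base)
  expect_equal(back$fossa, lm$fossa, ignore_attr = TRUE)
})
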