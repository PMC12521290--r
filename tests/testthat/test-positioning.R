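test_that("rigid transforms compose, invert and serialise correctly", {
  set.seed(1)
  a <- random_rigid()
  b <- random_rigid()
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(pts, compose_transform(a, b)),
               apply_transform(apply_transform(pts, b), a), tolerance = 1e-12)
  ident <- compose_transform(a, invert_transform(a))
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")

  path <- tempfile(fileext = ".json")
  write_transform(a, path)
  a2 <- read_transform(path)
  expect_equal(a2$rotation, a$rotation, tolerance = 1e-12)
  expect_equal(a2$translation, a$translation, tolerance = 1e-12)
})

test_that("initial alignment recovers identity and known pre-transforms", {
  pair <- conforming_pair()
  tf <- initial_alignment(pair$plate, pair$bone)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-6)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-6)

  # plate pre-rotated by 15 degrees about the shaft axis: the alignment
  # must recover the inverse
  ang <- 15 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  pre <- rigid_transform(Rz, c(5, -3, 8))
  moved <- transform_plate(pair$plate, pre)
  rec <- initial_alignment(moved, pair$bone)
  comp <- compose_transform(rec, pre)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-6)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-6)

  bone_nolm <- pair$bone
  bone_nolm$landmarks$distal_anterior_contact <- NULL
  expect_error(initial_alignment(pair$plate, bone_nolm), "missing landmark")
})

test_that("least-squares alignment never increases correspondence RMS", {
  kab <- getFromNamespace("kabsch", "platefit")
  set.seed(4)
  for (i in 1:20) {
    P <- matrix(rnorm(15, sd = 10), ncol = 3)
    Q <- apply_transform(P, random_rigid()) + matrix(rnorm(15, sd = 2), ncol = 3)
    tf <- kab(P, Q)
    rms_before <- sqrt(mean((P - Q)^2))
    rms_after <- sqrt(mean((apply_transform(P, tf) - Q)^2))
    expect_lte(rms_after, rms_before + 1e-12)
  }
})

test_that("refinement seats a conforming plate and recovers perturbations", {
  pair <- conforming_pair()
  pos <- refine_position(pair$plate, pair$bone)
  expect_true(pos$converged)
  expect_true(all(pos$contact_zones <= 0.2))
  expect_equal(pos$penetration_count, 0)
  expect_true(pos$screw_checks$fossa_clear)
  expect_true(pos$screw_checks$proximal_screw_in_canal)

  # 2 mm translation perturbation of the init
  pert <- compose_transform(rigid_transform(diag(3), c(1.2, 1.2, 0.9)),
                            initial_alignment(pair$plate, pair$bone))
  pos2 <- refine_position(pair$plate, pair$bone, init = pert)
  expect_true(pos2$converged)

  # objective is monotonically non-increasing across contact-phase sweeps
  expect_true(all(diff(pos$objective_trace) <= 1e-9))
  expect_true(all(diff(pos2$objective_trace) <= 1e-9))
})

test_that("the collision penalty pushes a buried plate out of the bone", {
  pair <- conforming_pair()
  # drive the plate medially so its undersurface starts buried in the bone
  buried <- compose_transform(rigid_transform(diag(3), c(0, -1.5, 0)),
                              initial_alignment(pair$plate, pair$bone))
  pts <- apply_transform(pair$plate$grid$points, buried)
  expect_gt(sum(point_inside_surface(pts, pair$bone$outer,
                                     check_watertight = FALSE)), 0)
  pos <- refine_position(pair$plate, pair$bone, init = buried)
  expect_equal(pos$penetration_count, 0)
})

test_that("converged constraints re-verify independently of the optimiser", {
  pair <- conforming_pair()
  pos <- refine_position(pair$plate, pair$bone)
  expect_true(pos$converged)
  # re-evaluate every constraint from scratch using only the transform
  zd <- sapply(seq_along(pair$plate$zone_samples), function(k) {
    pts <- apply_transform(pair$plate$zone_samples[[k]], pos$transform)
    min(nearest_vertex_distance(pts, pair$bone$outer)$distance)
  })
  expect_true(all(zd <= 0.2))
  pts <- apply_transform(pair$plate$grid$points, pos$transform)
  expect_equal(sum(point_inside_surface(pts, pair$bone$outer,
                                        check_watertight = FALSE)), 0)
  sc <- check_screws(pair$plate, pair$bone, pos$transform)
  expect_true(sc$fossa_clear && sc$proximal_screw_in_canal)
})

test_that("refinement is equivariant under joint rigid motion", {
  pair <- conforming_pair()
  pos <- refine_position(pair$plate, pair$bone)

  set.seed(9)
  G <- random_rigid()
  plate_g <- transform_plate(pair$plate, G)
  bone_g <- transform_femur(pair$bone, G)
  bone_g$outer <- validate_mesh(bone_g$outer)
  pos_g <- refine_position(plate_g, bone_g)
  expect_true(pos_g$converged)

  # G o T o G^-1 applied to the moved plate must equal the original seat
  anchors <- pair$plate$zone_anchor
  a1 <- apply_transform(apply_transform(anchors, pos$transform), G)
  a2 <- apply_transform(apply_transform(anchors, G), pos_g$transform)
  expect_lt(max(abs(a1 - a2)), 1e-6)
})

test_that("screw checks match construction and a brute-force oracle", {
  pair <- conforming_pair()
  ident <- rigid_transform()
  sc <- check_screws(pair$plate, pair$bone, ident)
  expect_true(sc$proximal_screw_in_canal)  # aimed at the canal centreline
  expect_true(sc$fossa_clear)

  # a screw aimed through the fossa region must trip the clearance check
  bad <- pair$plate
  fossa_mid <- colMeans(pair$bone$landmarks$intercondylar_fossa_region)
  o <- c(fossa_mid[1], 40, fossa_mid[3])
  d <- c(0, -1, 0)
  bad$screws <- rbind(bad$screws,
                      data.frame(ox = o[1], oy = o[2], oz = o[3],
                                 dx = d[1], dy = d[2], dz = d[3],
                                 length = 80, proximal = FALSE))
  expect_false(check_screws(bad, pair$bone, ident)$fossa_clear)

  # fossa distance agrees with a dense brute-force segment scan
  set.seed(12)
  fossa <- pair$bone$landmarks$intercondylar_fossa_region
  seg_dist <- getFromNamespace("segment_points_min_dist", "platefit")
  for (i in 1:8) {
    a <- c(runif(1, -30, 30), runif(1, -40, 40), runif(1, 0, 60))
    b <- a + rnorm(3, sd = 30)
    expect_equal(seg_dist(a, b, fossa),
                 brute_segment_points_dist(a, b, fossa), tolerance = 1e-4)
  }
})
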