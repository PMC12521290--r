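test_that("femur generation is valid, deterministic and parameter-checked", {
  p <- femur_params(r_bow = 900, diaphysis_length = 300)
  b <- make_femur(p, metadata = list(height = 160, sex = "female"), id = "f1")
  expect_true(is_watertight(b$outer))
  expect_true(is_watertight(b$inner))
  expect_equal(b$true_r_bow, 900)

  # inner cortex strictly contained in the outer cortex
  inside <- point_inside_surface(b$inner$vertices, b$outer,
                                 check_watertight = FALSE)
  expect_true(all(inside))

  # landmarks on or near the outer surface
  for (nm in c("lesser_trochanter_base", "lateral_condyle_start",
               "distal_anterior_contact", "distal_posterior_contact")) {
    d <- nearest_vertex_distance(b$landmarks[[nm]], b$outer)$distance
    expect_lt(d, 1.0)
  }
  lt_z <- b$landmarks$lesser_trochanter_base[3]
  ct_z <- b$landmarks$lateral_condyle_start[3]
  expect_gt(lt_z, ct_z)

  b2 <- make_femur(p, metadata = list(height = 160, sex = "female"), id = "f1")
  expect_identical(b$outer$vertices, b2$outer$vertices)
  expect_identical(b$inner$vertices, b2$inner$vertices)

  expect_error(femur_params(resolution = 1.5), "too coarse")
  expect_error(femur_params(r_bow = -5), "positive")
})

test_that("canal centreline arc is recovered from the generated meshes", {
  p <- femur_params(r_bow = 900, diaphysis_length = 300)
  b <- make_femur(p, id = "arc")
  cc <- canal_centroids(b)
  expect_equal(nrow(cc), 20)
  fit <- fit_circle_3d(cc)
  expect_lt(abs(fit$radius - 900) / 900, 0.005)

  # near-straight limit
  bs <- make_femur(femur_params(r_bow = 1e6, diaphysis_length = 300),
                   id = "straight")
  rs <- measure_bone_roc(bs)
  expect_gt(rs$radius, 1e5)
})

test_that("mirrored right femora are the sagittal reflection of left ones", {
  p <- femur_params(side = "right")
  br <- make_femur(p, id = "right")
  bl <- canonical_femur(br)
  expect_equal(bl$params$side, "left")
  pl <- femur_params(side = "left")
  ref <- make_femur(pl, id = "left")
  expect_equal(bl$outer$vertices, ref$outer$vertices)
  # bow measurement is side-agnostic
  expect_equal(measure_bone_roc(br)$radius, measure_bone_roc(ref)$radius,
               tolerance = 1e-9)
})

test_that("plate generation matches its parameters", {
  pl <- make_plate(plate_params(holes = 13))
  r <- measure_plate_roc(pl)
  expect_lt(abs(r$radius - 940) / 940, 0.01)

  # centre curve lies on the undersurface and is finely sampled
  d <- nearest_vertex_distance(pl$centre_curve, pl$mesh)$distance
  expect_lt(max(d), 1e-9)
  gaps <- diff(pl$centre_curve[, 3])
  expect_lt(max(abs(gaps)), 2)

  # anchors lie on the undersurface
  for (a in list(pl$anchors$c1, pl$anchors$c2, pl$anchors$c3)) {
    expect_lt(max(nearest_vertex_distance(a, pl$mesh)$distance), 0.75)
  }

  # screw directions are unit norm, one screw flagged most proximal
  dn <- sqrt(rowSums(as.matrix(pl$screws[, c("dx", "dy", "dz")])^2))
  expect_equal(dn, rep(1, nrow(pl$screws)), tolerance = 1e-12)
  expect_equal(sum(pl$screws$proximal), 1)

  # 9-hole plate is shorter than the 11-hole by exactly two hole pitches
  p9 <- plate_params(holes = 9)
  p11 <- plate_params(holes = 11)
  expect_equal(p11$shaft_length - p9$shaft_length, 2 * p9$pitch)
  expect_error(plate_params(holes = 10), "unsupported")
})

test_that("cohort sampling follows the stratified spec and the height-bow link", {
  co <- sample_cohort(seed = 5, mesh = FALSE)
  md <- co$metadata
  expect_equal(nrow(md), 159)
  expect_equal(sum(md$ethnicity == "caucasian"), 80)
  expect_equal(sum(md$ethnicity == "vietnamese"), 79)
  expect_true(all(md$true_R_bow_mm >= 400 & md$true_R_bow_mm <= 1800))
  expect_true(all(md$age_group == ifelse(md$age < 65, "young", "old")))

  rho <- cor(md$height_cm, md$true_R_bow_mm, method = "spearman")
  expect_gt(rho, 0.30)
  expect_lt(rho, 0.60)

  co2 <- sample_cohort(seed = 5, mesh = FALSE)
  expect_identical(md, co2$metadata)

  # zero-noise single stratum: monotone height-to-bow map
  spec1 <- data.frame(ethnicity = "x", age_group = "young", sex = "female",
                      n = 12L, height_median = 160, height_sd = 5,
                      height_min = 145, height_max = 175, age_min = 20,
                      age_max = 60, roc_intercept = -700, roc_slope = 10,
                      roc_noise_sd = 1e-9)
  c1 <- sample_cohort(spec1, seed = 2, mesh = FALSE)
  expect_equal(cor(c1$metadata$height_cm, c1$metadata$true_R_bow_mm,
                   method = "spearman"), 1.0)
  expect_error(sample_cohort(spec1[0, ], seed = 1), "empty")
})

test_that("femur models survive a disk round trip", {
  b <- make_femur(femur_params(diaphysis_length = 250), id = "io")
  dir <- tempfile()
  paths <- write_femur(b, dir)
  outer <- read_mesh(paths[["outer"]])
  expect_equal(nrow(outer$vertices), nrow(b$outer$vertices))
  lm <- read_landmarks(paths[["landmarks"]])
  expect_equal(lm$lesser_trochanter_base, b$landmarks$lesser_trochanter_base,
               tolerance = 1e-9)
})
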