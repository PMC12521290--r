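test_that("plate length selection respects the lesser-trochanter clearance", {
  # long bone: the 13-hole tip (365.5 mm) sits well clear of the
  # trochanter level
  long <- make_femur(femur_params(r_bow = 1e5, diaphysis_length = 340),
                     id = "long")
  expect_equal(select_plate_length(long), 13L)

  # mid-length bone: 13-hole violates the 20 mm clearance, 11-hole fits
  mid <- make_femur(femur_params(r_bow = 1e5, diaphysis_length = 310),
                    id = "mid")
  expect_equal(select_plate_length(mid), 11L)

  # the clearance bound is inclusive: selecting with the clearance set to
  # the bone's exact margin keeps the long plate; any tighter drops it
  edge <- make_femur(femur_params(r_bow = 1e5, diaphysis_length = 330.5),
                     id = "edge")
  lv <- getFromNamespace("bone_axial_levels", "platefit")(edge)
  margin <- lv$lt - plate_params(holes = 13)$tip_level
  expect_equal(select_plate_length(edge, clearance = margin), 13L)
  expect_equal(select_plate_length(edge, clearance = margin + 1e-6), 11L)

  short <- make_femur(femur_params(r_bow = 1e5, diaphysis_length = 160),
                      id = "short")
  expect_error(select_plate_length(short), "too short")
})

test_that("measurement layouts carry the documented point counts", {
  for (h in c(9, 11, 13)) {
    lay <- build_layout(make_plate(plate_params(holes = h)))
    expect_equal(nrow(lay$c1), 1)
    expect_equal(nrow(lay$c2), 9)
    expect_equal(nrow(lay$c3), c(`9` = 16, `11` = 19, `13` = 22)[[as.character(h)]])
    expect_equal(nrow(lay$points), 1 + 9 + nrow(lay$c3))
  }
  # layout counts do not depend on the plate bow
  lay_b <- build_layout(make_plate(plate_params(holes = 11, bow_radius = 1400)))
  expect_equal(nrow(lay_b$c3), 19)
})

test_that("criterion semantics follow inclusive conjunction thresholds", {
  thr <- fit_thresholds()
  # all zero distances: full fit
  r <- evaluate_fit_criteria(0, rep(0, 9), rep(0, 16), thr)
  expect_true(all(r$pass))
  expect_true(attr(r, "overall_fit"))

  # boundary equality is inclusive
  r <- evaluate_fit_criteria(1.0, rep(2.0, 9), rep(3.0, 16), thr)
  expect_true(all(r$pass))

  # one metaphyseal point over threshold fails criterion 2 and overall fit
  d2 <- rep(0, 9); d2[5] <- 2.5
  r <- evaluate_fit_criteria(0, d2, rep(0, 16), thr)
  expect_false(r$pass[r$criterion == "c2"])
  expect_true(r$pass[r$criterion == "c1"])
  expect_false(attr(r, "overall_fit"))

  # a proximal tip distance like the misfit magnitudes seen clinically
  # fails criterion 3 outright
  d3 <- rep(0.5, 16); d3[16] <- 11.6
  r <- evaluate_fit_criteria(0, rep(0, 9), d3, thr)
  expect_false(r$pass[r$criterion == "c3"])

  # raising a threshold never turns a pass into a fail
  set.seed(21)
  for (i in 1:25) {
    d1 <- runif(1, 0, 2); d2 <- runif(9, 0, 4); d3 <- runif(16, 0, 6)
    base <- evaluate_fit_criteria(d1, d2, d3, thr)
    up <- evaluate_fit_criteria(d1, d2, d3, fit_thresholds(2, 3, 5))
    expect_true(all(up$pass >= base$pass))
  }
})

test_that("fit measurement reports distances and self-consistent verdicts", {
  pair <- conforming_pair()
  pos <- refine_position(pair$plate, pair$bone)
  rep <- measure_fit(pair$plate, pair$bone, pos)
  expect_s3_class(rep, "fit_report")
  # a conforming plate on its own template fits everywhere
  expect_true(rep$overall_fit)
  expect_lt(rep$proximal_tip_distance, 0.3)

  # verdict equals the conjunction recomputed from the raw distances
  d <- rep$distances
  recompute <- all(d$distance[d$criterion == "c1"] <= 1) &&
    all(d$distance[d$criterion == "c2"] <= 2) &&
    all(d$distance[d$criterion == "c3"] <= 3)
  expect_equal(rep$overall_fit, recompute)

  # unconverged positioning is rejected
  bad <- pos
  bad$converged <- FALSE
  expect_error(measure_fit(pair$plate, pair$bone, bad), "converge")

  # JSON serialisation round trip
  path <- tempfile(fileext = ".json")
  write_fit_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall_fit, rep$overall_fit)
  expect_equal(nrow(back$distances), nrow(rep$distances))
})

test_that("cohort runs are deterministic and report exclusions", {
  p <- femur_params(r_bow = 940, diaphysis_length = 310)
  bones <- list(make_femur(p, id = "a"), make_femur(p, id = "b"))
  res <- cohort_fit_run(bones, plate_base = plate_params(template = p))
  expect_equal(nrow(res$summary), 2)
  expect_equal(res$summary$holes, c(11L, 11L))
  # identical bones give identical reports
  expect_equal(res$reports[["a"]]$distances$distance,
               res$reports[["b"]]$distances$distance, tolerance = 1e-12)
  expect_true(all(res$summary$proximal_tip_mm >= 0))

  # a bone too short for any plate is excluded with a reason
  short <- make_femur(femur_params(r_bow = 1e5, diaphysis_length = 160),
                      id = "tiny")
  res2 <- cohort_fit_run(list(short))
  expect_null(res2$summary)
  expect_equal(res2$excluded$id, "tiny")
  expect_match(res2$excluded$reason, "too short")
  expect_error(cohort_fit_run(list()), "empty")
})
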