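#' Fit criteria configuration
#'
#' The three clinical distance criteria: <= 1 mm at the most anterior
#' distal location, <= 2 mm at the nine metaphyseal points (including the
#' distal tip), and <= 3 mm at the shaft points in rows spaced about 4 cm
#' apart (including the proximal tip). Overall anatomical fit requires all
#' three. Thresholds are inclusive and overridable.
#'
#' @param c1,c2,c3 distance thresholds in mm.
#' @return named numeric vector of thresholds.
#' @export
fit_thresholds <- function(c1 = 1, c2 = 2, c3 = 3) {
  c(c1 = c1, c2 = c2, c3 = c3)
}

# Axial extent of the bone above its distal end, and the lesser-trochanter
# level, both measured along the landmark-derived shaft axis.
bone_axial_levels <- function(bone) {
  fr <- bone_frame(bone)
  uz <- fr$axes[, 3]
  tv <- as.vector(bone$outer$vertices %*% uz)
  t0 <- min(tv)
  list(distal = 0,
       lt = sum(bone$landmarks$lesser_trochanter_base * uz) - t0,
       top = max(tv) - t0)
}

#' Select the plate length for a bone
#'
#' Chooses the longest available plate whose proximal tip, with the plate
#' seated distally flush, stays at least `clearance` (default 20 mm) distal
#' to the base of the lesser trochanter. The bound is inclusive.
#'
#' @param bone a `femur_model`.
#' @param available candidate hole counts.
#' @param params a [plate_params()] supplying plate dimensions (tip level
#'   per hole count).
#' @param clearance minimum tip to lesser-trochanter distance, mm.
#' @return selected hole count (integer).
#' @export
select_plate_length <- function(bone, available = c(9, 11, 13),
                                params = plate_params(), clearance = 20) {
  lv <- bone_axial_levels(bone)
  for (h in sort(available, decreasing = TRUE)) {
    ph <- plate_params_with_holes(params, h)
    if (lv$lt - ph$tip_level >= clearance - 1e-9) return(as.integer(h))
  }
  stop("bone too short: even the shortest plate violates the ",
       clearance, " mm lesser-trochanter clearance")
}

#' Build the measurement-point layout of a plate
#'
#' One most-anterior distal point (criterion 1), nine metaphyseal points in
#' three anterior/centre/posterior rows with the distal tip as the first
#' row's centre (criterion 2), and shaft rows at 40 mm spacing plus the
#' proximal tip (criterion 3). Criterion 3 carries `3 * rows + 1` points
#' with 5/6/7 rows for 9/11/13-hole plates, i.e. 16/19/22 points.
#'
#' @param plate a `plate_model`.
#' @return object of class `measurement_layout`: list with point matrices
#'   `c1`, `c2`, `c3` and a long annotation data frame `points`.
#' @export
build_layout <- function(plate) {
  a <- plate$anchors
  if (nrow(a$c2) != 9)
    stop("anchor mismatch: criterion 2 must have 9 points")
  expected_rows <- 5L + (plate$holes - 9L) / 2L
  if (nrow(a$c3) != 3 * expected_rows + 1)
    stop("anchor mismatch: criterion 3 must have ", 3 * expected_rows + 1,
         " points for a ", plate$holes, "-hole plate")
  pts <- data.frame(
    point_id = c("c1_anterior",
                 sprintf("c2_r%d_%s", a$c2_info$row, a$c2_info$position),
                 sprintf("c3_r%d_%s", a$c3_info$row, a$c3_info$position)),
    criterion = c("c1", rep("c2", nrow(a$c2)), rep("c3", nrow(a$c3))),
    stringsAsFactors = FALSE)
  structure(list(c1 = a$c1, c2 = a$c2, c3 = a$c3, points = pts),
            class = "measurement_layout")
}

#' @export
print.measurement_layout <- function(x, ...) {
  cat(sprintf("measurement_layout: c1 = %d, c2 = %d, c3 = %d points\n",
              nrow(x$c1), nrow(x$c2), nrow(x$c3)))
  invisible(x)
}

#' Evaluate the three fit criteria on measured distances
#'
#' Pure criterion semantics: a criterion passes when every one of its
#' distances is within the (inclusive) threshold; overall fit is the
#' conjunction of the three.
#'
#' @param d1,d2,d3 numeric distance vectors (mm) for criteria 1-3.
#' @param thresholds from [fit_thresholds()].
#' @return data frame with one row per criterion (`n_points`, `max`,
#'   `mean`, `pass`) and attribute `overall_fit`.
#' @export
evaluate_fit_criteria <- function(d1, d2, d3, thresholds = fit_thresholds()) {
  ds <- list(c1 = d1, c2 = d2, c3 = d3)
  res <- data.frame(
    criterion = names(ds),
    n_points = vapply(ds, length, integer(1)),
    max = vapply(ds, max, numeric(1)),
    mean = vapply(ds, mean, numeric(1)),
    pass = vapply(names(ds), function(k) all(ds[[k]] <= thresholds[[k]]),
                  logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "overall_fit") <- all(res$pass)
  res
}

#' Measure plate-bone distances and evaluate fit
#'
#' Applies the converged positioning transform to every layout point and
#' measures the shortest Euclidean distance to the bone outer-cortex
#' vertices, then evaluates the three criteria.
#'
#' @param plate a `plate_model`.
#' @param bone a `femur_model`.
#' @param positioning a converged `positioning_result`.
#' @param layout a `measurement_layout`; default [build_layout()] of the
#'   plate.
#' @param thresholds from [fit_thresholds()].
#' @return object of class `fit_report`: `distances` (long data frame),
#'   `criteria` (per-criterion summary), `overall_fit`, `holes`,
#'   `proximal_tip_distance`, `distal_tip_distance`.
#' @export
measure_fit <- function(plate, bone, positioning,
                        layout = build_layout(plate),
                        thresholds = fit_thresholds()) {
  if (!inherits(positioning, "positioning_result"))
    stop("positioning must be a positioning_result")
  if (!positioning$converged)
    stop("positioning did not converge; plate-bone distances are undefined")
  P <- rbind(layout$c1, layout$c2, layout$c3)
  pts <- apply_transform(P, positioning$transform)
  d <- nearest_vertex_distance(pts, bone$outer)$distance
  dist_df <- cbind(layout$points, distance = d)
  n1 <- nrow(layout$c1); n2 <- nrow(layout$c2)
  d1 <- d[seq_len(n1)]
  d2 <- d[n1 + seq_len(n2)]
  d3 <- d[(n1 + n2 + 1):length(d)]
  crit <- evaluate_fit_criteria(d1, d2, d3, thresholds)
  structure(list(
    distances = dist_df, criteria = crit,
    overall_fit = attr(crit, "overall_fit"),
    holes = plate$holes,
    proximal_tip_distance = d[match(
      sprintf("c3_r%d_proximal_tip", max(plate$anchors$c3_info$row)),
      dist_df$point_id)],
    distal_tip_distance = d[match("c2_r1_centre", dist_df$point_id)]),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report (%d-hole plate): overall fit %s\n", x$holes,
              if (x$overall_fit) "ACHIEVED" else "not achieved"))
  print(x$criteria)
  cat(sprintf("  distal tip %.2f mm, proximal tip %.2f mm\n",
              x$distal_tip_distance, x$proximal_tip_distance))
  invisible(x)
}

#' Serialise a fit report to JSON
#'
#' @param report a `fit_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(list(
    holes = report$holes,
    overall_fit = report$overall_fit,
    criteria = report$criteria,
    distances = report$distances,
    proximal_tip_distance = report$proximal_tip_distance,
    distal_tip_distance = report$distal_tip_distance),
    path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

#' Run the fit protocol over a cohort
#'
#' For each bone: select the plate length, position the plate, measure the
#' layout distances and evaluate the criteria. Bones whose positioning does
#' not converge (or that are too short for the shortest plate) are excluded
#' with a recorded reason.
#'
#' @param cohort output of [sample_cohort()] (with meshes), or a list of
#'   `femur_model`s.
#' @param plate_base a [plate_params()] defining the plate family.
#' @param config a [position_config()].
#' @param thresholds from [fit_thresholds()].
#' @param available candidate hole counts (default 9/11/13).
#' @param verbose print one line per bone.
#' @return list with `summary` (per-bone data frame), `points` (long
#'   per-point distances), `excluded` (data frame of failures) and
#'   `reports` (list of `fit_report`s).
#' @export
cohort_fit_run <- function(cohort, plate_base = plate_params(),
                           config = position_config(),
                           thresholds = fit_thresholds(),
                           available = c(9, 11, 13), verbose = FALSE) {
  femora <- if (inherits(cohort, "synthetic_cohort")) cohort$femora else cohort
  if (length(femora) == 0) stop("empty cohort")
  plates <- list()
  summary_rows <- list()
  point_rows <- list()
  reports <- list()
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (bone in femora) {
    bone <- canonical_femur(bone)
    holes <- tryCatch(select_plate_length(bone, available, plate_base),
                      error = function(e) e)
    if (inherits(holes, "error")) {
      excluded <- rbind(excluded, data.frame(id = bone$id,
                                             reason = conditionMessage(holes)))
      next
    }
    key <- as.character(holes)
    if (is.null(plates[[key]]))
      plates[[key]] <- make_plate(plate_params_with_holes(plate_base, holes))
    plate <- plates[[key]]
    pos <- refine_position(plate, bone, config = config)
    if (!pos$converged) {
      excluded <- rbind(excluded,
                        data.frame(id = bone$id,
                                   reason = "positioning did not converge"))
      if (verbose) message(bone$id, ": positioning failed")
      next
    }
    rep <- measure_fit(plate, bone, pos, thresholds = thresholds)
    reports[[bone$id]] <- rep
    cr <- rep$criteria
    summary_rows[[bone$id]] <- data.frame(
      id = bone$id, holes = holes,
      ethnicity = bone$metadata$ethnicity, sex = bone$metadata$sex,
      age = bone$metadata$age, height_cm = bone$metadata$height,
      true_r_bow_mm = bone$true_r_bow,
      c1_mean = cr$mean[1], c2_mean = cr$mean[2], c3_mean = cr$mean[3],
      c1_max = cr$max[1], c2_max = cr$max[2], c3_max = cr$max[3],
      c1_pass = cr$pass[1], c2_pass = cr$pass[2], c3_pass = cr$pass[3],
      overall_fit = rep$overall_fit,
      proximal_tip_mm = rep$proximal_tip_distance,
      distal_tip_mm = rep$distal_tip_distance,
      stringsAsFactors = FALSE)
    point_rows[[bone$id]] <- cbind(id = bone$id, rep$distances,
                                   stringsAsFactors = FALSE)
    if (verbose) message(bone$id, ": ", holes, "-hole, proximal tip ",
                         sprintf("%.1f", rep$proximal_tip_distance), " mm")
  }
  bind_rows0 <- function(rows) {
    if (length(rows) == 0) return(NULL)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  list(summary = bind_rows0(summary_rows),
       points = bind_rows0(point_rows),
       excluded = excluded, reports = reports)
}
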