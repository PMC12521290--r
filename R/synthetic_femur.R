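#' Parameters of a synthetic femur
#'
#' Defines an idealised parametric femur: an arc-centreline cortical tube
#' (controllable anterior-bow radius) carrying a stylised distal condylar
#' block with lateral flare, a flattened lateral facet inclined medially,
#' and an intercondylar notch. The model is deliberately schematic — the
#' fit protocol needs controllable bow, landmarks and a condylar contact
#' geometry, not statistical shape realism.
#'
#' The canonical frame is a left femur: `z` runs along the shaft (0 at the
#' distal end, increasing proximally), `x` points anteriorly and `y`
#' laterally. The canal centreline is straight below the distal diaphysis
#' level and follows a circular arc of radius `r_bow` (tangent-continuous)
#' above it, so the condylar geometry is identical across bows.
#'
#' @param r_bow anterior-bow radius of curvature of the canal centreline, mm.
#' @param diaphysis_length proximal-to-distal extent of the diaphysis, mm.
#' @param canal_radius intramedullary canal radius, mm.
#' @param cortex_thickness cortical wall thickness, mm.
#' @param condyle_ap,condyle_ml condylar semi-axes (anterior-posterior and
#'   medio-lateral), mm.
#' @param condyle_height axial extent of the condylar block, mm; its top is
#'   the `lateral_condyle_start` landmark level.
#' @param metaphysis_top axial level where the metaphyseal taper reaches
#'   shaft diameter, mm.
#' @param medial_angulation_deg inclination of the flat lateral condyle
#'   facet relative to the shaft axis, degrees.
#' @param notch_depth relative radial depth of the intercondylar notch.
#' @param side `"left"` or `"right"` (right femora are mirrored copies).
#' @param resolution target mesh edge length, mm; must be <= 1 so that
#'   vertex-distance granularity is far below the 0.2-3 mm fit thresholds.
#' @param seed integer seed carried by the parameter set.
#' @return object of class `femur_params`.
#' @export
femur_params <- function(r_bow = 897, diaphysis_length = 340,
                         canal_radius = 7, cortex_thickness = 6,
                         condyle_ap = 26, condyle_ml = 34,
                         condyle_height = 45, metaphysis_top = 90,
                         medial_angulation_deg = 10, notch_depth = 0.25,
                         side = c("left", "right"), resolution = 1.0,
                         seed = 1L) {
  side <- match.arg(side)
  if (r_bow <= 0) stop("r_bow must be positive")
  if (diaphysis_length <= 0) stop("diaphysis_length must be positive")
  if (resolution > 1.0)
    stop("resolution too coarse: target edge length must be <= 1 mm")
  p <- list(r_bow = r_bow, diaphysis_length = diaphysis_length,
            canal_radius = canal_radius, cortex_thickness = cortex_thickness,
            condyle_ap = condyle_ap, condyle_ml = condyle_ml,
            condyle_height = condyle_height, metaphysis_top = metaphysis_top,
            medial_angulation_deg = medial_angulation_deg,
            notch_depth = notch_depth, side = side,
            resolution = resolution, seed = as.integer(seed))
  p$roc_distal_level <- condyle_height + 10
  p$lt_level <- p$roc_distal_level + diaphysis_length
  p$z_top <- p$lt_level + 35
  if (r_bow <= (p$z_top - p$roc_distal_level))
    stop("r_bow too small for bone length: arc does not span the shaft")
  class(p) <- "femur_params"
  p
}

#' @export
print.femur_params <- function(x, ...) {
  cat(sprintf("femur_params: bow %.0f mm, diaphysis %.0f mm, %s side\n",
              x$r_bow, x$diaphysis_length, x$side))
  invisible(x)
}

# Canal centreline anterior offset at axial level z: straight (0) below the
# distal diaphysis level, circular arc of radius r_bow above it.
femur_centreline_x <- function(params, z) {
  dz <- pmax(z - params$roc_distal_level, 0)
  params$r_bow - sqrt(params$r_bow^2 - dz^2)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Per-level cross-section geometry: centre offset, semi-axes, facet limit.
femur_section_geom <- function(params, z) {
  a_shaft <- params$canal_radius + params$cortex_thickness
  s <- smoothstep((z - params$condyle_height) /
                  (params$metaphysis_top - params$condyle_height))
  a <- params$condyle_ap + (a_shaft - params$condyle_ap) * s
  b <- params$condyle_ml + (a_shaft - params$condyle_ml) * s
  # distal rounding of the condylar block over the lowest 8 mm
  round_scale <- ifelse(z < 8, sqrt(pmax(1 - ((8 - z) / 8)^2, 0.05)), 1)
  # flat lateral facet, inclined medially over the condylar block
  tan_a <- tan(params$medial_angulation_deg * pi / 180)
  y_max <- ifelse(z < params$condyle_height,
                  params$condyle_ml - tan_a * (params$condyle_height - z), Inf)
  list(xc = femur_centreline_x(params, z), a = a * round_scale,
       b = b * round_scale, y_max = y_max,
       notch_ramp = pmax(0, 1 - z / 20))
}

# Outer-surface point(s) at paired (z, theta); theta measured from anterior
# (+x) towards lateral (+y).
femur_surface_points <- function(params, z, theta) {
  g <- femur_section_geom(params, z)
  notch <- 1 - params$notch_depth * exp(-((theta - pi) / 0.35)^2 / 2) * g$notch_ramp
  x <- g$xc + g$a * notch * cos(theta)
  y <- pmin(g$b * notch * sin(theta), g$y_max)
  cbind(x, y, z)
}

# Axial mesh lattice: fixed origin and spacing so that femora of different
# lengths (and the plate template) share vertex stations over their common
# span, which keeps conforming plate-to-bone vertex distances near zero.
femur_lattice_z <- function(params) {
  seq(0.5, params$z_top - 0.5 - 1e-9, by = params$resolution)
}

femur_lattice_theta <- function(params, n = NULL) {
  if (is.null(n)) {
    # Ramanujan perimeter of the condylar ellipse fixes the angular count;
    # a multiple of 12 keeps 30-degree multiples on the lattice
    a <- params$condyle_ap; b <- params$condyle_ml
    per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    n <- 12 * ceiling(per / (12 * params$resolution))
  }
  (0:(n - 1)) * 2 * pi / n
}

snap_to <- function(x, grid) grid[which.min(abs(grid - x))]

# Closed tube-with-caps triangulation of a ring lattice (nr rings of nt
# vertices, row-major), with apex points closing both ends.
tube_faces <- function(nr, nt) {
  i <- rep(1:(nr - 1), each = nt)
  j <- rep(1:nt, nr - 1)
  jn <- ifelse(j == nt, 1L, j + 1L)
  idx <- function(i, j) (i - 1L) * nt + j
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
  f2 <- cbind(idx(i, j), idx(i + 1L, jn), idx(i, jn))
  apex_b <- nr * nt + 1L
  apex_t <- nr * nt + 2L
  j1 <- 1:nt
  jn1 <- c(2:nt, 1L)
  cap_b <- cbind(rep(apex_b, nt), idx(1L, j1), idx(1L, jn1))
  cap_t <- cbind(rep(apex_t, nt), idx(nr, jn1), idx(nr, j1))
  rbind(f1, f2, cap_b, cap_t)
}

build_capped_tube <- function(points, nr, nt, apex_bottom, apex_top, name) {
  verts <- rbind(points, apex_bottom, apex_top)
  mark_watertight(triangle_mesh(verts, tube_faces(nr, nt), name = name))
}

#' Generate a synthetic femur model
#'
#' Builds watertight outer and inner cortex meshes from [femur_params()],
#' computes all landmarks analytically from the construction, and attaches
#' subject metadata and the ground-truth bow radius.
#'
#' @param params a [femur_params()].
#' @param metadata list with `age` (years), `sex`, `height` (cm),
#'   `ethnicity`; missing entries default to `NA`.
#' @param id subject identifier.
#' @return object of class `femur_model` with elements `outer`, `inner`
#'   ([triangle_mesh()]), `landmarks` (named list), `metadata`,
#'   `true_r_bow` and `params`.
#' @export
make_femur <- function(params = femur_params(), metadata = list(), id = "bone") {
  stopifnot(inherits(params, "femur_params"))
  zs <- femur_lattice_z(params)
  th <- femur_lattice_theta(params)
  nt <- length(th); nr <- length(zs)

  zz <- rep(zs, each = nt)
  tt <- rep(th, nr)
  outer_pts <- femur_surface_points(params, zz, tt)
  outer <- build_capped_tube(outer_pts, nr, nt,
                             apex_bottom = c(0, 0, 0),
                             apex_top = c(femur_centreline_x(params, params$z_top),
                                          0, params$z_top),
                             name = paste0(id, "_outer"))

  zi <- zs[zs >= 15.4 & zs <= params$z_top - 10]
  thi <- femur_lattice_theta(params,
          n = max(12, 12 * ceiling(2 * pi * params$canal_radius /
                                   (12 * params$resolution))))
  nti <- length(thi); nri <- length(zi)
  zzi <- rep(zi, each = nti)
  tti <- rep(thi, nri)
  xci <- femur_centreline_x(params, zzi)
  inner_pts <- cbind(xci + params$canal_radius * cos(tti),
                     params$canal_radius * sin(tti), zzi)
  inner <- build_capped_tube(inner_pts, nri, nti,
                             apex_bottom = c(femur_centreline_x(params, zi[1] - 1),
                                             0, zi[1] - 1),
                             apex_top = c(femur_centreline_x(params, zi[nri] + 1),
                                          0, zi[nri] + 1),
                             name = paste0(id, "_inner"))

  deg <- pi / 180
  lm_z <- function(z) snap_to(z, zs)
  fossa_th <- seq(168, 192, by = 4) * deg
  fossa_z <- c(3.5, 6.5, 9.5, 12.5)
  fg <- expand.grid(th = fossa_th, z = fossa_z)
  # lateral crown polyline at a fixed 1 mm spacing starting at z = 0.5:
  # carried as a landmark so downstream positioning can locate lateral
  # shaft targets by arc index on any (rigidly moved) copy of the bone
  ridge_z <- seq(0.5, params$z_top - 0.6, by = 1)
  landmarks <- list(
    lesser_trochanter_base =
      as.numeric(femur_surface_points(params, lm_z(params$lt_level), 230 * deg)),
    lateral_condyle_start =
      as.numeric(femur_surface_points(params, lm_z(params$condyle_height), 90 * deg)),
    distal_anterior_contact =
      as.numeric(femur_surface_points(params, lm_z(15.5), 60 * deg)),
    distal_posterior_contact =
      as.numeric(femur_surface_points(params, lm_z(15.5), 120 * deg)),
    intercondylar_fossa_region =
      unname(femur_surface_points(params, fg$z, fg$th)),
    lateral_shaft_ridge =
      unname(femur_surface_points(params, ridge_z, rep(pi / 2, length(ridge_z))))
  )

  md <- list(age = metadata$age %||% NA_real_,
             sex = metadata$sex %||% NA_character_,
             height = metadata$height %||% NA_real_,
             ethnicity = metadata$ethnicity %||% NA_character_)

  bone <- structure(list(id = id, outer = outer, inner = inner,
                         landmarks = landmarks, metadata = md,
                         true_r_bow = params$r_bow, params = params),
                    class = "femur_model")
  if (params$side == "right") {
    bone <- mirror_femur(bone)
    bone$params$side <- "right"  # the generated model IS a right femur
  }
  bone
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mirror_mesh_y <- function(mesh) {
  mesh$vertices[, 2] <- -mesh$vertices[, 2]
  mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# Mirror across the sagittal plane (y -> -y); used both to realise right
# femora and to map them back to the canonical left side before fitting.
mirror_femur <- function(bone) {
  bone$outer <- mirror_mesh_y(bone$outer)
  bone$inner <- mirror_mesh_y(bone$inner)
  bone$landmarks <- lapply(bone$landmarks, function(p) {
    if (is.matrix(p)) p[, 2] <- -p[, 2] else p[2] <- -p[2]
    p
  })
  bone$params$side <- if (bone$params$side == "left") "right" else "left"
  bone
}

#' Map a femur model to the canonical (left) side
#'
#' All positioning and measurement is side-agnostic after mirroring right
#' femora across the sagittal plane.
#'
#' @param bone a `femur_model`.
#' @return the bone, mirrored to the left side if needed.
#' @export
canonical_femur <- function(bone) {
  if (!is.null(bone$params) && identical(bone$params$side, "right"))
    mirror_femur(bone)
  else bone
}

#' @export
print.femur_model <- function(x, ...) {
  cat(sprintf("femur_model '%s': bow %.0f mm, %s side, outer %d verts, inner %d verts\n",
              x$id, x$true_r_bow, x$params$side,
              nrow(x$outer$vertices), nrow(x$inner$vertices)))
  invisible(x)
}

#' Write a femur model to disk
#'
#' Outer and inner cortex meshes as PLY (or STL), landmarks as a JSON
#' sidecar.
#'
#' @param bone a `femur_model`.
#' @param dir output directory.
#' @param format `"ply"` (default) or `"stl"`.
#' @return invisibly, the paths written.
#' @export
write_femur <- function(bone, dir, format = c("ply", "stl")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    outer = file.path(dir, paste0(bone$id, "_outer.", format)),
    inner = file.path(dir, paste0(bone$id, "_inner.", format)),
    landmarks = file.path(dir, paste0(bone$id, "_landmarks.json")))
  write_mesh(bone$outer, paths[["outer"]], format = format)
  write_mesh(bone$inner, paths[["inner"]], format = format)
  write_landmarks(bone$landmarks, paths[["landmarks"]])
  invisible(paths)
}
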