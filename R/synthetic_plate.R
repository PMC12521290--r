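#' Parameters of a synthetic pre-contoured distal femur plate
#'
#' The plate undersurface is modelled as a structured point grid over a
#' lateral band of a template femur: the head portion conforms to the
#' synthetic condylar/metaphyseal template and the shaft portion follows a
#' sagittal arc of the configured bow radius. The default bow radius is
#' 940 mm, the shaft radius of curvature of the plate the protocol targets.
#' Plate dimensions (hole pitch, shaft length) are configuration: the pitch
#' default is chosen so the shaft measurement rows at 40 mm spacing number
#' 5/6/7 for 9/11/13-hole plates.
#'
#' @param holes number of shaft holes: 9, 11 or 13.
#' @param pitch shaft hole pitch, mm (each longer plate adds two holes,
#'   i.e. `2 * pitch` of shaft length).
#' @param bow_radius sagittal bow radius of the plate shaft midline, mm.
#' @param band_deg angular extent of the undersurface over the plate head,
#'   degrees from anterior; default 60-120 (the head covers the lateral
#'   condyle).
#' @param shaft_band_deg angular extent of the undersurface over the
#'   shaft, degrees; the shaft of the plate is a narrow strip (about
#'   11 mm at the default shaft radius), so its default is 78-102.
#' @param distal_start axial level of the distal plate tip, mm.
#' @param shaft_start axial level of the head-to-shaft transition, mm.
#' @param template a [femur_params()] supplying the cross-section template
#'   the head conforms to; its bow radius is replaced by `bow_radius`.
#' @param seed integer seed carried by the parameter set.
#' @return object of class `plate_params`.
#' @export
plate_params <- function(holes = 13, pitch = 20, bow_radius = 940,
                         band_deg = c(60, 120), shaft_band_deg = c(78, 102),
                         distal_start = 8.5, shaft_start = 95.5,
                         template = femur_params(), seed = 1L) {
  if (!holes %in% c(9, 11, 13))
    stop("unsupported hole count: ", holes, " (must be 9, 11 or 13)")
  stopifnot(inherits(template, "femur_params"))
  p <- list(holes = as.integer(holes), pitch = pitch, bow_radius = bow_radius,
            band_deg = band_deg, shaft_band_deg = shaft_band_deg,
            distal_start = distal_start,
            shaft_start = shaft_start, template = template,
            seed = as.integer(seed))
  # 9-hole shaft carries five 40 mm measurement rows; each step of two
  # holes adds 2 * pitch = 40 mm and one row
  p$shaft_length <- 190 + (p$holes - 9L) / 2L * 2 * pitch
  p$tip_level <- shaft_start + p$shaft_length
  class(p) <- "plate_params"
  p
}

#' @export
print.plate_params <- function(x, ...) {
  cat(sprintf("plate_params: %d-hole, bow %.0f mm, tip at %.1f mm\n",
              x$holes, x$bow_radius, x$tip_level))
  invisible(x)
}

# Template femur with the plate's bow substituted: the undersurface is this
# surface restricted to the lateral band.
plate_template_params <- function(params) {
  t <- params$template
  t$r_bow <- params$bow_radius
  if (t$r_bow <= (t$z_top - t$roc_distal_level))
    stop("plate bow_radius too small for template length")
  t
}

#' Generate a synthetic plate undersurface model
#'
#' Builds the undersurface point grid, the shaft centre curve (sampled at
#' the template lattice spacing, well under 2 mm), the measurement anchors
#' for the three fit criteria, the contact-zone anchors used in
#' positioning, and the screw trajectories (head screws running medially
#' across the condyle and the most proximal screw aimed at the canal
#' centreline).
#'
#' @param params a [plate_params()].
#' @return object of class `plate_model`: list with `grid` (structured
#'   samples), `mesh` (open strip [triangle_mesh()]), `centre_curve`,
#'   `anchors`, `zones`, `screws`, `holes`, `params`.
#' @export
make_plate <- function(params = plate_params()) {
  stopifnot(inherits(params, "plate_params"))
  tp <- plate_template_params(params)
  deg <- pi / 180
  zs_all <- femur_lattice_z(tp)
  zs <- zs_all[zs_all >= params$distal_start - 1e-9 &
               zs_all <= params$tip_level + 1e-9]
  th_all <- femur_lattice_theta(tp)
  th <- th_all[th_all >= params$band_deg[1] * deg - 1e-9 &
               th_all <= params$band_deg[2] * deg + 1e-9]
  nt <- length(th); nr <- length(zs)

  # the plate head (over condyle and metaphysis) is wide; the shaft is a
  # narrow strip; the width tapers linearly across the head-shaft
  # transition
  band_limits <- function(z) {
    f <- pmin(pmax((z - tp$metaphysis_top) /
                   (params$shaft_start - tp$metaphysis_top), 0), 1)
    cbind(lo = (params$band_deg[1] + f * (params$shaft_band_deg[1] -
                                          params$band_deg[1])) * deg,
          hi = (params$band_deg[2] + f * (params$shaft_band_deg[2] -
                                          params$band_deg[2])) * deg)
  }

  zz_all <- rep(zs, each = nt)
  tt_all <- rep(th, nr)
  bl <- band_limits(zz_all)
  dth1 <- th[2] - th[1]
  in_band <- tt_all >= bl[, "lo"] - dth1 / 2 & tt_all <= bl[, "hi"] + dth1 / 2
  pts_all <- femur_surface_points(tp, zz_all, tt_all)
  pts <- pts_all[in_band, , drop = FALSE]

  # open strip mesh for I/O and inspection (quads with all corners in band)
  i <- rep(1:(nr - 1), each = nt - 1)
  j <- rep(1:(nt - 1), nr - 1)
  idx <- function(i, j) (i - 1L) * nt + j
  quads <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  keep_q <- in_band[quads[, 1]] & in_band[quads[, 2]] &
    in_band[quads[, 3]] & in_band[quads[, 4]]
  quads <- quads[keep_q, , drop = FALSE]
  remap <- integer(nr * nt)
  remap[in_band] <- seq_len(sum(in_band))
  faces <- rbind(cbind(remap[quads[, 1]], remap[quads[, 2]], remap[quads[, 3]]),
                 cbind(remap[quads[, 1]], remap[quads[, 3]], remap[quads[, 4]]))
  mesh <- triangle_mesh(pts, faces, name = sprintf("plate_%dhole", params$holes))

  surf <- function(z, theta) femur_surface_points(tp, z, theta)
  snapz <- function(z) snap_to(z, zs)
  th90 <- th[which.min(abs(th - 90 * deg))]
  th60 <- th[which.min(abs(th - params$band_deg[1] * deg))]
  th120 <- th[which.min(abs(th - params$band_deg[2] * deg))]
  th_s_ant <- th[which.min(abs(th - params$shaft_band_deg[1] * deg))]
  th_s_post <- th[which.min(abs(th - params$shaft_band_deg[2] * deg))]

  cc_z <- zs
  centre_curve <- surf(cc_z, rep(th90, nr))
  shaft_mask <- cc_z >= params$shaft_start - 1e-9

  # measurement anchors ----------------------------------------------------
  c1 <- surf(snapz(15.5), th60)
  c2_rows <- vapply(c(params$distal_start, 49.5, 89.5), snapz, numeric(1))
  c2_grid <- expand.grid(th = c(th60, th90, th120), z = c2_rows)
  c2 <- surf(c2_grid$z, c2_grid$th)
  n_rows <- 5L + (params$holes - 9L) / 2L
  c3_rowz <- vapply(params$shaft_start + 40 * (0:(n_rows - 1)), snapz, numeric(1))
  c3_grid <- expand.grid(th = c(th_s_ant, th90, th_s_post), z = c3_rowz)
  c3 <- rbind(surf(c3_grid$z, c3_grid$th), surf(snapz(params$tip_level), th90))
  anchors <- list(
    c1 = c1, c2 = c2, c3 = c3,
    c2_info = data.frame(row = rep(seq_along(c2_rows), each = 3),
                         position = rep(c("anterior", "centre", "posterior"), 3)),
    c3_info = rbind(data.frame(row = rep(seq_along(c3_rowz), each = 3),
                               position = rep(c("anterior", "centre", "posterior"),
                                              n_rows)),
                    data.frame(row = n_rows + 1L, position = "proximal_tip")))

  # contact-zone anchors (distal anterior, distal posterior, shaft at 60%
  # of the shaft span) and their sample patches
  zone_anchor <- rbind(
    distal_anterior = as.numeric(surf(snapz(15.5), th60)),
    distal_posterior = as.numeric(surf(snapz(15.5), th120)),
    shaft = as.numeric(surf(snapz(params$shaft_start + 0.6 * params$shaft_length),
                            th90)))
  zone_radius <- 5
  # dense undersurface patches around the zone anchors (4x the lattice
  # density, lattice nodes included): the zone distance is a minimum over
  # these samples, so its granularity must sit well below the 0.2 mm
  # contact threshold
  zone_param <- rbind(distal_anterior = c(snapz(15.5), th60),
                      distal_posterior = c(snapz(15.5), th120),
                      shaft = c(snapz(params$shaft_start +
                                      0.6 * params$shaft_length), th90))
  dth <- (th[2] - th[1]) / 4
  zone_samples <- lapply(seq_len(nrow(zone_param)), function(k) {
    z0 <- zone_param[k, 1]; t0 <- zone_param[k, 2]
    zd <- seq(z0 - 5, z0 + 5, by = 0.25)
    zd <- zd[zd >= zs[1] & zd <= zs[nr]]
    td <- seq(t0 - 48 * dth, t0 + 48 * dth, by = dth)
    blz <- band_limits(z0)
    td <- td[td >= max(th[1], blz[, "lo"]) & td <= min(th[nt], blz[, "hi"])]
    g <- expand.grid(z = zd, th = td)
    sp <- femur_surface_points(tp, g$z, g$th)
    sp[rowSums((sp - matrix(zone_anchor[k, ], nrow(sp), 3,
                            byrow = TRUE))^2) <= zone_radius^2, , drop = FALSE]
  })
  names(zone_samples) <- rownames(zone_anchor)
  # construction-frame axial levels of the zone anchors: intrinsic plate
  # parameters, invariant under rigid motion of the model
  zone_anchor_z <- setNames(zone_param[, 1], rownames(zone_param))

  # screws ------------------------------------------------------------------
  head_z <- vapply(c(15.5, 25.5, 35.5, 45.5), snapz, numeric(1))
  head_origin <- surf(head_z, rep(th90, length(head_z)))
  screws <- data.frame(
    ox = head_origin[, 1], oy = head_origin[, 2], oz = head_origin[, 3],
    dx = 0, dy = -1, dz = 0,
    length = 2 * tp$condyle_ml, proximal = FALSE)
  zp <- snapz(params$tip_level - 10)
  po <- as.numeric(surf(zp, th90))
  target <- c(femur_centreline_x(tp, zp), 0, zp)
  pd <- unit3(target - po)
  screws <- rbind(screws,
                  data.frame(ox = po[1], oy = po[2], oz = po[3],
                             dx = pd[1], dy = pd[2], dz = pd[3],
                             length = sqrt(sum((target - po)^2)),
                             proximal = TRUE))

  structure(list(
    grid = list(points = pts, z = zs, theta = th, nz = nr, ntheta = nt,
                in_band = in_band),
    mesh = mesh,
    centre_curve = centre_curve, shaft_mask = shaft_mask,
    anchors = anchors, zone_anchor = zone_anchor,
    zone_anchor_z = zone_anchor_z,
    zone_samples = zone_samples, zone_radius = zone_radius,
    screws = screws, holes = params$holes, params = params),
    class = "plate_model")
}

#' @export
print.plate_model <- function(x, ...) {
  cat(sprintf("plate_model: %d-hole, bow %.0f mm, %d undersurface samples\n",
              x$holes, x$params$bow_radius, nrow(x$grid$points)))
  invisible(x)
}

# Same plate family, different length.
plate_params_with_holes <- function(base, holes) {
  plate_params(holes = holes, pitch = base$pitch,
               bow_radius = base$bow_radius, band_deg = base$band_deg,
               shaft_band_deg = base$shaft_band_deg,
               distal_start = base$distal_start,
               shaft_start = base$shaft_start,
               template = base$template, seed = base$seed)
}
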