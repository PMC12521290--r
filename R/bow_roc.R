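#' Diaphysis span along the shaft axis
#'
#' The proximal level is the axial coordinate of the base of the lesser
#' trochanter; the distal level is the axial coordinate of the start of the
#' lateral condyle moved 10 mm (configurable) towards the proximal side.
#' Works in either axis orientation (distal coordinates increasing or
#' decreasing).
#'
#' @param lt_level axial coordinate of the lesser trochanter base, mm; or a
#'   `femur_model`, in which case levels are computed along the principal
#'   axis of the inner cortex.
#' @param condyle_level axial coordinate of the lateral condyle start, mm
#'   (ignored when a bone is given).
#' @param offset distal offset from the condyle start, mm (default 10).
#' @return named vector `c(proximal, distal)`.
#' @export
diaphysis_levels <- function(lt_level, condyle_level = NULL, offset = 10) {
  if (inherits(lt_level, "femur_model")) {
    bone <- lt_level
    ax <- inner_shaft_axis(bone)
    lt_level <- sum(bone$landmarks$lesser_trochanter_base * ax$axis)
    condyle_level <- sum(bone$landmarks$lateral_condyle_start * ax$axis)
  }
  if (is.null(condyle_level)) stop("condyle_level missing")
  towards_prox <- sign(lt_level - condyle_level)
  if (towards_prox == 0 || abs(lt_level - condyle_level) <= offset)
    stop("landmark levels not ordered: the lesser trochanter base must be ",
         "more than ", offset, " mm proximal to the condyle start")
  c(proximal = lt_level, distal = condyle_level + offset * towards_prox)
}

# Principal axis of the inner-cortex vertices, oriented towards the lesser
# trochanter; the section planes are perpendicular to it.
inner_shaft_axis <- function(bone, span = NULL) {
  v <- bone$inner$vertices
  if (!is.null(span)) {
    t_all <- as.vector(v %*% attr(span, "axis"))
    v <- v[t_all >= min(span) & t_all <= max(span), , drop = FALSE]
  }
  ctr <- colMeans(v)
  sv <- svd(sweep(v, 2, ctr), nu = 0, nv = 3)
  axis <- sv$v[, 1]
  dirp <- bone$landmarks$lesser_trochanter_base -
    bone$landmarks$lateral_condyle_start
  if (sum(axis * dirp) < 0) axis <- -axis
  list(axis = axis, centre = ctr)
}

#' Canal cross-section centre points
#'
#' Cuts the inner cortex with `n_sections` planes perpendicular to the
#' shaft axis, equally spaced over the diaphysis span (both end levels
#' included), and returns the area centroid of each section.
#'
#' @param bone a `femur_model` with a watertight inner cortex mesh.
#' @param levels optional `c(proximal, distal)` axial span; default
#'   [diaphysis_levels()] of the bone.
#' @param n_sections number of cross-sections (default 20).
#' @return `n_sections` x 3 matrix of centre points (mm).
#' @export
canal_centroids <- function(bone, levels = NULL, n_sections = 20) {
  ax <- inner_shaft_axis(bone)
  if (is.null(levels)) {
    lt <- sum(bone$landmarks$lesser_trochanter_base * ax$axis)
    ct <- sum(bone$landmarks$lateral_condyle_start * ax$axis)
    levels <- diaphysis_levels(lt, ct)
  }
  # re-estimate the axis from the diaphyseal span only
  span <- c(levels[["proximal"]], levels[["distal"]])
  v <- bone$inner$vertices
  t_all <- as.vector(v %*% ax$axis)
  sel <- t_all >= min(span) & t_all <= max(span)
  if (sum(sel) < 100) stop("diaphysis span contains too few inner vertices")
  ctr <- colMeans(v[sel, , drop = FALSE])
  sv <- svd(sweep(v[sel, , drop = FALSE], 2, ctr), nu = 0, nv = 3)
  axis <- sv$v[, 1]
  if (sum(axis * ax$axis) < 0) axis <- -axis
  # landmark levels along the refined axis
  lt <- sum(bone$landmarks$lesser_trochanter_base * axis)
  ct <- sum(bone$landmarks$lateral_condyle_start * axis)
  levels <- diaphysis_levels(lt, ct)
  offsets <- seq(levels[["distal"]], levels[["proximal"]],
                 length.out = n_sections)
  base <- ctr - sum(ctr * axis) * axis
  out <- matrix(NA_real_, n_sections, 3)
  for (i in seq_len(n_sections)) {
    sec <- tryCatch(
      section_mesh(bone$inner, base + offsets[i] * axis, axis),
      error = function(e) stop("empty canal section at offset ",
                               round(offsets[i], 1), " mm: ",
                               conditionMessage(e)))
    out[i, ] <- section_centroid(sec)
  }
  out
}

#' Best-fit circle to 3D points
#'
#' Fits a least-squares plane through the points (SVD), projects the points
#' into it, fits a circle algebraically and refines it with a geometric
#' Gauss-Newton step. Exact (to numerical precision) for points lying on a
#' circle.
#'
#' @param points n x 3 matrix, n >= 3, not all collinear.
#' @return object of class `roc_result`: `radius` (mm), `centre` (3D),
#'   `normal` (plane unit normal), `rms` (RMS radial residual, mm),
#'   `n_points`.
#' @export
fit_circle_3d <- function(points) {
  P <- as_point_matrix(points)
  if (nrow(P) < 3) stop("circle fit needs at least 3 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("points are collinear: no finite best-fit circle")
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  normal <- sv$v[, 3]
  x <- as.vector(Pc %*% e1)
  y <- as.vector(Pc %*% e2)

  # algebraic (Kasa) initialisation: solve |p|^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  ab <- qr.solve(A, rhs)
  cx <- ab[1]; cy <- ab[2]
  r <- sqrt(ab[3] + cx^2 + cy^2)

  # geometric refinement (Gauss-Newton on centre and radius)
  for (it in 1:50) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    if (any(di < 1e-12)) break
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < 1e-12 * max(r, 1)) break
  }
  dx <- x - cx; dy <- y - cy
  rms <- sqrt(mean((sqrt(dx^2 + dy^2) - r)^2))
  centre <- ctr + cx * e1 + cy * e2
  structure(list(radius = r, centre = as.numeric(centre),
                 normal = as.numeric(normal), rms = rms, n_points = nrow(P)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: radius %.1f mm (rms residual %.4f mm, %d points)\n",
              x$radius, x$rms, x$n_points))
  invisible(x)
}

#' Femoral anterior-bow radius of curvature
#'
#' Best-fit circle to the centre points of `n_sections` axial
#' cross-sections of the inner cortex, equally spaced over the diaphysis
#' (lesser-trochanter base to 10 mm proximal of the lateral condyle start).
#'
#' @param bone a `femur_model`.
#' @param n_sections number of cross-sections (default 20).
#' @return a `roc_result`.
#' @export
measure_bone_roc <- function(bone, n_sections = 20) {
  bone <- canonical_femur(bone)
  fit_circle_3d(canal_centroids(bone, n_sections = n_sections))
}

#' Plate shaft radius of curvature
#'
#' Best-fit circle to the shaft portion of the plate undersurface centre
#' curve.
#'
#' @param plate a `plate_model`.
#' @return a `roc_result`.
#' @export
measure_plate_roc <- function(plate) {
  pts <- plate$centre_curve[plate$shaft_mask, , drop = FALSE]
  fit_circle_3d(pts)
}
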