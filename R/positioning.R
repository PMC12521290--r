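#' Rigid transforms
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' `x' = R x + t`. Used to carry the plate model from its construction
#' frame onto a bone.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation 3-vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3 x 3")
  orth_dev <- max(abs(crossprod(rotation) - diag(3)))
  if (abs(det(rotation) - 1) > 1e-6 || orth_dev > 1e-6)
    stop("rotation must be a proper orthonormal matrix (determinant +1)")
  if (orth_dev > 1e-12) {
    # snap accumulated round-off from long composition chains back onto
    # the rotation group
    s <- svd(rotation)
    rotation <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param points n x 3 matrix or 3-vector.
#' @param transform a `rigid_transform`.
#' @export
apply_transform <- function(points, transform) {
  p <- as_point_matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (is.null(dim(points))) as.numeric(out) else out
}

#' @rdname rigid_transform
#' @param a,b transforms; `compose_transform(a, b)` applies `b` first.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*% transform$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  m <- cbind(x$rotation, x$translation)
  rownames(m) <- c("x", "y", "z")
  colnames(m) <- c("r1", "r2", "r3", "t")
  print(round(m, 6))
  invisible(x)
}

#' Serialise a transform as a homogeneous matrix
#'
#' @param transform a [rigid_transform()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_transform` returns the transform.
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(apply(m, 1, as.numeric, simplify = FALSE), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(m)) m <- do.call(rbind, m)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# Closed-form (weighted) least-squares rigid fit (Kabsch) mapping P onto Q.
kabsch <- function(P, Q, w = NULL) {
  P <- as_point_matrix(P); Q <- as_point_matrix(Q)
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- w / sum(w)
  pc <- colSums(P * w); qc <- colSums(Q * w)
  H <- crossprod(sweep(P, 2, pc) * w, sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, qc - as.numeric(R %*% pc))
}

# Bone-anchored orthonormal frame: z along the shaft principal axis
# (oriented from the condyle start towards the lesser trochanter base), y
# towards the lateral contact landmarks. Derived from the bone alone, so
# the refinement steps are equivariant under joint rigid motion of
# plate + bone.
bone_frame <- function(bone) {
  lm <- bone$landmarks
  v <- bone$outer$vertices
  ctr <- colMeans(v)
  ev <- eigen(crossprod(sweep(v, 2, ctr)), symmetric = TRUE)
  uz <- ev$vectors[, 1]
  if (sum(uz * (lm$lesser_trochanter_base - lm$lateral_condyle_start)) < 0)
    uz <- -uz
  mid <- (lm$distal_anterior_contact + lm$distal_posterior_contact) / 2
  l <- mid - ctr
  l <- l - sum(l * uz) * uz
  uy <- unit3(l)
  ux <- cross3(uy, uz)
  list(origin = mid, axes = cbind(ux, uy, uz))
}

# Lateral shaft surface point at a given arc length above the distal end.
# Preferred source is the lateral_shaft_ridge landmark (points at a fixed
# 1 mm spacing from z = 0.5, carried with the bone under any rigid
# motion); for generic meshes without it, the most lateral outer vertex at
# the matching level along the shaft axis is used.
bone_lateral_shaft_point <- function(bone, z_level) {
  ridge <- bone$landmarks$lateral_shaft_ridge
  if (!is.null(ridge)) {
    i <- min(max(round(z_level - 0.5) + 1, 1), nrow(ridge))
    return(as.numeric(ridge[i, ]))
  }
  if (!is.null(bone$params) && inherits(bone$params, "femur_params"))
    return(as.numeric(femur_surface_points(bone$params, z_level, pi / 2)))
  fr <- bone_frame(bone)
  uz <- fr$axes[, 3]; uy <- fr$axes[, 2]
  v <- bone$outer$vertices
  tv <- as.vector(v %*% uz)
  sel <- which(abs(tv - (min(tv) + z_level)) <= 1.5)
  if (length(sel) == 0) stop("no outer vertices at the requested shaft level")
  lat <- as.vector(v[sel, , drop = FALSE] %*% uy)
  v[sel[which.max(lat)], ]
}

#' Initial landmark-based plate alignment
#'
#' Closed-form least-squares rigid transform mapping the plate reference
#' points (distal anterior anchor, distal posterior anchor, the
#' centre-curve point at the lateral condyle start level, and the shaft
#' zone anchor) onto the corresponding bone targets (the two distal
#' contact landmarks, the lateral condyle start landmark, and the lateral
#' shaft surface point at matching arc length). The four correspondences
#' span a non-degenerate tetrahedron, so all six rigid degrees of freedom
#' are pinned by landmarks alone.
#'
#' @param plate a `plate_model`.
#' @param bone a `femur_model`.
#' @return a [rigid_transform()].
#' @export
initial_alignment <- function(plate, bone) {
  lm <- bone$landmarks
  need <- c("distal_anterior_contact", "distal_posterior_contact",
            "lateral_condyle_start", "lesser_trochanter_base")
  if (!all(need %in% names(lm)))
    stop("missing landmark(s): ", paste(setdiff(need, names(lm)), collapse = ", "))
  fr <- bone_frame(bone)
  uz <- fr$axes[, 3]
  t0 <- min(as.vector(bone$outer$vertices %*% uz))
  ct_height <- sum(lm$lateral_condyle_start * uz) - t0
  # intrinsic (construction-frame) parameters of the plate, so alignment
  # works for arbitrarily pre-transformed plate models
  cc_z <- plate$grid$z
  p_ct <- plate$centre_curve[which.min(abs(cc_z - ct_height)), ]
  P <- rbind(plate$zone_anchor["distal_anterior", ],
             plate$zone_anchor["distal_posterior", ],
             p_ct,
             plate$zone_anchor["shaft", ])
  Q <- rbind(lm$distal_anterior_contact,
             lm$distal_posterior_contact,
             lm$lateral_condyle_start,
             bone_lateral_shaft_point(bone, plate$zone_anchor_z[["shaft"]]))
  kabsch(P, Q)
}

#' Positioning configuration
#'
#' @param contact_tol maximum plate-bone distance that counts as contact in
#'   each of the three zones, mm.
#' @param lambda weight of the squared penetration-depth penalty.
#' @param max_iter maximum number of pattern-search sweeps.
#' @param obj_tol objective change below which iteration stops.
#' @param step_t,step_r initial translation (mm) / rotation (rad) steps.
#' @param min_step step size at which the search gives up.
#' @param r_fossa screw clearance radius around the intercondylar fossa, mm.
#' @param zone_vertex_radius radius of the bone-vertex neighbourhood cached
#'   per contact zone during iteration, mm.
#' @return list of class `position_config`.
#' @export
position_config <- function(contact_tol = 0.2, lambda = 1e3, max_iter = 500,
                            obj_tol = 1e-6, step_t = 1.0, step_r = 0.01,
                            min_step = 1e-4, r_fossa = 2,
                            zone_vertex_radius = 25) {
  structure(list(contact_tol = contact_tol, lambda = lambda,
                 max_iter = max_iter, obj_tol = obj_tol, step_t = step_t,
                 step_r = step_r, min_step = min_step, r_fossa = r_fossa,
                 zone_vertex_radius = zone_vertex_radius),
            class = "position_config")
}


# Area-weighted outward vertex normals of a mesh; used to estimate
# penetration depth as a projection, which stays near zero for grazing
# contact instead of inheriting the tangential vertex-lattice offset.
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  idx <- as.vector(f)
  acc <- rowsum(rbind(fn, fn, fn), idx)
  n <- matrix(0, nrow(v), 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

transform_screws <- function(screws, transform) {
  O <- as.matrix(screws[, c("ox", "oy", "oz")])
  D <- as.matrix(screws[, c("dx", "dy", "dz")])
  O2 <- apply_transform(O, transform)
  D2 <- D %*% t(transform$rotation)
  list(origin = O2, direction = D2, length = screws$length,
       proximal = screws$proximal)
}

segment_points_min_dist <- function(a, b, pts) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2, a)
  t <- pmin(pmax(as.vector(rel %*% ab) / len2, 0), 1)
  closest <- outer(t, ab)
  sqrt(min(rowSums((rel - closest)^2)))
}

#' Screw trajectory checks
#'
#' Verifies the two screw constraints of the positioning protocol: no screw
#' segment passes within `r_fossa` of the intercondylar fossa region, and
#' the tip of the most proximal screw lies within the intramedullary canal
#' (inside the inner cortex surface).
#'
#' @param plate a `plate_model`.
#' @param bone a `femur_model`.
#' @param transform the plate placement ([rigid_transform()]).
#' @param r_fossa clearance radius, mm.
#' @param inner_index optional containment index for the inner cortex mesh.
#' @return list with logicals `fossa_clear` and `proximal_screw_in_canal`
#'   and the minimum screw-fossa distance `fossa_min_dist`.
#' @export
check_screws <- function(plate, bone, transform, r_fossa = 2,
                         inner_index = NULL) {
  s <- transform_screws(plate$screws, transform)
  fossa <- bone$landmarks$intercondylar_fossa_region
  dmin <- Inf
  for (k in seq_len(nrow(s$origin))) {
    a <- s$origin[k, ]
    b <- a + s$direction[k, ] * s$length[k]
    dmin <- min(dmin, segment_points_min_dist(a, b, fossa))
  }
  tip_idx <- which(s$proximal)[1]
  tip <- s$origin[tip_idx, ] + s$direction[tip_idx, ] * s$length[tip_idx]
  in_canal <- point_inside_surface(tip, bone$inner,
                                   check_watertight = is.null(inner_index),
                                   index = inner_index)
  list(fossa_clear = dmin >= r_fossa, proximal_screw_in_canal = in_canal,
       fossa_min_dist = dmin)
}

# Contact-zone minimum vertex distances for a placed plate; `wsub` is a
# list of bone vertex subsets (or NULL to use the full vertex matrix).
zone_distances <- function(plate, transform, bone_verts, wsub = NULL) {
  vapply(seq_along(plate$zone_samples), function(k) {
    W <- if (is.null(wsub)) bone_verts else wsub[[k]]
    pts <- apply_transform(plate$zone_samples[[k]], transform)
    min(cpp_nearest_vertex(pts, W, "exhaustive")$distance)
  }, numeric(1))
}

#' Refine the plate position under contact and collision constraints
#'
#' Deterministic pattern search over the six rigid degrees of freedom,
#' minimising the sum of squared contact-zone distances plus a weighted
#' penalty on squared penetration depths, starting from an initial
#' alignment. The search terminates when the objective stalls (change
#' below `obj_tol` over a sweep), when steps shrink below `min_step`, or at
#' `max_iter` sweeps. The result is converged when all three contact zones
#' are within `contact_tol`, no undersurface sample penetrates the bone,
#' and both screw checks pass; these constraints are re-evaluated on the
#' full bone model before reporting.
#'
#' @param plate a `plate_model`.
#' @param bone a `femur_model`.
#' @param init initial [rigid_transform()]; default [initial_alignment()].
#' @param config a [position_config()].
#' @return object of class `positioning_result`: `transform`,
#'   `contact_zones` (named distances, mm), `penetration_count`,
#'   `screw_checks`, `converged`, `iterations`, `objective`, and
#'   `objective_trace` (per-sweep objective of the final contact phase).
#' @export
refine_position <- function(plate, bone, init = NULL,
                            config = position_config()) {
  if (is.null(init)) init <- initial_alignment(plate, bone)
  fr <- bone_frame(bone)
  axes <- fr$axes
  outer_index <- mesh_containment_index(bone$outer)
  inner_index <- mesh_containment_index(bone$inner)
  W <- bone$outer$vertices
  Wn <- mesh_vertex_normals(bone$outer)
  S <- plate$grid$points

  # static bone-vertex neighbourhoods around the initial zone positions
  anchors0 <- apply_transform(plate$zone_anchor, init)
  wsub <- lapply(seq_len(nrow(anchors0)), function(k) {
    d2 <- rowSums((W - matrix(anchors0[k, ], nrow(W), 3, byrow = TRUE))^2)
    sub <- W[d2 <= config$zone_vertex_radius^2, , drop = FALSE]
    if (nrow(sub) == 0) W else sub  # fall back when the init is far off
  })
  # rotations pivot at the distal contact midpoint: the seating motion
  # swings the shaft while the head stays put
  pivot <- (anchors0[1, ] + anchors0[2, ]) / 2

  # guidance targets for the seating phase: where the zone anchors should
  # land, from landmarks alone
  guide_targets <- rbind(
    bone$landmarks$distal_anterior_contact,
    bone$landmarks$distal_posterior_contact,
    bone_lateral_shaft_point(bone, plate$zone_anchor_z[["shaft"]]))

  evaluate <- function(tf, lambda, guided = FALSE) {
    pts <- apply_transform(S, tf)
    zd <- vapply(seq_along(plate$zone_samples), function(k) {
      min(cpp_nearest_vertex(apply_transform(plate$zone_samples[[k]], tf),
                             wsub[[k]], "exhaustive")$distance)
    }, numeric(1))
    inside <- as.logical(cpp_trigrid_inside(outer_index, pts))
    pen <- sum(inside)
    pen_term <- 0
    if (pen > 0) {
      nn <- cpp_nearest_vertex(pts[inside, , drop = FALSE], W, "grid")
      depths <- pmax(rowSums((W[nn$index, , drop = FALSE] -
                              pts[inside, , drop = FALSE]) *
                             Wn[nn$index, , drop = FALSE]), 0)
      # the small per-sample term keeps an incentive to expel grazing
      # penetrations whose projected depth is ~0
      pen_term <- sum(depths^2) + 1e-4 * pen
    }
    base <- if (guided) {
      sum((apply_transform(plate$zone_anchor, tf) - guide_targets)^2)
    } else {
      sum(zd^2)
    }
    list(obj = base + lambda * pen_term, zones = zd, pen = pen)
  }

  feasible <- function(ev, tf) {
    if (any(ev$zones > config$contact_tol) || ev$pen > 0) return(FALSE)
    sc <- check_screws(plate, bone, tf, config$r_fossa, inner_index)
    sc$fossa_clear && sc$proximal_screw_in_canal
  }

  rot_move <- function(k, ang) {
    u <- axes[, k]
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    rigid_transform(Rm, pivot - as.numeric(Rm %*% pivot))
  }

  # pattern search over the six rigid degrees of freedom at a fixed
  # penalty weight; returns the refined pose and sweep count
  search_phase <- function(tf, lambda, max_iter, check_feasible,
                           guided = FALSE) {
    ev <- evaluate(tf, lambda, guided)
    st <- config$step_t
    sr <- config$step_r
    iter <- 0L
    resets <- 0L
    trace <- ev$obj
    repeat {
      iter <- iter + 1L
      f_before <- ev$obj
      tf_before <- tf
      improved <- FALSE
      for (k in 1:3) {
        for (sgn in c(1, -1)) {
          cand <- compose_transform(
            rigid_transform(diag(3), sgn * st * axes[, k]), tf)
          ce <- evaluate(cand, lambda, guided)
          if (ce$obj < ev$obj - 1e-12) {
            tf <- cand; ev <- ce; improved <- TRUE
          }
        }
      }
      for (k in 1:3) {
        for (sgn in c(1, -1)) {
          cand <- compose_transform(rot_move(k, sgn * sr), tf)
          ce <- evaluate(cand, lambda, guided)
          if (ce$obj < ev$obj - 1e-12) {
            tf <- cand; ev <- ce; improved <- TRUE
          }
        }
      }
      if (improved) {
        # pattern move (Hooke-Jeeves): repeat the net displacement of the
        # sweep while it keeps paying off
        for (rep in 1:8) {
          cand <- compose_transform(
            compose_transform(tf, invert_transform(tf_before)), tf)
          ce <- tryCatch(evaluate(cand, lambda, guided), error = function(e) NULL)
          if (is.null(ce) || ce$obj >= ev$obj - 1e-12) break
          tf <- cand; ev <- ce
        }
      }
      trace <- c(trace, ev$obj)
      stalled <- (f_before - ev$obj) < config$obj_tol
      if (stalled && check_feasible && feasible(ev, tf)) break
      if (iter >= max_iter) break
      if (!improved) {
        st <- st / 2
        sr <- sr / 2
      }
      if (st < config$min_step && sr < config$min_step / 100) {
        if (check_feasible && resets < 2L) {
          # escape a prematurely shrunk step pattern before declaring the
          # pose final
          resets <- resets + 1L
          st <- config$step_t / (4^resets)
          sr <- config$step_r / (4^resets)
        } else break
      }
    }
    list(tf = tf, ev = ev, iter = iter, trace = trace)
  }

  # two-stage automation: a collision-aware seating phase pulls the zone
  # anchors towards their landmark targets under a softened penalty (this
  # supplies the tangential gradient the contact objective lacks), then
  # the contact phase minimises the protocol objective under the full
  # penalty
  seed <- init
  alt <- tryCatch(initial_alignment(plate, bone), error = function(e) NULL)
  if (!is.null(alt)) {
    # the landmark alignment is always a candidate seed: if the supplied
    # init is a perturbed or worse pose, this recovers it immediately
    if (evaluate(alt, config$lambda / 100, guided = TRUE)$obj <
        evaluate(init, config$lambda / 100, guided = TRUE)$obj)
      seed <- alt
  }
  tf <- seed
  iter <- 0L
  ev <- NULL
  for (round in 1:3) {
    ph1 <- search_phase(tf, config$lambda / 100,
                        max_iter = ceiling(config$max_iter / 2),
                        check_feasible = FALSE, guided = TRUE)
    ph2 <- search_phase(ph1$tf, config$lambda,
                        max_iter = config$max_iter, check_feasible = TRUE)
    tf <- ph2$tf
    ev <- ph2$ev
    iter <- iter + ph1$iter + ph2$iter
    if (feasible(ev, tf)) break
  }

  # post-hoc verification against the full bone model
  zd_full <- zone_distances(plate, tf, W)
  names(zd_full) <- names(plate$zone_samples)
  pts <- apply_transform(S, tf)
  pen_full <- sum(point_inside_surface(pts, bone$outer,
                                       check_watertight = FALSE,
                                       index = outer_index))
  sc <- check_screws(plate, bone, tf, config$r_fossa, inner_index)
  converged <- all(zd_full <= config$contact_tol) && pen_full == 0 &&
    sc$fossa_clear && sc$proximal_screw_in_canal
  structure(list(transform = tf, contact_zones = zd_full,
                 penetration_count = pen_full,
                 screw_checks = sc[c("fossa_clear", "proximal_screw_in_canal")],
                 converged = converged, iterations = iter,
                 objective = ev$obj, objective_trace = ph2$trace),
            class = "positioning_result")
}

#' @export
print.positioning_result <- function(x, ...) {
  cat(sprintf("positioning_result: %s after %d sweeps\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  contact zones (mm): %s\n",
              paste(sprintf("%s=%.3f", names(x$contact_zones), x$contact_zones),
                    collapse = ", ")))
  cat(sprintf("  penetrating samples: %d; fossa clear: %s; screw in canal: %s\n",
              x$penetration_count, x$screw_checks$fossa_clear,
              x$screw_checks$proximal_screw_in_canal))
  invisible(x)
}

#' Serialise a positioning result to JSON
#'
#' @param result a `positioning_result`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_positioning_result <- function(result, path) {
  out <- list(
    transform = apply(rbind(cbind(result$transform$rotation,
                                  result$transform$translation),
                            c(0, 0, 0, 1)), 1, as.numeric, simplify = FALSE),
    contact_zones = as.list(result$contact_zones),
    penetration_count = result$penetration_count,
    screw_checks = result$screw_checks,
    converged = result$converged,
    iterations = result$iterations,
    objective = result$objective)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
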