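# Small analytic meshes and brute-force oracles shared across tests.

tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f, name = "tetra")
}

# closed lat-long sphere
uv_sphere_mesh <- function(radius = 1, centre = c(0, 0, 0),
                           n_lat = 24, n_lon = 48) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- (0:(n_lon - 1)) * 2 * pi / n_lon
  g <- expand.grid(lon = lon, lat = lat)
  v <- cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon), sin(g$lat))
  v <- rbind(v, c(0, 0, -1), c(0, 0, 1)) * radius
  v <- sweep(v, 2, centre, "+")
  idx <- function(i, j) (i - 1L) * n_lon + j
  i <- rep(1:(n_lat - 1), each = n_lon)
  j <- rep(1:n_lon, n_lat - 1)
  jn <- ifelse(j == n_lon, 1L, j + 1L)
  f <- rbind(cbind(idx(i, j), idx(i, jn), idx(i + 1L, jn)),
             cbind(idx(i, j), idx(i + 1L, jn), idx(i + 1L, j)))
  south <- n_lat * n_lon + 1L
  north <- n_lat * n_lon + 2L
  j1 <- 1:n_lon
  jn1 <- c(2:n_lon, 1L)
  f <- rbind(f,
             cbind(rep(south, n_lon), idx(1L, jn1), idx(1L, j1)),
             cbind(rep(north, n_lon), idx(n_lat, j1), idx(n_lat, jn1)))
  triangle_mesh(v, f, name = "sphere")
}

# open or capped cylinder along z
cylinder_mesh <- function(radius = 10, height = 40, n_theta = 64,
                          n_z = 20, capped = TRUE) {
  th <- (0:(n_theta - 1)) * 2 * pi / n_theta
  zs <- seq(0, height, length.out = n_z)
  g <- expand.grid(th = th, z = zs)
  v <- cbind(radius * cos(g$th), radius * sin(g$th), g$z)
  idx <- function(i, j) (i - 1L) * n_theta + j
  i <- rep(1:(n_z - 1), each = n_theta)
  j <- rep(1:n_theta, n_z - 1)
  jn <- ifelse(j == n_theta, 1L, j + 1L)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn)),
             cbind(idx(i, j), idx(i + 1L, jn), idx(i, jn)))
  if (capped) {
    v <- rbind(v, c(0, 0, -1e-6), c(0, 0, height + 1e-6))
    bot <- n_z * n_theta + 1L
    top <- n_z * n_theta + 2L
    j1 <- 1:n_theta
    jn1 <- c(2:n_theta, 1L)
    f <- rbind(f,
               cbind(rep(bot, n_theta), idx(1L, j1), idx(1L, jn1)),
               cbind(rep(top, n_theta), idx(n_z, jn1), idx(n_z, j1)))
  }
  triangle_mesh(v, f, name = "cylinder")
}

# exhaustive nearest-vertex oracle (plain R loop)
brute_nearest_vertex <- function(point, verts) {
  d2 <- rep(NA_real_, nrow(verts))
  for (i in seq_len(nrow(verts))) {
    dx <- point[1] - verts[i, 1]
    dy <- point[2] - verts[i, 2]
    dz <- point[3] - verts[i, 3]
    d2[i] <- dx * dx + dy * dy + dz * dz
  }
  i <- which.min(d2)  # which.min returns the first (lowest-index) minimum
  list(distance = sqrt(d2[i]), index = i)
}

# brute-force minimum distance from a segment to a set of points
brute_segment_points_dist <- function(a, b, pts, n_steps = 2000) {
  t <- seq(0, 1, length.out = n_steps)
  best <- Inf
  for (ti in t) {
    q <- a + ti * (b - a)
    best <- min(best, sqrt(min(rowSums(sweep(pts, 2, q)^2))))
  }
  best
}

# random rigid transform
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, rnorm(3, sd = 20))
}

# apply a rigid transform to every geometric field of a plate model
transform_plate <- function(plate, tf) {
  plate$grid$points <- apply_transform(plate$grid$points, tf)
  plate$mesh$vertices <- apply_transform(plate$mesh$vertices, tf)
  plate$centre_curve <- apply_transform(plate$centre_curve, tf)
  plate$anchors$c1 <- apply_transform(plate$anchors$c1, tf)
  plate$anchors$c2 <- apply_transform(plate$anchors$c2, tf)
  plate$anchors$c3 <- apply_transform(plate$anchors$c3, tf)
  za <- apply_transform(plate$zone_anchor, tf)
  rownames(za) <- rownames(plate$zone_anchor)
  plate$zone_anchor <- za
  plate$zone_samples <- lapply(plate$zone_samples, apply_transform, tf)
  O <- apply_transform(as.matrix(plate$screws[, c("ox", "oy", "oz")]), tf)
  D <- as.matrix(plate$screws[, c("dx", "dy", "dz")]) %*% t(tf$rotation)
  plate$screws[, c("ox", "oy", "oz")] <- O
  plate$screws[, c("dx", "dy", "dz")] <- D
  plate
}

# apply a rigid transform to a femur model
transform_femur <- function(bone, tf) {
  bone$outer$vertices <- apply_transform(bone$outer$vertices, tf)
  bone$inner$vertices <- apply_transform(bone$inner$vertices, tf)
  bone$landmarks <- lapply(bone$landmarks, function(p) {
    if (is.matrix(p)) apply_transform(p, tf) else apply_transform(p, tf)
  })
  bone$params <- NULL  # transformed bones no longer match their construction
  bone
}

# a small conforming bone/plate pair shared by positioning tests
conforming_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- femur_params(r_bow = 940)
      cache <<- list(bone = make_femur(p, id = "conforming"),
                     plate = make_plate(plate_params(holes = 13,
                                                     bow_radius = 940,
                                                     template = p)))
    }
    cache
  }
})
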