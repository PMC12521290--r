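#' @useDynLib platefit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif setNames sd quantile
#' @importFrom utils read.csv write.csv
#' @importFrom tools file_ext md5sum
NULL

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3) stop("a 3D point must have exactly 3 coordinates")
    p <- matrix(p, nrow = 1)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("point matrix must have 3 columns")
  storage.mode(p) <- "double"
  p
}

#' Triangle surface mesh
#'
#' Construct an indexed triangle mesh, the substrate for every geometric
#' operation in the package. Coordinates are in millimetres by convention.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param name optional label carried through reports.
#' @param validate if `TRUE` (default), check coordinate finiteness and face
#'   index validity, and drop zero-area faces. A mesh whose faces are all
#'   degenerate is rejected.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3) stop("faces must be an m x 3 matrix")
  m <- structure(list(vertices = vertices, faces = faces, name = name),
                 class = "triangle_mesh")
  if (validate) m <- validate_mesh(m) else m
}

#' Validate a triangle mesh
#'
#' Checks that all coordinates are finite and all face indices reference
#' existing vertices, then removes zero-area (degenerate) faces.
#'
#' @param mesh a [triangle_mesh()].
#' @return the validated mesh (degenerate faces dropped).
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh validation failed: non-finite vertex coordinates")
  if (nrow(f) == 0) stop("mesh validation failed: no faces")
  if (min(f) < 1 || max(f) > nrow(v))
    stop("mesh validation failed: face references vertex index out of range (",
         max(f), " of ", nrow(v), " vertices)")
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area2 <- cx^2 + cy^2 + cz^2
  keep <- area2 > 1e-24
  if (!any(keep)) stop("mesh validation failed: all faces are degenerate")
  mesh$faces <- f[keep, , drop = FALSE]
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Test whether a mesh is a closed, consistently oriented surface
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and every directed half-edge appears exactly once. Bone cortex
#' meshes used in containment tests must be watertight.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  cached <- attr(mesh, "watertight")
  if (!is.null(cached)) return(cached)
  a <- cpp_edge_audit(mesh$faces, nrow(mesh$vertices))
  a$closed && a$oriented
}

mark_watertight <- function(mesh) {
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

#' Shortest plate-to-bone vertex distance
#'
#' Distance from a query point to the nearest *vertex* of a mesh, together
#' with the index of that vertex. The contract is deliberately vertex-based
#' (not point-to-triangle): the fit protocol measures the Euclidean distance
#' from each point of interest to every vertex of the bone model and keeps
#' the shortest. Ties are broken toward the lowest vertex index. The
#' grid-accelerated search returns the identical minimum to the exhaustive
#' scan.
#'
#' @param point a 3-vector or an n x 3 matrix of query points (mm).
#' @param mesh a [triangle_mesh()].
#' @param method `"grid"` (default, accelerated) or `"exhaustive"`.
#' @return list with `distance` (mm) and `index` (1-based vertex index);
#'   vectors when `point` is a matrix.
#' @export
nearest_vertex_distance <- function(point, mesh, method = c("grid", "exhaustive")) {
  method <- match.arg(method)
  if (nrow(mesh$vertices) == 0) stop("empty mesh")
  p <- as_point_matrix(point)
  r <- cpp_nearest_vertex(p, mesh$vertices, method)
  list(distance = as.numeric(r$distance), index = as.integer(r$index))
}

#' Point containment in a closed surface
#'
#' Tests whether points lie strictly inside a watertight mesh, by ray
#' parity. Points on the surface (within 1e-9 mm along the test ray) are
#' classified as outside, i.e. non-penetrating.
#'
#' @param point a 3-vector or n x 3 matrix (mm).
#' @param mesh a watertight [triangle_mesh()].
#' @param check_watertight verify closedness first (default `TRUE`; the
#'   check is cached on meshes produced by the generators).
#' @param index optional precomputed [mesh_containment_index()] for `mesh`.
#' @return logical scalar or vector.
#' @export
point_inside_surface <- function(point, mesh, check_watertight = TRUE,
                                 index = NULL) {
  if (check_watertight && !is_watertight(mesh))
    stop("containment test requires a watertight mesh")
  p <- as_point_matrix(point)
  if (is.null(index)) {
    as.logical(cpp_points_in_mesh(p, mesh$vertices, mesh$faces))
  } else {
    as.logical(cpp_trigrid_inside(index, p))
  }
}

#' Precompute a containment index for repeated queries
#'
#' Builds the spatial acceleration structure used by
#' [point_inside_surface()] once, so that many batches of points can be
#' tested against the same (static) mesh cheaply, as the positioning
#' optimiser does.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return an opaque index object to pass as `index`.
#' @export
mesh_containment_index <- function(mesh) {
  if (!is_watertight(mesh)) stop("containment index requires a watertight mesh")
  cpp_trigrid_build(mesh$vertices, mesh$faces)
}

#' Planar cross-section of a mesh
#'
#' Intersects a mesh with a plane and assembles the intersection segments
#' into ordered polylines (closed loops for sections through a closed
#' surface). Used to extract the axial cross-section curves from which
#' canal centre points are computed.
#'
#' @param mesh a [triangle_mesh()].
#' @param plane_point a point on the plane (mm).
#' @param plane_normal plane normal (normalised internally).
#' @return an object of class `plane_section`: list with `point`, `normal`,
#'   `loops` (list of k x 3 matrices, first point not repeated) and
#'   `closed` (logical per loop).
#' @export
section_mesh <- function(mesh, plane_point, plane_normal) {
  n <- unit3(as.numeric(plane_normal))
  p0 <- as.numeric(plane_point)
  v <- mesh$vertices
  scale <- max(abs(v)) + 1
  s <- as.vector((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% n)
  tries <- 0
  while (any(abs(s) < 1e-12 * scale) && tries < 8) {
    p0 <- p0 + 1e-7 * n
    s <- as.vector((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% n)
    tries <- tries + 1
  }
  if (any(abs(s) < 1e-12 * scale))
    stop("section failed: plane repeatedly grazes mesh vertices")

  f <- mesh$faces
  sf <- cbind(s[f[, 1]], s[f[, 2]], s[f[, 3]])
  edge_from <- cbind(f[, 1], f[, 2], f[, 3])
  edge_to   <- cbind(f[, 2], f[, 3], f[, 1])
  crossing <- (sf * sf[, c(2, 3, 1)]) < 0  # edge i connects vertex i -> i+1
  hit <- rowSums(crossing) == 2L
  if (!any(hit)) stop("empty section: the plane does not intersect the mesh")

  fh <- which(hit)
  seg_keys <- matrix("", length(fh), 2)
  seg_pts <- array(NA_real_, c(length(fh), 2, 3))
  for (e in 1:3) {
    sel <- crossing[fh, e]
    if (!any(sel)) next
    i <- edge_from[fh[sel], e]
    j <- edge_to[fh[sel], e]
    si <- s[i]; sj <- s[j]
    t <- si / (si - sj)
    pt <- v[i, , drop = FALSE] + t * (v[j, , drop = FALSE] - v[i, , drop = FALSE])
    key <- paste0(pmin(i, j), "_", pmax(i, j))
    rows <- which(sel)  # fill the first empty segment slot per face
    for (r in seq_along(rows)) {
      fr <- rows[r]
      sl <- if (seg_keys[fr, 1] == "") 1L else 2L
      seg_keys[fr, sl] <- key[r]
      seg_pts[fr, sl, ] <- pt[r, ]
    }
  }

  nodes <- unique(as.vector(seg_keys))
  node_id <- match(seg_keys, nodes)
  dim(node_id) <- dim(seg_keys)
  npt <- matrix(NA_real_, length(nodes), 3)
  npt[node_id[, 1], ] <- seg_pts[, 1, ]
  npt[node_id[, 2], ] <- seg_pts[, 2, ]

  nn <- length(nodes)
  adj <- vector("list", nn)
  deg <- integer(nn)
  for (k in seq_len(nrow(node_id))) {
    a <- node_id[k, 1]; b <- node_id[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    deg[a] <- deg[a] + 1L
    deg[b] <- deg[b] + 1L
  }

  visited <- logical(nn)
  loops <- list()
  closed <- logical(0)
  # start open chains at an endpoint (degree-1 node) so each is walked whole
  for (start in order(deg != 1L)) {
    if (visited[start]) next
    # walk the component; begin at a degree-1 node if one exists (open chain)
    comp_start <- start
    path <- integer(0)
    cur <- comp_start
    prev <- 0L
    repeat {
      path <- c(path, cur)
      visited[cur] <- TRUE
      nxt <- adj[[cur]][adj[[cur]] != prev & !visited[adj[[cur]]]]
      if (length(nxt) == 0) break
      prev <- cur
      cur <- nxt[1]
    }
    is_closed <- length(path) >= 3 &&
      path[1] %in% adj[[path[length(path)]]]
    loops[[length(loops) + 1]] <- npt[path, , drop = FALSE]
    closed <- c(closed, is_closed)
  }
  structure(list(point = p0, normal = n, loops = loops, closed = closed),
            class = "plane_section")
}

#' @export
print.plane_section <- function(x, ...) {
  cat(sprintf("plane_section: %d loop(s) (%d closed)\n",
              length(x$loops), sum(x$closed)))
  invisible(x)
}

plane_basis <- function(n) {
  n <- unit3(n)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(cross3(n, a))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

loop_area_centroid_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate loop: zero enclosed area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = a, centroid = c(cx, cy))
}

#' Centre point of a cross-section
#'
#' Area centroid of the planar region bounded by the outermost (largest
#' enclosed area) closed loop of a section. This is the "centre point" used
#' for canal centreline extraction; the area centroid is robust to
#' non-uniform sampling of the loop.
#'
#' @param section a `plane_section` from [section_mesh()].
#' @return 3-vector (mm).
#' @export
section_centroid <- function(section) {
  if (!inherits(section, "plane_section")) stop("not a plane_section")
  if (!any(section$closed)) stop("section has no closed loop")
  b <- plane_basis(section$normal)
  best <- NULL
  best_area <- -Inf
  for (i in which(section$closed)) {
    q <- section$loops[[i]]
    rel <- q - matrix(section$point, nrow(q), 3, byrow = TRUE)
    xy <- cbind(rel %*% b$e1, rel %*% b$e2)
    ac <- loop_area_centroid_2d(xy)
    if (abs(ac$area) > best_area) {
      best_area <- abs(ac$area)
      best <- ac$centroid
    }
  }
  as.numeric(section$point + best[1] * b$e1 + best[2] * b$e2)
}
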