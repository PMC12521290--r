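#' Read a triangle mesh from STL or PLY
#'
#' Reads ASCII or binary STL, or ASCII PLY. STL stores three loose vertices
#' per facet, so vertices are deduplicated (exact coordinate match) on load.
#' Meshes carry no unit metadata; coordinates are taken as millimetres, and
#' `scale` can be applied for files written in other units.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"stl"` or `"ply"`.
#' @param scale multiplicative factor applied to coordinates on load.
#' @param name label for the mesh; defaults to the file name.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply"), scale = 1,
                      name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply")) stop("cannot infer mesh format from '", path, "'")
    format <- ext
  }
  if (is.null(name)) name <- basename(path)
  m <- if (format == "stl") read_stl(path) else read_ply(path)
  m$vertices <- m$vertices * scale
  triangle_mesh(m$vertices, m$faces, name = name)
}

stl_is_binary <- function(path) {
  head <- readBin(path, "raw", n = 512)
  nz <- head[head != as.raw(0)]
  txt <- rawToChar(nz[seq_len(min(80, length(nz)))])
  if (!grepl("^\\s*solid", txt, useBytes = TRUE)) return(TRUE)
  # an ASCII stl must contain the word 'facet' early on
  !grepl("facet", rawToChar(nz), useBytes = TRUE)
}

read_stl <- function(path) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.finite(nf) || nf <= 0) stop("STL parse failure: bad facet count")
    rec <- readBin(con, "raw", n = nf * 50)
    if (length(rec) < nf * 50) stop("STL parse failure: truncated binary file")
    dim(rec) <- c(50, nf)
    tri <- matrix(NA_real_, nf * 3, 3)
    for (k in 1:3) {
      block <- rec[(12 * k + 1):(12 * k + 12), , drop = FALSE]
      vals <- readBin(as.vector(block), "numeric", n = 3 * nf, size = 4,
                      endian = "little")
      tri[seq(k, by = 3, length.out = nf), ] <- matrix(vals, nf, 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("STL parse failure: vertex count not a multiple of 3")
    tri <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                             "\\s+"))), ncol = 3, byrow = TRUE)
    if (any(!is.finite(tri))) stop("STL parse failure: non-numeric vertex data")
  }
  dedupe_triangles(tri)
}

dedupe_triangles <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  verts <- tri[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("PLY parse failure: missing header")
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop("PLY parse failure: no end_header")
  header <- lines[1:endh]
  if (!any(grepl("format ascii", header)))
    stop("PLY parse failure: only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY parse failure: missing element counts")
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("PLY parse failure: truncated body")
  vdata <- strsplit(trimws(body[1:nv]), "\\s+")
  verts <- matrix(as.numeric(unlist(lapply(vdata, `[`, 1:3))), ncol = 3, byrow = TRUE)
  fdata <- strsplit(trimws(body[(nv + 1):(nv + nf)]), "\\s+")
  faces <- t(vapply(fdata, function(x) {
    if (as.integer(x[1]) != 3L) stop("PLY parse failure: non-triangular face")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format inferred from extension unless given.
#' @param format `"auto"`, `"stl"` or `"ply"`.
#' @param binary write binary STL (default `FALSE`, ASCII). PLY is always
#'   ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "stl") {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- cc - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(raw(80), con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], cc[i, ])), con,
                 size = 4, endian = "little")
        writeBin(as.integer(0), con, size = 2, endian = "little")
      }
    } else {
      fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
      out <- c(sprintf("solid %s", mesh$name),
               as.vector(rbind(paste0("  facet normal ", fmt(n)),
                               "    outer loop",
                               paste0("      vertex ", fmt(a)),
                               paste0("      vertex ", fmt(b)),
                               paste0("      vertex ", fmt(cc)),
                               "    endloop",
                               "  endfacet")),
               sprintf("endsolid %s", mesh$name))
      writeLines(out, path)
    }
  } else if (format == "ply") {
    out <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header",
             sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    writeLines(out, path)
  } else stop("unsupported mesh format '", format, "'")
  invisible(path)
}

#' Read / write landmark sidecar files
#'
#' Landmark sets are stored as JSON objects mapping landmark names to
#' `[x, y, z]` coordinates in mm; point-set landmarks (such as the
#' intercondylar fossa region) map to an n x 3 array.
#'
#' @param path JSON file path.
#' @return named list of numeric vectors / matrices.
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(v) {
    if (is.list(v)) v <- do.call(rbind, v)
    if (is.matrix(v)) {
      storage.mode(v) <- "double"
      v
    } else as.numeric(v)
  })
}

#' @rdname read_landmarks
#' @param landmarks named list of 3-vectors or n x 3 matrices.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(v) {
    if (is.matrix(v)) unname(apply(v, 1, as.numeric, simplify = FALSE)) else as.numeric(v)
  }), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
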