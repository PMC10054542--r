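#' @title Triangulated membrane meshes
#' @name mesh
#' @description
#' Membranes of arbitrary shape are represented by a triangulated mesh
#' of the bilayer midplane.  Every vertex sits at signed depth 0; a
#' particle's depth is measured against the nearest vertex along its
#' normal.  Meshes can be generated programmatically (planar grids,
#' optionally bent onto a sphere), or loaded from ASCII OBJ/PLY files.
NULL

#' Construct a membrane mesh
#'
#' @param vertices n x 3 numeric matrix (Angstrom)
#' @param triangles m x 3 integer matrix of 1-based vertex indices with
#'   consistent winding
#' @param normals n x 3 matrix of unit vertex normals; recomputed from
#'   the triangle geometry when NULL
#' @param resolution grid spacing for generated meshes (Angstrom; NA for
#'   loaded meshes)
#' @return an object of class \code{membrane_mesh}
#' @export
membrane_mesh <- function(vertices, triangles, normals = NULL,
                          resolution = NA_real_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || nrow(vertices) == 0L)
    stop("vertices must be a non-empty n x 3 matrix")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (nrow(triangles) > 0L) {
    if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle vertex index out of range")
  }
  # drop degenerate triangles (repeated vertex indices)
  if (nrow(triangles) > 0L) {
    degen <- triangles[, 1] == triangles[, 2] |
      triangles[, 1] == triangles[, 3] | triangles[, 2] == triangles[, 3]
    if (any(degen)) {
      message(sprintf("dropped %d degenerate triangle(s)", sum(degen)))
      triangles <- triangles[!degen, , drop = FALSE]
    }
  }
  if (is.null(normals)) {
    normals <- vertex_normals(vertices, triangles)
  } else {
    normals <- as.matrix(normals)
    if (!identical(dim(normals), dim(vertices)))
      stop("normals must match vertices in dimension")
    len <- sqrt(rowSums(normals^2))
    if (any(len < 1e-12)) stop("zero-length vertex normal")
    normals <- normals / len
  }
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, resolution = resolution,
                 bounds = rbind(lo = apply(vertices, 2, min),
                                hi = apply(vertices, 2, max))),
            class = "membrane_mesh")
}

#' @export
print.membrane_mesh <- function(x, ...) {
  cat(sprintf("Membrane mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.na(x$resolution)) "" else
                sprintf(" (grid spacing %g A)", x$resolution)))
  invisible(x)
}

#' Area-weighted vertex normals from triangle geometry
#'
#' Each vertex normal is the renormalized sum of the (area-scaled)
#' normals of its incident triangles.  Isolated vertices get +z.
#'
#' @param vertices n x 3 matrix
#' @param triangles m x 3 index matrix
#' @return n x 3 matrix of unit normals
#' @export
vertex_normals <- function(vertices, triangles) {
  n <- nrow(vertices)
  acc <- matrix(0, n, 3)
  if (nrow(triangles) > 0L) {
    a <- vertices[triangles[, 1], , drop = FALSE]
    b <- vertices[triangles[, 2], , drop = FALSE]
    c_ <- vertices[triangles[, 3], , drop = FALSE]
    u <- b - a; v <- c_ - a
    # cross product rows; |cross| = 2 * area, so summing raw crosses is
    # the area weighting
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    for (k in 1:3) {
      idx <- triangles[, k]
      acc[, 1] <- acc[, 1] + tabulate_weighted(idx, cr[, 1], n)
      acc[, 2] <- acc[, 2] + tabulate_weighted(idx, cr[, 2], n)
      acc[, 3] <- acc[, 3] + tabulate_weighted(idx, cr[, 3], n)
    }
  }
  len <- sqrt(rowSums(acc^2))
  flat <- len < 1e-12
  acc[flat, ] <- matrix(rep(c(0, 0, 1), sum(flat)), ncol = 3, byrow = TRUE)
  len[flat] <- 1
  acc / len
}

# sum weights by integer bin (base rowsum without dimnames overhead)
tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Generate a planar midplane mesh
#'
#' A rectangular vertex grid at z = 0 centred on the origin, with
#' \code{xSize = floor(size_x/resolution)} columns of squares (and one
#' more of vertices), each square split into two triangles wound so all
#' triangle normals point to +z.
#'
#' @param size_x,size_y lateral extent (Angstrom)
#' @param resolution grid spacing between rows/columns (Angstrom)
#' @return a \code{membrane_mesh} with
#'   \code{(xSize+1)(ySize+1)} vertices and \code{2 xSize ySize}
#'   triangles
#' @export
#' @examples
#' m <- generate_planar_mesh(90, 90, 10)  # 100 vertices, 162 triangles
generate_planar_mesh <- function(size_x, size_y, resolution) {
  stopifnot(size_x > 0, size_y > 0, resolution > 0)
  if (resolution > size_x || resolution > size_y)
    stop("resolution exceeds the mesh size")
  nx <- floor(size_x / resolution)
  ny <- floor(size_y / resolution)
  xs <- (0:nx) * resolution - nx * resolution / 2
  ys <- (0:ny) * resolution - ny * resolution / 2
  verts <- cbind(x = rep(xs, times = ny + 1),
                 y = rep(ys, each = nx + 1),
                 z = 0)
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i  # i: 1..nx+1 along x
  tri <- matrix(0L, nrow = 2L * nx * ny, ncol = 3L)
  k <- 0L
  for (j in seq_len(ny)) {
    i <- seq_len(nx)
    v00 <- vid(i, j); v10 <- vid(i + 1L, j)
    v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
    # counter-clockwise seen from +z
    tri[k + seq_len(nx), ] <- cbind(v00, v10, v11)
    tri[k + nx + seq_len(nx), ] <- cbind(v00, v11, v01)
    k <- k + 2L * nx
  }
  membrane_mesh(verts, tri, normals = NULL, resolution = resolution)
}

#' Bend a mesh onto a sphere
#'
#' Sets each vertex z to \code{sign * (sqrt(r^2 - x^2 - y^2) - r)} so
#' the mesh centre stays at the origin; curvature is 1/r.  Normals are
#' recomputed from the deformed triangles.
#'
#' @param mesh a \code{membrane_mesh}
#' @param radius sphere radius (Angstrom)
#' @param sign +1 (dome opening down) or -1 (bowl opening up)
#' @return the curved \code{membrane_mesh}
#' @export
apply_spherical_curvature <- function(mesh, radius, sign = 1) {
  stopifnot(inherits(mesh, "membrane_mesh"), radius > 0, sign %in% c(-1, 1))
  v <- mesh$vertices
  rho2 <- v[, 1]^2 + v[, 2]^2
  if (any(rho2 > radius^2)) {
    stop(sprintf(
      "vertex outside the spherical disk: minimal admissible radius is %.3f A",
      sqrt(max(rho2))))
  }
  v[, 3] <- sign * (sqrt(radius^2 - rho2) - radius)
  membrane_mesh(v, mesh$triangles, normals = NULL,
                resolution = mesh$resolution)
}

# ---------------------------------------------------------------------
# ASCII OBJ / PLY I/O
# ---------------------------------------------------------------------

#' Write a mesh as ASCII OBJ or PLY
#'
#' @param mesh a \code{membrane_mesh}
#' @param path output file; format from the extension unless given
#' @param format \code{"obj"} or \code{"ply"}
#' @return invisibly, the path
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(sub(".*\\.", "", path))
  if (!format %in% c("obj", "ply")) stop("unsupported mesh format: ", format)
  v <- mesh$vertices; nrm <- mesh$normals; tr <- mesh$triangles
  con <- file(path, "w"); on.exit(close(con))
  if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("vn %.9g %.9g %.9g", nrm[, 1], nrm[, 2], nrm[, 3]), con)
    writeLines(sprintf("f %d//%d %d//%d %d//%d",
                       tr[, 1], tr[, 1], tr[, 2], tr[, 2], tr[, 3], tr[, 3]),
               con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 "property float nx", "property float ny", "property float nz",
                 sprintf("element face %d", nrow(tr)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g %.9g %.9g %.9g",
                       v[, 1], v[, 2], v[, 3],
                       nrm[, 1], nrm[, 2], nrm[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                       tr[, 3] - 1L), con)
  }
  invisible(path)
}

#' Load a mesh from an ASCII OBJ or PLY file
#'
#' Vertices and triangles are required; normals are recomputed from the
#' triangle geometry when absent.  Triangles whose winding disagrees
#' with the majority orientation (normal against the averaged vertex
#' normal) are reoriented with a warning; degenerate triangles are
#' dropped.
#'
#' @param path input file
#' @param format \code{"obj"} or \code{"ply"} (from extension by default)
#' @return a \code{membrane_mesh}
#' @export
load_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(sub(".*\\.", "", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mesh file: ", path)
  if (format == "obj") {
    parsed <- .parse_obj(lines)
  } else if (format == "ply") {
    parsed <- .parse_ply(lines)
  } else stop("unsupported mesh format: ", format)
  if (is.null(parsed$vertices) || nrow(parsed$vertices) == 0L)
    stop("mesh file contains no vertices: ", path)
  mesh <- membrane_mesh(parsed$vertices, parsed$triangles,
                        normals = parsed$normals)
  .fix_winding(mesh)
}

.parse_obj <- function(lines) {
  toks <- strsplit(trimws(lines), "[\t ]+")
  tag <- vapply(toks, `[[`, "", 1L)
  num3 <- function(rows) {
    if (!length(rows)) return(NULL)
    t(vapply(toks[rows], function(p) as.numeric(p[2:4]), numeric(3)))
  }
  v <- num3(which(tag == "v"))
  vn <- num3(which(tag == "vn"))
  frows <- which(tag == "f")
  tris <- NULL
  if (length(frows)) {
    tris <- t(vapply(toks[frows], function(p) {
      idx <- as.integer(sub("/.*", "", p[2:4]))
      idx
    }, integer(3)))
  }
  normals <- NULL
  if (!is.null(vn) && !is.null(v) && nrow(vn) == nrow(v)) normals <- vn
  list(vertices = v, triangles = if (is.null(tris))
    matrix(integer(0), 0, 3) else tris, normals = normals)
}

.parse_ply <- function(lines) {
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not an ASCII PLY file (no end_header)")
  header <- trimws(lines[seq_len(endh)])
  if (header[1] != "ply" || !any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)))
  if (!length(nf)) nf <- 0L
  # property order within the vertex element
  props <- sub("^property +\\S+ +", "",
               grep("^property (float|double)", header, value = TRUE))
  body <- trimws(lines[(endh + 1L):length(lines)])
  vlines <- strsplit(body[seq_len(nv)], "[\t ]+")
  vmat <- t(vapply(vlines, function(p) as.numeric(p), numeric(length(props))))
  colnames(vmat) <- props
  vertices <- vmat[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% props))
    vmat[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  tris <- matrix(integer(0), 0, 3)
  if (nf > 0L) {
    flines <- strsplit(body[nv + seq_len(nf)], "[\t ]+")
    tris <- t(vapply(flines, function(p) as.integer(p[2:4]) + 1L,
                     integer(3)))
  }
  list(vertices = vertices, triangles = tris, normals = normals)
}

# Reorient triangles whose face normal opposes the mean vertex normal.
.fix_winding <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(mesh)
  v <- mesh$vertices
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  vn <- (mesh$normals[tr[, 1], , drop = FALSE] +
           mesh$normals[tr[, 2], , drop = FALSE] +
           mesh$normals[tr[, 3], , drop = FALSE]) / 3
  flip <- rowSums(fn * vn) < 0
  if (any(flip)) {
    warning(sprintf("reoriented %d triangle(s) with inconsistent winding",
                    sum(flip)))
    tr[flip, ] <- tr[flip, c(1L, 3L, 2L)]
    mesh$triangles <- tr
  }
  mesh
}
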