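#' @title Spatial hash and mesh signed depth
#' @name spatial-hash
#' @description
#' Nearest-vertex queries against the membrane mesh point cloud go
#' through a uniform grid spatial hash.  The search expands cell shells
#' outward from the query point until the best candidate distance is
#' provably smaller than any vertex in an unvisited shell, so the
#' result always equals the brute-force nearest vertex.
NULL

#' Build a spatial hash over mesh vertices
#'
#' @param mesh a \code{membrane_mesh}
#' @param cell_size grid cell edge (Angstrom); defaults to twice the
#'   generated grid spacing, or the mean edge length for loaded meshes
#' @return an object of class \code{spatial_hash}
#' @export
build_spatial_hash <- function(mesh, cell_size = NULL) {
  stopifnot(inherits(mesh, "membrane_mesh"))
  v <- mesh$vertices
  if (is.null(cell_size)) {
    cell_size <- if (!is.na(mesh$resolution)) 2 * mesh$resolution
    else .mean_edge_length(mesh)
  }
  if (!is.finite(cell_size) || cell_size <= 0) cell_size <- 1
  origin <- apply(v, 2, min)
  ijk <- floor(sweep(v, 2, origin) / cell_size)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  cells <- split(seq_len(nrow(v)), key)
  structure(list(cell_size = cell_size, origin = origin,
                 cells = cells, n_vertices = nrow(v)),
            class = "spatial_hash")
}

.mean_edge_length <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(1)
  v <- mesh$vertices
  e <- rbind(cbind(tr[, 1], tr[, 2]), cbind(tr[, 2], tr[, 3]),
             cbind(tr[, 3], tr[, 1]))
  d <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                       v[e[, 2], , drop = FALSE])^2))
  mean(d)
}

#' Nearest mesh vertex to a point
#'
#' Ties are broken by the lowest vertex index.  The expanding shell
#' search is verified against brute force in the package tests.
#'
#' @param point length-3 coordinate vector (Angstrom)
#' @param mesh a \code{membrane_mesh}
#' @param hash a \code{spatial_hash} built over \code{mesh} (built on
#'   the fly when NULL)
#' @return the index of the Euclidean-nearest vertex
#' @export
nearest_vertex <- function(point, mesh, hash = NULL) {
  if (is.null(hash)) hash <- build_spatial_hash(mesh)
  if (hash$n_vertices == 0L) stop("empty mesh")
  v <- mesh$vertices
  h <- hash$cell_size
  p_ijk <- floor((point - hash$origin) / h)
  best_i <- NA_integer_; best_d2 <- Inf
  ring <- 0L
  max_ring <- 1L + ceiling(max(abs(sweep(mesh$bounds, 2, point))) / h)
  repeat {
    idx <- .ring_cells(hash, p_ijk, ring)
    if (length(idx)) {
      d2 <- (v[idx, 1] - point[1])^2 + (v[idx, 2] - point[2])^2 +
        (v[idx, 3] - point[3])^2
      ord <- order(d2, idx)
      if (d2[ord[1]] < best_d2 ||
          (d2[ord[1]] == best_d2 && idx[ord[1]] < best_i)) {
        best_d2 <- d2[ord[1]]; best_i <- idx[ord[1]]
      }
    }
    # any vertex in ring r+1 or beyond is at least r*h away from the
    # query cell; stop once that lower bound exceeds the best found
    if (!is.na(best_i) && sqrt(best_d2) <= ring * h) break
    ring <- ring + 1L
    if (ring > max_ring && !is.na(best_i)) break
    if (ring > max_ring + 1L) break
  }
  best_i
}

# vertex indices in the cubic shell at L-infinity cell distance `ring`
.ring_cells <- function(hash, p_ijk, ring) {
  rng <- -ring:ring
  if (ring == 0L) {
    keys <- paste(p_ijk[1], p_ijk[2], p_ijk[3])
  } else {
    # faces of the cube shell
    face <- expand.grid(a = rng, b = rng)
    keys <- c(
      paste(p_ijk[1] - ring, p_ijk[2] + face$a, p_ijk[3] + face$b),
      paste(p_ijk[1] + ring, p_ijk[2] + face$a, p_ijk[3] + face$b),
      paste(p_ijk[1] + face$a, p_ijk[2] - ring, p_ijk[3] + face$b),
      paste(p_ijk[1] + face$a, p_ijk[2] + ring, p_ijk[3] + face$b),
      paste(p_ijk[1] + face$a, p_ijk[2] + face$b, p_ijk[3] - ring),
      paste(p_ijk[1] + face$a, p_ijk[2] + face$b, p_ijk[3] + ring))
    keys <- unique(keys)
  }
  unlist(hash$cells[keys], use.names = FALSE)
}

#' Signed depth of points relative to a membrane mesh
#'
#' In \code{"projection"} mode (default) the depth is the component of
#' the offset from the nearest vertex along that vertex's normal,
#' \code{(p - v) . n}; exact for planar meshes at any resolution.  In
#' \code{"euclidean"} mode it is the full Euclidean distance to the
#' nearest vertex, signed by which side of the surface the point lies
#' (angle between offset and normal within +/-90 degrees = positive
#' side); this mode carries the grid-resolution-dependent error of a
#' raw point-cloud distance.
#'
#' @param points n x 3 matrix (or length-3 vector) of coordinates
#' @param mesh a \code{membrane_mesh}
#' @param hash optional prebuilt \code{spatial_hash}
#' @param mode \code{"projection"} or \code{"euclidean"}
#' @return numeric vector of signed depths (Angstrom)
#' @export
signed_depth <- function(points, mesh, hash = NULL,
                         mode = c("projection", "euclidean")) {
  mode <- match.arg(mode)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(hash)) hash <- build_spatial_hash(mesh)
  n <- nrow(points)
  out <- numeric(n)
  for (k in seq_len(n)) {
    i <- nearest_vertex(points[k, ], mesh, hash)
    off <- points[k, ] - mesh$vertices[i, ]
    proj <- sum(off * mesh$normals[i, ])
    out[k] <- if (mode == "projection") proj
    else sign(proj) * sqrt(sum(off^2))
  }
  out
}

#' Mesh-based implicit membrane
#'
#' Wraps a midplane mesh and a \code{membrane_geometry} into the
#' pluggable depth/profile contract used by the energy functions.
#' Pass several meshes to represent multiple membranes: each particle
#' then uses the mesh giving the smallest absolute depth.
#'
#' @param mesh a \code{membrane_mesh}, or a list of them
#' @param geom a \code{membrane_geometry}
#' @param mode depth mode, \code{"projection"} or \code{"euclidean"}
#' @return an object of classes \code{mesh_membrane}, \code{membrane}
#' @export
mesh_membrane <- function(mesh, geom = membrane_geometry(),
                          mode = c("projection", "euclidean")) {
  mode <- match.arg(mode)
  meshes <- if (inherits(mesh, "membrane_mesh")) list(mesh) else mesh
  stopifnot(all(vapply(meshes, inherits, TRUE, "membrane_mesh")))
  hashes <- lapply(meshes, build_spatial_hash)
  structure(list(meshes = meshes, hashes = hashes, geom = geom,
                 mode = mode),
            class = c("mesh_membrane", "membrane"))
}

#' @export
membrane_depth.mesh_membrane <- function(membrane, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  z <- rep(Inf, n)
  nrm <- matrix(0, n, 3)
  for (mi in seq_along(membrane$meshes)) {
    mesh <- membrane$meshes[[mi]]; hash <- membrane$hashes[[mi]]
    for (k in seq_len(n)) {
      i <- nearest_vertex(xyz[k, ], mesh, hash)
      off <- xyz[k, ] - mesh$vertices[i, ]
      proj <- sum(off * mesh$normals[i, ])
      zk <- if (membrane$mode == "projection") proj
      else sign(proj) * sqrt(sum(off^2))
      if (abs(zk) < abs(z[k])) {
        z[k] <- zk
        nrm[k, ] <- mesh$normals[i, ]
      }
    }
  }
  list(z = z, normal = nrm)
}

#' Insertion geometry of a particle system against a mesh
#'
#' Depth is the signed depth of the system centroid; tilt is the angle
#' between the insertion vector (from particle \code{a} to particle
#' \code{b}) and the membrane normal at the centroid's nearest vertex,
#' folded into [0, 90] degrees.
#'
#' @param ps a \code{particle_system}
#' @param vector_pair length-2 vector of particle ids (a, b) defining
#'   the insertion vector b - a
#' @param mesh a \code{membrane_mesh}
#' @param hash optional prebuilt \code{spatial_hash}
#' @param mode depth mode
#' @return list with \code{depth} (Angstrom) and \code{tilt} (degrees)
#' @export
mesh_insertion_geometry <- function(ps, vector_pair, mesh, hash = NULL,
                                    mode = c("projection", "euclidean")) {
  mode <- match.arg(mode)
  if (is.null(hash)) hash <- build_spatial_hash(mesh)
  a <- ps_coords(ps)[match(vector_pair[1], ps$id), ]
  b <- ps_coords(ps)[match(vector_pair[2], ps$id), ]
  if (anyNA(a) || anyNA(b)) stop("vector_pair particle id not found")
  v <- b - a
  if (sqrt(sum(v^2)) < 1e-9) stop("coincident particles: insertion vector undefined")
  com <- ps_center(ps)
  i <- nearest_vertex(com, mesh, hash)
  off <- com - mesh$vertices[i, ]
  nrm <- mesh$normals[i, ]
  depth <- if (mode == "projection") sum(off * nrm)
  else sign(sum(off * nrm)) * sqrt(sum(off^2))
  cosang <- sum(v * nrm) / sqrt(sum(v^2))
  tilt <- acos(pmin(1, pmax(-1, abs(cosang)))) * 180 / pi
  # angle vs the normal *line*, folded into [0, 90]
  tilt <- min(tilt, 180 - tilt)
  list(depth = depth, tilt = tilt)
}
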