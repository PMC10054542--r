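test_that("planar mesh generation follows the grid vertex/triangle count rule", {
  m <- generate_planar_mesh(90, 90, 10)
  expect_equal(nrow(m$vertices), 100)       # (9+1)^2
  expect_equal(nrow(m$triangles), 162)      # 9*9*2
  expect_true(all(m$vertices[, 3] == 0))
  expect_equal(m$normals, matrix(rep(c(0, 0, 1), each = 100), 100, 3))
  m1 <- generate_planar_mesh(1, 1, 1)
  expect_equal(nrow(m1$vertices), 4)
  expect_equal(nrow(m1$triangles), 2)
  expect_error(generate_planar_mesh(5, 5, 10), "resolution")
  # counts across the resolution sweep follow (floor(size/res)+1)^2
  for (res in c(10, 9, 5, 3, 1)) {
    mm <- generate_planar_mesh(90, 90, res)
    expect_equal(nrow(mm$vertices), (floor(90 / res) + 1)^2)
    expect_equal(nrow(mm$triangles), 2 * floor(90 / res)^2)
  }
})

test_that("spherical curvature bends vertices onto the sphere", {
  m <- generate_planar_mesh(60, 60, 5)
  r <- 100
  ms <- apply_spherical_curvature(m, r)
  v <- ms$vertices
  # every vertex lies on the sphere centred at (0, 0, -r)
  expect_equal(sqrt(v[, 1]^2 + v[, 2]^2 + (v[, 3] + r)^2),
               rep(r, nrow(v)), tolerance = 1e-9)
  ctr <- which(v[, 1] == 0 & v[, 2] == 0)
  expect_equal(unname(v[ctr, 3]), 0)
  # flat limit
  mf <- apply_spherical_curvature(m, 1e9)
  expect_true(all(abs(mf$vertices[, 3]) < 1e-2))
  # radius too small for the mesh extent
  expect_error(apply_spherical_curvature(m, 20), "minimal admissible")
  # normals stay unit length after recomputation
  expect_equal(sqrt(rowSums(ms$normals^2)), rep(1, nrow(v)),
               tolerance = 1e-9)
})

test_that("OBJ and PLY files round-trip generated meshes", {
  m <- generate_planar_mesh(90, 90, 10)
  for (fmt in c("obj", "ply")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    back <- load_mesh(path)
    expect_equal(back$vertices, m$vertices, ignore_attr = TRUE,
                 tolerance = 1e-7)
    expect_equal(back$triangles, m$triangles, ignore_attr = TRUE)
    expect_equal(back$normals, m$normals, ignore_attr = TRUE,
                 tolerance = 1e-7)
  }
  # missing normals are recomputed to unit length
  path <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  back <- load_mesh(path)
  expect_equal(sqrt(rowSums(back$normals^2)), rep(1, 3))
  expect_error(suppressWarnings(load_mesh(tempfile(fileext = ".obj"))))
  empty <- tempfile(fileext = ".obj"); writeLines(character(), empty)
  expect_error(load_mesh(empty), "empty")
})

test_that("inconsistent winding is reoriented and degenerate faces dropped", {
  path <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 1 1 0",
               "vn 0 0 1", "vn 0 0 1", "vn 0 0 1", "vn 0 0 1",
               "f 1 2 4", "f 1 4 3", "f 1 3 4"), path)
  # third face winds against the vertex normals
  expect_warning(m <- load_mesh(path), "reoriented")
  expect_equal(nrow(m$triangles), 3)
  # degenerate triangle
  path2 <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3", "f 1 1 2"),
             path2)
  expect_message(m2 <- load_mesh(path2), "degenerate")
  expect_equal(nrow(m2$triangles), 1)
})

test_that("nearest-vertex queries match brute force", {
  set.seed(42)
  m <- generate_planar_mesh(90, 90, 7)
  ms <- apply_spherical_curvature(m, 120)
  hash <- build_spatial_hash(ms)
  pts <- cbind(runif(300, -60, 60), runif(300, -60, 60),
               runif(300, -40, 40))
  for (k in seq_len(nrow(pts))) {
    d2 <- colSums((t(ms$vertices) - pts[k, ])^2)
    expect_equal(nearest_vertex(pts[k, ], ms, hash),
                 which.min(d2))
  }
  # a point identical to a vertex resolves to that vertex
  expect_equal(nearest_vertex(ms$vertices[57, ], ms, hash), 57)
  # far outside the bounds the ring search still resolves
  expect_equal(nearest_vertex(c(500, 500, 500), ms, hash),
               which.min(colSums((t(ms$vertices) - c(500, 500, 500))^2)))
})

test_that("projection-mode depth on a planar mesh is the analytic height", {
  for (res in c(10, 4, 1)) {
    m <- generate_planar_mesh(90, 90, res)
    expect_equal(signed_depth(c(13.2, 41.7, 5.0), m), 5.0,
                 tolerance = 1e-9)
    expect_equal(signed_depth(c(-8.05, 3.33, -17.2), m), -17.2,
                 tolerance = 1e-9)
  }
  m <- generate_planar_mesh(20, 20, 2)
  expect_equal(signed_depth(m$vertices[5, ], m), 0)
})

test_that("euclidean-mode depth error is bounded by the grid half-diagonal", {
  set.seed(9)
  pts <- cbind(runif(40, -30, 30), runif(40, -30, 30),
               runif(40, -20, 20))
  err_by_res <- vapply(c(10, 5, 2, 1), function(res) {
    m <- generate_planar_mesh(90, 90, res)
    z <- signed_depth(pts, m, mode = "euclidean")
    errs <- abs(z - pts[, 3])
    expect_true(all(errs <= sqrt(2) * res / 2 + 1e-9))
    mean(errs)
  }, 1.0)
  # finer grids reduce the mean depth error
  expect_true(all(diff(err_by_res) <= 1e-12))
  expect_lt(err_by_res[4], err_by_res[1])
})

test_that("depth against a curved mesh matches the analytic sphere", {
  r <- 100
  m <- apply_spherical_curvature(generate_planar_mesh(90, 90, 1), r)
  hash <- build_spatial_hash(m)
  set.seed(3)
  centre <- c(0, 0, -r)
  for (k in 1:25) {
    lat <- c(runif(1, -25, 25), runif(1, -25, 25))
    u <- c(lat, sqrt(r^2 - sum(lat^2)))
    u <- u / sqrt(sum(u^2))
    off <- runif(1, -10, 10)
    p <- centre + u * (r + off)
    expect_equal(signed_depth(p, m, hash), off, tolerance = 0.05)
  }
})

test_that("mesh-based energies match the analytic planar membrane", {
  ps <- random_system(100, seed = 5, spread = 25)
  geom <- membrane_geometry()
  analytic <- total_energy(ps, planar_membrane(geom))
  mm <- mesh_membrane(generate_planar_mesh(90, 90, 1), geom)
  meshy <- total_energy(ps, mm)
  expect_equal(meshy$e_imp, analytic$e_imp, tolerance = 1e-4)
  expect_lt(abs(meshy$e_imp - analytic$e_imp), 1e-4)
})

test_that("insertion geometry against a mesh reduces to the planar frame", {
  ps <- make_fixture("barrel_shell", size = 30)
  ps <- ps_rotate(ps, rotation_matrix(c(0, 1, 0), 35))
  ps <- ps_translate(ps, c(4, -6, 7))
  vp <- c(ps$id[1], ps$id[nrow(ps)])
  m <- generate_planar_mesh(120, 120, 1)
  mig <- mesh_insertion_geometry(ps, vp, m)
  ref <- insertion_metrics(ps, planar_membrane(membrane_geometry()), vp)
  expect_equal(mig$depth, ref$depth, tolerance = 1e-6)
  expect_equal(mig$tilt, ref$tilt, tolerance = 0.5)
  # degenerate pair
  expect_error(mesh_insertion_geometry(ps, c(ps$id[1], ps$id[1]), m),
               "coincident")
})

test_that("multiple meshes act as independent membranes via nearest depth", {
  geom <- membrane_geometry()
  m1 <- generate_planar_mesh(60, 60, 5)
  m2v <- m1$vertices; m2v[, 3] <- 40
  m2 <- membrane_mesh(m2v, m1$triangles, m1$normals, resolution = 5)
  mm <- mesh_membrane(list(m1, m2), geom)
  d <- membrane_depth(mm, rbind(c(0, 0, 5), c(0, 0, 36)))
  expect_equal(d$z, c(5, -4))
})
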