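test_that("oriented bounding box reads exact box extents, rotated or not", {
  box <- make_box_cloud(c(10, 5, 2), step = 0.5)
  expect_equal(obb_dimensions(box), c(L = 10, W = 5, H = 2),
               tolerance = 1e-9)
  rot <- rotate_cloud(box, rand_rotation(9), shift = c(3, -2, 7))
  expect_equal(obb_dimensions(rot), c(L = 10, W = 5, H = 2),
               tolerance = 1e-6)
})

test_that("a densely sampled ellipsoid yields its axis lengths within 2%", {
  g <- generate_grain(grain_spec("filled", semi_axes = c(3.5, 1.5, 1.0),
                                 n_points = 3000), seed = 2)
  d <- obb_dimensions(rotate_cloud(g, rand_rotation(4)))
  expect_equal(unname(d), c(7, 3, 2), tolerance = 0.02)
})

test_that("planar grids triangulate into the combinatorial triangle count", {
  for (rc in list(c(5, 4), c(8, 8), c(3, 7))) {
    grid <- make_grid_cloud(rc[1], rc[2])
    mesh <- triangulate_surface(grid, method = "planar")
    expect_equal(nrow(mesh$triangles), 2 * (rc[1] - 1) * (rc[2] - 1))
    expect_false(any(mesh$triangles[, 1] == mesh$triangles[, 2]))
  }
})

test_that("closed surfaces mesh watertight with sphere topology", {
  sph <- make_sphere_cloud(1500, r = 5, seed = 3)
  mesh <- triangulate_surface(sph, method = "auto")  # auto picks spherical
  expect_equal(nrow(boundary_edges(mesh)), 0)
  expect_equal(euler_characteristic(mesh), 2)
})

test_that("hole filling restores watertightness and is idempotent", {
  sph <- make_sphere_cloud(800, r = 5, seed = 5)
  mesh <- triangulate_surface(sph, method = "spherical")
  expect_identical(fill_holes(mesh)$triangles, mesh$triangles)  # no holes
  holey <- triangle_mesh(mesh$vertices, mesh$triangles[-c(5, 100), ])
  expect_gt(nrow(boundary_edges(holey)), 0)
  filled <- fill_holes(holey)
  expect_equal(nrow(boundary_edges(filled)), 0)
  expect_equal(euler_characteristic(filled), 2)
  v0 <- mesh_volume(mesh)
  expect_equal(mesh_volume(filled), v0, tolerance = 0.01)
})

test_that("Heron area is exact on a 3-4-5 triangle and matches cross products", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(surface_area(tri)), 6, tolerance = 1e-12)
  # degenerate triangle contributes zero and is counted
  deg <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       matrix(c(1, 2, 3), 1))
  s <- surface_area(deg)
  expect_equal(as.numeric(s), 0)
  expect_equal(attr(s, "n_degenerate"), 1)

  mesh <- triangulate_surface(make_sphere_cloud(1000, r = 5, seed = 6),
                              method = "spherical")
  v <- mesh$vertices
  t <- mesh$triangles
  ab <- v[t[, 2], ] - v[t[, 1], ]
  ac <- v[t[, 3], ] - v[t[, 1], ]
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  oracle <- sum(0.5 * sqrt(rowSums(cx^2)))
  expect_equal(as.numeric(surface_area(mesh)), oracle, tolerance = 1e-9)
})

test_that("sphere and cube geometry match closed forms within 3%", {
  sph <- make_sphere_cloud(3000, r = 5, seed = 7)
  mesh <- fill_holes(triangulate_surface(sph, method = "spherical"))
  expect_equal(as.numeric(surface_area(mesh)), 4 * pi * 25, tolerance = 0.03)
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 125, tolerance = 0.03)

  cube <- make_box_cloud(c(1, 1, 1), step = 0.05)
  cmesh <- fill_holes(triangulate_surface(cube, method = "spherical"))
  expect_equal(mesh_volume(cmesh), 1, tolerance = 0.03)
})

test_that("volume requires a watertight mesh", {
  sph <- make_sphere_cloud(500, r = 5, seed = 8)
  mesh <- triangulate_surface(sph, method = "spherical")
  holey <- triangle_mesh(mesh$vertices, mesh$triangles[-1, ])
  expect_error(mesh_volume(holey), "fill_holes")
})

test_that("projections of sphere and rectangle match disc and box formulas", {
  sph <- make_sphere_cloud(2500, r = 5, seed = 9)
  for (ax in c("x", "y", "z")) {
    pr <- project_traits(sph, ax)
    expect_equal(unname(pr["PA"]), pi * 25, tolerance = 0.03)
    expect_equal(unname(pr["PP"]), 2 * pi * 5, tolerance = 0.03)
  }
  rect <- make_box_cloud(c(10, 5, 0.2), step = 0.25)
  pr <- project_traits(point_cloud(rect$xyz), "z")
  expect_equal(unname(pr["PA"]), 50, tolerance = 0.02)
  expect_equal(unname(pr["PP"]), 30, tolerance = 0.02)
  flat <- point_cloud(cbind(1:10, 1:10 * 2, 0))
  expect_error(project_traits(flat, "z"), "collinear")
})

test_that("the eleven traits of an ellipsoid match analytic values within 5%", {
  a <- 3.5; b <- 1.5; cc <- 1.0
  g <- generate_grain(grain_spec("filled", semi_axes = c(a, b, cc),
                                 n_points = 4000), seed = 10)
  tr <- extract_traits(g)
  truth <- c(L = 2 * a, W = 2 * b, H = 2 * cc,
             V = 4 / 3 * pi * a * b * cc,
             S0 = ellipsoid_surface(a, b, cc),
             PA_x = pi * b * cc, PA_y = pi * a * cc, PA_z = pi * a * b,
             PP_x = ellipse_perimeter(b, cc),
             PP_y = ellipse_perimeter(a, cc),
             PP_z = ellipse_perimeter(a, b))
  for (nm in names(truth))
    expect_equal(unname(tr[nm]), unname(truth[nm]), tolerance = 0.05,
                 label = nm)
})

test_that("traits are invariant to rigid motion", {
  g <- generate_grain(grain_spec("unfilled", n_points = 2000), seed = 11)
  base <- extract_traits(g)
  for (s in 1:5) {
    moved <- rotate_cloud(g, rand_rotation(s), shift = rnorm(3, sd = 10))
    tr <- extract_traits(moved)
    expect_equal(tr, base, tolerance = 1e-3)
  }
})

test_that("traits obey the dimensional scaling laws under doubling", {
  g <- generate_grain(grain_spec("filled", n_points = 1500), seed = 12)
  base <- extract_traits(g)
  doubled <- g
  doubled$xyz <- 2 * g$xyz
  tr <- extract_traits(doubled)
  lengths <- c("L", "W", "H", "PP_x", "PP_y", "PP_z")
  areas <- c("S0", "PA_x", "PA_y", "PA_z")
  expect_equal(tr[lengths], 2 * base[lengths], tolerance = 1e-6)
  expect_equal(tr[areas], 4 * base[areas], tolerance = 1e-6)
  expect_equal(unname(tr["V"]), unname(8 * base["V"]), tolerance = 1e-6)
})

test_that("unfilled grains lose volume against the matched filled envelope", {
  tab <- extract_trait_table(list(
    generate_grain(grain_spec("filled", n_points = 1500), seed = 13),
    generate_grain(grain_spec("unfilled", n_points = 1500), seed = 13)))
  expect_lt(tab$V[2], tab$V[1])
  # compactness relative to the shared generating envelope (8abc)
  expect_lt(tab$V[2] / (7 * 3 * 2), tab$V[1] / (7 * 3 * 2))
})
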