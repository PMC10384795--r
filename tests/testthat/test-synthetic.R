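test_that("grain_spec enforces its geometric invariants", {
  expect_error(grain_spec(semi_axes = c(1, 2, 3)), "a >= b >= c")
  expect_error(grain_spec(semi_axes = c(3, 2, -1)), "positive")
  expect_error(grain_spec("unfilled", cavity_depth = 1.5,
                          semi_axes = c(3.5, 1.5, 1)), "cavity_depth")
  expect_error(grain_spec("unfilled", cavity_extent = 1.2), "cavity_extent")
  expect_error(grain_spec("filled", cavity_depth = 0.3), "filled grains")
})

test_that("grain generation is bit-identical under a fixed seed", {
  sp <- grain_spec("unfilled", n_points = 300)
  g1 <- generate_grain(sp, seed = 42)
  g2 <- generate_grain(sp, seed = 42)
  expect_identical(g1$xyz, g2$xyz)
  expect_identical(g1$normals, g2$normals)
  g3 <- generate_grain(sp, seed = 43)
  expect_false(identical(g1$xyz, g3$xyz))
})

test_that("filled ellipsoid encloses the analytic volume within 3%", {
  sp <- grain_spec("filled", semi_axes = c(3.5, 1.5, 1.0), n_points = 2000)
  g <- generate_grain(sp, seed = 7)
  mesh <- fill_holes(triangulate_surface(g, method = "spherical"))
  v_true <- 4 / 3 * pi * 3.5 * 1.5 * 1.0
  expect_lt(abs(mesh_volume(mesh) - v_true) / v_true, 0.03)
})

test_that("the cavity strictly removes enclosed volume at equal envelope", {
  vol <- function(cl, depth) {
    sp <- grain_spec(cl, semi_axes = c(3.5, 1.5, 1.0), cavity_depth = depth,
                     n_points = 2000)
    g <- generate_grain(sp, seed = 11)
    mesh_volume(fill_holes(triangulate_surface(g, method = "spherical")))
  }
  expect_lt(vol("unfilled", 0.55), vol("filled", 0))
})

test_that("single-grain noiseless scene has labels exactly {0, 1}", {
  sc <- generate_scene(scene_spec(rows = 1, cols = 1, noise_sd = 0,
                                  outlier_fraction = 0, plate_points = 500,
                                  seed = 3),
                       list(grain_spec("filled", n_points = 300)))
  expect_setequal(unique(sc$labels), c(0L, 1L))
})

test_that("default scene layout produces 25 grains at the grid spacing", {
  specs <- lapply(1:25, function(i)
    grain_spec(c("filled", "unfilled")[1 + i %% 2], n_points = 200))
  sc <- generate_scene(scene_spec(plate_points = 2000, seed = 5), specs)
  expect_setequal(unique(sc$labels), 0:25)
  # nearest-neighbour distance between recomputed grain centroids
  ctr <- t(vapply(1:25, function(id)
    colMeans(sc$xyz[sc$labels == id & !sc$meta$outlier, , drop = FALSE]),
    numeric(3)))
  dmat <- as.matrix(dist(ctr))
  diag(dmat) <- Inf
  expect_true(all(abs(apply(dmat, 1, min) - 20) < 1))
})

test_that("scenes reject grains that would overlap or overflow the plate", {
  expect_error(generate_scene(scene_spec(rows = 1, cols = 2, spacing = 10),
                              replicate(2, grain_spec(n_points = 100),
                                        simplify = FALSE)),
               "touch")
  expect_error(generate_scene(scene_spec(rows = 8, cols = 8, spacing = 20,
                                         plate_size = c(100, 100)),
                              replicate(64, grain_spec(n_points = 100),
                                        simplify = FALSE)),
               "plate")
})

test_that("datasets are balanced and seed-deterministic", {
  d1 <- generate_dataset(10, n_points = 200, seed = 9)
  d2 <- generate_dataset(10, n_points = 200, seed = 9)
  labs <- vapply(d1, function(g) g$class_label, "")
  expect_equal(sum(labs == "filled"), 10)
  expect_equal(sum(labs == "unfilled"), 10)
  expect_identical(labs, vapply(d2, function(g) g$class_label, ""))
  expect_identical(d1[[3]]$xyz, d2[[3]]$xyz)
})

test_that("trait extraction recovers the sampled length parameter", {
  d <- generate_dataset(15, n_points = 400, seed = 21)
  specs <- attr(d, "specs")
  L <- vapply(d, function(g) unname(obb_dimensions(g)["L"]), 0)
  expect_gt(cor(L, 2 * specs$a), 0.9)
})
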