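test_that("MLS plane fit matches the covariance eigen-oracle", {
  set.seed(14)
  # coplanar points: zero residual, axis normal
  flat <- cbind(runif(50), runif(50), 0)
  pm <- mls_fit_plane(flat)
  expect_equal(abs(pm$normal[3]), 1, tolerance = 1e-9)
  expect_equal(pm$S, 0, tolerance = 1e-9)
  # 100 random neighbourhoods vs the smallest eigenvector
  for (i in 1:100) {
    nb <- matrix(rnorm(36), 12, 3) %*% diag(c(2, 1, 0.1))
    fit <- mls_fit_plane(nb)
    ev <- eigen(cov(nb), symmetric = TRUE)$vectors[, 3]
    ang <- acos(pmin(1, abs(sum(fit$normal * ev))))
    expect_lt(ang, 1e-6)
  }
  expect_error(mls_fit_plane(cbind(1:5, 1:5 * 2, 1:5 * 3)), "collinear")
})

test_that("the MLS residual S is invariant to rigid motion", {
  set.seed(15)
  nb <- matrix(rnorm(60), 20, 3) %*% diag(c(2, 1, 0.2))
  s0 <- mls_fit_plane(nb)$S
  for (i in 1:10) {
    R <- rand_rotation(i)
    moved <- nb %*% t(R) + matrix(rnorm(3), 20, 3, byrow = TRUE)
    expect_equal(mls_fit_plane(moved)$S, s0, tolerance = 1e-9)
  }
})

test_that("estimated normals follow the analytic sphere radial field", {
  sph <- make_sphere_cloud(1500, r = 5, seed = 4)
  est <- estimate_normals(point_cloud(sph$xyz), search_radius = 0.8)
  ang <- acos(pmin(1, abs(rowSums(est$normals * sph$xyz / 5))))
  expect_lt(median(ang) * 180 / pi, 5)
})

test_that("planar patch normals are parallel and flipping negates them", {
  set.seed(16)
  patch <- point_cloud(cbind(runif(300, 0, 5), runif(300, 0, 5), 0))
  est <- estimate_normals(patch, search_radius = 0.8)
  ref <- est$normals[1, ]
  ang <- acos(pmin(1, abs(as.vector(est$normals %*% ref))))
  expect_true(all(ang * 180 / pi < 1))
  flipped <- flip_normals(est)
  expect_equal(flipped$normals, -est$normals)
  expect_error(flip_normals(patch), "no normals")
})

test_that("consistent orientation preserves concavity where outward forcing cannot", {
  g <- generate_grain(grain_spec("unfilled", semi_axes = c(3.5, 1.5, 1),
                                 cavity_depth = 0.6, n_points = 2000),
                      seed = 19)
  est <- estimate_normals(point_cloud(g$xyz), search_radius = 0.6)
  agree <- mean(rowSums(est$normals * g$normals) > 0)
  # global sign is arbitrary; the field should match the ground truth
  expect_gt(max(agree, 1 - agree), 0.98)
})

test_that("up-sampling keeps originals, hits the target count and the surface", {
  sph <- make_sphere_cloud(1000, r = 5, seed = 5)
  same <- mls_upsample(sph, factor = 1)
  expect_equal(same$xyz, sph$xyz)
  up <- mls_upsample(sph, factor = 4, search_radius = 1.2, seed = 3)
  expect_equal(n_points(up), 4000)
  expect_identical(up$xyz[1:1000, ], sph$xyz)  # originals untouched
  radial_err <- abs(sqrt(rowSums(up$xyz[1001:4000, ]^2)) - 5)
  expect_lt(mean(radial_err), 0.1)
  expect_error(mls_upsample(sph, factor = 0.5), ">= 1")
})

test_that("up-sampling does not worsen density uniformity", {
  sph <- make_sphere_cloud(800, r = 5, seed = 6)
  cv10 <- function(xyz) {
    nn <- knn_indices(xyz, 10)
    d <- sqrt(rowSums((xyz - xyz[nn[, 10], ])^2))
    sd(d) / mean(d)
  }
  before <- cv10(sph$xyz)
  after <- cv10(mls_upsample(sph, factor = 3, search_radius = 1.2,
                             seed = 2)$xyz)
  expect_lte(after, before + 0.02)
})

test_that("fixed-count resampling subsets, pads and reproduces by seed", {
  g <- generate_grain(grain_spec("filled", n_points = 1500), seed = 3)
  r1 <- resample_fixed(g, 1024, seed = 5)
  expect_equal(n_points(r1), 1024)
  r2 <- resample_fixed(g, 1024, seed = 5)
  expect_identical(r1$xyz, r2$xyz)
  # input exactly n: output is a permutation
  small <- subset_cloud(g, 1:200)
  perm <- resample_fixed(small, 200, seed = 2)
  expect_setequal(round(perm$xyz[, 1], 9), round(small$xyz[, 1], 9))
  # padding path up-samples first
  padded <- resample_fixed(small, 500, seed = 4)
  expect_equal(n_points(padded), 500)
  expect_error(resample_fixed(g, 0), "positive")
})

test_that("unit-sphere normalization is exact, invertible and idempotent", {
  g <- generate_grain(grain_spec("filled", n_points = 400), seed = 9)
  nm <- normalize_unit_sphere(g)
  expect_equal(max(sqrt(rowSums(nm$xyz^2))), 1, tolerance = 1e-9)
  expect_equal(colMeans(nm$xyz), c(x = 0, y = 0, z = 0), tolerance = 1e-9)
  back <- denormalize_cloud(nm)
  expect_equal(back$xyz, g$xyz, tolerance = 1e-9)
  again <- normalize_unit_sphere(nm)
  expect_equal(again$xyz, nm$xyz, tolerance = 1e-9)
  expect_error(normalize_unit_sphere(subset_cloud(g, 1)), "single-point")
})

test_that("the fixed-count text dataset round-trips with a stratified split", {
  grains <- generate_dataset(10, n_points = 400, seed = 13)
  ds <- prepare_dataset(grains, variant = "raw", n_points = 256, seed = 2)
  expect_length(ds$train, 16)
  expect_length(ds$test, 4)
  expect_equal(as.vector(table(ds$labels[ds$train])), c(8, 8))
  expect_equal(as.vector(table(ds$labels[ds$test])), c(2, 2))

  dir <- file.path(tempdir(), "modelnet_test")
  write_modelnet_dataset(ds, dir)
  line1 <- strsplit(readLines(list.files(file.path(dir, "filled"),
                                         full.names = TRUE)[1], n = 1),
                    ",")[[1]]
  expect_length(line1, 6)
  expect_false(anyNA(as.numeric(line1)))

  back <- read_modelnet_dataset(dir)
  expect_equal(length(back$samples), 20)
  expect_equal(back$n_points, 256)
  # order: train ids then test ids, per-class numbering
  m_written <- ds$samples[[ds$train[1]]]
  expect_equal(back$samples[[1]], m_written, tolerance = 1e-5,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("every enhancement variant emits complete six-channel samples", {
  g <- generate_dataset(2, n_points = 500, seed = 17)[[1]]
  for (v in c("raw", "up", "normal", "both")) {
    e <- enhance_grain(g, variant = v, n_points = 256, seed = 3)
    expect_equal(n_points(e), 256)
    expect_false(anyNA(e$normals))
    expect_equal(sqrt(rowSums(e$normals^2)), rep(1, 256), tolerance = 1e-6)
    expect_equal(max(sqrt(rowSums(e$xyz^2))), 1, tolerance = 1e-9)
  }
})
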