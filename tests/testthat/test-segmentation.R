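test_that("pca_frame matches a brute-force covariance eigendecomposition", {
  set.seed(5)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(300), 100, 3) %*% diag(c(3, 1.5, 0.5))
    fr <- pca_frame(xyz)
    # independent oracle: covariance from raw sums, base eigensolver
    n <- nrow(xyz)
    mu <- colSums(xyz) / n
    cc <- (t(xyz) %*% xyz - n * tcrossprod(mu)) / (n - 1)
    ev <- eigen(cc, symmetric = TRUE)
    expect_equal(fr$eigenvalues, ev$values, tolerance = 1e-8)
    for (i in 1:3)
      expect_equal(abs(sum(fr$rotation[i, ] * ev$vectors[, i])), 1,
                   tolerance = 1e-8)
  }
  expect_equal(tcrossprod(pca_frame(matrix(rnorm(60), 20, 3))$rotation),
               diag(3), tolerance = 1e-9)
})

test_that("pca_frame is equivariant under rotation and fails on degenerate input", {
  set.seed(8)
  xyz <- matrix(rnorm(450), 150, 3) %*% diag(c(4, 2, 1))
  fr <- pca_frame(xyz)
  for (s in 1:20) {
    R <- rand_rotation(s)
    fr_rot <- pca_frame(xyz %*% t(R))
    for (i in 1:3)
      expect_equal(abs(sum(fr_rot$rotation[i, ] * (R %*% fr$rotation[i, ]))),
                   1, tolerance = 1e-6)
  }
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(pca_frame(line), "collinear")
})

test_that("the frame transform centres, orders variance, and inverts exactly", {
  set.seed(2)
  pc <- point_cloud(matrix(rnorm(300), 100, 3) %*% diag(c(1, 5, 2)) +
                      matrix(10, 100, 3))
  al <- transform_to_frame(pc)
  expect_equal(colMeans(al$xyz), c(x = 0, y = 0, z = 0), tolerance = 1e-9)
  v <- apply(al$xyz, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  back <- transform_from_frame(al)
  expect_equal(back$xyz, pc$xyz, tolerance = 1e-9)
  # isometry: pairwise distances preserved
  idx <- cbind(sample(100, 30), sample(100, 30))
  d0 <- sqrt(rowSums((pc$xyz[idx[, 1], ] - pc$xyz[idx[, 2], ])^2))
  d1 <- sqrt(rowSums((al$xyz[idx[, 1], ] - al$xyz[idx[, 2], ])^2))
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("RANSAC recovers a noiseless plane exactly", {
  set.seed(4)
  xyz <- cbind(runif(400, -10, 10), runif(400, -10, 10), 0)
  pm <- ransac_plane(xyz, distance_threshold = 0.1, seed = 1)
  expect_equal(abs(pm$normal[3]), 1, tolerance = 1e-12)
  expect_true(all(pm$inlier_mask))
})

test_that("RANSAC separates a noisy plane from grains and outliers", {
  set.seed(10)
  n_pl <- 2000
  plate <- cbind(runif(n_pl, -20, 20), runif(n_pl, -20, 20),
                 rnorm(n_pl, sd = 0.02))
  g <- generate_grain(grain_spec("filled", n_points = 600), seed = 2)
  grain <- g$xyz %*% t(rand_rotation(3)) + matrix(c(5, 5, 3.6), 600, 3,
                                                  byrow = TRUE)
  n_out <- 100  # 5% sparse outliers well off the plane
  outl <- cbind(runif(n_out, -20, 20), runif(n_out, -20, 20),
                runif(n_out, 1, 10))
  xyz <- rbind(plate, grain, outl)
  truth <- rep(c("plate", "grain", "outlier"), c(n_pl, 600, n_out))
  pm <- ransac_plane(xyz, distance_threshold = 0.15, seed = 7)
  expect_gte(mean(pm$inlier_mask[truth == "plate"]), 0.99)
  expect_lte(mean(pm$inlier_mask[truth == "grain"]), 0.01)
})

test_that("RANSAC is seed-reproducible and monotone in its threshold", {
  set.seed(12)
  xyz <- rbind(cbind(runif(500, -5, 5), runif(500, -5, 5),
                     rnorm(500, sd = 0.05)),
               matrix(runif(150, -5, 5), 50, 3))
  p1 <- ransac_plane(xyz, seed = 3)
  p2 <- ransac_plane(xyz, seed = 3)
  expect_identical(p1$normal, p2$normal)
  expect_identical(p1$inlier_mask, p2$inlier_mask)
  counts <- vapply(c(0.05, 0.15, 0.5),
                   function(th) ransac_plane(xyz, distance_threshold = th,
                                             seed = 3)$n_inliers, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("region growing isolates spatially disjoint surfaces", {
  g <- generate_grain(grain_spec("filled", n_points = 500), seed = 6)
  lab1 <- region_grow(g, min_cluster_size = 50)
  expect_equal(setdiff(unique(lab1), 0L), 1L)

  s1 <- make_sphere_cloud(400, r = 3, seed = 1)
  s2 <- make_sphere_cloud(400, r = 3, seed = 2)
  s2$xyz <- s2$xyz + matrix(c(20, 0, 0), 400, 3, byrow = TRUE)
  both <- point_cloud(rbind(s1$xyz, s2$xyz))
  lab2 <- region_grow(both, min_cluster_size = 50)
  expect_equal(length(setdiff(unique(lab2), 0L)), 2L)
})

test_that("region growing estimates missing normals and matches a supplied field", {
  g <- generate_grain(grain_spec("filled", n_points = 300), seed = 1)
  stats <- graincloud:::local_surface_stats(g$xyz, 30)
  lab_auto <- region_grow(point_cloud(g$xyz), min_cluster_size = 50)
  lab_given <- region_grow(point_cloud(g$xyz), normals = stats$normals,
                           curvature = stats$curvature,
                           min_cluster_size = 50)
  expect_equal(lab_auto, lab_given)
})

test_that("a small scene segments into its grains with pure clusters", {
  specs <- replicate(4, grain_spec("filled", n_points = 500),
                     simplify = FALSE)
  sc <- generate_scene(scene_spec(rows = 2, cols = 2, plate_points = 3000,
                                  plate_size = c(60, 60), seed = 8), specs)
  grains <- segment_scene(sc, min_cluster_size = 100, seed = 2)
  expect_length(grains, 4)
  ev <- evaluate_segmentation(grains, sc)
  expect_gte(ev$min_purity, 0.99)
  expect_gte(ev$min_completeness, 0.9)
  # grain indices never overlap the fitted plate
  frame <- pca_frame(sc)
  pm <- ransac_plane(transform_to_frame(sc, frame), seed = 2)
  plate_idx <- which(pm$inlier_mask)
  for (g in grains)
    expect_length(intersect(g$meta$indices, plate_idx), 0)
  # reproducible ordering: row-major by centroid
  ctr <- t(vapply(grains, function(g) colMeans(g$xyz), numeric(3)))
  expect_true(all(diff(order(round(ctr[, 2] / 10), ctr[, 1])) == 1))
})
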