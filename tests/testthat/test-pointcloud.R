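test_that("point_cloud construction validates its inputs", {
  expect_error(point_cloud(matrix(1:8, 2, 4)), "3 columns")
  expect_error(point_cloud(matrix(1:6, 2, 3), normals = matrix(0, 3, 3)),
               "shape")
  expect_error(point_cloud(matrix(1:6, 2, 3), labels = 1L), "one entry")
  pc <- point_cloud(matrix(rnorm(30), 10, 3), labels = rep(1:2, 5))
  expect_s3_class(pc, "point_cloud")
  expect_equal(n_points(pc), 10)
})

test_that("subset_cloud keeps normals, labels and outlier flags aligned", {
  set.seed(1)
  xyz <- matrix(rnorm(30), 10, 3)
  nrm <- xyz / sqrt(rowSums(xyz^2))
  pc <- point_cloud(xyz, normals = nrm, labels = 1:10,
                    meta = list(outlier = rep(c(TRUE, FALSE), 5)))
  sub <- subset_cloud(pc, c(2, 5, 9))
  expect_equal(sub$labels, c(2L, 5L, 9L))
  expect_equal(sub$xyz, xyz[c(2, 5, 9), ], ignore_attr = TRUE)
  expect_equal(unname(sub$normals), unname(nrm[c(2, 5, 9), ]))
  expect_equal(sub$meta$outlier, c(FALSE, TRUE, TRUE))
})

test_that("PLY, PCD and XYZ files round-trip coordinates, normals, labels", {
  set.seed(7)
  pc <- point_cloud(matrix(rnorm(60), 20, 3),
                    normals = {
                      m <- matrix(rnorm(60), 20, 3)
                      m / sqrt(rowSums(m^2))
                    },
                    labels = rep(0:1, 10))
  for (ext in c("ply", "pcd", "xyz")) {
    path <- file.path(tempdir(), paste0("cloud.", ext))
    write_cloud(pc, path)
    back <- read_cloud(path)
    expect_equal(back$xyz, pc$xyz, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(unname(back$normals), unname(pc$normals), tolerance = 1e-6)
    expect_equal(back$labels, pc$labels)
    unlink(c(path, paste0(path, ".labels.csv")))
  }
})

test_that("neighbour searches agree with brute-force distances", {
  set.seed(3)
  xyz <- matrix(rnorm(150), 50, 3)
  d <- as.matrix(dist(xyz))
  nn <- knn_indices(xyz, 5)
  for (i in c(1, 17, 50)) {
    expect_equal(sort(nn[i, ]), sort(order(d[i, ])[2:6]))
  }
  rn <- radius_neighbors(xyz, xyz[1:3, , drop = FALSE], 1.0)
  for (i in 1:3) expect_setequal(rn[[i]], which(d[i, ] <= 1.0))
})
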