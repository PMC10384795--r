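# Tiny network configuration used throughout: 64 points, 32/16 centroids.
tiny_config <- function(...) {
  pointnet_config(n_points = 64, sa_point_counts = c(64, 32, 16),
                  widths = "reduced", ...)
}

tiny_sample <- function(seed) {
  set.seed(seed)
  s <- matrix(rnorm(64 * 6), 64, 6)
  s[, 1:3] <- s[, 1:3] / max(sqrt(rowSums(s[, 1:3]^2)))
  s[, 4:6] <- s[, 4:6] / sqrt(rowSums(s[, 4:6]^2))
  s
}

test_that("farthest-point sampling picks line endpoints first and matches brute force", {
  line <- cbind(seq(0, 10, length.out = 21), 0, 0)
  sel <- farthest_point_sampling(line, 3)
  expect_setequal(sel[1:2], c(1, 21))
  set.seed(41)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(90), 30, 3)
    expect_equal(farthest_point_sampling(xyz, 12), naive_fps(xyz, 12))
  }
})

test_that("grouping enforces the exact group size with truncation and padding", {
  set.seed(42)
  xyz <- matrix(rnorm(150), 50, 3)
  g <- sample_and_group(xyz, n_centroids = 10, radius = 0.5, group_size = 8,
                        pad_pool = 16)
  expect_equal(dim(g$groups), c(10, 8))
  expect_true(all(g$groups >= 1 & g$groups <= 50))
  # all-points case: centroids are a permutation
  g2 <- sample_and_group(xyz, n_centroids = 50, radius = 0.5, group_size = 4)
  expect_setequal(g2$centroid_idx, 1:50)
  expect_error(sample_and_group(xyz, n_centroids = 5, radius = -1,
                                group_size = 4), "radius")
})

test_that("network configuration validates radii and centroid counts", {
  expect_error(pointnet_config(msg_radii = c(0.4, 0.2, 0.1)), "increasing")
  expect_error(pointnet_config(sa_point_counts = c(256, 512, 128)),
               "decreasing")
  expect_error(pointnet_config(n_points = 128,
                               sa_point_counts = c(256, 128, 64)),
               "exceed")
})

test_that("forward pass yields finite logits and the documented point counts", {
  cfg <- pointnet_config(widths = "reduced")
  mdl <- build_pointnet(cfg, seed = 1)
  set.seed(50)
  s <- matrix(rnorm(1024 * 6), 1024, 6)
  s[, 1:3] <- s[, 1:3] / max(sqrt(rowSums(s[, 1:3]^2)))
  fw <- pointnet_forward(mdl, s)
  expect_length(fw$logits, 2)
  expect_true(all(is.finite(fw$logits)))
  expect_equal(unname(fw$sizes), c(1024, 512, 256))
  expect_error(pointnet_forward(mdl, s[1:100, ]), "1024")
})

test_that("eval logits are invariant to input point permutation", {
  cfg <- tiny_config()
  mdl <- build_pointnet(cfg, seed = 3)
  k <- length(mdl$params$head)
  set.seed(7)
  mdl$params$head[[k]]$W[] <- rnorm(length(mdl$params$head[[k]]$W), sd = 0.3)
  s <- tiny_sample(8)
  base <- pointnet_forward(mdl, s)$logits
  for (rep in 1:5) {
    p <- sample(64)
    expect_equal(pointnet_forward(mdl, s[p, ])$logits, base,
                 tolerance = 1e-5)
  }
})

test_that("the additional SA layer adds real trainable parameters", {
  with_extra <- build_pointnet(pointnet_config(widths = "reduced"), seed = 1)
  without <- build_pointnet(pointnet_config(widths = "reduced",
                                            extra_sa_layer = FALSE), seed = 1)
  expect_gt(n_params(with_extra), n_params(without))
})

tiny_dataset <- function(n = 16, seed = 60) {
  set.seed(seed)
  samples <- lapply(seq_len(n), function(i) tiny_sample(seed + i))
  labels <- factor(rep(c("filled", "unfilled"), length.out = n),
                   levels = c("filled", "unfilled"))
  list(samples = samples, labels = labels,
       train = seq_len(n - 4), test = (n - 3):n, n_points = 64)
}

test_that("a one-epoch training run completes with finite loss", {
  ds <- tiny_dataset()
  fit <- train_pointnet(ds, tiny_config(),
                        pointnet_train_config(epochs = 1, seed = 2))
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_loss))
  expect_s3_class(fit, "pointnet_model")
})

test_that("training is bit-reproducible under identical seeds", {
  ds <- tiny_dataset()
  f1 <- train_pointnet(ds, tiny_config(),
                       pointnet_train_config(epochs = 2, seed = 5))
  f2 <- train_pointnet(ds, tiny_config(),
                       pointnet_train_config(epochs = 2, seed = 5))
  expect_identical(f1$history, f2$history)
  expect_identical(unlist(f1$params), unlist(f2$params))
})

test_that("training validates the dataset against the configuration", {
  ds <- tiny_dataset()
  ds$samples[[3]] <- ds$samples[[3]][1:32, ]
  expect_error(train_pointnet(ds, tiny_config(),
                              pointnet_train_config(epochs = 1)), "32 points")
  ds2 <- tiny_dataset()
  ds2$train <- integer(0)
  expect_error(train_pointnet(ds2, tiny_config(),
                              pointnet_train_config(epochs = 1)), "empty")
  ds3 <- tiny_dataset()
  ds3$samples[[1]][5, 4:6] <- NA
  expect_error(train_pointnet(ds3, tiny_config(),
                              pointnet_train_config(epochs = 1)), "normal")
})

test_that("evaluation counts are conserved and match the predictions", {
  ds <- tiny_dataset(n = 20)
  fit <- train_pointnet(ds, tiny_config(),
                        pointnet_train_config(epochs = 1, seed = 4))
  rep <- evaluate_pointnet(fit, ds)
  expect_equal(rep$TP + rep$FP + rep$TN + rep$FN, length(ds$test))
  expect_equal(sum(rep$confusion), length(ds$test))
  misjudged <- sum(rep$predictions != ds$labels[ds$test])
  expect_equal(rep$FP + rep$FN, misjudged)
  expect_length(rep$times, length(ds$test))
})
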