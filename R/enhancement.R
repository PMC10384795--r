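## Point-cloud enhancement --------------------------------------------------
##
## Moving-least-squares (MLS) machinery: local plane fits, per-point normal
## estimation, surface-consistent up-sampling, fixed-count resampling,
## unit-sphere normalization and export in the fixed-count, six-column
## (x,y,z,nx,ny,nz) dataset layout the point-set classifier consumes.

#' Moving-least-squares plane fit of a neighbourhood
#'
#' Finds the plane `a0 x + a1 y + a2 z + b = 0` minimizing the sum of squared
#' point-plane distances `S` over the neighbourhood. The minimizer is the
#' total-least-squares plane: it passes through the neighbourhood centroid
#' with normal along the smallest-eigenvalue eigenvector of the local
#' covariance. The sign convention makes the largest-magnitude normal
#' component positive.
#'
#' @param neighborhood numeric `n x 3` matrix (n >= 3).
#' @return a `plane_model` with the residual sum `S` in `$S`.
#' @export
mls_fit_plane <- function(neighborhood) {
  P <- as.matrix(neighborhood)
  if (nrow(P) < 3) stop("need at least 3 points for a plane fit")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  M <- crossprod(Q)  # n * covariance; same eigenvectors
  ev <- eigen(M, symmetric = TRUE)
  if (ev$values[2] / max(ev$values[1], 1e-300) < 1e-12)
    stop("degenerate neighbourhood: points are collinear, plane undefined")
  nrm <- ev$vectors[, 3]
  if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
  structure(list(normal = nrm, offset = -sum(nrm * ctr),
                 S = max(ev$values[3], 0), inlier_mask = NULL),
            class = "plane_model")
}

#' Estimate per-point normals by MLS plane fits
#'
#' Each point's normal is the MLS plane normal of its radius neighbourhood
#' (k-NN fallback when the neighbourhood is too small). Curvature (surface
#' variation) is stored alongside.
#'
#' Orientation: the plane normal is sign-ambiguous, so a global convention is
#' needed. `"consistent"` (default) propagates the sign through the k-NN
#' graph from an anchor on the convex outer surface (the point farthest from
#' the centroid, oriented away from it), so normals inside a concave cavity
#' correctly point against the centroid direction — the signal that
#' distinguishes unfilled grains. `"outward"`/`"inward"` force every normal
#' to point away from / toward the centroid, which erases concavity.
#'
#' @param cloud a `point_cloud`.
#' @param search_radius neighbourhood radius in mm.
#' @param k_fallback neighbours used when fewer than 3 points fall in the
#'   radius.
#' @param orientation `"consistent"`, `"outward"` or `"inward"`.
#' @return the cloud with `$normals` set, plus `meta$curvature` and
#'   `meta$normal_orientation`.
#' @export
estimate_normals <- function(cloud, search_radius = 0.8, k_fallback = 10,
                             orientation = c("consistent", "outward",
                                             "inward")) {
  orientation <- match.arg(orientation)
  xyz <- cloud$xyz
  n <- nrow(xyz)
  if (n == 0) stop("cloud is empty")
  nbrs <- radius_neighbors(xyz, xyz, search_radius)
  small <- which(lengths(nbrs) < 3)
  if (length(small) > 0) {
    nn_fallback <- knn_indices(xyz, min(k_fallback, n - 1))
    for (i in small) nbrs[[i]] <- c(i, nn_fallback[i, ])
  }
  fr <- cpp_local_frames(xyz, nbrs)
  normals <- fr$normal
  curvature <- fr$curvature
  ctr <- colMeans(xyz)
  if (orientation == "consistent" && n > 2) {
    k <- min(10, n - 1)
    nn <- knn_indices(xyz, k)
    anchor <- which.max(rowSums(sweep(xyz, 2, ctr)^2))
    if (sum(normals[anchor, ] * (xyz[anchor, ] - ctr)) < 0)
      normals[anchor, ] <- -normals[anchor, ]
    visited <- rep(FALSE, n)
    visited[anchor] <- TRUE
    queue <- integer(n)
    queue[1] <- anchor
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      nbs <- nn[cur, ][!visited[nn[cur, ]]]
      if (length(nbs) == 0) next
      flip <- as.vector(normals[nbs, , drop = FALSE] %*% normals[cur, ]) < 0
      normals[nbs[flip], ] <- -normals[nbs[flip], , drop = FALSE]
      visited[nbs] <- TRUE
      queue[tail + seq_along(nbs)] <- nbs
      tail <- tail + length(nbs)
    }
    # disconnected leftovers fall back to the centroid convention
    left <- which(!visited)
    if (length(left) > 0) {
      flip <- rowSums(normals[left, , drop = FALSE] *
                        sweep(xyz[left, , drop = FALSE], 2, ctr)) < 0
      normals[left[flip], ] <- -normals[left[flip], , drop = FALSE]
    }
  } else if (orientation != "consistent") {
    flip <- rowSums(normals * sweep(xyz, 2, ctr)) < 0
    normals[flip, ] <- -normals[flip, , drop = FALSE]
    if (orientation == "inward") normals <- -normals
  }
  cloud$normals <- normals
  colnames(cloud$normals) <- c("nx", "ny", "nz")
  cloud$meta$curvature <- curvature
  cloud$meta$normal_orientation <- orientation
  cloud
}

#' Flip the orientation of a normal field
#' @param cloud a `point_cloud` with normals.
#' @return the cloud with every normal negated.
#' @export
flip_normals <- function(cloud) {
  if (is.null(cloud$normals)) stop("cloud has no normals")
  cloud$normals <- -cloud$normals
  cloud$meta$normal_orientation <-
    switch(cloud$meta$normal_orientation %||% "outward",
           outward = "inward", inward = "outward")
  cloud
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MLS surface up-sampling
#'
#' Increases point density by a given factor: candidate points are drawn
#' uniformly on local MLS tangent discs (disc centre = the seed point
#' projected onto its MLS plane, disc radius = the local point spacing),
#' with seeds chosen proportionally to the surface area each point
#' represents; progressive Poisson-disk thinning then keeps the `n_new`
#' candidates that best approach the spacing of the target density, so
#' up-sampling never worsens density uniformity. Original points are kept
#' unchanged; new points inherit the seed point's label and get the patch
#' normal.
#'
#' @param cloud a `point_cloud`.
#' @param factor target density multiplier, >= 1.
#' @param search_radius MLS neighbourhood radius (mm).
#' @param seed integer seed.
#' @return the densified `point_cloud`; `meta$n_original` records the input
#'   size.
#' @export
mls_upsample <- function(cloud, factor = 2, search_radius = 0.8, seed = 1L) {
  if (factor < 1) stop("up-sampling factor must be >= 1")
  n <- n_points(cloud)
  n_new <- round((factor - 1) * n)
  if (n_new == 0) {
    out <- cloud
    out$meta$n_original <- n
    return(out)
  }
  xyz <- cloud$xyz
  with_seed(seed, {
    # local spacing from the 10th NN; seed weight ~ spacing^2 (area per point)
    k <- min(10, n - 1)
    nn <- knn_indices(xyz, k)
    spacing <- sqrt(rowSums((xyz - xyz[nn[, k], ])^2))
    w <- pmax(spacing, 1e-9)^2
    # candidate points on local MLS tangent discs (disc radius = local
    # spacing), then progressive Poisson-disk thinning towards the spacing
    # of the target density — plain multinomial placement would clump and
    # degrade density uniformity
    n_cand <- 3L * n_new
    bases <- sample.int(n, n_cand, replace = TRUE, prob = w)
    fr_nbrs <- radius_neighbors(xyz, xyz, search_radius)
    small <- which(lengths(fr_nbrs) < 3)
    for (i in small) fr_nbrs[[i]] <- c(i, nn[i, ])
    fr <- cpp_local_frames(xyz, fr_nbrs)
    rho <- spacing[bases] * sqrt(runif(n_cand))
    phi <- runif(n_cand, 0, 2 * pi)
    # disc centre = the base point projected onto its MLS plane (denoises)
    bxyz <- xyz[bases, , drop = FALSE]
    bnrm <- fr$normal[bases, , drop = FALSE]
    off <- rowSums((bxyz - fr$center[bases, , drop = FALSE]) * bnrm)
    cand <- bxyz - off * bnrm +
      (rho * cos(phi)) * fr$e1[bases, , drop = FALSE] +
      (rho * sin(phi)) * fr$e2[bases, , drop = FALSE]
    r0 <- 0.75 * median(spacing) / sqrt(max(factor, 1))
    keep <- cpp_poisson_thin(xyz, cand, r0, n_new)
    bases <- bases[keep]
    new_xyz <- cand[keep, , drop = FALSE]
    new_nrm <- fr$normal[bases, , drop = FALSE]
    # align with the seed point's normal when known (keeps cavity
    # orientation); otherwise fall back to the centroid convention
    ref <- if (!is.null(cloud$normals)) cloud$normals[bases, , drop = FALSE]
           else sweep(xyz[bases, , drop = FALSE], 2, colMeans(xyz))
    flip <- rowSums(new_nrm * ref) < 0
    new_nrm[flip, ] <- -new_nrm[flip, , drop = FALSE]
    out_nrm <- if (!is.null(cloud$normals)) rbind(cloud$normals, new_nrm)
    out_lab <- if (!is.null(cloud$labels)) c(cloud$labels, cloud$labels[bases])
    pc_out <- point_cloud(rbind(xyz, new_xyz), normals = out_nrm,
                          labels = out_lab, class_label = cloud$class_label,
                          meta = cloud$meta)
    pc_out$meta$n_original <- n
    pc_out
  })
}

#' Resample a cloud to a fixed point count
#'
#' If the cloud has at least `n` points, a uniform random subset without
#' replacement is taken; otherwise the cloud is first MLS-up-sampled to the
#' needed density and then subset. Deterministic under a fixed seed.
#'
#' @param cloud a `point_cloud`.
#' @param n target point count (default 1024, the classifier's input size).
#' @param search_radius passed to [mls_upsample()] when padding is needed.
#' @param seed integer seed.
#' @return a `point_cloud` with exactly `n` points.
#' @export
resample_fixed <- function(cloud, n = 1024, search_radius = 0.8, seed = 1L) {
  if (n <= 0) stop("target point count must be positive")
  m <- n_points(cloud)
  if (m == 0) stop("cloud is empty")
  with_seed(seed, {
    if (m < n) {
      cloud <- mls_upsample(cloud, factor = n / m * 1.1 + 0.05,
                            search_radius = search_radius,
                            seed = sample.int(.Machine$integer.max, 1))
      m <- n_points(cloud)
    }
    subset_cloud(cloud, sample.int(m, n))
  })
}

#' Normalize a cloud into the unit sphere
#'
#' Centres the coordinates on the centroid and scales them so the farthest
#' point has norm exactly 1, recording centre and scale for inversion — the
#' convention of fixed-count point-set classification datasets.
#'
#' @param cloud a `point_cloud` with at least 2 points.
#' @return the normalized cloud; `meta$norm_center` and `meta$norm_scale`
#'   allow [denormalize_cloud()] to restore the original coordinates.
#' @export
normalize_unit_sphere <- function(cloud) {
  if (n_points(cloud) < 2)
    stop("cannot normalize a single-point cloud: scale undefined")
  ctr <- colMeans(cloud$xyz)
  centred <- sweep(cloud$xyz, 2, ctr)
  scale <- max(sqrt(rowSums(centred^2)))
  if (scale == 0) stop("cannot normalize: all points coincident")
  out <- cloud
  out$xyz <- centred / scale
  colnames(out$xyz) <- c("x", "y", "z")
  out$meta$norm_center <- ctr
  out$meta$norm_scale <- scale
  out
}

#' Invert [normalize_unit_sphere()]
#' @param cloud a normalized `point_cloud`.
#' @return the cloud in original coordinates.
#' @export
denormalize_cloud <- function(cloud) {
  if (is.null(cloud$meta$norm_scale)) stop("cloud carries no normalization record")
  out <- cloud
  out$xyz <- sweep(cloud$xyz * cloud$meta$norm_scale, 2,
                   cloud$meta$norm_center, `+`)
  out$meta$norm_center <- NULL
  out$meta$norm_scale <- NULL
  out
}

## ---------------------------------------------------------------------------
## Dataset variants and the fixed-count text export
## ---------------------------------------------------------------------------

#' Prepare a grain for classifier input
#'
#' One enhancement variant applied to one grain: optional MLS up-sampling,
#' optional MLS normal estimation ("normal vector fusion"), PCA alignment,
#' resampling to a fixed count and unit-sphere normalization. Without normal
#' fusion the normal channel holds surrogate normals (the normalized
#' coordinate directions), so every variant exports the same six channels.
#'
#' @param cloud a segmented grain `point_cloud`.
#' @param variant one of `"raw"`, `"up"`, `"normal"`, `"both"`.
#' @param n_points output point count.
#' @param upsample_factor density multiplier for the up-sampling variants.
#' @param search_radius MLS radius (mm).
#' @param seed integer seed.
#' @return a normalized `point_cloud` with exactly `n_points` points and a
#'   full normal channel.
#' @export
enhance_grain <- function(cloud, variant = c("both", "raw", "up", "normal"),
                          n_points = 1024, upsample_factor = 2,
                          search_radius = 0.8, seed = 1L) {
  variant <- match.arg(variant)
  with_seed(seed, {
    g <- transform_to_frame(cloud)
    if (variant %in% c("up", "both"))
      g <- mls_upsample(g, factor = upsample_factor,
                        search_radius = search_radius,
                        seed = sample.int(.Machine$integer.max, 1))
    if (variant %in% c("normal", "both")) {
      g <- estimate_normals(g, search_radius = search_radius)
    } else {
      g$normals <- NULL  # surrogate normals assigned after normalization
    }
    g <- resample_fixed(g, n = n_points, search_radius = search_radius,
                        seed = sample.int(.Machine$integer.max, 1))
    g <- normalize_unit_sphere(g)
    if (is.null(g$normals)) {
      nn <- g$xyz / pmax(sqrt(rowSums(g$xyz^2)), 1e-12)
      g$normals <- nn
      colnames(g$normals) <- c("nx", "ny", "nz")
      g$meta$surrogate_normals <- TRUE
    } else {
      # renormalize after the rigid transforms (unit length to 1e-6)
      g$normals <- g$normals / sqrt(rowSums(g$normals^2))
    }
    g$meta$variant <- variant
    g
  })
}

#' Build an in-memory classification dataset from grain clouds
#'
#' Applies [enhance_grain()] with one variant to every grain and draws a
#' seeded stratified train/test split.
#'
#' @param grains list of grain `point_cloud`s with class labels.
#' @param variant enhancement variant, see [enhance_grain()].
#' @param n_points points per sample.
#' @param split_ratio train fraction (default 0.8, i.e. a 4:1 split).
#' @param upsample_factor,search_radius see [enhance_grain()].
#' @param seed integer seed.
#' @return list with `samples` (list of `n_points x 6` matrices), `labels`
#'   (factor, levels `filled`/`unfilled`), `train`, `test` (index vectors)
#'   and `variant`.
#' @export
prepare_dataset <- function(grains, variant = "both", n_points = 1024,
                            split_ratio = 0.8, upsample_factor = 2,
                            search_radius = 0.8, seed = 1L) {
  labels <- vapply(grains, function(g) g$class_label %||% NA_character_, "")
  if (anyNA(labels)) stop("every grain needs a class_label")
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, length(grains))
    samples <- vector("list", length(grains))
    for (i in seq_along(grains)) {
      g <- enhance_grain(grains[[i]], variant = variant, n_points = n_points,
                         upsample_factor = upsample_factor,
                         search_radius = search_radius, seed = sub_seeds[i])
      samples[[i]] <- cbind(g$xyz, g$normals)
    }
    labels <- factor(labels, levels = c("filled", "unfilled"))
    train <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      train <- c(train, sort(sample(idx, round(split_ratio * length(idx)))))
    }
    train <- sort(train)
    list(samples = samples, labels = labels, train = train,
         test = setdiff(seq_along(grains), train), variant = variant,
         n_points = n_points)
  })
}

#' Write a dataset in the fixed-count six-column text layout
#'
#' One text file per sample under a class-name directory
#' (`<class>/<class>_<id>.txt`), each line `x,y,z,nx,ny,nz`, plus
#' `shape_names.txt`, `train.txt` and `test.txt` listing the sample ids of
#' the stratified 4:1 split — the layout of ModelNet-style normal-resampled
#' classification datasets.
#'
#' @param dataset result of [prepare_dataset()].
#' @param out_dir output directory (created if needed).
#' @param digits significant digits written per value.
#' @return `out_dir`, invisibly.
#' @export
write_modelnet_dataset <- function(dataset, out_dir, digits = 6) {
  labels <- dataset$labels
  classes <- levels(labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in classes)
    dir.create(file.path(out_dir, cl), showWarnings = FALSE)
  ids <- character(length(dataset$samples))
  counters <- stats::setNames(integer(length(classes)), classes)
  for (i in seq_along(dataset$samples)) {
    m <- dataset$samples[[i]]
    if (ncol(m) != 6) stop("sample ", i, " lacks the six x,y,z,nx,ny,nz columns")
    if (anyNA(m)) stop("sample ", i, " has missing normal values")
    cl <- as.character(labels[i])
    counters[cl] <- counters[cl] + 1L
    ids[i] <- sprintf("%s_%04d", cl, counters[cl])
    lines <- apply(m, 1, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = ","))
    writeLines(lines, file.path(out_dir, cl, paste0(ids[i], ".txt")))
  }
  writeLines(classes, file.path(out_dir, "shape_names.txt"))
  writeLines(ids[dataset$train], file.path(out_dir, "train.txt"))
  writeLines(ids[dataset$test], file.path(out_dir, "test.txt"))
  invisible(out_dir)
}

#' Read a dataset written by [write_modelnet_dataset()]
#'
#' @param dir dataset directory.
#' @return list in the layout of [prepare_dataset()].
#' @export
read_modelnet_dataset <- function(dir) {
  classes <- readLines(file.path(dir, "shape_names.txt"))
  train_ids <- readLines(file.path(dir, "train.txt"))
  test_ids <- readLines(file.path(dir, "test.txt"))
  ids <- c(train_ids, test_ids)
  samples <- vector("list", length(ids))
  labels <- character(length(ids))
  for (i in seq_along(ids)) {
    cl <- sub("_[0-9]+$", "", ids[i])
    path <- file.path(dir, cl, paste0(ids[i], ".txt"))
    vals <- strsplit(readLines(path), ",")
    samples[[i]] <- matrix(as.numeric(unlist(vals)), ncol = 6, byrow = TRUE,
                           dimnames = list(NULL, c("x", "y", "z",
                                                   "nx", "ny", "nz")))
    labels[i] <- cl
  }
  list(samples = samples, labels = factor(labels, levels = classes),
       train = seq_along(train_ids),
       test = length(train_ids) + seq_along(test_ids),
       n_points = nrow(samples[[1]]))
}
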