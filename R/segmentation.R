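## Single-grain segmentation ------------------------------------------------
##
## Scene cloud -> single grains in three steps: a PCA covariance-frame
## transform aligning the scene with its principal axes, robust plate removal
## by RANSAC plane fitting, and region growing on normals and curvature.

#' Principal-component frame of a point cloud
#'
#' Computes the centroid `A` and the orthonormal eigenvector matrix `MT`
#' (rows `e1, e2, e3`, eigenvalues descending) of the 3x3 covariance of the
#' coordinates. The sign of each eigenvector is fixed by making its
#' largest-magnitude component positive, so the frame is deterministic.
#'
#' @param cloud a `point_cloud` or an `n x 3` matrix.
#' @return object of class `covariance_frame`: list with `centroid`,
#'   `rotation` (3x3, rows are the eigenvectors) and `eigenvalues`.
#' @export
pca_frame <- function(cloud) {
  xyz <- if (inherits(cloud, "point_cloud")) cloud$xyz else as.matrix(cloud)
  if (nrow(xyz) < 3) stop("need at least 3 points for a PCA frame")
  ctr <- colMeans(xyz)
  cv <- cov(xyz)
  ev <- eigen(cv, symmetric = TRUE)  # eigenvalues descending
  if (ev$values[1] <= 0)
    stop("degenerate cloud: all points coincident (rank 0 covariance)")
  if (ev$values[2] / ev$values[1] < 1e-12)
    stop("degenerate cloud: points are collinear (rank 1 covariance)")
  R <- t(ev$vectors)
  for (i in 1:3) {
    j <- which.max(abs(R[i, ]))
    if (R[i, j] < 0) R[i, ] <- -R[i, ]
  }
  structure(list(centroid = ctr, rotation = R, eigenvalues = ev$values),
            class = "covariance_frame")
}

#' @export
print.covariance_frame <- function(x, ...) {
  cat("<covariance_frame>\n  centroid:",
      paste(sprintf("%.3f", x$centroid), collapse = " "), "\n")
  cat("  eigenvalues:", paste(sprintf("%.4g", x$eigenvalues), collapse = " "),
      "\n")
  invisible(x)
}

#' Transform a cloud into its covariance frame
#'
#' Applies `TA = MT (T0 - A)`: coordinates are centred on the centroid and
#' rotated onto the principal axes, so the output has zero centroid and
#' per-axis variances in non-increasing order. Normals are rotated along.
#' The transform is a rigid isometry; invert with [transform_from_frame()].
#'
#' @param cloud a `point_cloud`.
#' @param frame a [pca_frame()] result (defaults to the cloud's own frame).
#' @return the transformed `point_cloud`.
#' @export
transform_to_frame <- function(cloud, frame = pca_frame(cloud)) {
  xyz <- sweep(cloud$xyz, 2, frame$centroid) %*% t(frame$rotation)
  out <- cloud
  out$xyz <- xyz
  colnames(out$xyz) <- c("x", "y", "z")
  if (!is.null(cloud$normals)) {
    out$normals <- cloud$normals %*% t(frame$rotation)
    colnames(out$normals) <- c("nx", "ny", "nz")
  }
  out$meta$frame <- frame
  out
}

#' Invert a covariance-frame transform
#'
#' @param cloud a `point_cloud` in frame coordinates.
#' @param frame the `covariance_frame` used in the forward transform.
#' @return the `point_cloud` in original coordinates.
#' @export
transform_from_frame <- function(cloud, frame = cloud$meta$frame) {
  if (is.null(frame)) stop("no frame supplied or recorded on the cloud")
  out <- cloud
  out$xyz <- sweep(cloud$xyz %*% frame$rotation, 2, frame$centroid, `+`)
  colnames(out$xyz) <- c("x", "y", "z")
  if (!is.null(cloud$normals)) out$normals <- cloud$normals %*% frame$rotation
  out$meta$frame <- NULL
  out
}

#' Robust plane fit by random sample consensus
#'
#' Repeatedly fits planes through random point triplets, keeps the hypothesis
#' with the largest inlier count (|signed distance| <= `distance_threshold`),
#' and refits it by total least squares on its inliers. Used to separate the
#' flat sample plate from the grains.
#'
#' @param cloud a `point_cloud` or `n x 3` matrix.
#' @param distance_threshold inlier distance (mm). The default is three times
#'   the scanner point precision of 0.05 mm.
#' @param max_iterations number of random hypotheses.
#' @param seed integer seed; fixed seeds give bit-identical fits.
#' @return object of class `plane_model`: `normal` (unit length), `offset`
#'   (`b` in `a0 x + a1 y + a2 z + b = 0`), logical `inlier_mask`, and the
#'   inlier count.
#' @export
ransac_plane <- function(cloud, distance_threshold = 0.15,
                         max_iterations = 1000, seed = 1L) {
  xyz <- if (inherits(cloud, "point_cloud")) cloud$xyz else as.matrix(cloud)
  n <- nrow(xyz)
  if (n < 3) stop("need at least 3 points to fit a plane")
  with_seed(seed, {
    best_count <- -1L
    best_nrm <- NULL
    best_off <- NULL
    for (it in seq_len(max_iterations)) {
      tri <- sample.int(n, 3)
      p <- xyz[tri, ]
      u <- p[2, ] - p[1, ]
      v <- p[3, ] - p[1, ]
      nrm <- c(u[2] * v[3] - u[3] * v[2],
               u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      nn <- sqrt(sum(nrm^2))
      if (nn < 1e-12) next  # degenerate triplet, skip
      nrm <- nrm / nn
      off <- -sum(nrm * p[1, ])
      d <- abs(xyz %*% nrm + off)
      count <- sum(d <= distance_threshold)
      if (count > best_count) {
        best_count <- count
        best_nrm <- nrm
        best_off <- off
      }
    }
    # least-squares refit (total LS: smallest eigenvector of inlier covariance)
    mask <- abs(xyz %*% best_nrm + best_off) <= distance_threshold
    inl <- xyz[mask, , drop = FALSE]
    ctr <- colMeans(inl)
    ev <- eigen(cov(inl), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
    off <- -sum(nrm * ctr)
    mask <- as.vector(abs(xyz %*% nrm + off) <= distance_threshold)
    structure(list(normal = nrm, offset = off, inlier_mask = mask,
                   n_inliers = sum(mask)),
              class = "plane_model")
  })
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> %.4f x + %.4f y + %.4f z + %.4f = 0\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  if (!is.null(x$inlier_mask))
    cat(sprintf("  inliers: %d / %d\n", x$n_inliers, length(x$inlier_mask)))
  invisible(x)
}

# Per-point normals and curvature from the k-NN local covariance.
# Curvature is the surface variation lambda3 / (lambda1+lambda2+lambda3).
local_surface_stats <- function(xyz, k = 30) {
  n <- nrow(xyz)
  k <- min(k, n - 1)
  nn <- knn_indices(xyz, k)
  nbrs <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  fr <- cpp_local_frames(xyz, nbrs)
  list(normals = fr$normal, curvature = fr$curvature, knn = nn)
}

#' Region-growing clustering on normals and curvature
#'
#' Seeds regions at the lowest-curvature unassigned point, then grows through
#' the k-NN graph: a neighbour joins the region when the angle between its
#' normal and the current point's normal is at most `angle_threshold`, and
#' becomes a growth front itself when its curvature is below
#' `curvature_threshold`. Clusters smaller than `min_cluster_size` are
#' reassigned to the noise id 0.
#'
#' @param cloud a `point_cloud`; must carry normals unless `normals` given.
#' @param normals optional `n x 3` matrix overriding the cloud's normals.
#' @param curvature optional per-point curvature; computed from the local
#'   covariance when missing.
#' @param angle_threshold degrees.
#' @param curvature_threshold absolute threshold, or `NULL` for the 90th
#'   percentile of the observed curvatures. Growth only stalls at the very
#'   sharpest creases; grains on a plate are spatially disjoint, so a
#'   permissive seeding keeps each closed grain surface in one cluster
#'   instead of splitting it at its curved ends.
#' @param min_cluster_size minimum points per retained cluster.
#' @param k neighbourhood size of the growth graph.
#' @return integer cluster labels, 0 = noise, clusters numbered by
#'   decreasing size.
#' @export
region_grow <- function(cloud, normals = cloud$normals, curvature = NULL,
                        angle_threshold = 30, curvature_threshold = NULL,
                        min_cluster_size = 100, k = 30) {
  xyz <- cloud$xyz
  n <- nrow(xyz)
  if (is.null(normals) || is.null(curvature)) {
    stats <- local_surface_stats(xyz, k)
    if (is.null(normals)) normals <- stats$normals
    if (is.null(curvature)) curvature <- stats$curvature
    nn <- stats$knn
  } else {
    nn <- knn_indices(xyz, min(k, n - 1))
  }
  if (is.null(normals)) stop("normals are required for region growing")
  if (is.null(curvature_threshold))
    curvature_threshold <- quantile(curvature, 0.9, names = FALSE)
  cos_thr <- cos(angle_threshold * pi / 180)

  labels <- integer(n)           # 0 = unassigned
  order_idx <- order(curvature)  # flattest points seed first
  next_label <- 0L
  for (s in order_idx) {
    if (labels[s] != 0L) next
    next_label <- next_label + 1L
    labels[s] <- next_label
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      nbs <- nn[cur, ]
      nbs <- nbs[labels[nbs] == 0L]
      if (length(nbs) == 0) next
      ang_ok <- abs(as.vector(normals[nbs, , drop = FALSE] %*%
                                normals[cur, ])) >= cos_thr
      grow <- nbs[ang_ok]
      if (length(grow) == 0) next
      labels[grow] <- next_label
      seeds <- grow[curvature[grow] <= curvature_threshold]
      if (length(seeds) > 0) {
        queue[tail + seq_along(seeds)] <- seeds
        tail <- tail + length(seeds)
      }
    }
  }
  # drop small clusters to noise, renumber by decreasing size
  sizes <- table(labels)
  keep <- as.integer(names(sizes))[sizes >= min_cluster_size]
  keep <- keep[keep != 0L]
  labels[!(labels %in% keep)] <- 0L
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[as.character(keep)])]
    relab <- integer(max(ord))
    relab[ord] <- seq_along(ord)
    labels[labels != 0L] <- relab[labels[labels != 0L]]
  }
  labels
}

#' Segment a scene into single-grain clouds
#'
#' The full pipeline: PCA frame transform of the scene, RANSAC plate removal,
#' normal/curvature estimation, region growing, and ordering of the resulting
#' grain clouds by their centroid position (row-major in the plate frame) for
#' reproducibility. Each returned cloud records the original scene point
#' indices in `meta$indices`.
#'
#' @param cloud the scene `point_cloud`.
#' @param distance_threshold RANSAC inlier distance (mm).
#' @param max_iterations RANSAC hypothesis count.
#' @param angle_threshold,curvature_threshold,min_cluster_size,k region
#'   growing parameters, see [region_grow()].
#' @param seed integer seed for the RANSAC stage.
#' @return list of `point_cloud`s, one per grain; empty (with a warning) if
#'   nothing remains after plate removal.
#' @export
segment_scene <- function(cloud, distance_threshold = 0.15,
                          max_iterations = 1000, angle_threshold = 30,
                          curvature_threshold = NULL, min_cluster_size = 100,
                          k = 30, seed = 1L) {
  if (n_points(cloud) == 0) stop("scene cloud is empty")
  frame <- pca_frame(cloud)
  aligned <- transform_to_frame(cloud, frame)
  plane <- ransac_plane(aligned, distance_threshold = distance_threshold,
                        max_iterations = max_iterations, seed = seed)
  rest_idx <- which(!plane$inlier_mask)
  if (length(rest_idx) == 0) {
    warning("no points remain after plate removal")
    return(list())
  }
  rest <- subset_cloud(aligned, rest_idx)
  labels <- region_grow(rest, normals = NULL, curvature = NULL,
                        angle_threshold = angle_threshold,
                        curvature_threshold = curvature_threshold,
                        min_cluster_size = min_cluster_size, k = k)
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids) == 0) {
    warning("no clusters found after plate removal")
    return(list())
  }
  grains <- lapply(ids, function(id) {
    sel <- which(labels == id)
    g <- subset_cloud(rest, sel)
    g$meta$indices <- rest_idx[sel]
    g$meta$frame <- frame
    g
  })
  # order row-major by centroid in the plate frame (x = e1, y = e2)
  ctr <- t(vapply(grains, function(g) colMeans(g$xyz), numeric(3)))
  row_pitch <- if (length(grains) > 1) {
    d <- sort(unique(round(ctr[, 2], 0)))
    if (length(d) > 1) min(diff(d)) else 1
  } else 1
  ord <- order(round(ctr[, 2] / max(row_pitch, 1e-6)), ctr[, 1])
  grains[ord]
}

#' Compare a segmentation against ground-truth labels
#'
#' Matches each cluster to its majority ground-truth grain and reports
#' per-cluster purity (fraction of points from the majority grain) and
#' per-grain completeness (fraction of the grain's points recovered by its
#' matched cluster). Points flagged as outliers in the truth cloud are
#' excluded.
#'
#' @param grains list of segmented clouds from [segment_scene()] (each with
#'   `meta$indices`).
#' @param truth the generated scene cloud with ground-truth `labels`.
#' @return list with `n_clusters`, `purity`, `completeness` vectors and their
#'   minima.
#' @export
evaluate_segmentation <- function(grains, truth) {
  keep <- if (!is.null(truth$meta$outlier)) !truth$meta$outlier
          else rep(TRUE, n_points(truth))
  true_lab <- truth$labels
  purity <- numeric(length(grains))
  completeness <- numeric(length(grains))
  for (i in seq_along(grains)) {
    idx <- grains[[i]]$meta$indices
    idx <- idx[keep[idx]]
    tl <- true_lab[idx]
    maj <- as.integer(names(which.max(table(tl))))
    purity[i] <- mean(tl == maj)
    grain_total <- sum(true_lab == maj & keep)
    completeness[i] <- sum(tl == maj) / grain_total
  }
  list(n_clusters = length(grains), purity = purity,
       completeness = completeness,
       min_purity = min(purity), min_completeness = min(completeness))
}
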