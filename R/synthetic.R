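## Synthetic scanner scenes -------------------------------------------------
##
## A structured-light scan of rice grains mounted upright on a sample plate is
## emulated so that every downstream stage (plate removal, clustering, trait
## extraction, classification) can be exercised against known ground truth.
## Grains are superellipsoids at rice scale (~7 x 3 x 2 mm); unfilled grains
## carry a smooth concave cavity on one flank, the geometric signal that
## separates the two classes.

#' Specify a synthetic grain
#'
#' @param class_label `"filled"` or `"unfilled"`.
#' @param semi_axes numeric length-3 `(a, b, c)` in mm with `a >= b >= c > 0`;
#'   `a` is the half-length, `b` the half-width, `c` the half-thickness.
#' @param shape_exponent superellipsoid power; 2 gives an ellipsoid.
#' @param cavity_depth maximal inward radial displacement of the cavity (mm);
#'   must be 0 for filled grains and `< c` for unfilled ones.
#' @param cavity_extent fraction of the belly hemisphere (by solid angle)
#'   covered by the cavity, in (0, 1); unfilled grains only.
#' @param n_points number of surface points to sample.
#' @return a `grain_spec` list.
#' @export
grain_spec <- function(class_label = c("filled", "unfilled"),
                       semi_axes = c(3.5, 1.5, 1.0),
                       shape_exponent = 2,
                       cavity_depth = if (class_label == "unfilled") 0.55 else 0,
                       cavity_extent = 0.35,
                       n_points = 1500) {
  class_label <- match.arg(class_label)
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi_axes must be three positive numbers (a, b, c)")
  if (!(semi_axes[1] >= semi_axes[2] && semi_axes[2] >= semi_axes[3]))
    stop("semi_axes must satisfy a >= b >= c")
  if (shape_exponent <= 0) stop("shape_exponent must be positive")
  if (class_label == "filled" && cavity_depth != 0)
    stop("filled grains must have cavity_depth = 0")
  if (class_label == "unfilled") {
    if (cavity_depth <= 0 || cavity_depth >= semi_axes[3])
      stop("cavity_depth must lie in (0, c); got ", cavity_depth,
           " with c = ", semi_axes[3])
    if (cavity_extent <= 0 || cavity_extent >= 1)
      stop("cavity_extent must lie in (0, 1)")
  }
  if (n_points < 4) stop("n_points must be at least 4")
  structure(list(class_label = class_label, semi_axes = semi_axes,
                 shape_exponent = shape_exponent, cavity_depth = cavity_depth,
                 cavity_extent = cavity_extent, n_points = as.integer(n_points)),
            class = "grain_spec")
}

#' Specify a synthetic scanner scene
#'
#' Defaults reproduce the scanning layout the pipeline is designed for: a
#' 5 x 5 grid of grains at 20 mm pitch on a flat sample plate, with Gaussian
#' sensor noise at the scanner's 0.05 mm point precision.
#'
#' @param rows,cols grid dimensions.
#' @param spacing centre-to-centre grain distance (mm); must exceed twice the
#'   longest grain length so grains never touch.
#' @param plate_size plate extent `(x, y)` in mm.
#' @param plate_points number of points sampled on the plate.
#' @param noise_sd isotropic Gaussian noise standard deviation (mm).
#' @param outlier_fraction fraction of points displaced to uniform positions
#'   inside the scene bounding box (sparse outliers).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(rows = 5, cols = 5, spacing = 20,
                       plate_size = c(120, 120), plate_points = 8000,
                       noise_sd = 0.05, outlier_fraction = 0.002,
                       seed = 1L) {
  if (rows < 1 || cols < 1) stop("rows and cols must be at least 1")
  if (spacing <= 0) stop("spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spacing = spacing, plate_size = as.numeric(plate_size),
                 plate_points = as.integer(plate_points),
                 noise_sd = noise_sd, outlier_fraction = outlier_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Radial extent of the (possibly cavitied) grain surface along unit
# directions U (n x 3), in the grain's local frame (x = length axis,
# z = belly/thickness axis, cavity centred on +z).
grain_radius <- function(U, spec) {
  p <- spec$shape_exponent
  s <- spec$semi_axes
  r <- (abs(U[, 1] / s[1])^p + abs(U[, 2] / s[2])^p +
          abs(U[, 3] / s[3])^p)^(-1 / p)
  if (spec$class_label == "unfilled") {
    theta <- acos(pmin(1, pmax(-1, U[, 3])))
    theta0 <- acos(1 - spec$cavity_extent)  # cap with given solid-angle share
    bump <- ifelse(theta < theta0,
                   0.5 * (1 + cos(pi * theta / theta0)), 0)
    r <- r - spec$cavity_depth * bump
  }
  r
}

# Outward unit normals of the radial surface r(u) * u via central differences
# on the sphere; exact up to O(h^2), adequate as generator ground truth.
grain_surface_normals <- function(U, spec, h = 1e-5) {
  helper <- matrix(rep(c(0, 0, 1), each = nrow(U)), ncol = 3)
  flip <- abs(U[, 3]) > 0.9
  helper[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
  t1 <- helper - U * rowSums(helper * U)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(U[, 2] * t1[, 3] - U[, 3] * t1[, 2],
              U[, 3] * t1[, 1] - U[, 1] * t1[, 3],
              U[, 1] * t1[, 2] - U[, 2] * t1[, 1])
  surf <- function(D) {
    Dn <- D / sqrt(rowSums(D^2))
    grain_radius(Dn, spec) * Dn
  }
  e1 <- (surf(U + h * t1) - surf(U - h * t1)) / (2 * h)
  e2 <- (surf(U + h * t2) - surf(U - h * t2)) / (2 * h)
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  out <- rowSums(nrm * U) < 0
  nrm[out, ] <- -nrm[out, ]
  nrm
}

#' Generate a single grain point cloud
#'
#' Samples `n_points` on the closed grain surface with area-uniform density
#' (importance resampling of uniform sphere directions by the local area
#' element), attaching ground-truth outward normals and the class label.
#' Coordinates are in the grain's local frame: x along the length axis,
#' z along the thickness axis with the cavity (if any) centred on +z.
#'
#' @param spec a [grain_spec()].
#' @param seed integer seed.
#' @return a `point_cloud` with normals, `class_label` and `meta$spec`.
#' @export
generate_grain <- function(spec, seed = 1L) {
  if (!inherits(spec, "grain_spec")) stop("spec must be a grain_spec")
  with_seed(seed, {
    n <- spec$n_points
    m <- max(8L * n, 2000L)
    U <- matrix(rnorm(3 * m), ncol = 3)
    U <- U / sqrt(rowSums(U^2))
    r <- grain_radius(U, spec)
    nrm <- grain_surface_normals(U, spec)
    # area element of a radial graph: dA = r^2 / (u . n) dOmega
    w <- r^2 / pmax(rowSums(U * nrm), 0.05)
    keep <- sample.int(m, n, prob = w)
    pts <- r[keep] * U[keep, , drop = FALSE]
    point_cloud(pts, normals = nrm[keep, , drop = FALSE],
                class_label = spec$class_label,
                meta = list(spec = spec, seed = seed))
  })
}

#' Generate a scanner-like scene
#'
#' Places one grain per grid cell upright on a flat plate (long axis normal to
#' the plate, random yaw), adds Gaussian sensor noise and sparse uniform
#' outliers. Plate points carry label 0, grain points labels `1..rows*cols`
#' in row-major order; displaced outlier points keep their source label and
#' are flagged in `meta$outlier`.
#'
#' @param spec a [scene_spec()].
#' @param grain_specs list of [grain_spec()]s, one per grid cell
#'   (`rows * cols` of them, row-major).
#' @return a labeled `point_cloud`; `meta$centers` holds the true grain
#'   centre positions.
#' @export
generate_scene <- function(spec, grain_specs) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  n_grains <- spec$rows * spec$cols
  if (length(grain_specs) != n_grains)
    stop("need exactly rows * cols = ", n_grains, " grain specs, got ",
         length(grain_specs))
  max_len <- max(vapply(grain_specs, function(g) 2 * g$semi_axes[1], 0))
  if (spec$spacing <= 2 * max_len)
    stop("grains would touch: spacing (", spec$spacing,
         " mm) must exceed twice the longest grain length (",
         2 * max_len, " mm)")
  grid_extent <- c((spec$cols - 1), (spec$rows - 1)) * spec$spacing +
    2 * max(vapply(grain_specs, function(g) g$semi_axes[2], 0))
  if (any(grid_extent > spec$plate_size))
    stop("grain grid (", paste(round(grid_extent, 1), collapse = " x "),
         " mm) does not fit on the plate")

  with_seed(spec$seed, {
    # plate: uniform samples on the rectangle z = 0
    pp <- cbind(runif(spec$plate_points, -spec$plate_size[1] / 2,
                      spec$plate_size[1] / 2),
                runif(spec$plate_points, -spec$plate_size[2] / 2,
                      spec$plate_size[2] / 2),
                0)
    plate_nrm <- matrix(rep(c(0, 0, 1), each = spec$plate_points), ncol = 3)

    # local length axis -> world z (grains mounted vertically)
    align <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
    xs <- (seq_len(spec$cols) - (spec$cols + 1) / 2) * spec$spacing
    ys <- (seq_len(spec$rows) - (spec$rows + 1) / 2) * spec$spacing

    xyz <- list(pp)
    nrm <- list(plate_nrm)
    lab <- list(rep(0L, spec$plate_points))
    centers <- matrix(0, n_grains, 3)
    gid <- 0L
    for (r in seq_len(spec$rows)) {
      for (cc in seq_len(spec$cols)) {
        gid <- gid + 1L
        g <- generate_grain(grain_specs[[gid]],
                            seed = sample.int(.Machine$integer.max, 1))
        yaw <- runif(1, 0, 2 * pi)
        Rz <- matrix(c(cos(yaw), -sin(yaw), 0,
                       sin(yaw), cos(yaw), 0,
                       0, 0, 1), 3, 3, byrow = TRUE)
        R <- Rz %*% align
        ctr <- c(xs[cc], ys[r], grain_specs[[gid]]$semi_axes[1])
        xyz[[gid + 1L]] <- g$xyz %*% t(R) + matrix(ctr, n_points(g), 3,
                                                   byrow = TRUE)
        nrm[[gid + 1L]] <- g$normals %*% t(R)
        lab[[gid + 1L]] <- rep(gid, n_points(g))
        centers[gid, ] <- ctr
      }
    }
    xyz <- do.call(rbind, xyz)
    nrm <- do.call(rbind, nrm)
    lab <- unlist(lab)
    n <- nrow(xyz)

    if (spec$noise_sd > 0)
      xyz <- xyz + matrix(rnorm(3 * n, sd = spec$noise_sd), ncol = 3)
    outlier <- rep(FALSE, n)
    n_out <- round(spec$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      bb_lo <- apply(xyz, 2, min)
      bb_hi <- apply(xyz, 2, max)
      xyz[idx, ] <- cbind(runif(n_out, bb_lo[1], bb_hi[1]),
                          runif(n_out, bb_lo[2], bb_hi[2]),
                          runif(n_out, bb_lo[3], bb_hi[3]))
      outlier[idx] <- TRUE
    }
    point_cloud(xyz, normals = nrm, labels = lab,
                meta = list(scene_spec = spec, centers = centers,
                            outlier = outlier))
  })
}

#' Generate a balanced labeled grain dataset
#'
#' Emulates a pool of segmented single-grain clouds: per-grain shape
#' parameters are drawn from the stated ranges, classes are exactly balanced,
#' each cloud gets a uniform random 3D orientation and Gaussian sensor noise.
#' The sampled specs are attached as attribute `"specs"` for parameter
#' recovery studies.
#'
#' @param n_per_class grains per class.
#' @param variability named list of ranges: `a`, `b`, `c` (mm, semi-axes),
#'   `cavity_depth_frac` (fraction of `c`), `cavity_extent`.
#' @param n_points points per grain before any resampling.
#' @param noise_sd sensor noise (mm).
#' @param seed integer seed.
#' @return list of `point_cloud`s in seeded random class order, with
#'   attribute `specs` (data.frame of the sampled parameters).
#' @export
generate_dataset <- function(n_per_class,
                             variability = list(a = c(3.2, 3.8),
                                                b = c(1.4, 1.7),
                                                c = c(0.9, 1.15),
                                                cavity_depth_frac = c(0.4, 0.7),
                                                cavity_extent = c(0.25, 0.45)),
                             n_points = 1500, noise_sd = 0.05, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be at least 1")
  with_seed(seed, {
    labels <- sample(rep(c("filled", "unfilled"), n_per_class))
    n <- length(labels)
    a <- runif(n, variability$a[1], variability$a[2])
    b <- pmin(runif(n, variability$b[1], variability$b[2]), a)
    cc <- pmin(runif(n, variability$c[1], variability$c[2]), b)
    depth <- runif(n, variability$cavity_depth_frac[1],
                   variability$cavity_depth_frac[2]) * cc
    extent <- runif(n, variability$cavity_extent[1],
                    variability$cavity_extent[2])
    clouds <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- grain_spec(class_label = labels[i], semi_axes = c(a[i], b[i], cc[i]),
                       cavity_depth = if (labels[i] == "unfilled") depth[i] else 0,
                       cavity_extent = extent[i], n_points = n_points)
      g <- generate_grain(sp, seed = sample.int(.Machine$integer.max, 1))
      # random orientation, as segmented grains land in arbitrary frames
      M <- matrix(rnorm(9), 3, 3)
      qr_d <- qr(M)
      R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      g$xyz <- g$xyz %*% t(R)
      g$normals <- g$normals %*% t(R)
      if (noise_sd > 0)
        g$xyz <- g$xyz + matrix(rnorm(3 * n_points(g), sd = noise_sd), ncol = 3)
      clouds[[i]] <- g
    }
    attr(clouds, "specs") <- data.frame(
      grain = seq_len(n), class_label = labels, a = a, b = b, c = cc,
      cavity_depth = ifelse(labels == "unfilled", depth, 0),
      cavity_extent = extent)
    clouds
  })
}
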