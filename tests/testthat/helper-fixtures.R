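# Shared fixtures: all geometric test objects are generated in code.

# Uniform points on a sphere of radius r.
make_sphere_cloud <- function(n, r = 5, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  point_cloud(r * u, normals = u)
}

# Regular grid covering the closed surface of an axis-aligned box.
make_box_cloud <- function(dims = c(10, 5, 2), step = 0.25) {
  sx <- seq(0, dims[1], by = step)
  sy <- seq(0, dims[2], by = step)
  sz <- seq(0, dims[3], by = step)
  faces <- rbind(
    as.matrix(expand.grid(x = sx, y = sy, z = c(0, dims[3]))),
    as.matrix(expand.grid(x = sx, y = c(0, dims[2]), z = sz)),
    as.matrix(expand.grid(x = c(0, dims[1]), y = sy, z = sz)))
  point_cloud(unique(faces))
}

# Planar grid in the z = 0 plane.
make_grid_cloud <- function(rows, cols, spacing = 1) {
  g <- as.matrix(expand.grid(x = seq_len(cols) * spacing,
                             y = seq_len(rows) * spacing))
  point_cloud(cbind(g, 0))
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
rand_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rotate_cloud <- function(cloud, R, shift = c(0, 0, 0)) {
  out <- cloud
  out$xyz <- cloud$xyz %*% t(R) + matrix(shift, nrow(cloud$xyz), 3,
                                         byrow = TRUE)
  if (!is.null(cloud$normals)) out$normals <- cloud$normals %*% t(R)
  out
}

# Independent brute-force farthest-point sampling oracle: same start rule
# (farthest from centroid), plain double loop.
naive_fps <- function(xyz, m) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  d_ctr <- apply(xyz, 1, function(p) sum((p - ctr)^2))
  sel <- which.max(d_ctr)
  while (length(sel) < m) {
    best <- -1
    best_i <- NA
    for (i in seq_len(n)) {
      if (i %in% sel) next
      di <- min(apply(xyz[sel, , drop = FALSE], 1,
                      function(p) sum((p - xyz[i, ])^2)))
      if (di > best) { best <- di; best_i <- i }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# Ramanujan approximation of an ellipse perimeter (oracle for projections).
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Knud Thomsen approximation of the ellipsoid surface (about 1% accurate).
ellipsoid_surface <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}
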