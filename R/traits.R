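## 3D shape traits ----------------------------------------------------------
##
## Eleven morphometric traits per grain: oriented-bounding-box length, width
## and thickness; mesh surface area (Heron's formula per triangle) and
## enclosed volume (signed central-plane prisms, the divergence theorem);
## projected area and perimeter onto the three principal planes.

#' Construct a triangle mesh
#'
#' @param vertices numeric `n x 3` matrix (mm).
#' @param triangles integer `m x 3` matrix of 1-based vertex indices.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop("vertices and triangles must have 3 columns")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3]))
    stop("triangles with duplicate vertex indices")
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  be <- boundary_edges(x)
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles, %d boundary edges%s\n",
              nrow(x$vertices), nrow(x$triangles), nrow(be),
              if (nrow(be) == 0) " (watertight)" else ""))
  invisible(x)
}

# Directed edges of every triangle, m*3 x 2.
directed_edges <- function(mesh) {
  t <- mesh$triangles
  rbind(cbind(t[, 1], t[, 2]), cbind(t[, 2], t[, 3]), cbind(t[, 3], t[, 1]))
}

#' Boundary edges of a mesh
#'
#' Edges used by exactly one triangle, returned as directed pairs in the
#' orientation of their triangle. A watertight mesh has none.
#'
#' @param mesh a `triangle_mesh`.
#' @return integer matrix with columns `from`, `to` (0 rows if watertight).
#' @export
boundary_edges <- function(mesh) {
  de <- directed_edges(mesh)
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  b <- de[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  colnames(b) <- c("from", "to")
  b
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` over the vertices actually used by triangles; 2 for a
#' watertight sphere-topology surface.
#'
#' @param mesh a `triangle_mesh`.
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  v <- length(unique(as.vector(mesh$triangles)))
  de <- directed_edges(mesh)
  e <- length(unique(paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))))
  v - e + nrow(mesh$triangles)
}

#' Triangulate a point cloud surface
#'
#' Projection triangulation with two backends. `"planar"` projects the cloud
#' onto its best-fit plane and triangulates there (Delaunay), suited to open
#' sheet-like clouds. `"spherical"` projects the points onto unit directions
#' about the centroid (after whitening by the principal-axis scales) and
#' takes the convex-hull connectivity of the directions — for closed
#' star-shaped surfaces such as grains this yields a watertight,
#' consistently outward-oriented mesh directly. `"auto"` picks planar when
#' the cloud is flat (smallest/largest covariance eigenvalue ratio below
#' 1e-4) and spherical otherwise.
#'
#' @param cloud a `point_cloud` or `n x 3` matrix.
#' @param method `"auto"`, `"planar"` or `"spherical"`.
#' @param max_edge drop planar triangles with an edge longer than this (mm);
#'   `NULL` keeps all (convex support).
#' @return a `triangle_mesh` over the input points; points that end up
#'   unused (interior to the direction hull) are listed in
#'   `attr(, "unused")`.
#' @export
triangulate_surface <- function(cloud, method = c("auto", "planar", "spherical"),
                                max_edge = NULL) {
  method <- match.arg(method)
  xyz <- if (inherits(cloud, "point_cloud")) cloud$xyz else as.matrix(cloud)
  n <- nrow(xyz)
  if (n < 4) stop("too few points to triangulate a surface")
  if (method == "auto") {
    ev <- eigen(cov(xyz), symmetric = TRUE, only.values = TRUE)$values
    method <- if (ev[3] / ev[1] < 1e-4) "planar" else "spherical"
  }
  if (method == "spherical") {
    ctr <- colMeans(xyz)
    Q <- sweep(xyz, 2, ctr)
    sds <- pmax(apply(Q, 2, sd), 1e-9)
    W <- sweep(Q, 2, sds, "/")  # whitened: elongated grains become round
    U <- W / pmax(sqrt(rowSums(W^2)), 1e-12)
    tri <- cpp_convhull3(U)
    mesh <- triangle_mesh(xyz, tri)
    attr(mesh, "unused") <- setdiff(seq_len(n), unique(as.vector(tri)))
    mesh
  } else {
    fr <- pca_frame(xyz)
    P2 <- sweep(xyz, 2, fr$centroid) %*% t(fr$rotation)
    uv <- P2[, 1:2, drop = FALSE]
    dup <- duplicated(round(uv, 9))
    idx_map <- which(!dup)
    tri <- cpp_delaunay2(uv[idx_map, , drop = FALSE])
    tri[] <- idx_map[tri]
    if (!is.null(max_edge)) {
      v <- xyz
      el <- cbind(sqrt(rowSums((v[tri[, 1], ] - v[tri[, 2], ])^2)),
                  sqrt(rowSums((v[tri[, 2], ] - v[tri[, 3], ])^2)),
                  sqrt(rowSums((v[tri[, 3], ] - v[tri[, 1], ])^2)))
      tri <- tri[apply(el, 1, max) <= max_edge, , drop = FALSE]
    }
    mesh <- triangle_mesh(xyz, tri)
    attr(mesh, "unused") <- setdiff(seq_len(n), unique(as.vector(tri)))
    mesh
  }
}

#' Fill mesh holes by boundary-loop fans
#'
#' Walks every boundary loop and triangulates it with a fan from the loop
#' centroid, oriented consistently with the adjacent triangles. Loops that
#' cannot be walked (non-manifold boundary vertices) are left open with a
#' warning.
#'
#' @param mesh a `triangle_mesh`.
#' @return a watertight `triangle_mesh` (when all loops are simple).
#' @export
fill_holes <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) return(mesh)
  nxt <- split(seq_len(nrow(be)), be[, "from"])
  if (any(lengths(nxt) > 1)) {
    warning("non-manifold boundary vertex; hole left open")
    multi <- names(nxt)[lengths(nxt) > 1]
    drop_rows <- be[, "from"] %in% as.integer(multi) |
      be[, "to"] %in% as.integer(multi)
    be <- be[!drop_rows, , drop = FALSE]
    if (nrow(be) == 0) return(mesh)
    nxt <- split(seq_len(nrow(be)), be[, "from"])
  }
  used <- rep(FALSE, nrow(be))
  verts <- mesh$vertices
  tris <- mesh$triangles
  for (start in seq_len(nrow(be))) {
    if (used[start]) next
    loop <- integer(0)
    e <- start
    ok <- TRUE
    repeat {
      used[e] <- TRUE
      loop <- c(loop, be[e, "from"])
      nxt_e <- nxt[[as.character(be[e, "to"])]]
      if (is.null(nxt_e) || used[nxt_e[1]] && be[e, "to"] != be[start, "from"]) {
        if (be[e, "to"] == be[start, "from"]) break
        ok <- FALSE
        break
      }
      if (be[e, "to"] == be[start, "from"]) break
      e <- nxt_e[1]
    }
    if (!ok || length(loop) < 3) {
      warning("open or self-intersecting boundary loop left unfilled")
      next
    }
    # fan from loop centroid; boundary edges ran (from -> to) in their
    # triangle, so the patch traverses them reversed for consistent orientation
    cvert <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, cvert)
    ci <- nrow(verts)
    m <- length(loop)
    new_tris <- cbind(loop[c(2:m, 1)], loop, ci)
    tris <- rbind(tris, new_tris)
  }
  out <- triangle_mesh(verts, tris)
  attr(out, "unused") <- attr(mesh, "unused")
  out
}

#' Mesh surface area by Heron's formula
#'
#' Sums per-triangle areas computed from the three side lengths via the
#' semi-perimeter (Heron). Degenerate (collinear) triangles contribute zero
#' and are counted in `attr(, "n_degenerate")`.
#'
#' @param mesh a `triangle_mesh`.
#' @return total area (mm^2).
#' @export
surface_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0) stop("mesh has no triangles")
  v <- mesh$vertices
  t <- mesh$triangles
  a <- sqrt(rowSums((v[t[, 1], , drop = FALSE] - v[t[, 2], , drop = FALSE])^2))
  b <- sqrt(rowSums((v[t[, 2], , drop = FALSE] - v[t[, 3], , drop = FALSE])^2))
  cc <- sqrt(rowSums((v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE])^2))
  p <- (a + b + cc) / 2
  sq <- p * (p - a) * (p - b) * (p - cc)
  degenerate <- sq <= 0
  s <- sqrt(pmax(sq, 0))
  out <- sum(s)
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Enclosed mesh volume
#'
#' Signed sum of the prisms between each triangle and its projection onto the
#' central plane through the vertex centroid normal to the minor principal
#' axis; for a closed, consistently oriented mesh this equals the
#' divergence-theorem volume and handles concave regions (grain cavities)
#' correctly. The result is orientation-independent (absolute value).
#'
#' @param mesh a watertight `triangle_mesh` (run [fill_holes()] first if
#'   needed).
#' @return volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  if (nrow(boundary_edges(mesh)) > 0)
    stop("mesh is not watertight; run fill_holes() first")
  v <- mesh$vertices
  fr <- pca_frame(v)
  p <- sweep(v, 2, fr$centroid) %*% t(fr$rotation)  # column 3 = minor axis
  t <- mesh$triangles
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]; z1 <- p[t[, 1], 3]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]; z2 <- p[t[, 2], 3]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]; z3 <- p[t[, 3], 3]
  signed_area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  abs(sum(signed_area * (z1 + z2 + z3) / 3))
}

#' Oriented-bounding-box dimensions
#'
#' PCA-aligns the grain and reads the per-axis extents
#' (`xmax - xmin`, ...), returned in decreasing order so that
#' `L >= W >= H`.
#'
#' @param grain a `point_cloud` (>= 3 non-collinear points).
#' @return named numeric `c(L, W, H)` in mm.
#' @export
obb_dimensions <- function(grain) {
  aligned <- transform_to_frame(if (inherits(grain, "point_cloud")) grain
                                else point_cloud(grain))
  ext <- apply(aligned$xyz, 2, function(v) max(v) - min(v))
  ext <- sort(ext, decreasing = TRUE)
  names(ext) <- c("L", "W", "H")
  ext
}

#' Projected area and perimeter along one principal axis
#'
#' Drops the named coordinate (projection onto the plane `x = 0`, `y = 0` or
#' `z = 0` of the PCA-aligned grain), triangulates the 2D footprint, and
#' reports the summed triangle area and the summed boundary-edge length of
#' the triangulation. With the default `max_edge_factor = Inf` the boundary
#' is the convex hull of the footprint (grain silhouettes are convex); a
#' finite factor discards triangles with edges beyond that multiple of the
#' median edge, letting the boundary follow concave silhouettes — use with
#' care on projections whose point density varies strongly.
#'
#' @param grain a PCA-aligned `point_cloud` (see [transform_to_frame()]).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param max_edge_factor silhouette tightness; `Inf` for the convex hull.
#' @return named numeric `c(PA, PP)` (mm^2, mm).
#' @export
project_traits <- function(grain, axis = c("x", "y", "z"),
                           max_edge_factor = Inf) {
  axis <- match.arg(axis)
  xyz <- if (inherits(grain, "point_cloud")) grain$xyz else as.matrix(grain)
  keep_cols <- setdiff(1:3, match(axis, c("x", "y", "z")))
  uv <- xyz[, keep_cols, drop = FALSE]
  dup <- duplicated(round(uv, 9))
  uv <- uv[!dup, , drop = FALSE]
  if (nrow(uv) < 3) stop("projection collapsed: fewer than 3 distinct points")
  ev <- eigen(cov(uv), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] / max(ev[1], 1e-300) < 1e-12)
    stop("projection collapsed: points are collinear")
  tri <- cpp_delaunay2(uv)
  e1 <- sqrt(rowSums((uv[tri[, 1], , drop = FALSE] - uv[tri[, 2], , drop = FALSE])^2))
  e2 <- sqrt(rowSums((uv[tri[, 2], , drop = FALSE] - uv[tri[, 3], , drop = FALSE])^2))
  e3 <- sqrt(rowSums((uv[tri[, 3], , drop = FALSE] - uv[tri[, 1], , drop = FALSE])^2))
  if (is.finite(max_edge_factor)) {
    med <- median(c(e1, e2, e3))
    keep <- pmax(e1, e2, e3) <= max_edge_factor * med
    tri <- tri[keep, , drop = FALSE]
  }
  if (nrow(tri) == 0) stop("projection triangulation is empty")
  a <- abs(0.5 * ((uv[tri[, 2], 1] - uv[tri[, 1], 1]) *
                    (uv[tri[, 3], 2] - uv[tri[, 1], 2]) -
                  (uv[tri[, 3], 1] - uv[tri[, 1], 1]) *
                    (uv[tri[, 2], 2] - uv[tri[, 1], 2])))
  pa <- sum(a)
  m2 <- triangle_mesh(cbind(uv, 0), tri)
  be <- boundary_edges(m2)
  pp <- sum(sqrt(rowSums((uv[be[, 1], , drop = FALSE] -
                            uv[be[, 2], , drop = FALSE])^2)))
  c(PA = pa, PP = pp)
}

#' Extract the eleven 3D shape traits of a grain
#'
#' PCA-aligns the grain, then computes length/width/thickness from the
#' oriented bounding box, volume and surface from the watertight surface
#' mesh, and projected area/perimeter onto the three principal planes.
#'
#' @param grain a segmented grain `point_cloud`.
#' @param min_points minimum cloud size accepted.
#' @param max_edge_factor silhouette tightness for the projections.
#' @return named numeric vector
#'   `L, W, H, V, S0, PA_x, PA_y, PA_z, PP_x, PP_y, PP_z`
#'   (mm, mm^3, mm^2 as appropriate).
#' @export
extract_traits <- function(grain, min_points = 30, max_edge_factor = Inf) {
  if (n_points(grain) < min_points)
    stop("too few points (", n_points(grain), ") for trait extraction")
  aligned <- transform_to_frame(grain)
  ext <- apply(aligned$xyz, 2, function(v) max(v) - min(v))
  ext <- sort(ext, decreasing = TRUE)
  mesh <- tryCatch(fill_holes(triangulate_surface(aligned, method = "spherical")),
                   error = function(e) stop("trait V/S0 failed: ",
                                            conditionMessage(e)))
  s0 <- surface_area(mesh)
  vol <- mesh_volume(mesh)
  pr <- lapply(c("x", "y", "z"), function(ax)
    tryCatch(project_traits(aligned, ax, max_edge_factor = max_edge_factor),
             error = function(e) stop("trait PA/PP (", ax, ") failed: ",
                                      conditionMessage(e))))
  out <- c(L = unname(ext[1]), W = unname(ext[2]), H = unname(ext[3]),
           V = vol, S0 = as.numeric(s0),
           PA_x = unname(pr[[1]]["PA"]), PA_y = unname(pr[[2]]["PA"]),
           PA_z = unname(pr[[3]]["PA"]),
           PP_x = unname(pr[[1]]["PP"]), PP_y = unname(pr[[2]]["PP"]),
           PP_z = unname(pr[[3]]["PP"]))
  out
}

#' Trait table for a list of grains
#'
#' @param grains list of grain `point_cloud`s.
#' @param ... passed to [extract_traits()].
#' @return data.frame with `grain_id`, `class_label` (if present) and the
#'   eleven trait columns.
#' @export
extract_trait_table <- function(grains, ...) {
  rows <- lapply(seq_along(grains), function(i) {
    tr <- extract_traits(grains[[i]], ...)
    cbind(data.frame(grain_id = i,
                     class_label = grains[[i]]$class_label %||% NA_character_),
          as.data.frame(as.list(tr)))
  })
  do.call(rbind, rows)
}
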