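#' @useDynLib graincloud, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cov quantile rnorm runif sd median prcomp predict
#' @importFrom utils head write.csv read.csv
NULL

#' Construct a point cloud
#'
#' The central container of the package: an `n x 3` coordinate matrix in mm,
#' with optional per-point unit normals, integer labels (0 = plate,
#' 1..k = grain id), an optional class label (`"filled"`/`"unfilled"`) and
#' free-form metadata.
#'
#' @param xyz numeric matrix with 3 columns (mm).
#' @param normals optional numeric matrix, same shape as `xyz`, unit rows.
#' @param labels optional integer vector, one per point.
#' @param class_label optional single string, e.g. `"filled"`.
#' @param meta optional named list of metadata (kept verbatim).
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(xyz, normals = NULL, labels = NULL,
                        class_label = NULL, meta = list()) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have exactly 3 columns")
  if (!is.numeric(xyz)) stop("xyz must be numeric")
  storage.mode(xyz) <- "double"
  colnames(xyz) <- c("x", "y", "z")
  n <- nrow(xyz)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(xyz)))
      stop("normals must match xyz in shape")
    colnames(normals) <- c("nx", "ny", "nz")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels must have one entry per point")
  }
  structure(list(xyz = xyz, normals = normals, labels = labels,
                 class_label = class_label, meta = meta),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points", nrow(x$xyz)))
  if (!is.null(x$normals)) cat(", with normals")
  if (!is.null(x$labels))
    cat(sprintf(", %d labels", length(unique(x$labels))))
  if (!is.null(x$class_label)) cat(sprintf(", class '%s'", x$class_label))
  cat("\n")
  rng <- apply(x$xyz, 2, range)
  cat(sprintf("  extent x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$xyz)

#' Subset a point cloud by point index
#'
#' Keeps normals, labels and metadata aligned with the retained points.
#'
#' @param cloud a `point_cloud`.
#' @param idx integer (or logical) index of points to keep.
#' @return a `point_cloud`.
#' @export
subset_cloud <- function(cloud, idx) {
  pc <- point_cloud(cloud$xyz[idx, , drop = FALSE],
                    normals = if (!is.null(cloud$normals))
                      cloud$normals[idx, , drop = FALSE],
                    labels = if (!is.null(cloud$labels)) cloud$labels[idx],
                    class_label = cloud$class_label,
                    meta = cloud$meta)
  if (!is.null(cloud$meta$outlier))
    pc$meta$outlier <- cloud$meta$outlier[idx]
  pc
}

# Run code under a temporary RNG state; bit-reproducible and side-effect free.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## ---------------------------------------------------------------------------
## File formats: ASCII PLY, PCD and plain XYZ, the formats structured-light
## scanner pipelines exchange. Normals are written when present.
## ---------------------------------------------------------------------------

#' Write a point cloud to disk
#'
#' Format is inferred from the file extension: `.ply` (ASCII PLY), `.pcd`
#' (ASCII PCD v0.7) or `.xyz` (whitespace-separated coordinates). A side-car
#' label file (`<path>.labels.csv` with columns `point_index,label`) is
#' written when the cloud carries labels.
#'
#' @param cloud a `point_cloud`.
#' @param path output file path; extension selects the format.
#' @param labels_sidecar write the label side-car when labels are present.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, labels_sidecar = TRUE) {
  ext <- tolower(tools::file_ext(path))
  xyz <- cloud$xyz
  nrm <- cloud$normals
  n <- nrow(xyz)
  fmt_mat <- function(m) apply(m, 1, function(r) paste(sprintf("%.8g", r), collapse = " "))
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", n),
             "property float x", "property float y", "property float z")
    if (!is.null(nrm))
      hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
    hdr <- c(hdr, "end_header")
    body <- fmt_mat(if (is.null(nrm)) xyz else cbind(xyz, nrm))
    writeLines(c(hdr, body), path)
  } else if (ext == "pcd") {
    fields <- if (is.null(nrm)) "x y z" else "x y z normal_x normal_y normal_z"
    k <- if (is.null(nrm)) 3L else 6L
    hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
             "VERSION 0.7",
             paste("FIELDS", fields),
             paste("SIZE", paste(rep(4L, k), collapse = " ")),
             paste("TYPE", paste(rep("F", k), collapse = " ")),
             paste("COUNT", paste(rep(1L, k), collapse = " ")),
             sprintf("WIDTH %d", n), "HEIGHT 1",
             "VIEWPOINT 0 0 0 1 0 0 0",
             sprintf("POINTS %d", n), "DATA ascii")
    body <- fmt_mat(if (is.null(nrm)) xyz else cbind(xyz, nrm))
    writeLines(c(hdr, body), path)
  } else if (ext == "xyz") {
    writeLines(fmt_mat(if (is.null(nrm)) xyz else cbind(xyz, nrm)), path)
  } else {
    stop("unsupported extension '", ext, "' (use ply, pcd or xyz)")
  }
  if (labels_sidecar && !is.null(cloud$labels)) {
    write.csv(data.frame(point_index = seq_len(n), label = cloud$labels),
              paste0(path, ".labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a point cloud from disk
#'
#' Counterpart of [write_cloud()]; reads ASCII PLY/PCD/XYZ. A label side-car
#' written by [write_cloud()] is picked up automatically.
#'
#' @param path file path; extension selects the parser.
#' @return a `point_cloud`.
#' @export
read_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    end <- which(lines == "end_header")[1]
    if (is.na(end)) stop("not an ASCII PLY file: ", path)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    props <- sub("^property \\S+ ", "",
                 grep("^property", lines[seq_len(end)], value = TRUE))
    body <- lines[(end + 1):(end + nv)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                   nrow = nv, byrow = TRUE)
    colnames(vals) <- props[seq_len(ncol(vals))]
    xyz <- vals[, c("x", "y", "z"), drop = FALSE]
    nrm <- if (all(c("nx", "ny", "nz") %in% props))
      vals[, c("nx", "ny", "nz"), drop = FALSE]
  } else if (ext == "pcd") {
    data_ln <- grep("^DATA", lines)[1]
    if (!grepl("ascii", lines[data_ln])) stop("only ASCII PCD supported")
    fields <- strsplit(sub("^FIELDS ", "", grep("^FIELDS", lines, value = TRUE)[1]),
                       " ")[[1]]
    body <- lines[(data_ln + 1):length(lines)]
    body <- body[nzchar(trimws(body))]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                   nrow = length(body), byrow = TRUE)
    colnames(vals) <- fields[seq_len(ncol(vals))]
    xyz <- vals[, c("x", "y", "z"), drop = FALSE]
    nrm <- if (all(c("normal_x", "normal_y", "normal_z") %in% fields))
      vals[, c("normal_x", "normal_y", "normal_z"), drop = FALSE]
  } else if (ext == "xyz") {
    body <- lines[nzchar(trimws(lines))]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                   nrow = length(body), byrow = TRUE)
    xyz <- vals[, 1:3, drop = FALSE]
    nrm <- if (ncol(vals) >= 6) vals[, 4:6, drop = FALSE]
  } else {
    stop("unsupported extension '", ext, "'")
  }
  labels <- NULL
  sidecar <- paste0(path, ".labels.csv")
  if (file.exists(sidecar)) labels <- read.csv(sidecar)$label
  point_cloud(xyz, normals = nrm, labels = labels)
}

#' k-nearest-neighbour indices
#'
#' @param xyz numeric `n x 3` matrix.
#' @param k neighbours per point (self excluded).
#' @return `n x k` integer matrix of indices, nearest first.
#' @export
knn_indices <- function(xyz, k) cpp_knn(as.matrix(xyz), as.integer(k))

#' Radius neighbourhoods
#'
#' @param xyz reference points, `n x 3`.
#' @param query query points, `m x 3` (defaults to `xyz`).
#' @param radius search radius (mm).
#' @return list of `m` integer vectors, each ordered by distance.
#' @export
radius_neighbors <- function(xyz, query = xyz, radius) {
  cpp_radius_neighbors(as.matrix(xyz), as.matrix(query), radius)
}
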