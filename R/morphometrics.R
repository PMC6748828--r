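#' Nematic-tensor texture orientation and anisotropy
#'
#' Gradient-based orientation statistic for fibrillar textures: at every
#' pixel with non-negligible intensity gradient the unit direction normal
#' to the gradient (the local fibril direction) contributes to the average
#' nematic tensor `M = mean(t t^T)`. The anisotropy score is the difference
#' of the eigenvalues of `M` (0 for a fully isotropic texture, 1 for a
#' perfectly parallel one, since `trace(M) = 1`) and the reported angle is
#' the principal eigenvector, in degrees in `(-90, 90]` measured from the
#' image x axis (columns).
#'
#' @param image numeric matrix, indexed `[y, x]` with y increasing upward.
#' @param roi optional region of interest: a logical mask of the same shape
#'   or a polygon (k x 2 matrix of (x, y) vertices, pixel units). At least
#'   100 pixels must remain.
#' @param grad_tol gradients with squared magnitude below
#'   `grad_tol * max` are treated as flat.
#' @return Object of class `anisotropy_score`: `angle` (degrees),
#'   `anisotropy` (0-1), `n_pixels`, `degenerate` (TRUE when the image is
#'   constant over the ROI; angle is then reported as 0 by convention).
#' @export
nematic_orientation_anisotropy <- function(image, roi = NULL,
                                           grad_tol = 1e-8) {
  stopifnot(is.matrix(image), is.numeric(image))
  mask <- resolve_roi(image, roi)
  if (sum(mask) < 100) stop("ROI must contain at least 100 pixels")
  ny <- nrow(image); nx <- ncol(image)
  # central differences on the interior
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  gx[, 2:(nx - 1)] <- (image[, 3:nx] - image[, 1:(nx - 2)]) / 2
  gy[2:(ny - 1), ] <- (image[3:ny, ] - image[1:(ny - 2), ]) / 2
  ok <- mask
  ok[c(1, ny), ] <- FALSE; ok[, c(1, nx)] <- FALSE
  g2 <- gx^2 + gy^2
  valid <- ok & g2 > grad_tol * max(g2[ok], 0)
  if (!any(valid))
    return(structure(list(angle = 0, anisotropy = 0,
                          n_pixels = sum(mask), degenerate = TRUE),
                     class = "anisotropy_score"))
  gn <- sqrt(g2[valid])
  tx <- -gy[valid] / gn            # fibril direction = normal to gradient
  ty <- gx[valid] / gn
  M <- matrix(c(mean(tx * tx), mean(tx * ty),
                mean(tx * ty), mean(ty * ty)), 2, 2)
  e <- eigen(M, symmetric = TRUE)
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  if (ang <= -90) ang <- ang + 180
  structure(list(angle = ang, anisotropy = e$values[1] - e$values[2],
                 n_pixels = sum(valid), degenerate = FALSE),
            class = "anisotropy_score")
}

#' @export
print.anisotropy_score <- function(x, ...) {
  cat(sprintf("anisotropy %.3f at %.1f deg (%d px%s)\n", x$anisotropy,
              x$angle, x$n_pixels, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

resolve_roi <- function(image, roi) {
  if (is.null(roi)) return(matrix(TRUE, nrow(image), ncol(image)))
  if (is.logical(roi)) {
    stopifnot(all(dim(roi) == dim(image)))
    return(roi)
  }
  roi <- as.matrix(roi)
  stopifnot(ncol(roi) == 2)
  px <- as.vector(col(image)); py <- as.vector(row(image))
  matrix(point_in_polygon(px, py, roi[, 1], roi[, 2]),
         nrow(image), ncol(image))
}

# even-odd ray crossing, vectorised over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Per-cell normalised anisotropy score
#'
#' `(a_max - a_min) / (a_max + a_min)` for a cell's maximum and minimum raw
#' anisotropy values: 0 for a purely isotropic array (`a_max = a_min`), 1
#' for a purely anisotropic one (`a_min = 0`). This per-cell normalisation
#' is a distinct statistic from the raw eigenvalue-difference anisotropy of
#' [nematic_orientation_anisotropy()].
#'
#' @param a_max,a_min per-cell extreme anisotropy values,
#'   `a_max >= a_min >= 0`, `a_max > 0`.
#' @return Dimensionless score in `[0, 1]`.
#' @export
normalized_cell_anisotropy <- function(a_max, a_min) {
  if (any(a_min < 0) || any(a_max < a_min))
    stop("require a_max >= a_min >= 0")
  if (any(a_max == 0))
    stop("undefined for a_max = a_min = 0")
  (a_max - a_min) / (a_max + a_min)
}

#' Hysteresis threshold filter
#'
#' Keeps the connected components (26-connectivity; 8-connectivity for 2D)
#' of the `low`-threshold mask that contain at least one voxel at or above
#' the `high` threshold — the standard two-threshold background removal for
#' cytosolic signal. Threshold rules follow the mean / mean + 2 SD reading:
#' `low = mean(image)` and `high = min(mean + 2 sd, max)`; explicit numeric
#' thresholds are also accepted.
#'
#' @param image 2D or 3D numeric array.
#' @param low,high numeric thresholds, or the strings `"mean"` and
#'   `"mean+2sd"` (capped at the image maximum).
#' @return Logical array of the input shape.
#' @export
hysteresis_filter <- function(image, low = "mean", high = "mean+2sd") {
  a <- as.array(image)
  d <- dim(a)
  if (length(d) == 2) d <- c(d, 1L)
  if (length(d) != 3) stop("image must be a 2D or 3D array")
  rule <- function(r) {
    if (is.numeric(r)) return(r)
    switch(r,
           "mean" = mean(a),
           "mean+2sd" = min(mean(a) + 2 * stats::sd(a), max(a)),
           stop("unknown threshold rule: ", r))
  }
  if (min(a) == max(a))          # constant image: nothing above background
    return(array(FALSE, dim(a)))
  lo <- rule(low); hi <- rule(high)
  if (lo > hi) stop("low threshold exceeds high threshold")
  cand <- array(a >= lo, dim(a))
  seed <- array(a >= hi, dim(a))
  if (!any(seed & cand)) {
    out <- array(FALSE, dim(a))
    return(out)
  }
  m <- .cpp_hysteresis_mask(as.vector(cand), as.vector(seed),
                            d[1], d[2], d[3])
  array(m, dim(a))
}

#' Manders colocalisation coefficients at cell-edge regions
#'
#' For each edge region, `M1 = sum(A over B > 0) / sum(A)` and symmetrically
#' `M2`; regions where either channel occupies less than `min_occupancy` of
#' the pixels are flagged as excluded (to avoid bias from nearly empty
#' regions).
#'
#' @param channel_a,channel_b registered equal-shape numeric arrays
#'   (typically hysteresis-filtered, with background at zero).
#' @param edge_regions named list of logical masks (one per edge), e.g. the
#'   region extending 1 um each way from the edge line.
#' @param min_occupancy exclusion threshold (default 0.1).
#' @return A data.frame with columns `edge, M1, M2, occupancy_a,
#'   occupancy_b, n_pixels, excluded`.
#' @export
manders_edge_colocalisation <- function(channel_a, channel_b, edge_regions,
                                        min_occupancy = 0.1) {
  stopifnot(all(dim(channel_a) == dim(channel_b)))
  if (!length(edge_regions)) stop("no edge regions supplied")
  if (is.null(names(edge_regions)))
    names(edge_regions) <- paste0("edge", seq_along(edge_regions))
  rows <- lapply(names(edge_regions), function(nm) {
    reg <- edge_regions[[nm]]
    stopifnot(all(dim(reg) == dim(channel_a)))
    if (!any(reg)) stop("empty edge region: ", nm)
    a <- channel_a[reg]; b <- channel_b[reg]
    occ_a <- mean(a > 0); occ_b <- mean(b > 0)
    M1 <- if (sum(a) > 0) sum(a[b > 0]) / sum(a) else NA_real_
    M2 <- if (sum(b) > 0) sum(b[a > 0]) / sum(b) else NA_real_
    data.frame(edge = nm, M1 = M1, M2 = M2, occupancy_a = occ_a,
               occupancy_b = occ_b, n_pixels = sum(reg),
               excluded = occ_a < min_occupancy | occ_b < min_occupancy)
  })
  do.call(rbind, rows)
}

#' Mean root diameter from two outline traces
#'
#' For each trace pixel outside the tip-exclusion arc length, the Euclidean
#' distance to its nearest neighbour on the opposite trace is computed; the
#' mean over all evaluated pixels of both sides is the root diameter. The
#' tip-most region (default 100 um) is excluded to avoid the tapering tip.
#'
#' @param side_a,side_b m x 2 matrices of pixel coordinates tracing the two
#'   root flanks; the tip end is the first row of each trace.
#' @param pixel_size um per pixel.
#' @param tip_exclusion arc length from the tip to exclude (um).
#' @return Mean diameter (um).
#' @export
mean_root_diameter <- function(side_a, side_b, pixel_size = 1,
                               tip_exclusion = 100) {
  side_a <- as.matrix(side_a); side_b <- as.matrix(side_b)
  stopifnot(ncol(side_a) == 2, ncol(side_b) == 2,
            nrow(side_a) >= 2, nrow(side_b) >= 2)
  retain <- function(tr) {
    s <- c(0, cumsum(sqrt(rowSums(diff(tr)^2)))) * pixel_size
    if (max(s) <= tip_exclusion)
      stop("trace shorter than the tip exclusion")
    tr[s >= tip_exclusion, , drop = FALSE]
  }
  ra <- retain(side_a); rb <- retain(side_b)
  d_ab <- nearest_distances(ra, side_b) * pixel_size
  d_ba <- nearest_distances(rb, side_a) * pixel_size
  mean(c(d_ab, d_ba))
}

# exact nearest-neighbour distances from each row of `from` to `to`,
# chunked to bound memory
nearest_distances <- function(from, to, chunk = 2048L) {
  out <- numeric(nrow(from))
  t2 <- rowSums(to^2)
  for (s in seq(1L, nrow(from), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(from))
    f <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), t2, "+") - 2 * tcrossprod(f, to)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Decompose cell growth between two timepoints
#'
#' Total volume growth from watertight surface-mesh volumes, and
#' directional growth as the ratio of cell extents along the organ frame
#' axes (longitudinal, radial, circumferential) — exact for affine growth.
#' Cells are classified `meristematic` when volume growth is below the
#' threshold (default 1.5-fold per interval), `elongation` otherwise.
#'
#' @param mesh_t0,mesh_t1 triangulated surface meshes of the same cell:
#'   lists with `vertices` (n x 3) and `faces` (m x 3, consistent
#'   orientation).
#' @param frame 3 x 3 matrix whose rows are the orthonormal longitudinal,
#'   radial and circumferential unit vectors (default identity).
#' @param threshold volume-growth zone threshold.
#' @return Object of class `growth_report` with `volume_ratio`,
#'   `longitudinal_ratio`, `radial_ratio`, `circumferential_ratio`, `zone`.
#' @export
growth_decomposition <- function(mesh_t0, mesh_t1, frame = diag(3),
                                 threshold = 1.5) {
  frame <- as.matrix(frame)
  if (max(abs(crossprod(frame) - diag(3))) > 1e-8)
    stop("frame must be orthonormal")
  v0 <- surface_mesh_volume(mesh_t0)
  v1 <- surface_mesh_volume(mesh_t1)
  ext <- function(m) apply(m$vertices %*% t(frame), 2,
                           function(x) diff(range(x)))
  r <- ext(mesh_t1) / ext(mesh_t0)
  vol <- v1 / v0
  structure(list(volume_ratio = vol, longitudinal_ratio = r[1],
                 radial_ratio = r[2], circumferential_ratio = r[3],
                 threshold = threshold,
                 zone = if (vol < threshold) "meristematic" else "elongation"),
            class = "growth_report")
}

#' @export
print.growth_report <- function(x, ...) {
  cat(sprintf(
    "growth: vol %.3f, long %.3f, rad %.3f, circ %.3f -> %s\n",
    x$volume_ratio, x$longitudinal_ratio, x$radial_ratio,
    x$circumferential_ratio, x$zone))
  invisible(x)
}

# signed volume by the divergence theorem; errors when not watertight
surface_mesh_volume <- function(mesh) {
  v <- as.matrix(mesh$vertices); f <- as.matrix(mesh$faces)
  stopifnot(ncol(v) == 3, ncol(f) == 3)
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) stop("mesh is not watertight")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
             a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  abs(vol)
}

#' Edge intensity enrichment of a labelled cell
#'
#' Restricts the analysis to the outer shell of the cell (voxels within
#' `shell_depth` of the outer surface) and treats voxels within `edge_band`
#' of an anticlinal wall as edge voxels, assigned to the nearest of the four
#' outer-face edges. Per-edge relative intensity is the edge mean divided
#' by the voxel-weighted mean over all edge voxels of the cell, so the
#' weighted mean of the reported ratios is 1 and the statistic is invariant
#' to intensity rescaling.
#'
#' @param volume 3D intensity array (x, y, z index order).
#' @param surface a [cell_surface()] describing the labelled cell.
#' @param shell_depth outer-shell depth (um, default 2).
#' @param edge_band anticlinal-wall distance defining edges (um, default 1).
#' @return Object of class `enrichment_report`: data.frame `edges` with
#'   `edge, class, length, n_voxels, mean_intensity, relative_intensity`.
#' @export
edge_enrichment <- function(volume, surface, shell_depth = 2,
                            edge_band = 1) {
  stopifnot(inherits(surface, "cell_surface"))
  masks <- edge_voxel_masks(dim(volume), surface, shell_depth, edge_band)
  if (!any(masks$edge_id > 0)) stop("edge band contains no voxels")
  ids <- sort(unique(masks$edge_id[masks$edge_id > 0]))
  all_mean <- mean(volume[masks$edge_id > 0])
  rows <- lapply(ids, function(e) {
    sel <- masks$edge_id == e
    m <- mean(volume[sel])
    data.frame(edge = surface$edges$edge[e], class = surface$edges$class[e],
               length = surface$edges$length[e], n_voxels = sum(sel),
               mean_intensity = m, relative_intensity = m / all_mean)
  })
  structure(list(edges = do.call(rbind, rows),
                 mean_edge_intensity = all_mean),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("edge enrichment (relative to mean edge intensity):\n")
  print(x$edges[, c("edge", "class", "length", "relative_intensity")],
        row.names = FALSE)
  invisible(x)
}

#' Labelled cuboid cell surface
#'
#' A minimal labelled-surface description for edge-enrichment analysis: an
#' axis-aligned cuboid cell (x longitudinal, y transverse, z radial with
#' the outer organ surface at high z) with its four outer-face edges
#' classified by direction — an edge is `transverse` when its line runs
#' within 45 degrees of the transverse axis, else `longitudinal`.
#'
#' @param box numeric `c(x0, x1, y0, y1, z0, z1)` cell extents (um).
#' @param voxel_size um per voxel (isotropic).
#' @return Object of class `cell_surface` with an `edges` data.frame.
#' @export
cell_surface <- function(box, voxel_size = 0.25) {
  stopifnot(length(box) == 6, box[2] > box[1], box[4] > box[3],
            box[6] > box[5])
  edges <- data.frame(
    edge = c("xmin", "xmax", "ymin", "ymax"),
    class = c("transverse", "transverse", "longitudinal", "longitudinal"),
    length = c(box[4] - box[3], box[4] - box[3],
               box[2] - box[1], box[2] - box[1]))
  structure(list(box = box, voxel_size = voxel_size, edges = edges),
            class = "cell_surface")
}

# voxel classification for edge_enrichment; returns edge_id array
# (0 = not an edge voxel) aligned with the volume
edge_voxel_masks <- function(dims, surface, shell_depth, edge_band) {
  vs <- surface$voxel_size
  b <- surface$box
  cx <- (seq_len(dims[1]) - 0.5) * vs
  cy <- (seq_len(dims[2]) - 0.5) * vs
  cz <- (seq_len(dims[3]) - 0.5) * vs
  X <- array(rep(cx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  inside <- X >= b[1] & X <= b[2] & Y >= b[3] & Y <= b[4] &
    Z >= b[5] & Z <= b[6]
  shell <- inside & (b[6] - Z) <= shell_depth
  dwall <- array(Inf, c(dims, 4))
  dw <- list(X - b[1], b[2] - X, Y - b[3], b[4] - Y)
  dmin <- pmin(dw[[1]], dw[[2]], dw[[3]], dw[[4]])
  nearest <- array(0L, dims)
  for (w in 4:1) nearest[dw[[w]] == dmin] <- w
  edge_id <- array(0L, dims)
  sel <- shell & dmin <= edge_band
  edge_id[sel] <- nearest[sel]
  list(edge_id = edge_id, shell = shell)
}

#' Read and write grayscale TIFF images
#'
#' Thin wrappers: images are numeric matrices (2D) or x-y-z arrays
#' (stacks); values are stored as 32-bit float samples.
#'
#' @param path file path.
#' @return `read_image_tiff` returns a matrix or 3D array.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) == 1) return(img[[1]])
  simplify2array(img)
}

#' @rdname read_image_tiff
#' @param image matrix or 3D array.
#' @export
write_image_tiff <- function(image, path) {
  if (is.matrix(image)) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
  } else {
    slices <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Write a triangulated surface mesh as ASCII PLY
#'
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @param path output path.
#' @export
write_surface_ply <- function(mesh, path) {
  v <- as.matrix(mesh$vertices); f <- as.matrix(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(v, digits = 8, trim = TRUE), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, f - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write outline traces as CSV
#'
#' Traces are tables with columns `x, y` (pixel coordinates, tip first),
#' the format produced by manual outline tracing.
#'
#' @param path file path.
#' @return `read_trace_csv` returns an m x 2 matrix.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("trace CSV must have columns x and y")
  as.matrix(df[, c("x", "y")])
}

#' @rdname read_trace_csv
#' @param trace m x 2 matrix of pixel coordinates.
#' @export
write_trace_csv <- function(trace, path) {
  trace <- as.matrix(trace)
  utils::write.csv(data.frame(x = trace[, 1], y = trace[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.enrichment_report <- function(x, ...) x$edges

#' @export
as.data.frame.growth_report <- function(x, ...) {
  data.frame(volume_ratio = x$volume_ratio,
             longitudinal_ratio = x$longitudinal_ratio,
             radial_ratio = x$radial_ratio,
             circumferential_ratio = x$circumferential_ratio,
             zone = x$zone)
}
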