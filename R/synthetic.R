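# Seeded generators for every input the morphometric statistics consume.
# All randomness goes through with_local_seed(): the global RNG state is
# saved and restored, so identical (seed, parameters) give bit-identical
# payloads and callers' random streams are untouched.

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian blur with reflected edges
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (q in seq_along(k))
      out <- out + k[q] * mp[q:(q + n - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Synthetic oriented fibril texture
#'
#' A band-limited texture blending parallel stripes at a known angle with
#' isotropic filtered noise: the gradient-nematic anisotropy of the result
#' increases with `coherence` (0 fully isotropic, 1 parallel stripes).
#' Stands in for cortical-microtubule array images.
#'
#' @param angle fibril direction in degrees from the x axis.
#' @param coherence mixing weight in `[0, 1]`.
#' @param noise_sd additive Gaussian pixel noise (image is clipped at 0).
#' @param size image side (pixels).
#' @param seed integer seed.
#' @param wavelength stripe wavelength (pixels).
#' @return List with `image` (size x size matrix, `[y, x]`) and `truth`
#'   (`angle`, `coherence`, `seed`).
#' @export
make_fibril_texture <- function(angle = 30, coherence = 1, noise_sd = 0,
                                size = 128, seed = 1, wavelength = 8) {
  if (coherence < 0 || coherence > 1) stop("coherence must lie in [0, 1]")
  with_local_seed(seed, {
    xs <- seq_len(size); ys <- seq_len(size)
    X <- matrix(rep(xs, each = size), size, size)   # [y, x]
    Y <- matrix(rep(ys, times = size), size, size)
    th <- angle * pi / 180
    # stripes constant along (cos th, sin th): phase varies along the normal
    phase <- (-sin(th) * X + cos(th) * Y) * 2 * pi / wavelength
    stripes <- sin(phase + stats::runif(1, 0, 2 * pi))
    iso <- gauss_blur(matrix(stats::rnorm(size^2), size, size),
                      wavelength / 4)
    norm1 <- function(m) (m - mean(m)) / stats::sd(m)
    img <- coherence * norm1(stripes) + (1 - coherence) * norm1(iso)
    img <- img + 3     # positive baseline before clipping
    if (noise_sd > 0)
      img <- img + stats::rnorm(size^2, sd = noise_sd)
    img <- pmax(img, 0)
    list(image = img, truth = list(angle = angle, coherence = coherence,
                                   seed = seed))
  })
}

#' Synthetic two-channel colocalisation pair
#'
#' Binary supports with controlled overlap plus optional positive noise.
#' With equal occupancies and no noise, the expected Manders coefficients
#' equal the realized overlap counts recorded in the truth.
#'
#' @param overlap fraction of the smaller support shared by both channels.
#' @param occupancy_a,occupancy_b support fractions of the image.
#' @param size image side (pixels).
#' @param seed integer seed.
#' @param noise_sd multiplicative-intensity jitter on the supports.
#' @return List with `channel_a`, `channel_b` and `truth` (`M1`, `M2`,
#'   realized pixel counts).
#' @export
make_colocalised_pair <- function(overlap, occupancy_a, occupancy_b,
                                  size = 64, seed = 1, noise_sd = 0) {
  for (v in c(overlap, occupancy_a, occupancy_b))
    if (v < 0 || v > 1) stop("fractions must lie in [0, 1]")
  n <- size^2
  na <- round(occupancy_a * n); nb <- round(occupancy_b * n)
  nab <- round(overlap * min(na, nb))
  if (na + nb - nab > n)
    stop("infeasible occupancy/overlap combination")
  if (na == 0 || nb == 0) stop("occupancies must be positive")
  with_local_seed(seed, {
    perm <- sample.int(n)
    ia <- perm[seq_len(na)]
    ib <- c(ia[seq_len(nab)],
            if (nb > nab) perm[(na + 1):(na + nb - nab)])
    intens <- function(idx) {
      ch <- numeric(n)
      ch[idx] <- 1
      if (noise_sd > 0)
        ch[idx] <- pmax(ch[idx] + stats::rnorm(length(idx), sd = noise_sd),
                        .Machine$double.eps)
      matrix(ch, size, size)
    }
    list(channel_a = intens(ia), channel_b = intens(ib),
         truth = list(M1 = nab / na, M2 = nab / nb, n_a = na, n_b = nb,
                      n_ab = nab, seed = seed))
  })
}

#' Synthetic tapering root outline
#'
#' Two flank traces of a root whose diameter rises linearly from
#' `0.5 * diameter` at the tip to `diameter` over `taper_length`, then
#' stays constant. The truth records the analytic mean diameter over the
#' region retained after a tip exclusion.
#'
#' @param diameter shaft diameter (um).
#' @param taper_length taper extent from the tip (um); 0 for parallel sides.
#' @param noise_sd flank jitter (pixels).
#' @param length root length (um).
#' @param pixel_size um per pixel.
#' @param seed integer seed.
#' @param tip_exclusion exclusion used for the recorded truth (um).
#' @return List with `side_a`, `side_b` (pixel-coordinate traces, tip
#'   first) and `truth` (`mean_diameter_retained`, parameters).
#' @export
make_root_outline <- function(diameter = 100, taper_length = 150,
                              noise_sd = 0, length = 600, pixel_size = 1,
                              seed = 1, tip_exclusion = 100) {
  stopifnot(diameter > 0, length > taper_length, length > tip_exclusion)
  with_local_seed(seed, {
    x <- seq(0, length, by = pixel_size)
    d <- if (taper_length > 0)
      diameter * (0.5 + 0.5 * pmin(x / taper_length, 1))
    else rep(diameter, length(x))
    ya <- d / 2; yb <- -d / 2
    if (noise_sd > 0) {
      ya <- ya + stats::rnorm(length(x), sd = noise_sd) * pixel_size
      yb <- yb + stats::rnorm(length(x), sd = noise_sd) * pixel_size
    }
    # analytic mean of d(x) over [tip_exclusion, length]
    mean_seg <- function(a, b) {   # mean of d over [a, b], noiseless
      if (a >= b) return(0)
      tl <- taper_length
      f <- function(x0, x1) {      # integral over taper part
        0.5 * diameter * (x1 - x0) +
          0.5 * diameter * (x1^2 - x0^2) / (2 * tl)
      }
      tot <- 0
      if (a < tl && tl > 0) tot <- tot + f(a, min(b, tl))
      if (b > tl) tot <- tot + diameter * (b - max(a, tl))
      tot / (b - a)
    }
    truth_mean <- if (taper_length > 0)
      mean_seg(tip_exclusion, length) else diameter
    list(side_a = cbind(x = x / pixel_size, y = ya / pixel_size),
         side_b = cbind(x = x / pixel_size, y = yb / pixel_size),
         truth = list(mean_diameter_retained = truth_mean,
                      diameter = diameter, taper_length = taper_length,
                      tip_exclusion = tip_exclusion, seed = seed))
  })
}

#' Triangulated cuboid surface mesh
#'
#' @param dims `c(Lx, Ly, Lz)` extents (um).
#' @param origin corner position.
#' @return List with `vertices` (8 x 3) and `faces` (12 x 3, outward
#'   orientation).
#' @export
box_surface_mesh <- function(dims = c(10, 5, 5), origin = c(0, 0, 0)) {
  corners <- as.matrix(expand.grid(c(0, dims[1]), c(0, dims[2]),
                                   c(0, dims[3])))
  v <- sweep(corners, 2, origin, "+")
  dimnames(v) <- NULL
  faces <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = max
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = max
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = max
  list(vertices = v, faces = faces)
}

#' Synthetic cell mesh pair across a growth interval
#'
#' A cuboid cell surface and its affinely grown copy (axis scale factors
#' about the cell centroid), optionally with vertex jitter (off by
#' default). Stands in for segmented time-lapse cell meshes.
#'
#' @param dims base cell extents `c(L, R, C)` along the organ frame (um).
#' @param scale factors `c(sL, sR, sC)`.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @param jitter_sd vertex jitter (um).
#' @return List with `mesh_t0`, `mesh_t1` and `truth` (expected growth
#'   ratios).
#' @export
make_cell_timepair <- function(dims = c(10, 5, 5), scale = c(1.2, 1, 1),
                               seed = 1, jitter_sd = 0) {
  stopifnot(length(scale) == 3, all(scale > 0))
  m0 <- box_surface_mesh(dims)
  ctr <- colMeans(m0$vertices)
  m1 <- m0
  m1$vertices <- sweep(sweep(m0$vertices, 2, ctr, "-") %*% diag(scale),
                       2, ctr, "+")
  if (jitter_sd > 0) {
    m1$vertices <- with_local_seed(seed, m1$vertices +
      matrix(stats::rnorm(length(m1$vertices), sd = jitter_sd),
             ncol = 3))
  }
  list(mesh_t0 = m0, mesh_t1 = m1,
       truth = list(volume_ratio = prod(scale),
                    longitudinal_ratio = scale[1],
                    radial_ratio = scale[2],
                    circumferential_ratio = scale[3], seed = seed))
}

#' Synthetic edge-enriched intensity volume with labelled surface
#'
#' Builds a cuboid cell in a voxel volume whose outer-shell edge bands
#' carry prescribed relative intensities over a uniform background, plus
#' clipped Gaussian noise. The truth records the exact noiseless relative
#' enrichment per edge (voxel-weighted normalisation), computed from the
#' generator's own voxel assignment.
#'
#' @param edge_ratios named numeric `c(xmin=, xmax=, ymin=, ymax=)` edge
#'   intensity multipliers over background.
#' @param background baseline intensity.
#' @param noise_sd additive Gaussian noise (clipped at 0).
#' @param voxel_size um per voxel.
#' @param box cell extents `c(x0, x1, y0, y1, z0, z1)` (um).
#' @param margin volume padding around the cell (um).
#' @param shell_depth,edge_band geometry of the enrichment analysis (um).
#' @param seed integer seed.
#' @return List with `volume`, `surface` (a [cell_surface()]) and `truth`.
#' @export
make_edge_intensity_cell <- function(edge_ratios = c(xmin = 1, xmax = 1,
                                                     ymin = 2, ymax = 2),
                                     background = 1, noise_sd = 0,
                                     voxel_size = 0.25,
                                     box = c(2, 14, 2, 8, 0, 6),
                                     margin = 1, shell_depth = 2,
                                     edge_band = 1, seed = 1) {
  stopifnot(all(edge_ratios > 0), background > 0)
  surface <- cell_surface(box + margin, voxel_size)  # translate by margin
  dims <- ceiling((c(surface$box[2], surface$box[4], surface$box[6]) +
                     margin) / voxel_size)
  masks <- edge_voxel_masks(dims, surface, shell_depth, edge_band)
  base <- array(background, dims)
  ord <- c("xmin", "xmax", "ymin", "ymax")
  for (w in seq_len(4)) {
    sel <- masks$edge_id == w
    base[sel] <- background * edge_ratios[[ord[w]]]
  }
  # exact noiseless relative enrichment under voxel-weighted normalisation
  nv <- sapply(seq_len(4), function(w) sum(masks$edge_id == w))
  mu <- background * unname(edge_ratios[ord])
  mbar <- sum(nv * mu) / sum(nv)
  vol <- base
  if (noise_sd > 0)
    vol <- with_local_seed(seed, pmax(base +
      array(stats::rnorm(length(base), sd = noise_sd), dims), 0))
  list(volume = vol, surface = surface,
       truth = list(relative_intensity =
                      stats::setNames(mu / mbar, ord),
                    n_voxels = stats::setNames(nv, ord), seed = seed))
}
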