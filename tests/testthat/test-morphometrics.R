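# image- and mesh-derived statistics, scored against generator ground truth

test_that("nematic estimator recovers stripe orientation within 2 degrees", {
  for (ang in c(0, 30, -60, 75)) {
    fx <- make_fibril_texture(angle = ang, coherence = 1, noise_sd = 0,
                              size = 128, seed = 4)
    sc <- nematic_orientation_anisotropy(fx$image)
    d <- abs(sc$angle - ang)
    expect_lt(min(d, 180 - d), 2)
    expect_gt(sc$anisotropy, 0.9)
  }
})

test_that("anisotropy is monotone in generator coherence and bounded", {
  co <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cc)
    nematic_orientation_anisotropy(
      make_fibril_texture(30, cc, noise_sd = 0.2, size = 128,
                          seed = 7)$image)$anisotropy, 0)
  expect_true(all(diff(co) > 0))
  expect_true(all(co >= 0 & co <= 1))
  expect_lt(co[1], 0.05)
})

test_that("nematic estimator is rotation-equivariant and scale-invariant", {
  fx <- make_fibril_texture(20, 1, 0, 128, seed = 5)
  sc0 <- nematic_orientation_anisotropy(fx$image)
  # 90-degree image rotation shifts the reported angle by 90
  rot <- t(fx$image)[, nrow(fx$image):1]
  sc90 <- nematic_orientation_anisotropy(rot)
  d <- abs(((sc90$angle - sc0$angle - 90) + 90) %% 180 - 90)
  expect_lt(d, 3)
  expect_equal(sc90$anisotropy, sc0$anisotropy, tolerance = 0.05)
  # positive rescaling leaves both statistics unchanged
  sc_scaled <- nematic_orientation_anisotropy(3.7 * fx$image)
  expect_equal(sc_scaled$angle, sc0$angle, tolerance = 1e-8)
  expect_equal(sc_scaled$anisotropy, sc0$anisotropy, tolerance = 1e-8)
})

test_that("constant images are reported as degenerate isotropic", {
  sc <- nematic_orientation_anisotropy(matrix(1, 64, 64))
  expect_true(sc$degenerate)
  expect_equal(sc$anisotropy, 0)
  expect_equal(sc$angle, 0)
})

test_that("polygon ROIs restrict the analysis and enforce the size floor", {
  fx <- make_fibril_texture(40, 1, 0, 96, seed = 9)
  roi <- cbind(c(20, 70, 70, 20), c(20, 20, 70, 70))
  sc <- nematic_orientation_anisotropy(fx$image, roi)
  expect_lt(abs(sc$angle - 40), 2)
  expect_lt(sc$n_pixels, 96^2)
  small <- cbind(c(10, 14, 14, 10), c(10, 10, 14, 14))
  expect_error(nematic_orientation_anisotropy(fx$image, small), "100")
})

test_that("per-cell anisotropy normalisation matches its printed endpoints", {
  expect_equal(normalized_cell_anisotropy(0.25, 0.25), 0)
  expect_equal(normalized_cell_anisotropy(0.3, 0), 1)
  expect_equal(normalized_cell_anisotropy(0.3, 0.1), 0.5)
  expect_error(normalized_cell_anisotropy(0, 0), "undefined")
  expect_error(normalized_cell_anisotropy(0.1, 0.3), "a_max")
})

test_that("hysteresis filter keeps seeded components and only those", {
  img <- matrix(0, 40, 40)
  img[10:15, 10:15] <- 1       # bright blob: above high
  img[30:32, 30:32] <- 0.3     # dim blob: above low only
  m <- hysteresis_filter(img, low = 0.2, high = 0.8)
  expect_equal(sum(m[10:15, 10:15]), 36)
  expect_equal(sum(m), 36)
  # dim blob below high everywhere: empty mask
  m2 <- hysteresis_filter(img * 0.5, low = 0.1, high = 0.8)
  expect_equal(sum(m2), 0)
  expect_equal(sum(hysteresis_filter(array(0, c(8, 8, 3)))), 0)
  expect_error(hysteresis_filter(img, low = 0.9, high = 0.1), "exceeds")
  # mask is always a subset of the low-threshold set
  m3 <- hysteresis_filter(img, low = 0.25, high = 0.9)
  expect_true(all(img[m3] >= 0.25))
  # mean / mean+2sd rules recover an isolated bright blob over noise
  set.seed(12)
  img2 <- matrix(abs(rnorm(64^2, 0.1, 0.02)), 64, 64)
  img2[20:26, 20:26] <- 1
  m4 <- hysteresis_filter(img2)
  expect_true(all(m4[20:26, 20:26]))
  expect_lt(sum(m4), 2 * 49)
  # 3D stacks: a bright component spanning slices survives
  st <- array(0, c(16, 16, 4))
  st[4:6, 4:6, 2] <- 1
  st[4:6, 4:6, 3] <- 0.4
  m5 <- hysteresis_filter(st, low = 0.3, high = 0.8)
  expect_true(all(m5[4:6, 4:6, 2:3]))
})

test_that("Manders coefficients hit their analytic endpoints", {
  a <- matrix(0, 32, 32); a[1:16, ] <- 1
  reg <- list(all = matrix(TRUE, 32, 32))
  same <- manders_edge_colocalisation(a, a, reg)
  expect_equal(same$M1, 1)
  expect_equal(same$M2, 1)
  b <- matrix(0, 32, 32); b[17:32, ] <- 1
  disj <- manders_edge_colocalisation(a, b, reg)
  expect_equal(disj$M1, 0)
  expect_equal(disj$M2, 0)
  expect_false(disj$excluded)   # both occupy 50%
  expect_error(manders_edge_colocalisation(a, b, list()), "regions")
  empty <- list(r = matrix(FALSE, 32, 32))
  expect_error(manders_edge_colocalisation(a, b, empty), "empty")
})

test_that("generator-controlled overlap is recovered and the 10% rule fires", {
  cp <- make_colocalised_pair(0.5, 0.3, 0.3, size = 64, seed = 2)
  reg <- list(all = matrix(TRUE, 64, 64))
  mc <- manders_edge_colocalisation(cp$channel_a, cp$channel_b, reg)
  expect_equal(mc$M1, cp$truth$M1, tolerance = 0.02)
  expect_equal(mc$M2, cp$truth$M2, tolerance = 0.02)
  low <- make_colocalised_pair(0.5, 0.05, 0.3, size = 64, seed = 2)
  mc2 <- manders_edge_colocalisation(low$channel_a, low$channel_b, reg)
  expect_true(mc2$excluded)
})

test_that("root diameter is exact on parallel traces and unbiased on taper", {
  par <- make_root_outline(diameter = 80, taper_length = 0, noise_sd = 0,
                           length = 500, pixel_size = 1, seed = 3)
  expect_equal(mean_root_diameter(par$side_a, par$side_b, 1, 100), 80)
  # straight 50 um apart, no exclusion structure beyond the tip
  a <- cbind(seq(0, 400, by = 1), rep(25, 401))
  b <- cbind(seq(0, 400, by = 1), rep(-25, 401))
  expect_equal(mean_root_diameter(a, b, 1, 100), 50)
  tap <- make_root_outline(diameter = 100, taper_length = 150, noise_sd = 0,
                           length = 600, pixel_size = 1, seed = 3)
  d <- mean_root_diameter(tap$side_a, tap$side_b, 1, 100)
  expect_lt(abs(d - tap$truth$mean_diameter_retained) /
              tap$truth$mean_diameter_retained, 0.01)
  # removing the tip exclusion admits the narrow tip: smaller mean
  d0 <- mean_root_diameter(tap$side_a, tap$side_b, 1, 0)
  expect_lt(d0, d)
  expect_error(mean_root_diameter(a[1:50, ], b[1:50, ], 1, 100), "shorter")
  # sub-pixel accuracy on noisy parallel-sided roots
  noisy <- make_root_outline(diameter = 80, taper_length = 0, noise_sd = 0.3,
                             length = 500, pixel_size = 1, seed = 8)
  expect_lt(abs(mean_root_diameter(noisy$side_a, noisy$side_b, 1, 100) - 80),
            1)
})

test_that("growth decomposition is exact on affine growth", {
  tp <- make_cell_timepair(scale = c(2, 1, 1))
  g <- growth_decomposition(tp$mesh_t0, tp$mesh_t1)
  expect_equal(g$volume_ratio, 2)
  expect_equal(g$longitudinal_ratio, 2)
  expect_equal(g$radial_ratio, 1)
  expect_equal(g$circumferential_ratio, 1)
  expect_equal(g$zone, "elongation")
  same <- growth_decomposition(tp$mesh_t0, tp$mesh_t0)
  expect_equal(same$volume_ratio, 1)
  expect_equal(same$zone, "meristematic")
  iso <- make_cell_timepair(scale = c(1.2, 1.2, 1.2))
  gi <- growth_decomposition(iso$mesh_t0, iso$mesh_t1)
  expect_equal(gi$volume_ratio, 1.728)
  expect_equal(gi$zone, "elongation")
  # 1.5-fold zone threshold splits just below and above
  lo <- make_cell_timepair(scale = c(1.49, 1, 1))
  expect_equal(growth_decomposition(lo$mesh_t0, lo$mesh_t1)$zone,
               "meristematic")
  hi <- make_cell_timepair(scale = c(1.51, 1, 1))
  expect_equal(growth_decomposition(hi$mesh_t0, hi$mesh_t1)$zone,
               "elongation")
  # rotated organ frame measures the same growth along its own axes
  tp2 <- make_cell_timepair(scale = c(1.3, 1.1, 1))
  g2 <- growth_decomposition(tp2$mesh_t0, tp2$mesh_t1, frame = diag(3)[c(2, 3, 1), ])
  expect_equal(g2$longitudinal_ratio, 1.1)
  expect_equal(g2$radial_ratio, 1)
  expect_equal(g2$circumferential_ratio, 1.3)
  expect_error(growth_decomposition(tp$mesh_t0, tp$mesh_t1,
                                    frame = matrix(1, 3, 3)), "orthonormal")
  broken <- tp$mesh_t1
  broken$faces <- broken$faces[-1, ]
  expect_error(growth_decomposition(tp$mesh_t0, broken), "watertight")
})

test_that("edge enrichment recovers generator ratios and normalises to 1", {
  ec <- make_edge_intensity_cell(edge_ratios = c(xmin = 1, xmax = 1,
                                                 ymin = 2, ymax = 2),
                                 noise_sd = 0.05, seed = 6)
  er <- edge_enrichment(ec$volume, ec$surface)
  tab <- er$edges
  expect_setequal(tab$class, c("transverse", "longitudinal"))
  long <- tab$relative_intensity[tab$class == "longitudinal"]
  trans <- tab$relative_intensity[tab$class == "transverse"]
  expect_true(all(long > 1) && all(trans < 1))
  expect_equal(mean(long) / mean(trans), 2, tolerance = 0.1)
  expect_equal(tab$relative_intensity,
               unname(ec$truth$relative_intensity[tab$edge]),
               tolerance = 0.1)
  # voxel-weighted mean of relative intensities is 1 by construction
  expect_equal(sum(tab$relative_intensity * tab$n_voxels) /
                 sum(tab$n_voxels), 1, tolerance = 1e-12)
  # uniform volume: every enrichment is 1
  un <- make_edge_intensity_cell(edge_ratios = c(xmin = 1, xmax = 1,
                                                 ymin = 1, ymax = 1),
                                 noise_sd = 0, seed = 6)
  eu <- edge_enrichment(un$volume, un$surface)
  expect_equal(eu$edges$relative_intensity, rep(1, 4))
  # intensity rescaling leaves the report unchanged
  er2 <- edge_enrichment(2.5 * ec$volume, ec$surface)
  expect_equal(er2$edges$relative_intensity, tab$relative_intensity)
  # translating volume and surface jointly leaves the report unchanged
  shift <- 8L  # voxels
  vol_t <- array(1, dim = dim(ec$volume) + c(shift, 0, 0))
  vol_t[(shift + 1):dim(vol_t)[1], , ] <- ec$volume
  surf_t <- ec$surface
  surf_t$box[1:2] <- surf_t$box[1:2] + shift * surf_t$voxel_size
  er3 <- edge_enrichment(vol_t, surf_t)
  expect_equal(er3$edges$relative_intensity, tab$relative_intensity,
               tolerance = 1e-10)
})

test_that("edge classes follow the 45-degree rule on the cell surface", {
  s <- cell_surface(c(0, 12, 0, 6, 0, 5))
  expect_equal(s$edges$class[s$edges$edge %in% c("xmin", "xmax")],
               c("transverse", "transverse"))
  expect_equal(s$edges$length[s$edges$edge == "ymin"], 12)
})

test_that("TIFF and PLY round-trips preserve the data", {
  img <- matrix(runif(32 * 32), 32, 32)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  expect_equal(read_image_tiff(path), img, tolerance = 1e-6)
  stack <- array(runif(16 * 16 * 3), c(16, 16, 3))
  write_image_tiff(stack, path)
  expect_equal(read_image_tiff(path), stack, tolerance = 1e-6)
  mesh <- box_surface_mesh(c(2, 3, 4))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_surface_ply(mesh, ply)
  txt <- readLines(ply)
  expect_equal(txt[1], "ply")
  expect_equal(sum(grepl("^3 ", txt)), 12)
})

test_that("trace CSVs round-trip and reports coerce to data frames", {
  tr <- cbind(x = 1:10, y = sin(1:10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_equal(read_trace_csv(path), tr, ignore_attr = TRUE)
  expect_error(read_trace_csv({
    p2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p2, row.names = FALSE)
    p2
  }), "columns")
  tp <- make_cell_timepair(scale = c(1.2, 1, 1))
  df <- as.data.frame(growth_decomposition(tp$mesh_t0, tp$mesh_t1))
  expect_equal(df$volume_ratio, 1.2)
  expect_equal(df$zone, "meristematic")
  ec <- make_edge_intensity_cell(seed = 2)
  df2 <- as.data.frame(edge_enrichment(ec$volume, ec$surface))
  expect_s3_class(df2, "data.frame")
  expect_true("relative_intensity" %in% names(df2))
})
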