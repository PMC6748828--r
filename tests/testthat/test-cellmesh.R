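# box-shell mesh generation, region labelling and parameter assignment

shell_volume <- function(g)
  g$length_L * g$width_T * g$depth_R -
    (g$length_L - 2 * g$wall_thickness) * (g$width_T - 2 * g$wall_thickness) *
    (g$depth_R - 2 * g$wall_thickness)

test_that("default mesh is watertight with all 18 regions labelled", {
  mesh <- build_cell_mesh(cell_geometry())
  expect_setequal(unique(mesh$region_kind), c("face", "edge"))
  labs <- unique(mesh$region)
  expect_length(labs, 18)          # 6 faces + 12 edges, none unassigned
  expect_length(grep("^edge:", labs), 12)
  expect_true(all(nchar(mesh$region) > 0))
  # lumen surface closed: every facet edge shared by exactly two facets
  f <- mesh$inner_facets
  edges <- rbind(f[, 1:2], f[, 2:3], f[, 3:4], f[, c(4, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # all element volumes positive, summing to the analytic shell volume
  expect_true(all(mesh$elem_vol > 0))
  expect_equal(sum(mesh$elem_vol), shell_volume(mesh$geom))
  # facet normals all point out of the lumen: enclosed volume equals the
  # analytic lumen volume
  g <- mesh$geom
  V <- turgorcell:::.cpp_enclosed_volume(mesh$nodes, mesh$inner_facets - 1L,
                                         numeric(3 * nrow(mesh$nodes)))
  expect_equal(V, (g$length_L - 2 * g$wall_thickness) *
                 (g$width_T - 2 * g$wall_thickness) *
                 (g$depth_R - 2 * g$wall_thickness))
})

test_that("region volumes partition the wall and persist under refinement", {
  g1 <- cell_geometry(n_thickness = 2, h_plane = 2.5)
  g2 <- cell_geometry(n_thickness = 4, h_plane = 1.25)
  m1 <- build_cell_mesh(g1)
  m2 <- build_cell_mesh(g2)
  expect_equal(sum(mesh_region_volumes(m1)), sum(m1$elem_vol))
  # doubled resolution: element count x ~8
  expect_gt(nrow(m2$elems) / nrow(m1$elems), 6)
  expect_lt(nrow(m2$elems) / nrow(m1$elems), 10)
  # labelled volume per region stable within 5%
  v1 <- mesh_region_volumes(m1)
  v2 <- mesh_region_volumes(m2)
  expect_setequal(names(v1), names(v2))
  expect_true(all(abs(v2[names(v1)] / v1 - 1) < 0.05))
})

test_that("edge-region volume matches a numeric band-volume oracle", {
  g <- cell_geometry(length_L = 10, width_T = 10, depth_R = 10,
                     wall_thickness = 0.5, edge_band = 0.5,
                     n_thickness = 2, h_plane = 1)
  mesh <- build_cell_mesh(g)
  v_edge <- mesh_region_volumes(mesh, "kind")[["edge"]]
  # independent oracle: fine-grid integration of the indicator
  # (inside wall) & (within band of an edge line)
  n <- 100
  s <- (seq_len(n) - 0.5) / n * 10
  xs <- rep(s, times = n * n)
  ys <- rep(rep(s, each = n), times = n)
  zs <- rep(s, each = n * n)
  t <- 0.5
  inwall <- xs < t | xs > 10 - t | ys < t | ys > 10 - t | zs < t | zs > 10 - t
  dx <- pmin(xs, 10 - xs); dy <- pmin(ys, 10 - ys); dz <- pmin(zs, 10 - zs)
  dedge <- pmin(sqrt(dx^2 + dy^2), sqrt(dx^2 + dz^2), sqrt(dy^2 + dz^2))
  v_ref <- sum(inwall & dedge <= g$edge_band) * (10 / n)^3
  expect_lt(abs(v_edge - v_ref) / v_ref, 0.10)
})

test_that("coarse resolutions that starve faces of elements are rejected", {
  expect_error(build_cell_mesh(
    cell_geometry(length_L = 6, width_T = 6, depth_R = 6,
                  wall_thickness = 1, edge_band = 2.8, h_plane = 2)),
    "coarse")
  expect_error(cell_geometry(edge_band = 0.2), "edge_band")
  expect_error(cell_geometry(wall_thickness = 4), "wall_thickness")
})

test_that("case 1 with edge factor 1 yields a uniform parameter field", {
  mesh <- tiny_mesh()
  P <- assign_regions(mesh, make_scenario(1, edge_factor = 1,
                                          geom = tiny_geometry()))
  for (col in c("K", "mu_m", "mu_f", "mu_c", "theta_f", "fa"))
    expect_length(unique(P[, col]), 1L)
  d <- default_face_parameters()
  expect_equal(unname(P[1, 1:5]),
               c(d$K, d$mu_m, d$mu_f, d$mu_c, d$theta_f))
})

test_that("edge factor scales only the shear moduli of edge elements", {
  mesh <- tiny_mesh()
  sc1 <- make_scenario(1, edge_factor = 1, geom = tiny_geometry())
  sc01 <- make_scenario(1, edge_factor = 0.1, geom = tiny_geometry())
  P1 <- assign_regions(mesh, sc1)
  P01 <- assign_regions(mesh, sc01)
  at_edge <- mesh$region_kind == "edge"
  expect_identical(P01[!at_edge, ], P1[!at_edge, ])
  expect_equal(P01[at_edge, c("mu_m", "mu_f", "mu_c")],
               0.1 * P1[at_edge, c("mu_m", "mu_f", "mu_c")])
  expect_identical(P01[, "K"], P1[, "K"])
  expect_identical(P01[, "theta_f"], P1[, "theta_f"])
})

test_that("cases differ only in which faces carry anisotropic fibers", {
  mesh <- build_cell_mesh(cell_geometry())
  g <- cell_geometry()
  p2 <- assign_regions(mesh, make_scenario(2, 0.1, 0, 1, geom = g))
  p3 <- assign_regions(mesh, make_scenario(3, 0.1, 0, 1, geom = g))
  aniso3 <- c("longitudinal-anticlinal-ymin", "longitudinal-anticlinal-ymax",
              "inner-periclinal", "outer-periclinal")
  for (f in aniso3)
    expect_true(all(p3[mesh$region == f, "fa"] == 1))
  expect_true(all(p3[grepl("transverse-anticlinal", mesh$region), "fa"] == 0))
  # case 2 vs case 3: only the outer-periclinal assignment differs
  outer <- mesh$region == "outer-periclinal"
  expect_identical(p2[!outer, ], p3[!outer, ])
  expect_true(all(p2[outer, "fa"] == 0))
  expect_true(all(p3[outer, "fa"] == 1))
  # anisotropic a0 is transverse: in-plane and perpendicular to x
  for (f in aniso3) {
    a0 <- unique(p3[mesh$region == f, c("a0x", "a0y", "a0z")])
    expect_equal(nrow(a0), 1L)
    expect_equal(unname(a0[1, "a0x"]), 0)
  }
  expect_error(assign_regions(mesh, structure(
    list(case_id = 4), class = "scenario_spec")), "case")
})

test_that("case-1 parameter field is invariant under cell reflections", {
  mesh <- build_cell_mesh(cell_geometry())
  P <- assign_regions(mesh, make_scenario(1, 0.1, 0.08, 0.08))
  cent <- t(sapply(seq_len(nrow(mesh$elems)), function(e)
    colMeans(mesh$nodes[mesh$elems[e, ], ])))
  g <- mesh$geom
  dims <- c(g$length_L, g$width_T, g$depth_R)
  for (ax in 1:3) {
    refl <- cent
    refl[, ax] <- dims[ax] - refl[, ax]
    match_id <- apply(refl, 1, function(x)
      which.min(colSums((t(cent) - x)^2)))
    expect_equal(P[match_id, ], P, ignore_attr = TRUE)
  }
})

test_that("mesh export writes a legacy VTK file with fields", {
  mesh <- tiny_mesh()
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, path,
                 point_data = list(disp = matrix(0, nrow(mesh$nodes), 3)),
                 cell_data = list(vol = mesh$elem_vol))
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^CELL_TYPES", txt)))
  expect_true(any(grepl("VECTORS disp", txt)))
  expect_true(any(grepl("SCALARS vol", txt)))
})
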