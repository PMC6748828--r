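#' Geometry of the idealised meristematic cell
#'
#' The cell is a closed box shell: outer dimensions `length_L` (longitudinal,
#' x), `width_T` (transverse, y) and `depth_R` (radial, z), with a wall of
#' uniform thickness. Elements whose centroid lies within `edge_band` of one
#' of the 12 geometric edge lines form the mechanically distinct edge
#' region; the default 1 um band mirrors the 0-1 um edge definition used in
#' the image analysis. `n_thickness` elements span the wall thickness and
#' faces are meshed with a target in-plane element size `h_plane`.
#'
#' @param length_L,width_T,depth_R outer cell dimensions (um).
#' @param wall_thickness wall thickness (um).
#' @param edge_band edge-region half-width (um), at least `wall_thickness`.
#' @param n_thickness elements through the wall thickness.
#' @param h_plane target in-plane element size (um).
#' @return Object of class `cell_geometry`.
#' @export
cell_geometry <- function(length_L = 20, width_T = 10, depth_R = 10,
                          wall_thickness = 0.5, edge_band = 1,
                          n_thickness = 2, h_plane = 2.5) {
  g <- list(length_L = length_L, width_T = width_T, depth_R = depth_R,
            wall_thickness = wall_thickness, edge_band = edge_band,
            n_thickness = as.integer(n_thickness), h_plane = h_plane)
  if (any(unlist(g[1:5]) <= 0)) stop("all dimensions must be positive")
  if (wall_thickness >= min(length_L, width_T, depth_R) / 4)
    stop("wall_thickness must be below a quarter of the smallest dimension")
  if (edge_band < wall_thickness)
    stop("edge_band must be at least wall_thickness")
  if (g$n_thickness < 1) stop("n_thickness must be >= 1")
  class(g) <- "cell_geometry"
  g
}

# axis breakpoints: n_thickness wall layers at each end, ~h interior spacing
axis_breaks <- function(a, t, n_thick, h) {
  n_int <- max(1L, round((a - 2 * t) / h))
  c(seq(0, t, length.out = n_thick + 1),
    seq(t, a - t, length.out = n_int + 1)[-1],
    seq(a - t, a, length.out = n_thick + 1)[-1])
}

face_label_of_plane <- c(
  xmin = "transverse-anticlinal-xmin",
  xmax = "transverse-anticlinal-xmax",
  ymin = "longitudinal-anticlinal-ymin",
  ymax = "longitudinal-anticlinal-ymax",
  zmin = "inner-periclinal",
  zmax = "outer-periclinal")

#' Build the hexahedral mesh of the closed cell-wall shell
#'
#' Generates a structured grid of the box, removes the lumen, labels every
#' element as one of the 6 faces or 12 edge bands (ties at corners resolved
#' toward the nearest edge line), and collects the quadrilateral facets of
#' the lumen (inner) surface, oriented with normals pointing from the lumen
#' into the wall. Deterministic for fixed geometry.
#'
#' @param geom a [cell_geometry()].
#' @return Object of class `cell_mesh` with fields `nodes` (n x 3, um),
#'   `elems` (ne x 8, VTK node order), `region` (per-element label),
#'   `region_kind` (`"face"` or `"edge"`), `inner_facets` (nf x 4),
#'   `elem_vol`, `constraint_nodes` and `geom`.
#' @export
build_cell_mesh <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  t <- geom$wall_thickness
  dims <- c(geom$length_L, geom$width_T, geom$depth_R)
  bx <- axis_breaks(dims[1], t, geom$n_thickness, geom$h_plane)
  by <- axis_breaks(dims[2], t, geom$n_thickness, geom$h_plane)
  bz <- axis_breaks(dims[3], t, geom$n_thickness, geom$h_plane)
  nx <- length(bx) - 1L; ny <- length(by) - 1L; nz <- length(bz) - 1L
  nt <- geom$n_thickness
  nxn <- nx + 1L; nyn <- ny + 1L
  nid <- function(i, j, k) i + nxn * ((j - 1L) + nyn * (k - 1L))

  seg_kind <- function(n, nt) {
    k <- rep("int", n)
    k[seq_len(nt)] <- "wall"
    k[seq(n - nt + 1L, n)] <- "wall"
    k
  }
  kx <- seg_kind(nx, nt); ky <- seg_kind(ny, nt); kz <- seg_kind(nz, nt)

  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  lumen <- kx[cells$i] == "int" & ky[cells$j] == "int" & kz[cells$k] == "int"
  wall <- cells[!lumen, , drop = FALSE]
  ne <- nrow(wall)

  elems <- matrix(0L, ne, 8)
  i <- wall$i; j <- wall$j; k <- wall$k
  elems[, 1] <- nid(i, j, k);         elems[, 2] <- nid(i + 1L, j, k)
  elems[, 3] <- nid(i + 1L, j + 1L, k); elems[, 4] <- nid(i, j + 1L, k)
  elems[, 5] <- nid(i, j, k + 1L);    elems[, 6] <- nid(i + 1L, j, k + 1L)
  elems[, 7] <- nid(i + 1L, j + 1L, k + 1L); elems[, 8] <- nid(i, j + 1L, k + 1L)

  cx <- (bx[i] + bx[i + 1L]) / 2
  cy <- (by[j] + by[j + 1L]) / 2
  cz <- (bz[k] + bz[k + 1L]) / 2
  dpl <- cbind(xmin = cx, xmax = dims[1] - cx,
               ymin = cy, ymax = dims[2] - cy,
               zmin = cz, zmax = dims[3] - cz)

  pairs <- rbind(
    c("xmin", "ymin"), c("xmin", "ymax"), c("xmax", "ymin"), c("xmax", "ymax"),
    c("xmin", "zmin"), c("xmin", "zmax"), c("xmax", "zmin"), c("xmax", "zmax"),
    c("ymin", "zmin"), c("ymin", "zmax"), c("ymax", "zmin"), c("ymax", "zmax"))
  edist <- sapply(seq_len(nrow(pairs)), function(q)
    sqrt(dpl[, pairs[q, 1]]^2 + dpl[, pairs[q, 2]]^2))
  emin <- max.col(-edist, ties.method = "first")
  emind <- edist[cbind(seq_len(ne), emin)]

  is_edge <- emind <= geom$edge_band
  region <- character(ne)
  region[is_edge] <- paste0("edge:", pairs[emin[is_edge], 1], "-",
                            pairs[emin[is_edge], 2])
  fmin <- max.col(-dpl, ties.method = "first")
  region[!is_edge] <- face_label_of_plane[colnames(dpl)[fmin[!is_edge]]]
  region_kind <- ifelse(is_edge, "edge", "face")

  if (!all(face_label_of_plane %in% region))
    stop("resolution too coarse: some faces contain no non-edge element; ",
         "decrease h_plane or edge_band")

  # lumen (inner) surface: facets of wall cells adjacent to removed cells
  in_lumen <- function(ii, jj, kk) {
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & kk >= 1L & kk <= nz
    res <- rep(FALSE, length(ii))
    res[ok] <- kx[ii[ok]] == "int" & ky[jj[ok]] == "int" & kz[kk[ok]] == "int"
    res
  }
  facets <- NULL
  # for each direction, facet node order gives right-hand normal = lumen->wall
  dir_spec <- list(
    list(d = c(-1L, 0L, 0L), nodes = function(i, j, k)  # lumen at -x, n=+x
      cbind(nid(i, j, k), nid(i, j + 1L, k), nid(i, j + 1L, k + 1L),
            nid(i, j, k + 1L))),
    list(d = c(1L, 0L, 0L), nodes = function(i, j, k)   # lumen at +x, n=-x
      cbind(nid(i + 1L, j, k), nid(i + 1L, j, k + 1L),
            nid(i + 1L, j + 1L, k + 1L), nid(i + 1L, j + 1L, k))),
    list(d = c(0L, -1L, 0L), nodes = function(i, j, k)  # n=+y
      cbind(nid(i, j, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
            nid(i + 1L, j, k))),
    list(d = c(0L, 1L, 0L), nodes = function(i, j, k)   # n=-y
      cbind(nid(i, j + 1L, k), nid(i + 1L, j + 1L, k),
            nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))),
    list(d = c(0L, 0L, -1L), nodes = function(i, j, k)  # n=+z
      cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
            nid(i, j + 1L, k))),
    list(d = c(0L, 0L, 1L), nodes = function(i, j, k)   # n=-z
      cbind(nid(i, j, k + 1L), nid(i, j + 1L, k + 1L),
            nid(i + 1L, j + 1L, k + 1L), nid(i + 1L, j, k + 1L))))
  for (ds in dir_spec) {
    adj <- in_lumen(i + ds$d[1], j + ds$d[2], k + ds$d[3])
    if (any(adj))
      facets <- rbind(facets, ds$nodes(i[adj], j[adj], k[adj]))
  }

  # drop unused nodes, remap ids
  grid_nodes <- as.matrix(expand.grid(x = bx, y = by, z = bz))
  used <- sort(unique(c(elems)))
  remap <- integer(nrow(grid_nodes))
  remap[used] <- seq_along(used)
  nodes <- grid_nodes[used, , drop = FALSE]
  dimnames(nodes) <- NULL
  elems[] <- remap[elems]
  facets[] <- remap[facets]

  vol <- hex_volumes(nodes, elems)
  if (any(vol <= 0)) stop("mesh generation produced inverted elements")

  mesh <- list(nodes = nodes, elems = elems, region = region,
               region_kind = region_kind, inner_facets = facets,
               elem_vol = vol, geom = geom)
  mesh$constraint_nodes <- default_constraint_nodes(mesh)
  class(mesh) <- "cell_mesh"
  mesh
}

# element volumes by 2x2x2 quadrature of the reference Jacobian
hex_volumes <- function(nodes, elems) {
  g <- 1 / sqrt(3)
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  xi <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  eta <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  zet <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  vol <- numeric(nrow(elems))
  for (q in seq_len(8)) {
    p <- g * sgn[q, ]
    dN <- cbind(0.125 * xi * (1 + eta * p[2]) * (1 + zet * p[3]),
                0.125 * (1 + xi * p[1]) * eta * (1 + zet * p[3]),
                0.125 * (1 + xi * p[1]) * (1 + eta * p[2]) * zet)
    for (c1 in seq_len(nrow(elems))) {
      X <- nodes[elems[c1, ], ]
      vol[c1] <- vol[c1] + det(crossprod(X, dN))
    }
  }
  vol
}

# three-point (3-2-1) rigid-body pins on the inner-periclinal outer surface
default_constraint_nodes <- function(mesh) {
  g <- mesh$geom
  on_face <- which(abs(mesh$nodes[, 3]) < 1e-9)
  pick <- function(target) {
    d <- colSums((t(mesh$nodes[on_face, 1:2]) - target)^2)
    on_face[which.min(d)]
  }
  a <- pick(c(g$length_L / 2, g$width_T / 2))
  b <- pick(c(g$length_L - g$wall_thickness, g$width_T / 2))
  c3 <- pick(c(g$length_L / 2, g$width_T - g$wall_thickness))
  c(a, b, c3)
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("cell_mesh: %d nodes, %d hexahedra (%d edge, %d face), %d lumen facets\n",
              nrow(x$nodes), nrow(x$elems), sum(x$region_kind == "edge"),
              sum(x$region_kind == "face"), nrow(x$inner_facets)))
  invisible(x)
}

#' Per-region wall volumes
#'
#' @param mesh a `cell_mesh`.
#' @param by `"region"` for all 18 labels, `"kind"` for edge vs face totals.
#' @return Named numeric vector of volumes (um^3).
#' @export
mesh_region_volumes <- function(mesh, by = c("region", "kind")) {
  by <- match.arg(by)
  f <- if (by == "region") mesh$region else mesh$region_kind
  tapply(mesh$elem_vol, f, sum)
}

#' Thin spherical shell mesh (verification fixture)
#'
#' A cubed-sphere hexahedral mesh of a closed spherical shell with a
#' pressurised inner surface, produced by radially mapping the box-shell
#' mesh of a cube. Used to verify the solver against the thin-shell
#' closed form `sigma_hoop = p R / (2 t)`.
#'
#' @param outer_radius,thickness sphere outer radius and wall thickness (um).
#' @param n_thickness elements through the thickness.
#' @param n_panel elements along each cube-panel edge.
#' @return A `cell_mesh` (region labels retain their box-shell names; they
#'   carry no meaning on the sphere).
#' @export
build_sphere_shell_mesh <- function(outer_radius = 10, thickness = 0.4,
                                    n_thickness = 2, n_panel = 8) {
  that <- 0.25  # wall thickness of the unit-cube template (max-norm units)
  side <- 2
  geom <- cell_geometry(length_L = side, width_T = side, depth_R = side,
                        wall_thickness = that, edge_band = that,
                        n_thickness = n_thickness,
                        h_plane = (side - 2 * that) / n_panel)
  mesh <- build_cell_mesh(geom)
  p <- mesh$nodes - 1           # centre the cube at the origin
  s <- apply(abs(p), 1, max)    # max-norm radius in [1 - that, 1]
  u <- p / s
  u <- u / sqrt(rowSums(u^2))
  ri <- outer_radius - thickness
  r <- ri + (s - (1 - that)) / that * thickness
  mesh$nodes <- r * u
  mesh$elem_vol <- hex_volumes(mesh$nodes, mesh$elems)
  if (any(mesh$elem_vol <= 0)) stop("sphere mapping inverted an element")
  # pins: 3-2-1 on three well-separated inner-surface nodes (-z pole,
  # +x and +y equator); nearly coincident pins leave rotations almost
  # unconstrained and stall the solver
  inn <- which(abs(sqrt(rowSums(mesh$nodes^2)) - ri) < 1e-6 * outer_radius)
  mesh$constraint_nodes <- c(inn[which.min(mesh$nodes[inn, 3])],
                             inn[which.max(mesh$nodes[inn, 1])],
                             inn[which.max(mesh$nodes[inn, 2])])
  mesh$geom$outer_radius <- outer_radius
  mesh$geom$thickness <- thickness
  mesh
}

#' Assign material parameters to mesh regions for a scenario
#'
#' Face elements receive the scenario's face parameters; faces designated
#' anisotropic by the case carry `fa = fa_aniso` with a transverse mean
#' fibril direction (in the wall tangent plane, perpendicular to the
#' longitudinal organ axis), all other elements carry `fa = fa_iso` with the
#' fixed transverse convention `a0 = (0, 1, 0)` (orientation is mechanically
#' irrelevant at `fa = 0` and nearly so at 0.08). Edge elements get
#' `mu_m, mu_f, mu_c` multiplied by the scenario edge factor; `K` and
#' `theta_f` are never scaled.
#'
#' Cases (anisotropic faces): 1 - none; 2 - both longitudinal-anticlinal
#' faces and the inner periclinal face; 3 - both longitudinal-anticlinal
#' faces and both periclinal faces.
#'
#' @param mesh a `cell_mesh`.
#' @param scenario a [make_scenario()] spec.
#' @return Numeric matrix ne x 9 with columns
#'   `K, mu_m, mu_f, mu_c, theta_f, a0x, a0y, a0z, fa`.
#' @export
assign_regions <- function(mesh, scenario) {
  stopifnot(inherits(mesh, "cell_mesh"), inherits(scenario, "scenario_spec"))
  base <- scenario$face_parameters
  ne <- nrow(mesh$elems)
  P <- matrix(rep(c(base$K, base$mu_m, base$mu_f, base$mu_c, base$theta_f,
                    0, 1, 0, scenario$fa_iso), each = ne), ne, 9)
  colnames(P) <- c("K", "mu_m", "mu_f", "mu_c", "theta_f",
                   "a0x", "a0y", "a0z", "fa")
  aniso <- switch(as.character(scenario$case_id),
    "1" = character(0),
    "2" = c("longitudinal-anticlinal-ymin", "longitudinal-anticlinal-ymax",
            "inner-periclinal"),
    "3" = c("longitudinal-anticlinal-ymin", "longitudinal-anticlinal-ymax",
            "inner-periclinal", "outer-periclinal"),
    stop("unknown case id: ", scenario$case_id))
  # transverse a0 in the tangent plane of each anisotropic face
  a0_of_face <- list(
    "inner-periclinal" = c(0, 1, 0),
    "outer-periclinal" = c(0, 1, 0),
    "longitudinal-anticlinal-ymin" = c(0, 0, 1),
    "longitudinal-anticlinal-ymax" = c(0, 0, 1))
  for (f in aniso) {
    sel <- mesh$region == f
    P[sel, "fa"] <- scenario$fa_aniso
    P[sel, c("a0x", "a0y", "a0z")] <-
      matrix(a0_of_face[[f]], sum(sel), 3, byrow = TRUE)
  }
  at_edge <- mesh$region_kind == "edge"
  P[at_edge, c("mu_m", "mu_f", "mu_c")] <-
    P[at_edge, c("mu_m", "mu_f", "mu_c")] * scenario$edge_factor
  apply_overrides(P, mesh, scenario$overrides)
}

# overrides: named list; scalar entries apply globally, list entries named
# by region label apply per region. a0 overrides take a 3-vector.
apply_overrides <- function(P, mesh, overrides) {
  if (is.null(overrides) || !length(overrides)) return(P)
  set_field <- function(P, sel, nm, value) {
    if (nm == "a0") {
      P[sel, c("a0x", "a0y", "a0z")] <-
        matrix(value, sum(sel), 3, byrow = TRUE)
    } else {
      if (!nm %in% colnames(P)) stop("unknown override field: ", nm)
      P[sel, nm] <- value
    }
    P
  }
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (is.list(ov)) {
      for (reg in names(ov))
        P <- set_field(P, mesh$region == reg, nm, ov[[reg]])
    } else {
      P <- set_field(P, rep(TRUE, nrow(P)), nm, ov)
    }
  }
  P
}

#' Export a mesh (and optional fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid `.vtk` file with hexahedral cells, the region
#' label as cell data, and any additional per-node (`point_data`, n x 3 or
#' n-vector) or per-element (`cell_data`) fields.
#'
#' @param mesh a `cell_mesh`.
#' @param path output path.
#' @param point_data,cell_data named lists of numeric fields.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "cell wall mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  write.table(format(mesh$nodes, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl(sprintf("CELLS %d %d", ne, 9 * ne))
  write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  wl(sprintf("CELL_TYPES %d", ne))
  writeLines(rep("12", ne), con)
  wl(sprintf("CELL_DATA %d", ne), "SCALARS region_id int 1",
     "LOOKUP_TABLE default")
  writeLines(as.character(as.integer(factor(mesh$region)) - 1L), con)
  for (nm in names(cell_data)) {
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    writeLines(format(cell_data[[nm]], digits = 10, trim = TRUE), con)
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        wl(sprintf("VECTORS %s double", nm))
        write.table(format(v, digits = 10, trim = TRUE), con,
                    row.names = FALSE, col.names = FALSE, quote = FALSE)
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        writeLines(format(v, digits = 10, trim = TRUE), con)
      }
    }
  }
  invisible(path)
}
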