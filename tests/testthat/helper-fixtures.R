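# shared fixtures: small meshes and material parameter sets

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_F <- function(sd = 0.05) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, sd = sd), 3, 3)
    if (det(F) > 0.2) return(F)
  }
}

# small cubic cell: 56 elements, solves in well under a second
tiny_geometry <- function() {
  cell_geometry(length_L = 6, width_T = 6, depth_R = 6, wall_thickness = 1,
                edge_band = 1, n_thickness = 1, h_plane = 2)
}

tiny_mesh <- function() build_cell_mesh(tiny_geometry())

param_matrix <- function(mesh, p) {
  matrix(rep(turgorcell:::par_row(p), each = nrow(mesh$elems)),
         nrow(mesh$elems), 9)
}

# results cache shared between the ordering and sensitivity suites
.scenario_cache <- new.env(parent = emptyenv())

# coarse ordering mesh: qualitative sweep conditions of the edge/face
# heterogeneity experiments, solved once and shared across tests
ordering_results <- function() {
  if (!is.null(.scenario_cache$ordering)) return(.scenario_cache$ordering)
  geom <- cell_geometry(h_plane = 3.4)
  mesh <- build_cell_mesh(geom)
  run1 <- function(case, ef, fi, fa, init = NULL, ov = NULL) {
    run_scenario(make_scenario(case, edge_factor = ef, fa_iso = fi,
                               fa_aniso = fa, overrides = ov, geom = geom),
                 mesh = mesh, init = init)
  }
  res <- list()
  res$base <- run1(1, 1, 0, 0)
  res$fa1_ef1 <- run1(3, 1, 0, 1, init = res$base)
  res$c3_soft <- run1(3, 0.1, 0, 1, init = res$fa1_ef1)
  res$c2_soft <- run1(2, 0.1, 0, 1, init = res$c3_soft)
  res$soft <- run1(1, 0.1, 0, 0, init = res$base)
  res$stiff <- run1(1, 10, 0, 0, init = res$base)
  res$fa08_soft <- run1(1, 0.1, 0.08, 0.08, init = res$soft)
  res$fa02_soft <- run1(3, 0.1, 0.08, 0.2, init = res$fa08_soft)
  res$theta_half <- run1(1, 1, 0, 0, init = res$base,
                         ov = list(theta_f = 0.25))
  .scenario_cache$ordering <- res
  res
}
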