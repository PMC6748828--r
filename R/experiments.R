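#' Define one edge-face heterogeneity scenario
#'
#' A scenario fixes the case (which faces carry anisotropic microfibrils),
#' the multiplicative edge factor on the shear moduli `mu_m, mu_f, mu_c` at
#' edges, the fractional anisotropies of isotropic and anisotropic faces,
#' the turgor pressure, and optional parameter overrides. Face parameters
#' default to the printed set ([default_face_parameters()]); the default
#' 0.8 MPa turgor is a typical root-cell turgor scale and is configurable.
#'
#' @param case_id 1, 2 or 3 (see [assign_regions()]).
#' @param edge_factor multiplier (> 0) on `mu_m, mu_f, mu_c` at edges.
#' @param fa_iso,fa_aniso fractional anisotropy at isotropic and anisotropic
#'   faces; `0 <= fa_iso <= fa_aniso <= 1`.
#' @param turgor_pressure MPa.
#' @param overrides named list of parameter overrides, globally (scalar) or
#'   per region label (named sub-list); see [assign_regions()].
#' @param geom cell geometry (defaults to [cell_geometry()]).
#' @param face_parameters base face `material_parameters`.
#' @param load_steps Newton load increments.
#' @return Object of class `scenario_spec`.
#' @export
make_scenario <- function(case_id, edge_factor = 1, fa_iso = 0,
                          fa_aniso = fa_iso, turgor_pressure = 0.8,
                          overrides = NULL, geom = cell_geometry(),
                          face_parameters = default_face_parameters(),
                          load_steps = 4) {
  if (!case_id %in% 1:3) stop("case_id must be 1, 2 or 3")
  if (!(edge_factor > 0)) stop("edge_factor must be positive")
  if (fa_iso < 0 || fa_aniso > 1 || fa_iso > fa_aniso)
    stop("require 0 <= fa_iso <= fa_aniso <= 1")
  if (turgor_pressure < 0) stop("turgor_pressure must be non-negative")
  structure(list(case_id = as.integer(case_id), edge_factor = edge_factor,
                 fa_iso = fa_iso, fa_aniso = fa_aniso,
                 turgor_pressure = turgor_pressure, overrides = overrides,
                 geom = geom, face_parameters = face_parameters,
                 load_steps = as.integer(load_steps)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario: case %d, edge factor %g, FA iso/aniso %g/%g, P = %g MPa\n",
    x$case_id, x$edge_factor, x$fa_iso, x$fa_aniso, x$turgor_pressure))
  if (!is.null(x$overrides))
    cat("  overrides:", paste(names(x$overrides), collapse = ", "), "\n")
  invisible(x)
}

#' Run one scenario end to end
#'
#' Builds the mesh, assigns regional parameters, solves the inflation
#' problem and extracts the swelling readouts: maximum displacement
#' magnitude over the outer-periclinal face and the edge/face von Mises
#' concentration ratio.
#'
#' @param spec a [make_scenario()] spec.
#' @param opts [solver_options()].
#' @param mesh optional prebuilt mesh (to share one mesh across a sweep).
#' @param init optional warm start: an `fe_solution` or `swelling_report`
#'   from a related scenario on the same mesh.
#' @return Object of class `swelling_report`: the scenario echo,
#'   `max_outer_displacement` (um), `edge_face_vm_ratio`, `max_displacement`
#'   (whole cell) and convergence metadata.
#' @export
run_scenario <- function(spec, opts = solver_options(), mesh = NULL,
                         init = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(mesh)) mesh <- build_cell_mesh(spec$geom)
  P <- assign_regions(mesh, spec)
  load <- load_case(turgor_pressure = spec$turgor_pressure,
                    load_steps = spec$load_steps)
  if (inherits(init, "swelling_report")) init <- init$solution
  sol <- tryCatch(solve_inflation(mesh, P, load, opts, u0 = init),
                  error = function(e)
    stop(sprintf("scenario (case %d, edge factor %g) failed: %s",
                 spec$case_id, spec$edge_factor, conditionMessage(e)),
         call. = FALSE))
  stress <- compute_stress_field(sol, mesh, P)
  ualign <- remove_rigid_motion(sol$u, mesh$nodes, nodal_volumes(mesh))
  structure(list(
    scenario = spec,
    max_outer_displacement = max_outer_displacement(sol, mesh),
    max_displacement = max(sqrt(rowSums(ualign^2))),
    edge_face_vm_ratio = edge_stress_concentration(stress, mesh),
    iterations = sum(lengths(sol$residual_history)),
    converged = sol$converged,
    solution = sol, mesh = mesh, params = P, stress = stress),
    class = "swelling_report")
}

#' @export
print.swelling_report <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  max outer-face displacement: %.4g um\n",
              x$max_outer_displacement))
  cat(sprintf("  edge/face von Mises ratio:   %.4g\n", x$edge_face_vm_ratio))
  invisible(x)
}

#' Maximum displacement over the outer-periclinal face
#'
#' The swelling readout: the maximum displacement magnitude over all nodes
#' of elements labelled `outer-periclinal`, measured after removing the
#' best-fit rigid motion ([remove_rigid_motion()]) so the value does not
#' depend on the rigid-body pin choice.
#'
#' @param solution converged `fe_solution`.
#' @param mesh the solved `cell_mesh`.
#' @return Displacement magnitude (um).
#' @export
max_outer_displacement <- function(solution, mesh) {
  sel <- mesh$region == "outer-periclinal"
  if (!any(sel)) stop("mesh has no outer-periclinal face elements")
  nodes <- unique(as.integer(mesh$elems[sel, ]))
  u <- remove_rigid_motion(solution$u, mesh$nodes, nodal_volumes(mesh))
  max(sqrt(rowSums(u[nodes, , drop = FALSE]^2)))
}

#' Edge stress-concentration ratio
#'
#' Mean element von Mises stress over edge elements divided by the mean
#' over face elements (volume-weighted).
#'
#' @param stress a [compute_stress_field()] result.
#' @param mesh the solved `cell_mesh`.
#' @return Dimensionless ratio.
#' @export
edge_stress_concentration <- function(stress, mesh) {
  for (kind in c("edge", "face"))
    if (!any(mesh$region_kind == kind)) stop("empty ", kind, " region")
  wmean <- function(sel)
    sum(stress$von_mises[sel] * mesh$elem_vol[sel]) / sum(mesh$elem_vol[sel])
  wmean(mesh$region_kind == "edge") / wmean(mesh$region_kind == "face")
}

#' Run a grid of scenarios
#'
#' @param specs list of `scenario_spec`s (non-empty).
#' @param opts [solver_options()].
#' @param share_mesh reuse one mesh for all scenarios with the default
#'   geometry (they differ only in parameters).
#' @return A data.frame with one row per scenario (case, edge factor, FA
#'   values, readouts, convergence); failed scenarios are recorded with
#'   `NA` readouts and the error message, not raised.
#' @export
sweep_scenarios <- function(specs, opts = solver_options(),
                            share_mesh = TRUE) {
  if (!length(specs)) stop("empty scenario grid")
  mesh <- if (share_mesh) build_cell_mesh(specs[[1]]$geom) else NULL
  last_sol <- NULL
  rows <- lapply(specs, function(sp) {
    rep <- tryCatch(run_scenario(sp, opts, mesh = mesh,
                                 init = if (share_mesh) last_sol),
                    error = function(e) e)
    if (!inherits(rep, "error")) last_sol <<- rep$solution
    if (inherits(rep, "error")) {
      data.frame(case_id = sp$case_id, edge_factor = sp$edge_factor,
                 fa_iso = sp$fa_iso, fa_aniso = sp$fa_aniso,
                 turgor_pressure = sp$turgor_pressure,
                 max_outer_displacement = NA_real_,
                 max_displacement = NA_real_,
                 edge_face_vm_ratio = NA_real_, converged = FALSE,
                 error = conditionMessage(rep))
    } else {
      data.frame(case_id = sp$case_id, edge_factor = sp$edge_factor,
                 fa_iso = sp$fa_iso, fa_aniso = sp$fa_aniso,
                 turgor_pressure = sp$turgor_pressure,
                 max_outer_displacement = rep$max_outer_displacement,
                 max_displacement = rep$max_displacement,
                 edge_face_vm_ratio = rep$edge_face_vm_ratio,
                 converged = rep$converged, error = NA_character_)
    }
  })
  do.call(rbind, rows)
}

#' The default edge-factor x case x anisotropy sweep grid
#'
#' The 2 x 3 x 3 grid of anisotropy regimes (idealised FA 0/1 and measured
#' FA 0.08/0.2), cases 1-3 and edge factors 0.1, 1, 10.
#'
#' @param turgor_pressure MPa.
#' @param geom cell geometry.
#' @return List of 18 `scenario_spec`s.
#' @export
default_sweep_grid <- function(turgor_pressure = 0.8,
                               geom = cell_geometry()) {
  fa_sets <- list(idealised = c(0, 1), measured = c(0.08, 0.2))
  specs <- list()
  for (fa in fa_sets) for (case_id in 1:3) for (ef in c(0.1, 1, 10))
    specs[[length(specs) + 1L]] <- make_scenario(
      case_id, edge_factor = ef, fa_iso = fa[1], fa_aniso = fa[2],
      turgor_pressure = turgor_pressure, geom = geom)
  specs
}

#' Read or write a scenario as a flat YAML config
#'
#' The config carries the case id, edge factor, FA values, turgor pressure,
#' geometry fields, optional overrides and optional face parameters (as a
#' nested block with the [read_material_config()] keys).
#'
#' @param path file path.
#' @return `read_scenario_config` returns a `scenario_spec`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- do.call(cell_geometry, cfg$geometry %||% list())
  fp <- if (is.null(cfg$face_parameters)) default_face_parameters() else
    do.call(material_parameters, cfg$face_parameters)
  make_scenario(case_id = cfg$case_id %||% 1,
                edge_factor = cfg$edge_factor %||% 1,
                fa_iso = cfg$fa_iso %||% 0,
                fa_aniso = cfg$fa_aniso %||% (cfg$fa_iso %||% 0),
                turgor_pressure = cfg$turgor_pressure %||% 0.8,
                overrides = cfg$overrides,
                geom = geom, face_parameters = fp,
                load_steps = cfg$load_steps %||% 4)
}

#' @rdname read_scenario_config
#' @param spec a `scenario_spec` to write.
#' @export
write_scenario_config <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  g <- spec$geom
  fp <- spec$face_parameters
  yaml::write_yaml(list(
    case_id = spec$case_id, edge_factor = spec$edge_factor,
    fa_iso = spec$fa_iso, fa_aniso = spec$fa_aniso,
    turgor_pressure = spec$turgor_pressure,
    load_steps = spec$load_steps,
    overrides = spec$overrides,
    geometry = list(length_L = g$length_L, width_T = g$width_T,
                    depth_R = g$depth_R,
                    wall_thickness = g$wall_thickness,
                    edge_band = g$edge_band,
                    n_thickness = g$n_thickness, h_plane = g$h_plane),
    face_parameters = list(K = fp$K, mu_m = fp$mu_m, mu_f = fp$mu_f,
                           mu_c = fp$mu_c, theta_f = fp$theta_f,
                           a0 = fp$a0, fa = fp$fa)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-at-a-time parameter-variation grid
#'
#' Scenario specs in which each constitutive parameter (`theta_f, mu_c,
#' mu_m, mu_f, K`) is varied individually by the given factors while all
#' others stay at their defaults — the sensitivity companion to the main
#' edge-factor x case sweep.
#'
#' @param factors multiplicative factors applied one at a time.
#' @param case_id,edge_factor,fa_iso,fa_aniso,turgor_pressure scenario
#'   fields shared by every variant.
#' @param geom cell geometry.
#' @return Named list of `scenario_spec`s (`<param>_x<factor>`), including
#'   the unvaried `reference`.
#' @export
parameter_variation_grid <- function(factors = c(0.5, 2), case_id = 1,
                                     edge_factor = 1, fa_iso = 0,
                                     fa_aniso = fa_iso,
                                     turgor_pressure = 0.8,
                                     geom = cell_geometry()) {
  base <- default_face_parameters()
  specs <- list(reference = make_scenario(
    case_id, edge_factor, fa_iso, fa_aniso, turgor_pressure, geom = geom))
  for (nm in c("theta_f", "mu_c", "mu_m", "mu_f", "K")) {
    for (f in factors) {
      ov <- list()
      ov[[nm]] <- base[[nm]] * f
      specs[[sprintf("%s_x%g", nm, f)]] <- make_scenario(
        case_id, edge_factor, fa_iso, fa_aniso, turgor_pressure,
        overrides = ov, geom = geom)
    }
  }
  specs
}
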