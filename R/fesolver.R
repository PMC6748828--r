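#' Load case for quasi-static inflation
#'
#' @param turgor_pressure turgor pressure applied on the lumen surface
#'   (MPa, follower load by default).
#' @param load_steps number of equal pressure increments.
#' @param constraint rigid-body constraint mode: `"pins"` (3-2-1 pins on the
#'   three mesh constraint nodes; the pressure on the closed lumen surface
#'   is self-equilibrated so pins carry no load) or `"fix_inner"` (all nodes
#'   of the inner-periclinal face fixed; the in-tissue variant).
#' @return Object of class `load_case`.
#' @export
load_case <- function(turgor_pressure = 0.8, load_steps = 2,
                      constraint = c("pins", "fix_inner")) {
  constraint <- match.arg(constraint)
  if (turgor_pressure < 0) stop("pressure must be non-negative")
  if (load_steps < 1) stop("load_steps must be >= 1")
  structure(list(turgor_pressure = turgor_pressure,
                 load_steps = as.integer(load_steps),
                 constraint = constraint),
            class = "load_case")
}

#' Solver options
#'
#' The discrete problem is a potential minimisation (hyperelastic strain
#' energy minus the pressure-volume potential of the follower load), solved
#' by Newton's method with an Armijo backtracking line search on the total
#' potential and an adaptive Levenberg shift whenever the Newton direction
#' fails to descend — the flat reference state of a thin pressurised wall
#' has a nearly singular bending-dominated tangent, and plain Newton stalls
#' there.
#'
#' @param rtol,atol residual convergence test
#'   `||R|| <= max(rtol * ||f_ext||, atol)`.
#' @param max_iter Newton iterations per load step.
#' @param fbar use the energy-consistent F-bar centroid volumetric
#'   correction (locking mitigation for the near-incompressible wall).
#' @param follower_load deformation-dependent pressure (dead load if FALSE).
#' @param tension_only_fibers drop the fiber term under fiber compression.
#' @param line_search maximum Armijo halvings per iteration.
#' @return List of class `solver_options`.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-10, max_iter = 400,
                           fbar = TRUE, follower_load = TRUE,
                           tension_only_fibers = FALSE, line_search = 40,
                           verbose = FALSE) {
  structure(list(rtol = rtol, atol = atol, max_iter = as.integer(max_iter),
                 fbar = fbar, follower_load = follower_load,
                 tension_only_fibers = tension_only_fibers,
                 line_search = as.integer(line_search), verbose = verbose),
            class = "solver_options")
}

constraint_dofs <- function(mesh, load) {
  if (load$constraint == "fix_inner") {
    nodes <- which(abs(mesh$nodes[, 3] - min(mesh$nodes[, 3])) < 1e-9)
    sort(c(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2, 3 * nodes))
  } else {
    cn <- mesh$constraint_nodes
    sort(c(3 * (cn[1] - 1) + 1:3,      # node A: all components
           3 * (cn[2] - 1) + 2:3,      # node B: y, z
           3 * cn[3]))                 # node C: z
  }
}

# total potential, gradient and external load at state u
potential_state <- function(mesh, P, u, p, opts) {
  asm <- .cpp_assemble(mesh$nodes, mesh$elems - 1L, P, u,
                       opts$fbar, opts$tension_only_fibers, FALSE)
  uext <- if (opts$follower_load) u else 0 * u
  ext <- .cpp_pressure_load(mesh$nodes, mesh$inner_facets - 1L, uext, p,
                            FALSE)
  Ein <- .cpp_internal_energy(mesh$nodes, mesh$elems - 1L, P, u,
                              opts$fbar, opts$tension_only_fibers)
  V <- .cpp_enclosed_volume(mesh$nodes, mesh$inner_facets - 1L, uext)
  list(R = asm$fint - ext$fext, fext = ext$fext,
       Pi = Ein - if (opts$follower_load) p * V else sum(ext$fext * u))
}

tangent_matrix <- function(mesh, P, u, p, opts, ndof) {
  asm <- .cpp_assemble(mesh$nodes, mesh$elems - 1L, P, u,
                       opts$fbar, opts$tension_only_fibers, TRUE)
  Ki <- asm$Ki; Kj <- asm$Kj; Kx <- asm$Kx
  if (opts$follower_load && p != 0) {
    ext <- .cpp_pressure_load(mesh$nodes, mesh$inner_facets - 1L, u, p, TRUE)
    Ki <- c(Ki, ext$Ki); Kj <- c(Kj, ext$Kj); Kx <- c(Kx, -ext$Kx)
  }
  Matrix::sparseMatrix(i = Ki, j = Kj, x = Kx, dims = c(ndof, ndof))
}

#' Solve the turgor-inflation problem
#'
#' Incremental-load minimisation of the total potential of the pressurised
#' cell shell: trilinear hexahedra with an energy-consistent F-bar
#' volumetric treatment, follower pressure from the enclosed-volume
#' potential of the lumen surface, consistent tangent (finite-differenced
#' at element level, hence consistent with both F-bar and the follower
#' load), Armijo line search and adaptive Levenberg damping.
#' Deterministic for fixed inputs.
#'
#' @param mesh a `cell_mesh`.
#' @param params ne x 9 parameter matrix from [assign_regions()], or a
#'   single `material_parameters` applied to every element.
#' @param load a [load_case()].
#' @param opts a [solver_options()].
#' @param prescribed optional list `(dofs, values)` of additional Dirichlet
#'   constraints (dof index = 3 * (node - 1) + component), ramped with the
#'   load factor.
#' @param u0 optional initial displacement guess (n x 3 matrix or an
#'   `fe_solution` from a related scenario); warm starts skip the
#'   ill-conditioned flat-wall phase and speed up parameter sweeps.
#' @return Object of class `fe_solution` with nodal displacements `u`
#'   (n x 3, um), `converged`, `residual_history` and solve metadata.
#' @export
solve_inflation <- function(mesh, params, load = load_case(),
                            opts = solver_options(), prescribed = NULL,
                            u0 = NULL) {
  stopifnot(inherits(mesh, "cell_mesh"))
  if (inherits(params, "material_parameters"))
    params <- matrix(rep(par_row(params), each = nrow(mesh$elems)),
                     nrow(mesh$elems), 9)
  stopifnot(is.matrix(params), nrow(params) == nrow(mesh$elems),
            ncol(params) == 9)
  n <- nrow(mesh$nodes); ndof <- 3L * n
  fixed <- constraint_dofs(mesh, load)
  fixed_val <- numeric(length(fixed))
  if (!is.null(prescribed)) {
    # explicit prescriptions take precedence over the rigid-body pins
    fixed <- c(prescribed$dofs, fixed)
    fixed_val <- c(prescribed$values, fixed_val)
    keep <- !duplicated(fixed)
    fixed <- fixed[keep]; fixed_val <- fixed_val[keep]
  }
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  steps <- seq_len(load$load_steps) / load$load_steps
  if (!is.null(u0)) {
    if (inherits(u0, "fe_solution")) u0 <- u0$u
    stopifnot(is.matrix(u0), nrow(u0) == n, ncol(u0) == 3)
    u <- as.numeric(t(u0))
    steps <- 1            # warm start: solve at full load directly
  }
  history <- list()

  for (step in seq_along(steps)) {
    lam <- steps[step]
    p <- lam * load$turgor_pressure
    u[fixed] <- lam * fixed_val
    st <- potential_state(mesh, params, u, p, opts)
    rhist <- numeric(0)
    ok <- length(free) == 0L
    lev <- 0                      # Levenberg shift, re-used across iters
    scl <- NULL
    for (iter in seq_len(opts$max_iter)) {
      rnorm <- sqrt(sum(st$R[free]^2))
      rhist <- c(rhist, rnorm)
      ref <- max(sqrt(sum(st$fext[free]^2)), 1)
      if (rnorm <= max(opts$rtol * ref, opts$atol)) { ok <- TRUE; break }
      K <- tangent_matrix(mesh, params, u, p, opts, ndof)
      Kff <- K[free, free, drop = FALSE]
      if (is.null(scl))
        scl <- mean(abs(Matrix::diag(Kff))) + 1e-12
      # the exact tangent is the symmetric Hessian of the total potential;
      # symmetrise away the finite-difference asymmetry and factorise with
      # Cholesky, whose failure doubles as the indefiniteness detector for
      # the Levenberg shift
      Ksym <- Matrix::forceSymmetric((Kff + Matrix::t(Kff)) / 2)
      repeat {
        Ksys <- if (lev > 0)
          Ksym + Matrix::Diagonal(length(free), lev) else Ksym
        du_f <- tryCatch(suppressWarnings({
          # CHOLMOD warns (rather than fails) on indefinite systems; the
          # linear-residual check below rejects bad factorisations
          fac <- Matrix::Cholesky(Ksys, LDL = FALSE, perm = TRUE)
          d <- as.numeric(Matrix::solve(fac, -st$R[free]))
          # one step of iterative refinement: the penalty-stiffened thin
          # shell is ill-conditioned enough for the raw solve to limit the
          # attainable residual
          r2 <- as.numeric(Ksys %*% d) + st$R[free]
          d - as.numeric(Matrix::solve(fac, r2))
        }), error = function(e) NULL)
        ok_dir <- !is.null(du_f) && all(is.finite(du_f)) &&
          sum(du_f * st$R[free]) < 0
        if (ok_dir) {
          lin_res <- sqrt(sum((as.numeric(Ksys %*% du_f) +
                                 st$R[free])^2)) / max(rnorm, 1e-300)
          ok_dir <- lin_res < 0.1
        }
        if (ok_dir) break
        lev <- max(lev * 10, 1e-6 * scl)
        if (lev > 1e10 * scl)
          stop("tangent system unsolvable: Levenberg shift exhausted")
      }
      du <- numeric(ndof)
      du[free] <- du_f
      gtd <- sum(st$R[free] * du_f)
      # near the minimum the energy decrease per step drops below the
      # energy-evaluation noise floor; switch to residual-norm acceptance
      endgame <- rnorm <= 1e-4 * ref
      alpha <- 1
      accepted <- FALSE
      for (ls in 0:opts$line_search) {
        trial <- tryCatch(
          potential_state(mesh, params, u + alpha * du, p, opts),
          error = function(e) NULL)
        if (!is.null(trial)) {
          good <- if (endgame)
            sqrt(sum(trial$R[free]^2)) < rnorm
          else trial$Pi <= st$Pi + 1e-4 * alpha * gtd
          if (good) { accepted <- TRUE; break }
        }
        alpha <- alpha / 2
      }
      if (!accepted) {
        # descent direction but no acceptable step: raise damping and retry
        lev <- max(lev * 100, 1e-4 * scl)
        next
      }
      u <- u + alpha * du
      st <- trial
      if (opts$verbose)
        message(sprintf("  step %d it %d |R| %.3e alpha %.3g lev %.2e%s",
                        step, iter, rnorm, alpha, lev,
                        if (endgame) " [endgame]" else ""))
      # relax damping when steps are healthy
      lev <- if (alpha >= 0.5) lev / 10 else lev
      if (lev < 1e-8 * scl) lev <- 0
    }
    history[[step]] <- rhist
    if (!ok) {
      e <- simpleError(sprintf(
        "Newton solver did not converge (last residual %.3e)",
        utils::tail(rhist, 1)))
      e$residual_history <- history
      stop(e)
    }
  }
  structure(list(u = matrix(u, n, 3, byrow = TRUE),
                 converged = TRUE, residual_history = history,
                 load = load, opts = opts),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("fe_solution: %s, max |u| = %.4g um, %d load step(s), %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              max(sqrt(rowSums(x$u^2))), length(x$residual_history),
              sum(lengths(x$residual_history))))
  invisible(x)
}

#' Remove the best-fit rigid motion from a displacement field
#'
#' The pressure load on the closed lumen surface is self-equilibrated, so
#' the equilibrium is determined only up to a rigid motion and the pins fix
#' an arbitrary gauge. Displacement readouts therefore quotient the rigid
#' part out: the deformed configuration is aligned onto the reference by
#' the least-squares (Kabsch) rotation and translation, which makes the
#' readouts independent of the pin choice.
#'
#' @param u n x 3 displacement field.
#' @param nodes n x 3 reference coordinates.
#' @param weights optional per-node weights for the least-squares fit;
#'   lumped nodal volumes make the gauge independent of local mesh
#'   density (readouts pass them automatically).
#' @return The aligned displacement field (n x 3).
#' @export
remove_rigid_motion <- function(u, nodes, weights = NULL) {
  stopifnot(nrow(u) == nrow(nodes), ncol(u) == 3)
  w <- if (is.null(weights)) rep(1, nrow(nodes)) else weights
  w <- w / sum(w)
  Y <- nodes + u
  Xc <- colSums(nodes * w); Yc <- colSums(Y * w)
  H <- crossprod(sweep(nodes, 2, Xc) * w, sweep(Y, 2, Yc))
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) {
    sv$v[, 3] <- -sv$v[, 3]
    R <- sv$v %*% t(sv$u)
  }
  Yp <- sweep(sweep(Y, 2, Yc) %*% R, 2, Xc, "+")
  Yp - nodes
}

# lumped nodal volumes: each element spreads its volume over its 8 nodes
nodal_volumes <- function(mesh) {
  idx <- as.integer(mesh$elems)
  add <- rep(mesh$elem_vol / 8, 8)
  s <- rowsum(add, idx)
  w <- numeric(nrow(mesh$nodes))
  w[as.integer(rownames(s))] <- s[, 1]
  w
}

#' Element-averaged Cauchy stress and von Mises field
#'
#' Quadrature-point Cauchy stresses (consistent with the material model and
#' the solver's F-bar treatment) averaged per element.
#'
#' @param solution a converged [solve_inflation()] result.
#' @param mesh,params the mesh and parameter matrix of the solve.
#' @return List with `stress` (ne x 6: xx, yy, zz, xy, yz, xz, MPa),
#'   `von_mises` (ne) and mean volume ratio `J` (ne).
#' @export
compute_stress_field <- function(solution, mesh, params) {
  if (!isTRUE(solution$converged))
    stop("refusing to post-process an unconverged solution")
  if (inherits(params, "material_parameters"))
    params <- matrix(rep(par_row(params), each = nrow(mesh$elems)),
                     nrow(mesh$elems), 9)
  u <- as.numeric(t(solution$u))
  out <- .cpp_element_stress(mesh$nodes, mesh$elems - 1L, params, u,
                             solution$opts$fbar,
                             solution$opts$tension_only_fibers)
  colnames(out$stress) <- c("xx", "yy", "zz", "xy", "yz", "xz")
  out$von_mises <- as.numeric(out$von_mises)
  out$J <- as.numeric(out$J)
  out
}

#' Export a solution as legacy ASCII VTK
#'
#' Writes the mesh with the displacement field (raw and rigid-motion
#' removed) as point data and the region id plus von Mises stress as cell
#' data.
#'
#' @param solution a converged `fe_solution`.
#' @param mesh,params the solved mesh and parameter matrix.
#' @param path output path.
#' @export
write_solution_vtk <- function(solution, mesh, params, path) {
  st <- compute_stress_field(solution, mesh, params)
  write_mesh_vtk(mesh, path,
                 point_data = list(
                   displacement = solution$u,
                   displacement_aligned = remove_rigid_motion(
                     solution$u, mesh$nodes, nodal_volumes(mesh))),
                 cell_data = list(von_mises = st$von_mises, J = st$J))
}

#' Interpolate a displacement field onto another mesh
#'
#' Inverse-distance-weighted interpolation from the nodes of a coarse mesh
#' onto a finer mesh of the same geometry, for warm-starting refinement
#' studies.
#'
#' @param mesh_from,mesh_to source and target `cell_mesh`.
#' @param u source displacement field (n_from x 3).
#' @param k number of nearest source nodes per target node.
#' @return n_to x 3 displacement matrix.
#' @export
interpolate_displacement <- function(mesh_from, mesh_to, u, k = 4) {
  if (inherits(u, "fe_solution")) u <- u$u
  from <- mesh_from$nodes
  out <- matrix(0, nrow(mesh_to$nodes), 3)
  t2 <- rowSums(from^2)
  chunk <- 1024L
  for (s in seq(1L, nrow(mesh_to$nodes), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(mesh_to$nodes))
    f <- mesh_to$nodes[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), t2, "+") - 2 * tcrossprod(f, from)
    d2 <- pmax(d2, 1e-20)
    for (r in seq_along(idx)) {
      nn <- order(d2[r, ])[seq_len(k)]
      w <- 1 / d2[r, nn]
      out[idx[r], ] <- colSums(u[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}
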