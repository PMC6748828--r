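#' Constitutive parameters of the cell-wall composite
#'
#' The wall is modelled as a fiber-reinforced hyperelastic composite: a
#' near-incompressible isotropic matrix, a dispersed cellulose-microfibril
#' phase with mean orientation `a0` and fractional anisotropy `fa`, and an
#' isotropic cross-linking term. Internally the package works in
#' micrometre-megapascal units; `units = "SI"` accepts pascals and converts.
#'
#' @param K bulk modulus (MPa, or Pa with `units = "SI"`).
#' @param mu_m matrix shear modulus.
#' @param mu_f microfibril shear modulus.
#' @param mu_c cross-link shear modulus.
#' @param theta_f microfibril volume fraction in `[0, 1]`.
#' @param a0 mean microfibril direction, unit 3-vector (reference
#'   configuration).
#' @param fa fractional anisotropy in `[0, 1]`; 0 is a fully dispersed
#'   (isotropic) microfibril phase, 1 a perfectly parallel one.
#' @param units `"um_MPa"` (internal) or `"SI"` (moduli in Pa).
#' @return An object of class `material_parameters`.
#' @export
material_parameters <- function(K, mu_m, mu_f, mu_c, theta_f,
                                a0 = c(0, 1, 0), fa = 0,
                                units = c("um_MPa", "SI")) {
  units <- match.arg(units)
  if (units == "SI") {
    K <- K / 1e6; mu_m <- mu_m / 1e6; mu_f <- mu_f / 1e6; mu_c <- mu_c / 1e6
  }
  p <- list(K = K, mu_m = mu_m, mu_f = mu_f, mu_c = mu_c,
            theta_f = theta_f, a0 = as.numeric(a0), fa = fa)
  class(p) <- "material_parameters"
  validate_material_parameters(p)
  p
}

validate_material_parameters <- function(p) {
  stopifnot(is.numeric(p$K), length(p$K) == 1L)
  if (!(p$K > 0)) stop("bulk modulus K must be positive")
  for (nm in c("mu_m", "mu_f", "mu_c"))
    if (p[[nm]] < 0) stop(sprintf("%s must be non-negative", nm))
  if (p$theta_f < 0 || p$theta_f > 1)
    stop("theta_f must lie in [0, 1]")
  if (p$fa < 0 || p$fa > 1)
    stop("fa must lie in [0, 1]")
  if (length(p$a0) != 3L || abs(sqrt(sum(p$a0^2)) - 1) > 1e-12)
    stop("a0 must be a unit 3-vector")
  invisible(p)
}

#' Default face parameters of the meristematic-cell wall
#'
#' The printed face parameter set: K = 10 GPa, mu_m = 18 MPa,
#' mu_f = 1.2 GPa, mu_c = 18 MPa, theta_f = 0.5 (internal units MPa).
#'
#' @param a0,fa mean fibril direction and fractional anisotropy.
#' @return A `material_parameters` object.
#' @export
default_face_parameters <- function(a0 = c(0, 1, 0), fa = 0) {
  material_parameters(K = 10000, mu_m = 18, mu_f = 1200, mu_c = 18,
                      theta_f = 0.5, a0 = a0, fa = fa)
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("Cell-wall material parameters (MPa, um):\n")
  cat(sprintf("  K = %g, mu_m = %g, mu_f = %g, mu_c = %g, theta_f = %g\n",
              x$K, x$mu_m, x$mu_f, x$mu_c, x$theta_f))
  cat(sprintf("  a0 = (%g, %g, %g), fa = %g\n",
              x$a0[1], x$a0[2], x$a0[3], x$fa))
  invisible(x)
}

#' Generalized structure tensor of the microfibril phase
#'
#' `H = fa * (a0 %o% a0) + ((1 - fa)/3) * I`: the second-moment tensor of an
#' FA-weighted mixture of a perfectly aligned and a fully isotropic fiber
#' distribution. `trace(H) = 1` and `H` is positive semi-definite.
#'
#' @param a0 unit 3-vector, mean fiber direction.
#' @param fa fractional anisotropy in `[0, 1]`.
#' @return Symmetric 3x3 matrix.
#' @export
structure_tensor <- function(a0, fa) {
  a0 <- as.numeric(a0)
  if (length(a0) != 3L || abs(sqrt(sum(a0^2)) - 1) > 1e-12)
    stop("a0 must be a unit 3-vector")
  if (!is.numeric(fa) || fa < 0 || fa > 1)
    stop("fa must lie in [0, 1]")
  fa * tcrossprod(a0) + ((1 - fa) / 3) * diag(3)
}

#' Kinematic state derived from a deformation gradient
#'
#' Packages the deformation measures the strain energy depends on: `J`,
#' the right Cauchy-Green tensor `C`, the isochoric first invariant and the
#' generalized fiber invariant `I4_star = tr(H C_iso)` for given fiber
#' structure.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param a0,fa fiber structure used for `I4_star` (optional; defaults give
#'   the isotropic `tr(C_iso)/3`).
#' @return Object of class `deformation_state`.
#' @export
deformation_state <- function(F, a0 = c(0, 1, 0), fa = 0) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!(J > 0)) stop("invalid deformation: det(F) <= 0")
  C <- crossprod(F)
  Ciso <- J^(-2 / 3) * C
  H <- structure_tensor(a0, fa)
  st <- list(F = F, J = J, C = C, I1_iso = sum(diag(Ciso)),
             I4_star = sum(H * Ciso))
  class(st) <- "deformation_state"
  st
}

par_row <- function(p) {
  c(p$K, p$mu_m, p$mu_f, p$mu_c, p$theta_f, p$a0, p$fa)
}

as_state <- function(state) {
  if (inherits(state, "deformation_state")) return(state$F)
  as.matrix(state)
}

#' Strain-energy density of the wall composite
#'
#' `Psi = K/2 (ln J)^2 + ((1 - theta_f) mu_m + mu_c)/2 (I1_iso - 3)
#'  + theta_f mu_f/2 (I4_star - 1)^2`. Zero in the reference configuration
#' and invariant to superposed rigid rotations.
#'
#' @param state a `deformation_state` or a 3x3 deformation gradient.
#' @param p `material_parameters`.
#' @param tension_only drop the fiber term when `I4_star < 1` (off by
#'   default: instantaneous inflation puts the wall in tension).
#' @return Energy density (MPa).
#' @export
strain_energy <- function(state, p, tension_only = FALSE) {
  validate_material_parameters(p)
  F <- as_state(state)
  st <- deformation_state(F, p$a0, p$fa)
  psi <- 0.5 * p$K * log(st$J)^2 +
    0.5 * ((1 - p$theta_f) * p$mu_m + p$mu_c) * (st$I1_iso - 3)
  if (!(tension_only && st$I4_star < 1))
    psi <- psi + 0.5 * p$theta_f * p$mu_f * (st$I4_star - 1)^2
  psi
}

#' Cauchy stress of the wall composite
#'
#' The push-forward of the derivative of [strain_energy()]:
#' `sigma = (K ln J / J) I + (mu_bar / J) dev(b_iso)
#'  + (2 theta_f mu_f (I4_star - 1) / J) dev(F_iso H F_iso^T)` with
#' `mu_bar = (1 - theta_f) mu_m + mu_c`. Symmetric, zero at `F = I`.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress (MPa).
#' @export
cauchy_stress <- function(state, p, tension_only = FALSE) {
  validate_material_parameters(p)
  F <- as_state(state)
  J <- det(F)
  if (!(J > 0)) stop("invalid deformation: det(F) <= 0")
  I3 <- diag(3)
  bbar <- J^(-2 / 3) * tcrossprod(F)
  H <- structure_tensor(p$a0, p$fa)
  A <- J^(-2 / 3) * F %*% H %*% t(F)
  I4 <- sum(diag(A))
  mubar <- (1 - p$theta_f) * p$mu_m + p$mu_c
  sig <- (p$K * log(J) / J) * I3 +
    (mubar / J) * (bbar - mean(diag(bbar)) * I3)
  if (!(tension_only && I4 < 1)) {
    g <- 2 * p$theta_f * p$mu_f * (I4 - 1)
    sig <- sig + (g / J) * (A - (I4 / 3) * I3)
  }
  (sig + t(sig)) / 2
}

#' Material tangent operator
#'
#' The second elasticity tensor `C_IJKL = 2 dS_IJ / dC_KL` (S the second
#' Piola-Kirchhoff stress), evaluated by central differencing of the stress
#' under symmetric perturbations of `C`; minor symmetries hold by
#' construction. At `F = I` with `fa = 0` it reduces to the classical
#' isotropic operator with bulk modulus `K` and the apparent composite shear
#' modulus `(1 - theta_f) mu_m + mu_c`.
#'
#' @inheritParams strain_energy
#' @param h relative finite-difference step.
#' @return A 3x3x3x3 array (MPa).
#' @export
material_tangent <- function(state, p, tension_only = FALSE, h = 1e-5) {
  validate_material_parameters(p)
  F <- as_state(state)
  J <- det(F)
  if (!(J > 0)) stop("invalid deformation: det(F) <= 0")
  pk2 <- function(Fm) {
    sig <- cauchy_stress(Fm, p, tension_only)
    Fi <- solve(Fm)
    det(Fm) * Fi %*% sig %*% t(Fi)
  }
  # S is a function of C alone (frame indifference); perturb C symmetrically
  # and evaluate at the rotation-free state F = sqrt(C).
  C <- crossprod(F)
  D <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (l in k:3) {
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[l, k] <- h
    dS <- (pk2(sqrtm3(C + dC)) - pk2(sqrtm3(C - dC))) /
      (2 * h * (if (k == l) 1 else 2))
    D[, , k, l] <- 2 * dS
    D[, , l, k] <- 2 * dS
  }
  D
}

# principal square root of a near-identity SPD 3x3 matrix
sqrtm3 <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Read or write material parameters as a flat YAML config
#'
#' Keys are exactly `K, mu_m, mu_f, mu_c, theta_f, a0, fa` plus a `units`
#' field (`"um_MPa"` or `"SI"`).
#'
#' @param path file path.
#' @return `read_material_config` returns `material_parameters`.
#' @export
read_material_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  units <- if (is.null(cfg$units)) "um_MPa" else cfg$units
  material_parameters(K = cfg$K, mu_m = cfg$mu_m, mu_f = cfg$mu_f,
                      mu_c = cfg$mu_c, theta_f = cfg$theta_f,
                      a0 = if (is.null(cfg$a0)) c(0, 1, 0) else cfg$a0,
                      fa = if (is.null(cfg$fa)) 0 else cfg$fa,
                      units = units)
}

#' @rdname read_material_config
#' @param p `material_parameters` to write (always written in internal
#'   micrometre-megapascal units).
#' @export
write_material_config <- function(p, path) {
  validate_material_parameters(p)
  yaml::write_yaml(list(units = "um_MPa", K = p$K, mu_m = p$mu_m,
                        mu_f = p$mu_f, mu_c = p$mu_c, theta_f = p$theta_f,
                        a0 = p$a0, fa = p$fa), path)
  invisible(path)
}
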