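# constitutive model of the wall composite

test_that("structure tensor has the FA-mixture form, unit trace and PSD", {
  expect_equal(structure_tensor(c(1, 0, 0), 0), diag(3) / 3)
  expect_equal(structure_tensor(c(0, 0, 1), 1), diag(c(0, 0, 1)))
  H <- structure_tensor(c(0, 1, 0), 0.2)
  expect_equal(round(H, 4),
               diag(c(0.2667, 0.4667, 0.2667)), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    fa <- runif(1)
    H <- structure_tensor(a, fa)
    expect_equal(sum(diag(H)), 1)
    expect_true(all(eigen(H, symmetric = TRUE)$values > -1e-14))
    # second moment of the mixture distribution: fa-weighted aligned and
    # isotropic parts, checked against direct averaging over directions
    expect_equal(H, fa * tcrossprod(a) + (1 - fa) / 3 * diag(3))
  }
  expect_error(structure_tensor(c(1, 1, 0), 0.5), "unit")
  expect_error(structure_tensor(c(1, 0, 0), 1.2), "fa")
})

test_that("parameter validation enforces the physical ranges", {
  expect_error(material_parameters(-1, 18, 1200, 18, 0.5), "positive")
  expect_error(material_parameters(1e4, -1, 1200, 18, 0.5), "non-negative")
  expect_error(material_parameters(1e4, 18, 1200, 18, 1.5), "theta_f")
  expect_error(material_parameters(1e4, 18, 1200, 18, 0.5, fa = 2), "fa")
  expect_error(material_parameters(1e4, 18, 1200, 18, 0.5,
                                   a0 = c(1, 1, 0)), "unit")
  p <- default_face_parameters()
  expect_equal(c(p$K, p$mu_m, p$mu_f, p$mu_c, p$theta_f),
               c(10000, 18, 1200, 18, 0.5))
  # SI input converts Pa to MPa
  psi <- material_parameters(1e10, 1.8e7, 1.2e9, 1.8e7, 0.5, units = "SI")
  expect_equal(psi$K, 1e4)
  expect_equal(psi$mu_f, 1200)
})

test_that("deformation state invariants hold at identity and reject J <= 0", {
  st <- deformation_state(diag(3))
  expect_equal(st$J, 1)
  expect_equal(st$I1_iso, 3)
  expect_equal(st$I4_star, 1)
  expect_error(deformation_state(diag(c(-1, 1, 1))), "det")
})

test_that("strain energy vanishes in the reference state and under rotation", {
  p <- default_face_parameters(fa = 0.4)
  expect_equal(strain_energy(diag(3), p), 0)
  set.seed(21)
  for (i in 1:5)
    expect_equal(strain_energy(random_rotation(), p), 0, tolerance = 1e-12)
})

test_that("uniaxial stretch energy matches the closed-form evaluation", {
  # lambda = 1.05 along x, fa = 0, default face parameters: scalar formula
  # evaluated independently from J, I1_iso and I4_star = I1_iso / 3
  p <- default_face_parameters(fa = 0)
  expect_equal(strain_energy(diag(c(1.05, 1, 1)), p),
               11.946068580712, tolerance = 1e-10)
})

test_that("Cauchy stress is the finite-difference derivative of the energy", {
  p <- default_face_parameters(fa = 0.3)
  expect_equal(cauchy_stress(diag(3), p), matrix(0, 3, 3))
  set.seed(31)
  h <- 1e-6
  for (i in 1:3) {
    F <- random_F()
    G <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) {
      Fp <- F; Fp[r, cc] <- Fp[r, cc] + h
      Fm <- F; Fm[r, cc] <- Fm[r, cc] - h
      G[r, cc] <- (strain_energy(Fp, p) - strain_energy(Fm, p)) / (2 * h)
    }
    sig_fd <- G %*% t(F) / det(F)
    sig <- cauchy_stress(F, p)
    expect_lt(max(abs(sig - (sig_fd + t(sig_fd)) / 2)) / max(abs(sig)),
              1e-5)
    expect_equal(sig, t(sig))
  }
})

test_that("FA = 0 gives an exactly isotropic response", {
  p1 <- default_face_parameters(a0 = c(1, 0, 0), fa = 0)
  p2 <- default_face_parameters(a0 = c(0, 0, 1), fa = 0)
  set.seed(41)
  F <- random_F()
  expect_identical(cauchy_stress(F, p1), cauchy_stress(F, p2))
  expect_identical(strain_energy(F, p1), strain_energy(F, p2))
})

test_that("compiled and interpreted material points agree", {
  set.seed(51)
  for (i in 1:5) {
    p <- material_parameters(1e4, 18, 1200, 18, runif(1),
                             a0 = c(0, 1, 0), fa = runif(1))
    F <- random_F()
    pr <- turgorcell:::par_row(p)
    expect_equal(turgorcell:::.cpp_cauchy_stress(F, pr, FALSE),
                 cauchy_stress(F, p), tolerance = 1e-12)
    expect_equal(turgorcell:::.cpp_strain_energy(F, pr, FALSE),
                 strain_energy(F, p), tolerance = 1e-12)
  }
})

test_that("material tangent has minor symmetries and the small-strain limit", {
  p <- material_parameters(200, 30, 0, 10, 0.5, fa = 0)
  D <- material_tangent(diag(3), p)
  # minor symmetries by construction, major symmetry from hyperelasticity
  expect_equal(D, aperm(D, c(2, 1, 3, 4)))
  expect_equal(D, aperm(D, c(1, 2, 4, 3)))
  expect_equal(D, aperm(D, c(3, 4, 1, 2)), tolerance = 1e-6)
  # classical isotropic operator with bulk K and apparent shear
  # mu = (1 - theta_f) mu_m + mu_c
  mu <- (1 - 0.5) * 30 + 10
  Dref <- array(0, c(3, 3, 3, 3))
  d <- diag(3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    Dref[i, j, k, l] <- 200 * d[i, j] * d[k, l] +
      2 * mu * ((d[i, k] * d[j, l] + d[i, l] * d[j, k]) / 2 -
                d[i, j] * d[k, l] / 3)
  expect_equal(D, Dref, tolerance = 1e-4 * max(abs(Dref)))
})

test_that("uniaxial stress along the fiber direction stiffens with FA", {
  F <- diag(c(1, 1.1, 1))
  s22 <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(fa)
    cauchy_stress(F, default_face_parameters(a0 = c(0, 1, 0), fa = fa))[2, 2])
  expect_true(all(diff(s22) > 0))
})

test_that("joint shear-modulus scaling scales the deviatoric stress", {
  set.seed(61)
  F <- random_F()
  p1 <- material_parameters(1e4, 18, 1200, 18, 0.5, fa = 0.3)
  p2 <- material_parameters(1e4, 3 * 18, 3 * 1200, 3 * 18, 0.5, fa = 0.3)
  dev <- function(s) s - mean(diag(s)) * diag(3)
  expect_equal(dev(cauchy_stress(F, p2)), 3 * dev(cauchy_stress(F, p1)),
               tolerance = 1e-12)
})

test_that("tension-only fiber switch removes the fiber term in compression", {
  p <- default_face_parameters(a0 = c(0, 1, 0), fa = 1)
  Fc <- diag(c(1, 0.9, 1))   # fiber compressed
  s_on <- cauchy_stress(Fc, p)
  s_off <- cauchy_stress(Fc, p, tension_only = TRUE)
  p0 <- material_parameters(p$K, p$mu_m, 0, p$mu_c, p$theta_f,
                            a0 = p$a0, fa = p$fa)
  expect_equal(s_off, cauchy_stress(Fc, p0))
  expect_false(isTRUE(all.equal(s_on, s_off)))
  # in tension the switch is inert
  Ft <- diag(c(1, 1.1, 1))
  expect_equal(cauchy_stress(Ft, p, tension_only = TRUE),
               cauchy_stress(Ft, p))
})

test_that("material configs round-trip through YAML with unit conversion", {
  p <- default_face_parameters(a0 = c(0, 0, 1), fa = 0.2)
  path <- withr::local_tempfile(fileext = ".yml")
  write_material_config(p, path)
  q <- read_material_config(path)
  expect_equal(q[names(q) != "a0"], p[names(p) != "a0"])
  expect_equal(q$a0, p$a0)
})
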