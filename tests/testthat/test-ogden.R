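# Ogden material: closed forms against independent oracles (energy
# differentiation, constrained minimization), plane-stress consistency,
# and fit round-trips.

skin <- facial_skin_ogden()

test_that("strain energy: reference state, symmetry, direct evaluation", {
  expect_equal(ogden_strain_energy(1, 1, 1, skin), 0)
  lam <- 1.2
  l2 <- 1 / sqrt(lam)
  # independent direct evaluation of the two-term sum
  mu <- c(7.5809e-7, 0.1683); al <- c(2.1065, 12.006)
  W_direct <- sum(mu / al * (lam^al + 2 * l2^al - 3))
  expect_equal(ogden_strain_energy(lam, l2, l2, skin), W_direct,
               tolerance = 1e-12)
  # symmetric in the principal stretches
  expect_equal(ogden_strain_energy(l2, lam, l2, skin),
               ogden_strain_energy(l2, l2, lam, skin))
  expect_error(ogden_strain_energy(1.2, 1, 1, skin), "incompressible")
  expect_error(ogden_strain_energy(-1, 1, 1, skin), "positive")
  # compressible form with a bulk modulus admits J != 1
  pk <- ogden_parameters(skin$mu, skin$alpha, K = 10)
  J <- 1.05
  W_vol <- sum(mu / al * (J^(-al / 3) * (1.05^al + 1 + 1) - 3)) +
    4.5 * 10 * (J^(1 / 3) - 1)^2
  expect_equal(ogden_strain_energy(1.05, 1, 1, pk), W_vol, tolerance = 1e-12)
})

test_that("uniaxial stress matches the energy-differentiation oracle", {
  lam <- seq(0.8, 1.6, by = 0.02)
  # sigma = lambda * dW_hat/dlambda with W_hat(l) = W(l, l^-1/2, l^-1/2)
  h <- 1e-6
  What <- function(l) ogden_strain_energy(l, 1 / sqrt(l), 1 / sqrt(l), skin)
  sig_fd <- vapply(lam, function(l) l * (What(l + h) - What(l - h)) / (2 * h),
                   numeric(1))
  expect_equal(ogden_uniaxial_stress(lam, skin), sig_fd, tolerance = 1e-6)
  expect_equal(ogden_uniaxial_stress(1, skin), 0)
  expect_true(all(sign(ogden_uniaxial_stress(lam, skin)) == sign(lam - 1)))
  # monotone (stable) response over the working range
  expect_true(all(diff(ogden_uniaxial_stress(lam, skin)) > 0))
})

test_that("uniaxial stress matches the constrained-minimization oracle", {
  for (lam in c(0.9, 1.0, 1.15, 1.3, 1.5)) {
    expect_equal(ogden_uniaxial_stress(lam, skin),
                 uniaxial_stress_brute(lam, skin),
                 tolerance = 1e-6)
  }
})

test_that("one-term model reduces to linear elasticity at small strain", {
  G <- 0.05
  one <- ogden_parameters(mu = 2 * G / 3, alpha = 3)
  lam <- 1 + c(1e-4, 5e-4, 1e-3)
  expect_equal(ogden_uniaxial_stress(lam, one), 3 * G * (lam - 1),
               tolerance = 1e-2)
})

test_that("plane-stress response: identity, uniaxial reduction, objectivity", {
  r0 <- plane_stress_response(diag(2), skin)
  expect_equal(r0$sigma, matrix(0, 2, 2))
  expect_equal(r0$lambda3, 1)
  set.seed(11)
  for (k in 1:100) {
    lam <- runif(1, 0.85, 1.6)
    Fu <- diag(c(lam, 1 / sqrt(lam)))
    r <- plane_stress_response(Fu, skin)
    expect_equal(r$sigma[1, 1], ogden_uniaxial_stress(lam, skin),
                 tolerance = 1e-10)
    expect_equal(r$sigma[2, 2], 0, tolerance = 1e-12)
    expect_equal(r$lambda3, 1 / sqrt(lam), tolerance = 1e-12)
  }
  # frame indifference: rotation leaves the von Mises invariant unchanged
  lam <- 1.33
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ru <- plane_stress_response(diag(c(lam, 1 / sqrt(lam))), skin)
  rr <- plane_stress_response(R %*% diag(c(lam, 1 / sqrt(lam))), skin)
  expect_equal(von_mises(rr$sigma), von_mises(ru$sigma), tolerance = 1e-10)
  expect_equal(rr$sigma[1, 2], rr$sigma[2, 1])
  expect_error(plane_stress_response(diag(c(-1, 1)), skin), "inverted")
})

test_that("parameter container validates its invariants", {
  expect_error(ogden_parameters(c(1, 2), 1), "equal-length")
  expect_error(ogden_parameters(1, -2), "positive")
  p <- ogden_parameters(c(0.1, 0.2), c(2, 4))
  expect_equal(p$N, 2L)
})

test_that("fit round-trips a noiseless generated curve", {
  curve <- make_stress_stretch_curve(skin, c(1, 1.5), n = 50)
  fit <- fit_ogden(curve, N = 2)
  expect_lt(fit$rms, 1e-4)
  pred <- ogden_uniaxial_nominal_stress(curve$stretch, fit$params)
  expect_equal(pred, curve$stress_mpa, tolerance = 1e-3)
  expect_gt(sum(fit$params$mu * fit$params$alpha), 0)
})

test_that("fit recovers the ground-state shear modulus from linear data", {
  G <- 0.04
  lam <- seq(1, 1.05, length.out = 30)
  curve <- data.frame(stretch = lam, stress_mpa = 3 * G * (lam - 1))
  fit <- fit_ogden(curve, N = 1)
  G0 <- sum(fit$params$mu * fit$params$alpha) / 2
  expect_equal(G0, G, tolerance = 0.05)
})

test_that("fit handles noisy and degenerate curves", {
  curve <- make_stress_stretch_curve(skin, c(1, 1.5), n = 60,
                                     noise_sd = 0.01, seed = 3)
  fit <- fit_ogden(curve, N = 2)
  expect_lt(fit$rms, 0.012)  # about the noise SD
  flat <- data.frame(stretch = seq(1, 1.4, length.out = 20),
                     stress_mpa = rep(0, 20))
  fit0 <- fit_ogden(flat, N = 1)
  expect_lt(fit0$rms, 1e-8)
  expect_lt(max(fit0$params$mu), 1e-6)
  expect_error(fit_ogden(curve[1:3, ], N = 2), "at least")
})

test_that("curve and material configs round-trip through files", {
  tmp <- withr::local_tempdir()
  curve <- make_stress_stretch_curve(skin, n = 10)
  pcsv <- file.path(tmp, "c.csv")
  write_stress_stretch_csv(curve, pcsv)
  back <- read_stress_stretch_csv(pcsv)
  expect_equal(back$stress_mpa, curve$stress_mpa, tolerance = 1e-12)
  pcfg <- file.path(tmp, "m.cfg")
  write_material_config(skin, pcfg)
  skin2 <- read_material_config(pcfg)
  expect_identical(skin2$mu, skin$mu)
  expect_identical(skin2$alpha, skin$alpha)
})
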