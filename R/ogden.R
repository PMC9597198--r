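# Ogden hyperelastic material model for skin.
#
# Strain energy in principal stretches (incompressible form, J = 1):
#   W = sum_n (mu_n / alpha_n) (l1^a_n + l2^a_n + l3^a_n - 3)
# Compressible variant (used only when a bulk modulus K is supplied):
#   W = sum_n (mu_n / alpha_n) (J^(-a_n/3) (l1^a_n + l2^a_n + l3^a_n) - 3)
#       + 4.5 K (J^(1/3) - 1)^2
# Stresses follow from sigma_a = l_a dW/dl_a - p with the pressure p
# eliminated by the traction-free condition of the relevant loading mode.

#' Ogden material parameters
#'
#' Container for an N-term Ogden model.  The ground-state shear modulus is
#' `G0 = sum(mu * alpha) / 2`, which must be positive.
#'
#' @param mu Numeric vector of shear parameters (MPa).
#' @param alpha Numeric vector of dimensionless exponents, same length.
#' @param K Optional bulk modulus (MPa).  When `NULL` (default) the model is
#'   fully incompressible.
#' @return Object of class `ogden_parameters` with elements `mu`, `alpha`,
#'   `N` and `K`.
#' @examples
#' ogden_parameters(mu = c(7.5809e-7, 0.1683), alpha = c(2.1065, 12.006))
#' @export
ogden_parameters <- function(mu, alpha, K = NULL) {
  if (length(mu) != length(alpha) || length(mu) < 1L) {
    stop("mu and alpha must be equal-length vectors with at least one term",
         call. = FALSE)
  }
  if (any(!is.finite(mu)) || any(!is.finite(alpha))) {
    stop("non-finite Ogden parameters", call. = FALSE)
  }
  if (sum(mu * alpha) <= 0) {
    stop("ground-state shear modulus sum(mu * alpha)/2 must be positive",
         call. = FALSE)
  }
  if (!is.null(K) && (length(K) != 1L || K <= 0)) {
    stop("bulk modulus K must be a single positive number", call. = FALSE)
  }
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                 N = length(mu), K = K),
            class = "ogden_parameters")
}

#' @export
print.ogden_parameters <- function(x, ...) {
  cat(sprintf("Ogden material, N = %d (%s)\n", x$N,
              if (is.null(x$K)) "incompressible" else
                sprintf("K = %g MPa", x$K)))
  for (n in seq_len(x$N)) {
    cat(sprintf("  mu_%d = %.6g MPa, alpha_%d = %.6g\n",
                n, x$mu[n], n, x$alpha[n]))
  }
  cat(sprintf("  ground-state shear modulus G0 = %.6g MPa\n",
              sum(x$mu * x$alpha) / 2))
  invisible(x)
}

#' Two-term Ogden parameters for facial skin
#'
#' The default material of the simulation: a two-term incompressible Ogden
#' model fitted to uniaxial tension data of human facial skin,
#' `mu = (7.5809e-7, 0.1683) MPa`, `alpha = (2.1065, 12.006)`.
#'
#' @return An `ogden_parameters` object.
#' @export
facial_skin_ogden <- function() {
  ogden_parameters(mu = c(7.5809e-7, 0.1683), alpha = c(2.1065, 12.006))
}

#' Ogden strain-energy density
#'
#' Evaluates the strain energy at a principal-stretch triple.  In
#' incompressible mode (no bulk modulus) the caller must supply stretches
#' with `l1 l2 l3 = 1` to within `1e-8`.
#'
#' @param l1,l2,l3 Principal stretches (> 0).  Vectorized.
#' @param params An [ogden_parameters()] object.
#' @return Energy density in MPa (energy per unit reference volume).
#' @examples
#' ogden_strain_energy(1.2, 1.2^-0.5, 1.2^-0.5, facial_skin_ogden())
#' @export
ogden_strain_energy <- function(l1, l2, l3, params) {
  stopifnot(inherits(params, "ogden_parameters"))
  if (any(l1 <= 0 | l2 <= 0 | l3 <= 0)) {
    stop("principal stretches must be positive", call. = FALSE)
  }
  J <- l1 * l2 * l3
  if (is.null(params$K)) {
    if (any(abs(J - 1) > 1e-8)) {
      stop("incompressible mode requires l1*l2*l3 = 1 (|J - 1| <= 1e-8)",
           call. = FALSE)
    }
    W <- 0
    for (n in seq_len(params$N)) {
      a <- params$alpha[n]
      W <- W + params$mu[n] / a * (l1^a + l2^a + l3^a - 3)
    }
    return(W)
  }
  W <- 4.5 * params$K * (J^(1 / 3) - 1)^2
  for (n in seq_len(params$N)) {
    a <- params$alpha[n]
    W <- W + params$mu[n] / a * (J^(-a / 3) * (l1^a + l2^a + l3^a) - 3)
  }
  W
}

#' Uniaxial Cauchy stress of an incompressible Ogden solid
#'
#' Closed form for uniaxial tension/compression with traction-free lateral
#' faces (`l_lat = lambda^(-1/2)`, pressure eliminated by the lateral
#' zero-stress condition):
#' `sigma(lambda) = sum_n mu_n (lambda^a_n - lambda^(-a_n/2))`.
#'
#' @param lambda Axial stretch (> 0).  Vectorized.
#' @param params An [ogden_parameters()] object (incompressible).
#' @return Cauchy stress in MPa; zero at `lambda = 1`, sign of `lambda - 1`.
#' @export
ogden_uniaxial_stress <- function(lambda, params) {
  stopifnot(inherits(params, "ogden_parameters"))
  if (any(lambda <= 0)) stop("stretch must be positive", call. = FALSE)
  s <- 0
  for (n in seq_len(params$N)) {
    a <- params$alpha[n]
    s <- s + params$mu[n] * (lambda^a - lambda^(-a / 2))
  }
  s
}

#' Uniaxial nominal (first Piola-Kirchhoff) stress
#'
#' Force per unit reference area, `P(lambda) = sigma(lambda) / lambda` for
#' the incompressible uniaxial mode; this is what a uniaxial extensometer
#' reports.
#'
#' @inheritParams ogden_uniaxial_stress
#' @return Nominal stress in MPa.
#' @export
ogden_uniaxial_nominal_stress <- function(lambda, params) {
  ogden_uniaxial_stress(lambda, params) / lambda
}

# Vectorized plane-stress constitutive kernel.
#
# Inputs are the components of the in-plane deformation gradient for many
# quadrature points at once.  Incompressibility fixes the thickness stretch
# l3 = 1 / det(F); the hydrostatic pressure is eliminated by sigma_33 = 0,
# giving principal Cauchy stresses
#   sigma_a = sum_n mu_n (l_a^a_n - l3^a_n),  a = 1, 2.
# The in-plane Cauchy tensor is reassembled from the spectral decomposition
# of b = F F^T; the nominal stress is P = sigma F^(-T) (full 3-D J = 1).
# Returns NULL if any det(F) <= 0 (element inversion signal).
ogden_ps_kernel <- function(F11, F21, F12, F22, params) {
  detF <- F11 * F22 - F12 * F21
  if (any(detF <= 0)) return(NULL)
  b11 <- F11 * F11 + F12 * F12
  b12 <- F11 * F21 + F12 * F22
  b22 <- F21 * F21 + F22 * F22
  mean_b <- 0.5 * (b11 + b22)
  diff_b <- 0.5 * (b11 - b22)
  disc <- sqrt(diff_b * diff_b + b12 * b12)
  ev1 <- pmax(mean_b + disc, 1e-12)
  ev2 <- pmax(mean_b - disc, 1e-12)
  l1 <- sqrt(ev1)
  l2 <- sqrt(ev2)
  l3 <- 1 / detF
  s1 <- 0
  s2 <- 0
  for (n in seq_len(params$N)) {
    a <- params$alpha[n]
    l3a <- l3^a
    s1 <- s1 + params$mu[n] * (l1^a - l3a)
    s2 <- s2 + params$mu[n] * (l2^a - l3a)
  }
  # sigma = m I + dd * [cos2phi, sin2phi; sin2phi, -cos2phi]
  m <- 0.5 * (s1 + s2)
  dd <- 0.5 * (s1 - s2)
  safe <- disc > 1e-14
  c2 <- ifelse(safe, diff_b / disc, 0)
  s2phi <- ifelse(safe, b12 / disc, 0)
  sig11 <- m + dd * c2
  sig22 <- m - dd * c2
  sig12 <- dd * s2phi
  # P = sigma %*% F^(-T);  F^(-T) = (1/detF) [F22, -F21; -F12, F11]
  inv <- 1 / detF
  P11 <- (sig11 * F22 - sig12 * F12) * inv
  P12 <- (-sig11 * F21 + sig12 * F11) * inv
  P21 <- (sig12 * F22 - sig22 * F12) * inv
  P22 <- (-sig12 * F21 + sig22 * F11) * inv
  list(sig11 = sig11, sig22 = sig22, sig12 = sig12,
       P11 = P11, P21 = P21, P12 = P12, P22 = P22,
       l3 = l3, detF = detF)
}

#' Plane-stress response of the incompressible Ogden model
#'
#' Cauchy stress and thickness stretch for a single in-plane deformation
#' gradient under the plane-stress incompressible idealization: the
#' thickness stretch is `l3 = 1/det(F)` and the pressure is eliminated by
#' `sigma_33 = 0`.
#'
#' @param F A 2x2 in-plane deformation gradient with `det(F) > 0`.
#' @param params An [ogden_parameters()] object (incompressible).
#' @return A list with `sigma` (symmetric 2x2 Cauchy stress, MPa),
#'   `lambda3` (thickness stretch) and `P` (2x2 nominal stress).
#' @examples
#' lam <- 1.2
#' plane_stress_response(diag(c(lam, 1 / sqrt(lam))), facial_skin_ogden())
#' @export
plane_stress_response <- function(F, params) {
  stopifnot(is.matrix(F), all(dim(F) == c(2, 2)))
  if (det(F) <= 0) {
    stop("det(F) <= 0: inverted in-plane deformation state", call. = FALSE)
  }
  k <- ogden_ps_kernel(F[1, 1], F[2, 1], F[1, 2], F[2, 2], params)
  list(sigma = matrix(c(k$sig11, k$sig12, k$sig12, k$sig22), 2, 2),
       lambda3 = k$l3,
       P = matrix(c(k$P11, k$P21, k$P12, k$P22), 2, 2))
}

#' Fit an Ogden model to a uniaxial stress-stretch curve
#'
#' Multi-start bounded nonlinear least squares on the uniaxial response.
#' Because a two-term Ogden model is notoriously non-identifiable from a
#' single uniaxial curve, fit quality should be judged by the RMS residual
#' of the predicted stress curve, not by parameter recovery.
#'
#' The model is linear in `mu` for fixed `alpha`; each start therefore seeds
#' `mu` by linear least squares at sampled exponents before the joint
#' Levenberg-Marquardt refinement ([minpack.lm::nls.lm()]) with bounds
#' `mu >= 0`, `alpha` in `[0.1, 30]`.
#'
#' @param curve A data frame with columns `stretch` and `stress_mpa` (e.g.
#'   from [make_stress_stretch_curve()] or [read_stress_stretch_csv()]).
#' @param N Number of Ogden terms (1, 2 or 3).
#' @param stress_measure Convention of the `stress_mpa` column: `"nominal"`
#'   (first Piola-Kirchhoff, the uniaxial-extensometer default) or
#'   `"cauchy"`.
#' @param n_starts Number of random multi-starts.
#' @param seed Seed for start-point sampling (fit is deterministic given it).
#' @return An object of class `ogden_fit`: list with `params`
#'   (an [ogden_parameters()]), `rms` (RMS stress residual, MPa),
#'   `converged`, and `n_starts_tried`.
#' @export
fit_ogden <- function(curve, N = 2,
                      stress_measure = c("nominal", "cauchy"),
                      n_starts = 12, seed = 1) {
  stress_measure <- match.arg(stress_measure)
  lam <- as.numeric(curve$stretch)
  y <- as.numeric(curve$stress_mpa)
  if (length(lam) < 2 * N) {
    stop("need at least 2*N data points to fit an N-term model",
         call. = FALSE)
  }
  if (any(lam <= 0) || any(diff(lam) <= 0)) {
    stop("stretches must be positive and strictly increasing", call. = FALSE)
  }
  if (!N %in% 1:3) stop("N must be 1, 2 or 3", call. = FALSE)

  predict_stress <- function(mu, alpha) {
    s <- rep(0, length(lam))
    for (n in seq_along(mu)) {
      s <- s + mu[n] * (lam^alpha[n] - lam^(-alpha[n] / 2))
    }
    if (stress_measure == "nominal") s / lam else s
  }
  basis <- function(alpha) {
    B <- vapply(alpha, function(a) lam^a - lam^(-a / 2), numeric(length(lam)))
    if (stress_measure == "nominal") B / lam else B
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  lower <- c(rep(1e-12, N), rep(0.1, N))
  upper <- c(rep(Inf, N), rep(30, N))
  best <- NULL
  n_tried <- 0L
  for (k in seq_len(n_starts)) {
    alpha0 <- sort(exp(stats::runif(N, log(0.5), log(25))))
    B <- basis(alpha0)
    mu0 <- tryCatch(pmax(as.numeric(stats::coef(stats::lm.fit(B, y))), 1e-10),
                    error = function(e) rep(0.1, N))
    mu0[!is.finite(mu0)] <- 1e-10
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(mu0, alpha0),
        lower = lower, upper = upper,
        fn = function(p) predict_stress(p[1:N], p[(N + 1):(2 * N)]) - y,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    n_tried <- n_tried + 1L
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) {
      best <- list(par = fit$par, rms = rms, info = fit$info)
    }
    if (best$rms < 1e-10) break
  }
  if (is.null(best)) {
    stop("Ogden fit failed to converge from any start point", call. = FALSE)
  }
  mu <- best$par[1:N]
  alpha <- best$par[(N + 1):(2 * N)]
  params <- ogden_parameters(mu = mu, alpha = alpha)
  structure(list(params = params, rms = best$rms,
                 converged = best$info %in% 1:4,
                 n_starts_tried = n_tried,
                 stress_measure = stress_measure),
            class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat(sprintf("Ogden fit (%s stress), RMS residual %.3g MPa%s\n",
              x$stress_measure, x$rms,
              if (x$converged) "" else " [not converged]"))
  print(x$params)
  invisible(x)
}

#' Read / write stress-stretch curves as CSV
#'
#' Columns `stretch` (dimensionless) and `stress_mpa` (MPa).
#'
#' @param path CSV path.
#' @return `read_stress_stretch_csv`: a data frame with the two columns.
#' @export
read_stress_stretch_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("stretch", "stress_mpa") %in% names(df))) {
    stop("curve CSV must have columns 'stretch' and 'stress_mpa'",
         call. = FALSE)
  }
  df[, c("stretch", "stress_mpa")]
}

#' @rdname read_stress_stretch_csv
#' @param curve Data frame with columns `stretch`, `stress_mpa`.
#' @export
write_stress_stretch_csv <- function(curve, path) {
  utils::write.csv(curve[, c("stretch", "stress_mpa")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read Ogden parameters as a structured text config
#'
#' YAML with fields `mu`, `alpha` and optional `K`; round-trips exactly via
#' full-precision character encoding.
#'
#' @param params An [ogden_parameters()] object.
#' @param path File path.
#' @return `read_material_config`: an [ogden_parameters()] object.
#' @export
write_material_config <- function(params, path) {
  stopifnot(inherits(params, "ogden_parameters"))
  obj <- list(model = "ogden",
              mu = sprintf("%.17g", params$mu),
              alpha = sprintf("%.17g", params$alpha))
  if (!is.null(params$K)) obj$K <- sprintf("%.17g", params$K)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_material_config
#' @export
read_material_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$model, "ogden")) {
    stop("material config must declare model: ogden", call. = FALSE)
  }
  ogden_parameters(mu = as.numeric(obj$mu), alpha = as.numeric(obj$alpha),
                   K = if (is.null(obj$K)) NULL else as.numeric(obj$K))
}
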