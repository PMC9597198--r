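# Synthetic data and independent oracles.
#
# The uniaxial experimental curve behind the default skin parameters is not
# publicly tabulated, so fitting and material tests run against synthetic
# curves generated from known parameters.  The brute-force uniaxial oracle
# recomputes the uniaxial stress by constrained energy minimization, sharing
# no code with the closed form it checks.

#' Synthesize a uniaxial stress-stretch curve from Ogden parameters
#'
#' Nominal (first Piola-Kirchhoff) stress from the closed-form uniaxial
#' response, with optional additive Gaussian noise on the stress channel
#' (the uniaxial-extensometer convention).  Deterministic for a fixed seed.
#'
#' @param params Generating [ogden_parameters()].
#' @param lambda_range Length-2 stretch range (default `c(1, 1.5)`).
#' @param n Number of equally spaced samples (>= 4).
#' @param noise_sd Noise standard deviation in MPa (default 0).
#' @param seed Optional integer seed used when `noise_sd > 0`.
#' @return Data frame with columns `stretch`, `stress_mpa`; attributes
#'   `noise_sd` and `seed` record the generator settings.
#' @examples
#' make_stress_stretch_curve(facial_skin_ogden(), n = 50)
#' @export
make_stress_stretch_curve <- function(params, lambda_range = c(1, 1.5),
                                      n = 50, noise_sd = 0, seed = NULL) {
  stopifnot(length(lambda_range) == 2L, all(lambda_range > 0),
            lambda_range[1] < lambda_range[2], n >= 4)
  lam <- seq(lambda_range[1], lambda_range[2], length.out = n)
  stress <- ogden_uniaxial_nominal_stress(lam, params)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    if (!is.null(seed)) set.seed(seed)
    stress <- stress + stats::rnorm(n, 0, noise_sd)
  }
  out <- data.frame(stretch = lam, stress_mpa = stress)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Brute-force uniaxial stress oracle
#'
#' Independent check of [ogden_uniaxial_stress()]: for a prescribed axial
#' stretch the lateral stretch is found by minimizing the strain energy
#' `W(lambda, l2, 1/(lambda l2))` over `l2` ([stats::optimize()]), and the
#' Cauchy stress follows from a central difference of the minimized energy,
#' `sigma = lambda * d(min_l2 W)/d(lambda)`.  No closed-form stress
#' expression is used anywhere on this path.
#'
#' @param lambda Axial stretch (scalar or vector).
#' @param params An incompressible [ogden_parameters()].
#' @return Cauchy stress in MPa.
#' @export
uniaxial_stress_brute <- function(lambda, params) {
  energy_min <- function(l) {
    # minimized energy over the lateral stretch at fixed axial stretch
    f <- function(l2) {
      a <- params$alpha
      sum(params$mu / a * (l^a + l2^a + (1 / (l * l2))^a - 3))
    }
    stats::optimize(f, interval = c(1e-3, 1e3), tol = 1e-12)$objective
  }
  h <- 1e-6
  vapply(lambda, function(l) {
    l * (energy_min(l + h) - energy_min(l - h)) / (2 * h)
  }, numeric(1))
}

#' Library of tiny reference meshes
#'
#' Small meshes with known analytic properties for solver testing: a single
#' square element, a structured `2 x 2` patch, and a coarse miniature A-T
#' model (`r = 4` mm in a 40 x 44 mm domain).
#'
#' @param element_size Side length in mm of the square elements for the
#'   single-element and patch meshes (default 3).
#' @return Named list of `skin_mesh` objects: `single`, `patch2x2`,
#'   `mini_at`.
#' @export
patch_meshes <- function(element_size = 3) {
  single <- rect_grid_mesh(c(0, element_size), c(0, element_size), 1, 1)
  patch <- rect_grid_mesh(c(0, 2 * element_size), c(0, 2 * element_size), 2, 2)
  design <- design_flap(4, 60)
  dom <- build_domain(design, width = 40, height = 44)
  mini <- generate_mesh(dom, element_size = 6)
  list(single = single, patch2x2 = patch, mini_at = mini)
}
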