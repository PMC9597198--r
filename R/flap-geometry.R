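# Closed-form geometric model of the A-T advancement flap.
#
# The defect is idealized as a circle of radius r inscribed in the triangular
# excision: the circle is tangent to the base line and to both waists of the
# triangle.  With half-apex angle theta (apex angle of the flap = 2*theta):
#   h/d = 1 / (2 tan theta)                length-width ratio
#   d   = 2 r (1 + sin theta) / cos theta  maximum suture distance (base BC)
#   S   = r^2 (1 + sin theta)^2 / (sin theta cos theta)  suture (excision) area
# All lengths in mm, areas in mm^2, angles in degrees at the user interface
# and radians internally.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# Round half away from zero (printed tables use this convention, not the
# IEEE round-half-even of base round()).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta >= pi / 2)) {
    stop("half-apex angle theta must lie in the open interval (0, pi/2)",
         call. = FALSE)
  }
  invisible(theta)
}

check_radius <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("defect radius r must be a single positive number", call. = FALSE)
  }
  invisible(r)
}

#' Length-width ratio of an A-T flap
#'
#' Ratio of flap length `h` to flap width `d` as a function of the half-apex
#' angle: `h/d = 1/(2 tan(theta))`.  The ratio decreases strictly as the apex
#' angle opens.
#'
#' @param theta Half-apex angle in radians, in the open interval (0, pi/2).
#'   The apex angle of the flap is `2 * theta`.
#' @return The dimensionless ratio `h/d`.
#' @examples
#' length_width_ratio(pi / 6)   # apex angle 60 degrees -> 0.866
#' @export
length_width_ratio <- function(theta) {
  check_theta(theta)
  1 / (2 * tan(theta))
}

#' Maximum suture distance of an A-T flap
#'
#' Width `d` of the triangular excision base (segment BC), the largest span
#' that must be pulled together during closure:
#' `d = 2 r (1 + sin(theta)) / cos(theta)`.
#'
#' @param r Defect radius in mm (radius of the circular lesion inscribed in
#'   the excision triangle).
#' @param theta Half-apex angle in radians, in (0, pi/2).
#' @return Maximum suture distance in mm.
#' @examples
#' max_suture_distance(10, pi / 6)  # 34.64 mm at apex angle 60 degrees
#' @export
max_suture_distance <- function(r, theta) {
  check_radius(r)
  check_theta(theta)
  2 * r * (1 + sin(theta)) / cos(theta)
}

#' Suture area of an A-T flap
#'
#' Area `S` of the excised triangle,
#' `S = r^2 (1 + sin(theta))^2 / (sin(theta) cos(theta))`,
#' a proxy for wound-closure burden.  Identical to `d * h / 2` computed from
#' [max_suture_distance()] and [length_width_ratio()].
#'
#' @inheritParams max_suture_distance
#' @return Suture area in mm^2.
#' @export
suture_area <- function(r, theta) {
  check_radius(r)
  check_theta(theta)
  r^2 * (1 + sin(theta))^2 / (sin(theta) * cos(theta))
}

#' Sweep the geometric design table over apex angles
#'
#' Evaluates the three design quantities for a set of apex angles at a fixed
#' defect radius, one row per angle.  Values are stored at full precision;
#' `print()` rounds to two decimals, the convention of the published design
#' table.  `S_norm` is the suture area divided by `r^2` (the area in units of
#' the squared defect radius), the scale on which design tables are usually
#' printed.
#'
#' @param r Defect radius in mm.
#' @param apex_deg Numeric vector of apex angles `2 theta` in degrees,
#'   each in (0, 180).  An empty vector yields an empty table.
#' @return A `data.frame` with columns `apex_deg`, `ratio` (h/d), `d_mm`,
#'   `S_mm2`, `S_norm` (S/r^2) and `h_mm`, of class `flap_sweep`.
#' @examples
#' flap_sweep(10, c(40, 50, 60, 70, 80))
#' @export
flap_sweep <- function(r, apex_deg) {
  check_radius(r)
  if (length(apex_deg) == 0L) {
    out <- data.frame(apex_deg = numeric(0), ratio = numeric(0),
                      d_mm = numeric(0), S_mm2 = numeric(0),
                      S_norm = numeric(0), h_mm = numeric(0))
    class(out) <- c("flap_sweep", "data.frame")
    return(out)
  }
  theta <- deg2rad(apex_deg) / 2
  check_theta(theta)
  ratio <- length_width_ratio(theta)
  d <- 2 * r * (1 + sin(theta)) / cos(theta)
  S <- r^2 * (1 + sin(theta))^2 / (sin(theta) * cos(theta))
  out <- data.frame(apex_deg = apex_deg, ratio = ratio, d_mm = d,
                    S_mm2 = S, S_norm = S / r^2, h_mm = ratio * d)
  class(out) <- c("flap_sweep", "data.frame")
  out
}

#' @export
print.flap_sweep <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print(y, ...)
  invisible(x)
}

#' Write a design sweep table to CSV
#'
#' @param sweep A table from [flap_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Optimal apex angle under the clinical length-width constraint
#'
#' Minimizes the suture area `S(theta)` subject to the clinical bound
#' `h/d <= ratio_max`.  `dS/dtheta` has the closed-form root
#' `sin(theta) = 1/2`, so the unconstrained optimum is an apex angle of
#' exactly 60 degrees; `S` is unimodal, so a binding constraint moves the
#' optimum to the nearest feasible angle.
#'
#' @param ratio_max Upper bound on `h/d` (default 3, the classic clinical
#'   limit protecting flap blood supply; common designs use 1-2).
#' @param apex_range Numeric length-2 vector, the admissible apex-angle
#'   interval in degrees (default `c(0, 90)`, open at both ends).
#' @return Optimal apex angle `2 theta` in degrees.
#' @examples
#' optimal_apex()            # 60
#' optimal_apex(ratio_max = 1)  # still 60: constraint not binding
#' @export
optimal_apex <- function(ratio_max = 3, apex_range = c(0, 90)) {
  if (!is.numeric(ratio_max) || length(ratio_max) != 1L || ratio_max <= 0) {
    stop("ratio_max must be a single positive number", call. = FALSE)
  }
  stopifnot(length(apex_range) == 2L, apex_range[1] < apex_range[2])
  eps <- 1e-9
  # h/d <= ratio_max  <=>  tan(theta) >= 1/(2 ratio_max)
  theta_lo_constraint <- atan(1 / (2 * ratio_max))
  theta_lo <- max(deg2rad(apex_range[1]) / 2, theta_lo_constraint, eps)
  theta_hi <- min(deg2rad(apex_range[2]) / 2, pi / 2 - eps)
  if (theta_lo > theta_hi) {
    stop("infeasible constraint set: no apex angle satisfies h/d <= ",
         ratio_max, " within the requested range", call. = FALSE)
  }
  # S is unimodal on (0, pi/2) with its minimum at sin(theta) = 1/2.
  theta_star <- min(max(pi / 6, theta_lo), theta_hi)
  if (identical(theta_star, pi / 6)) 60 else rad2deg(2 * theta_star)
}

#' Derivative of the suture area with respect to the half-apex angle
#'
#' `dS/dtheta` divided by `S` equals
#' `2 cos(theta)/(1 + sin(theta)) - cot(theta) + tan(theta)`, which vanishes
#' exactly at `theta = pi/6` (apex angle 60 degrees).  Exposed for
#' optimality verification.
#'
#' @inheritParams length_width_ratio
#' @return The logarithmic derivative `S'(theta)/S(theta)` (1/rad).
#' @export
suture_area_dlog <- function(theta) {
  check_theta(theta)
  2 * cos(theta) / (1 + sin(theta)) - 1 / tan(theta) + tan(theta)
}

#' Design an A-T flap
#'
#' Builds the full geometric design for a circular defect: derived lengths,
#' areas, and the incision layout in the operative plane.  Coordinates place
#' the triangle base on the x-axis centered at the origin (the future
#' T-junction), apex on +y, defect circle center at `(0, r)`.
#'
#' The base incision is extended laterally so that its total length is
#' `base_extension_factor` times the defect diameter (clinical rule of thumb:
#' about 3 diameters), relieving "cat ear" folds at the ends of the closure.
#' Extensions are floored at zero when the triangle base is already longer.
#'
#' @param r Defect radius in mm.
#' @param apex_deg Apex angle `2 theta` in degrees, in (0, 180).
#' @param base_extension_factor Total base-incision length as a multiple of
#'   the defect diameter `2 r`; must be >= 1.  Default 3.
#' @return An object of class `flap_design`: a list with elements `r`,
#'   `theta` (rad), `apex_deg`, `h`, `d`, `ratio`, `S` (mm^2),
#'   `base_extension_factor` and `layout`, the incision layout as a list of
#'   2-D points (mm): `apex`, `B`, `C` (base corners), `EL`, `ER` (lateral
#'   base-incision endpoints) and `defect_center`.
#' @examples
#' design_flap(10, 60)
#' @export
design_flap <- function(r, apex_deg, base_extension_factor = 3) {
  check_radius(r)
  if (!is.numeric(apex_deg) || length(apex_deg) != 1L ||
      apex_deg <= 0 || apex_deg >= 180) {
    stop("apex angle must be a single value in (0, 180) degrees",
         call. = FALSE)
  }
  if (base_extension_factor < 1) {
    stop("base_extension_factor must be >= 1", call. = FALSE)
  }
  theta <- deg2rad(apex_deg) / 2
  ratio <- length_width_ratio(theta)
  d <- max_suture_distance(r, theta)
  h <- ratio * d
  S <- suture_area(r, theta)
  e <- max(d / 2, base_extension_factor * r)  # half total incision length
  design <- list(
    r = r, theta = theta, apex_deg = apex_deg,
    h = h, d = d, ratio = ratio, S = S,
    base_extension_factor = base_extension_factor,
    layout = list(
      apex = c(0, h),
      B = c(-d / 2, 0), C = c(d / 2, 0),
      EL = c(-e, 0), ER = c(e, 0),
      defect_center = c(0, r)
    )
  )
  class(design) <- "flap_design"
  design
}

#' @export
print.flap_design <- function(x, ...) {
  cat("A-T flap design\n")
  cat(sprintf("  defect radius r      : %.2f mm\n", x$r))
  cat(sprintf("  apex angle 2*theta   : %.2f deg\n", x$apex_deg))
  cat(sprintf("  flap length h        : %.2f mm\n", x$h))
  cat(sprintf("  flap width  d        : %.2f mm (max suture distance)\n", x$d))
  cat(sprintf("  ratio h/d            : %.2f\n", x$ratio))
  cat(sprintf("  suture area S        : %.2f mm^2 (S/r^2 = %.2f)\n",
              x$S, x$S / x$r^2))
  cat(sprintf("  base incision span   : %.2f mm\n", 2 * abs(x$layout$EL[1])))
  invisible(x)
}

#' Plot the incision layout of a flap design
#'
#' Draws the excision triangle, lateral base incisions and defect circle in
#' the operative plane (mm).
#'
#' @param x A `flap_design`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.flap_design <- function(x, ...) {
  L <- x$layout
  e <- abs(L$EL[1])
  graphics::plot(NA, xlim = c(-e, e) * 1.15,
                 ylim = c(-0.25 * x$h, 1.15 * x$h), asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("A-T flap: r = %g mm, apex = %g°",
                                x$r, x$apex_deg), ...)
  tt <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(L$defect_center[1] + x$r * cos(tt),
                  L$defect_center[2] + x$r * sin(tt),
                  lty = 2, col = "red")
  graphics::segments(L$B[1], L$B[2], L$apex[1], L$apex[2], lwd = 2, col = "blue")
  graphics::segments(L$C[1], L$C[2], L$apex[1], L$apex[2], lwd = 2, col = "blue")
  graphics::segments(L$EL[1], 0, L$ER[1], 0, lwd = 2, col = "blue")
  invisible(x)
}

#' Export an incision layout as a CSV point list
#'
#' @param design A `flap_design`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(design, path) {
  L <- design$layout
  pts <- do.call(rbind, L)
  df <- data.frame(point = rownames(pts), x_mm = pts[, 1], y_mm = pts[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
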