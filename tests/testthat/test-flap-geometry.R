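# Closed-form geometric model: published design-table values, the exact
# 60-degree optimum, and internal consistency of the three relations.

d2r <- function(deg) deg * pi / 180
r2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100  # half away from 0

test_that("design relations reproduce the published table values", {
  # apex 60: h/d = 0.87, d = 34.64 mm (r = 10), S/r^2 = 5.20
  expect_equal(r2(length_width_ratio(d2r(30))), 0.87)
  expect_equal(r2(max_suture_distance(10, d2r(30))), 34.64)
  expect_equal(r2(suture_area(1, d2r(30))), 5.20)
  # apex 40
  expect_equal(r2(length_width_ratio(d2r(20))), 1.37)
  expect_equal(r2(suture_area(1, d2r(20))), 5.60)
  # apex 80
  expect_equal(r2(max_suture_distance(10, d2r(40))), 42.89)
  # trivial anchors
  expect_equal(length_width_ratio(pi / 4), 0.5)
  expect_equal(max_suture_distance(1, 1e-9), 2, tolerance = 1e-6)
  expect_equal(suture_area(2, d2r(30)), 4 * suture_area(1, d2r(30)))
  expect_error(length_width_ratio(0), "theta")
  expect_error(max_suture_distance(-1, d2r(30)), "positive")
})

test_that("sweep reproduces the full five-row design table to 2 decimals", {
  tab <- flap_sweep(10, c(40, 50, 60, 70, 80))
  expect_s3_class(tab, "flap_sweep")
  expect_equal(r2(tab$ratio), c(1.37, 1.07, 0.87, 0.71, 0.60))
  expect_equal(r2(tab$d_mm), c(28.56, 31.39, 34.64, 38.42, 42.89))
  expect_equal(r2(tab$S_norm), c(5.60, 5.28, 5.20, 5.27, 5.48))
  expect_equal(nrow(flap_sweep(10, numeric(0))), 0L)
})

test_that("monotonicity: h/d decreases and d increases with apex angle", {
  theta <- d2r(seq(1, 89, by = 0.5)) / 2
  expect_true(all(diff(length_width_ratio(theta)) < 0))
  expect_true(all(diff(max_suture_distance(5, theta)) > 0))
})

test_that("area relation agrees with the triangle identity d*h/2", {
  set.seed(7)
  r <- runif(1000, 0.5, 30)
  theta <- runif(1000, 0.02, pi / 2 - 0.02)
  S_eq <- suture_area(1, theta) * r^2
  d <- 2 * r * (1 + sin(theta)) / cos(theta)
  h <- length_width_ratio(theta) * d
  expect_equal(S_eq, d * h / 2, tolerance = 1e-9)
})

test_that("optimal apex is exactly 60 degrees and matches a grid oracle", {
  expect_identical(optimal_apex(), 60)
  # analytic derivative identity at theta = 30 degrees
  expect_lt(abs(suture_area_dlog(pi / 6)), 1e-12)
  # independent fine-grid oracle for the unconstrained minimum
  th <- d2r(seq(5, 85, by = 0.001))
  S <- (1 + sin(th))^2 / (sin(th) * cos(th))
  expect_equal(th[which.min(S)] * 180 / pi, 30, tolerance = 0.002)
  # binding constraint: h/d <= 0.6 excludes the unconstrained optimum
  feasible <- th[1 / (2 * tan(th)) <= 0.6]
  oracle <- 2 * feasible[which.min((1 + sin(feasible))^2 /
                                     (sin(feasible) * cos(feasible)))] * 180 / pi
  expect_equal(optimal_apex(ratio_max = 0.6), oracle, tolerance = 0.01)
  expect_error(optimal_apex(ratio_max = 0.2, apex_range = c(0, 30)),
               "infeasible")
})

test_that("design_flap populates a consistent layout", {
  d60 <- design_flap(10, 60)
  expect_equal(d60$h, 30, tolerance = 1e-9)
  expect_equal(d60$d, 20 * 1.5 / cos(pi / 6), tolerance = 1e-12)
  expect_equal(d60$S, d60$d * d60$h / 2, tolerance = 1e-9)
  # equilateral at 60 degrees: waist length equals the base width
  waist <- sqrt((d60$d / 2)^2 + d60$h^2)
  expect_equal(waist, d60$d, tolerance = 1e-9)
  # inscribed defect circle: tangent to base and both waists
  cc <- d60$layout$defect_center
  expect_equal(cc[2], d60$r)  # distance to the base line y = 0
  A <- d60$layout$apex; B <- d60$layout$B
  n <- c(-(A[2] - B[2]), A[1] - B[1])
  n <- n / sqrt(sum(n^2))
  expect_equal(abs(sum((cc - B) * n)), d60$r, tolerance = 1e-9)
  # base incision 3 defect diameters by default
  expect_equal(abs(d60$layout$EL[1]), 30)
  expect_error(design_flap(-1, 60), "positive")
  expect_error(design_flap(10, 190), "apex")
})
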