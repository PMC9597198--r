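# Meshing: structured grids, the A-T block decomposition, cut duplication,
# suture pairing and quality metrics.

default_mesh <- function() {
  memo("default_mesh",
       generate_mesh(build_domain(design_flap(10, 60)), 3))
}

test_that("domain description carries the incision cuts", {
  d <- design_flap(10, 60)
  dom <- build_domain(d)
  expect_s3_class(dom, "flap_domain")
  waist <- sqrt((d$d / 2)^2 + d$h^2)
  ext <- 30 - d$d / 2
  expect_equal(dom$cut_length, 2 * waist + 2 * ext, tolerance = 1e-9)
  expect_error(build_domain(design_flap(30, 60)), "exceeds")
  expect_error(design_flap(0, 60), "positive")
})

test_that("plain rectangle meshes to a structured grid", {
  m <- generate_mesh(build_domain(NULL, width = 6, height = 6), 3)
  expect_equal(nrow(m$elems), 4L)
  expect_equal(nrow(m$nodes), 9L)
  q <- quality_report(m)
  expect_equal(c(q$n_inverted, q$n_distorted, q$n_bad_aspect), c(0L, 0L, 0L))
  expect_error(generate_mesh(build_domain(NULL), 0.1), "element_size")
})

test_that("default A-T mesh has the expected size and positive Jacobians", {
  m <- default_mesh()
  expect_gte(nrow(m$elems), 800)
  expect_lte(nrow(m$elems), 1350)
  expect_gt(nrow(m$nodes), nrow(m$elems))
  expect_equal(quality_report(m)$n_inverted, 0L)
  expect_setequal(unique(m$region), c("flap", "skin"))
  # all reference Jacobians positive across the standard element sizes
  for (sz in c(4, 2, 1)) {
    q <- quality_report(generate_mesh(build_domain(design_flap(10, 60)), sz))
    expect_equal(q$n_inverted, 0L)
  }
})

test_that("meshing is deterministic and refines about fourfold", {
  dom <- build_domain(design_flap(10, 60))
  m1 <- generate_mesh(dom, 3)
  m2 <- generate_mesh(dom, 3)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  mh <- generate_mesh(dom, 1.5)
  ratio <- nrow(mh$elems) / nrow(m1$elems)
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("base-cut nodes are duplicated and coincident; waists are not cut", {
  m <- default_mesh()
  bc <- m$base_cut_pairs
  expect_gt(nrow(bc), 0)
  gap <- m$nodes[bc$flap, , drop = FALSE] - m$nodes[bc$lower, , drop = FALSE]
  expect_lt(max(abs(gap)), 1e-9)
  expect_true(all(bc$flap != bc$lower))
  # duplicated nodes sit strictly inside the lateral base cuts
  xs <- m$nodes[bc$flap, 1]
  expect_true(all(abs(xs) > m$domain$design$d / 2 - 1e-6))
  expect_true(all(abs(xs) < 30 - 1e-6))
})

test_that("suture pairs are mirror-symmetric with targets on the midline", {
  m <- default_mesh()
  pr <- suture_pairs(m)
  a <- m$nodes[pr$node_a, , drop = FALSE]
  b <- m$nodes[pr$node_b, , drop = FALSE]
  # mirror images on the two waists
  expect_equal(a[, 1], -b[, 1], tolerance = 1e-9)
  expect_equal(a[, 2], b[, 2], tolerance = 1e-9)
  expect_true(all(pr$target_x == 0))
  # pairs lie on the waist segment from B to the apex
  d <- m$domain$design
  t <- 1 - pr$arc_from_apex / sqrt((d$d / 2)^2 + d$h^2)
  expect_equal(a[, 1], -(1 - t) * d$d / 2, tolerance = 1e-9)
  expect_equal(a[, 2], t * d$h, tolerance = 1e-9)
  # isometric default: corner pair meets at (0, h - L_w)
  waist <- sqrt((d$d / 2)^2 + d$h^2)
  expect_equal(min(pr$target_y), d$h - waist, tolerance = 1e-9)
  # pairing is a bijection between distinct waist sides
  expect_true(all(pr$node_a != pr$node_b))
  expect_false(anyDuplicated(pr$node_a) > 0)
  expect_false(anyDuplicated(pr$node_b) > 0)
  # both members of every pair belong to flap-region elements
  flap_nodes <- unique(as.vector(m$elems[m$region == "flap", ]))
  expect_true(all(c(pr$node_a, pr$node_b) %in% flap_nodes))
  # proportional variant pins the corners at the T-junction
  mp <- generate_mesh(m$domain, 3, target_strategy = "proportional")
  expect_equal(min(suture_pairs(mp)$target_y), 0, tolerance = 1e-12)
  expect_error(suture_pairs(rect_grid_mesh(c(0, 1), c(0, 1), 1, 1)),
               "no suture pairs")
})

test_that("quality metrics flag stretched and degenerate elements", {
  sq <- rect_grid_mesh(c(0, 2), c(0, 2), 2, 2)
  q <- quality_report(sq)
  expect_equal(c(q$n_inverted, q$n_distorted, q$n_bad_aspect), c(0L, 0L, 0L))
  stretched <- rect_grid_mesh(c(0, 3), c(0, 1), 1, 1)  # aspect 3 > 1.5
  expect_equal(quality_report(stretched)$n_bad_aspect, 1L)
  expect_equal(quality_report(stretched)$n_inverted, 0L)
})

test_that("fixture meshes are sane", {
  pm <- patch_meshes()
  expect_equal(nrow(pm$single$elems), 1L)
  expect_equal(nrow(pm$patch2x2$elems), 4L)
  expect_equal(quality_report(pm$mini_at)$n_inverted, 0L)
  # mirror-symmetric node set of the mini A-T mesh
  expect_false(anyNA(mirror_map(pm$mini_at$nodes)))
})

test_that("mesh exports are readable text", {
  tmp <- withr::local_tempdir()
  m <- patch_meshes()$patch2x2
  pv <- file.path(tmp, "m.vtk")
  write_vtk_mesh(m, pv)
  lines <- readLines(pv)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_equal(sum(lines == "9"), nrow(m$elems))
  pm <- file.path(tmp, "m.msh")
  write_msh_mesh(m, pm)
  expect_true(any(readLines(pm) == "$EndElements"))
})
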