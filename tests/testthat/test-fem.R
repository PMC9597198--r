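# Nonlinear FE solver: element-level oracles (closed-form stress, rigid
# motion, finite-difference tangent), patch tests, constraint handling and
# the two-stage staging machinery on the miniature A-T fixture.

skin <- facial_skin_ogden()
sq3 <- matrix(c(0, 0, 3, 0, 3, 3, 0, 3), 4, 2, byrow = TRUE)

test_that("element force vanishes for zero and rigid-body motion", {
  r0 <- element_internal_force(sq3, matrix(0, 4, 2), skin)
  expect_equal(max(abs(r0$f)), 0)
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  u_rot <- t(R %*% t(sq3)) - sq3
  u_rot[, 1] <- u_rot[, 1] + 1.7   # add a translation
  rr <- element_internal_force(sq3, u_rot, skin)
  expect_lt(max(abs(rr$f)), 1e-9)
  expect_lt(max(abs(rr$stress)), 1e-9)
})

test_that("single element under uniaxial stretch recovers the closed form", {
  for (lam in c(0.9, 1.1, 1.3, 1.5)) {
    u <- cbind(sq3[, 1] * (lam - 1), sq3[, 2] * (1 / sqrt(lam) - 1))
    re <- element_internal_force(sq3, u, skin)
    sig <- ogden_uniaxial_stress(lam, skin)
    expect_equal(unname(re$stress[, "s11"]), rep(sig, 4),
                 tolerance = 1e-8)
    expect_lt(max(abs(re$stress[, "s22"])), 1e-8 * max(1, abs(sig)))
    expect_lt(max(abs(re$stress[, "s12"])), 1e-8 * max(1, abs(sig)))
  }
})

test_that("tangent matches finite differences and is symmetric", {
  mesh <- patch_meshes()$patch2x2
  pre <- atflap:::fem_precompute(mesh)
  set.seed(42)
  for (k in 1:10) {
    u <- rnorm(pre$ndof, 0, 0.05)
    K <- atflap:::assemble_tangent(pre, u, skin)
    v <- rnorm(pre$ndof); v <- v / sqrt(sum(v^2))
    eps <- 1e-6
    fp <- atflap:::assemble_internal_force(pre, u + eps * v, skin)$f
    fm <- atflap:::assemble_internal_force(pre, u - eps * v, skin)$f
    fd <- (fp - fm) / (2 * eps)
    Kv <- as.numeric(K %*% v)
    expect_lt(max(abs(fd - Kv)) / max(abs(Kv)), 1e-5)
    expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-8)
  }
})

test_that("rigid modes: unconstrained mesh has exactly three", {
  K <- tangent_stiffness(patch_meshes()$single, matrix(0, 4, 2), skin)
  expect_equal(count_rigid_modes(K), 3L)
  # pinning three dofs removes them: reduced tangent is positive definite
  free <- setdiff(1:8, c(1, 2, 4))
  ev <- eigen(as.matrix(K)[free, free], symmetric = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("patch test: affine boundary displacement gives the homogeneous state", {
  mesh <- patch_meshes()$patch2x2
  A <- matrix(c(1.15, 0.05, -0.03, 0.92), 2, 2)   # affine map, det > 0
  u_aff <- t(A %*% t(mesh$nodes)) - mesh$nodes
  nd <- nrow(mesh$nodes)
  boundary <- which(apply(mesh$nodes, 1, function(p)
    any(abs(p - 0) < 1e-9 | abs(p - 6) < 1e-9)))
  presc <- data.frame(dof = c(2L * boundary - 1L, 2L * boundary),
                      value = c(u_aff[boundary, 1], u_aff[boundary, 2]))
  st <- stage_definition("patch", prescribed = presc)
  sol <- solve_stage(mesh, skin, st, solver_config(steps = 2))
  expect_equal(sol$u, u_aff, tolerance = 1e-8)
  ref <- plane_stress_response(A, skin)$sigma
  for (g in 1:4) {
    expect_equal(unname(sol$gp_stress[[g]][, "s11"]), rep(ref[1, 1], 4),
                 tolerance = 1e-8)
    expect_equal(unname(sol$gp_stress[[g]][, "s12"]), rep(ref[1, 2], 4),
                 tolerance = 1e-8)
  }
  # nodal recovery reproduces the homogeneous stress exactly
  expect_equal(unname(sol$nodal_stress[, 1]), rep(ref[1, 1], nd),
               tolerance = 1e-8)
})

test_that("von Mises closed forms", {
  expect_equal(von_mises(matrix(c(2, 0, 0, 0), 2, 2)), 2)
  expect_equal(von_mises(matrix(c(0, 1.5, 1.5, 0), 2, 2)), 1.5 * sqrt(3))
  expect_equal(von_mises(matrix(c(-2, 0, 0, -2), 2, 2)), 2)
  expect_error(von_mises(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("zero prescribed displacement yields the zero field", {
  mesh <- patch_meshes()$patch2x2
  nd <- nrow(mesh$nodes)
  st <- stage_definition("null", fixed_nodes = 1:nd)
  sol <- solve_stage(mesh, skin, st, solver_config(steps = 1))
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$max_vm, 0)
})

test_that("singular tangent is reported as missing constraints", {
  mesh <- patch_meshes()$single
  st <- stage_definition("loose", prescribed = data.frame(dof = 1L, value = 0.1))
  expect_error(solve_stage(mesh, skin, st, solver_config(steps = 1)),
               "rigid modes")
})

test_that("mini A-T: two stages solve, ties hold, stress relaxes", {
  mr <- mini_run()
  mesh <- mr$mesh; sols <- mr$sols
  expect_true(sols$suture$converged)
  expect_true(sols$release$converged)
  pr <- suture_pairs(mesh)
  # suture stage: pair members meet at their common target
  xa <- mesh$nodes[pr$node_a, , drop = FALSE] + sols$suture$u[pr$node_a, ]
  expect_lt(max(abs(xa[, 1] - pr$target_x)), 1e-6)
  expect_lt(max(abs(xa[, 2] - pr$target_y)), 1e-6)
  # release stage: tied pairs remain coincident
  ga <- mesh$nodes[pr$node_a, , drop = FALSE] + sols$release$u[pr$node_a, ]
  gb <- mesh$nodes[pr$node_b, , drop = FALSE] + sols$release$u[pr$node_b, ]
  expect_lt(max(abs(ga - gb)), 1e-6)
  # releasing the sutures lowers the peak stress
  expect_lt(sols$release$max_vm, sols$suture$max_vm)
  expect_true(all(sols$suture$nodal_vm >= 0))
})

test_that("stiffness scaling leaves the Dirichlet suture field unchanged", {
  mr <- mini_run()
  mesh <- mr$mesh
  stiff <- ogden_parameters(10 * skin$mu, skin$alpha)
  pre <- atflap:::fem_precompute(mesh)
  s1 <- solve_stage(mesh, skin, suture_stage(mesh), pre = pre)
  s2 <- solve_stage(mesh, stiff, suture_stage(mesh), pre = pre)
  expect_equal(s2$u, s1$u, tolerance = 1e-6)
  expect_equal(s2$max_vm, 10 * s1$max_vm, tolerance = 1e-5)
})

test_that("equilibrium: internal forces balance at free dofs on convergence", {
  mr <- mini_run()
  mesh <- mr$mesh
  pre <- atflap:::fem_precompute(mesh)
  f <- atflap:::assemble_internal_force(pre, mr$sols$suture$u_vec, skin)$f
  st <- suture_stage(mesh)
  con <- atflap:::stage_constraints(st, pre$ndof)
  rred <- as.numeric(Matrix::crossprod(con$Tm, f))
  # residual small relative to the reaction forces carried by the sutures
  expect_lt(sqrt(sum(rred^2)), 1e-6 * max(abs(f)))
})
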