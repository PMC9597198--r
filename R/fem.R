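# Total-Lagrangian plane-stress finite-element solver for incompressible
# Ogden hyperelasticity on bilinear quadrilaterals (2x2 Gauss quadrature).
#
# Incompressibility is enforced analytically: the thickness stretch is
# l3 = 1/det(F) and the pressure is eliminated through sigma_33 = 0 inside
# the constitutive kernel, so the discrete problem has displacement
# unknowns only.  The consistent tangent is obtained by central differences
# of the nominal stress with respect to the deformation gradient at each
# quadrature point (h = 1e-7), which preserves Newton's fast convergence to
# the 1e-8 residual tolerances used here.

GAUSS_PT <- 1 / sqrt(3)
# corner order (-1,-1), (1,-1), (1,1), (-1,1); Gauss points in the same cycle
REF_XI <- c(-1, 1, 1, -1)
REF_ETA <- c(-1, -1, 1, 1)

# Precompute reference-configuration quantities per element and Gauss point.
fem_precompute <- function(mesh) {
  el <- mesh$elems
  M <- nrow(el)
  X <- matrix(mesh$nodes[el, 1], ncol = 4L)
  Y <- matrix(mesh$nodes[el, 2], ncol = 4L)
  gps <- vector("list", 4L)
  for (g in 1:4) {
    xi <- GAUSS_PT * REF_XI[g]
    eta <- GAUSS_PT * REF_ETA[g]
    dNdxi <- 0.25 * REF_XI * (1 + eta * REF_ETA)
    dNdeta <- 0.25 * REF_ETA * (1 + xi * REF_XI)
    J11 <- X %*% dNdxi; J12 <- X %*% dNdeta
    J21 <- Y %*% dNdxi; J22 <- Y %*% dNdeta
    detJ <- as.numeric(J11 * J22 - J12 * J21)
    if (any(detJ <= 0)) {
      stop("mesh contains elements with non-positive reference Jacobian",
           call. = FALSE)
    }
    Gx <- matrix(0, M, 4L); Gy <- matrix(0, M, 4L)
    for (i in 1:4) {
      Gx[, i] <- (as.numeric(J22) * dNdxi[i] - as.numeric(J21) * dNdeta[i]) / detJ
      Gy[, i] <- (-as.numeric(J12) * dNdxi[i] + as.numeric(J11) * dNdeta[i]) / detJ
    }
    gps[[g]] <- list(Gx = Gx, Gy = Gy, wdet = detJ)  # unit Gauss weights
  }
  edof <- cbind(2L * el - 1L, 2L * el)   # (x1..x4, y1..y4)
  list(elems = el, ndof = 2L * nrow(mesh$nodes), M = M, gps = gps,
       edof = edof, nnode = nrow(mesh$nodes))
}

# Deformation gradient components at one Gauss point for all elements.
def_grad <- function(gp, Ux, Uy) {
  list(F11 = 1 + rowSums(Ux * gp$Gx), F12 = rowSums(Ux * gp$Gy),
       F21 = rowSums(Uy * gp$Gx), F22 = 1 + rowSums(Uy * gp$Gy))
}

# Assembled internal force vector; also returns Gauss-point Cauchy stresses.
# Signals condition "atflap_inversion" if any element inverts.
assemble_internal_force <- function(pre, u, params, want_stress = FALSE) {
  el <- pre$elems
  Ux <- matrix(u[2L * el - 1L], ncol = 4L)
  Uy <- matrix(u[2L * el], ncol = 4L)
  fx <- matrix(0, pre$M, 4L)
  fy <- matrix(0, pre$M, 4L)
  stress <- if (want_stress) vector("list", 4L) else NULL
  for (g in 1:4) {
    gp <- pre$gps[[g]]
    Fg <- def_grad(gp, Ux, Uy)
    k <- ogden_ps_kernel(Fg$F11, Fg$F21, Fg$F12, Fg$F22, params)
    if (is.null(k)) {
      cond <- structure(class = c("atflap_inversion", "error", "condition"),
                        list(message = "element inversion during iteration",
                             call = NULL))
      stop(cond)
    }
    for (i in 1:4) {
      fx[, i] <- fx[, i] + (k$P11 * gp$Gx[, i] + k$P12 * gp$Gy[, i]) * gp$wdet
      fy[, i] <- fy[, i] + (k$P21 * gp$Gx[, i] + k$P22 * gp$Gy[, i]) * gp$wdet
    }
    if (want_stress) {
      stress[[g]] <- cbind(s11 = k$sig11, s22 = k$sig22, s12 = k$sig12)
    }
  }
  f <- numeric(pre$ndof)
  idx <- as.vector(el)
  acc_x <- rowsum(as.vector(fx), idx)
  acc_y <- rowsum(as.vector(fy), idx)
  present <- as.integer(rownames(acc_x))
  f[2L * present - 1L] <- acc_x[, 1L]
  f[2L * present] <- acc_y[, 1L]
  list(f = f, stress = stress)
}

# Assembled tangent stiffness (sparse), consistent with
# assemble_internal_force by central differencing of P w.r.t. F.
assemble_tangent <- function(pre, u, params, h = 1e-7) {
  el <- pre$elems
  Ux <- matrix(u[2L * el - 1L], ncol = 4L)
  Uy <- matrix(u[2L * el], ncol = 4L)
  M <- pre$M
  Ke <- matrix(0, M, 64L)   # column-major 8x8 blocks per element
  for (g in 1:4) {
    gp <- pre$gps[[g]]
    Fg <- def_grad(gp, Ux, Uy)
    Fc <- list(Fg$F11, Fg$F21, Fg$F12, Fg$F22)  # vec order (11, 21, 12, 22)
    A <- vector("list", 4L)
    for (b in 1:4) {
      Fp <- Fc; Fp[[b]] <- Fp[[b]] + h
      Fm <- Fc; Fm[[b]] <- Fm[[b]] - h
      kp <- ogden_ps_kernel(Fp[[1]], Fp[[2]], Fp[[3]], Fp[[4]], params)
      km <- ogden_ps_kernel(Fm[[1]], Fm[[2]], Fm[[3]], Fm[[4]], params)
      if (is.null(kp) || is.null(km)) {
        cond <- structure(class = c("atflap_inversion", "error", "condition"),
                          list(message = "element inversion during tangent",
                               call = NULL))
        stop(cond)
      }
      A[[b]] <- list(P11 = (kp$P11 - km$P11) / (2 * h),
                     P21 = (kp$P21 - km$P21) / (2 * h),
                     P12 = (kp$P12 - km$P12) / (2 * h),
                     P22 = (kp$P22 - km$P22) / (2 * h))
    }
    w <- gp$wdet
    for (i in 1:4) {
      gxi <- gp$Gx[, i]; gyi <- gp$Gy[, i]
      for (j in 1:4) {
        gxj <- gp$Gx[, j]; gyj <- gp$Gy[, j]
        # d f_(x i) / d u_(x j):  dF11 = gxj, dF12 = gyj
        kxx <- gxi * (A[[1]]$P11 * gxj + A[[3]]$P11 * gyj) +
          gyi * (A[[1]]$P12 * gxj + A[[3]]$P12 * gyj)
        # d f_(x i) / d u_(y j):  dF21 = gxj, dF22 = gyj
        kxy <- gxi * (A[[2]]$P11 * gxj + A[[4]]$P11 * gyj) +
          gyi * (A[[2]]$P12 * gxj + A[[4]]$P12 * gyj)
        kyx <- gxi * (A[[1]]$P21 * gxj + A[[3]]$P21 * gyj) +
          gyi * (A[[1]]$P22 * gxj + A[[3]]$P22 * gyj)
        kyy <- gxi * (A[[2]]$P21 * gxj + A[[4]]$P21 * gyj) +
          gyi * (A[[2]]$P22 * gxj + A[[4]]$P22 * gyj)
        Ke[, (j - 1L) * 8L + i] <- Ke[, (j - 1L) * 8L + i] + w * kxx
        Ke[, (j + 3L) * 8L + i] <- Ke[, (j + 3L) * 8L + i] + w * kxy
        Ke[, (j - 1L) * 8L + i + 4L] <- Ke[, (j - 1L) * 8L + i + 4L] + w * kyx
        Ke[, (j + 3L) * 8L + i + 4L] <- Ke[, (j + 3L) * 8L + i + 4L] + w * kyy
      }
    }
  }
  p_idx <- rep(1:8, times = 8)
  q_idx <- rep(1:8, each = 8)
  ii <- pre$edof[, p_idx, drop = FALSE]
  jj <- pre$edof[, q_idx, drop = FALSE]
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(Ke),
                       dims = c(pre$ndof, pre$ndof))
}

#' Internal force and stress of a single quadrilateral element
#'
#' Total-Lagrangian internal nodal forces of one 4-node element under the
#' plane-stress incompressible Ogden model (2x2 Gauss quadrature).  Exactly
#' zero for rigid-body motion.
#'
#' @param coords 4x2 matrix of reference node coordinates (mm),
#'   counterclockwise.
#' @param u_element 4x2 matrix of nodal displacements (mm).
#' @param material An [ogden_parameters()] object.
#' @return List with `f` (4x2 nodal forces, N per unit thickness) and
#'   `stress` (per-Gauss-point Cauchy components `s11`, `s22`, `s12`, MPa).
#' @export
element_internal_force <- function(coords, u_element, material) {
  mesh <- list(nodes = coords, elems = matrix(1:4, 1L))
  pre <- fem_precompute(mesh)
  u <- as.vector(t(u_element))
  res <- assemble_internal_force(pre, u, material, want_stress = TRUE)
  list(f = matrix(res$f, ncol = 2L, byrow = TRUE),
       stress = do.call(rbind, res$stress))
}

#' Assembled tangent stiffness matrix
#'
#' Sparse consistent tangent of the internal force at a displacement state,
#' symmetric up to round-off.  An unconstrained mesh has a rank deficiency
#' of exactly 3 (two translations and one in-plane rotation); see
#' [count_rigid_modes()].
#'
#' @param mesh A `skin_mesh` (or any list with `nodes` and `elems`).
#' @param u Displacement vector of length `2 * n_nodes`, interleaved
#'   `(u_x1, u_y1, u_x2, ...)`, or an `n_nodes x 2` matrix.
#' @param material An [ogden_parameters()] object.
#' @return A sparse `dgCMatrix` of size `2 n x 2 n`.
#' @export
tangent_stiffness <- function(mesh, u, material) {
  pre <- fem_precompute(mesh)
  if (is.matrix(u)) u <- as.vector(t(u))
  assemble_tangent(pre, u, material)
}

#' Count rigid-body modes of a stiffness matrix
#'
#' Number of near-zero eigenvalues relative to the largest one.  Intended
#' for small diagnostic meshes (dense eigendecomposition).
#'
#' @param K Stiffness matrix (dense or sparse).
#' @param tol Relative eigenvalue threshold (default 1e-8).
#' @return Integer count of (near-)rigid modes.
#' @export
count_rigid_modes <- function(K, tol = 1e-8) {
  ev <- eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev) < tol * max(abs(ev)))
}

#' Plane-stress von Mises equivalent stress
#'
#' `sqrt(s11^2 - s11 s22 + s22^2 + 3 s12^2)` with zero thickness stress.
#'
#' @param sigma Symmetric 2x2 Cauchy stress matrix (MPa).
#' @return Equivalent stress in MPa (non-negative).
#' @export
von_mises <- function(sigma) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(2, 2)))
  if (abs(sigma[1, 2] - sigma[2, 1]) > 1e-9 * max(1, max(abs(sigma)))) {
    stop("von_mises requires a symmetric stress tensor", call. = FALSE)
  }
  von_mises_components(sigma[1, 1], sigma[2, 2], sigma[1, 2])
}

von_mises_components <- function(s11, s22, s12) {
  sqrt(pmax(s11^2 - s11 * s22 + s22^2 + 3 * s12^2, 0))
}

#' Solver configuration
#'
#' @param steps Number of load-ramp increments (default 20).
#' @param rtol Newton tolerance on the residual norm relative to the
#'   initial unbalanced force of each increment (default 1e-8).
#' @param max_iter Maximum Newton iterations per increment (default 30).
#' @param line_search Backtracking line search toggle (default TRUE).
#' @param max_bisections Maximum step bisections on divergence (default 4).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(steps = 20, rtol = 1e-8, max_iter = 30,
                          line_search = TRUE, max_bisections = 4) {
  stopifnot(steps >= 1, rtol > 0, max_iter >= 1)
  structure(list(steps = steps, rtol = rtol, max_iter = max_iter,
                 line_search = line_search, max_bisections = max_bisections),
            class = "solver_config")
}

#' Analysis stage definition
#'
#' A stage is defined by its Dirichlet data: prescribed dof values (ramped
#' from the stage's initial state to the target), tie constraints binding a
#' slave dof to a master dof (equal displacement increments, constant
#' offset), and fixed nodes.  The suture stage uses prescribed
#' displacements and no ties; the release stage uses one tie per suture
#' pair and no prescribed displacements beyond the fixed nodes.
#'
#' @param tag Stage label, `"suture"` or `"release"` (free-form allowed).
#' @param prescribed Data frame with columns `dof` (global dof index,
#'   `2*node-1` for x, `2*node` for y) and `value` (total displacement at
#'   full load, mm); may be empty.
#' @param ties Data frame with columns `slave` and `master` (dof indices);
#'   may be empty.
#' @param fixed_nodes Integer node indices pinned in both dofs.
#' @return A list of class `stage_definition`.
#' @export
stage_definition <- function(tag, prescribed = NULL, ties = NULL,
                             fixed_nodes = integer(0)) {
  if (is.null(prescribed)) {
    prescribed <- data.frame(dof = integer(0), value = numeric(0))
  }
  if (is.null(ties)) ties <- data.frame(slave = integer(0), master = integer(0))
  if (nrow(prescribed) > 0 && nrow(ties) > 0) {
    overlap <- intersect(prescribed$dof, c(ties$slave, ties$master))
    if (length(overlap)) {
      stop("dofs cannot be both prescribed and tied", call. = FALSE)
    }
  }
  structure(list(tag = tag, prescribed = prescribed, ties = ties,
                 fixed_nodes = as.integer(fixed_nodes)),
            class = "stage_definition")
}

#' Suture-stage definition for an A-T mesh
#'
#' Prescribes both displacement components of every suture-pair node so the
#' pair members meet at the pair's target point on the T midline; the four
#' domain corner nodes are fixed.
#'
#' @param mesh A `skin_mesh` with suture pairs.
#' @return A [stage_definition()].
#' @export
suture_stage <- function(mesh) {
  pr <- suture_pairs(mesh)
  rows <- list()
  for (side in c("node_a", "node_b")) {
    n <- pr[[side]]
    rows[[side]] <- data.frame(
      dof = c(2L * n - 1L, 2L * n),
      value = c(pr$target_x - mesh$nodes[n, 1],
                pr$target_y - mesh$nodes[n, 2]))
  }
  stage_definition("suture", prescribed = do.call(rbind, rows),
                   fixed_nodes = mesh$fixed_nodes)
}

#' Release-stage definition for an A-T mesh
#'
#' Replaces the suture-stage prescribed displacements by tie constraints:
#' each pair's left node is slaved to its right node in both dofs, keeping
#' the sutured margins coincident while tissue elasticity redistributes
#' stress.  Corner nodes stay fixed.
#'
#' @param mesh A `skin_mesh` with suture pairs.
#' @return A [stage_definition()].
#' @export
release_stage <- function(mesh) {
  pr <- suture_pairs(mesh)
  ties <- data.frame(
    slave = c(2L * pr$node_a - 1L, 2L * pr$node_a),
    master = c(2L * pr$node_b - 1L, 2L * pr$node_b))
  stage_definition("release", ties = ties, fixed_nodes = mesh$fixed_nodes)
}

# Build the constraint transformation for a stage.
# Returns list(free, presc_dof, presc_val, slave, master, Tm) with
# u = expand(u_free) + boundary data; Tm is ndof x nfree.
stage_constraints <- function(stage, ndof) {
  fixed_dofs <- c(2L * stage$fixed_nodes - 1L, 2L * stage$fixed_nodes)
  presc_dof <- c(stage$prescribed$dof, fixed_dofs)
  presc_val <- c(stage$prescribed$value, rep(0, length(fixed_dofs)))
  if (anyDuplicated(presc_dof)) {
    dup <- !duplicated(presc_dof)
    presc_dof <- presc_dof[dup]; presc_val <- presc_val[dup]
  }
  slave <- stage$ties$slave
  master <- stage$ties$master
  free <- setdiff(seq_len(ndof), c(presc_dof, slave))
  if (length(master) && any(!master %in% free)) {
    stop("tie master dofs must be unconstrained", call. = FALSE)
  }
  col_of <- integer(ndof)
  col_of[free] <- seq_along(free)
  ii <- c(free, slave)
  jj <- c(col_of[free], col_of[master])
  Tm <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                             dims = c(ndof, length(free)))
  list(free = free, presc_dof = presc_dof, presc_val = presc_val,
       slave = slave, master = master, Tm = Tm)
}

#' Solve one analysis stage
#'
#' Incremental-iterative solution: the Dirichlet data (and any external
#' force) is ramped linearly over the load steps, with a full Newton loop
#' per step, backtracking line search, and step bisection on divergence or
#' element inversion.
#'
#' @param mesh A `skin_mesh`.
#' @param material An [ogden_parameters()] object.
#' @param stage A [stage_definition()].
#' @param config A [solver_config()].
#' @param u0 Initial displacement vector (length `2 n`), default zero.
#' @param f_ext_fun Optional function of the load factor `t` in `[0, 1]`
#'   returning an external force vector (used by the release continuation).
#' @param pre Optional precomputed structure (internal reuse).
#' @return A `field_solution`: nodal displacements `u` (n x 2, mm),
#'   Gauss-point and nodal-averaged Cauchy stress (MPa), nodal von Mises,
#'   field maxima with node locations, convergence flag and residual
#'   history.
#' @export
solve_stage <- function(mesh, material, stage, config = solver_config(),
                        u0 = NULL, f_ext_fun = NULL, pre = NULL) {
  stopifnot(inherits(stage, "stage_definition"))
  if (is.null(pre)) pre <- fem_precompute(mesh)
  ndof <- pre$ndof
  con <- stage_constraints(stage, ndof)
  u <- if (is.null(u0)) numeric(ndof) else as.numeric(u0)
  stopifnot(length(u) == ndof)
  # tie offsets captured from the initial state (constant along the stage)
  tie_off <- if (length(con$slave)) u[con$slave] - u[con$master] else numeric(0)
  presc_from <- u[con$presc_dof]
  apply_bc <- function(uu, t) {
    uu[con$presc_dof] <- presc_from + t * (con$presc_val - presc_from)
    if (length(con$slave)) uu[con$slave] <- uu[con$master] + tie_off
    uu
  }
  residual <- function(uu, t) {
    r <- assemble_internal_force(pre, uu, material)$f
    if (!is.null(f_ext_fun)) r <- r - f_ext_fun(t)
    r
  }
  history <- list()
  t_cur <- 0
  dt0 <- 1 / config$steps
  dt <- dt0
  n_bisect <- 0L
  while (t_cur < 1 - 1e-12) {
    t_new <- min(t_cur + dt, 1)
    res_step <- tryCatch(
      newton_step(u, t_new, apply_bc, residual, pre, material, con, config),
      atflap_inversion = function(e) NULL)
    if (is.null(res_step)) {
      n_bisect <- n_bisect + 1L
      if (n_bisect > config$max_bisections) {
        stop(sprintf(
          "stage '%s' failed to converge at load factor %.4f after %d bisections",
          stage$tag, t_new, config$max_bisections), call. = FALSE)
      }
      dt <- dt / 2
      next
    }
    u <- res_step$u
    history[[length(history) + 1L]] <-
      list(t = t_new, iters = res_step$iters, res_norms = res_step$res_norms)
    t_cur <- t_new
    if (res_step$iters <= 5L && dt < dt0) dt <- min(2 * dt, dt0)
  }
  build_field_solution(mesh, pre, u, material, stage$tag, history, con,
                       f_ext_fun)
}

newton_step <- function(u, t, apply_bc, residual, pre, material, con, config) {
  u <- apply_bc(u, t)
  Tm <- con$Tm
  r <- residual(u, t)
  rred <- as.numeric(Matrix::crossprod(Tm, r))
  r0 <- sqrt(sum(rred^2))
  tol <- max(config$rtol * r0, 1e-12)
  res_norms <- r0
  iters <- 0L
  rn <- r0
  while (rn > tol) {
    if (iters >= config$max_iter) {
      cond <- structure(class = c("atflap_inversion", "error", "condition"),
                        list(message = "Newton iteration limit", call = NULL))
      stop(cond)
    }
    K <- assemble_tangent(pre, u, material)
    Kred <- Matrix::crossprod(Tm, K %*% Tm)
    du <- tryCatch(as.numeric(Matrix::solve(Kred, rred)),
                   error = function(e) {
                     stop(paste0("singular tangent: the constraint set leaves ",
                                 "free rigid modes (translations/rotation)"),
                          call. = FALSE)
                   })
    alpha <- 1
    repeat {
      u_try <- u
      u_try[con$free] <- u[con$free] - alpha * du[seq_along(con$free)]
      if (length(con$slave)) {
        u_try[con$slave] <- u_try[con$master] +
          (u[con$slave] - u[con$master])
      }
      ok <- tryCatch({
        r_try <- residual(u_try, t)
        TRUE
      }, atflap_inversion = function(e) FALSE)
      if (ok) {
        rred_try <- as.numeric(Matrix::crossprod(Tm, r_try))
        rn_try <- sqrt(sum(rred_try^2))
        if (!config$line_search || rn_try < rn || alpha <= 0.125) break
      } else if (alpha <= 0.125) {
        cond <- structure(class = c("atflap_inversion", "error", "condition"),
                          list(message = "inversion in line search",
                               call = NULL))
        stop(cond)
      }
      alpha <- alpha / 2
    }
    u <- u_try
    rred <- rred_try
    rn <- rn_try
    iters <- iters + 1L
    res_norms <- c(res_norms, rn)
  }
  list(u = u, iters = iters, res_norms = res_norms)
}

# Gauss-to-node extrapolation matrix (bilinear fit through the 4 GP values,
# evaluated at the element corners).
gp_extrapolation_matrix <- function() {
  g <- GAUSS_PT
  Mg <- cbind(1, g * REF_XI, g * REF_ETA, g^2 * REF_XI * REF_ETA)
  Mc <- cbind(1, REF_XI, REF_ETA, REF_XI * REF_ETA)
  Mc %*% solve(Mg)
}

build_field_solution <- function(mesh, pre, u, material, tag, history, con,
                                 f_ext_fun) {
  res <- assemble_internal_force(pre, u, material, want_stress = TRUE)
  E <- gp_extrapolation_matrix()
  M <- pre$M
  # per-element corner values for each stress component
  gp_mat <- function(comp) {
    vapply(1:4, function(g) res$stress[[g]][, comp], numeric(M))  # M x 4 (gp)
  }
  idx <- as.vector(pre$elems)
  nodal <- matrix(0, pre$nnode, 3L)
  counts <- rowsum(rep(1, length(idx)), idx)
  present <- as.integer(rownames(counts))
  for (c_i in 1:3) {
    corner_vals <- gp_mat(c_i) %*% t(E)     # M x 4 (corners)
    acc <- rowsum(as.vector(corner_vals), idx)
    nodal[present, c_i] <- acc[, 1L] / counts[, 1L]
  }
  nodal_vm <- von_mises_components(nodal[, 1L], nodal[, 2L], nodal[, 3L])
  disp <- matrix(u, ncol = 2L, byrow = TRUE)
  dmag <- sqrt(rowSums(disp^2))
  reactions <- res$f
  if (!is.null(f_ext_fun)) reactions <- reactions - f_ext_fun(1)
  structure(list(
    stage = tag,
    u = disp,
    u_vec = u,
    gp_stress = res$stress,
    nodal_stress = nodal,
    nodal_vm = nodal_vm,
    max_vm = max(nodal_vm),
    max_vm_node = which.max(nodal_vm),
    max_disp = max(dmag),
    max_disp_node = which.max(dmag),
    converged = TRUE,
    residual_history = history,
    constrained_dofs = con$presc_dof,
    reactions = reactions
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution [%s]: %s\n", x$stage,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  max von Mises   : %.4f MPa at node %d\n",
              x$max_vm, x$max_vm_node))
  cat(sprintf("  max displacement: %.4f mm at node %d\n",
              x$max_disp, x$max_disp_node))
  cat(sprintf("  load steps: %d\n", length(x$residual_history)))
  invisible(x)
}

#' Run the two-stage suture / release simulation
#'
#' Solves the suture stage from the reference state (prescribed
#' displacements close the wound onto the T midline), then the release
#' stage continued from the converged suture state: the prescribed
#' displacements are removed, each suture pair is bound by a tie
#' constraint, and the suture-stage reaction forces are ramped down to zero
#' so tissue elasticity redistributes stress.
#'
#' @param mesh A `skin_mesh` with suture pairs.
#' @param material An [ogden_parameters()] object.
#' @param config A [solver_config()].
#' @return List with elements `suture` and `release`, both `field_solution`.
#' @export
run_suture_then_release <- function(mesh, material,
                                    config = solver_config()) {
  pre <- fem_precompute(mesh)
  st1 <- suture_stage(mesh)
  sol1 <- solve_stage(mesh, material, st1, config, pre = pre)
  # reaction forces held by the sutures at the end of the suture stage
  R0 <- numeric(pre$ndof)
  cdofs <- st1$prescribed$dof
  R0[cdofs] <- sol1$reactions[cdofs]
  st2 <- release_stage(mesh)
  sol2 <- solve_stage(mesh, material, st2, config, u0 = sol1$u_vec,
                      f_ext_fun = function(t) (1 - t) * R0, pre = pre)
  list(suture = sol1, release = sol2)
}
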