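# Block-structured quadrilateral meshing of the operative skin region.
#
# The rectangular skin domain (origin at the T-junction, y up) is decomposed
# into mapped-mesh blocks conforming to the A-shaped incision:
#   - LB / RB : the two advancing flap sheets between base line and apex
#               level, bounded medially by the triangle waists (Coons
#               patches with prescribed edge stations),
#   - US      : structured strip above the apex level,
#   - LS      : structured strip below the base line.
# The excised defect triangle is absent from the mesh; its waists are the
# suture margins.  Nodes along the lateral base-extension cuts are
# duplicated (flap side vs. lower skin side, coincident in the reference
# state) so the flap can slide over the stationary lower skin.

GEOM_TOL <- 1e-6

#' Build the simulation domain for a flap design
#'
#' Describes the rectangular skin region with the embedded A-shaped incision:
#' cut polylines (two waists, two lateral base extensions) and the excised
#' defect triangle.  The coordinate origin is the T-junction (base center),
#' y up; the domain spans `[-width/2, width/2] x [-height/2, height/2]`.
#'
#' @param design A [design_flap()] object, or `NULL` for a plain rectangle
#'   with no cuts (useful for patch tests).
#' @param width,height Domain size in mm (defaults 90 x 100, roughly three
#'   times the flap size, beyond which stresses are negligible).
#' @return An object of class `flap_domain`.
#' @export
build_domain <- function(design, width = 90, height = 100) {
  stopifnot(width > 0, height > 0)
  if (!is.null(design)) {
    stopifnot(inherits(design, "flap_design"))
    if (design$r <= 0) stop("degenerate design: r must be > 0", call. = FALSE)
    b <- design$d / 2
    e <- abs(design$layout$EL[1])
    if (design$h >= height / 2 || e >= width / 2) {
      stop("flap exceeds the domain: increase width/height or shrink the flap",
           call. = FALSE)
    }
    waist_len <- sqrt(b^2 + design$h^2)
    cuts <- list(
      waist_left = rbind(c(0, design$h), c(-b, 0)),
      waist_right = rbind(c(0, design$h), c(b, 0)),
      base_left = rbind(c(-e, 0), c(-b, 0)),
      base_right = rbind(c(b, 0), c(e, 0))
    )
    cut_length <- 2 * waist_len + 2 * max(e - b, 0)
  } else {
    cuts <- list()
    cut_length <- 0
  }
  structure(list(design = design, width = width, height = height,
                 cuts = cuts, cut_length = cut_length),
            class = "flap_domain")
}

#' @export
print.flap_domain <- function(x, ...) {
  cat(sprintf("Skin domain %g x %g mm, %d cut polyline(s), total cut length %.2f mm\n",
              x$width, x$height, length(x$cuts), x$cut_length))
  invisible(x)
}

# Structured grid on a rectangle; returns an un-merged sub-mesh.
grid_submesh <- function(xsta, ysta) {
  nx <- length(xsta) - 1L
  ny <- length(ysta) - 1L
  nodes <- cbind(rep(xsta, times = ny + 1L), rep(ysta, each = nx + 1L))
  elems <- matrix(0L, nx * ny, 4L)
  k <- 1L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      n1 <- (j - 1L) * (nx + 1L) + i
      elems[k, ] <- c(n1, n1 + 1L, n1 + nx + 2L, n1 + nx + 1L)
      k <- k + 1L
    }
  }
  list(nodes = nodes, elems = elems)
}

# Coons (transfinite) patch from four edge point lists.
# bottom/top have m+1 points (left to right), left/right n+1 (bottom to top);
# corners must agree: bottom[1] == left[1], bottom[m+1] == right[1],
# top[1] == left[n+1], top[m+1] == right[n+1].
coons_submesh <- function(bottom, top, left, right) {
  m <- nrow(bottom) - 1L
  n <- nrow(left) - 1L
  stopifnot(nrow(top) == m + 1L, nrow(right) == n + 1L)
  u <- seq(0, 1, length.out = m + 1L)
  v <- seq(0, 1, length.out = n + 1L)
  P1 <- bottom[1L, ]; P2 <- bottom[m + 1L, ]
  P4 <- top[1L, ];    P3 <- top[m + 1L, ]
  nodes <- matrix(0, (m + 1L) * (n + 1L), 2L)
  k <- 1L
  for (j in seq_len(n + 1L)) {
    for (i in seq_len(m + 1L)) {
      ui <- u[i]; vj <- v[j]
      pt <- (1 - vj) * bottom[i, ] + vj * top[i, ] +
        (1 - ui) * left[j, ] + ui * right[j, ] -
        ((1 - ui) * (1 - vj) * P1 + ui * (1 - vj) * P2 +
           ui * vj * P3 + (1 - ui) * vj * P4)
      nodes[k, ] <- pt
      k <- k + 1L
    }
  }
  elems <- grid_submesh(seq_len(m + 1L), seq_len(n + 1L))$elems
  list(nodes = nodes, elems = elems, m = m, n = n)
}

# Mirror a sub-mesh about x = 0, restoring counterclockwise orientation.
mirror_submesh <- function(sm) {
  nodes <- sm$nodes
  nodes[, 1] <- -nodes[, 1]
  elems <- sm$elems[, c(1L, 4L, 3L, 2L), drop = FALSE]
  out <- sm
  out$nodes <- nodes
  out$elems <- elems
  out
}

#' Structured rectangular quad mesh
#'
#' Plain tensor-product grid, mainly for patch tests and fixtures.
#'
#' @param xlim,ylim Length-2 ranges in mm.
#' @param nx,ny Element counts per direction.
#' @return A `skin_mesh` with no cuts and no suture pairs.
#' @export
rect_grid_mesh <- function(xlim, ylim, nx, ny) {
  sm <- grid_submesh(seq(xlim[1], xlim[2], length.out = nx + 1L),
                     seq(ylim[1], ylim[2], length.out = ny + 1L))
  new_skin_mesh(nodes = sm$nodes, elems = sm$elems,
                region = rep("skin", nrow(sm$elems)),
                pairs = empty_pairs(), base_cut_pairs = NULL,
                fixed_nodes = integer(0), element_size = NA_real_,
                domain = NULL)
}

empty_pairs <- function() {
  data.frame(node_a = integer(0), node_b = integer(0),
             target_x = numeric(0), target_y = numeric(0),
             arc_from_apex = numeric(0))
}

new_skin_mesh <- function(nodes, elems, region, pairs, base_cut_pairs,
                          fixed_nodes, element_size, domain) {
  structure(list(nodes = nodes, elems = elems, region = region,
                 pairs = pairs, base_cut_pairs = base_cut_pairs,
                 fixed_nodes = fixed_nodes, element_size = element_size,
                 domain = domain),
            class = "skin_mesh")
}

#' @export
print.skin_mesh <- function(x, ...) {
  cat(sprintf("skin_mesh: %d nodes, %d quad elements", nrow(x$nodes),
              nrow(x$elems)))
  if (!is.na(x$element_size)) cat(sprintf(", element size %g mm", x$element_size))
  cat("\n")
  if (nrow(x$pairs)) {
    cat(sprintf("  %d suture pairs, %d fixed nodes, %d duplicated base-cut pairs\n",
                nrow(x$pairs), length(x$fixed_nodes),
                if (is.null(x$base_cut_pairs)) 0L else nrow(x$base_cut_pairs)))
  }
  invisible(x)
}

#' Generate the quadrilateral mesh for a domain
#'
#' Block-structured paving conforming to the incision cuts; deterministic
#' for fixed inputs.  For an A-T domain the mesh carries the suture node
#' pairs (left-waist node paired with its mirror right-waist node, common
#' target on the closed T midline), the duplicated coincident node pairs
#' along the lateral base cuts, and the four fixed domain corner nodes.
#'
#' @param domain A [build_domain()] object.
#' @param element_size Nominal element side length in mm, in `[0.5, 10]`.
#' @param target_strategy Mapping of the waist margins onto the closed T
#'   midline.  `"isometric"` (default): each waist is rigidly rotated about
#'   the apex onto the midline, so the sutured seam keeps the waist's arc
#'   length (sutures impose no tangential strain on the margins) and the
#'   base corners meet at `(0, h - L_w)` with `L_w` the waist length.
#'   `"proportional"`: arc-length-proportional mapping onto the segment
#'   from apex to origin, so the corners meet exactly at the T-junction at
#'   the price of a tangential seam compression `h / L_w`.
#' @return A `skin_mesh`: list with `nodes` (n x 2, mm), `elems` (m x 4
#'   counterclockwise node indices), `region` (per-element `"flap"` /
#'   `"skin"` tag), `pairs` (suture pairs with target positions),
#'   `base_cut_pairs`, `fixed_nodes`, `element_size`, `domain`.
#' @export
generate_mesh <- function(domain, element_size,
                          target_strategy = c("isometric", "proportional")) {
  stopifnot(inherits(domain, "flap_domain"))
  target_strategy <- match.arg(target_strategy)
  if (!is.numeric(element_size) || length(element_size) != 1L ||
      element_size < 0.5 || element_size > 10) {
    stop("element_size must be a single value in [0.5, 10] mm", call. = FALSE)
  }
  W2 <- domain$width / 2
  H2 <- domain$height / 2
  if (is.null(domain$design)) {
    nx <- max(1L, round(domain$width / element_size))
    ny <- max(1L, round(domain$height / element_size))
    out <- rect_grid_mesh(c(-W2, W2), c(-H2, H2), nx, ny)
    out$element_size <- element_size
    out$domain <- domain
    return(out)
  }
  design <- domain$design
  h <- design$h
  b <- design$d / 2
  e <- max(abs(design$layout$EL[1]), b)
  if (H2 - h < element_size || W2 - e < element_size) {
    stop("flap margin to domain boundary is smaller than one element size",
         call. = FALSE)
  }
  waist_len <- sqrt(b^2 + h^2)
  has_base_cut <- (e - b) > GEOM_TOL

  # -- division counts -------------------------------------------------
  m1 <- max(2L, round(W2 / element_size))
  if (has_base_cut) {
    m1b <- min(max(1L, round(m1 * (e - b) / (W2 - b))), m1 - 1L)
    m1a <- m1 - m1b
    xsta_bottom <- c(seq(-W2, -e, length.out = m1a + 1L),
                     seq(-e, -b, length.out = m1b + 1L)[-1L])
  } else {
    xsta_bottom <- seq(-W2, -b, length.out = m1 + 1L)
  }
  xsta_top_half <- seq(-W2, 0, length.out = m1 + 1L)
  n_w <- max(2L, round(((h + waist_len) / 2) / element_size))
  n_u <- max(1L, round((H2 - h) / element_size))
  n_l <- max(1L, round(H2 / element_size))
  m_w <- max(2L, round(2 * b / element_size))
  xsta_wound <- seq(-b, b, length.out = m_w + 1L)

  # -- sub-meshes ------------------------------------------------------
  t_w <- seq(0, 1, length.out = n_w + 1L)
  LB <- coons_submesh(
    bottom = cbind(xsta_bottom, 0),
    top = cbind(xsta_top_half, h),
    left = cbind(-W2, seq(0, h, length.out = n_w + 1L)),
    right = cbind(-b + t_w * b, t_w * h)
  )
  RB <- mirror_submesh(LB)
  xsta_us <- c(xsta_top_half, rev(-xsta_top_half)[-1L])
  US <- grid_submesh(xsta_us, seq(h, H2, length.out = n_u + 1L))
  xsta_ls <- c(xsta_bottom, xsta_wound[-1L], rev(-xsta_bottom)[-1L])
  LS <- grid_submesh(xsta_ls, seq(-H2, 0, length.out = n_l + 1L))

  subs <- list(LS = LS, LB = LB, RB = RB, US = US)
  sheets <- c(LS = "lower", LB = "upper", RB = "upper", US = "upper")
  regions <- c(LS = "skin", LB = "flap", RB = "flap", US = "skin")

  offs <- integer(length(subs))
  nodes <- NULL
  elems <- NULL
  region <- character(0)
  sheet <- character(0)
  for (k in seq_along(subs)) {
    offs[k] <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <- rbind(nodes, subs[[k]]$nodes)
    elems <- rbind(elems, subs[[k]]$elems + offs[k])
    region <- c(region, rep(regions[k], nrow(subs[[k]]$elems)))
    sheet <- c(sheet, rep(sheets[k], nrow(subs[[k]]$nodes)))
  }
  names(offs) <- names(subs)

  # -- merge coincident nodes, except across the base cuts -------------
  key_xy <- paste(round(nodes[, 1] / GEOM_TOL), round(nodes[, 2] / GEOM_TOL))
  on_cut <- abs(nodes[, 2]) < GEOM_TOL &
    abs(nodes[, 1]) > b - GEOM_TOL & abs(nodes[, 1]) < e - GEOM_TOL
  key <- ifelse(on_cut & has_base_cut, paste(key_xy, sheet), key_xy)
  newid <- match(key, unique(key))
  keep <- !duplicated(key)
  nodes_m <- nodes[keep, , drop = FALSE]
  elems_m <- matrix(newid[elems], ncol = 4L)

  # -- suture pairs: left waist <-> right waist ------------------------
  # LB grid: (m1+1) x (n_w+1) nodes; right edge i = m1+1 (1-based), row j.
  lb_edge <- offs["LB"] + (seq_len(n_w + 1L) - 1L) * (m1 + 1L) + (m1 + 1L)
  rb_edge <- offs["RB"] + (seq_len(n_w + 1L) - 1L) * (m1 + 1L) + (m1 + 1L)
  lw <- newid[lb_edge]   # j = 1 at base corner B ... j = n_w + 1 at apex
  rw <- newid[rb_edge]
  jj <- seq_len(n_w)     # exclude the shared apex node
  tj <- t_w[jj]
  arc <- (1 - tj) * waist_len
  target_y <- if (target_strategy == "isometric") h - arc else tj * h
  pairs <- data.frame(node_a = lw[jj], node_b = rw[jj],
                      target_x = 0, target_y = target_y,
                      arc_from_apex = arc)

  # -- duplicated coincident pairs along the base cuts -----------------
  base_cut_pairs <- NULL
  if (has_base_cut) {
    nb <- length(xsta_bottom)
    cut_cols <- which(xsta_bottom > -e + GEOM_TOL)  # strictly inside the cut
    lb_bot <- newid[offs["LB"] + cut_cols]                    # flap side
    ls_top <- newid[offs["LS"] + n_l * length(xsta_ls) + cut_cols]  # lower side
    left_pairs <- cbind(flap = lb_bot, lower = ls_top)
    # mirrored right side
    rb_bot <- newid[offs["RB"] + cut_cols]
    ls_top_r <- newid[offs["LS"] + n_l * length(xsta_ls) +
                        (length(xsta_ls) + 1L - cut_cols)]
    base_cut_pairs <- as.data.frame(rbind(left_pairs,
                                          cbind(flap = rb_bot, lower = ls_top_r)))
  }

  # -- fixed nodes: the four domain corners ----------------------------
  corner_of <- function(cx, cy) {
    which(abs(nodes_m[, 1] - cx) < GEOM_TOL & abs(nodes_m[, 2] - cy) < GEOM_TOL)
  }
  fixed <- c(corner_of(-W2, -H2), corner_of(W2, -H2),
             corner_of(-W2, H2), corner_of(W2, H2))
  stopifnot(length(fixed) == 4L)

  out <- new_skin_mesh(nodes = nodes_m, elems = elems_m, region = region,
                       pairs = pairs, base_cut_pairs = base_cut_pairs,
                       fixed_nodes = fixed, element_size = element_size,
                       domain = domain)
  out$target_strategy <- target_strategy
  out
}

#' Suture node pairs of an A-T mesh
#'
#' Returns the ordered suture pairs computed at meshing time: each row binds
#' a left-waist node to its mirror right-waist node, with the pair's common
#' target position on the closed T midline (by default the isometric
#' rotation of each waist about the apex, which stays put while the base
#' corners meet at the T joint; see `target_strategy` in
#' [generate_mesh()]).  The pairing is mirror-symmetric across the
#' centerline.
#'
#' @param mesh A `skin_mesh` built from an A-T domain.
#' @return Data frame with columns `node_a`, `node_b`, `target_x`,
#'   `target_y`, `arc_from_apex`.
#' @export
suture_pairs <- function(mesh) {
  stopifnot(inherits(mesh, "skin_mesh"))
  if (nrow(mesh$pairs) == 0L) {
    stop("mesh has no suture pairs (was it built from an A-T domain?)",
         call. = FALSE)
  }
  da <- sqrt(rowSums((mesh$nodes[mesh$pairs$node_a, , drop = FALSE] -
                        mesh$nodes[mesh$pairs$node_b, , drop = FALSE])^2))
  if (any(!is.finite(da))) stop("unmatched cut node in pairing", call. = FALSE)
  mesh$pairs
}

#' Mesh quality report
#'
#' Counts, per element: inverted elements (non-positive corner Jacobian),
#' distorted elements (minimum scaled Jacobian below 0.5, i.e. a corner
#' angle outside 30-150 degrees) and bad-aspect elements (longest to
#' shortest edge ratio above 1.5).  For a bilinear quad the Jacobian
#' determinant is linear in each reference coordinate, so the corner values
#' bound the values at any interior quadrature point.
#'
#' @param mesh A `skin_mesh`.
#' @param distortion_threshold Scaled-Jacobian threshold (default 0.5).
#' @param aspect_threshold Edge-ratio threshold (default 1.5).
#' @return Object of class `mesh_quality_report` with counts and totals.
#' @export
quality_report <- function(mesh, distortion_threshold = 0.5,
                           aspect_threshold = 1.5) {
  stopifnot(inherits(mesh, "skin_mesh"))
  el <- mesh$elems
  x <- matrix(mesh$nodes[el, 1], ncol = 4L)
  y <- matrix(mesh$nodes[el, 2], ncol = 4L)
  nxt <- c(2L, 3L, 4L, 1L)
  prv <- c(4L, 1L, 2L, 3L)
  min_scaled <- rep(Inf, nrow(el))
  min_det <- rep(Inf, nrow(el))
  edge_len <- matrix(0, nrow(el), 4L)
  for (k in 1:4) {
    ax <- x[, nxt[k]] - x[, k]; ay <- y[, nxt[k]] - y[, k]
    bx <- x[, prv[k]] - x[, k]; by <- y[, prv[k]] - y[, k]
    cr <- ax * by - ay * bx
    min_det <- pmin(min_det, cr)
    min_scaled <- pmin(min_scaled, cr / (sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2)))
    edge_len[, k] <- sqrt(ax^2 + ay^2)
  }
  aspect <- apply(edge_len, 1L, max) / apply(edge_len, 1L, min)
  structure(list(
    n_inverted = sum(min_det <= 0),
    n_distorted = sum(min_scaled < distortion_threshold),
    n_bad_aspect = sum(aspect > aspect_threshold),
    n_elements = nrow(el),
    n_nodes = nrow(mesh$nodes),
    min_scaled_jacobian = min(min_scaled),
    max_aspect = max(aspect)
  ), class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf(paste0("mesh quality: %d elements, %d nodes\n",
                     "  inverted: %d | distorted (<0.5): %d | bad aspect (>1.5): %d\n",
                     "  min scaled Jacobian %.3f, max aspect %.2f\n"),
              x$n_elements, x$n_nodes, x$n_inverted, x$n_distorted,
              x$n_bad_aspect, x$min_scaled_jacobian, x$max_aspect))
  invisible(x)
}

#' Quality report as a one-row data frame
#'
#' @param report A [quality_report()] result.
#' @return One-row `data.frame` (convenient for CSV/JSON export).
#' @export
as.data.frame.mesh_quality_report <- function(x, ...) {
  data.frame(n_elements = x$n_elements, n_nodes = x$n_nodes,
             n_inverted = x$n_inverted, n_distorted = x$n_distorted,
             n_bad_aspect = x$n_bad_aspect)
}
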