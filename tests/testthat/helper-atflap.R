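# Shared fixtures.  The heavy simulations are memoized so several test
# files can assert against one solved model.

.atflap_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .atflap_cache)) {
    assign(key, force(expr), envir = .atflap_cache)
  }
  get(key, envir = .atflap_cache)
}

# Default operative scenario solved at 3 mm (both stages).
default_run <- function() {
  memo("default_run", run_pipeline(simulation_config()))
}

# Element-size sensitivity study over the standard sizes.
sensitivity_table <- function() {
  memo("sens_tab",
       mesh_sensitivity_study(simulation_config(), sizes = c(4, 3, 2, 1)))
}

# Mini A-T solution on the coarse fixture mesh.
mini_run <- function() {
  memo("mini_run", {
    mesh <- patch_meshes()$mini_at
    list(mesh = mesh,
         sols = run_suture_then_release(mesh, facial_skin_ogden()))
  })
}

# Match nodes to their mirror images about x = 0 (by rounded coordinates).
mirror_map <- function(nodes, tol = 1e-6) {
  key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol))
  mkey <- paste(round(-nodes[, 1] / tol), round(nodes[, 2] / tol))
  match(mkey, key)
}

# Mirror map for a full A-T mesh: coordinate matching is ambiguous where
# nodes are duplicated along the base cuts (and at the waist corners), so
# those entries are corrected from the stored pairings, keeping each node
# on its own material sheet.
mirror_map_mesh <- function(mesh, tol = 1e-6) {
  map <- mirror_map(mesh$nodes, tol)
  bc <- mesh$base_cut_pairs
  if (!is.null(bc)) {
    for (side in c("flap", "lower")) {
      ids <- bc[[side]]
      mk <- paste(round(-mesh$nodes[ids, 1] / tol),
                  round(mesh$nodes[ids, 2] / tol))
      k <- paste(round(mesh$nodes[ids, 1] / tol),
                 round(mesh$nodes[ids, 2] / tol))
      map[ids] <- ids[match(mk, k)]
    }
  }
  if (nrow(mesh$pairs)) {
    map[mesh$pairs$node_a] <- mesh$pairs$node_b
    map[mesh$pairs$node_b] <- mesh$pairs$node_a
  }
  map
}
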