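# Shared fixtures, built in code.

cubic_cif <- function(a = 10, atoms = "C1 C 0 0 0") {
  paste(c("data_fix",
          sprintf("_cell_length_a %g", a),
          sprintf("_cell_length_b %g", a),
          sprintf("_cell_length_c %g", a),
          "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
          "loop_",
          "_atom_site_label", "_atom_site_type_symbol",
          "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
          atoms), collapse = "\n")
}

# random triclinic-but-valid cell
random_cell <- function() {
  unit_cell(runif(1, 5, 20), runif(1, 5, 20), runif(1, 5, 20),
            runif(1, 70, 110), runif(1, 70, 110), runif(1, 70, 110))
}

# angular distance between two orientations (degrees)
rotation_distance_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# cached synthetic project (one per seed within a test file run)
.syn_cache <- new.env(parent = emptyenv())
synthetic_project_cached <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.syn_cache[[key]])) {
    tr <- synthetic_truth(seed = seed, ...)
    .syn_cache[[key]] <- make_synthetic_project(tr, file.path(tempdir(), key))
  }
  .syn_cache[[key]]
}
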