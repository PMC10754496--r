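# small deterministic morphologies used across test files

# soma + one basal cylinder of given geometry
cylinder_morphology <- function(length = 500, diameter = 1,
                                soma_diameter = 1e-3, n_segments = 1,
                                tree = "basal") {
  segs <- list(tibble::tibble(
    segment_id = 1L, parent_id = NA_integer_, tree_label = "soma",
    length = soma_diameter, diameter = soma_diameter, path_distance = 0))
  Lc <- length / n_segments
  for (k in seq_len(n_segments)) {
    segs[[k + 1]] <- tibble::tibble(
      segment_id = k + 1L, parent_id = k, tree_label = tree,
      length = Lc, diameter = diameter, path_distance = (k - 0.5) * Lc)
  }
  segments <- dplyr::bind_rows(segs)
  segments$branch_order <- apicobasal:::compute_branch_order(segments)
  m <- apicobasal:::new_morphology(segments,
                                   soma_area_um2 = pi * soma_diameter^2)
  apicobasal:::validate_morphology(m, require_both_trees = FALSE)
}

# soma + basal stem branching twice (branch orders 0,1,1,2,2) + one apical
two_branch_morphology <- function() {
  segments <- tibble::tibble(
    segment_id = 1:7,
    parent_id = c(NA, 1L, 2L, 2L, 3L, 3L, 1L),
    tree_label = c("soma", rep("basal", 5), "apical"),
    length = c(10, 50, 40, 40, 30, 30, 120),
    diameter = c(10, 1.2, 1, 1, 0.8, 0.8, 1.5),
    path_distance = c(0, 25, 70, 70, 105, 105, 60))
  segments$branch_order <- apicobasal:::compute_branch_order(segments)
  m <- apicobasal:::new_morphology(segments, soma_area_um2 = pi * 10^2)
  apicobasal:::validate_morphology(m)
}

# compact synthetic cell shared by the protocol tests (built once per file)
small_cell <- function() generate_synthetic_morphology(seed = 1)

write_swc_text <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}
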