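#' Passive membrane parameters
#'
#' Container for the passive electrical properties of the membrane. Defaults
#' give a membrane time constant of 17.3 ms (`c_m / g_leak`) and a passive
#' resting potential of -79 mV, the operating point the active model is
#' validated against.
#'
#' @param c_m Specific membrane capacitance, uF/cm^2.
#' @param r_a Axial resistivity, Ohm cm.
#' @param g_leak Leak conductance density, S/cm^2. The default `1/17300`
#'   corresponds to a membrane resistivity R_m of 17300 Ohm cm^2.
#' @param e_leak Leak reversal potential, mV.
#' @return An object of class `ab_passive` (a named list).
#' @examples
#' p <- passive_params()
#' p$c_m / p$g_leak # membrane time constant, ms (uF/cm^2 / (S/cm^2) = ms)
#' @export
passive_params <- function(c_m = 1, r_a = 100, g_leak = 1 / 17300, e_leak = -79) {
  if (c_m <= 0 || r_a <= 0 || g_leak <= 0) {
    abort("passive parameters c_m, r_a and g_leak must all be positive",
          class = "ab_domain_error")
  }
  structure(list(c_m = c_m, r_a = r_a, g_leak = g_leak, e_leak = e_leak),
            class = "ab_passive")
}

swc_type_codes <- c(soma = 1L, basal = 3L, apical = 4L)

new_morphology <- function(segments, soma_area_um2, coords = NULL) {
  structure(list(segments = segments,
                 soma_area_um2 = soma_area_um2,
                 coords = coords),
            class = "ab_morphology")
}

#' @export
print.ab_morphology <- function(x, ...) {
  s <- x$segments
  cat("<ab_morphology> ", nrow(s), " segments (",
      sum(s$tree_label == "apical"), " apical, ",
      sum(s$tree_label == "basal"), " basal), total dendritic length ",
      round(sum(s$length[s$tree_label != "soma"]), 1), " um\n", sep = "")
  invisible(x)
}

validate_morphology <- function(m, require_both_trees = TRUE) {
  s <- m$segments
  root <- which(is.na(s$parent_id))
  if (length(root) != 1) {
    abort("morphology must have exactly one root", class = "ab_structure_error")
  }
  if (s$tree_label[root] != "soma") {
    abort("morphology root must be the soma", class = "ab_structure_error")
  }
  if (any(s$length <= 0) || any(s$diameter <= 0)) {
    abort("all segment lengths and diameters must be positive",
          class = "ab_structure_error")
  }
  non_root <- s[-root, , drop = FALSE]
  if (nrow(non_root) && !all(non_root$parent_id %in% s$segment_id)) {
    abort("segment references a missing parent id", class = "ab_structure_error")
  }
  # connect + acyclic: walking parents must reach the root
  idx <- setNames(seq_len(nrow(s)), s$segment_id)
  for (i in seq_len(nrow(s))) {
    j <- i; hops <- 0L
    while (!is.na(s$parent_id[j])) {
      j <- idx[[as.character(s$parent_id[j])]]
      hops <- hops + 1L
      if (hops > nrow(s)) {
        abort("cycle detected in morphology", class = "ab_structure_error")
      }
    }
  }
  if (require_both_trees &&
      (!any(s$tree_label == "apical") || !any(s$tree_label == "basal"))) {
    abort("morphology must contain at least one apical and one basal segment",
          class = "ab_structure_error")
  }
  invisible(m)
}

#' Load a neuronal morphology from an SWC file
#'
#' Reads the standard 7-column SWC interchange format (id, type, x, y, z,
#' radius, parent; `#` comments). Type codes 1 (soma), 3 (basal dendrite) and
#' 4 (apical dendrite) are accepted. All soma samples are merged into a single
#' isopotential root compartment (equivalent-area sphere). Unbranched runs of
#' dendritic sample points are merged into one dendritic segment, the unit all
#' protocols and morphometrics operate on; segments are re-discretised for
#' simulation by [build_system()].
#'
#' @param path Path to an SWC file.
#' @param require_both_trees Require at least one apical and one basal
#'   segment (the protocols need both); set `FALSE` for partial morphologies.
#' @return An `ab_morphology`: a validated segment table plus soma geometry.
#'   Per-segment columns: `segment_id`, `parent_id` (NA for the soma root),
#'   `tree_label`, `length` and `diameter` (um), `path_distance` (um, soma
#'   centre to segment midpoint), `branch_order`.
#' @seealso [write_swc()], [morphometrics()], [generate_synthetic_morphology()]
#' @export
load_swc <- function(path, require_both_trees = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("SWC file not found: ", path), class = "ab_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad)) {
    abort(paste0("malformed SWC line ", lineno[bad[1]],
                 ": expected 7 columns"), class = "ab_parse_error")
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(mat)) {
    r <- which(apply(is.na(mat), 1, any))[1]
    abort(paste0("malformed SWC line ", lineno[r], ": non-numeric field"),
          class = "ab_parse_error")
  }
  pts <- tibble(id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
                x = mat[, 3], y = mat[, 4], z = mat[, 5], r = mat[, 6],
                parent = as.integer(mat[, 7]))
  unknown <- setdiff(unique(pts$type), unname(swc_type_codes))
  if (length(unknown)) {
    abort(paste0("unknown SWC type code(s): ",
                 paste(sort(unknown), collapse = ", "),
                 " (accepted: 1 = soma, 3 = basal, 4 = apical)"),
          class = "ab_label_error")
  }
  roots <- pts$id[pts$parent == -1]
  if (length(roots) != 1) {
    abort(paste0("SWC must have exactly one root, found ", length(roots)),
          class = "ab_structure_error")
  }
  if (pts$type[pts$id == roots] != 1L) {
    abort("SWC root sample must be a soma point", class = "ab_structure_error")
  }
  if (!all(pts$parent[pts$parent != -1] %in% pts$id)) {
    miss <- setdiff(pts$parent[pts$parent != -1], pts$id)
    abort(paste0("SWC sample references missing parent id ", miss[1]),
          class = "ab_structure_error")
  }

  soma_ids <- pts$id[pts$type == 1L]
  idx <- setNames(seq_len(nrow(pts)), pts$id)
  dist_to_parent <- function(i) {
    p <- idx[[as.character(pts$parent[i])]]
    sqrt((pts$x[i] - pts$x[p])^2 + (pts$y[i] - pts$y[p])^2 +
           (pts$z[i] - pts$z[p])^2)
  }
  # soma: equivalent-area sphere from the sample chain
  if (length(soma_ids) == 1L) {
    soma_area <- 4 * pi * pts$r[idx[[as.character(soma_ids)]]]^2
  } else {
    soma_area <- 0
    for (sid in soma_ids) {
      i <- idx[[as.character(sid)]]
      if (pts$parent[i] == -1) next
      soma_area <- soma_area + pi * 2 * pts$r[i] * dist_to_parent(i)
    }
    if (soma_area <= 0) soma_area <- 4 * pi * max(pts$r[pts$type == 1L])^2
  }
  soma_d <- sqrt(soma_area / pi)

  children <- split(pts$id, pts$parent)
  n_children <- function(pid) length(children[[as.character(pid)]])

  # walk dendritic points, merging unbranched same-type runs into segments
  segs <- list()
  seg_id <- 1L
  # queue entries: (start point id, parent segment id or NA, start distance)
  queue <- list()
  for (cid in children[[as.character(roots)]]) {
    i <- idx[[as.character(cid)]]
    if (pts$type[i] == 1L) {
      # further soma samples: their non-soma children attach to the root
      stack <- cid
      while (length(stack)) {
        s0 <- stack[[1]]; stack <- stack[-1]
        for (cc in children[[as.character(s0)]]) {
          if (pts$type[idx[[as.character(cc)]]] == 1L) stack <- c(stack, cc)
          else queue[[length(queue) + 1]] <- list(cc, NA_integer_, 0)
        }
      }
    } else {
      queue[[length(queue) + 1]] <- list(cid, NA_integer_, 0)
    }
  }
  while (length(queue)) {
    job <- queue[[1]]; queue <- queue[-1]
    cur <- job[[1]]; parent_seg <- job[[2]]; d0 <- job[[3]]
    i <- idx[[as.character(cur)]]
    type <- pts$type[i]
    len <- dist_to_parent(i)
    wdiam <- 2 * pts$r[i] * len
    first <- i; last <- i
    while (n_children(pts$id[last]) == 1L) {
      nxt <- idx[[as.character(children[[as.character(pts$id[last])]])]]
      if (pts$type[nxt] != type) break
      el <- dist_to_parent(nxt)
      len <- len + el
      wdiam <- wdiam + 2 * pts$r[nxt] * el
      last <- nxt
    }
    if (len <= 0) {
      abort(paste0("zero-length segment at SWC sample id ", pts$id[first]),
            class = "ab_parse_error")
    }
    segs[[seg_id]] <- list(
      segment_id = seg_id, parent_id = parent_seg,
      tree_label = names(swc_type_codes)[match(type, swc_type_codes)],
      length = len, diameter = wdiam / len,
      start_distance = d0,
      x1 = pts$x[last], y1 = pts$y[last], z1 = pts$z[last])
    for (cc in children[[as.character(pts$id[last])]]) {
      queue[[length(queue) + 1]] <- list(cc, seg_id, d0 + len)
    }
    seg_id <- seg_id + 1L
  }

  st <- bind_rows(lapply(segs, function(s) {
    tibble(segment_id = s$segment_id + 1L,
           parent_id = if (is.na(s$parent_id)) 1L else s$parent_id + 1L,
           tree_label = s$tree_label, length = s$length, diameter = s$diameter,
           path_distance = s$start_distance + s$length / 2)
  }))
  soma_row <- tibble(segment_id = 1L, parent_id = NA_integer_,
                     tree_label = "soma", length = soma_d, diameter = soma_d,
                     path_distance = 0)
  segments <- bind_rows(soma_row, st)
  segments$branch_order <- compute_branch_order(segments)
  m <- new_morphology(segments, soma_area)
  validate_morphology(m, require_both_trees = require_both_trees)
}

compute_branch_order <- function(segments) {
  n_kids <- table(factor(segments$parent_id, levels = segments$segment_id))
  ord <- rep(0L, nrow(segments))
  idx <- setNames(seq_len(nrow(segments)), segments$segment_id)
  # parents always have smaller row index by construction
  for (i in seq_len(nrow(segments))) {
    p <- segments$parent_id[i]
    if (is.na(p)) next
    pi <- idx[[as.character(p)]]
    is_branch <- n_kids[[as.character(p)]] >= 2 && segments$tree_label[pi] != "soma"
    ord[i] <- ord[pi] + as.integer(is_branch)
  }
  ord
}

#' Write a morphology to an SWC file
#'
#' Each dendritic segment is written as a single straight SWC sample at its
#' segment's path length from its parent, so lengths and diameters round-trip
#' exactly through [load_swc()]. When the morphology carries no 3-D
#' coordinates a deterministic planar fan layout is synthesised.
#'
#' @param m An `ab_morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  s <- m$segments
  soma_r <- s$diameter[1] / 2
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d", 1L, 1L, 0, 0, 0, soma_r, -1L)
  # deterministic fan layout: children of a node spread around parent direction
  pos <- list(`1` = c(0, 0, 0))
  dir <- list(`1` = c(0, 1, 0))
  kids <- split(s$segment_id, s$parent_id)
  point_id <- setNames(1L, "1")
  for (i in seq_len(nrow(s))[-1]) {
    sid <- s$segment_id[i]; pid <- s$parent_id[i]
    sibs <- kids[[as.character(pid)]]
    k <- match(sid, sibs); nk <- length(sibs)
    base <- if (s$tree_label[i] == "basal" && pid == 1L) c(0, -1, 0) else dir[[as.character(pid)]]
    ang <- if (nk == 1) 0 else (k - (nk + 1) / 2) * (pi / (nk + 1))
    # rotate base direction by ang in the plane spanned with a perpendicular
    perp <- c(base[2], -base[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    u <- cos(ang) * base + sin(ang) * perp
    u <- u / sqrt(sum(u^2))
    p <- pos[[as.character(pid)]] + u * s$length[i]
    pos[[as.character(sid)]] <- p
    dir[[as.character(sid)]] <- u
    type <- unname(swc_type_codes[s$tree_label[i]])
    this_id <- length(point_id) + 1L
    point_id[as.character(sid)] <- this_id
    lines <- c(lines, sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                              this_id, type, p[1], p[2], p[3],
                              s$diameter[i] / 2,
                              point_id[[as.character(pid)]]))
  }
  writeLines(c("# generated by apicobasal", lines), path)
  invisible(path)
}

#' Passive length constant and electrotonic length
#'
#' `lambda_um()` returns the steady-state passive length constant
#' lambda = sqrt(R_m d / (4 R_a)) in um; `electrotonic_length()` returns a
#' cylinder's physical length divided by lambda (dimensionless), the distance
#' scale over which a steady voltage decays along the cable.
#'
#' @param diameter_um Cylinder diameter, um.
#' @param passive An [passive_params()] object (R_m is `1/g_leak`).
#' @param length_um Cylinder length, um.
#' @return lambda in um, or the dimensionless electrotonic length.
#' @examples
#' lambda_um(1, passive_params(g_leak = 1e-4, r_a = 100)) # 500 um
#' electrotonic_length(100, 1, passive_params(g_leak = 1e-4, r_a = 100)) # 0.2
#' @export
lambda_um <- function(diameter_um, passive = passive_params()) {
  if (any(diameter_um <= 0)) {
    abort("diameter must be positive", class = "ab_domain_error")
  }
  r_m <- 1 / passive$g_leak                      # Ohm cm^2
  d_cm <- diameter_um * 1e-4
  sqrt(r_m * d_cm / (4 * passive$r_a)) * 1e4     # cm -> um
}

#' @rdname lambda_um
#' @export
electrotonic_length <- function(length_um, diameter_um, passive = passive_params()) {
  if (any(length_um < 0)) {
    abort("length must be non-negative", class = "ab_domain_error")
  }
  length_um / lambda_um(diameter_um, passive)
}

#' Per-segment morphometrics table
#'
#' One row per non-soma dendritic segment with the morphometric and
#' electrotonic quantities the attenuation and threshold analyses condition
#' on. Column order is fixed: `segment_id`, `tree_label`, `length`,
#' `diameter`, `volume`, `path_distance`, `path_volume`, `branch_order`,
#' `electrotonic_length`. Volumes are cylinder volumes pi (d/2)^2 L (um^3);
#' `path_volume` sums segment volumes along the soma-to-segment path
#' (the segment itself included, soma excluded).
#'
#' @param m An `ab_morphology`.
#' @param passive Passive parameters for the electrotonic length.
#' @return A tibble, one row per non-soma segment.
#' @export
morphometrics <- function(m, passive = passive_params()) {
  s <- m$segments
  vol <- pi * (s$diameter / 2)^2 * s$length
  idx <- setNames(seq_len(nrow(s)), s$segment_id)
  pvol <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$tree_label[i] == "soma") next
    p <- s$parent_id[i]
    pv <- vol[i]
    while (!is.na(p)) {
      j <- idx[[as.character(p)]]
      if (s$tree_label[j] != "soma") pv <- pv + vol[j]
      p <- s$parent_id[j]
    }
    pvol[i] <- pv
  }
  out <- tibble(segment_id = s$segment_id, tree_label = s$tree_label,
                length = s$length, diameter = s$diameter, volume = vol,
                path_distance = s$path_distance, path_volume = pvol,
                branch_order = s$branch_order,
                electrotonic_length = ifelse(
                  s$tree_label == "soma", 0,
                  electrotonic_length(s$length, s$diameter, passive)))
  out[out$tree_label != "soma", , drop = FALSE]
}

#' @rdname morphometrics
#' @param path CSV output path.
#' @export
write_morphometrics <- function(m, path, passive = passive_params()) {
  write.csv(morphometrics(m, passive), path, row.names = FALSE)
  invisible(path)
}

#' Remove the apical tree from a morphology
#'
#' Returns the morphology with every apical segment deleted (soma and basal
#' tree retained), emulating an apical-tree ablation. The result is a valid
#' input to [build_system()]; synapse tables built on the intact cell can be
#' restricted with `synapses[synapses$tree_label != "apical", ]`.
#'
#' @param m An `ab_morphology`.
#' @return An `ab_morphology` without apical segments.
#' @export
ablate_apical_tree <- function(m) {
  s <- m$segments[m$segments$tree_label != "apical", , drop = FALSE]
  out <- new_morphology(s, m$soma_area_um2)
  validate_morphology(out, require_both_trees = FALSE)
}
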