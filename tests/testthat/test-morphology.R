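test_that("a minimal SWC file reads back as one basal cylinder", {
  path <- write_swc_text(c(
    "# soma + one basal cylinder",
    "1 1 0 0 0 5 -1",
    "2 3 0 -5 0 1 1",
    "3 3 0 -15 0 1 2"))
  m <- load_swc(path, require_both_trees = FALSE)
  dend <- m$segments[m$segments$tree_label != "soma", ]
  expect_equal(nrow(dend), 1)
  expect_equal(dend$tree_label, "basal")
  expect_equal(dend$length, 15) # measured from the soma sample
  expect_equal(dend$diameter, 2)
})

test_that("malformed and structurally invalid SWC files fail informatively", {
  bad_cols <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 0 0 0 1"))
  expect_error(load_swc(bad_cols), "line 2", class = "ab_parse_error")

  missing_parent <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 0 5 0 1 9"))
  expect_error(load_swc(missing_parent), "missing parent",
               class = "ab_structure_error")

  two_roots <- write_swc_text(c("1 1 0 0 0 5 -1", "2 1 30 0 0 5 -1"))
  expect_error(load_swc(two_roots), "exactly one root",
               class = "ab_structure_error")

  axon <- write_swc_text(c("1 1 0 0 0 5 -1", "2 2 0 5 0 1 1"))
  expect_error(load_swc(axon), "type code.*2", class = "ab_label_error")
})

test_that("synthetic morphologies round-trip through SWC", {
  m <- generate_synthetic_morphology(seed = 7)
  path <- tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- load_swc(path)
  a <- m$segments[m$segments$tree_label != "soma", ]
  b <- m2$segments[m2$segments$tree_label != "soma", ]
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$path_distance, a$length), ]
  b <- b[order(b$path_distance, b$length), ]
  expect_equal(a$length, b$length, tolerance = 1e-6)
  expect_equal(a$diameter, b$diameter, tolerance = 1e-6)
  expect_equal(a$tree_label, b$tree_label)
})

test_that("electrotonic length follows the cable length constant", {
  p <- passive_params(g_leak = 1e-4, r_a = 100) # R_m = 10 kOhm cm^2
  expect_equal(lambda_um(1, p), 500)
  expect_equal(electrotonic_length(100, 1, p), 0.2)
  # quadrupling diameter doubles lambda, halves electrotonic length
  expect_equal(electrotonic_length(100, 4, p),
               electrotonic_length(100, 1, p) / 2)
  expect_equal(electrotonic_length(0, 1, p), 0)
  expect_error(lambda_um(-1, p), class = "ab_domain_error")
  expect_error(passive_params(g_leak = 0), class = "ab_domain_error")
  # invariant under subdividing into colinear pieces
  pieces <- electrotonic_length(rep(100 / 7, 7), 1.3, p)
  expect_equal(sum(pieces), electrotonic_length(100, 1.3, p),
               tolerance = 1e-9)
})

test_that("morphometrics reports per-segment geometry correctly", {
  m <- two_branch_morphology()
  mm <- morphometrics(m)
  expect_false(1L %in% mm$segment_id) # root excluded
  expect_equal(nrow(mm), 6)
  cyl <- mm[mm$segment_id == 2L, ]
  expect_equal(cyl$volume, pi * (1.2 / 2)^2 * 50, tolerance = 1e-9)
  # two branch points deep -> branch order 2
  expect_equal(mm$branch_order[mm$segment_id %in% c(5L, 6L)], c(2L, 2L))
  expect_equal(mm$branch_order[mm$segment_id == 2L], 0L)
  # path volume accumulates along the path
  expect_equal(mm$path_volume[mm$segment_id == 5L],
               sum(mm$volume[mm$segment_id %in% c(2L, 3L, 5L)]))
  # 10 um, d = 2 cylinder volume example
  expect_equal(pi * 1^2 * 10, 31.41593, tolerance = 1e-6)
})

test_that("path distance increases from root to tip", {
  m <- generate_synthetic_morphology(seed = 3)
  s <- m$segments
  for (i in seq_len(nrow(s))[-1]) {
    p <- s$parent_id[i]
    expect_gt(s$path_distance[i], s$path_distance[s$segment_id == p])
  }
})

test_that("apical ablation removes exactly the apical tree", {
  m <- two_branch_morphology()
  m2 <- ablate_apical_tree(m)
  expect_false(any(m2$segments$tree_label == "apical"))
  expect_equal(sum(m2$segments$tree_label == "basal"),
               sum(m$segments$tree_label == "basal"))
})
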