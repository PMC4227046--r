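swc_tbl <- function(...) {
  mnphys:::new_morphology(tibble::tribble(...))
}

test_that("SWC files parse, validate, and round-trip", {
  m <- swc_tbl(
    ~id, ~type, ~x, ~y, ~z, ~radius, ~parent,
    1L, 1L, 0, 0, 0, 10, -1L,
    2L, 3L, 100, 0, 0, 1, 1L,
    3L, 3L, 200, 0, 0, 1, 2L)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  back <- read_swc(f)
  expect_equal(compute_metrics(back)$n_primary, 1L)
  expect_equal(back$parent, m$parent)
  expect_equal(back$x, m$x, tolerance = 1e-6)

  tree <- generate_tree(tree_spec("WT", "immediate"), seed = 41)
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, f2)
  tree2 <- read_swc(f2)
  expect_equal(nrow(tree2), nrow(tree))
  expect_lt(max(abs(tree2$x - tree$x)), 1e-6)

  orphan <- "1 1 0 0 0 10 -1\n2 3 5 0 0 1 9"
  f3 <- withr::local_tempfile(fileext = ".swc")
  writeLines(orphan, f3)
  expect_error(read_swc(f3), "node 2 references missing parent 9")

  cyclic <- "1 1 0 0 0 10 -1\n2 3 5 0 0 1 3\n3 3 9 0 0 1 2"
  f4 <- withr::local_tempfile(fileext = ".swc")
  writeLines(cyclic, f4)
  expect_error(read_swc(f4), "cycle")
})

test_that("the slice filter removes plunging subtrees and nothing else", {
  shallow <- generate_tree(tree_spec("WT", "immediate",
                                     z_range = c(0, 20)), seed = 42)
  expect_identical(nrow(apply_slice_filter(shallow)), nrow(shallow))

  # one dendrite at constant 80 um depth, one in-plane
  deep <- swc_tbl(
    ~id, ~type, ~x, ~y, ~z, ~radius, ~parent,
    1L, 1L, 0, 0, 0, 10, -1L,
    2L, 3L, 100, 0, 80, 1, 1L,
    3L, 3L, 200, 0, 80, 1, 2L,
    4L, 3L, -100, 0, 10, 1, 1L)
  filt <- apply_slice_filter(deep)
  expect_equal(filt$id, c(1L, 4L))
  expect_equal(compute_metrics(filt)$n_primary, 1L)

  all_deep <- swc_tbl(
    ~id, ~type, ~x, ~y, ~z, ~radius, ~parent,
    1L, 1L, 0, 0, 0, 10, -1L,
    2L, 3L, 100, 0, 60, 1, 1L,
    3L, 3L, -50, 0, 70, 1, 1L)
  soma_only <- apply_slice_filter(all_deep)
  mm <- compute_metrics(soma_only)
  expect_equal(mm$n_primary, 0L)
  expect_equal(mm$total_length, 0)

  # node-depth scan: the filtered tree never contains a too-deep node, and
  # every removed node was deep or descended from one
  plunging <- generate_tree(tree_spec("WT", "delayed", deep_fraction = 0.5),
                            seed = 43)
  filt2 <- apply_slice_filter(plunging)
  expect_true(all(filt2$z <= 50))
  expect_gte(attr(plunging, "ground_truth")$n_deep, 1)
})

test_that("slice filtering never increases any metric", {
  for (seed in 44:47) {
    tree <- generate_tree(tree_spec("WT", "immediate", deep_fraction = 0.4),
                          seed = seed)
    before <- compute_metrics(tree)
    after <- compute_metrics(apply_slice_filter(tree))
    expect_lte(after$n_primary, before$n_primary)
    expect_lte(after$n_branch_points, before$n_branch_points)
    expect_lte(after$total_length, before$total_length + 1e-12)
    expect_lte(length(after$dendritic_paths), length(before$dendritic_paths))
  }
})

test_that("metrics match hand arithmetic on canonical trees", {
  # full binary dendrite: stem + 3 bifurcations, 7 straight 100 um segments
  bin <- swc_tbl(
    ~id, ~type, ~x, ~y, ~z, ~radius, ~parent,
    1L, 1L, 0, 0, 0, 10, -1L,
    2L, 3L, 100, 0, 0, 1, 1L,     # stem
    3L, 3L, 200, 50, 0, 1, 2L,    # level 1
    4L, 3L, 200, -50, 0, 1, 2L,
    5L, 3L, 300, 80, 0, 1, 3L,    # level 2 tips
    6L, 3L, 300, 20, 0, 1, 3L,
    7L, 3L, 300, -20, 0, 1, 4L,
    8L, 3L, 300, -80, 0, 1, 4L)
  # rescale so every edge is exactly 100 um
  idx <- match(bin$parent, bin$id)
  el <- sqrt((bin$x - bin$x[idx])^2 + (bin$y - bin$y[idx])^2)
  for (i in seq_len(nrow(bin))[-1]) {
    scale <- 100 / el[i]
    dx <- (bin$x[i] - bin$x[idx[i]]) * scale
    dy <- (bin$y[i] - bin$y[idx[i]]) * scale
    kids <- which(idx == i)
    bin$x[i] <- bin$x[idx[i]] + dx; bin$y[i] <- bin$y[idx[i]] + dy
    el <- sqrt((bin$x - bin$x[match(bin$parent, bin$id)])^2 +
                 (bin$y - bin$y[match(bin$parent, bin$id)])^2)
  }
  mm <- compute_metrics(bin)
  expect_equal(mm$n_primary, 1L)
  expect_equal(mm$n_branch_points, 3L)
  expect_equal(mm$total_length, 0.7, tolerance = 1e-9)
  expect_equal(sort(mm$terminal_segment_lengths), rep(100, 4), tolerance = 1e-9)
  expect_equal(sort(mm$dendritic_paths), rep(300, 4), tolerance = 1e-9)

  straight <- swc_tbl(
    ~id, ~type, ~x, ~y, ~z, ~radius, ~parent,
    1L, 1L, 0, 0, 0, 10, -1L,
    2L, 3L, 250, 0, 0, 1, 1L,
    3L, 3L, 500, 0, 0, 1, 2L)
  ms <- compute_metrics(straight)
  expect_equal(ms$n_branch_points, 0L)
  expect_equal(ms$dendritic_paths, 500)
  expect_equal(ms$terminal_segment_lengths, 500)
})

test_that("generated trees honour a forced degenerate spec", {
  tab <- dplyr::mutate(
    mn_reference_table(), sd = 0,
    mean = dplyr::case_when(property == "n_primary" ~ 1,
                            property == "n_branch_points" ~ 3,
                            property == "total_length" ~ 0.7,
                            property == "terminal_segment" ~ 100,
                            TRUE ~ mean),
    min = pmin(min, mean), max = pmax(max, mean))
  tr <- generate_tree(tree_spec("WT", "immediate", table = tab,
                                z_range = c(0, 0)), seed = 48)
  mm <- compute_metrics(tr)
  expect_equal(mm$n_primary, 1L)
  expect_equal(mm$n_branch_points, 3L)
  expect_equal(mm$total_length, 0.7, tolerance = 1e-9)
  expect_equal(length(mm$terminal_segment_lengths), 4L)
})

test_that("metrics agree with a brute-force traversal on small trees", {
  for (seed in 1:12) {
    m <- random_small_tree(20, seed = seed)
    a <- compute_metrics(m)
    b <- brute_metrics(m)
    expect_equal(a$n_primary, b$n_primary)
    expect_equal(a$n_branch_points, b$n_branch_points)
    expect_equal(a$total_length, b$total_length, tolerance = 1e-12)
    expect_equal(sort(a$dendritic_paths), sort(b$dendritic_paths),
                 tolerance = 1e-9)
    expect_equal(sort(a$terminal_segment_lengths),
                 sort(b$terminal_segment_lengths), tolerance = 1e-9)
  }
})

test_that("total length is additive over primary dendrites and bounds paths", {
  tree <- generate_tree(tree_spec("WT", "delayed"), seed = 49)
  mm <- compute_metrics(tree)
  root_id <- tree$id[tree$parent == -1L]
  prim_ids <- tree$id[tree$parent == root_id]
  per_dendrite <- vapply(prim_ids, function(pid) {
    keep <- pid
    repeat {
      grow <- tree$id[tree$parent %in% keep & !(tree$id %in% keep)]
      if (length(grow) == 0) break
      keep <- c(keep, grow)
    }
    sub <- tree[tree$id %in% c(root_id, keep), ]
    compute_metrics(mnphys:::new_morphology(sub))$total_length
  }, numeric(1))
  expect_equal(sum(per_dendrite), mm$total_length, tolerance = 1e-9)
  expect_lte(max(mm$dendritic_paths) / 1000, mm$total_length)
  expect_true(all(mm$terminal_segment_lengths <= mm$dendritic_paths + 1e-9))
})
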