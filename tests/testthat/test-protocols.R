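test_that("step search lands on the first grid point at or above rheobase", {
  c058 <- make_cell("immediate", delta_v = 20, g_in = 29)   # 0.58 nA
  expect_equal(rheobase_search(c058)$rheobase, 0.6)
  c093 <- make_cell("immediate", delta_v = 20, g_in = 46.5) # 0.93 nA
  expect_equal(rheobase_search(c093)$rheobase, 1.0)
  silent <- make_cell("immediate", delta_v = 40, g_in = 150) # 6 nA
  expect_error(rheobase_search(silent), "ceiling")
})

test_that("measured rheobase dominates the true one by less than a step", {
  cells <- dplyr::bind_rows(
    sample_population(group_spec("WT", "immediate"), 8, seed = 21),
    sample_population(group_spec("mSOD1", "delayed"), 8, seed = 22))
  for (i in seq_len(nrow(cells))) {
    r <- rheobase_search(cells[i, ])$rheobase
    true <- cells$rheobase_true[i]
    step <- if (true > 0.9) 0.1 else 0.05
    expect_gte(r + 1e-9, true)
    expect_lt(r - true, step + 0.05) # one grid cell (0.9 -> 1.0 gap included)
  }
})

test_that("the search also runs over pre-recorded step protocols", {
  cell <- make_cell("immediate", delta_v = 20, g_in = 29)   # 0.58 nA
  rec <- synthesize_protocol(cell, "RHEO_STEPS",
                             amplitudes = seq(0.3, 0.9, by = 0.05), seed = 32)
  rs <- rheobase_search(rec)
  expect_equal(rs$rheobase, 0.6)
  expect_equal(rs$tested, seq(0.3, 0.6, by = 0.05))
  sub <- synthesize_protocol(cell, "RHEO_STEPS", amplitudes = c(0.2, 0.4),
                             seed = 33)
  expect_error(rheobase_search(sub), "ceiling")
})

test_that("fewer than three ramp trials warns but proceeds", {
  cell <- make_cell("immediate")
  rp <- synthesize_protocol(cell, "RAMP", n_trials = 2, seed = 34)
  expect_warning(rr <- analyze_ramp(rp), "3 ramp trials")
  expect_true(is.finite(rr$recruitment_current))
})

test_that("firing patterns are classified from latency and acceleration", {
  del <- make_cell("delayed", delay_scale = 2.9)
  swd <- mnphys:::with_seed(23, mnphys:::template_step_sweep(
    as.list(del), del$rheobase_true))
  expect_equal(classify_pattern(swd), "delayed")

  imm <- make_cell("immediate")
  swi <- mnphys:::with_seed(24, mnphys:::template_step_sweep(
    as.list(imm), imm$rheobase_true))
  expect_equal(classify_pattern(swi), "immediate")

  expect_error(classify_pattern(make_flat_sweep(-65)), "spike")

  mixed <- dplyr::bind_rows(
    sample_population(group_spec("WT", "immediate"), 15, seed = 25),
    sample_population(group_spec("WT", "delayed"), 15, seed = 26))
  hits <- vapply(seq_len(nrow(mixed)), function(i) {
    rs <- rheobase_search(mixed[i, ])
    classify_pattern(rs$sweep, rs$spikes) == mixed$pattern[i]
  }, logical(1))
  expect_true(all(hits))
})

test_that("ramp analysis recovers recruitment, gain and hysteresis", {
  cell <- make_cell("immediate", delta_v = 20, g_in = 15, noise_sd = 0) # 0.3 nA
  rr <- analyze_ramp(synthesize_protocol(cell, "RAMP", seed = 27,
                                         noise = FALSE))
  expect_lt(abs(rr$recruitment_current - 0.3), 0.01)
  expect_lte(rr$derecruitment_current, rr$recruitment_current)
  expect_lt(abs(rr$recruitment_current - cell$rheobase_true), 0.1)

  g29 <- make_cell("immediate", gain_true = 29)
  rr2 <- analyze_ramp(synthesize_protocol(g29, "RAMP", seed = 28))
  expect_lt(abs(rr2$gain - 29), 2)

  del <- make_cell("delayed", f_half = 30)
  rr3 <- analyze_ramp(synthesize_protocol(del, "RAMP", seed = 29))
  expect_lt(abs(rr3$f_half_second - 30) / 30, 0.1)
  expect_lte(rr3$derecruitment_current, rr3$recruitment_current)
})

test_that("MMO detection flags oscillating cells and only those", {
  mmo <- make_cell("immediate", mmo = TRUE)
  sw <- mnphys:::with_seed(30, mnphys:::template_step_sweep(
    as.list(mmo), mmo$rheobase_true))
  res <- detect_mmos(sw)
  expect_true(res$flag)
  expect_gt(res$count, 4)

  quiet <- make_cell("immediate", mmo = FALSE, noise_sd = 0)
  sw0 <- mnphys:::template_step_sweep(as.list(quiet), quiet$rheobase_true,
                                      noise = FALSE)
  res0 <- detect_mmos(sw0)
  expect_false(res0$flag)
  expect_equal(res0$count, 0L)

  # fewer than two spikes: no intervals, flag stays down
  expect_false(detect_mmos(make_flat_sweep(-65, spike_at = 0.2))$flag)
})

test_that("sub-primary/primary segmentation follows the last MMO interval", {
  fi <- tibble::tibble(current = seq(0.4, 1.6, by = 0.1),
                       freq_inst = seq(10, 34, by = 2),
                       phase = "ascending")
  isis <- tibble::tibble(isi = 1:12, n_osc = c(rep(3L, 8), rep(0L, 4)),
                         t_start = 1:12, t_end = 2:13,
                         current_end = seq(0.5, 1.6, by = 0.1))
  seg <- segment_ranges(fi, isis)
  expect_equal(seg$boundary, 1.2)
  expect_true(seg$has_primary)

  none <- dplyr::mutate(isis, n_osc = 0L)
  seg0 <- segment_ranges(fi, none)
  expect_null(seg0$boundary)
  expect_true(seg0$has_primary)

  all_mmo <- dplyr::mutate(isis, n_osc = 3L)
  seg1 <- segment_ranges(fi, all_mmo)
  expect_false(seg1$has_primary)
})

test_that("a cell with MMOs to the ramp peak yields no measurable gain", {
  del <- make_cell("delayed", mmo = TRUE)
  rr <- analyze_ramp(synthesize_protocol(del, "RAMP", seed = 31))
  expect_true(rr$mmo_present)
  expect_true(is.na(rr$gain))
})
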