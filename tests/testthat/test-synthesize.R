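test_that("immediate cells discharge from pulse onset at steady rate", {
  cell <- make_cell("immediate")
  sw <- mnphys:::with_seed(1, mnphys:::template_step_sweep(
    as.list(cell), cell$rheobase_true))
  sp <- detect_spikes(sw)
  expect_gt(nrow(sp), 10)
  latency <- sp$t_peak[1] - sw$meta$t_on
  expect_lt(latency, 0.1)
  f <- sp$freq_inst[-1]
  expect_lt(sd(f) / mean(f), 0.2)
})

test_that("a delayed cell at rheobase fires its first spike at delay_scale", {
  cell <- make_cell("delayed", delay_scale = 2.9)
  sw <- mnphys:::with_seed(2, mnphys:::template_step_sweep(
    as.list(cell), cell$rheobase_true))
  sp <- detect_spikes(sw)
  latency <- sp$t_peak[1] - sw$meta$t_on
  # peak trails the upstroke onset by ~2 ms of rendered waveform
  expect_lt(abs(latency - 2.9), 0.003)
  # discharge accelerates
  slope <- mnphys:::theil_sen_slope(sp$t_peak[-1], sp$freq_inst[-1])
  expect_gt(slope, 0)
})

test_that("delayed latency shrinks with current and vanishes by twice rheobase", {
  cell <- make_cell("delayed", delay_scale = 3)
  r <- cell$rheobase_true
  lat <- vapply(c(1, 1.3, 1.6, 2) * r, function(i) {
    sw <- mnphys:::with_seed(3, mnphys:::template_step_sweep(as.list(cell), i))
    detect_spikes(sw)$t_peak[1] - sw$meta$t_on
  }, numeric(1))
  expect_true(all(diff(lat) < 0))
  expect_lt(lat[4], 0.15)
})

test_that("noise-free I-V steps obey Ohm's law exactly at steady state", {
  cell <- make_cell("immediate", g_in = 40, noise_sd = 0)
  iv <- synthesize_protocol(cell, "IV_STEPS", seed = 4, noise = FALSE)
  sw <- iv$sweeps[[1]]       # -100 pA
  on <- which(sw$current != 0)
  ss <- mean(sw$voltage[(max(on) - 999):max(on)])
  expect_equal(ss - cell$v_rest, 1000 * (-0.1) / 40, tolerance = 1e-6)
})

test_that("identical seeds give bit-identical sweeps", {
  cell <- make_cell("immediate", mmo = TRUE)
  a <- synthesize_protocol(cell, "RHEO_STEPS", amplitudes = c(0.3, 0.7), seed = 5)
  b <- synthesize_protocol(cell, "RHEO_STEPS", amplitudes = c(0.3, 0.7), seed = 5)
  expect_identical(a$sweeps[[2]]$voltage, b$sweeps[[2]]$voltage)
  tr1 <- generate_tree(tree_spec("WT", "immediate"), seed = 6)
  tr2 <- generate_tree(tree_spec("WT", "immediate"), seed = 6)
  expect_identical(tr1$x, tr2$x)
})

test_that("template and mechanistic modes agree on rheobase within one step", {
  cells <- dplyr::bind_rows(
    sample_population(group_spec("WT", "immediate"), 3, seed = 71),
    sample_population(group_spec("WT", "delayed"), 3, seed = 72))
  for (i in seq_len(nrow(cells))) {
    rt <- rheobase_search(cells[i, ], mode = "template")$rheobase
    rm_ <- rheobase_search(cells[i, ], mode = "mechanistic")$rheobase
    step <- if (max(rt, rm_) > 0.9) 0.1 else 0.05
    expect_lte(abs(rt - rm_), step + 1e-9)
  }
})

test_that("unsupported protocol requests fail loudly", {
  cell <- make_cell("immediate")
  expect_error(synthesize_protocol(cell, "RAMP", mode = "mechanistic"),
               "mechanistic")
  nogain <- dplyr::mutate(cell, gain_true = NA_real_)
  expect_error(synthesize_protocol(nogain, "RAMP"), "gain")
})
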