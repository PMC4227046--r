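test_that("resting potential is the 200 ms pre-pulse baseline mean", {
  sw <- make_flat_sweep(-65, n = 5000,
                        current = c(rep(0, 3000), rep(0.1, 2000)))
  expect_equal(resting_potential(sw), -65)
  cell <- make_cell("immediate", v_rest = -64)
  sw2 <- mnphys:::with_seed(8, mnphys:::template_step_sweep(
    as.list(cell), cell$rheobase_true))
  expect_lt(abs(resting_potential(sw2) - (-64)), 0.1)
  short <- make_flat_sweep(-65, n = 400,
                           current = c(rep(0, 100), rep(0.1, 300)))
  expect_error(resting_potential(short), "baseline")
})

test_that("spike detection finds rendered spikes and inverse-ISI frequencies", {
  cell <- make_cell("immediate", noise_sd = 0)
  sub <- mnphys:::template_step_sweep(as.list(cell),
                                      0.5 * cell$rheobase_true, noise = FALSE)
  expect_equal(nrow(detect_spikes(sub)), 0L)

  sw <- mnphys:::with_seed(9, mnphys:::template_step_sweep(
    as.list(make_cell("immediate")), make_cell("immediate")$rheobase_true))
  sp <- detect_spikes(sw)
  truth <- sw$meta$spike_peak_times
  expect_equal(nrow(sp), length(truth))
  expect_lt(max(abs(sp$t_peak - truth)), sw$dt + 1e-12)

  two <- make_flat_sweep(-65, n = 5000, spike_at = c(0.1, 0.2))
  sp2 <- detect_spikes(two)
  expect_equal(nrow(sp2), 2L)
  expect_equal(sp2$freq_inst[2], 10, tolerance = 1e-6)
})

test_that("the 10 mV/ms criterion recovers the rendered threshold", {
  cell <- make_cell("immediate", delta_v = 21)  # threshold -44 mV
  sw <- mnphys:::with_seed(10, mnphys:::template_step_sweep(
    as.list(cell), cell$rheobase_true))
  expect_lt(abs(spike_threshold(sw) - (-44)), 0.5)

  # slow depolarization never reaching 10 mV/ms: criterion unattainable
  n <- 5000
  v <- c(rep(-65, 2000), seq(-65, 10, by = 5 * 0.1), rep(10, 50))
  v <- c(v, seq(10, -65, length.out = 200), rep(-65, n))[1:n]
  slow <- mnphys:::new_sweep(1e-4, v, rep(0, n), 1L, "TEST")
  expect_error(spike_threshold(slow), "10 mV/ms")
})

test_that("shifting the generator threshold shifts the measurement equally", {
  base <- make_cell("immediate", delta_v = 18)
  up <- make_cell("immediate", delta_v = 23)
  th <- vapply(list(base, up), function(cl) {
    sw <- mnphys:::with_seed(11, mnphys:::template_step_sweep(
      as.list(cl), cl$rheobase_true))
    spike_threshold(sw)
  }, numeric(1))
  expect_lt(abs((th[2] - th[1]) - 5), 1)
})

test_that("input conductance inverts the I-V slope", {
  ohmic <- make_cell("immediate", g_in = 10, noise_sd = 0)  # 100 MOhm
  iv0 <- synthesize_protocol(ohmic, "IV_STEPS", seed = 12, noise = FALSE)
  expect_equal(input_conductance(iv0), 10, tolerance = 1e-6)

  cell <- make_cell("immediate", g_in = 33)
  iv <- synthesize_protocol(cell, "IV_STEPS", seed = 13)
  expect_lt(abs(input_conductance(iv) - 33) / 33, 0.02)

  one_amp <- iv0
  one_amp$sweeps <- iv0$sweeps[1:10]   # single amplitude
  expect_error(input_conductance(one_amp), "amplitudes")
})

test_that("AP shape is measured on the aligned trial average", {
  cell <- make_cell("immediate", ap_amplitude = 89, ap_halfwidth = 1.4,
                    v_rest = -65)
  sa <- synthesize_protocol(cell, "SINGLE_AP", seed = 14)
  sh <- ap_shape(sa)
  expect_lt(abs(sh$amplitude - 89), 0.5)
  expect_lt(abs(sh$halfwidth - 1.4), 0.15)

  # symmetric triangular spike: half-width = half the base duration
  n <- 4000; dt <- 1e-4
  w <- 20L  # 2 ms up, 2 ms down
  tri <- c(seq(0, 80, length.out = w + 1), seq(80, 0, length.out = w + 1)[-1]) - 65
  v <- rep(-65, n); v[2001:(2001 + length(tri) - 1)] <- tri
  sw <- mnphys:::new_sweep(dt, v, rep(0, n), 1L, "SINGLE_AP")
  sh2 <- ap_shape(list(sw))
  expect_equal(sh2$amplitude, 80, tolerance = 1e-6)
  expect_equal(sh2$halfwidth, 2, tolerance = 0.15)

  # averaging property: 30 identical noiseless trials == single trial
  cell0 <- make_cell("immediate", noise_sd = 0)
  sa0 <- synthesize_protocol(cell0, "SINGLE_AP", seed = 15, noise = FALSE)
  one <- ap_shape(sa0$sweeps[1])
  all30 <- ap_shape(sa0)
  expect_equal(all30$amplitude, one$amplitude, tolerance = 1e-9)
  expect_equal(all30$halfwidth, one$halfwidth, tolerance = 1e-9)
})

test_that("the AHP mono-exponential fit recovers tau across the printed range", {
  mk <- function(tau, noise) {
    cell <- make_cell("immediate", ahp_tau = tau, noise_sd = noise)
    sa <- synthesize_protocol(cell, "SINGLE_AP", seed = 16,
                              noise = noise > 0)
    sh <- ap_shape(sa)
    fit_ahp(sh$avg_sweep, baseline = sh$baseline)
  }
  expect_lt(abs(mk(37, 0) - 37) / 37, 0.005)
  expect_lt(abs(mk(17, 0.3) - 17), 1)
  for (tau in c(11, 30, 60, 91)) {
    expect_lt(abs(mk(tau, 0.3) - tau) / tau, 0.05)
  }
  flat <- make_flat_sweep(-65, n = 5000, spike_at = 0.2)
  expect_error(fit_ahp(flat), "trough|fit")
})
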