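# Template-mode trace synthesis.
#
# Sweeps are composed analytically: an RC subthreshold trajectory (time
# constant tau_m) toward V_rest + I/G_in, stereotyped action potentials
# grafted at scheduled onset times, and a mono-exponential AHP recovery
# (time constant ahp_tau) between spikes. The spike upstroke is an
# exponential runaway (time constant tau_up = 0.3 ms) whose derivative grows
# through 10 mV/ms exactly at the rendered threshold voltage; the
# repolarization is linear with its slope set so the width at half-amplitude
# equals the cell's ap_halfwidth.

new_sweep <- function(dt, voltage, current, sweep_index = 1L,
                      protocol_id = "unknown", meta = list()) {
  stopifnot(length(voltage) == length(current), dt > 0)
  structure(list(dt = dt, voltage = voltage, current = current,
                 sweep_index = as.integer(sweep_index),
                 protocol_id = protocol_id, meta = meta),
            class = "mn_sweep")
}

#' @export
print.mn_sweep <- function(x, ...) {
  cat("<mn_sweep> ", x$protocol_id, " #", x$sweep_index, ": ",
      length(x$voltage), " samples @ ", 1 / x$dt, " Hz, ",
      signif(length(x$voltage) * x$dt, 4), " s\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.mn_sweep <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$voltage) - 1) * x$dt,
                 voltage = x$voltage, current = x$current)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

sweep_time <- function(sweep) (seq_along(sweep$voltage) - 1) * sweep$dt

# Geometry of the stereotyped AP waveform for one cell.
#
# The upstroke obeys dV/dt = (V - v_base)/tau_up with v_base set
# 10*tau_up mV below the rendered threshold, so the derivative grows
# smoothly through 10 mV/ms exactly when V crosses the threshold. The graft
# starts 0.5 mV above v_base (derivative ~1.7 mV/ms, continuous with the
# subthreshold trajectory).
spike_geometry <- function(cell, dt) {
  dtm <- dt * 1000
  tau_up <- 0.3                        # ms
  d_base <- 10 * tau_up                # 3 mV below threshold
  d_start <- 0.5
  v_base <- cell$v_threshold_render - d_base
  peak <- cell$v_rest + cell$ap_amplitude
  half <- cell$v_rest + cell$ap_amplitude / 2
  vb <- v_base + d_start               # upstroke foot (graft level)
  if (peak <= vb + 1) abort("AP peak not above threshold; invalid cell")
  n_up <- ceiling(tau_up / dtm * log((peak - v_base) / d_start))
  v_up <- v_base + d_start * exp(dtm * seq_len(n_up) / tau_up)
  v_up <- pmin(v_up, peak)
  v_up[n_up] <- peak
  t_rise_half <- tau_up * log((peak - v_base) / max(half - v_base, 0.5))
  t_fall_half <- max(cell$ap_halfwidth - t_rise_half, 0.15)
  slope_fall <- (peak - half) / t_fall_half        # mV/ms
  trough <- cell$v_rest - cell$ahp_amplitude
  n_fall <- ceiling((peak - trough) / (slope_fall * dtm))
  v_fall <- pmax(peak - slope_fall * dtm * seq_len(n_fall), trough)
  v_fall[n_fall] <- trough
  list(core = c(v_up, v_fall), peak_offset = n_up, trough = trough,
       foot = vb, foot_gap = cell$v_threshold_render - vb)
}

# Graft scheduled spikes (+ AHP recoveries) into a subthreshold trajectory.
# onsets: sample indices where the upstroke leaves the foot voltage.
# baseline: inter-spike recovery target (mV); seg_end: last sample index that
# may carry firing (end of pulse / derecruitment).
graft_spikes <- function(v, dt, onsets, geom, cell, baseline, seg_end) {
  dtm <- dt * 1000
  n <- length(v)
  n_core <- length(geom$core)
  peaks <- integer(length(onsets))
  troughs <- integer(length(onsets))
  for (k in seq_along(onsets)) {
    i0 <- onsets[k]
    stop_at <- if (k < length(onsets)) onsets[k + 1] - 1L else min(seg_end, n)
    if (i0 > stop_at) next
    m <- min(n_core, stop_at - i0 + 1L)
    v[i0:(i0 + m - 1L)] <- geom$core[seq_len(m)]
    peaks[k] <- i0 + min(geom$peak_offset, m) - 1L
    i_tr <- i0 + n_core - 1L
    troughs[k] <- min(i_tr, stop_at)
    if (i_tr < stop_at) {
      idx <- (i_tr + 1L):stop_at
      tms <- dtm * seq_along(idx)
      v[idx] <- baseline - (baseline - geom$trough) * exp(-tms / cell$ahp_tau)
    }
  }
  ok <- peaks > 0L
  list(v = v, peaks = peaks[ok], troughs = troughs[ok])
}

# Damped subthreshold oscillations added inside inter-spike windows.
add_mmo <- function(v, dt, windows, amplitude, freq = 150, tau_damp = 0.04) {
  for (w in windows) {
    if (w[2] - w[1] < 5) next
    idx <- w[1]:w[2]
    t <- dt * (seq_along(idx) - 1)
    v[idx] <- v[idx] + amplitude * exp(-t / tau_damp) * sin(2 * pi * freq * t)
  }
  v
}

# RC charging curve (deflection from rest, mV) for a step of I nA.
rc_deflection <- function(t, i_na, g_ns, tau_m_ms) {
  1000 * i_na / g_ns * (1 - exp(-1000 * t / tau_m_ms))
}

# First-spike latency law for delayed cells: linear decay in current,
# vanishing at twice rheobase.
delayed_latency <- function(cell, i_na) {
  cell$delay_scale * max(0, (2 * cell$rheobase_true - i_na) / cell$rheobase_true)
}

# Onset schedule (sample indices, relative to pulse onset) for a square pulse.
step_schedule <- function(cell, i_na, dur, dt) {
  if (i_na < cell$rheobase_true - 1e-12) return(integer(0))
  dv_inf <- 1000 * i_na / cell$g_in
  if (cell$pattern == "immediate") {
    # first crossing of (emission threshold - foot) on the RC trajectory
    gap <- max(cell$delta_v - 2.5, 0.5)
    frac <- min(gap / dv_inf, 0.999)
    t1 <- -cell$tau_m / 1000 * log(1 - frac)
    f <- max(15 + cell$gain_true * (i_na - cell$rheobase_true), 3)
    if (t1 >= dur) return(integer(0))
    tt <- seq(t1, dur - 0.002, by = 1 / f)
    round(tt / dt) + 1L
  } else {
    t1 <- max(delayed_latency(cell, i_na), 0.1)
    if (t1 >= dur) return(integer(0))
    f_asym <- max(cell$f_half_second_true + 20 * (i_na - cell$rheobase_true), 5)
    # instantaneous rate accelerates from 0.6x to 1x of asymptote over the
    # remainder of the pulse
    tt <- numeric(0)
    t <- t1
    while (t < dur - 0.002) {
      tt <- c(tt, t)
      frac <- (t - t1) / max(dur - t1, 0.5)
      f <- f_asym * (0.6 + 0.4 * min(frac, 1))
      t <- t + 1 / f
    }
    round(tt / dt) + 1L
  }
}

# Render one square-pulse sweep in template mode.
template_step_sweep <- function(cell, i_na, pre = 0.5, dur = 5, post = 0.5,
                                dt = 1e-4, sweep_index = 1L,
                                protocol_id = "RHEO_STEPS",
                                noise = TRUE, allow_mmo = TRUE) {
  n_pre <- round(pre / dt)
  n_dur <- round(dur / dt)
  n_post <- round(post / dt)
  n <- n_pre + n_dur + n_post
  current <- c(rep(0, n_pre), rep(i_na, n_dur), rep(0, n_post))
  t_pulse <- dt * seq_len(n_dur)
  v <- rep(cell$v_rest, n)
  defl <- rc_deflection(t_pulse, i_na, cell$g_in, cell$tau_m)
  geom <- spike_geometry(cell, dt)
  onsets_rel <- step_schedule(cell, i_na, dur, dt)
  fires <- length(onsets_rel) > 0

  if (fires && cell$pattern == "delayed") {
    # plateau below the rendered threshold, then a slow depolarizing creep
    # reaching the upstroke foot at the scheduled first-spike time
    t1 <- dt * (onsets_rel[1] - 1L)
    plateau <- geom$foot - 3
    sub <- pmin(defl, plateau - cell$v_rest)
    t_creep0 <- min(0.1, 0.5 * t1)
    creep_idx <- which(t_pulse >= t_creep0 & t_pulse <= t1)
    if (length(creep_idx) > 1) {
      v0 <- sub[creep_idx[1]]
      sub[creep_idx] <- v0 + (geom$foot - cell$v_rest - v0) *
        (t_pulse[creep_idx] - t_pulse[creep_idx[1]]) / (t1 - t_pulse[creep_idx[1]])
    }
    v[n_pre + seq_len(n_dur)] <- cell$v_rest + pmin(sub, geom$foot - cell$v_rest)
  } else {
    v[n_pre + seq_len(n_dur)] <- cell$v_rest + pmin(defl, geom$foot - cell$v_rest)
  }

  peaks <- integer(0); troughs <- integer(0)
  if (fires) {
    onsets <- n_pre + onsets_rel
    baseline <- cell$v_threshold_render - 3
    g <- graft_spikes(v, dt, onsets, geom, cell, baseline, n_pre + n_dur)
    v <- g$v; peaks <- g$peaks; troughs <- g$troughs
    if (allow_mmo && isTRUE(cell$mmo_present) &&
        i_na <= 1.2 * cell$rheobase_true && length(onsets) > 1) {
      wins <- mmo_windows(troughs, onsets, dt)
      v <- add_mmo(v, dt, wins, cell$mmo_amplitude)
    }
  }
  # relaxation back to rest after the pulse
  if (n_post > 0) {
    i_end <- n_pre + n_dur
    v[(i_end + 1):n] <- cell$v_rest + (v[i_end] - cell$v_rest) *
      exp(-1000 * dt * seq_len(n_post) / cell$tau_m)
  }
  if (noise && cell$noise_sd > 0) v <- v + rnorm(n, 0, cell$noise_sd)
  new_sweep(dt, v, current, sweep_index, protocol_id,
            meta = list(amplitude = i_na, t_on = pre, t_off = pre + dur,
                        spike_peak_times = (peaks - 1) * dt,
                        n_spikes = length(peaks)))
}

# Inter-spike oscillation windows: skip 6 ms after the trough (~9 ms after
# the peak) and stop 3 ms before the next upstroke foot.
mmo_windows <- function(troughs, onsets, dt) {
  wins <- list()
  for (k in seq_len(length(onsets) - 1)) {
    a <- troughs[k] + round(0.006 / dt)
    b <- onsets[k + 1] - round(0.003 / dt)
    if (b - a > 5) wins[[length(wins) + 1]] <- c(a, b)
  }
  wins
}

# Render one triangular-ramp sweep (0 -> peak -> 0 at `speed` nA/s).
template_ramp_sweep <- function(cell, speed = 0.1, peak = NULL, pre = 1,
                                post = 1, dt = 1e-4, sweep_index = 1L,
                                noise = TRUE, mmo_boundary = NULL) {
  if (is.null(peak)) peak <- max(1, 1.5 * cell$rheobase_true)
  n_pre <- round(pre / dt)
  n_up <- round(peak / speed / dt)
  n_post <- round(post / dt)
  n <- n_pre + 2 * n_up + n_post
  tt <- dt * (seq_len(n) - 1)
  t_on <- pre
  t_peak <- pre + peak / speed
  t_off <- pre + 2 * peak / speed
  current <- pmax(0, peak - abs(tt - t_peak) * speed) * (tt >= t_on & tt <= t_off)
  geom <- spike_geometry(cell, dt)

  # quasi-static subthreshold trajectory (ramp is slow vs tau_m)
  v <- cell$v_rest + pmin(1000 * current / cell$g_in, geom$foot - cell$v_rest)

  r <- cell$rheobase_true
  i_first <- which(tt >= t_on & current >= r)[1]
  peaks <- integer(0); troughs <- integer(0); onsets <- integer(0)
  if (!is.na(i_first)) {
    # firing persists on the descending phase down to 0.85x rheobase
    fire_ok <- current >= 0.85 * r & tt >= tt[i_first]
    i_last <- max(which(fire_ok))
    idx <- i_first:i_last
    t_rec <- tt[i_first]
    if (cell$pattern == "immediate") {
      f <- pmax(10 + cell$gain_true * (current[idx] - r), 3)
    } else {
      f <- cell$f_half_second_true *
        (0.6 + 0.4 * pmin((tt[idx] - t_rec) / 0.5, 1)) *
        (1 + 0.15 * (current[idx] - r))
      f <- pmax(f, 3)
    }
    phase <- cumsum(f * dt)
    ks <- seq_len(floor(phase[length(phase)]))
    later <- idx[findInterval(ks, phase) + 1L]
    onsets <- unique(c(i_first, later[!is.na(later)]))
    g <- graft_spikes(v, dt, onsets, geom, cell, cell$v_threshold_render - 3,
                      i_last)
    v <- g$v; peaks <- g$peaks; troughs <- g$troughs
    # past derecruitment the trace rejoins the quasi-static trajectory
    if (i_last < n) {
      tail_idx <- (i_last + 1L):n
      v[tail_idx] <- cell$v_rest +
        pmin(1000 * current[tail_idx] / cell$g_in, geom$foot - cell$v_rest)
    }
    if (isTRUE(cell$mmo_present) && length(onsets) > 1) {
      if (is.null(mmo_boundary)) mmo_boundary <- Inf
      wins <- mmo_windows(troughs, onsets, dt)
      # oscillations belong to the low-current (sub-primary) discharge
      keep <- vapply(wins, function(w) current[w[2]] <= mmo_boundary, logical(1))
      v <- add_mmo(v, dt, wins[keep], cell$mmo_amplitude)
    }
  }
  if (noise && cell$noise_sd > 0) v <- v + rnorm(n, 0, cell$noise_sd)
  new_sweep(dt, v, current, sweep_index, "RAMP",
            meta = list(speed = speed, peak = peak, t_on = t_on,
                        t_peak = t_peak, t_off = t_off,
                        spike_peak_times = (peaks - 1) * dt,
                        mmo_boundary = mmo_boundary))
}

# Render one short-pulse (1 ms) single-AP sweep.
template_single_ap_sweep <- function(cell, i_na = 2, pre = 0.15, total = 0.5,
                                     dt = 1e-4, sweep_index = 1L,
                                     noise = TRUE) {
  n <- round(total / dt)
  n_pre <- round(pre / dt)
  n_pulse <- round(0.001 / dt)
  current <- rep(0, n)
  current[n_pre + seq_len(n_pulse)] <- i_na
  v <- rep(cell$v_rest, n)
  onset <- n_pre + n_pulse + 1L
  geom <- spike_geometry(cell, dt)
  # fast charge toward the upstroke foot during the strong 1 ms pulse
  v[n_pre + seq_len(n_pulse)] <- cell$v_rest +
    (geom$foot - cell$v_rest) * seq_len(n_pulse) / n_pulse
  g <- graft_spikes(v, dt, onset, geom, cell, cell$v_rest, n)
  v <- g$v
  if (noise && cell$noise_sd > 0) v <- v + rnorm(n, 0, cell$noise_sd)
  new_sweep(dt, v, current, sweep_index, "SINGLE_AP",
            meta = list(amplitude = i_na, t_on = pre, t_off = pre + 0.001,
                        spike_peak_times = (g$peaks - 1) * dt))
}
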