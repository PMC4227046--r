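#' Resting membrane potential from the pre-pulse baseline
#'
#' Mean voltage over the 200 ms immediately preceding current onset.
#'
#' @param sweep an `mn_sweep`.
#' @param window baseline duration in seconds (default 0.2).
#' @return resting potential in mV.
#' @export
resting_potential <- function(sweep, window = 0.2) {
  stopifnot(inherits(sweep, "mn_sweep"))
  on_idx <- which(sweep$current != 0)[1]
  if (is.na(on_idx)) on_idx <- length(sweep$voltage) + 1L
  n_win <- round(window / sweep$dt)
  if (on_idx - 1L < n_win) {
    abort(sprintf("pre-pulse baseline shorter than %g ms", window * 1000))
  }
  mean(sweep$voltage[(on_idx - n_win):(on_idx - 1L)])
}

#' Detect action potentials in a sweep
#'
#' Spikes are local voltage maxima exceeding `min_overshoot` (overshooting
#' action potentials), separated by at least `refractory` seconds.
#'
#' @param sweep an `mn_sweep`.
#' @param min_overshoot peak criterion in mV (0 = overshooting).
#' @param refractory minimal peak separation in seconds.
#' @return An `mn_spike_train` tibble: `t_peak` (s), `v_peak` (mV), `i_peak`
#'   (sample index), `freq_inst` (Hz; inverse of the ISI *ending* at that
#'   spike, `NA` for the first spike).
#' @export
detect_spikes <- function(sweep, min_overshoot = 0, refractory = 0.001) {
  stopifnot(inherits(sweep, "mn_sweep"))
  v <- sweep$voltage
  cand <- local_maxima(v)
  cand <- cand[v[cand] > min_overshoot]
  keep <- integer(0)
  last_t <- -Inf
  min_gap <- refractory / sweep$dt
  for (i in cand) {
    if (i - last_t >= min_gap) {
      keep <- c(keep, i)
      last_t <- i
    }
  }
  t_peak <- (keep - 1) * sweep$dt
  out <- tibble::tibble(
    t_peak = t_peak,
    v_peak = v[keep],
    i_peak = keep,
    freq_inst = c(NA_real_, 1 / diff(t_peak))
  )
  attr(out, "dt") <- sweep$dt
  class(out) <- c("mn_spike_train", class(out))
  out
}

#' Voltage threshold for spiking (dV/dt criterion)
#'
#' The spiking threshold is the membrane potential at which the first time
#' derivative of the voltage exceeds `criterion` (10 mV/ms by convention),
#' evaluated on the upstroke of a given spike. The derivative is a central
#' difference computed after light boxcar smoothing (0.2 ms), and the
#' crossing voltage is linearly interpolated between samples.
#'
#' @param sweep an `mn_sweep`.
#' @param spike either a spike-train row index into `spikes`, or a peak
#'   sample index; by default the first detected spike.
#' @param spikes optional precomputed [detect_spikes()] result.
#' @param criterion derivative criterion in mV/ms.
#' @param smooth_ms boxcar width for derivative smoothing (ms).
#' @param search_ms how far before the peak the upstroke may start (ms).
#' @return threshold voltage in mV.
#' @export
spike_threshold <- function(sweep, spike = 1L, spikes = NULL, criterion = 10,
                            smooth_ms = 0.2, search_ms = 5) {
  stopifnot(inherits(sweep, "mn_sweep"))
  if (is.null(spikes)) spikes <- detect_spikes(sweep)
  if (nrow(spikes) == 0) abort("no spike in sweep")
  i_peak <- spikes$i_peak[spike]
  dt_ms <- sweep$dt * 1000
  i0 <- max(1L, i_peak - round(search_ms / dt_ms))
  v <- sweep$voltage[i0:i_peak]
  if (length(v) < 5) abort("upstroke window too short for the derivative")
  vs <- boxcar(v, round(smooth_ms / dt_ms) + 1)
  n <- length(vs)
  dv <- c(NA, (vs[3:n] - vs[1:(n - 2)]) / (2 * dt_ms), NA)
  hit <- which(dv >= criterion)[1]
  if (is.na(hit)) {
    abort(sprintf("dV/dt never reached %g mV/ms before the spike peak",
                  criterion))
  }
  if (hit == 1 || is.na(dv[hit - 1])) return(vs[hit])
  # linear interpolation of the voltage at the exact criterion crossing
  frac <- (criterion - dv[hit - 1]) / (dv[hit] - dv[hit - 1])
  vs[hit - 1] + frac * (vs[hit] - vs[hit - 1])
}

#' Input conductance from the I-V step protocol
#'
#' For each pulse amplitude the steady-state voltage deflection is the mean
#' over the last 100 ms of the pulse (averaged across the 10 repeats); the
#' input conductance is the inverse of the slope of the least-squares line of
#' steady-state voltage on injected current.
#'
#' @param iv an `mn_protocol` with descriptor `IV_STEPS` (or a list of step
#'   sweeps with at least 3 distinct amplitudes).
#' @param ss_window steady-state window in seconds (end of pulse).
#' @return input conductance in nS.
#' @export
input_conductance <- function(iv, ss_window = 0.1) {
  sweeps <- if (inherits(iv, "mn_protocol")) iv$sweeps else iv
  meas <- purrr::map_dfr(sweeps, function(sw) {
    on <- which(sw$current != 0)
    if (length(on) == 0) {
      return(tibble::tibble(amplitude = 0, v_ss = NA_real_))
    }
    i_off <- max(on)
    n_win <- round(ss_window / sw$dt)
    idx <- (i_off - n_win + 1L):i_off
    tibble::tibble(amplitude = sw$current[on[1]],
                   v_ss = mean(sw$voltage[idx]))
  })
  meas <- dplyr::filter(meas, is.finite(.data$v_ss))
  by_amp <- dplyr::summarise(dplyr::group_by(meas, .data$amplitude),
                             v_ss = mean(.data$v_ss), .groups = "drop")
  if (nrow(by_amp) < 3) abort("need at least 3 distinct pulse amplitudes")
  x <- by_amp$amplitude
  y <- by_amp$v_ss
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("degenerate I-V fit: all amplitudes equal")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx   # mV per nA = MOhm
  1000 / slope                                        # nS
}

#' Action-potential amplitude and width at half-amplitude
#'
#' Averages the aligned single-AP trials (alignment on the peak sample),
#' then measures amplitude = peak minus baseline and half-width = time spent
#' above baseline + amplitude/2.
#'
#' @param single_aps an `mn_protocol` with descriptor `SINGLE_AP` (or list of
#'   sweeps, each containing exactly one spike).
#' @param baseline_window pre-pulse window used for the baseline (s).
#' @return A list with `amplitude` (mV), `halfwidth` (ms), and the averaged
#'   waveform (`avg_sweep`, an `mn_sweep` usable by [fit_ahp()]).
#' @export
ap_shape <- function(single_aps, baseline_window = 0.1) {
  sweeps <- if (inherits(single_aps, "mn_protocol")) single_aps$sweeps else
    single_aps
  if (length(sweeps) == 0) abort("no sweeps supplied")
  dt <- sweeps[[1]]$dt
  peaks <- purrr::map_int(sweeps, function(sw) {
    sp <- detect_spikes(sw)
    if (nrow(sp) != 1) {
      abort(sprintf("sweep %d does not contain exactly one spike",
                    sw$sweep_index))
    }
    sp$i_peak[1]
  })
  if (diff(range(peaks)) * dt > 0.01) {
    abort("trials misaligned by more than 10 ms")
  }
  span_l <- min(peaks) - 1L
  span_r <- min(purrr::map_int(sweeps, ~ length(.x$voltage)) - peaks)
  avg <- rowMeans(do.call(cbind, purrr::map2(sweeps, peaks, function(sw, p) {
    sw$voltage[(p - span_l):(p + span_r)]
  })))
  cur <- sweeps[[1]]$current[(peaks[1] - span_l):(peaks[1] + span_r)]
  avg_sweep <- new_sweep(dt, avg, cur, 1L, "SINGLE_AP_AVG",
                         meta = sweeps[[1]]$meta)
  n_base <- round(baseline_window / dt)
  on_idx <- which(cur != 0)[1]
  # without a recorded stimulus, take the baseline up to 5 ms before the peak
  base_end <- if (is.na(on_idx)) max(span_l - round(0.005 / dt), 1L) else
    on_idx - 1L
  baseline <- mean(avg[max(1, base_end - n_base):base_end])
  i_peak <- which.max(avg)
  amplitude <- avg[i_peak] - baseline
  half <- baseline + amplitude / 2
  above <- avg >= half
  # the contiguous run of supra-half samples containing the peak
  lo <- i_peak; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i_peak; while (hi < length(avg) && above[hi + 1]) hi <- hi + 1
  list(amplitude = amplitude, halfwidth = (hi - lo + 1) * dt * 1000,
       avg_sweep = avg_sweep, baseline = baseline)
}

#' Relaxation time constant of the after-hyperpolarization
#'
#' Fits a mono-exponential `V(t) = B - A * exp(-(t - t0)/tau)` to the AHP
#' relaxation, from the post-spike trough until the voltage has recovered to
#' within 5% of the trough depth (or the next stimulus, whichever comes
#' first), and returns tau in ms.
#'
#' @param avg_sweep averaged sweep (e.g. `ap_shape()$avg_sweep`).
#' @param spike peak sample index, or `NULL` to use the detected first spike.
#' @param baseline optional baseline voltage (mV); estimated from the fit
#'   when `NULL`.
#' @return fitted time constant in ms.
#' @export
fit_ahp <- function(avg_sweep, spike = NULL, baseline = NULL) {
  stopifnot(inherits(avg_sweep, "mn_sweep"))
  v <- avg_sweep$voltage
  dt <- avg_sweep$dt
  if (is.null(spike)) {
    sp <- detect_spikes(avg_sweep)
    if (nrow(sp) == 0) abort("no spike in sweep")
    spike <- sp$i_peak[1]
  }
  # locate the trough on a lightly smoothed trace: the raw argmin rides on
  # noise dips and would bias the fit start downward
  vs <- boxcar(v, round(0.001 / dt) + 1)
  post <- vs[spike:length(v)]
  i_tr <- which.min(post) + spike - 1L
  b_ref <- if (is.null(baseline)) mean(v[max(1, spike - 200):max(1, spike - 50)]) else baseline
  depth <- b_ref - vs[i_tr]
  if (depth < 0.5) abort("no AHP trough after the spike")
  # fit window: trough -> recovery to 5% of depth (or next stimulus)
  rec <- which(vs[i_tr:length(v)] >= b_ref - 0.05 * depth)[1]
  nxt <- which(avg_sweep$current[i_tr:length(v)] != 0)[1]
  if (is.na(rec)) rec <- Inf
  if (is.na(nxt)) nxt <- Inf
  i_end <- min(i_tr + min(rec, nxt, length(v) - i_tr), length(v))
  if (i_end - i_tr < 20) abort("AHP window too short to fit")
  idx <- i_tr:i_end
  t_ms <- (idx - i_tr) * dt * 1000
  # the relaxation asymptote is the resting potential, measured before the
  # spike and held fixed: leaving it free makes tau poorly identified on a
  # window truncated near recovery
  df <- data.frame(t = t_ms, v = v[idx] - b_ref)
  tau0 <- max(t_ms[which(vs[idx] >= b_ref - depth * exp(-1))[1]], 1)
  fit <- tryCatch(
    nls(v ~ -A * exp(-t / tau), data = df,
        start = list(A = depth, tau = tau0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ -A * exp(-t / tau), data = df,
                        start = list(A = depth, tau = tau0)),
      error = function(e) NULL)
  }
  if (is.null(fit)) abort("mono-exponential AHP fit did not converge")
  unname(coef(fit)["tau"])
}
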