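#' Synthesize the voltage response of a model cell to an acquisition protocol
#'
#' Generates the full sweep set for one of the four acquisition protocols used
#' to characterize motoneuron excitability:
#'
#' * `IV_STEPS` — 500 ms subthreshold pulses, -100 pA to +20 pA in 30 pA
#'   steps, each repeated 10 times (input-conductance protocol);
#' * `RHEO_STEPS` — 5 s square pulses of the requested amplitudes
#'   (rheobase-search protocol);
#' * `SINGLE_AP` — 30 repeats of a 1 ms suprathreshold pulse (AP shape / AHP
#'   protocol);
#' * `RAMP` — triangular current ramps at 0.1 nA/s (three trials).
#'
#' `template` mode composes the traces analytically (RC charging, stereotyped
#' AP/AHP waveforms, scheduled discharge; see the package vignette).
#' `mechanistic` mode integrates a leaky integrate-and-fire model carrying a
#' slowly inactivating potassium conductance that reproduces the delayed
#' firing phenotype; it supports the square-pulse descriptors.
#'
#' @param cell one row of a [sample_population()] tibble (or an equivalent
#'   named list of ground-truth parameters).
#' @param descriptor protocol descriptor.
#' @param mode `"template"` or `"mechanistic"`.
#' @param seed integer seed (defaults to the cell's own seed).
#' @param dt sample interval in seconds (10 kHz digitization by default).
#' @param amplitudes square-pulse amplitudes in nA (`RHEO_STEPS` only).
#' @param n_trials number of ramp trials or single-AP repeats.
#' @param noise add Gaussian recording noise of the cell's `noise_sd`.
#' @param ... renderer options passed through (e.g. `peak`, `speed`,
#'   `mmo_boundary` for ramps).
#' @return An `mn_protocol` object: list of `mn_sweep`s plus protocol
#'   parameters.
#' @export
#' @examples
#' cell <- sample_population(group_spec("WT", "immediate"), 1, seed = 2)
#' iv <- synthesize_protocol(cell, "IV_STEPS")
#' length(iv$sweeps)
synthesize_protocol <- function(cell,
                                descriptor = c("IV_STEPS", "RHEO_STEPS",
                                               "SINGLE_AP", "RAMP"),
                                mode = c("template", "mechanistic"),
                                seed = NULL, dt = 1e-4, amplitudes = NULL,
                                n_trials = NULL, noise = TRUE, ...) {
  descriptor <- match.arg(descriptor)
  mode <- match.arg(mode)
  cell <- as_model_cell(cell)
  if (is.null(seed)) seed <- cell$seed
  if (mode == "mechanistic" && descriptor %in% c("RAMP", "SINGLE_AP")) {
    abort(paste0("mechanistic mode does not support descriptor ", descriptor))
  }
  if (descriptor == "RAMP") {
    if (cell$pattern == "immediate" && !is.finite(cell$gain_true %||% NA)) {
      abort("ramp requested for an immediate cell with undefined gain")
    }
    if (cell$pattern == "delayed" &&
        !is.finite(cell$f_half_second_true %||% NA)) {
      abort("ramp requested for a delayed cell with undefined ramp frequency")
    }
  }
  with_seed(seed, {
    sweeps <- switch(descriptor,
      IV_STEPS = {
        amps <- rep(seq(-0.1, 0.02, by = 0.03), each = 10)
        purrr::imap(amps, function(a, i) {
          synth_step(cell, a, mode, pre = 0.2, dur = 0.5, post = 0.2, dt = dt,
                     sweep_index = i, protocol_id = "IV_STEPS", noise = noise)
        })
      },
      RHEO_STEPS = {
        if (is.null(amplitudes)) amplitudes <- rheobase_grid()
        purrr::imap(amplitudes, function(a, i) {
          synth_step(cell, a, mode, pre = 0.5, dur = 5, post = 0.5, dt = dt,
                     sweep_index = i, protocol_id = "RHEO_STEPS", noise = noise)
        })
      },
      SINGLE_AP = {
        k <- n_trials %||% 30
        purrr::map(seq_len(k), function(i) {
          template_single_ap_sweep(cell, dt = dt, sweep_index = i,
                                   noise = noise)
        })
      },
      RAMP = {
        k <- n_trials %||% 3
        mmo_boundary <- ramp_mmo_boundary(cell, ...)
        purrr::map(seq_len(k), function(i) {
          template_ramp_sweep(cell, dt = dt, sweep_index = i, noise = noise,
                              mmo_boundary = mmo_boundary, ...)
        })
      }
    )
    params <- switch(descriptor,
      IV_STEPS = list(amplitudes = seq(-0.1, 0.02, by = 0.03), repeats = 10,
                      pulse_dur = 0.5),
      RHEO_STEPS = list(amplitudes = amplitudes %||% rheobase_grid(),
                        pulse_dur = 5, interpulse = 20),
      SINGLE_AP = list(amplitude = 2, pulse_dur = 0.001,
                       repeats = n_trials %||% 30),
      RAMP = list(speed = 0.1, trials = n_trials %||% 3)
    )
    structure(list(descriptor = descriptor, sweeps = sweeps, params = params,
                   mode = mode, cell_id = cell$id %||% NA_character_),
              class = "mn_protocol")
  })
}

#' @export
print.mn_protocol <- function(x, ...) {
  cat("<mn_protocol> ", x$descriptor, " (", x$mode, "): ",
      length(x$sweeps), " sweeps\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Sub-primary/primary boundary rendered on ramps: MMO-positive immediate cells
# express oscillations over the lower part of the ascending discharge; in
# delayed cells they persist up to the ramp peak (no primary range).
ramp_mmo_boundary <- function(cell, peak = NULL, ...) {
  if (!isTRUE(cell$mmo_present)) return(-Inf)
  if (cell$pattern == "delayed") return(Inf)
  if (is.null(peak)) peak <- max(1, 1.5 * cell$rheobase_true)
  r <- cell$rheobase_true
  r + runif(1, 0.25, 0.5) * (peak - r)
}

synth_step <- function(cell, i_na, mode, pre, dur, post, dt, sweep_index,
                       protocol_id, noise) {
  if (mode == "template") {
    return(template_step_sweep(cell, i_na, pre, dur, post, dt, sweep_index,
                               protocol_id, noise))
  }
  mechanistic_step_sweep(cell, i_na, pre, dur, post, dt, sweep_index,
                         protocol_id, noise)
}

# Mechanistic mode: LIF + slowly inactivating K conductance; the subthreshold
# integration decides when spikes occur, the stereotyped waveform is grafted
# at the crossings so downstream detectors see realistic APs.
mechanistic_step_sweep <- function(cell, i_na, pre, dur, post, dt, sweep_index,
                                   protocol_id, noise) {
  n_pre <- round(pre / dt); n_dur <- round(dur / dt); n_post <- round(post / dt)
  current <- c(rep(0, n_pre), rep(i_na, n_dur), rep(0, n_post))
  e_k <- -90
  if (cell$pattern == "delayed") {
    g_k <- 100 / (cell$v_threshold - e_k)      # ~0.1 nA of K current at V_th
    tau_h <- max(cell$delay_scale, 0.2) / log(2)
  } else {
    g_k <- 0
    tau_h <- 1
  }
  out <- lif_integrate(current, dt, cell$v_rest, cell$g_in, cell$tau_m,
                       cell$v_threshold, cell$v_rest - cell$ahp_amplitude,
                       g_k, e_k, tau_h)
  v <- out$voltage
  geom <- spike_geometry(cell, dt)
  onsets <- out$spike_idx + 1L
  peaks <- integer(0)
  if (length(onsets) > 0) {
    n_core <- length(geom$core)
    for (i0 in onsets) {
      m <- min(n_core, length(v) - i0 + 1L)
      v[i0:(i0 + m - 1L)] <- geom$core[seq_len(m)]
    }
    peaks <- pmin(onsets + geom$peak_offset - 1L, length(v))
  }
  if (noise && cell$noise_sd > 0) v <- v + rnorm(length(v), 0, cell$noise_sd)
  new_sweep(dt, v, current, sweep_index, protocol_id,
            meta = list(amplitude = i_na, t_on = pre, t_off = pre + dur,
                        spike_peak_times = (peaks - 1) * dt,
                        n_spikes = length(peaks)))
}
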