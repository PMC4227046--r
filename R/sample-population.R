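#' Sample a population of ground-truth model motoneurons
#'
#' Draws `n` model cells from a group specification. Every property is drawn
#' from a normal distribution truncated to the printed range (moment-matched,
#' see [mn_reference_table()]), with the Ohmic constraint
#' `rheobase = g_in * delta_v / 1000` enforced exactly for every cell.
#'
#' The anchoring differs by firing pattern, mirroring the physiology:
#' * **immediate** cells are threshold-anchored: resting potential, spiking
#'   threshold and rheobase are drawn from their rows (rheobase and threshold
#'   rank-correlated), and the input conductance is derived as
#'   `1000 * rheobase / delta_v`. For these cells the measured threshold is the
#'   emission threshold (the zero-intercept slope U of the rheobase-conductance
#'   law is close to the mean delta-V).
#' * **delayed** cells are conductance-anchored: conductance is drawn from
#'   its row, the *emission* delta-V follows the group's `I = G.U` law (`U`
#'   derived from the printed rheobase and conductance means, with a few mV
#'   of cell-to-cell scatter) and the rheobase is their product, so rheobase
#'   grows with conductance as in the rheobase-conductance scatter. Because
#'   the membrane depolarizes for seconds before the first spike, the
#'   rendered first-spike threshold additionally carries an accommodation
#'   offset so that the measured threshold follows the printed (more
#'   depolarized) threshold row.
#'
#' @param spec an [group_spec()] object.
#' @param n number of cells (> 0).
#' @param seed integer seed; the draw is fully reproducible.
#' @param noise_sd recording-noise standard deviation (mV) stored per cell.
#' @param tau_m membrane time constant (ms) used by the trace synthesizer.
#' @param mmo_amplitude peak amplitude (mV) of rendered mixed-mode
#'   oscillations for MMO-positive cells.
#' @return A tibble (class `mn_population`) with one row per cell: identifiers,
#'   group labels, and the ground-truth intrinsic parameters (`v_rest` mV,
#'   `g_in` nS, `v_threshold` mV, `delta_v` mV, `rheobase_true` nA, AP/AHP
#'   shape, `gain_true` Hz/nA, `f_half_second_true` Hz, `mmo_present`,
#'   `delay_scale` s, per-cell `seed`).
#' @export
#' @examples
#' cells <- sample_population(group_spec("WT", "immediate"), n = 5, seed = 1)
#' cells$rheobase_true
sample_population <- function(spec, n, seed = NULL, noise_sd = 0.3,
                              tau_m = 20, mmo_amplitude = 2) {
  stopifnot(inherits(spec, "mn_group_spec"))
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n != round(n)) {
    abort("n must be a positive integer")
  }
  n <- as.integer(n)
  with_seed(seed, {
    v_rest <- draw_property(spec, "v_rest", n)
    rheo <- draw_property(spec, "rheobase", n)

    if (spec$pattern == "immediate") {
      # threshold-anchored: correlate threshold with rheobase (rank rho 0.6)
      rho <- 0.6
      z1 <- qnorm(rank(rheo, ties.method = "random") / (n + 1))
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      v_th <- draw_property_z(spec, "v_threshold", z2)
      delta_v <- v_th - v_rest            # > 0 by the printed ranges
      g_in <- 1000 * rheo / delta_v
      v_th_render <- v_th
      gain_true <- draw_property(spec, "gain", n)
      f_half <- rep(NA_real_, n)
      delay_scale <- rep(0, n)
    } else {
      # conductance-anchored: G is drawn from its row; the emission delta-V
      # follows the group's I = G.U law (U derived from the printed rheobase
      # and conductance means), and rheobase is their product. The rendered
      # first-spike threshold carries the accommodation offset of the slow
      # pre-spike depolarization, drawn from the printed delta-V row.
      g_in <- draw_property(spec, "g_in", n)
      u_law <- 1000 * spec_row(spec, "rheobase")$mean /
        spec_row(spec, "g_in")$mean
      dv_hi <- pmin(u_law + 15, 4500 / g_in)   # keep rheobase below the grid
      delta_v <- numeric(n)
      for (i in seq_len(n)) {
        delta_v[i] <- rtrunc_norm(1, u_law, 4, max(u_law - 10, 8), dv_hi[i],
                                  match_moments = FALSE)
      }
      rheo <- g_in * delta_v / 1000
      v_th <- v_rest + delta_v
      dv_meas <- pmax(draw_property(spec, "delta_v", n), delta_v)
      v_th_render <- v_rest + dv_meas
      gain_true <- rep(NA_real_, n)
      f_half <- draw_property(spec, "f_half_second", n)
      delay_scale <- draw_property(spec, "delay_scale", n)
    }

    amp <- draw_property(spec, "ap_amplitude", n)
    # inclusion criterion: retained motoneurons have overshooting spikes
    amp <- pmax(amp, 5 - v_rest)

    cells <- tibble::tibble(
      id = sprintf("%s_%s_%04d", spec$genotype, substr(spec$pattern, 1, 3),
                   seq_len(n)),
      genotype = spec$genotype,
      pattern = spec$pattern,
      v_rest = v_rest,
      g_in = g_in,
      v_threshold = v_th,
      v_threshold_render = v_th_render,
      delta_v = delta_v,
      rheobase_true = rheo,
      recruitment_true = rheo,
      ap_amplitude = amp,
      ap_halfwidth = draw_property(spec, "ap_halfwidth", n),
      ahp_amplitude = 5,
      ahp_tau = draw_property(spec, "ahp_tau", n),
      gain_true = gain_true,
      f_half_second_true = f_half,
      mmo_present = runif(n) < spec$mmo_prob,
      mmo_amplitude = mmo_amplitude,
      delay_scale = delay_scale,
      soma_area = if (!is.null(spec_row(spec, "soma_area", required = FALSE)))
        draw_property(spec, "soma_area", n) else NA_real_,
      tau_m = tau_m,
      noise_sd = noise_sd,
      seed = sample.int(.Machine$integer.max - 1L, n)
    )
    class(cells) <- c("mn_population", class(cells))
    cells
  })
}

# Coerce a one-row population slice (or list) to the plain list the trace
# synthesizer consumes.
as_model_cell <- function(cell) {
  if (inherits(cell, "data.frame")) {
    if (nrow(cell) != 1) abort("expected exactly one cell")
    cell <- as.list(cell)
  }
  needed <- c("v_rest", "g_in", "v_threshold", "delta_v", "rheobase_true",
              "ap_amplitude", "ap_halfwidth", "ahp_amplitude", "ahp_tau",
              "pattern", "noise_sd", "tau_m")
  missing <- setdiff(needed, names(cell))
  if (length(missing)) {
    abort(paste0("cell is missing fields: ", paste(missing, collapse = ", ")))
  }
  if (is.null(cell$v_threshold_render)) cell$v_threshold_render <- cell$v_threshold
  if (is.null(cell$delay_scale)) cell$delay_scale <- 0
  if (is.null(cell$mmo_present)) cell$mmo_present <- FALSE
  if (is.null(cell$mmo_amplitude)) cell$mmo_amplitude <- 2
  if (is.null(cell$seed)) cell$seed <- NULL
  cell
}
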