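#' Current grid of the rheobase step-search protocol
#'
#' 5 s pulses increase by 50 pA steps from 0; above 0.9 nA the steps widen to
#' 100 pA.
#'
#' @param ceiling largest tested amplitude in nA.
#' @return vector of amplitudes in nA.
#' @export
rheobase_grid <- function(ceiling = 5) {
  c(seq(0.05, 0.9, by = 0.05), seq(1, ceiling, by = 0.1))
}

#' Rheobase by the step-search protocol
#'
#' Walks the 50/100 pA current grid upward and returns the smallest tested
#' amplitude whose 5 s pulse elicits at least one action potential, together
#' with that sweep (the "rheobase sweep" used for threshold measurement and
#' firing-pattern classification).
#'
#' @param x a model cell (one row of [sample_population()]) whose responses
#'   are synthesized on demand, or an `mn_protocol` of recorded `RHEO_STEPS`
#'   sweeps.
#' @param ceiling search ceiling in nA.
#' @param mode trace-synthesis mode for model cells.
#' @param dt sample interval (s).
#' @param ... passed to [synthesize_protocol()] machinery.
#' @return list with `rheobase` (nA), `sweep` (the rheobase sweep), `spikes`
#'   (its spike train) and `tested` (amplitudes examined, in order).
#' @export
rheobase_search <- function(x, ceiling = 5, mode = "template", dt = 1e-4, ...) {
  if (inherits(x, "mn_protocol")) {
    if (x$descriptor != "RHEO_STEPS") abort("expected RHEO_STEPS recordings")
    amps <- purrr::map_dbl(x$sweeps, ~ .x$meta$amplitude)
    ord <- order(amps)
    tested <- numeric(0)
    for (i in ord) {
      tested <- c(tested, amps[i])
      sp <- detect_spikes(x$sweeps[[i]])
      if (nrow(sp) > 0) {
        return(list(rheobase = amps[i], sweep = x$sweeps[[i]], spikes = sp,
                    tested = tested))
      }
    }
    abort(sprintf("no spike up to the %g nA ceiling", max(amps)))
  }
  cell <- as_model_cell(x)
  grid <- rheobase_grid(ceiling)
  tested <- numeric(0)
  # reproducible per-amplitude rendering regardless of how far the search runs
  base_seed <- cell$seed %||% 0
  for (k in seq_along(grid)) {
    a <- grid[k]
    tested <- c(tested, a)
    sweep <- with_seed((base_seed + k) %% 2147483646 + 1, {
      if (mode == "template") {
        template_step_sweep(cell, a, dt = dt, ...)
      } else {
        mechanistic_step_sweep(cell, a, pre = 0.5, dur = 5, post = 0.5,
                               dt = dt, sweep_index = k,
                               protocol_id = "RHEO_STEPS", noise = TRUE)
      }
    })
    sp <- detect_spikes(sweep)
    if (nrow(sp) > 0) {
      return(list(rheobase = a, sweep = sweep, spikes = sp, tested = tested))
    }
  }
  abort(sprintf("no spike up to the %g nA ceiling", ceiling))
}

# Theil-Sen slope (median of pairwise slopes).
theil_sen_slope <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- c()
  for (i in 1:(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    s <- c(s, dy[dx != 0] / dx[dx != 0])
  }
  median(s)
}

#' Classify the firing pattern on the rheobase sweep
#'
#' A motoneuron is **delayed**-firing when its first spike on the 5 s
#' rheobase pulse occurs more than `latency_cutoff` after pulse onset, or
#' when the latency exceeds `accel_cutoff` *and* the discharge accelerates
#' (positive Theil-Sen slope of instantaneous frequency against time, with at
#' least 3 spikes). Otherwise it is **immediate**-firing (discharge from
#' pulse onset at steady rate).
#'
#' @param rheobase_sweep the sweep returned by [rheobase_search()].
#' @param spikes its [detect_spikes()] train (recomputed when `NULL`).
#' @param latency_cutoff unconditional latency criterion (s).
#' @param accel_cutoff latency criterion used together with acceleration (s).
#' @return `"immediate"` or `"delayed"`.
#' @export
classify_pattern <- function(rheobase_sweep, spikes = NULL,
                             latency_cutoff = 0.5, accel_cutoff = 0.2) {
  if (is.null(spikes)) spikes <- detect_spikes(rheobase_sweep)
  if (nrow(spikes) == 0) abort("cannot classify a sweep without spikes")
  t_on <- rheobase_sweep$meta$t_on %||%
    ((which(rheobase_sweep$current != 0)[1] - 1) * rheobase_sweep$dt)
  latency <- spikes$t_peak[1] - t_on
  if (latency > latency_cutoff) return("delayed")
  if (latency > accel_cutoff && nrow(spikes) >= 3) {
    slope <- theil_sen_slope(spikes$t_peak[-1], spikes$freq_inst[-1])
    if (is.finite(slope) && slope > 0) return("delayed")
  }
  "immediate"
}

#' Detect mixed-mode oscillations between spikes
#'
#' Counts subthreshold oscillations inside each inter-spike interval:
#' local maxima of the (2 ms boxcar-smoothed) voltage with prominence of at
#' least `prominence`, whose peak stays below the spiking threshold. The
#' first 10 ms after the preceding spike and the last ~5 ms before the next
#' upstroke are excluded. The MMO flag is raised when at least `min_per_isi`
#' oscillations occur in each of at least `min_isis` intervals.
#'
#' @param sweep an `mn_sweep`.
#' @param spikes its spike train (recomputed when `NULL`).
#' @param prominence minimal oscillation prominence (mV).
#' @param threshold_mv spiking-threshold ceiling for oscillation peaks; when
#'   `NULL` it is measured on the first spike (10 mV/ms criterion).
#' @param min_per_isi,min_isis flag rule (see above).
#' @param smooth_ms boxcar width (ms).
#' @return list with `flag`, total oscillation `count`, and a `per_isi`
#'   tibble (`isi`, `n_osc`, `t_start`, `t_end`, `current_end`).
#' @export
detect_mmos <- function(sweep, spikes = NULL, prominence = 1,
                        threshold_mv = NULL, min_per_isi = 2, min_isis = 2,
                        smooth_ms = 2) {
  if (is.null(spikes)) spikes <- detect_spikes(sweep)
  empty <- list(flag = FALSE, count = 0L,
                per_isi = tibble::tibble(isi = integer(0), n_osc = integer(0),
                                         t_start = numeric(0),
                                         t_end = numeric(0),
                                         current_end = numeric(0)))
  if (nrow(spikes) < 2) return(empty)
  if (is.null(threshold_mv)) {
    threshold_mv <- tryCatch(spike_threshold(sweep, 1L, spikes),
                             error = function(e) Inf)
  }
  dt <- sweep$dt
  vs <- boxcar(sweep$voltage, round(smooth_ms / 1000 / dt) + 1)
  skip_a <- round(0.010 / dt)
  skip_b <- round(0.0062 / dt)   # ~5 ms before the upstroke foot
  detrend_w <- round(0.010 / dt) + 1
  n_isi <- nrow(spikes) - 1L
  n_osc <- integer(n_isi)
  for (k in seq_len(n_isi)) {
    a <- spikes$i_peak[k] + skip_a
    b <- spikes$i_peak[k + 1] - skip_b
    if (b - a < 5) next
    seg <- vs[a:b]
    # remove the slow inter-spike trend (AHP recovery / ramp drift) so that
    # oscillation prominence is judged against a flat reference
    trend <- boxcar(seg, detrend_w)
    pk <- local_maxima(seg - trend, min_prom = prominence)
    n_osc[k] <- sum(seg[pk] < threshold_mv)
  }
  rows <- tibble::tibble(
    isi = seq_len(n_isi), n_osc = n_osc,
    t_start = spikes$t_peak[-nrow(spikes)],
    t_end = spikes$t_peak[-1],
    current_end = sweep$current[spikes$i_peak[-1]])
  n_mmo_isi <- sum(rows$n_osc >= min_per_isi)
  list(flag = n_mmo_isi >= min_isis, count = sum(rows$n_osc), per_isi = rows)
}

#' Segment the F-I curve into sub-primary and primary ranges
#'
#' On the ascending ramp, the boundary between the sub-primary range (where
#' mixed-mode oscillations populate the inter-spike intervals) and the
#' primary range is the injected current at the end of the last
#' MMO-containing interval. When no interval contains MMOs the whole
#' ascending discharge is primary; when MMOs persist to the ramp peak there
#' is no primary range (and no measurable gain).
#'
#' @param ficurve an `mn_ficurve` tibble (see [analyze_ramp()]), or any tibble
#'   with `current` and `phase` columns for the spikes.
#' @param mmo_per_isi the `per_isi` tibble from [detect_mmos()] computed on
#'   the ascending discharge.
#' @param min_per_isi an interval "contains MMOs" when it carries at least
#'   this many oscillations.
#' @param min_span a primary range must cover more than this current span
#'   (nA) above the boundary, otherwise the gain is declared absent.
#' @return list with `boundary` (nA or `NULL`), `has_primary` (logical).
#' @export
segment_ranges <- function(ficurve, mmo_per_isi, min_per_isi = 2,
                           min_span = 0.05) {
  asc <- dplyr::filter(ficurve, .data$phase == "ascending")
  if (nrow(asc) == 0) abort("no ascending-phase spikes")
  mmo <- dplyr::filter(mmo_per_isi, .data$n_osc >= min_per_isi)
  if (nrow(mmo) == 0) {
    return(list(boundary = NULL, has_primary = TRUE))
  }
  boundary <- max(mmo$current_end)
  has_primary <- max(asc$current) > boundary + min_span
  list(boundary = boundary, has_primary = has_primary)
}

#' Analyze the response to slow triangular current ramps
#'
#' Extracts, per the ramp protocol: the recruitment current (current at the
#' first ascending spike, averaged over the trials), the derecruitment
#' current (last descending spike), the instantaneous frequency of the
#' inter-spike interval containing recruitment + 0.5 s, the F-I curve, the
#' sub-primary/primary boundary from the MMO schedule, and the gain
#' (least-squares slope of instantaneous frequency on current over the
#' ascending primary range; absent when no primary range exists).
#'
#' @param ramp an `mn_protocol` with descriptor `RAMP`.
#' @param threshold_mv optional spiking-threshold estimate for the MMO
#'   detector.
#' @param mmo_prominence MMO detector prominence (mV).
#' @return list of class `mn_ramp_result`: `recruitment_current`,
#'   `derecruitment_current`, `f_half_second`, `gain`, `boundary`,
#'   `mmo_present`, `ficurve` (tibble with `trial`, `t_peak`, `current`,
#'   `freq_inst`, `phase`).
#' @export
analyze_ramp <- function(ramp, threshold_mv = NULL, mmo_prominence = 1) {
  sweeps <- if (inherits(ramp, "mn_protocol")) ramp$sweeps else ramp
  if (length(sweeps) < 3) {
    warn("fewer than 3 ramp trials; proceeding with what is available")
  }
  per_trial <- purrr::imap(sweeps, function(sw, trial) {
    sp <- detect_spikes(sw)
    t_top <- sw$meta$t_peak %||% ((which.max(sw$current) - 1) * sw$dt)
    fi <- tibble::tibble(
      trial = trial,
      t_peak = sp$t_peak,
      current = sw$current[sp$i_peak],
      freq_inst = sp$freq_inst,
      phase = ifelse(sp$t_peak <= t_top, "ascending", "descending")
    )
    asc <- which(fi$phase == "ascending")
    if (length(asc) == 0) abort("no spikes on the ascending ramp phase")
    rec <- fi$current[asc[1]]
    desc <- which(fi$phase == "descending")
    derec <- if (length(desc)) fi$current[desc[length(desc)]] else NA_real_
    # ISI containing first-spike time + 0.5 s
    tgt <- fi$t_peak[1] + 0.5
    k <- which(sp$t_peak[-nrow(sp)] <= tgt & sp$t_peak[-1] > tgt)[1]
    f_half <- if (!is.na(k)) 1 / (sp$t_peak[k + 1] - sp$t_peak[k]) else NA_real_
    mmo <- detect_mmos(sw, sp, prominence = mmo_prominence,
                       threshold_mv = threshold_mv)
    asc_isis <- dplyr::filter(mmo$per_isi, .data$t_end <= t_top)
    seg <- segment_ranges(fi, asc_isis)
    gain <- NA_real_
    if (seg$has_primary) {
      pri <- dplyr::filter(fi, .data$phase == "ascending",
                           is.finite(.data$freq_inst),
                           .data$current > (seg$boundary %||% -Inf))
      if (nrow(pri) >= 3) {
        gain <- sum((pri$current - mean(pri$current)) *
                      (pri$freq_inst - mean(pri$freq_inst))) /
          sum((pri$current - mean(pri$current))^2)
      }
    }
    list(fi = fi, recruitment = rec, derecruitment = derec, f_half = f_half,
         gain = gain, boundary = seg$boundary, mmo_flag = mmo$flag)
  })
  fic <- dplyr::bind_rows(purrr::map(per_trial, "fi"))
  class(fic) <- c("mn_ficurve", class(fic))
  gains <- purrr::map_dbl(per_trial, "gain")
  bounds <- purrr::map_dbl(per_trial, ~ .x$boundary %||% NA_real_)
  structure(list(
    recruitment_current = mean(purrr::map_dbl(per_trial, "recruitment")),
    derecruitment_current = mean(purrr::map_dbl(per_trial, "derecruitment"),
                                 na.rm = TRUE),
    f_half_second = mean(purrr::map_dbl(per_trial, "f_half"), na.rm = TRUE),
    gain = if (all(is.na(gains))) NA_real_ else mean(gains, na.rm = TRUE),
    boundary = if (all(is.na(bounds))) NULL else mean(bounds, na.rm = TRUE),
    mmo_present = any(purrr::map_lgl(per_trial, "mmo_flag")),
    ficurve = fic
  ), class = "mn_ramp_result")
}

#' @export
print.mn_ramp_result <- function(x, ...) {
  cat("<mn_ramp_result>\n",
      "  recruitment: ", signif(x$recruitment_current, 3), " nA",
      "   derecruitment: ", signif(x$derecruitment_current, 3), " nA\n",
      "  f(rec + 0.5 s): ", signif(x$f_half_second, 3), " Hz",
      "   gain: ", signif(x$gain, 3), " Hz/nA\n",
      "  MMOs: ", x$mmo_present,
      "   sub-primary boundary: ",
      if (is.null(x$boundary)) "none" else paste(signif(x$boundary, 3), "nA"),
      "\n", sep = "")
  invisible(x)
}
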