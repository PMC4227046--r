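# Pipeline orchestration: per-cell feature extraction, trace file I/O and the
# end-to-end population run.

offset_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (seed + k) %% 2147483646 + 1
}

#' Measure the full feature vector of one cell
#'
#' Runs the requested acquisition protocols on a model cell (synthesizing the
#' sweeps) or on pre-recorded protocols, and extracts the per-cell feature
#' vector: resting potential, input conductance, rheobase, spiking threshold
#' (10 mV/ms criterion on the first spike of the rheobase sweep), firing
#' pattern, AP amplitude/half-width, AHP relaxation time constant, and the
#' ramp measures (recruitment/derecruitment current, frequency 0.5 s after
#' recruitment, sub-primary boundary and primary-range gain, MMO flag).
#'
#' @param cell one row of a [sample_population()] tibble.
#' @param protocols subset of `c("rheo", "iv", "single_ap", "ramp")`.
#' @param mode trace-synthesis mode.
#' @param dt sample interval (s).
#' @param recordings optional named list of pre-recorded `mn_protocol`s
#'   (names among `IV_STEPS`, `RHEO_STEPS`, `SINGLE_AP`, `RAMP`); protocols
#'   found here are consumed instead of being synthesized.
#' @param config detector thresholds, see [run_config()].
#' @return one-row tibble of measured features.
#' @export
measure_cell <- function(cell, protocols = c("rheo", "iv", "single_ap", "ramp"),
                         mode = "template", dt = 1e-4, recordings = NULL,
                         config = run_config()) {
  cell <- as_model_cell(cell)
  out <- tibble::tibble(id = cell$id %||% NA_character_,
                        genotype = cell$genotype %||% NA_character_,
                        pattern_true = cell$pattern %||% NA_character_)
  v_threshold <- NA_real_
  if ("rheo" %in% protocols) {
    rs <- if (!is.null(recordings$RHEO_STEPS)) {
      rheobase_search(recordings$RHEO_STEPS)
    } else {
      rheobase_search(cell, ceiling = config$rheobase_ceiling, mode = mode,
                      dt = dt)
    }
    v_rest <- resting_potential(rs$sweep)
    v_threshold <- tryCatch(
      spike_threshold(rs$sweep, 1L, rs$spikes,
                      criterion = config$dvdt_criterion),
      error = function(e) NA_real_)
    out$v_rest <- v_rest
    out$rheobase <- rs$rheobase
    out$v_threshold <- v_threshold
    out$delta_v <- v_threshold - v_rest
    out$pattern <- classify_pattern(rs$sweep, rs$spikes,
                                    latency_cutoff = config$latency_cutoff,
                                    accel_cutoff = config$accel_cutoff)
    out$first_spike_latency <- rs$spikes$t_peak[1] - rs$sweep$meta$t_on
  }
  if ("iv" %in% protocols) {
    iv <- recordings$IV_STEPS %||%
      synthesize_protocol(cell, "IV_STEPS", mode = mode,
                          seed = offset_seed(cell$seed, 1000003), dt = dt)
    out$g_in <- input_conductance(iv)
  }
  if ("single_ap" %in% protocols) {
    sa <- recordings$SINGLE_AP %||%
      synthesize_protocol(cell, "SINGLE_AP", mode = "template",
                          seed = offset_seed(cell$seed, 3000017), dt = dt)
    shape <- ap_shape(sa)
    out$ap_amplitude <- shape$amplitude
    out$ap_halfwidth <- shape$halfwidth
    out$ahp_tau <- tryCatch(fit_ahp(shape$avg_sweep, baseline = shape$baseline),
                            error = function(e) NA_real_)
  }
  if ("ramp" %in% protocols) {
    rp <- recordings$RAMP %||%
      synthesize_protocol(cell, "RAMP", mode = "template",
                          seed = offset_seed(cell$seed, 2000029), dt = dt)
    rr <- analyze_ramp(rp, threshold_mv = v_threshold,
                       mmo_prominence = config$mmo_prominence)
    out$recruitment_current <- rr$recruitment_current
    out$derecruitment_current <- rr$derecruitment_current
    out$f_half_second <- rr$f_half_second
    out$gain <- rr$gain
    out$mmo_present <- rr$mmo_present
    out$subprimary_boundary <- rr$boundary %||% NA_real_
  }
  out
}

#' Measure a whole population
#'
#' @param cells a [sample_population()] tibble.
#' @param ... passed to [measure_cell()].
#' @param progress print a dot every 50 cells.
#' @return tibble of measured features, one row per cell.
#' @export
measure_population <- function(cells, ..., progress = FALSE) {
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    if (progress && i %% 50 == 0) message("  measured ", i, " cells")
    measure_cell(cells[i, ], ...)
  })
}

#' Detector and protocol configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' the dV/dt spiking-threshold criterion (10 mV/ms), the delayed-pattern
#' latency cutoffs (0.5 s unconditional, 0.2 s with acceleration), the MMO
#' detector prominence (1 mV), the rheobase search ceiling (5 nA), the ramp
#' velocity (0.1 nA/s) and the significance level.
#'
#' @param dvdt_criterion mV/ms.
#' @param latency_cutoff,accel_cutoff s.
#' @param mmo_prominence mV.
#' @param rheobase_ceiling nA.
#' @param ramp_speed nA/s.
#' @param alpha significance level for reports.
#' @param dt sample interval (s).
#' @return list of class `mn_config`.
#' @export
run_config <- function(dvdt_criterion = 10, latency_cutoff = 0.5,
                       accel_cutoff = 0.2, mmo_prominence = 1,
                       rheobase_ceiling = 5, ramp_speed = 0.1, alpha = 0.05,
                       dt = 1e-4) {
  cfg <- list(dvdt_criterion = dvdt_criterion, latency_cutoff = latency_cutoff,
              accel_cutoff = accel_cutoff, mmo_prominence = mmo_prominence,
              rheobase_ceiling = rheobase_ceiling, ramp_speed = ramp_speed,
              alpha = alpha, dt = dt)
  bad <- names(cfg)[!purrr::map_lgl(cfg, ~ is.numeric(.x) && .x > 0)]
  if (length(bad)) {
    abort(paste0("config values must be positive: ", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = c("mn_config", "list"))
}

#' Run the full synthetic pipeline
#'
#' Samples the requested groups, runs the acquisition protocols on every
#' cell, optionally generates and measures a dendritic tree per cell,
#' assembles the population table and the group-comparison report.
#'
#' @param groups list of `c(genotype, pattern)` pairs.
#' @param n_per_group cells per group.
#' @param seed master seed: the whole run is reproducible.
#' @param protocols protocols to run per cell.
#' @param morphology also generate/measure a synthetic tree per cell.
#' @param config [run_config()].
#' @param out_dir optional directory: writes `population.tsv`,
#'   `summary.tsv`, `comparison.tsv` and a `provenance.json` block.
#' @return list with `population`, `summary`, `comparison`, `provenance`.
#' @export
run_pipeline <- function(groups = list(c("WT", "immediate"),
                                       c("WT", "delayed"),
                                       c("mSOD1", "immediate"),
                                       c("mSOD1", "delayed")),
                         n_per_group = 10, seed = 1,
                         protocols = c("rheo", "iv"),
                         morphology = FALSE,
                         config = run_config(), out_dir = NULL) {
  pop <- purrr::imap_dfr(groups, function(gp, gi) {
    spec <- group_spec(gp[1], gp[2])
    cells <- sample_population(spec, n_per_group,
                               seed = offset_seed(seed, 7919 * gi))
    feats <- measure_population(cells, protocols = protocols,
                                dt = config$dt, config = config)
    feats$soma_area <- cells$soma_area
    if (morphology) {
      ts <- tree_spec(gp[1], gp[2])
      morph <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
        tree <- generate_tree(ts, seed = offset_seed(cells$seed[i], 13))
        tidy(compute_metrics(apply_slice_filter(tree),
                             soma_area = cells$soma_area[i]))[, 1:6]
      })
      feats <- dplyr::bind_cols(feats, morph)
    }
    feats
  })
  summary <- summarize_population(
    pop, c("genotype", "pattern_true"),
    properties = setdiff(names(pop)[purrr::map_lgl(pop, is.numeric)],
                         "seed"))
  comparison <- tryCatch(
    compare_groups(pop, compare = "genotype", within = "pattern_true"),
    error = function(e) NULL)
  prov <- list(package = "mnphys",
               version = as.character(utils::packageVersion("mnphys")),
               seed = seed, n_per_group = n_per_group,
               groups = purrr::map_chr(groups, paste, collapse = ":"),
               protocols = protocols, config = unclass(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_stable(pop, file.path(out_dir, "population.tsv"))
    write_tsv_stable(summary, file.path(out_dir, "summary.tsv"))
    if (!is.null(comparison)) {
      write_tsv_stable(comparison, file.path(out_dir, "comparison.tsv"))
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(population = pop, summary = summary, comparison = comparison,
       provenance = prov)
}

write_tsv_stable <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ signif(.x, 10)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trace container: one two-column-plus-current TSV per sweep and a JSON
# sidecar per protocol carrying dt, units, descriptor and the ground truth.

#' Write a protocol's sweeps to disk
#'
#' One delimited file per sweep (`time` s, `voltage` mV, `current` nA) plus a
#' JSON sidecar carrying the sample interval, units, protocol descriptor,
#' per-sweep metadata and an optional ground-truth block.
#'
#' @param protocol an `mn_protocol`.
#' @param dir output directory.
#' @param cell_id file-name stem.
#' @param ground_truth optional list stored verbatim in the sidecar.
#' @return sidecar path, invisibly.
#' @export
write_protocol <- function(protocol, dir, cell_id = protocol$cell_id,
                           ground_truth = NULL) {
  stopifnot(inherits(protocol, "mn_protocol"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cell_id) || is.na(cell_id)) cell_id <- "cell"
  stem <- paste0(cell_id, "_", protocol$descriptor)
  files <- purrr::imap_chr(protocol$sweeps, function(sw, k) {
    fn <- sprintf("%s_%03d.tsv", stem, k)
    df <- data.frame(time = sprintf("%.6f", sweep_time(sw)),
                     voltage = sprintf("%.6f", sw$voltage),
                     current = sprintf("%.6f", sw$current))
    utils::write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fn
  })
  sidecar <- list(
    cell_id = cell_id,
    descriptor = protocol$descriptor,
    mode = protocol$mode,
    dt = protocol$sweeps[[1]]$dt,
    units = list(time = "s", voltage = "mV", current = "nA"),
    params = protocol$params,
    sweeps = purrr::imap(protocol$sweeps, function(sw, k) {
      list(file = files[[k]], sweep_index = sw$sweep_index,
           n_samples = length(sw$voltage), meta = sw$meta)
    }),
    ground_truth = ground_truth
  )
  path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a directory of trace files back into protocols
#'
#' Reads every JSON sidecar in `dir`, validates units and sweep lengths, and
#' rebuilds the protocol objects grouped by cell.
#'
#' @param dir directory produced by [write_protocol()].
#' @return named list: `cells[[cell_id]][[descriptor]]` -> `mn_protocol`.
#' @export
read_traces <- function(dir) {
  sidecars <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(sidecars) == 0) abort(paste0("no trace sidecars found in ", dir))
  out <- list()
  for (sc in sidecars) {
    info <- jsonlite::read_json(sc)
    u <- info$units
    if (!identical(u$time, "s") || !identical(u$voltage, "mV") ||
        !identical(u$current, "nA")) {
      abort(paste0("unit mismatch in sidecar ", basename(sc),
                   " (expected s/mV/nA)"))
    }
    dt <- as.numeric(info$dt)
    sweeps <- purrr::map(info$sweeps, function(sinfo) {
      fn <- file.path(dir, sinfo$file)
      df <- utils::read.table(fn, header = TRUE, sep = "\t")
      if (!all(c("time", "voltage", "current") %in% names(df))) {
        abort(paste0("malformed trace file ", sinfo$file))
      }
      if (length(df$voltage) != length(df$current) ||
          (!is.null(sinfo$n_samples) && nrow(df) != sinfo$n_samples)) {
        abort(paste0("voltage/current length mismatch in ", sinfo$file))
      }
      meta <- sinfo$meta
      if (!is.null(meta$spike_peak_times)) {
        meta$spike_peak_times <- as.numeric(unlist(meta$spike_peak_times))
      }
      new_sweep(dt, as.numeric(df$voltage), as.numeric(df$current),
                sinfo$sweep_index %||% 1L, info$descriptor, meta = meta)
    })
    proto <- structure(list(descriptor = info$descriptor, sweeps = sweeps,
                            params = info$params, mode = info$mode %||% "template",
                            cell_id = info$cell_id,
                            ground_truth = info$ground_truth),
                       class = "mn_protocol")
    out[[info$cell_id]][[info$descriptor]] <- proto
  }
  out
}
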