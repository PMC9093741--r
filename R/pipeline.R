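#' Configuration for an end-to-end imaging run
#'
#' A run either simulates a population of cells (list of [sim_config()]s) or
#' reads per-ROI count traces from CSV files. All module parameter blocks and
#' the seed are recorded in the run summary so re-runs with the same
#' configuration are bit-identical.
#'
#' @param cells List of [sim_config()]s, or character vector of CSV trace
#'   paths (columns `time_s`, `value`).
#' @param camera A [camera_model()].
#' @param detection A [detection_params()].
#' @param sto An [sto_params()].
#' @param calibration An `io_calibration` used to infer spike widths.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param seed Integer master seed, recorded in the summary.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cells, camera = camera_model(),
                       detection = detection_params(), sto = sto_params(),
                       calibration = default_calibration(),
                       out_dir = NULL, seed = 0L) {
  if (is.character(cells)) {
    missing <- cells[!file.exists(cells)]
    if (length(missing)) {
      rlang::abort(paste0("input file(s) not found: ",
                          paste(missing, collapse = ", ")))
    }
  }
  structure(list(cells = cells, camera = camera, detection = detection,
                 sto = sto, calibration = calibration, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the imaging analysis pipeline
#'
#' Chains the full fluorescence workflow per cell: counts to calibrated power,
#' event detection and waveform metrics, event excision, DFF conversion and
#' STO spectral classification, and rise-time-to-width inference. Writes
#' `events.csv`, `sto.csv`, `widths.csv` and a `summary.json` embedding the
#' configuration hash and seed when an output directory is configured.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with tibbles `events`, `sto`, `widths` and the
#'   `summary` list.
#' @export
run_imaging_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cells <- config$cells
  ids <- if (is.character(cells)) basename(cells) else {
    sprintf("cell%03d", seq_along(cells))
  }
  res <- purrr::map(seq_along(cells), function(i) {
    tr_counts <- tryCatch({
      if (is.character(cells)) read_trace_csv(cells[i])
      else simulate_fluorescence(cells[[i]], config$camera)$trace
    }, error = function(e) {
      rlang::abort(sprintf("stage 'input' failed for %s: %s", ids[i],
                           conditionMessage(e)))
    })
    with_stage <- function(stage, expr) {
      tryCatch(expr, error = function(e) {
        rlang::abort(sprintf("stage '%s' failed for %s: %s", stage, ids[i],
                             conditionMessage(e)))
      })
    }
    tr_fw <- with_stage("photometry", counts_to_power(tr_counts, config$camera))
    ev <- with_stage("events", {
      detect_events(tr_fw, config$detection) |>
        event_metrics(trace = tr_fw, params = config$detection)
    })
    ev$roi_id <- ids[i]
    sto_row <- with_stage("sto", {
      quiet <- excise_events(tr_fw, ev)
      f0 <- stats::median(quiet$value)
      d <- dff(quiet, f0)
      r <- welch_psd(d, config$sto)
      tibble::tibble(roi_id = ids[i], peak_freq_hz = r$peak_freq,
                     band_power = r$band_power, dff_amp_pct = r$dff_amp_pct,
                     oscillating = classify_oscillating(r, config$sto,
                                                        "fluorescence"))
    })
    widths <- with_stage("calibration", {
      ok <- ev$flag == "ok" & ev$rise_time_ms >= 150
      w <- rep(NA_real_, nrow(ev))
      if (any(ok)) w[ok] <- rt_to_width(ev$rise_time_ms[ok],
                                        config$calibration)
      tibble::tibble(roi_id = ids[i], onset_s = ev$onset_s,
                     rise_time_ms = ev$rise_time_ms, width_ms = w,
                     flag = ifelse(ev$rise_time_ms < 150, "sIO-s", ev$flag))
    })
    list(events = ev, sto = sto_row, widths = widths)
  })
  events <- dplyr::bind_rows(purrr::map(res, "events"))
  sto_tbl <- dplyr::bind_rows(purrr::map(res, "sto"))
  widths <- dplyr::bind_rows(purrr::map(res, "widths"))
  summary <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[c("cells", "camera", "detection",
                                       "sto", "calibration", "seed")]),
    n_cells = length(cells), n_events = nrow(events),
    n_oscillating = sum(sto_tbl$oscillating),
    mean_rise_time_ms = if (nrow(events)) mean(events$rise_time_ms) else NA,
    mean_width_ms = if (any(!is.na(widths$width_ms))) {
      mean(widths$width_ms, na.rm = TRUE)
    } else NA,
    parameters = list(
      z_threshold = config$detection$z_threshold,
      min_separation_ms = config$detection$min_separation_ms,
      band = config$sto$band,
      vm_threshold = config$sto$vm_threshold,
      dff_threshold_pct = config$sto$dff_threshold_pct,
      calibration_slope = config$calibration$slope,
      calibration_intercept = config$calibration$intercept)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(events, file.path(config$out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(sto_tbl, file.path(config$out_dir, "sto.csv"),
                     row.names = FALSE)
    utils::write.csv(widths, file.path(config$out_dir, "widths.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(events = events, sto = sto_tbl, widths = widths,
                 summary = summary))
}

#' Run the anatomy quantification pipeline
#'
#' Classifies somata by area, computes reference-normalized expression,
#' cell-type preference against a reference population and, when images and a
#' region mask are supplied, structural specificity. Writes `soma_table.csv`
#' and `anatomy_report.json` when an output directory is configured.
#'
#' @param somata Soma table with `area_um2`, `egfp`, `tdtomato`, `x_um`,
#'   `y_um` columns (e.g. from [simulate_anatomy()]).
#' @param ref_somata Optional reference-construct soma table (same columns)
#'   for cell-type preference.
#' @param test_image,ref_image,io_mask Optional matrices for
#'   [structure_specificity()].
#' @param out_dir Output directory or `NULL`.
#' @param seed Seed recorded in the report.
#' @return Invisibly, a list with `somata` (labeled, with
#'   `normalized_expression`), `preference_pct`, `specificity`, `nn_um`,
#'   and the `report` list.
#' @export
run_anatomy_pipeline <- function(somata, ref_somata = NULL,
                                 test_image = NULL, ref_image = NULL,
                                 io_mask = NULL, out_dir = NULL, seed = 0L) {
  if (!is.null(io_mask) && is.character(io_mask)) {
    if (!file.exists(io_mask)) {
      rlang::abort(paste0("mask file not found: ", io_mask))
    }
  }
  somata <- classify_by_area(somata)
  somata$normalized_expression <-
    normalized_expression(somata$egfp, somata$tdtomato)
  neurons <- dplyr::filter(somata, .data$label == "neuron")
  nn <- if (nrow(neurons) >= 2) {
    nn_distances(neurons[, c("x_um", "y_um")])
  } else numeric(0)
  pref <- if (!is.null(ref_somata)) {
    ref_lab <- classify_by_area(ref_somata)
    cell_type_preference(
      list(neuron = sum(somata$label == "neuron"),
           astro = sum(somata$label == "non-neuron")),
      list(neuron = sum(ref_lab$label == "neuron"),
           astro = sum(ref_lab$label == "non-neuron")))
  } else NA_real_
  spec <- if (!is.null(test_image)) {
    structure_specificity(test_image, ref_image, io_mask)
  } else NULL
  report <- list(
    seed = as.integer(seed),
    n_somata = nrow(somata),
    n_neurons = sum(somata$label == "neuron"),
    n_non_neurons = sum(somata$label == "non-neuron"),
    mean_normalized_expression = mean(somata$normalized_expression),
    preference_pct = pref,
    mean_nn_um = if (length(nn)) mean(nn) else NA_real_,
    specificity = if (!is.null(spec)) as.list(spec) else NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(somata, file.path(out_dir, "soma_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "anatomy_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(somata = somata, preference_pct = pref, specificity = spec,
                 nn_um = nn, report = report))
}
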