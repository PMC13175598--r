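#' Write / read one signal cycle as CSV
#'
#' Plain-text interchange format for acquisition cycles: a header row
#' `t_s,ecg,ppg` followed by one row per sample at uniform 1 ms steps (for
#' 1 kHz data). Real recordings in the same layout enter the pipeline through
#' [read_signal_csv()].
#'
#' @param cycle One-row cycle tibble (with `ecg`, `ppg` list-columns).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(cycle, path) {
  n <- length(cycle$ecg[[1]])
  readr::write_csv(tibble::tibble(
    t_s = (0:(n - 1)) / cycle$fs_hz[1],
    ecg = cycle$ecg[[1]], ppg = cycle$ppg[[1]]
  ), path)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param subject_id,session,cycle_index Identity attached to the cycle read.
#' @param tol Tolerance (s) for time-base uniformity.
#' @return For `read_signal_csv()`: a one-row cycle tibble.
#' @export
read_signal_csv <- function(path, subject_id = NA_integer_,
                            session = NA_character_, cycle_index = NA_integer_,
                            tol = 1e-6) {
  df <- tryCatch(
    suppressWarnings(readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_double()),
      progress = FALSE)),
    error = function(e) abort(paste0("cannot parse ", path, ": ", conditionMessage(e)))
  )
  missing <- setdiff(c("t_s", "ecg", "ppg"), names(df))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing columns ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) < 2) abort(paste0(path, ": empty or single-row signal file"))
  if (any(is.na(df$t_s)) || any(is.na(df$ecg)) || any(is.na(df$ppg))) {
    abort(paste0(path, ": malformed rows (NA) at row ",
                 which(is.na(df$t_s) | is.na(df$ecg) | is.na(df$ppg))[1]))
  }
  dt <- diff(df$t_s)
  step <- median(dt)
  bad <- which(abs(dt - step) > tol)
  if (length(bad) > 0) {
    abort(paste0(path, ": non-uniform time base at row ", bad[1] + 1,
                 " (step ", format(dt[bad[1]]), " s, expected ",
                 format(step), " s)"))
  }
  fs <- round(1 / step)
  tibble::tibble(subject_id = as.integer(subject_id), session = session,
                 cycle_index = as.integer(cycle_index), fs_hz = fs,
                 duration_s = nrow(df) / fs, artifact = NA_character_,
                 ecg = list(df$ecg), ppg = list(df$ppg))
}

cycle_filename <- function(subject_id, session, cycle_index) {
  sprintf("S%02d_%s_%02d.csv", subject_id, session, cycle_index)
}

#' Persist / load a campaign as plain-text files
#'
#' `write_campaign()` writes one CSV per cycle (`S{subject}_{session}_{cycle}.csv`),
#' a cuff-readings CSV (`cuff_readings.csv`: `subject,session,after_cycle,sbp,dbp`)
#' and `manifest.json` holding the schedule, the seed, the file index and --
#' clearly separated under `ground_truth` -- the subject profiles.
#' `read_campaign()` reconstructs a campaign from such a directory (beat-level
#' ground truth is not persisted; analysis does not need it).
#'
#' @param campaign A `pat_campaign`.
#' @param dir Directory (created if needed).
#' @return `write_campaign()`: `dir` invisibly. `read_campaign()`: a
#'   `pat_campaign` (without `truths`).
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cy <- campaign$cycles
  files <- character(nrow(cy))
  for (i in seq_len(nrow(cy))) {
    files[i] <- cycle_filename(cy$subject_id[i], cy$session[i], cy$cycle_index[i])
    write_signal_csv(cy[i, ], file.path(dir, files[i]))
  }
  rd <- campaign$readings
  readr::write_csv(tibble::tibble(subject = rd$subject_id, session = rd$session,
                                  after_cycle = rd$after_cycle,
                                  sbp = rd$sbp_mmHg, dbp = rd$dbp_mmHg),
                   file.path(dir, "cuff_readings.csv"))
  manifest <- list(
    schedule = campaign$manifest,
    seed = campaign$seed,
    files = dplyr::bind_cols(cy[, c("subject_id", "session", "cycle_index")],
                             tibble::tibble(file = files, artifact = cy$artifact)),
    ground_truth = list(profiles = campaign$profiles)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(paste0("no manifest.json in ", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- manifest$files
  cycles <- purrr::map_dfr(seq_len(nrow(files)), function(i) {
    cyc <- read_signal_csv(file.path(dir, files$file[i]),
                           subject_id = files$subject_id[i],
                           session = files$session[i],
                           cycle_index = files$cycle_index[i])
    cyc$artifact <- files$artifact[i] %||% NA_character_
    cyc
  })
  rd <- readr::read_csv(file.path(dir, "cuff_readings.csv"),
                        col_types = "icidd", progress = FALSE)
  readings <- tibble::tibble(subject_id = rd$subject, session = rd$session,
                             after_cycle = rd$after_cycle,
                             sbp_mmHg = rd$sbp, dbp_mmHg = rd$dbp)
  structure(list(profiles = tibble::as_tibble(manifest$ground_truth$profiles),
                 cycles = cycles, truths = NULL, readings = readings,
                 manifest = manifest$schedule, seed = manifest$seed),
            class = "pat_campaign")
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate-extract-analyze chain with its
#' default. The configuration (and the seed) is echoed into the output
#' directory of every [run_pipeline()] run.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Root seed for all randomness.
#' @param out_dir Output directory.
#' @param artifact_prob Per-cycle artifact probability override (or `NULL`).
#' @param min_beats,window,k_sd,pat_bounds Quality-control settings.
#' @param z_threshold,alpha Analysis settings.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 19, seed = 1, out_dir = tempfile("patrec_run_"),
                       artifact_prob = NULL, min_beats = 3, window = 3, k_sd = 3,
                       pat_bounds = c(100, 600), z_threshold = 2, alpha = 0.05) {
  structure(list(n_subjects = n_subjects, seed = seed, out_dir = out_dir,
                 artifact_prob = artifact_prob,
                 qc = list(min_beats = min_beats, window = window, k_sd = k_sd,
                           pat_bounds = pat_bounds),
                 analysis = list(z_threshold = z_threshold, alpha = alpha)),
            class = "run_config")
}

#' Run the full simulate-extract-analyze pipeline
#'
#' Deterministic end-to-end driver: generates a campaign from the config
#' seed, extracts per-cycle summaries, computes Recovery Indices, recovery
#' fits and the agreement battery, and persists every intermediate
#' (`summaries.csv`, `ri_series.csv`, `fits.json`, `agreement.json`,
#' `log.json`, `config.json`) into `config$out_dir`. Input files are never
#' modified.
#'
#' @param config A [run_config()].
#' @param campaign Optional pre-built campaign (e.g. from [read_campaign()]);
#'   when `NULL` one is generated from the config.
#' @return The `pat_analysis`, invisibly; the output directory path is
#'   attached as attribute `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), campaign = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(campaign)) {
    campaign <- generate_campaign(config$n_subjects, seed = config$seed,
                                  artifact_prob = config$artifact_prob)
  }
  summaries <- extract_cycles(campaign, min_beats = config$qc$min_beats,
                              window = config$qc$window, k_sd = config$qc$k_sd,
                              pat_bounds = config$qc$pat_bounds)
  analysis <- analyze_summaries(summaries, campaign$readings,
                                z_threshold = config$analysis$z_threshold,
                                alpha = config$analysis$alpha)

  out <- config$out_dir
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(dplyr::rename(summaries, subject = "subject_id",
                                 cycle = "cycle_index"),
                   file.path(out, "summaries.csv"))
  readr::write_csv(dplyr::rename(analysis$ri, subject = "subject_id"),
                   file.path(out, "ri_series.csv"))
  fits <- list(
    aggregate = list(
      trajectory = analysis$aggregate$trajectory,
      models = dplyr::select(analysis$aggregate$models, -"fit"),
      best_params = as.list(analysis$aggregate$models$fit[[1]]$params)
    ),
    subjects = analysis$subject_fits
  )
  jsonlite::write_json(fits, file.path(out, "fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  agreement <- list(
    phase_tests = purrr::map(analysis$phase_reports, function(r) {
      list(shapiro = r$shapiro, kruskal = r$kruskal,
           posthoc = r$posthoc, posthoc_run = r$posthoc_run)
    }),
    correlations = analysis$screen$correlations,
    correlation_summary = analysis$screen$summary,
    bland_altman = glance(analysis$agreement$bland_altman),
    ccc = analysis$agreement$ccc
  )
  jsonlite::write_json(agreement, file.path(out, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_csv(analysis$agreement$pairs, file.path(out, "ba_pairs.csv"))
  jsonlite::write_json(analysis$log, file.path(out, "log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  attr(analysis, "out_dir") <- out
  invisible(analysis)
}
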