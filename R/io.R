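#' @importFrom utils packageVersion read.csv write.csv combn
NULL

# comment header embedded at the top of every file the package writes:
# seed, package version and a short config hash, so any output can be
# traced back to the run that produced it
output_header <- function(seed = NA, config = NULL) {
  h <- "0"
  if (!is.null(config)) {
    js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    bytes <- utf8ToInt(as.character(js))
    acc <- 0
    for (b in bytes) acc <- (acc * 31 + b) %% 2147483647
    h <- sprintf("%08x", acc)
  }
  c(sprintf("# seed=%s", seed),
    sprintf("# package=biocyloop %s", as.character(packageVersion("biocyloop"))),
    sprintf("# config_hash=%s", h))
}

write_with_header <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read the package's RR-interval CSV dialect
#'
#' Columns `beat_index` and one interval column whose name declares the
#' unit: `rr_device_units` (1/1024 s), `rr_ms` or `rr_s`.  Comment lines
#' starting with `#` carry the seed, package version and config hash.
#' On load, values are normalized to device units (ms x 1.024, s x 1024,
#' rounded).
#'
#' @param rri An [rri_series].
#' @param path File path.
#' @param unit Unit to write: `"device_units"`, `"ms"` or `"s"`.
#' @param seed Seed recorded in the header.
#' @return `write_rri_csv`: the path, invisibly.  `load_rri_csv`: an
#'   [rri_series] in device units.
#' @export
write_rri_csv <- function(rri, path, unit = c("device_units", "ms", "s"),
                          seed = NA) {
  stopifnot(inherits(rri, "rri_series"))
  unit <- match.arg(unit)
  vals <- switch(unit,
                 device_units = rri$intervals,
                 ms = rri$intervals / 1.024,
                 s = rri$intervals / 1024)
  df <- data.frame(beat_index = seq_along(vals), v = vals)
  names(df)[2] <- paste0("rr_", unit)
  write_with_header(df, path, seed = seed, config = list(unit = unit))
}

#' @rdname write_rri_csv
#' @export
load_rri_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#")
  if (nrow(df) == 0) stop("empty RRI file: ", path)
  unit_col <- grep("^rr_", names(df), value = TRUE)
  if (length(unit_col) != 1) {
    stop("expected exactly one rr_<unit> column, found: ",
         paste(unit_col, collapse = ", "))
  }
  unit <- sub("^rr_", "", unit_col)
  if (!unit %in% c("device_units", "ms", "s")) {
    stop("unknown RR unit '", unit, "' (use device_units, ms or s)")
  }
  vals <- df[[unit_col]]
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    stop("non-numeric RR value at data row ", bad[1], " of ", path)
  }
  dev <- switch(unit,
                device_units = vals,
                ms = round(vals * 1.024),
                s = round(vals * 1024))
  rri_series(dev, origin = path)
}

#' Write / read the package's EEG CSV dialect
#'
#' Columns `t_s`, `TP9`, `Fp1`, `Fp2`, `TP10` (time in seconds, voltages
#' in uV).  On load, the sampling rate is inferred from the median time
#' step; time-step jitter above 1% of the median is a non-uniform
#' sampling error.
#'
#' @param rec An [eeg_recording].
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return `write_eeg_csv`: the path, invisibly.  `load_eeg_csv`: an
#'   [eeg_recording].
#' @export
write_eeg_csv <- function(rec, path, seed = NA) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(t_s = (seq_len(nrow(rec$samples)) - 1) / rec$fs)
  df <- cbind(df, as.data.frame(rec$samples))
  write_with_header(df, path, seed = seed, config = list(fs = rec$fs))
}

#' @rdname write_eeg_csv
#' @export
load_eeg_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#")
  need <- c("t_s", eeg_channels())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  dt <- diff(df$t_s)
  med <- stats::median(dt)
  if (med <= 0 || any(abs(dt - med) > 0.01 * med)) {
    stop("non-uniform sampling: time steps deviate more than 1% from the median")
  }
  eeg_recording(as.matrix(df[, eeg_channels()]), fs = 1 / med)
}

#' Write / read a JSON configuration file
#'
#' Plain JSON serialization for profile, rule and run configurations.
#'
#' @param config Named list.
#' @param path File path.
#' @return `config_write`: the path, invisibly.  `config_read`: the
#'   parsed list.
#' @export
config_write <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Simulate per-block shooting performance for a cohort
#'
#' Binomial destroyed-over-shots draws around the condition hit rates
#' (easy 0.64, medium 0.46, hard 0.24 — the observed performance
#' levels); the baseline block involves no shooting and gets `NA`.
#'
#' @param n_participants Number of trainees.
#' @param seed Integer seed.
#' @param hit_rates Named hit probabilities per shooting condition.
#' @param shots_mean Mean bullets per block (Poisson around it, min 10).
#' @return Tidy data.frame: `participant`, `condition`, `shots`,
#'   `destroyed`, `performance`.
#' @export
simulate_performance <- function(n_participants, seed = 1,
                                 hit_rates = c(easy = 0.64, medium = 0.46,
                                               hard = 0.24),
                                 shots_mean = 30) {
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      for (cond in c("baseline", names(hit_rates))) {
        if (cond == "baseline") {
          rows[[length(rows) + 1L]] <- data.frame(
            participant = p, condition = cond, shots = 0L, destroyed = 0L,
            performance = NA_real_)
        } else {
          shots <- max(stats::rpois(1, shots_mean), 10L)
          hit <- stats::rbinom(1, shots, hit_rates[[cond]])
          rows[[length(rows) + 1L]] <- data.frame(
            participant = p, condition = cond, shots = shots,
            destroyed = hit, performance = shooting_performance(shots, hit))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Run a complete synthetic study
#'
#' End-to-end orchestration of the session protocol: a seeded cohort
#' (3-min baseline plus three 3-min difficulty blocks), feature
#' extraction through both pipelines, shooting performance, the full
#' statistical battery, and SSQ scoring — with every table written to
#' `out_dir` (when given) under a seed/version/config-hash header.
#'
#' @param seed Integer seed.
#' @param n_participants Cohort size (default 10).
#' @param block_duration Block length in seconds (default 180).
#' @param fs EEG sampling rate in Hz.
#' @param condition_effects Profiles per condition
#'   (default [condition_profiles()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List of class `study_bundle`: `features` (tidy per-block
#'   table), `performance`, `report` (the [characterize()] output),
#'   `ssq` (scored responses with flags), `config`.
#' @export
run_full_study <- function(seed = 1, n_participants = 10,
                           block_duration = 180, fs = 500,
                           condition_effects = condition_profiles(),
                           out_dir = NULL) {
  config <- list(seed = seed, n_participants = n_participants,
                 block_duration = block_duration, fs = fs)
  spec <- cohort_spec(n_participants, condition_effects, block_duration,
                      seed = seed)
  cohort <- generate_cohort(spec, signals = "both", fs = fs)
  features <- extract_cohort_features(cohort)
  perf <- simulate_performance(n_participants, seed = seed + 1L)

  eeg_feats <- c("frontal_theta", "theta_beta", "engagement", "asymmetry")
  hrv_feats <- c("mean_hr", "sdnn", "rmssd", "vlf", "lf", "hf")
  mats <- lapply(c(eeg_feats, hrv_feats), function(f) feature_matrix(features, f))
  names(mats) <- c(eeg_feats, hrv_feats)
  mats$performance <- feature_matrix(perf, "performance",
                                     conditions = c("easy", "medium", "hard"))
  report <- characterize(mats)

  resp <- simulate_ssq_responses(n_participants, seed = seed + 2L)
  ssq <- do.call(rbind, lapply(seq_len(nrow(resp)), function(i) {
    sc <- score_ssq(unlist(resp[i, ]))
    fl <- flag_cutoffs(sc)
    data.frame(participant = i, nausea = sc$nausea,
               oculomotor = sc$oculomotor,
               disorientation = sc$disorientation, total = sc$total,
               flag_nausea = fl[["nausea"]],
               flag_oculomotor = fl[["oculomotor"]],
               flag_disorientation = fl[["disorientation"]],
               flag_total = fl[["total"]])
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_with_header(features, file.path(out_dir, "features.csv"),
                      seed, config)
    write_with_header(perf, file.path(out_dir, "performance.csv"),
                      seed, config)
    write_with_header(report$omnibus, file.path(out_dir, "omnibus.csv"),
                      seed, config)
    write_with_header(report$posthoc, file.path(out_dir, "posthoc.csv"),
                      seed, config)
    write_with_header(report$normality, file.path(out_dir, "normality.csv"),
                      seed, config)
    write_with_header(ssq, file.path(out_dir, "ssq.csv"), seed, config)
  }
  structure(list(features = features, performance = perf, report = report,
                 ssq = ssq, config = config),
            class = "study_bundle")
}
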