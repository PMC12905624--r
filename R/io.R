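parse_iso_timestamp <- function(x, file, rows) {
  ts <- rep(as.POSIXct(NA), length(x))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad))
    stop("malformed timestamp in ", file, " at row(s) ",
         paste(utils::head(rows[bad], 5), collapse = ", "))
  attr(ts, "tzone") <- "UTC"
  ts
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(file, ": missing column(s) ", paste(missing, collapse = ", "))
}

#' Read a CGM export
#'
#' Comma-separated, UTF-8, dot decimal; columns `participant_id`,
#' `timestamp` (ISO-8601, device-local clock, no timezone), `glucose_mg_dl`,
#' `sensor_id`. Rows are typed and sorted per participant; duplicate
#' timestamps within a sensor are collapsed to their mean with a warning.
#'
#' @param path CSV path.
#' @return Typed, sorted data frame.
#' @export
read_cgm_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("participant_id", "timestamp", "glucose_mg_dl",
                        "sensor_id"), path)
  rows <- seq_len(nrow(df)) + 1L  # header is row 1
  g <- suppressWarnings(as.numeric(df$glucose_mg_dl))
  bad <- which(is.na(g) | g <= 0)
  if (length(bad))
    stop(path, ": non-numeric or non-positive glucose at row(s) ",
         paste(utils::head(rows[bad], 5), collapse = ", "))
  df$glucose_mg_dl <- g
  df$timestamp <- parse_iso_timestamp(df$timestamp, path, rows)

  key <- paste(df$participant_id, df$sensor_id, as.numeric(df$timestamp))
  if (anyDuplicated(key)) {
    warning("duplicate timestamps within a sensor collapsed to their mean",
            call. = FALSE)
    agg <- tapply(df$glucose_mg_dl, key, mean)
    df <- df[!duplicated(key), , drop = FALSE]
    df$glucose_mg_dl <- as.numeric(agg[paste(df$participant_id, df$sensor_id,
                                             as.numeric(df$timestamp))])
  }
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an EMA export
#'
#' Columns `participant_id`, `timestamp`, and VAS items `happy`, `sad`,
#' `hunger`, `satiety` in \[0, 100\].
#'
#' @param path CSV path.
#' @return Typed, sorted data frame.
#' @export
read_ema_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- c("happy", "sad", "hunger", "satiety")
  require_columns(df, c("participant_id", "timestamp", items), path)
  rows <- seq_len(nrow(df)) + 1L
  df$timestamp <- parse_iso_timestamp(df$timestamp, path, rows)
  for (col in items) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which((is.na(v) & !is.na(df[[col]])) | v < 0 | v > 100)
    if (length(bad))
      stop(path, ": invalid ", col, " rating at row(s) ",
           paste(utils::head(rows[bad], 5), collapse = ", "))
    df[[col]] <- v
  }
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read the participant table
#'
#' @param path CSV path with `participant_id`, `sex`, `age`, `bmi` and the
#'   fasting panels `fasting_glucose_1..3`, `fasting_insulin_1..3`,
#'   `triglycerides_1..3` (missing draws empty).
#' @return Typed data frame.
#' @export
read_participants_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("participant_id", "sex", "age", "bmi"), path)
  df
}

iso_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write the cohort tables of a simulated cohort
#'
#' Writes `cgm.csv`, `ema.csv`, `participants.csv` and a `ground_truth.json`
#' sidecar (per-participant couplings, global paths, implied true effects).
#'
#' @param cohort A `glyco_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(cohort$cgm)) {
    cgm <- cohort$cgm[, c("participant_id", "timestamp", "glucose_mg_dl",
                          "sensor_id")]
    cgm$timestamp <- iso_ts(cgm$timestamp)
    paths$cgm <- file.path(dir, "cgm.csv")
    utils::write.csv(cgm, paths$cgm, row.names = FALSE)
  }
  ema <- cohort$ema
  ema$timestamp <- iso_ts(ema$timestamp)
  paths$ema <- file.path(dir, "ema.csv")
  utils::write.csv(ema, paths$ema, row.names = FALSE)
  paths$participants <- file.path(dir, "participants.csv")
  utils::write.csv(cohort$participants, paths$participants, row.names = FALSE)
  truth <- cohort$truth
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(a = as.list(truth$a), b = truth$b, c_prime = truth$c_prime,
         acme = truth$acme, ade = truth$ade, total = truth$total,
         basal = as.list(truth$basal),
         glucose_center = truth$glucose_center,
         glucose_scale = truth$glucose_scale),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

fit_to_list <- function(fit) {
  list(coefficients = fit$coefficients, fallback = fit$fallback,
       singular = fit$singular, n_obs = fit$n_obs, n_groups = fit$n_groups)
}

mediation_to_list <- function(med) {
  s <- function(x) list(estimate = x$estimate, ci = x$ci, p = x$p)
  list(acme = s(med$acme), ade = s(med$ade), total = s(med$total),
       prop_mediated = s(med$prop_mediated),
       prop_unstable = med$prop_unstable, prop_excluded = med$prop_excluded,
       n_sims = med$n_sims,
       total_effect_model = med$total_effect_model)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load), preprocess, align, derive indices, fit the study
#' models, extract interoceptive accuracy and run the mediation — returning
#' one results bundle. Identical config and seed give identical output.
#'
#' @param params A [cohort_params()] for simulation, or `NULL` when `cgm`,
#'   `ema` and `participants` are supplied.
#' @param config A [preprocess_config()].
#' @param cgm,ema,participants Optional pre-loaded input tables.
#' @param n_sims Mediation resamples.
#' @param extended Also fit the covariate-extended models.
#' @param out_dir Optional directory for `aligned.csv`,
#'   `participants_derived.csv`, `results.json`, `mediation.json`,
#'   `manifest.json`.
#' @param verbose Per-participant preprocessing log messages.
#' @return List of class `glyco_results`: `aligned`, `qc`, `participants`,
#'   `fits`, `accuracy`, `moods`, `accuracy_fits`, `mediation`, and `truth`
#'   when simulated.
#' @export
run_pipeline <- function(params = cohort_params(), config = preprocess_config(),
                         cgm = NULL, ema = NULL, participants = NULL,
                         n_sims = 10000, extended = FALSE, out_dir = NULL,
                         verbose = FALSE) {
  truth <- NULL
  if (is.null(cgm) || is.null(ema) || is.null(participants)) {
    if (is.null(params)) stop("either supply data tables or simulation params")
    cohort <- simulate_cohort(params)
    cgm <- cohort$cgm
    ema <- cohort$ema
    participants <- cohort$participants
    truth <- cohort$truth
  }
  pre <- preprocess_cgm(cgm, config, verbose = verbose)
  ema_matched <- align_glucose_to_ema(pre$gridded, ema, config)
  participants <- derive_indices(participants)
  built <- build_aligned(ema_matched, participants, config)
  aligned <- built$aligned

  fits <- fit_study_models(aligned, extended = FALSE)
  if (extended) fits <- c(fits, stats::setNames(
    fit_study_models(aligned, extended = TRUE),
    paste0(names(model_catalogue()), "_ext")))

  scores <- interoceptive_accuracy(aligned)
  moods <- mood_summary(aligned)
  acc_fits <- accuracy_models(scores, moods, participants)
  seed_med <- if (!is.null(params)) params$seed else 1L
  med <- mediate_glucose_mood(aligned, n_sims = n_sims, seed = seed_med)

  results <- structure(list(
    aligned = aligned, qc = built$qc, participants = participants,
    preprocess_log = pre$log, fits = fits, accuracy = scores, moods = moods,
    accuracy_fits = acc_fits, mediation = med, truth = truth,
    params = params, config = config
  ), class = "glyco_results")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    al_out <- aligned
    al_out$timestamp <- iso_ts(al_out$timestamp)
    utils::write.csv(al_out, file.path(out_dir, "aligned.csv"),
                     row.names = FALSE)
    utils::write.csv(participants,
                     file.path(out_dir, "participants_derived.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(fits, fit_to_list),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(mediation_to_list(med),
                         file.path(out_dir, "mediation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- list(
      package_version = as.character(utils::packageVersion("glycomood")),
      r_version = as.character(getRversion()),
      seed = seed_med,
      n_sims = n_sims,
      config = unclass(config),
      params = if (!is.null(params))
        unclass(params)[!vapply(unclass(params), is.function, TRUE)] else NULL
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results
}

#' @export
print.glyco_results <- function(x, ...) {
  cat("glycomood results:", length(unique(x$aligned$participant_id)),
      "included participants,", nrow(x$aligned), "aligned observations\n\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    key <- f$spec$slopes[1]
    row <- f$coefficients[f$coefficients$term == key, ]
    if (nrow(row))
      cat(sprintf("  %-28s b = %7.3f  95%% CI [%7.3f, %7.3f]  p = %.3g\n",
                  f$spec$label, row$estimate, row$ci_lo, row$ci_hi, row$p))
  }
  cat("\n")
  print(x$mediation)
  invisible(x)
}
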