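#' Split a CGM record into gap-free, single-sensor segments
#'
#' Splits strictly where the interval between consecutive samples exceeds
#' `max_gap` minutes, or where the sensor identifier changes (a replacement
#' sensor has its own calibration regime even when no time gap occurred).
#' A gap of exactly `max_gap` does not split. Concatenating the returned
#' segments reproduces the input exactly.
#'
#' @param samples Data frame with `timestamp` (POSIXct), `glucose_mg_dl`, and
#'   `sensor_id`, time-sorted for one participant.
#' @param max_gap Maximum bridgeable gap, minutes.
#' @return The input with an integer `segment` column added.
#' @export
segment_by_gaps <- function(samples, max_gap = 20) {
  if (nrow(samples) == 0) {
    samples$segment <- integer(0)
    return(samples)
  }
  t <- as.numeric(samples$timestamp)
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing within a participant")
  gap_min <- diff(t) / 60
  new_seg <- c(TRUE, gap_min > max_gap |
                 samples$sensor_id[-1] != samples$sensor_id[-nrow(samples)])
  samples$segment <- cumsum(new_seg)
  samples
}

#' Fill short gaps inside segments by linear interpolation
#'
#' Each segment is placed on the regular `grid_step`-minute grid between its
#' first and last sample (grid aligned to clock time, bins labelled by their
#' left edge). Missing interior grid points are filled by linear interpolation
#' between the flanking observations; nothing is extrapolated beyond segment
#' ends, and segments are never merged, so no gap longer than the segmentation
#' threshold is ever bridged.
#'
#' @param segment Data frame with `timestamp`, `glucose_mg_dl`, `sensor_id`
#'   and (optionally) a `segment` column; processed per segment.
#' @param grid_step Grid spacing, minutes.
#' @return Data frame on the grid with a logical `observed` column (`FALSE`
#'   for interpolated points).
#' @export
interpolate_short_gaps <- function(segment, grid_step = 5) {
  if (!"segment" %in% names(segment)) segment$segment <- 1L
  step <- grid_step * 60
  out <- lapply(split(segment, segment$segment), function(seg) {
    t <- round(as.numeric(seg$timestamp) / step) * step
    grid <- seq(t[1], t[length(t)], by = step)
    vals <- if (length(t) > 1) {
      approx(t, seg$glucose_mg_dl, xout = grid, method = "linear")$y
    } else {
      seg$glucose_mg_dl
    }
    data.frame(
      participant_id = seg$participant_id[1],
      timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
      glucose_mg_dl = vals,
      sensor_id = seg$sensor_id[1],
      segment = seg$segment[1],
      observed = grid %in% t,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$timestamp), , drop = FALSE]
}

# sliding-window quantile baseline, smoothed with a monotone (shape
# preserving) cubic interpolant through the window anchors
estimate_drift_baseline <- function(t_min, values, config) {
  dur <- t_min[length(t_min)] - t_min[1]
  rel <- t_min - t_min[1]
  centers <- seq(0, dur, by = config$drift_step)
  if (length(centers) < 2) centers <- c(0, dur)
  half <- config$drift_window / 2
  anchors <- vapply(centers, function(cc) {
    idx <- rel >= cc - half & rel <= cc + half
    quantile(values[idx], config$drift_quantile, names = FALSE, type = 7)
  }, 0)
  if (length(unique(centers)) < 2) return(rep(anchors[1], length(values)))
  f <- splinefun(centers, anchors, method = "monoH.FC")
  b <- f(pmin(pmax(rel, 0), dur))
  b
}

#' Remove slow non-physiological sensor drift within each segment
#'
#' Estimates a slowly varying baseline per segment by sliding a
#' `drift_window`-minute window across it in `drift_step`-minute steps, taking
#' a low quantile (`drift_quantile`) of the values in each window — tracking
#' the fasting envelope without chasing meal peaks — smoothing the anchored
#' points with a monotone cubic interpolant, and subtracting it. The output is
#' centred near zero; meal excursions survive as positive deviations. Segments
#' shorter than `min_drift_duration` minutes lack support for a windowed
#' baseline: they have their within-segment `drift_quantile` quantile
#' subtracted instead and are flagged (`drift_skipped`) with a warning.
#'
#' @param segment Gridded data frame (see [interpolate_short_gaps()]).
#' @param config A [preprocess_config()].
#' @return Data frame with `glucose_mg_dl` replaced by drift-removed values,
#'   plus `drift_baseline` (the subtracted curve) and `drift_skipped` columns.
#' @export
correct_drift <- function(segment, config = preprocess_config()) {
  if (!"segment" %in% names(segment)) segment$segment <- 1L
  out <- lapply(split(segment, segment$segment), function(seg) {
    t_min <- as.numeric(seg$timestamp) / 60
    dur <- t_min[length(t_min)] - t_min[1]
    if (nrow(seg) < 2 || dur < config$min_drift_duration) {
      warning("segment of ", round(dur), " min too short for windowed drift ",
              "correction; subtracting its ", config$drift_quantile,
              " quantile", call. = FALSE)
      base <- rep(quantile(seg$glucose_mg_dl, config$drift_quantile,
                           names = FALSE), nrow(seg))
      skipped <- TRUE
    } else {
      base <- estimate_drift_baseline(t_min, seg$glucose_mg_dl, config)
      skipped <- FALSE
    }
    seg$drift_baseline <- base
    seg$glucose_mg_dl <- seg$glucose_mg_dl - base
    seg$drift_skipped <- skipped
    seg
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$timestamp), , drop = FALSE]
}

#' Participant-specific stable overnight baseline
#'
#' Scans the raw (pre-correction) values in the overnight fasting window
#' (by default 00:00-08:00) of every study night with a sliding
#' `baseline_window`-minute window advanced in `baseline_step`-minute steps.
#' Window variability is the sample SD; each night's candidate is the mean of
#' its lowest-SD complete window, and the returned baseline is the minimum
#' candidate across nights — a conservative fasting reference that gives both
#' sensors a common absolute anchor. If no night has a complete window the
#' baseline falls back to the 5th percentile of all raw values and is flagged.
#'
#' @param samples Raw samples for one participant (`timestamp`,
#'   `glucose_mg_dl`).
#' @param config A [preprocess_config()].
#' @return List with `value` (mg/dL), `source_night` (Date), `source_window`
#'   (POSIXct window start), `fallback` (logical).
#' @export
compute_stable_baseline <- function(samples, config = preprocess_config()) {
  t <- as.numeric(samples$timestamp)
  v <- samples$glucose_mg_dl
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  dates <- as.Date(samples$timestamp[ord], tz = "UTC")
  secs_of_day <- t %% 86400
  on_lo <- config$overnight_window[1] * 3600
  on_hi <- config$overnight_window[2] * 3600
  win <- config$baseline_window * 60
  step <- config$baseline_step * 60
  min_pts <- floor(config$baseline_window / config$grid_step)

  best_value <- Inf
  best_night <- as.Date(NA)
  best_start <- as.POSIXct(NA, tz = "UTC")
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  range_sum <- function(i, j) if (i > j) 0 else cs[j] - if (i > 1) cs[i - 1] else 0
  range_sum2 <- function(i, j) if (i > j) 0 else cs2[j] - if (i > 1) cs2[i - 1] else 0

  for (d in unique(dates)) {
    day0 <- as.numeric(as.POSIXct(as.character(as.Date(d, origin = "1970-01-01")),
                                  tz = "UTC"))
    starts <- seq(day0 + on_lo, day0 + on_hi - win, by = step)
    night_best_sd <- Inf
    night_mean <- NA_real_
    night_start <- NA_real_
    for (s in starts) {
      i <- findInterval(s - 1e-6, t) + 1L
      j <- findInterval(s + win - 1e-6, t)
      npts <- j - i + 1L
      if (npts < min_pts) next
      m <- range_sum(i, j) / npts
      ss <- range_sum2(i, j) - npts * m^2
      sdv <- sqrt(max(ss, 0) / (npts - 1))
      if (sdv < night_best_sd) {
        night_best_sd <- sdv
        night_mean <- m
        night_start <- s
      }
    }
    if (is.finite(night_best_sd) && night_mean < best_value) {
      best_value <- night_mean
      best_night <- as.Date(d, origin = "1970-01-01")
      best_start <- as.POSIXct(night_start, origin = "1970-01-01", tz = "UTC")
    }
  }

  if (!is.finite(best_value)) {
    return(list(value = quantile(v, 0.05, names = FALSE),
                source_night = as.Date(NA), source_window = as.POSIXct(NA),
                fallback = TRUE))
  }
  list(value = best_value, source_night = best_night,
       source_window = best_start, fallback = FALSE)
}

#' Re-reference drift-removed values to the stable overnight baseline
#'
#' Adds the participant's stable baseline to every drift-removed sample so
#' the overnight lowest-variability windows sit near the baseline value and
#' both sensors share a common absolute reference.
#'
#' @param segment Drift-removed data frame.
#' @param baseline Result of [compute_stable_baseline()] (or a number).
#' @return Data frame with shifted `glucose_mg_dl`.
#' @export
rebaseline <- function(segment, baseline) {
  value <- if (is.list(baseline)) baseline$value else baseline
  segment$glucose_mg_dl <- segment$glucose_mg_dl + value
  segment
}

# kernel-weighted moving average with edge renormalisation (kernel re-summed
# to 1 where it is truncated by a segment boundary)
smooth_values <- function(x, kernel) {
  n <- length(x)
  h <- (length(kernel) - 1) / 2
  if (n == 1) return(x)
  num <- as.numeric(stats::filter(c(rep(0, h), x, rep(0, h)), kernel, sides = 2))
  den <- as.numeric(stats::filter(c(rep(0, h), rep(1, n), rep(0, h)), kernel,
                                  sides = 2))
  (num / den)[(h + 1):(h + n)]
}

#' Gaussian smoothing within segments
#'
#' Convolves each segment with a truncated Gaussian kernel (`smooth_window`
#' taps, SD `smooth_sigma` grid steps), renormalised to sum to one at segment
#' edges. Smoothing never crosses segment boundaries.
#'
#' @param series Gridded data frame with a `segment` column.
#' @param config A [preprocess_config()].
#' @return Data frame with smoothed `glucose_mg_dl`.
#' @export
gaussian_smooth <- function(series, config = preprocess_config()) {
  if (!"segment" %in% names(series)) series$segment <- 1L
  h <- (config$smooth_window - 1) / 2
  kernel <- dnorm(seq(-h, h), 0, config$smooth_sigma)
  kernel <- kernel / sum(kernel)
  out <- lapply(split(series, series$segment), function(seg) {
    seg$glucose_mg_dl <- smooth_values(seg$glucose_mg_dl, kernel)
    seg
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$timestamp), , drop = FALSE]
}

#' Assign samples to a global 5-minute grid
#'
#' Bins are left-closed `[t, t + grid_step)` and labelled by their left edge;
#' multiple samples falling into one bin are averaged. Gaps remain empty (no
#' rows are invented).
#'
#' @param series Data frame with `timestamp` and `glucose_mg_dl`.
#' @param grid_step Grid spacing, minutes.
#' @return Data frame with one row per occupied bin.
#' @export
resample_to_grid <- function(series, grid_step = 5) {
  step <- grid_step * 60
  bin <- floor(as.numeric(series$timestamp) / step) * step
  agg <- tapply(series$glucose_mg_dl, bin, mean)
  keep_first <- !duplicated(bin)
  first <- series[keep_first, , drop = FALSE]
  first <- first[order(bin[keep_first]), , drop = FALSE]
  out <- data.frame(
    timestamp = as.POSIXct(sort(unique(bin)), origin = "1970-01-01", tz = "UTC"),
    glucose_mg_dl = as.numeric(agg[order(as.numeric(names(agg)))]),
    stringsAsFactors = FALSE
  )
  for (col in intersect(c("participant_id", "sensor_id", "segment", "observed"),
                        names(series)))
    out[[col]] <- first[[col]]
  out
}

#' Match each EMA to its lag-appropriate glucose value
#'
#' Interstitial glucose trails blood glucose by several minutes, so the value
#' physiologically concurrent with an assessment at time `t` is recorded
#' shortly after it: all gridded samples with timestamps in
#' `[t + lag_window[1], t + lag_window[2]]` minutes (closed interval, so both
#' the 5- and the 10-minute grid points qualify under the default window) are
#' averaged into the matched value. An empty window yields `NA`: that
#' assessment has no concurrent glucose and is dropped from modelling and from
#' the concurrent-run count.
#'
#' @param gridded Gridded CGM data frame (may contain several participants).
#' @param ema EMA data frame with `participant_id` and `timestamp`.
#' @param config A [preprocess_config()].
#' @return `ema` with `glucose` (matched value, mg/dL) added.
#' @export
align_glucose_to_ema <- function(gridded, ema, config = preprocess_config()) {
  lo <- config$lag_window[1] * 60
  hi <- config$lag_window[2] * 60
  ema$glucose <- NA_real_
  for (pid in unique(ema$participant_id)) {
    g <- gridded[gridded$participant_id == pid, , drop = FALSE]
    e_idx <- which(ema$participant_id == pid)
    if (nrow(g) == 0) next
    gt <- as.numeric(g$timestamp)
    ord <- order(gt)
    gt <- gt[ord]
    gv <- g$glucose_mg_dl[ord]
    cs <- c(0, cumsum(gv))
    et <- as.numeric(ema$timestamp[e_idx])
    i <- findInterval(et + lo - 1e-6, gt) + 1L
    j <- findInterval(et + hi + 1e-6, gt)
    n_in <- pmax(j - i + 1L, 0L)
    val <- ifelse(n_in > 0, (cs[j + 1L] - cs[i]) / n_in, NA_real_)
    ema$glucose[e_idx] <- val
  }
  ema
}

#' Participant inclusion decision
#'
#' A participant enters the analysis only with at least `min_runs` EMA runs
#' that have a concurrent (matched) CGM value.
#'
#' @param aligned Aligned observations for one participant (needs `glucose`).
#' @param min_runs Inclusion threshold.
#' @return List with `include` (logical) and `n_concurrent`.
#' @export
qc_participant <- function(aligned, min_runs = 20) {
  n <- sum(!is.na(aligned$glucose))
  list(include = n >= min_runs, n_concurrent = n)
}

#' Run the full CGM conditioning chain for a cohort
#'
#' Per participant: segment by gaps and sensor changes, interpolate short gaps
#' onto the grid, remove per-segment drift, compute the stable overnight
#' baseline from the raw samples, re-reference, Gaussian-smooth within
#' segments, and assign to the global 5-minute grid.
#'
#' @param cgm Raw CGM data frame (`participant_id`, `timestamp`,
#'   `glucose_mg_dl`, `sensor_id`).
#' @param config A [preprocess_config()].
#' @param verbose Emit one log message per participant.
#' @return List with `gridded` (processed samples, all participants) and
#'   `log` (per-participant data frame: segments, interpolated points,
#'   baseline value, fallback flag).
#' @export
preprocess_cgm <- function(cgm, config = preprocess_config(), verbose = FALSE) {
  pieces <- list()
  logs <- list()
  for (pid in unique(cgm$participant_id)) {
    raw <- cgm[cgm$participant_id == pid, , drop = FALSE]
    raw <- raw[order(raw$timestamp), , drop = FALSE]
    seg <- segment_by_gaps(raw, config$max_gap)
    grid <- interpolate_short_gaps(seg, config$grid_step)
    corrected <- withCallingHandlers(
      correct_drift(grid, config),
      warning = function(w) invokeRestart("muffleWarning")
    )
    baseline <- compute_stable_baseline(raw, config)
    shifted <- rebaseline(corrected, baseline)
    smoothed <- gaussian_smooth(shifted, config)
    gridded <- resample_to_grid(smoothed, config$grid_step)
    gridded$participant_id <- pid
    pieces[[pid]] <- gridded
    logs[[pid]] <- data.frame(
      participant_id = pid,
      n_raw = nrow(raw),
      n_segments = max(seg$segment),
      n_interpolated = sum(!grid$observed),
      baseline = baseline$value,
      baseline_fallback = baseline$fallback,
      stringsAsFactors = FALSE
    )
    if (verbose)
      message(sprintf(
        "%s: %d segments, %d interpolated points, baseline %.1f mg/dL%s",
        pid, max(seg$segment), sum(!grid$observed), baseline$value,
        if (baseline$fallback) " (fallback)" else ""))
  }
  gridded <- do.call(rbind, pieces)
  rownames(gridded) <- NULL
  list(gridded = gridded, log = do.call(rbind, c(logs, make.row.names = FALSE)))
}
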