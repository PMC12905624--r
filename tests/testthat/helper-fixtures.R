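# hand-built CGM sample tables on the 5-minute grid
make_samples <- function(minutes, values, sensor = "S1", pid = "P1",
                         origin = as.POSIXct("2024-01-08 00:00:00", tz = "UTC")) {
  data.frame(
    participant_id = pid,
    timestamp = origin + minutes * 60,
    glucose_mg_dl = values,
    sensor_id = sensor,
    stringsAsFactors = FALSE
  )
}

# small cohort parameter sets reused across test files
quiet_params <- function(...) {
  cohort_params(noise_sd = 0, drift_amplitude = 0, circadian_amplitude = 0,
                meal_amplitude = 0, meal_amp_cv = 0, short_gap_rate = 0,
                long_gap_rate = 0, sensor_offset_sd = 0, ...)
}
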