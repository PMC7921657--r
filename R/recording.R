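#' Construct an ERG recording
#'
#' One time-voltage trace for one animal, flash and adaptation state.
#' Time is in ms relative to flash onset (t = 0); the trace must include a
#' pre-flash baseline segment of at least 10 ms and sit on a uniform grid.
#' Voltage is in microvolts.
#'
#' @param animal_id Identifier (coerced to character).
#' @param group `"WT"` or `"MODEL"`.
#' @param stimulus A [flash_stimulus()].
#' @param sampling_rate Sampling rate in Hz.
#' @param time Numeric vector, ms relative to flash onset, strictly
#'   increasing, uniformly spaced (relative tolerance 1e-6).
#' @param voltage Numeric vector, microvolts, same length as `time`.
#' @return An `erg_recording` object.
#' @export
erg_recording <- function(animal_id, group = c("WT", "MODEL"), stimulus,
                          sampling_rate, time, voltage) {
  group <- match.arg(group)
  if (!inherits(stimulus, "flash_stimulus")) {
    abort_invalid("stimulus must be a flash_stimulus")
  }
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    abort_invalid("sampling_rate must be positive")
  }
  if (length(time) != length(voltage)) {
    abort_invalid("time and voltage must have equal length")
  }
  dt <- check_uniform_time(time, context = paste0("recording ", animal_id))
  if (abs(dt - 1000 / sampling_rate) > 1e-6 * dt) {
    abort_invalid(sprintf(
      "sample interval %.6g ms inconsistent with sampling_rate %g Hz",
      dt, sampling_rate))
  }
  if (time[1] > -10) {
    abort_invalid("recording must include a pre-flash segment of >= 10 ms")
  }
  structure(list(animal_id = as.character(animal_id), group = group,
                 stimulus = stimulus, sampling_rate = sampling_rate,
                 time = as.numeric(time), voltage = as.numeric(voltage)),
            class = "erg_recording")
}

#' @export
print.erg_recording <- function(x, ...) {
  cat(sprintf(
    "<erg_recording> animal %s (%s), %s %.4g cd s m^-2, %g Hz, %d samples [%g, %g] ms\n",
    x$animal_id, x$group, x$stimulus$adaptation, x$stimulus$luminance,
    x$sampling_rate, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

# Internal fast-path constructor: skips validation (caller guarantees a
# valid uniform grid), used by the simulator.
new_erg_recording <- function(animal_id, group, stimulus, sampling_rate,
                              time, voltage) {
  structure(list(animal_id = animal_id, group = group, stimulus = stimulus,
                 sampling_rate = sampling_rate, time = time,
                 voltage = voltage),
            class = "erg_recording")
}

recording_key <- function(rec) {
  paste(rec$animal_id, rec$stimulus$adaptation, rec$stimulus$luminance,
        sep = "|")
}

REC_COLUMNS <- c("animal_id", "group", "adaptation", "luminance_cdsm2",
                 "time_ms", "voltage_uV")

#' Read a set of ERG recordings from long-format CSV
#'
#' The file dialect is comma-delimited UTF-8 with a header row
#' `animal_id,group,adaptation,luminance_cdsm2,time_ms,voltage_uV` and one
#' sample per line. One [erg_recording()] is built per
#' (animal, adaptation, luminance) combination; rows may appear in any order.
#' Sampling rate is inferred from the time grid.
#'
#' @param path File path.
#' @return Named list of `erg_recording` objects (keys
#'   `animal|adaptation|luminance`).
#' @export
read_recording_set <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(REC_COLUMNS, names(df))
  if (length(missing)) {
    abort_parse(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(df$group %in% c("WT", "MODEL"))) {
    abort_parse("group must be WT or MODEL")
  }
  if (!all(df$adaptation %in% c("DA", "LA"))) {
    abort_parse("adaptation must be DA or LA")
  }
  key <- paste(df$animal_id, df$adaptation, df$luminance_cdsm2, sep = "|")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, ]
    sub <- sub[order(sub$time_ms), ]
    if (anyDuplicated(sub$time_ms)) {
      abort_parse(sprintf("duplicate time samples in record %s/%s/%g",
                          sub$animal_id[1], sub$adaptation[1],
                          sub$luminance_cdsm2[1]))
    }
    if (length(unique(sub$group)) != 1L) {
      abort_parse(sprintf("conflicting group labels for animal %s",
                          sub$animal_id[1]))
    }
    dt <- check_uniform_time(
      sub$time_ms,
      context = sprintf("record %s/%s/%g", sub$animal_id[1],
                        sub$adaptation[1], sub$luminance_cdsm2[1]))
    erg_recording(sub$animal_id[1], sub$group[1],
                  flash_stimulus(sub$luminance_cdsm2[1], sub$adaptation[1]),
                  sampling_rate = 1000 / dt,
                  time = sub$time_ms, voltage = sub$voltage_uV)
  })
  out[order(names(out))]
}

#' Write a set of ERG recordings to long-format CSV
#'
#' Inverse of [read_recording_set()]; the round trip reproduces each trace at
#' the printed precision.
#'
#' @param recordings List of [erg_recording()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording_set <- function(recordings, path) {
  rows <- lapply(recordings, function(r) {
    data.frame(animal_id = r$animal_id, group = r$group,
               adaptation = r$stimulus$adaptation,
               luminance_cdsm2 = r$stimulus$luminance,
               time_ms = r$time, voltage_uV = r$voltage,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write recordings to %s", path))
  invisible(path)
}
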