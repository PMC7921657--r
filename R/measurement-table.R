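# Measurement table: one row per recording with every component measurement
# and reliability flags. Plain data.frame so the full tidy/statistics stack
# applies directly.

MEAS_NUMERIC <- c("luminance", "a_amp", "a_it", "a_fixed_amp", "b_amp",
                  "b_it", "mop_amp", "op_time_sum", "phnr_amp", "phnr_it")
MEAS_COLUMNS <- c("animal_id", "group", "adaptation", MEAS_NUMERIC, "flags")

#' Construct a component measurement row
#'
#' Holds the per-recording amplitudes (microvolts) and implicit times (ms) of
#' the a-wave (trough and fixed-time), b-wave, oscillatory potentials (mean
#' amplitude and summed peak time) and PhNR, plus semicolon-joinable
#' reliability flags. PhNR fields must be `NA` for dark-adapted rows.
#'
#' @param animal_id,group,adaptation Identifiers (`group` in WT/MODEL,
#'   `adaptation` in DA/LA).
#' @param luminance Flash energy in cd s m^-2.
#' @param a_amp,a_it,a_fixed_amp,b_amp,b_it,mop_amp,op_time_sum,phnr_amp,phnr_it
#'   Measurements; `NA` where a component was not measured.
#' @param flags Character vector of flag tokens (may be empty).
#' @return One-row data.frame with class `component_row` semantics.
#' @export
component_row <- function(animal_id, group, adaptation, luminance,
                          a_amp = NA_real_, a_it = NA_real_,
                          a_fixed_amp = NA_real_,
                          b_amp = NA_real_, b_it = NA_real_,
                          mop_amp = NA_real_, op_time_sum = NA_real_,
                          phnr_amp = NA_real_, phnr_it = NA_real_,
                          flags = character()) {
  amps <- c(a_amp, a_fixed_amp, b_amp, mop_amp, phnr_amp)
  if (any(!is.na(amps) & amps < -1e-9)) {
    abort_invalid("amplitudes are stored as magnitudes and must be >= 0")
  }
  if (adaptation == "DA" && (!is.na(phnr_amp) || !is.na(phnr_it))) {
    abort_invalid("PhNR fields must be NA for dark-adapted rows")
  }
  data.frame(animal_id = as.character(animal_id), group = group,
             adaptation = adaptation, luminance = luminance,
             a_amp = a_amp, a_it = a_it, a_fixed_amp = a_fixed_amp,
             b_amp = b_amp, b_it = b_it, mop_amp = mop_amp,
             op_time_sum = op_time_sum, phnr_amp = phnr_amp,
             phnr_it = phnr_it,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Assemble and validate a measurement table
#'
#' Binds component rows and enforces the uniqueness of
#' (animal_id, adaptation, luminance) keys.
#'
#' @param rows A list of [component_row()] data.frames, or a single
#'   data.frame with the measurement columns.
#' @return data.frame with class `measurement_table`.
#' @export
measurement_table <- function(rows) {
  df <- if (is.data.frame(rows)) {
    rows
  } else if (is.null(rows) || !length(rows)) {
    NULL
  } else {
    do.call(rbind, rows)
  }
  if (is.null(df)) {
    df <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(MEAS_COLUMNS))), MEAS_COLUMNS)
    df$animal_id <- character(); df$group <- character()
    df$adaptation <- character(); df$flags <- character()
    for (col in MEAS_NUMERIC) df[[col]] <- numeric()
  }
  missing <- setdiff(MEAS_COLUMNS, names(df))
  if (length(missing)) {
    abort_invalid(paste0("measurement table missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  df <- df[, MEAS_COLUMNS]
  key <- paste(df$animal_id, df$adaptation, df$luminance, sep = "|")
  if (anyDuplicated(key)) {
    abort_invalid(sprintf("duplicate measurement key: %s",
                          key[anyDuplicated(key)]))
  }
  rownames(df) <- NULL
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Write a measurement table to CSV
#'
#' Numeric fields are serialized at 6 significant digits and `flags` as
#' semicolon-joined tokens, so a [read_measurement_table()] round trip
#' returns an equal table at that precision.
#'
#' @param table A [measurement_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_measurement_table <- function(table, path) {
  table <- measurement_table(table)
  out <- as.data.frame(table)
  for (col in MEAS_NUMERIC) out[[col]] <- signif(out[[col]], 6)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write measurement table to %s", path))
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' @param path File written by [write_measurement_table()].
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal_id = "character"))
  if (nrow(df)) {
    df$flags <- ifelse(is.na(df$flags), "", as.character(df$flags))
    for (col in MEAS_NUMERIC) df[[col]] <- as.numeric(df[[col]])
  } else {
    df$flags <- character()
    df$animal_id <- character()
  }
  measurement_table(df)
}

# Split a flags string into tokens.
flag_tokens <- function(flags) {
  if (!length(flags)) return(character())
  unlist(strsplit(flags, ";", fixed = TRUE))
}

row_has_flag <- function(table, token) {
  vapply(strsplit(table$flags, ";", fixed = TRUE),
         function(f) token %in% f, logical(1))
}
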