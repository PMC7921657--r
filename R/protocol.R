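#' Canonical 8-step flash luminance protocol
#'
#' The flash energies (cd s m^-2) of the standard 8-step full-field series
#' used throughout the package: 0.01 to 25.0 in steps of approximately
#' 0.5 log units. These are the named stimulus strengths of a conventional
#' rodent dark-/light-adapted luminance series.
#'
#' @format Numeric vector of length 8, strictly increasing.
#' @export
ERG_PROTOCOL_8STEP <- c(0.01, 0.03, 0.10, 0.30, 1.0, 3.0, 10.0, 25.0)

#' Build a log-spaced flash luminance protocol
#'
#' Returns `n_steps` flash energies equally spaced in log10 between
#' `min_luminance` and `max_luminance` (both included). The conventional
#' 8-step series 0.01--25 cd s m^-2 has a constant spacing of
#' `log10(25/0.01)/7` (about 0.485, i.e. roughly half a log unit).
#'
#' @param min_luminance,max_luminance Flash energies in cd s m^-2;
#'   `0 < min < max`.
#' @param n_steps Number of flashes (>= 2).
#' @return Strictly increasing numeric vector of length `n_steps`.
#' @examples
#' build_flash_protocol(0.01, 25, 8)
#' @seealso [ERG_PROTOCOL_8STEP] for the canonical rounded series.
#' @export
build_flash_protocol <- function(min_luminance, max_luminance, n_steps) {
  if (!is_scalar_number(min_luminance) || !is_scalar_number(max_luminance) ||
      min_luminance <= 0 || max_luminance <= min_luminance) {
    abort_invalid("require max_luminance > min_luminance > 0")
  }
  if (!is_scalar_number(n_steps) || n_steps < 2 || n_steps != round(n_steps)) {
    abort_invalid("n_steps must be an integer >= 2")
  }
  10^seq(log10(min_luminance), log10(max_luminance), length.out = n_steps)
}

#' Flash stimulus descriptor
#'
#' A single flash condition: energy, adaptation state and background.
#' Dark-adapted (DA) flashes are presented on a dark background; light-adapted
#' (LA) flashes on a rod-suppressing background (30 cd m^-2 by default).
#'
#' @param luminance Flash energy in cd s m^-2 (> 0).
#' @param adaptation `"DA"` or `"LA"`.
#' @param background_luminance Background in cd m^-2; defaults to 0 for DA and
#'   30 for LA. DA requires a 0 background.
#' @return A `flash_stimulus` object (list with the three fields).
#' @export
flash_stimulus <- function(luminance, adaptation = c("DA", "LA"),
                           background_luminance = NULL) {
  adaptation <- match.arg(adaptation)
  if (!is_scalar_number(luminance) || luminance <= 0) {
    abort_invalid("luminance must be a single positive number")
  }
  background_luminance <- background_luminance %||%
    if (adaptation == "DA") 0 else 30
  if (!is_scalar_number(background_luminance) || background_luminance < 0) {
    abort_invalid("background_luminance must be >= 0")
  }
  if (adaptation == "DA" && background_luminance != 0) {
    abort_invalid("dark-adapted stimuli require background_luminance = 0")
  }
  structure(list(luminance = luminance, adaptation = adaptation,
                 background_luminance = background_luminance),
            class = "flash_stimulus")
}

#' @export
print.flash_stimulus <- function(x, ...) {
  cat(sprintf("<flash_stimulus> %s %.4g cd s m^-2 (background %g cd m^-2)\n",
              x$adaptation, x$luminance, x$background_luminance))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise threshold `alpha / m` used for the per-luminance follow-up
#' models; with the default 8-flash series and `alpha = 0.05` this is 0.00625,
#' conventionally displayed as 0.0063.
#'
#' @param alpha Nominal level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 8) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_invalid("alpha must lie in (0, 1)")
  }
  if (!is_scalar_number(m) || m < 1 || m != round(m)) {
    abort_invalid("m must be an integer >= 1")
  }
  alpha / m
}
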