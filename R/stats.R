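# Median-based group comparison statistics.
#
# The estimand is the median group difference (MODEL - WT) for one component
# measure, adjusting for log10 flash luminance, with animal-level clustering
# honoured by a cluster bootstrap (whole animals resampled with replacement
# within group). This approximates a random-intercept median (quantile) model
# while keeping the inference fully nonparametric.

#' Pinball (check) loss
#'
#' `sum(u * (tau - 1(u < 0)))` over residuals `u`; the asymmetric absolute
#' loss whose minimizer is the conditional `tau`-quantile.
#'
#' @param residuals Numeric vector.
#' @param tau Quantile level in (0, 1).
#' @return Non-negative scalar.
#' @export
pinball_loss <- function(residuals, tau = 0.5) {
  if (!is_scalar_number(tau) || tau <= 0 || tau >= 1) {
    abort_invalid("tau must lie in (0, 1)")
  }
  sum(residuals * (tau - (residuals < 0)))
}

#' Fit a linear quantile regression
#'
#' Minimizes the pinball loss of `response - design %*% beta` at level
#' `tau`. The solver is a smoothed iteratively-reweighted scheme finished by
#' exact coordinate-wise minimization, which attains the linear-programming
#' optimum for the small design matrices used here; with an intercept-only
#' design it returns the sample `tau`-quantile (the median for `tau = 0.5`).
#'
#' @param design Numeric matrix (rows >= columns, no missing values).
#' @param response Numeric vector.
#' @param tau Quantile level in (0, 1); default 0.5 (median regression).
#' @return A `quantile_fit` list: `coefficients`, `tau`, `loss`,
#'   `degenerate` (TRUE for rank-deficient designs, in which case the fit is
#'   flagged rather than trusted).
#' @export
fit_quantile <- function(design, response, tau = 0.5) {
  if (!is_scalar_number(tau) || tau <= 0 || tau >= 1) {
    abort_invalid("tau must lie in (0, 1)")
  }
  design <- as.matrix(design)
  if (anyNA(design) || anyNA(response)) {
    abort_invalid("design and response must not contain missing values")
  }
  if (nrow(design) != length(response)) {
    abort_invalid("design rows must match response length")
  }
  if (nrow(design) < ncol(design)) {
    abort_invalid("need at least as many rows as columns")
  }
  degenerate <- qr(design)$rank < ncol(design)
  fit <- .qr_fit_cpp(design, as.numeric(response), tau)
  structure(list(coefficients = as.numeric(fit$coefficients), tau = tau,
                 loss = fit$loss, degenerate = degenerate),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("<quantile_fit> tau = %g, loss = %.6g%s\n", x$tau, x$loss,
              if (x$degenerate) " (degenerate design)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Percentile bootstrap confidence interval for a median
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' 2.5/97.5 percentile interval of the resampled medians. Deterministic
#' given `seed`.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of resamples (>= 200).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000, seed = 1,
                                level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort_invalid("need at least 2 values")
  if (n_boot < 200) abort_invalid("n_boot must be >= 200")
  meds <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(matrix(values[idx], nrow = n), 2, stats::median)
  })
  unname(stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                         type = 7))
}

#' Spearman rank correlation with large-sample test
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with a p-value
#' from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` (pairs with missing
#'   values are dropped).
#' @return List `(rho, p_value, n, flags)`; a constant input yields
#'   `rho = NA` with flag `undefined_rho`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort_invalid("need equal-length vectors with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                flags = "undefined_rho"))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, flags = character())
}

# ---- measurement-table plumbing --------------------------------------------

MEASURE_COLS <- c(
  a_amplitude = "a_amp", a_it = "a_it", a_fixed_amplitude = "a_fixed_amp",
  b_amplitude = "b_amp", b_it = "b_it", mop_amplitude = "mop_amp",
  op_it = "op_time_sum", phnr_amplitude = "phnr_amp", phnr_it = "phnr_it")

# Map (component, measure) to a table column.
measure_column <- function(component, measure) {
  key <- paste(component, measure, sep = "_")
  if (!key %in% names(MEASURE_COLS)) {
    abort_invalid(sprintf("unknown component/measure: %s/%s",
                          component, measure))
  }
  MEAS <- MEASURE_COLS[[key]]
  MEAS
}

# Rows eligible for analysis of one component measure: valid values, implicit
# times not flagged unreliable, light-adapted rows restricted to the bright
# flashes (>= luminance_min).
analysis_rows <- function(table, component, measure, adaptation,
                          luminance_min = NULL) {
  col <- measure_column(component, measure)
  sub <- table[table$adaptation == adaptation, ]
  if (adaptation == "LA") {
    luminance_min <- luminance_min %||% 1.0
  }
  if (!is.null(luminance_min)) {
    sub <- sub[sub$luminance >= luminance_min, ]
  }
  keep <- !is.na(sub[[col]])
  if (measure == "it") {
    base <- sub("_.*", "", col)           # a_it -> a, phnr_it -> phnr
    unrel <- row_has_flag(sub, paste0(base, "_it_unreliable")) |
      row_has_flag(sub, "la_it_low_luminance")
    if (col == "op_time_sum") {
      unrel <- row_has_flag(sub, "ops_absent") |
        row_has_flag(sub, "la_it_low_luminance")
    }
    keep <- keep & !unrel
  }
  sub[keep, c("animal_id", "group", "luminance", col)]
}

# Cluster bootstrap: resample whole animals with replacement within group.
cluster_resample_idx <- function(animal_rows_by_id, groups_of_animal) {
  ids_wt <- names(groups_of_animal)[groups_of_animal == "WT"]
  ids_tg <- names(groups_of_animal)[groups_of_animal == "MODEL"]
  draw <- c(sample(ids_wt, length(ids_wt), replace = TRUE),
            sample(ids_tg, length(ids_tg), replace = TRUE))
  unlist(animal_rows_by_id[draw], use.names = FALSE)
}

boot_p_value <- function(boot_est, estimate) {
  # symmetrized percentile p: how often the null-centred bootstrap statistic
  # exceeds the observed one in magnitude (small tolerance so degenerate
  # all-equal bootstraps land on the p = 1 boundary, not 1/(B+1))
  b <- boot_est[!is.na(boot_est)]
  tol <- 1e-10 * (1 + abs(estimate))
  (1 + sum(abs(b - estimate) >= abs(estimate) - tol)) / (length(b) + 1)
}

#' Overall median group comparison for one component measure
#'
#' Fits a median (tau = 0.5) regression of the measure on a MODEL-group
#' indicator plus `log10(luminance)`, pooling all eligible flashes of one
#' adaptation state. The group coefficient estimates the median MODEL - WT
#' difference adjusted for flash luminance. Inference is by cluster
#' bootstrap: whole animals are resampled with replacement within group
#' (honouring the repeated measures per animal). The two-sided p-value is
#' the symmetrized null-centred bootstrap percentile, and the 95% CI is the
#' interval that inverts the same statistic
#' (`estimate +/- q95(|theta* - estimate|)`), so `p < 0.05` exactly when 0
#' falls outside the CI. Deterministic given `seed`.
#'
#' Flagged implicit times are excluded; light-adapted analyses are
#' restricted to flashes at or above `luminance_min` (default
#' 1.0 cd s m^-2), where light-adapted responses are measurable.
#'
#' @param table A [measurement_table()].
#' @param component One of `"a"`, `"a_fixed"`, `"b"`, `"mop"`, `"op"`,
#'   `"phnr"`.
#' @param adaptation `"DA"` or `"LA"`.
#' @param measure `"amplitude"` or `"it"` (implicit time; for `"op"` the
#'   summed peak-time measure).
#' @param n_boot Number of bootstrap resamples (>= 1000; default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param luminance_min Optional lower flash-energy bound (defaults to
#'   1.0 cd s m^-2 for LA, none for DA).
#' @param tau Quantile level (default 0.5).
#' @return A `group_comparison` list: `component`, `adaptation`, `measure`,
#'   `estimate` (MODEL - WT), `ci95`, `p_value`, `n_boot`, `n_rows`,
#'   `n_animals`, `seed`.
#' @export
compare_groups_overall <- function(table, component, adaptation,
                                   measure = "amplitude",
                                   n_boot = 2000, seed = 1,
                                   luminance_min = NULL, tau = 0.5) {
  if (n_boot < 1000) abort_invalid("n_boot must be >= 1000")
  sub <- analysis_rows(table, component, measure, adaptation, luminance_min)
  col <- names(sub)[4]
  groups_of_animal <- tapply(sub$group, sub$animal_id, function(g) g[1])
  if (sum(groups_of_animal == "WT") < 2 ||
      sum(groups_of_animal == "MODEL") < 2) {
    abort_invalid("need at least 2 animals per group")
  }
  X <- cbind(1, sub$group == "MODEL", log10(sub$luminance))
  y <- sub[[col]]
  est <- fit_quantile(X, y, tau)$coefficients[2]
  animal_rows <- split(seq_len(nrow(sub)), sub$animal_id)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- cluster_resample_idx(animal_rows, groups_of_animal)
      Xb <- X[idx, , drop = FALSE]
      # luminance can become constant only in degenerate resamples; group
      # cannot (resampling is within group)
      fit <- .qr_fit_cpp(Xb, y[idx], tau)
      fit$coefficients[2]
    }, numeric(1))
  })
  # symmetrized bootstrap CI: inverts the same null-centred statistic as the
  # p-value below, so p < 0.05 iff 0 lies outside ci95
  half <- unname(stats::quantile(abs(boot - est), 0.95, type = 7))
  ci <- c(est - half, est + half)
  structure(list(component = component, adaptation = adaptation,
                 measure = measure, tau = tau,
                 estimate = unname(est), ci95 = ci,
                 p_value = boot_p_value(boot, est),
                 n_boot = n_boot, n_rows = nrow(sub),
                 n_animals = length(groups_of_animal), seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s %s %s: MODEL - WT = %.3f [%.3f, %.3f], p = %.4g (%d boot)\n",
    x$adaptation, x$component, x$measure, x$estimate, x$ci95[1], x$ci95[2],
    x$p_value, x$n_boot))
  invisible(x)
}

#' Per-luminance median group comparisons with Bonferroni correction
#'
#' Fits a univariate median group-difference model separately at each flash
#' luminance (the median MODEL - WT difference within the stratum), with a
#' cluster bootstrap p-value per stratum and two significance flags: nominal
#' (`p < alpha`) and Bonferroni (`p < alpha / m`). Empty or single-group
#' strata are flagged, not fatal.
#'
#' @inheritParams compare_groups_overall
#' @param alpha Nominal level (default 0.05).
#' @param m Number of comparisons for the Bonferroni correction (defaults to
#'   the number of strata tested).
#' @return data.frame with one row per luminance: `luminance`, `estimate`,
#'   `p_value`, `significant_nominal`, `significant_bonferroni`, `n`,
#'   `flag`.
#' @export
compare_groups_per_luminance <- function(table, component, adaptation,
                                         measure = "amplitude",
                                         alpha = 0.05, m = NULL,
                                         n_boot = 2000, seed = 1,
                                         luminance_min = NULL, tau = 0.5) {
  sub <- analysis_rows(table, component, measure, adaptation, luminance_min)
  col <- names(sub)[4]
  lums <- sort(unique(table$luminance[table$adaptation == adaptation]))
  if (adaptation == "LA") lums <- lums[lums >= (luminance_min %||% 1.0)]
  m <- m %||% length(lums)
  cut_bonf <- bonferroni_threshold(alpha, m)
  rows <- lapply(seq_along(lums), function(k) {
    lum <- lums[k]
    s <- sub[sub$luminance == lum, ]
    out <- data.frame(luminance = lum, estimate = NA_real_,
                      p_value = NA_real_, significant_nominal = FALSE,
                      significant_bonferroni = FALSE, n = nrow(s),
                      flag = "", stringsAsFactors = FALSE)
    n_wt <- length(unique(s$animal_id[s$group == "WT"]))
    n_tg <- length(unique(s$animal_id[s$group == "MODEL"]))
    if (n_wt < 2 || n_tg < 2) {
      out$flag <- "insufficient_stratum"
      return(out)
    }
    y <- s[[col]]
    g <- s$group == "MODEL"
    est <- stats::median(y[g]) - stats::median(y[!g])
    boot <- with_seed(seed + k, {
      vapply(seq_len(n_boot), function(i) {
        iw <- sample(which(!g), n_wt, replace = TRUE)
        it <- sample(which(g), n_tg, replace = TRUE)
        stats::median(y[it]) - stats::median(y[iw])
      }, numeric(1))
    })
    out$estimate <- est
    out$p_value <- boot_p_value(boot, est)
    out$significant_nominal <- out$p_value < alpha
    out$significant_bonferroni <- out$p_value < cut_bonf
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "alpha") <- alpha
  attr(res, "m") <- m
  attr(res, "bonferroni_threshold") <- cut_bonf
  res
}
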