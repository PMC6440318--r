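#' Control parameters for the tri-phase fit
#'
#' Collects the tunable constants of the fitting procedure. Defaults
#' follow the published protocol: a 24 h thermal window assumed free of
#' water limitation, quarter-interval bins of log10 soil potential on
#' absolute 0.25 boundaries, the 0.9 / 0.2 normalized-growth thresholds,
#' and retention of the driest normal bin in the slow-phase regression.
#'
#' @param window_h thermal-fit window from experiment start, h.
#' @param normal_threshold bins with mean RGRa above this are "normal".
#' @param arrest_threshold bins with mean RGRa below this are "arrest".
#' @param bin_width width of the soil-potential bins, log10 hPa.
#' @param retain_max_normal include the hourly points of the driest
#'   (highest-potential) normal bin in the slow-phase regression, which
#'   anchors the estimate of the slow-onset breakpoint.
#' @param response response variable of the slow-phase regression:
#'   \code{"rgra"} (thermally corrected, the default and the variable
#'   from which the breakpoints are defined) or \code{"ler"} (raw rate,
#'   for comparison only; breakpoints are always computed on RGRa).
#' @return a list of class \code{triphase_control}.
#' @export
triphase_control <- function(window_h = 24, normal_threshold = 0.9,
                             arrest_threshold = 0.2, bin_width = 0.25,
                             retain_max_normal = TRUE,
                             response = c("rgra", "ler")) {
  response <- match.arg(response)
  if (!(arrest_threshold > 0 && arrest_threshold < normal_threshold &&
        normal_threshold < 1)) {
    stop("invalid control: thresholds must satisfy 0 < arrest < normal < 1",
         call. = FALSE)
  }
  if (bin_width <= 0) {
    stop("invalid control: bin_width must be > 0", call. = FALSE)
  }
  structure(list(window_h = window_h,
                 normal_threshold = normal_threshold,
                 arrest_threshold = arrest_threshold,
                 bin_width = bin_width,
                 retain_max_normal = retain_max_normal,
                 response = response),
            class = "triphase_control")
}

#' Thermal growth rate: through-origin fit of LER on temperature
#'
#' Fits LER = a * T by least squares with the intercept fixed at zero,
#' using the hours from the start of the experiment up to
#' \code{window_h}, under the assumption that soil water is not yet
#' limiting there. The closed form is a = sum(T * LER) / sum(T^2); the
#' coefficient of determination is the uncentered R^2 of the
#' through-origin model.
#'
#' @param series an \code{hourly_series}.
#' @param window_h window length in hours (default 24).
#' @return an object of class \code{thermal_fit} with elements \code{a}
#'   (mm h^-1 degC^-1), \code{a_um} (um degC^-1 h^-1), \code{r_squared},
#'   \code{n_points}, \code{window_h}.
#' @export
fit_thermal_rate <- function(series, window_h = 24) {
  rows <- series$hour < window_h & !series$after_rewatering &
    is.finite(series$ler_mm_h) & is.finite(series$temp_c)
  d <- series[rows, , drop = FALSE]
  if (nrow(d) > 0 && all(d$temp_c == 0)) {
    stop("degenerate-fit error: all temperatures are zero in the thermal ",
         "window", call. = FALSE)
  }
  d <- d[d$temp_c > 0, , drop = FALSE]
  if (nrow(d) < 3) {
    stop("insufficient-data error: need >= 3 hourly points with T > 0 in ",
         "the first ", window_h, " h; got ", nrow(d), call. = FALSE)
  }
  a <- sum(d$temp_c * d$ler_mm_h) / sum(d$temp_c^2)
  ss_res <- sum((d$ler_mm_h - a * d$temp_c)^2)
  ss_tot <- sum(d$ler_mm_h^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(a = a, a_um = a * 1000, r_squared = r2,
                 n_points = nrow(d), window_h = window_h),
            class = "thermal_fit")
}

#' Thermally corrected relative growth rate
#'
#' Fills the \code{rgra} column: RGRa = LER / (a * T) for every hour,
#' the observed rate relative to the rate the thermal response predicts.
#' Hours with non-positive temperature are marked missing.
#'
#' @param series an \code{hourly_series}.
#' @param fit a \code{thermal_fit} with \code{a > 0}.
#' @return the series with an \code{rgra} column added.
#' @export
relative_growth <- function(series, fit) {
  if (!inherits(fit, "thermal_fit") || !is.finite(fit$a) || fit$a <= 0) {
    stop("domain error: thermal rate a must be positive", call. = FALSE)
  }
  rgra <- series$ler_mm_h / (fit$a * series$temp_c)
  rgra[!is.finite(series$temp_c) | series$temp_c <= 0] <- NA_real_
  series$rgra <- rgra
  series
}

#' Classify quarter-interval soil-potential bins into growth phases
#'
#' Averages RGRa within half-open bins of log10 soil potential on
#' absolute quarter boundaries (2.00-2.25, 2.25-2.50, ...) spanning the
#' observed range, and labels each bin \code{normal} (mean above the 0.9
#' threshold), \code{arrest} (mean below 0.2), or \code{slow}
#' (otherwise; boundary values are slow). A rebound rule then relabels
#' as normal any slow bin whose next non-empty bin is normal — a
#' one-increment dip below 0.9 followed by recovery is not treated as a
#' stress response. Arrest bins are never rescued. Hours after
#' re-watering are excluded.
#'
#' @param series an \code{hourly_series} with \code{rgra} filled.
#' @param control a [triphase_control()].
#' @return a data frame of class \code{psi_bins} with columns \code{lo},
#'   \code{hi}, \code{mean_rgra}, \code{n_points}, \code{phase}.
#' @export
classify_bins <- function(series, control = triphase_control()) {
  w <- control$bin_width
  d <- series[!series$after_rewatering & is.finite(series$rgra) &
                is.finite(series$psi_log10), , drop = FALSE]
  if (nrow(d) == 0) {
    stop("insufficient-data error: no usable hours for binning",
         call. = FALSE)
  }
  k <- seq(floor(min(d$psi_log10) / w), floor(max(d$psi_log10) / w))
  lo <- k * w
  mean_rgra <- rep(NA_real_, length(lo))
  n_points <- integer(length(lo))
  for (k in seq_along(lo)) {
    in_bin <- d$psi_log10 >= lo[k] & d$psi_log10 < lo[k] + w
    n_points[k] <- sum(in_bin)
    if (n_points[k] > 0) mean_rgra[k] <- mean(d$rgra[in_bin])
  }
  phase <- ifelse(n_points == 0, "empty",
                  ifelse(mean_rgra > control$normal_threshold, "normal",
                         ifelse(mean_rgra < control$arrest_threshold,
                                "arrest", "slow")))
  # rebound rule: a slow bin whose next non-empty bin is normal stays
  # normal; a single pass over the original labels, arrest never rescued
  orig <- phase
  nonempty <- which(orig != "empty")
  for (j in seq_along(nonempty)) {
    k <- nonempty[j]
    if (orig[k] == "slow" && j < length(nonempty) &&
        orig[nonempty[j + 1]] == "normal") {
      phase[k] <- "normal"
    }
  }
  structure(data.frame(lo = lo, hi = lo + w, mean_rgra = mean_rgra,
                       n_points = n_points, phase = phase,
                       stringsAsFactors = FALSE),
            class = c("psi_bins", "data.frame"))
}

#' Select the hourly points entering the slow-phase regression
#'
#' Takes every hourly point falling in a bin labeled \code{slow}, plus
#' (by default) all points of the driest bin labeled \code{normal},
#' which anchors the regression near RGRa = 1 and improves the estimate
#' of the slow-onset breakpoint. Arrest is treated as terminal: the
#' first arrest bin caps the range, and points in bins at higher
#' potential are excluded even if a later bin mean drifts upward.
#'
#' If no slow bin exists (e.g., a well-watered control), the tiller
#' shows no water-deficit response; a \code{triphase_no_response} marker
#' is returned rather than an error.
#'
#' @param series an \code{hourly_series} with \code{rgra} filled.
#' @param bins output of [classify_bins()].
#' @param control a [triphase_control()].
#' @return the selected rows of \code{series}, or a
#'   \code{triphase_no_response} object.
#' @export
select_slow_subset <- function(series, bins, control = triphase_control()) {
  d <- series[!series$after_rewatering & is.finite(series$rgra) &
                is.finite(series$psi_log10), , drop = FALSE]
  arrest_lo <- bins$lo[bins$phase == "arrest"]
  cutoff <- if (length(arrest_lo)) min(arrest_lo) else Inf
  slow_bins <- bins[bins$phase == "slow" & bins$lo < cutoff, , drop = FALSE]
  if (nrow(slow_bins) == 0) {
    return(structure(list(message = "normal throughout: no slow phase ",
                          phase = "normal throughout"),
                     class = "triphase_no_response"))
  }
  keep_lo <- slow_bins$lo
  if (control$retain_max_normal) {
    normal_lo <- bins$lo[bins$phase == "normal" & bins$lo < cutoff]
    if (length(normal_lo)) keep_lo <- c(keep_lo, max(normal_lo))
  }
  # match on the integer bin index to dodge floating-point lo comparisons
  keep_idx <- round(keep_lo / control$bin_width)
  bin_idx <- floor(d$psi_log10 / control$bin_width)
  d[bin_idx %in% keep_idx, , drop = FALSE]
}

#' Slow-phase linear regression
#'
#' Ordinary least squares of the response (RGRa by default) on the
#' log10 soil potential with a free intercept: RGRa = i + c * Psi. A
#' valid water-deficit response has negative slope c; the breakpoints
#' follow from where the line crosses 1 and 0.
#'
#' @param points selected hourly rows from [select_slow_subset()].
#' @param response \code{"rgra"} or \code{"ler"} (comparison variant).
#' @return an object of class \code{slow_fit} with \code{i}, \code{c},
#'   \code{r_squared}, \code{n_points}, \code{response}.
#' @export
fit_slow_phase <- function(points, response = "rgra") {
  y <- points[[response]]
  x <- points$psi_log10
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(x) < 3) {
    stop("insufficient-data error: slow-phase fit needs >= 3 points; got ",
         length(x), call. = FALSE)
  }
  if (diff(range(x)) < 0.25 - 1e-12) {
    stop("insufficient-spread error: slow-phase points span ",
         signif(diff(range(x)), 3), " log10 hPa; need >= 0.25",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  if (!is.finite(co[2]) || co[2] >= 0) {
    stop("non-decreasing-response error: slow-phase slope c must be ",
         "negative (growth must decline with drying)", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else
    NA_real_
  structure(list(i = unname(co[1]), c = unname(co[2]),
                 r_squared = r2,
                 n_points = length(x), response = response),
            class = "slow_fit")
}

#' Breakpoints of the tri-phase response
#'
#' From the slow-phase line RGRa = i + c * Psi, the slow-onset
#' breakpoint Sigma is where the line crosses RGRa = 1 and the arrest
#' breakpoint sigma is where it crosses RGRa = 0:
#' Sigma = (1 - i) / c, sigma = -i / c. For c < 0, Sigma < sigma and
#' sigma - Sigma = -1 / c hold exactly.
#'
#' @param fit a \code{slow_fit} (or any list with \code{i} and \code{c}).
#' @return named numeric vector \code{c(sigma_upper, sigma_lower)} in
#'   log10 hPa.
#' @export
breakpoints <- function(fit) {
  if (!is.finite(fit$c) || fit$c >= 0) {
    stop("domain error: breakpoints require a negative slope c",
         call. = FALSE)
  }
  c(sigma_upper = (1 - fit$i) / fit$c, sigma_lower = -fit$i / fit$c)
}

#' Fit the tri-phase model to one tiller
#'
#' Runs the five stages in order on an aligned hourly series: thermal
#' rate (through-origin, first \code{window_h} hours), thermally
#' corrected relative growth, quarter-bin phase classification,
#' slow-phase subset selection and regression, and the two breakpoints.
#' Hours after re-watering are excluded from all fitting. A well-watered
#' series yields the thermal fit plus a no-response marker instead of
#' breakpoints. Errors from individual stages are re-signalled with the
#' stage name.
#'
#' @param series an \code{hourly_series}.
#' @param control a [triphase_control()].
#' @param tiller_id label carried into the result.
#' @return an object of class \code{triphase_fit}: list with
#'   \code{tiller_id}, \code{thermal}, \code{bins}, \code{slow},
#'   \code{sigma_upper}, \code{sigma_lower}, \code{no_response},
#'   \code{extrapolated} (breakpoints outside the observed potential
#'   range), \code{n_hours} and the input \code{series} (with
#'   \code{rgra}) for audit.
#' @export
fit_triphase <- function(series, control = triphase_control(),
                         tiller_id = "tiller") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  thermal <- stage("thermal", fit_thermal_rate(series, control$window_h))
  series <- stage("rgra", relative_growth(series, thermal))
  bins <- stage("bins", classify_bins(series, control))
  subset <- stage("select", select_slow_subset(series, bins, control))
  res <- list(tiller_id = tiller_id, thermal = thermal, bins = bins,
              slow = NULL, sigma_upper = NA_real_, sigma_lower = NA_real_,
              no_response = FALSE, extrapolated = c(sigma_upper = NA,
                                                    sigma_lower = NA),
              n_hours = sum(!series$after_rewatering),
              series = series)
  if (inherits(subset, "triphase_no_response")) {
    res$no_response <- TRUE
    class(res) <- "triphase_fit"
    return(res)
  }
  slow <- stage("slow", fit_slow_phase(subset, control$response))
  if (control$response == "rgra") {
    bp <- stage("breakpoints", breakpoints(slow))
    res$sigma_upper <- bp[["sigma_upper"]]
    res$sigma_lower <- bp[["sigma_lower"]]
    obs <- range(series$psi_log10[!series$after_rewatering &
                                    is.finite(series$psi_log10)])
    res$extrapolated <- c(
      sigma_upper = res$sigma_upper < obs[1] | res$sigma_upper > obs[2],
      sigma_lower = res$sigma_lower < obs[1] | res$sigma_lower > obs[2]
    )
  }
  res$slow <- slow
  class(res) <- "triphase_fit"
  res
}

#' @export
print.triphase_fit <- function(x, ...) {
  cat("Tri-phase fit:", x$tiller_id, "\n")
  cat(sprintf("  thermal rate a: %.4g um degC^-1 h^-1 (R^2 = %.3f, n = %d)\n",
              x$thermal$a_um, x$thermal$r_squared, x$thermal$n_points))
  if (x$no_response) {
    cat("  no water-deficit response: normal phase throughout\n")
  } else {
    cat(sprintf("  slow phase: RGRa = %.3f %+.3f Psi (R^2 = %.3f, n = %d)\n",
                x$slow$i, x$slow$c, x$slow$r_squared, x$slow$n_points))
    cat(sprintf("  breakpoints: Sigma = %.3f, sigma = %.3f log10 hPa%s\n",
                x$sigma_upper, x$sigma_lower,
                if (any(x$extrapolated, na.rm = TRUE)) " (extrapolated)"
                else ""))
  }
  invisible(x)
}

#' Flatten a tri-phase fit to a one-row data frame
#'
#' @param fit a \code{triphase_fit}.
#' @return one-row data frame with columns \code{tiller_id},
#'   \code{a_um}, \code{i}, \code{c}, \code{sigma_upper},
#'   \code{sigma_lower}, \code{r2_thermal}, \code{r2_slow},
#'   \code{n_hours}, \code{no_response}.
#' @export
as_result_row <- function(fit) {
  stopifnot(inherits(fit, "triphase_fit"))
  data.frame(tiller_id = fit$tiller_id,
             a_um = fit$thermal$a_um,
             i = if (is.null(fit$slow)) NA_real_ else fit$slow$i,
             c = if (is.null(fit$slow)) NA_real_ else fit$slow$c,
             sigma_upper = fit$sigma_upper,
             sigma_lower = fit$sigma_lower,
             r2_thermal = fit$thermal$r_squared,
             r2_slow = if (is.null(fit$slow)) NA_real_ else
               fit$slow$r_squared,
             n_hours = fit$n_hours,
             no_response = fit$no_response,
             stringsAsFactors = FALSE)
}

#' Serialize a tri-phase fit to JSON
#'
#' Writes every field of the result (thermal fit, bins, slow fit,
#' breakpoints, flags) as one JSON document.
#'
#' @param fit a \code{triphase_fit}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_triphase_json <- function(fit, path) {
  doc <- list(tiller_id = fit$tiller_id,
              thermal = unclass(fit$thermal),
              bins = as.data.frame(fit$bins),
              slow = if (is.null(fit$slow)) NULL else unclass(fit$slow),
              sigma_upper = fit$sigma_upper,
              sigma_lower = fit$sigma_lower,
              no_response = fit$no_response,
              extrapolated = as.list(fit$extrapolated),
              n_hours = fit$n_hours)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Fit one tiller from raw traces
#'
#' Builds the hourly series ([hourly_series()]) and fits the tri-phase
#' model.
#'
#' @param growth,temp,soil raw traces for one tiller.
#' @param rewater_time re-watering hour, or \code{NULL} to auto-detect.
#' @param control a [triphase_control()].
#' @param tiller_id label; defaults to the trace's id if present.
#' @param ... further arguments to [hourly_series()].
#' @return a \code{triphase_fit}.
#' @export
fit_tiller <- function(growth, temp, soil, rewater_time = NULL,
                       control = triphase_control(), tiller_id = NULL, ...) {
  if (is.null(tiller_id)) {
    tiller_id <- if ("tiller_id" %in% names(growth)) {
      as.character(growth$tiller_id[1])
    } else "tiller"
  }
  series <- hourly_series(growth, temp, soil, rewater_time = rewater_time,
                          ...)
  fit_triphase(series, control = control, tiller_id = tiller_id)
}

#' Fit every replicate of a simulated or loaded experiment
#'
#' @param sim a \code{sim_experiment}, or a list with elements
#'   \code{growth} (list of single-tiller traces), \code{temp},
#'   \code{soil} and optionally \code{cfg$rewater_time}.
#' @param control a [triphase_control()].
#' @param rewater_time overrides the experiment's re-watering hour.
#' @return list with \code{fits} (list of \code{triphase_fit}) and
#'   \code{results} (flat data frame, one row per tiller).
#' @export
fit_experiment <- function(sim, control = triphase_control(),
                           rewater_time = NULL) {
  if (is.null(rewater_time) && !is.null(sim$cfg)) {
    rewater_time <- sim$cfg$rewater_time
  }
  fits <- lapply(sim$growth, function(g) {
    fit_tiller(g, sim$temp, sim$soil, rewater_time = rewater_time,
               control = control)
  })
  list(fits = fits, results = do.call(rbind, lapply(fits, as_result_row)))
}
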