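#' @name timeseries-io
#' @title Raw trace CSV formats
#'
#' @description
#' Three tidy CSV dialects are used for raw sensor data, all UTF-8 with
#' a header row and decimal points:
#' \itemize{
#'   \item growth: \code{tiller_id, time_min, length_mm} (cumulative
#'     leaf length per tiller, typically every 2 min);
#'   \item temperature: \code{time_min, temp_c} (meristem temperature);
#'   \item soil: \code{time_min, psi_hpa} (soil matric potential
#'     magnitude, hPa, > 0).
#' }
#' Numeric columns are written with 17 significant digits so a
#' write/read round trip reproduces doubles bit-exactly.
NULL

# Format numeric columns for bit-exact round-tripping through text.
write_trace_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_trace_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error: ", basename(path), " lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read and write raw trace CSV files
#'
#' Readers validate the required columns (see [timeseries-io]) and
#' return plain data frames; writers emit numerics at full precision so
#' round trips are bit-exact.
#'
#' @param path CSV file path.
#' @return the trace as a data frame.
#' @export
read_growth_csv <- function(path) {
  df <- read_trace_csv(path, c("tiller_id", "time_min", "length_mm"))
  structure(df, class = c("growth_trace", "data.frame"))
}

#' @rdname read_growth_csv
#' @export
read_temperature_csv <- function(path) {
  df <- read_trace_csv(path, c("time_min", "temp_c"))
  structure(df, class = c("meristem_temp_trace", "data.frame"))
}

#' @rdname read_growth_csv
#' @export
read_soil_csv <- function(path) {
  df <- read_trace_csv(path, c("time_min", "psi_hpa"))
  structure(df, class = c("soil_moisture_trace", "data.frame"))
}

#' @rdname read_growth_csv
#' @param trace a trace data frame.
#' @export
write_growth_csv <- function(trace, path) write_trace_csv(trace, path)

#' @rdname read_growth_csv
#' @export
write_temperature_csv <- function(trace, path) write_trace_csv(trace, path)

#' @rdname read_growth_csv
#' @export
write_soil_csv <- function(trace, path) write_trace_csv(trace, path)

check_monotone_time <- function(time_min, what) {
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0)) {
    stop("format error: ", what, " timestamps must be finite and strictly ",
         "increasing", call. = FALSE)
  }
}

#' Hourly leaf elongation rate from a cumulative length trace
#'
#' Summarizes a single tiller's cumulative leaf length to one elongation
#' rate per hour: within each half-open hour window \code{[h, h+1)} from
#' the experiment start, LER = (L1 - L0) / (t1 - t0) * 60 mm h^-1, where
#' L1 and L0 are the maximum and minimum length observed in the window
#' and t is in minutes. For noisy traces the maximum can precede the
#' minimum; the rate is then signed (negative) and the hour flagged in
#' the \code{reversed} column. Hours with fewer than two samples are
#' marked missing (\code{NA}), never zero-filled. Negative rates are
#' retained unless \code{clip_negative = TRUE}.
#'
#' @param trace a single-tiller growth trace with \code{time_min} and
#'   \code{length_mm}.
#' @param clip_negative clip negative hourly rates to zero.
#' @return data frame with \code{hour}, \code{ler_mm_h}, \code{n_samples}
#'   and \code{reversed}, one row per hour of the trace span.
#' @export
compute_hourly_ler <- function(trace, clip_negative = FALSE) {
  stopifnot(all(c("time_min", "length_mm") %in% names(trace)))
  if (length(unique(trace$tiller_id)) > 1) {
    stop("format error: compute_hourly_ler expects a single tiller",
         call. = FALSE)
  }
  check_monotone_time(trace$time_min, "growth")
  if (any(!is.finite(trace$length_mm))) {
    stop("format error: leaf lengths must be finite", call. = FALSE)
  }
  hour <- trace$time_min %/% 60
  hours <- seq(min(hour), max(hour))
  rows <- lapply(hours, function(h) {
    idx <- which(hour == h)
    if (length(idx) < 2) {
      return(data.frame(hour = h, ler_mm_h = NA_real_,
                        n_samples = length(idx), reversed = NA))
    }
    len <- trace$length_mm[idx]
    tt <- trace$time_min[idx]
    if (max(len) == min(len)) {
      return(data.frame(hour = h, ler_mm_h = 0, n_samples = length(idx),
                        reversed = FALSE))
    }
    # first time the minimum is attained, last time the maximum is
    i_min <- which.min(len)
    i_max <- length(len) - which.max(rev(len)) + 1L
    ler <- (len[i_max] - len[i_min]) / (tt[i_max] - tt[i_min]) * 60
    data.frame(hour = h, ler_mm_h = ler, n_samples = length(idx),
               reversed = tt[i_max] < tt[i_min])
  })
  out <- do.call(rbind, rows)
  if (clip_negative) out$ler_mm_h <- pmax(out$ler_mm_h, 0)
  out
}

#' Hourly mean meristem temperature
#'
#' Arithmetic mean of all temperature samples within each half-open hour
#' window from the experiment start; hours without samples are marked
#' missing.
#'
#' @param trace a temperature trace with \code{time_min} and
#'   \code{temp_c}.
#' @return data frame with \code{hour}, \code{temp_c} and
#'   \code{n_samples}.
#' @export
summarize_temperature <- function(trace) {
  stopifnot(all(c("time_min", "temp_c") %in% names(trace)))
  if (nrow(trace) == 0) {
    stop("format error: empty temperature trace", call. = FALSE)
  }
  check_monotone_time(trace$time_min, "temperature")
  hour <- trace$time_min %/% 60
  hours <- seq(min(hour), max(hour))
  means <- vapply(hours, function(h) {
    v <- trace$temp_c[hour == h]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  n <- vapply(hours, function(h) sum(hour == h), integer(1))
  data.frame(hour = hours, temp_c = means, n_samples = n)
}

#' Detect a re-watering event in a soil moisture trace
#'
#' Scans consecutive observations for a drop of at least
#' \code{threshold} log10 hPa and returns the time (hours) of the first
#' observation after the drop, or \code{NULL} if none is found. Used
#' when files carry no re-watering annotation.
#'
#' @param trace a soil trace with \code{time_min} and \code{psi_hpa}.
#' @param threshold drop size in log10 hPa that signals re-watering.
#' @return re-watering time in hours, or \code{NULL}.
#' @export
detect_rewatering <- function(trace, threshold = 0.5) {
  psi <- log10(trace$psi_hpa)
  drop <- which(diff(psi) <= -threshold)
  if (length(drop) == 0) return(NULL)
  trace$time_min[drop[1] + 1] / 60
}

#' Impute hourly log10 soil matric potential by loess
#'
#' The raw matric potential is log10-transformed first, then a loess
#' curve (default span 0.75, locally quadratic) is fitted against time
#' and evaluated at hour midpoints. Only observations strictly before
#' \code{rewater_time} enter the fit; including post-re-watering data
#' would drag the curve down and severely underestimate the final soil
#' moisture. By default no value is produced outside the time range of
#' the pre-re-watering observations (no extrapolation); hours without a
#' value are \code{NA}.
#'
#' @param trace a soil trace with \code{time_min} and \code{psi_hpa}.
#' @param rewater_time re-watering time in hours, \code{NULL} to
#'   auto-detect via [detect_rewatering()], or \code{NA} to force use of
#'   all data.
#' @param span,degree loess smoothing parameters.
#' @param extrapolate allow evaluation beyond the first/last observation.
#' @return data frame with \code{hour} and \code{psi_log10} covering the
#'   full trace span.
#' @export
impute_psi_hourly <- function(trace, rewater_time = NULL, span = 0.75,
                              degree = 2, extrapolate = FALSE) {
  stopifnot(all(c("time_min", "psi_hpa") %in% names(trace)))
  check_monotone_time(trace$time_min, "soil")
  if (any(trace$psi_hpa <= 0)) {
    stop("domain error: psi_hpa must be > 0 for the log10 transform",
         call. = FALSE)
  }
  if (is.null(rewater_time)) rewater_time <- detect_rewatering(trace)
  t_h <- trace$time_min / 60
  use <- if (is.null(rewater_time) || is.na(rewater_time)) {
    rep(TRUE, nrow(trace))
  } else {
    t_h < rewater_time
  }
  dat <- data.frame(t = t_h[use], psi = log10(trace$psi_hpa[use]))
  if (nrow(dat) < degree + 2 || floor(nrow(dat) * span) < degree + 2) {
    stop("imputation error: ", nrow(dat), " pre-re-watering observation(s) ",
         "are too few for a loess fit with span ", span, " and degree ",
         degree, call. = FALSE)
  }
  hours <- seq(floor(min(t_h)), floor(max(t_h)))
  mid <- hours + 0.5
  fit <- tryCatch(
    stats::loess(psi ~ t, data = dat, span = span, degree = degree,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) {
      stop("imputation error: loess fit with span ", span,
           " failed (", conditionMessage(e), "); too few soil observations?",
           call. = FALSE)
    }
  )
  pred <- as.numeric(stats::predict(fit, newdata = data.frame(t = mid)))
  if (!extrapolate) {
    pred[mid < min(dat$t) | mid > max(dat$t)] <- NA_real_
  }
  if (!is.null(rewater_time) && !is.na(rewater_time)) {
    pred[mid >= rewater_time] <- NA_real_
  }
  data.frame(hour = hours, psi_log10 = pred)
}

#' Align hourly streams into one fitting substrate
#'
#' Inner-joins the hourly elongation rate, mean temperature and imputed
#' log10 soil potential on the hour index. Hours missing the rate or the
#' temperature are dropped (and counted in a message); before
#' re-watering the soil value is also required, while hours at or after
#' \code{rewater_time} are kept with \code{psi_log10 = NA} and flagged
#' \code{after_rewatering} (they are excluded from all fitting).
#'
#' @param ler output of [compute_hourly_ler()].
#' @param temp output of [summarize_temperature()].
#' @param psi output of [impute_psi_hourly()].
#' @param rewater_time re-watering time in hours, or \code{NULL}.
#' @return an \code{hourly_series} data frame with columns \code{hour},
#'   \code{ler_mm_h}, \code{temp_c}, \code{psi_log10},
#'   \code{after_rewatering}.
#' @export
align_hourly <- function(ler, temp, psi, rewater_time = NULL) {
  m <- merge(ler[, c("hour", "ler_mm_h")], temp[, c("hour", "temp_c")],
             by = "hour")
  m <- merge(m, psi[, c("hour", "psi_log10")], by = "hour", all.x = TRUE)
  m$after_rewatering <- if (is.null(rewater_time)) {
    rep(FALSE, nrow(m))
  } else {
    m$hour >= rewater_time
  }
  keep <- is.finite(m$ler_mm_h) & is.finite(m$temp_c) &
    (m$after_rewatering | is.finite(m$psi_log10))
  dropped <- sum(!keep)
  if (dropped > 0) {
    message("align_hourly: dropped ", dropped,
            " hour(s) missing at least one stream")
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    stop("alignment error: no hours with all three streams present",
         call. = FALSE)
  }
  m <- m[order(m$hour), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, class = c("hourly_series", "data.frame"))
}

#' Write the aligned hourly series to CSV
#'
#' Columns: \code{hour, ler_mm_h, temp_c, psi_log10, after_rewatering}
#' (plus \code{rgra} when present).
#'
#' @param series an \code{hourly_series}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_hourly_csv <- function(series, path) {
  write_trace_csv(as.data.frame(series), path)
}

#' Build the hourly fitting substrate from raw traces
#'
#' Convenience wrapper running [compute_hourly_ler()],
#' [summarize_temperature()], [impute_psi_hourly()] and [align_hourly()]
#' for one tiller. If \code{rewater_time} is \code{NULL} it is detected
#' from the soil trace.
#'
#' @param growth,temp,soil raw traces (single tiller growth).
#' @param rewater_time re-watering time in hours, or \code{NULL} to
#'   auto-detect.
#' @param span,degree loess parameters for [impute_psi_hourly()].
#' @param clip_negative passed to [compute_hourly_ler()].
#' @return an \code{hourly_series}.
#' @export
hourly_series <- function(growth, temp, soil, rewater_time = NULL,
                          span = 0.75, degree = 2, clip_negative = FALSE) {
  if (is.null(rewater_time)) rewater_time <- detect_rewatering(soil)
  ler <- compute_hourly_ler(growth, clip_negative = clip_negative)
  tm <- summarize_temperature(temp)
  psi <- impute_psi_hourly(soil, rewater_time = rewater_time, span = span,
                           degree = degree)
  align_hourly(ler, tm, psi, rewater_time = rewater_time)
}
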