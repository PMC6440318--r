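#' Configuration of a synthetic water-deprivation experiment
#'
#' Builds a validated configuration object describing one simulated
#' drying experiment: the ground-truth tri-phase growth response of the
#' plant, the climate-chamber settings, the soil drying trajectory, and
#' the sensor cadences. The defaults emulate a standard run: a 16/8 h
#' photoperiod at 25/15 degC day/night, ca. 130 h of water deprivation
#' drying towards a plateau near 4.3 log10 hPa followed by re-watering,
#' and seven clonal replicates.
#'
#' The ground truth is the piecewise-linear stress response
#' \eqn{g(\Psi)}: growth is unaffected (\eqn{g = 1}) while the log10
#' soil matric potential \eqn{\Psi} stays below the slow-onset
#' breakpoint \code{sigma_upper_true} (\eqn{\Sigma}), declines linearly
#' to zero at the arrest breakpoint \code{sigma_lower_true}
#' (\eqn{\sigma}), and is zero beyond. The instantaneous elongation
#' rate is \code{a_true} * T(t) * g(psi(t)).
#'
#' @param a_true thermal growth rate, mm h^-1 degC^-1 (52.9 um degC^-1
#'   h^-1 is a typical perennial ryegrass value).
#' @param sigma_upper_true slow-onset breakpoint Sigma, log10 hPa.
#' @param sigma_lower_true arrest breakpoint sigma, log10 hPa; must
#'   exceed \code{sigma_upper_true}.
#' @param psi_start initial log10 soil matric potential, log10 hPa.
#' @param psi_plateau asymptotic log10 matric potential of the drying
#'   curve, log10 hPa.
#' @param psi_timescale exponential drying time constant, h.
#' @param duration experiment length, h.
#' @param rewater_time hour at which pots are re-watered (soil potential
#'   resets to \code{psi_start}), or \code{NULL} for no re-watering.
#' @param photoperiod_day day-light length, h (of a 24 h cycle).
#' @param temp_day,temp_night set-point meristem temperatures, degC.
#' @param temp_lag first-order thermal lag of the meristem behind the
#'   air set point, h; 0 gives the exact square wave.
#' @param noise_sd_ler standard deviation of Gaussian noise added to the
#'   instantaneous elongation rate, mm h^-1.
#' @param growth_cadence leaf-length sampling interval, minutes.
#' @param temp_cadence meristem temperature sampling interval, minutes.
#' @param soil_cadence soil moisture sampling interval, hours.
#' @param n_replicates number of clonal replicate tillers.
#' @param seed integer seed; replicate i uses \code{seed + i}.
#' @param no_shrink if \code{TRUE}, noise is truncated so the cumulative
#'   leaf length never decreases; by default small decreases are allowed,
#'   as with real marker-tracking jitter.
#' @return an object of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(duration = 48, rewater_time = NULL, n_replicates = 1)
#' head(simulate_soil_drying(cfg))
sim_config <- function(a_true = 0.0529,
                       sigma_upper_true = 2.70,
                       sigma_lower_true = 3.83,
                       psi_start = 1.8,
                       psi_plateau = 4.3,
                       psi_timescale = 60,
                       duration = 165,
                       rewater_time = 130,
                       photoperiod_day = 16,
                       temp_day = 25,
                       temp_night = 15,
                       temp_lag = 0,
                       noise_sd_ler = 0.05,
                       growth_cadence = 2,
                       temp_cadence = 2,
                       soil_cadence = 4,
                       n_replicates = 7,
                       seed = 1L,
                       no_shrink = FALSE) {
  cfg <- list(
    a_true = a_true,
    sigma_upper_true = sigma_upper_true,
    sigma_lower_true = sigma_lower_true,
    psi_start = psi_start,
    psi_plateau = psi_plateau,
    psi_timescale = psi_timescale,
    duration = duration,
    rewater_time = rewater_time,
    photoperiod_day = photoperiod_day,
    temp_day = temp_day,
    temp_night = temp_night,
    temp_lag = temp_lag,
    noise_sd_ler = noise_sd_ler,
    growth_cadence = growth_cadence,
    temp_cadence = temp_cadence,
    soil_cadence = soil_cadence,
    n_replicates = n_replicates,
    seed = as.integer(seed),
    no_shrink = isTRUE(no_shrink)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$duration) || cfg$duration <= 0) {
    stop("invalid config: 'duration' must be a positive number of hours",
         call. = FALSE)
  }
  if (cfg$sigma_upper_true >= cfg$sigma_lower_true) {
    stop("invalid config: sigma_upper_true (Sigma) must be smaller than ",
         "sigma_lower_true (sigma)", call. = FALSE)
  }
  if (cfg$psi_start >= cfg$psi_plateau) {
    stop("invalid config: psi_start must be below psi_plateau", call. = FALSE)
  }
  ts <- c(psi_timescale = cfg$psi_timescale,
          photoperiod_day = cfg$photoperiod_day,
          growth_cadence = cfg$growth_cadence,
          temp_cadence = cfg$temp_cadence,
          soil_cadence = cfg$soil_cadence)
  if (any(!is.finite(ts) & !is.infinite(ts)) || any(ts <= 0)) {
    stop("invalid config: all timescales and cadences must be > 0",
         call. = FALSE)
  }
  if (cfg$photoperiod_day > 24) {
    stop("invalid config: photoperiod_day must be at most 24 h", call. = FALSE)
  }
  if (cfg$temp_lag < 0) {
    stop("invalid config: temp_lag must be >= 0", call. = FALSE)
  }
  if (cfg$noise_sd_ler < 0) {
    stop("invalid config: noise_sd_ler must be >= 0", call. = FALSE)
  }
  if (!is.null(cfg$rewater_time) &&
      (!is.finite(cfg$rewater_time) || cfg$rewater_time <= 0)) {
    stop("invalid config: rewater_time must be a positive hour or NULL",
         call. = FALSE)
  }
  if (cfg$n_replicates < 1) {
    stop("invalid config: n_replicates must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Derive a simulation configuration from a ground-truth parameter set
#'
#' Convenience constructor used in validation studies: given target
#' breakpoints, it picks a drying trajectory such that the soil stays in
#' the normal phase throughout the thermal-fit window (first
#' \code{window_h} hours) and passes through the full slow phase into
#' arrest before the experiment ends. The drying time constant solves
#' psi(window_h) = Sigma - margin, and the duration is extended until the
#' trajectory reaches sigma + 0.3 (capped just below the plateau) plus a
#' day of arrest-phase observation.
#'
#' @param a_true,sigma_upper_true,sigma_lower_true ground truth, as in
#'   [sim_config()].
#' @param window_h thermal-fit window the drying must not contaminate, h.
#' @param margin how far below Sigma the trajectory sits at the end of
#'   the window, log10 hPa.
#' @param ... further arguments passed to [sim_config()].
#' @return a \code{sim_config}.
#' @export
sim_config_for_truth <- function(a_true, sigma_upper_true, sigma_lower_true,
                                 window_h = 24, margin = 0.1, ...) {
  psi_start <- min(1.8, sigma_upper_true - 0.5)
  psi_plateau <- max(4.3, sigma_lower_true + 0.5)
  span <- psi_plateau - psi_start
  target_window <- sigma_upper_true - margin
  if (target_window <= psi_start) {
    stop("sigma_upper_true too close to psi_start for a valid drying curve",
         call. = FALSE)
  }
  tau <- window_h / log(span / (psi_plateau - target_window))
  arrest_target <- min(sigma_lower_true + 0.3, psi_plateau - 0.1)
  t_arrest <- tau * log(span / (psi_plateau - arrest_target))
  duration <- ceiling(t_arrest) + 24
  sim_config(a_true = a_true,
             sigma_upper_true = sigma_upper_true,
             sigma_lower_true = sigma_lower_true,
             psi_start = psi_start,
             psi_plateau = psi_plateau,
             psi_timescale = tau,
             duration = duration,
             rewater_time = NULL,
             ...)
}

# Evaluate the square-wave air temperature target at time t (minutes).
square_wave_target <- function(t_min, cfg) {
  ifelse(((t_min / 60) %% 24) < cfg$photoperiod_day, cfg$temp_day,
         cfg$temp_night)
}

#' Simulate the meristem temperature trace
#'
#' Produces a day/night square wave on the configured photoperiod,
#' optionally smoothed by a first-order lag with time constant
#' \code{temp_lag} (the meristem tracks the air set point with some
#' thermal inertia). The lag response is evaluated exactly, segment by
#' segment, so with \code{temp_lag = 0} the output is the exact square
#' wave. The experiment starts at the beginning of a day period with the
#' meristem at the night temperature.
#'
#' @param cfg a [sim_config()].
#' @return a \code{meristem_temp_trace}: data frame with \code{time_min}
#'   and \code{temp_c}.
#' @export
simulate_temperature <- function(cfg) {
  validate_sim_config(cfg)
  t_min <- seq(0, cfg$duration * 60, by = cfg$temp_cadence)
  if (cfg$temp_lag <= 0 || cfg$temp_day == cfg$temp_night) {
    temp <- square_wave_target(t_min, cfg)
  } else {
    tau_min <- cfg$temp_lag * 60
    # day/night transition times, minutes
    n_days <- ceiling(cfg$duration / 24)
    bounds <- sort(unique(c(
      0,
      rep(seq_len(n_days) - 1, each = 2) * 1440 +
        c(0, cfg$photoperiod_day * 60),
      cfg$duration * 60
    )))
    bounds <- bounds[bounds >= 0 & bounds <= cfg$duration * 60]
    temp <- numeric(length(t_min))
    state <- cfg$temp_night
    for (k in seq_len(length(bounds) - 1)) {
      s0 <- bounds[k]
      s1 <- bounds[k + 1]
      target <- square_wave_target(s0, cfg)
      in_seg <- t_min >= s0 & (t_min < s1 | (k == length(bounds) - 1 &
                                               t_min <= s1))
      temp[in_seg] <- target + (state - target) *
        exp(-(t_min[in_seg] - s0) / tau_min)
      state <- target + (state - target) * exp(-(s1 - s0) / tau_min)
    }
  }
  structure(data.frame(time_min = t_min, temp_c = temp),
            class = c("meristem_temp_trace", "data.frame"))
}

# log10 soil matric potential at time t (hours), per the configured
# exponential-saturating drying curve with optional re-watering reset.
psi_log10_curve <- function(cfg, t_h) {
  psi <- cfg$psi_plateau -
    (cfg$psi_plateau - cfg$psi_start) * exp(-t_h / cfg$psi_timescale)
  if (!is.null(cfg$rewater_time)) {
    psi[t_h >= cfg$rewater_time] <- cfg$psi_start
  }
  psi
}

#' Simulate the soil moisture trace
#'
#' The log10 matric potential follows an exponential-saturating drying
#' curve from \code{psi_start} towards \code{psi_plateau} with time
#' constant \code{psi_timescale}, sampled every \code{soil_cadence}
#' hours; raw output is in hPa (10^psi). If \code{rewater_time} is set,
#' the potential resets instantaneously to \code{psi_start} at that hour
#' and stays there.
#'
#' @param cfg a [sim_config()].
#' @return a \code{soil_moisture_trace}: data frame with \code{time_min}
#'   and \code{psi_hpa}.
#' @export
simulate_soil_drying <- function(cfg) {
  validate_sim_config(cfg)
  t_h <- seq(0, cfg$duration, by = cfg$soil_cadence)
  psi <- psi_log10_curve(cfg, t_h)
  structure(data.frame(time_min = t_h * 60, psi_hpa = 10^psi),
            class = c("soil_moisture_trace", "data.frame"))
}

# Piecewise-linear stress response g(psi): 1 in the normal phase,
# linear decline between the breakpoints, 0 in arrest.
stress_response <- function(psi_log10, sigma_upper, sigma_lower) {
  g <- (sigma_lower - psi_log10) / (sigma_lower - sigma_upper)
  pmin(1, pmax(0, g))
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a cumulative leaf-length trace
#'
#' Integrates the instantaneous elongation rate
#' \code{a_true * T(t) * g(psi(t))} (plus optional Gaussian rate noise)
#' over the experiment, sampling the cumulative length every
#' \code{growth_cadence} minutes. Temperature and log10 soil potential
#' are linearly interpolated from the supplied traces; integration is
#' trapezoidal between consecutive samples. With \code{noise_sd_ler = 0}
#' the trace is deterministic and non-decreasing; identical seeds give
#' identical traces.
#'
#' @param cfg a [sim_config()].
#' @param temp a \code{meristem_temp_trace} covering \code{cfg$duration}.
#' @param soil a \code{soil_moisture_trace} covering \code{cfg$duration}.
#' @param tiller_id label for the simulated tiller.
#' @param seed RNG seed for the noise; defaults to \code{cfg$seed}.
#' @param length0 initial leaf length, mm.
#' @return a \code{growth_trace}: data frame with \code{tiller_id},
#'   \code{time_min} and \code{length_mm}.
#' @export
simulate_growth <- function(cfg, temp = simulate_temperature(cfg),
                            soil = simulate_soil_drying(cfg),
                            tiller_id = "tiller_01", seed = cfg$seed,
                            length0 = 20) {
  validate_sim_config(cfg)
  end_min <- cfg$duration * 60
  if (max(temp$time_min) < end_min || max(soil$time_min) + 1e-9 <
      end_min - cfg$soil_cadence * 60) {
    stop("alignment error: temperature/soil traces do not cover the ",
         "requested duration", call. = FALSE)
  }
  t_min <- seq(0, end_min, by = cfg$growth_cadence)
  temp_fun <- stats::approxfun(temp$time_min, temp$temp_c, rule = 2)
  psi_fun <- stats::approxfun(soil$time_min, log10(soil$psi_hpa), rule = 2)
  rate <- cfg$a_true * temp_fun(t_min) *
    stress_response(psi_fun(t_min), cfg$sigma_upper_true,
                    cfg$sigma_lower_true)
  dt_h <- diff(t_min) / 60
  inc <- dt_h * (rate[-1] + rate[-length(rate)]) / 2
  if (cfg$noise_sd_ler > 0) {
    eps <- with_seed(seed, stats::rnorm(length(inc), 0, cfg$noise_sd_ler))
    inc <- inc + eps * dt_h
  }
  if (cfg$no_shrink) inc <- pmax(inc, 0)
  out <- data.frame(tiller_id = tiller_id,
                    time_min = t_min,
                    length_mm = length0 + c(0, cumsum(inc)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("growth_trace", "data.frame"))
}

#' Simulate a full replicated drying experiment
#'
#' Generates one temperature trace, one soil moisture trace and
#' \code{n_replicates} growth traces (replicate i seeded with
#' \code{seed + i}), together with the ground-truth parameters.
#'
#' @param cfg a [sim_config()].
#' @return a list of class \code{sim_experiment} with elements
#'   \code{temp}, \code{soil}, \code{growth} (list of traces),
#'   \code{truth} (named list) and \code{cfg}.
#' @export
simulate_experiment <- function(cfg) {
  validate_sim_config(cfg)
  temp <- simulate_temperature(cfg)
  soil <- simulate_soil_drying(cfg)
  ids <- sprintf("tiller_%02d", seq_len(cfg$n_replicates))
  growth <- lapply(seq_len(cfg$n_replicates), function(i) {
    simulate_growth(cfg, temp, soil, tiller_id = ids[i],
                    seed = cfg$seed + i)
  })
  truth <- list(a_true = cfg$a_true,
                a_true_um = cfg$a_true * 1000,
                sigma_upper_true = cfg$sigma_upper_true,
                sigma_lower_true = cfg$sigma_lower_true,
                rewater_time = cfg$rewater_time,
                seed = cfg$seed)
  structure(list(temp = temp, soil = soil, growth = growth,
                 truth = truth, cfg = cfg),
            class = "sim_experiment")
}

#' Write a simulated experiment to tidy CSV files
#'
#' Writes \code{growth.csv} (tiller_id, time_min, length_mm; all
#' replicates stacked), \code{temperature.csv} (time_min, temp_c),
#' \code{soil.csv} (time_min, psi_hpa) and a \code{truth.json} sidecar
#' recording every ground-truth parameter and the seed.
#'
#' @param sim a \code{sim_experiment} from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of file paths.
#' @export
write_experiment_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(growth = file.path(dir, "growth.csv"),
             temperature = file.path(dir, "temperature.csv"),
             soil = file.path(dir, "soil.csv"),
             truth = file.path(dir, "truth.json"))
  growth_all <- do.call(rbind, lapply(sim$growth, as.data.frame))
  write_trace_csv(growth_all, paths[["growth"]])
  write_trace_csv(as.data.frame(sim$temp), paths[["temperature"]])
  write_trace_csv(as.data.frame(sim$soil), paths[["soil"]])
  sidecar <- c(sim$cfg[setdiff(names(sim$cfg), "rewater_time")],
               list(rewater_time = if (is.null(sim$cfg$rewater_time)) NA
                    else sim$cfg$rewater_time))
  jsonlite::write_json(sidecar, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
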