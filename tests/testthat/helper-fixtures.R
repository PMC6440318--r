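# Shared fixtures: all test inputs are generated in code.

# Day-length-weighted mean chamber temperature, used to express rate-noise
# levels as a percentage of the mean elongation rate.
mean_chamber_temp <- function(cfg = sim_config()) {
  (cfg$temp_day * cfg$photoperiod_day +
     cfg$temp_night * (24 - cfg$photoperiod_day)) / 24
}

noise_sd_pct <- function(pct, a_true = 0.0529) {
  pct / 100 * a_true * mean_chamber_temp()
}

# Hand-built hourly series: one row per (psi, rgra) pair; temperature and
# rate are arbitrary but consistent so that relative_growth() reproduces
# the requested rgra with a = 1.
series_from_rgra <- function(psi, rgra, after_rewatering = FALSE) {
  n <- length(psi)
  structure(data.frame(hour = seq_len(n) - 1,
                       ler_mm_h = rgra * 20,
                       temp_c = 20,
                       psi_log10 = psi,
                       after_rewatering = rep_len(after_rewatering, n),
                       rgra = rgra),
            class = c("hourly_series", "data.frame"))
}

# n points spread uniformly inside a quarter bin [lo, lo + 0.25), all at
# the same rgra value.
bin_points <- function(lo, rgra, n) {
  list(psi = lo + 0.25 * (seq_len(n) - 0.5) / n, rgra = rep(rgra, n))
}

series_from_bins <- function(...) {
  parts <- list(...)
  psi <- unlist(lapply(parts, `[[`, "psi"))
  rgra <- unlist(lapply(parts, `[[`, "rgra"))
  series_from_rgra(psi, rgra)
}

# Brute-force least-squares minimizers used as independent oracles.
brute_force_origin_slope <- function(t, y) {
  stats::optimize(function(a) sum((y - a * t)^2),
                  interval = range(y / t) + c(-1, 1), tol = 1e-12)$minimum
}

brute_force_line <- function(x, y) {
  sse <- function(p) sum((y - p[1] - p[2] * x)^2)
  par <- c(mean(y), 0)
  for (round in 1:3) {
    par <- stats::optim(par, sse, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 5000))$par
  }
  par
}

# Exhaustive permutation test for the one-way F statistic (small n only).
permutation_p <- function(values, groups) {
  obs <- one_way_anova(values, groups)$f_stat
  perms <- combinat_perms(length(values))
  stats <- apply(perms, 1, function(ix) {
    one_way_anova(values[ix], groups)$f_stat
  })
  mean(stats >= obs - 1e-12)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
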