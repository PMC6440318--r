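make_series <- function(temp, ler, psi = 2, after = FALSE) {
  n <- max(length(temp), length(ler))
  structure(data.frame(hour = seq_len(n) - 1,
                       ler_mm_h = rep_len(ler, n),
                       temp_c = rep_len(temp, n),
                       psi_log10 = rep_len(psi, n),
                       after_rewatering = rep_len(after, n)),
            class = c("hourly_series", "data.frame"))
}

test_that("through-origin thermal fit has the closed form a = S(T*L)/S(T^2)", {
  # exact linearity: LER = 2 * T
  temps <- rep(c(25, 15), 12)
  s <- make_series(temps, 2 * temps)
  fit <- fit_thermal_rate(s)
  expect_equal(fit$a, 2, tolerance = 1e-14)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 24)

  # two-point worked example: (10, 0.5), (20, 1.1)
  s2 <- make_series(c(10, 20, 30), c(0.5, 1.1, 1.6))
  fit2 <- fit_thermal_rate(s2)
  two_pt <- sum(c(10, 20) * c(0.5, 1.1)) / sum(c(10, 20)^2)
  expect_equal(two_pt, 0.054)
  # oracle: brute-force minimization over the slope
  expect_equal(fit2$a, brute_force_origin_slope(c(10, 20, 30),
                                                c(0.5, 1.1, 1.6)),
               tolerance = 1e-8)

  expect_error(fit_thermal_rate(make_series(20, 1)[1:2, ]),
               "insufficient-data")
  expect_error(fit_thermal_rate(make_series(0, 1)), "degenerate-fit")
})

test_that("thermal window honours its bounds and re-watering exclusion", {
  s <- make_series(rep(c(25, 15), 24), 1)
  s$ler_mm_h[s$hour >= 24] <- 99 # junk outside the window must be ignored
  fit <- fit_thermal_rate(s, window_h = 24)
  expect_equal(fit$n_points, 24)
  expect_equal(fit$a, sum(s$temp_c[1:24]) / sum(s$temp_c[1:24]^2))
})

test_that("relative growth divides out the thermal expectation", {
  temps <- rep(c(25, 15), 12)
  s <- make_series(temps, 0.05 * temps)
  fit <- fit_thermal_rate(s)
  s <- relative_growth(s, fit)
  expect_equal(s$rgra, rep(1, 24), tolerance = 1e-12)

  s2 <- make_series(20, 0)
  s2 <- relative_growth(s2, fit)
  expect_equal(unique(s2$rgra), 0)

  s3 <- make_series(20, 0.6)
  fit3 <- structure(list(a = 0.05), class = "thermal_fit")
  expect_equal(relative_growth(s3, fit3)$rgra[1], 0.6)

  expect_error(relative_growth(s3, structure(list(a = -1),
                                             class = "thermal_fit")),
               "domain error")
})

test_that("bins are classified on quarter boundaries with the rebound rule", {
  s <- series_from_bins(bin_points(2.00, 1.0, 4), bin_points(2.25, 1.0, 4),
                        bin_points(2.50, 1.0, 4))
  bins <- classify_bins(s)
  expect_equal(bins$phase, rep("normal", 3))
  expect_equal(bins$hi - bins$lo, rep(0.25, 3))
  expect_equal(bins$lo %% 0.25, rep(0, 3))

  # a one-increment dip below 0.9 is rescued by the following normal bin
  s2 <- series_from_bins(bin_points(2.00, 1.0, 4), bin_points(2.25, 0.85, 4),
                         bin_points(2.50, 0.96, 4), bin_points(2.75, 0.6, 4),
                         bin_points(3.00, 0.1, 4))
  expect_equal(classify_bins(s2)$phase,
               c("normal", "normal", "normal", "slow", "arrest"))

  # monotone decline, no rescue
  s3 <- series_from_bins(bin_points(2.00, 1.0, 4), bin_points(2.25, 0.5, 4),
                         bin_points(2.50, 0.15, 4))
  expect_equal(classify_bins(s3)$phase, c("normal", "slow", "arrest"))

  # an arrest bin is never rescued, even before a higher bin mean
  s4 <- series_from_bins(bin_points(2.00, 1.0, 4), bin_points(2.25, 0.1, 4),
                         bin_points(2.50, 0.95, 4))
  expect_equal(classify_bins(s4)$phase, c("normal", "arrest", "normal"))

  # boundary values are slow (0.9 and 0.2 are not above/below)
  s5 <- series_from_bins(bin_points(2.00, 0.9, 4), bin_points(2.25, 0.2, 4))
  expect_equal(classify_bins(s5)$phase, c("slow", "slow"))

  # gaps in the observed range yield empty bins
  s6 <- series_from_bins(bin_points(2.00, 1.0, 4), bin_points(2.75, 0.5, 4))
  b6 <- classify_bins(s6)
  expect_equal(b6$phase, c("normal", "empty", "empty", "slow"))
  expect_equal(b6$n_points, c(4L, 0L, 0L, 4L))
})

test_that("slow-subset selection keeps slow bins plus the driest normal bin", {
  s <- series_from_bins(bin_points(2.00, 1.0, 5), bin_points(2.25, 0.6, 4),
                        bin_points(2.50, 0.1, 6))
  bins <- classify_bins(s)
  pts <- select_slow_subset(s, bins)
  expect_equal(nrow(pts), 9) # 4 slow + 5 retained normal

  # without retention only the slow bins remain
  pts2 <- select_slow_subset(s, bins,
                             triphase_control(retain_max_normal = FALSE))
  expect_equal(nrow(pts2), 4)

  # all normal -> a no-response signal, not an error
  s3 <- series_from_bins(bin_points(2.00, 1.0, 5), bin_points(2.25, 0.98, 5))
  expect_s3_class(select_slow_subset(s3, classify_bins(s3)),
                  "triphase_no_response")

  # rebound: of two disjoint normal stretches only the driest normal bin
  # is retained
  s4 <- series_from_bins(bin_points(2.00, 1.0, 3), bin_points(2.25, 0.85, 3),
                         bin_points(2.50, 0.95, 3), bin_points(2.75, 0.5, 4),
                         bin_points(3.00, 0.3, 4), bin_points(3.25, 0.1, 4))
  pts4 <- select_slow_subset(s4, classify_bins(s4))
  expect_equal(nrow(pts4), 11) # 8 slow + 3 from bin 2.50-2.75 only
  expect_true(all(pts4$psi_log10 >= 2.50))

  # arrest is terminal: bins beyond the first arrest bin are excluded
  s5 <- series_from_bins(bin_points(2.00, 1.0, 3), bin_points(2.25, 0.5, 3),
                         bin_points(2.50, 0.1, 3), bin_points(2.75, 0.5, 3))
  pts5 <- select_slow_subset(s5, classify_bins(s5))
  expect_true(all(pts5$psi_log10 < 2.5))
})

test_that("slow-phase regression recovers exact lines and rejects bad input", {
  s <- series_from_rgra(seq(2.0, 2.8, by = 0.1),
                        3 - seq(2.0, 2.8, by = 0.1))
  fit <- fit_slow_phase(s)
  expect_equal(fit$i, 3, tolerance = 1e-12)
  expect_equal(fit$c, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # worked three-point example against the closed form and a brute-force
  # minimizer
  s2 <- series_from_rgra(c(2.5, 3.0, 3.5), c(0.9, 0.5, 0.1))
  fit2 <- fit_slow_phase(s2)
  expect_equal(fit2$i, 2.9, tolerance = 1e-12)
  expect_equal(fit2$c, -0.8, tolerance = 1e-12)
  oracle <- brute_force_line(c(2.5, 3.0, 3.5), c(0.9, 0.5, 0.1))
  expect_equal(c(fit2$i, fit2$c), oracle, tolerance = 1e-8)

  expect_error(fit_slow_phase(s2[1:2, ]), "insufficient-data")
  expect_error(fit_slow_phase(series_from_rgra(c(2.5, 2.55, 2.6),
                                               c(0.9, 0.5, 0.1))),
               "insufficient-spread")
  expect_error(fit_slow_phase(series_from_rgra(c(2.5, 3.0, 3.5),
                                               c(0.1, 0.5, 0.9))),
               "non-decreasing-response")
})

test_that("breakpoints follow from the line and satisfy the identities", {
  bp <- breakpoints(list(i = 3, c = -1))
  expect_equal(unname(bp), c(2, 3))
  bp2 <- breakpoints(list(i = 3.4, c = -1.0))
  expect_equal(unname(bp2), c(2.4, 3.4), tolerance = 1e-12)
  expect_error(breakpoints(list(i = 3, c = 0.2)), "domain error")

  set.seed(7)
  for (k in 1:50) {
    i <- runif(1, 1, 5)
    c <- -runif(1, 0.2, 3)
    bp <- breakpoints(list(i = i, c = c))
    expect_lt(bp[["sigma_upper"]], bp[["sigma_lower"]])
    expect_equal(bp[["sigma_lower"]] - bp[["sigma_upper"]], -1 / c,
                 tolerance = 1e-10)
    expect_equal(bp[["sigma_upper"]], (1 - i) / c, tolerance = 1e-10)
  }
})

test_that("OLS stages agree with brute-force minimization on small instances", {
  set.seed(13)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    t <- runif(n, 10, 30)
    y <- 0.05 * t + rnorm(n, 0, 0.1)
    s <- make_series(t, y)
    expect_equal(fit_thermal_rate(s, window_h = n + 1)$a,
                 brute_force_origin_slope(t, y), tolerance = 1e-8)

    x <- runif(n, 2, 4)
    r <- 3 - x + rnorm(n, 0, 0.05)
    sf <- fit_slow_phase(series_from_rgra(x, r))
    expect_equal(c(sf$i, sf$c), brute_force_line(x, r), tolerance = 1e-8)
  }
})

test_that("a control tiller yields a thermal fit and a no-response result", {
  cfg <- sim_config(psi_timescale = Inf, duration = 60, rewater_time = NULL,
                    noise_sd_ler = 0, n_replicates = 1)
  sim <- simulate_experiment(cfg)
  fit <- suppressMessages(fit_tiller(sim$growth[[1]], sim$temp, sim$soil))
  expect_true(fit$no_response)
  expect_true(is.na(fit$sigma_upper))
  expect_equal(fit$thermal$a, cfg$a_true, tolerance = 1e-12)
  row <- as_result_row(fit)
  expect_true(row$no_response)
})

test_that("stage errors carry the failing stage's name", {
  s <- make_series(20, 1)[1:2, ]
  expect_error(fit_triphase(s), "^\\[thermal\\]")
})

test_that("scaling LER scales a and leaves RGRa and breakpoints unchanged", {
  cfg <- sim_config_for_truth(0.0529, 2.4, 3.4, noise_sd_ler = 0,
                              n_replicates = 1)
  sim <- simulate_experiment(cfg)
  s <- suppressMessages(hourly_series(sim$growth[[1]], sim$temp, sim$soil))
  f1 <- fit_triphase(s)
  s2 <- s
  s2$ler_mm_h <- s2$ler_mm_h * 3.7
  f2 <- fit_triphase(s2)
  expect_equal(f2$thermal$a, 3.7 * f1$thermal$a, tolerance = 1e-12)
  expect_equal(f2$slow$i, f1$slow$i, tolerance = 1e-9)
  expect_equal(f2$sigma_upper, f1$sigma_upper, tolerance = 1e-9)
  expect_equal(f2$sigma_lower, f1$sigma_lower, tolerance = 1e-9)
})

test_that("noiseless pipelines recover the ground truth", {
  # a is exact; breakpoints recovered within the published tolerance where
  # the slow phase spans at least a full unit, and within one bin width
  # even for the narrowest slow phases the binning can resolve
  for (S in c(2.0, 2.6, 3.2)) {
    for (gap in c(0.5, 1.0, 1.5)) {
      cfg <- sim_config_for_truth(0.0529, S, S + gap, noise_sd_ler = 0,
                                  n_replicates = 1)
      fe <- suppressMessages(fit_experiment(simulate_experiment(cfg)))
      expect_equal(fe$results$a_um, 52.9, tolerance = 1e-9)
      tol <- if (gap >= 1) 0.1 else 0.25
      expect_lt(abs(fe$results$sigma_upper - S), tol)
      expect_lt(abs(fe$results$sigma_lower - (S + gap)), tol)
    }
  }
})

test_that("breakpoint recovery stays within 0.2 under 10% rate noise", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config_for_truth(0.0529, 2.70, 3.83,
                                noise_sd_ler = noise_sd_pct(10),
                                n_replicates = 1, seed = seed)
    fe <- suppressMessages(fit_experiment(simulate_experiment(cfg)))
    expect_lt(abs(fe$results$sigma_upper - 2.70), 0.2)
    expect_lt(abs(fe$results$sigma_lower - 3.83), 0.2)
  }
})

test_that("results serialize to JSON and a flat row", {
  cfg <- sim_config_for_truth(0.0529, 2.4, 3.4, noise_sd_ler = 0,
                              n_replicates = 1)
  sim <- simulate_experiment(cfg)
  fit <- suppressMessages(fit_tiller(sim$growth[[1]], sim$temp, sim$soil))
  path <- withr::local_tempfile(fileext = ".json")
  write_triphase_json(fit, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$sigma_upper, fit$sigma_upper, tolerance = 1e-12)
  expect_equal(doc$thermal$a_um, fit$thermal$a_um, tolerance = 1e-12)
  row <- as_result_row(fit)
  expect_named(row, c("tiller_id", "a_um", "i", "c", "sigma_upper",
                      "sigma_lower", "r2_thermal", "r2_slow", "n_hours",
                      "no_response"))
  expect_equal(row$sigma_lower - row$sigma_upper, -1 / row$c,
               tolerance = 1e-10)
})
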