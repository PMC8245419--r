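test_that("log compression passes sparse input through and averages constants", {
  tt <- 10^seq(-6, -1, by = 0.5)     # far sparser than 100/decade
  out <- quasi_log_compress(tt, seq_along(tt))
  expect_equal(out$times, tt)
  expect_equal(out$values, seq_along(tt))

  tt <- seq(1e-5, 1e-2, length.out = 5000)
  out <- quasi_log_compress(tt, rep(4.2, 5000))
  expect_true(all(abs(out$values - 4.2) < 1e-12))
  expect_lte(length(out$times), 5000)
})

test_that("dense linear traces compress to ~100 points per covered decade", {
  tt <- seq(1e-7, 1e-7 * 32000, length.out = 32000)  # ~4.5 decades
  out <- quasi_log_compress(tt, sin(tt * 1e4), points_per_decade = 100)
  dec <- floor(log10(out$times))
  counts <- table(dec)
  # decades fully inside the span and densely sampled by the input
  full <- counts[names(counts) %in% c("-5", "-4")]
  expect_true(all(abs(full - 100) <= 1))
})

test_that("compression preserves per-bin means exactly", {
  set.seed(2)
  tt <- sort(runif(2000, 1e-6, 1e-2))
  vv <- rnorm(2000)
  out <- quasi_log_compress(tt, vv, points_per_decade = 50)
  # total signal mass is conserved when weighted by bin occupancy
  lt <- log10(tt)
  edges <- seq(lt[1], lt[length(lt)] + 1 / 50, by = 1 / 50)
  bin <- findInterval(lt, edges, rightmost.closed = TRUE)
  occup <- as.vector(table(bin))
  expect_equal(sum(out$values * occup), sum(vv), tolerance = 1e-9)
})

test_that("a noiseless single exponential is recovered to machine accuracy", {
  spec <- photocycle_spec(
    lifetimes = 5e-3,
    states = tibble::tibble(state = "M", lambda_max = 410, fwhm = 70,
                            peak = 0.8),
    f = 0.3, noise_sd = 0, seed = 1)
  sim <- simulate_photocycle_dataset(spec)
  fit <- fit_global_exponentials(sim$dataset, 1)
  expect_lt(abs(fit$tau / 5e-3 - 1), 1e-6)
  expect_lt(fit$sd_weighted, 1e-9)
})

test_that("three noiseless exponentials with smooth random spectra are recovered", {
  set.seed(14)
  tau <- c(1e-5, 1e-3, 5e-2)
  wl <- seq(330, 700, 10)
  times <- 10^seq(-7, 0, by = 0.02)
  amps <- sapply(1:3, function(i) {
    gaussian_band(wl, runif(1, 400, 620), runif(1, 60, 110),
                  runif(1, 0.5, 1)) - gaussian_band(wl, 550, 80, 0.4)
  })
  Y <- amps %*% t(exp(-outer(times, 1 / tau)))
  d <- transient_absorption(wl, times, Y)
  fit <- fit_global_exponentials(d, 3)
  expect_true(all(abs(fit$tau / tau - 1) < 1e-4))
})

test_that("lifetimes stay within 5% at SNR 50", {
  spec <- photocycle_spec(snr = 50, seed = 33)
  sim <- simulate_photocycle_dataset(spec)
  fit <- fit_global_exponentials(sim$dataset, 5)
  expect_true(all(abs(fit$tau / spec$lifetimes - 1) < 0.05))
})

test_that("variable projection is self-consistent at the returned lifetimes", {
  spec <- photocycle_spec(snr = 100, seed = 3)
  sim <- simulate_photocycle_dataset(spec)
  fit <- fit_global_exponentials(sim$dataset, 5)
  E <- cbind(exp(-outer(sim$dataset$times, 1 / fit$tau)), 1)
  coef <- qr.solve(E, t(sim$dataset$delta_A))
  expect_equal(t(coef[1:5, ]), fit$amplitudes, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(coef[6, ], fit$offset, tolerance = 1e-10)
})

test_that("residual SD is non-increasing in the component count", {
  spec <- photocycle_spec(snr = 100, seed = 8)
  sim <- simulate_photocycle_dataset(spec)
  sel <- select_component_count(sim$dataset, n_max = 6)
  expect_true(all(diff(sel$sd_ladder$sd_weighted) <= 1e-12))
})

test_that("component selection stops at the true count", {
  spec1 <- photocycle_spec(
    lifetimes = 2e-3,
    states = tibble::tibble(state = "M", lambda_max = 410, fwhm = 70,
                            peak = 0.8),
    f = 0.3, snr = 200, seed = 5)
  sim1 <- simulate_photocycle_dataset(spec1)
  expect_equal(select_component_count(sim1$dataset, n_max = 3)$n, 1)

  spec5 <- photocycle_spec(snr = 100, seed = 6)
  sim5 <- simulate_photocycle_dataset(spec5)
  expect_equal(select_component_count(sim5$dataset, n_max = 6)$n, 5)
})

test_that("white noise selects a single near-zero component", {
  set.seed(10)
  wl <- seq(330, 700, 10)
  times <- 10^seq(-7, 0, by = 0.05)
  d <- transient_absorption(wl, times,
                            matrix(rnorm(length(wl) * length(times),
                                         sd = 0.01),
                                   length(wl), length(times)))
  sel <- select_component_count(d, n_max = 3)
  expect_equal(sel$n, 1)
  expect_lt(max(abs(sel$fit$amplitudes)), 0.02)
})

test_that("Bateman concentrations match closed forms and an ODE oracle", {
  cc <- sequential_concentrations(2, c(0.1, 1, 3))
  expect_equal(cc$S1, exp(-2 * c(0.1, 1, 3)))

  # textbook two-state chain k1 = 2, k2 = 1: c2(ln 2) = 1/2
  cc <- sequential_concentrations(c(2, 1), log(2))
  expect_equal(cc$S2, 0.5, tolerance = 1e-12)

  rates <- c(500, 90, 17, 4, 0.8)
  times <- 10^seq(-4, 1, by = 0.1)
  cc <- sequential_concentrations(rates, times)
  C <- as.matrix(cc[, paste0("S", 1:5)])
  expect_true(all(rowSums(C) <= 1 + 1e-9))
  expect_equal(sum(C[1, ]), 1, tolerance = 1e-4)
  expect_true(all(diff(cc$recovered) >= -1e-9))   # monotone recovery

  ode <- deSolve::lsoda(
    y = c(1, rep(0, 4)),
    times = c(0, times),
    func = function(t, y, p) {
      flow <- p * y
      list(c(-flow[1], flow[-5] - flow[-1]))
    },
    parms = rates, rtol = 1e-10, atol = 1e-12)
  expect_equal(C, unname(ode[-1, -1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("near-degenerate rates switch to the matrix-exponential path", {
  expect_warning(cc <- sequential_concentrations(c(1, 1), c(0.5, 1, 2)),
                 "degenerate")
  # analytic: c2(t) = t exp(-t) for equal unit rates
  expect_equal(cc$S2, c(0.5, 1, 2) * exp(-c(0.5, 1, 2)), tolerance = 1e-8)
})

test_that("a noiseless two-state cycle returns the true fraction and spectra", {
  spec <- photocycle_spec(
    lifetimes = c(1e-4, 1e-2),
    states = tibble::tibble(state = c("M", "O"),
                            lambda_max = c(410, 630), fwhm = c(70, 90),
                            peak = c(0.8, 1.0)),
    f = 0.3, noise_sd = 0, seed = 2)
  sim <- simulate_photocycle_dataset(spec)
  fit <- fit_global_exponentials(sim$dataset, 2)
  gr <- tibble::tibble(wavelength = spec$wavelengths,
                       absorbance = sim$truth$ground_spectrum)
  rec <- reconstruct_intermediate_spectra(fit, gr,
                                          state_names = c("M", "O"))
  expect_lt(abs(rec$f - 0.3), 0.02)
  expect_lt(max(abs(rec$absolute - sim$truth$state_spectra)),
            0.01 * max(sim$truth$state_spectra))
})

test_that("an all-zero surface reconstructs to the ground spectrum at f = 1", {
  spec <- photocycle_spec(
    lifetimes = c(1e-4, 1e-2),
    states = tibble::tibble(state = c("M", "O"),
                            lambda_max = c(410, 630), fwhm = c(70, 90),
                            peak = c(0.8, 1.0)),
    f = 0, noise_sd = 0, seed = 2)
  sim <- simulate_photocycle_dataset(spec)
  fit <- fit_global_exponentials(sim$dataset, 2,
                                 init = c(1e-4, 1e-2))
  gr <- tibble::tibble(wavelength = spec$wavelengths,
                       absorbance = sim$truth$ground_spectrum)
  rec <- reconstruct_intermediate_spectra(fit, gr)
  expect_equal(rec$f, 1)
  expect_equal(rec$absolute[1, ], sim$truth$ground_spectrum,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("five-state reconstruction recovers each state's absorbance maximum", {
  spec <- photocycle_spec(snr = 100, seed = 21)
  sim <- simulate_photocycle_dataset(spec)
  fit <- fit_global_exponentials(sim$dataset, 5)
  gr <- tibble::tibble(wavelength = spec$wavelengths,
                       absorbance = sim$truth$ground_spectrum)
  rec <- reconstruct_intermediate_spectra(fit, gr,
                                          state_names = spec$states$state)
  lam <- apply(rec$absolute, 1, function(s) spec$wavelengths[which.max(s)])
  expect_true(all(abs(lam - spec$states$lambda_max) <= 10))
})

test_that("transient datasets round-trip through delimited text", {
  spec <- photocycle_spec(snr = 100, seed = 4,
                          points_per_decade = 10)
  sim <- simulate_photocycle_dataset(spec)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_transient_dataset(sim$dataset, f)
  d2 <- read_transient_dataset(f)
  expect_equal(d2$wavelengths, sim$dataset$wavelengths)
  expect_equal(d2$times, sim$dataset$times, tolerance = 1e-9)
  expect_equal(d2$delta_A, sim$dataset$delta_A, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("single and double unfolding transitions are localized to the grid step", {
  c1 <- simulate_unfolding_curve(66.5, seed = 3)
  t1 <- detect_unfolding_transitions(c1)
  expect_length(t1, 1)
  expect_lt(abs(t1 - 66.5), 0.25 + 1e-9)

  c2 <- simulate_unfolding_curve(c(49.3, 64.8), seed = 4)
  t2 <- detect_unfolding_transitions(c2)
  expect_length(t2, 2)
  expect_true(all(abs(t2 - c(49.3, 64.8)) < 0.25 + 1e-9))
})

test_that("flat and linear-ramp curves yield no transition", {
  flat <- simulate_unfolding_curve(50, amplitudes = 0, noise_sd = 0,
                                   baseline = c(0.8, 0), seed = 1)
  expect_length(detect_unfolding_transitions(flat), 0)
  ramp <- tibble::tibble(temperature = seq(15, 98, 0.25),
                         ratio = 0.01 * seq(15, 98, 0.25))
  expect_length(detect_unfolding_transitions(ramp), 0)
})
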