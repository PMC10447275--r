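test_that("noise-free exponential release data are recovered exactly", {
  d <- generate_release_data(500, 3600, n_points = 10, noise = "none")
  fit <- fit_exponential_release(d)
  expect_equal(fit$M_Released, 500, tolerance = 1e-6)
  expect_equal(fit$T, 3600, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
  expect_identical(fit$n_points, 10L)

  # plateau identification: sparse data with a long-time anchor
  tt <- c(0, 1800, 3600, 7200, 20 * 3600)
  d2 <- release_dataset(tt, 500 * (1 - exp(-tt / 3600)))
  fit2 <- fit_exponential_release(d2)
  expect_equal(fit2$M_Released, 500, tolerance = 1e-4)
})

test_that("release fitting rejects degenerate input", {
  expect_error(
    fit_exponential_release(release_dataset(c(0, 10, 20), c(0, 0, 0))),
    "no release signal")
  expect_error(
    fit_exponential_release(release_dataset(c(0, 10), c(0, 5))),
    "at least 3")
  expect_error(release_dataset(c(0, 10, 5), c(0, 1, 2)),
               "strictly increasing")
  expect_error(release_dataset(c(-5, 0, 10), c(0, 1, 2)),
               "non-negative")
  expect_warning(release_dataset(c(0, 10, 20), c(0, 100, 20)),
                 "decreases")
})

test_that("release rate follows the closed form and integrates to M", {
  fit <- release_fit(M_Released = 500, T = 3600)
  expect_equal(release_rate(0, fit), 500 / 3600)
  expect_equal(release_rate(3600, fit), (500 / 3600) * exp(-1))
  expect_error(release_rate(-1, fit), ">= 0")

  total <- stats::integrate(release_rate, 0, 20 * 3600, fit = fit,
                            rel.tol = 1e-12)$value
  expect_equal(total, 500 * (1 - exp(-20)), tolerance = 1e-10)
  expect_equal(total / 500, 1, tolerance = 1e-8)
})

test_that("noisy release data are recovered with small bias and spread", {
  n_rep <- 200
  Ms <- Ts <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- generate_release_data(500, 3600, n_points = 10,
                               noise = "multiplicative-gaussian",
                               cv = 0.1, seed = 1000 + i)
    fit <- fit_exponential_release(d)
    Ms[i] <- fit$M_Released
    Ts[i] <- fit$T
  }
  expect_lt(abs(mean(Ms) / 500 - 1), 0.03)
  expect_lt(abs(mean(Ts) / 3600 - 1), 0.03)
  expect_lt(stats::sd(Ms) / mean(Ms), 0.15)
  expect_lt(stats::sd(Ts) / mean(Ts), 0.15)
})

test_that("bioavailability from exact exponential data is the closed form", {
  d <- generate_aqueous_data(50, 7200, n_points = 10, noise = "none")
  f <- compute_bioavailability(d, Q_Aq = 7e-5, M_Released = 1e4)
  expect_equal(attr(f, "AUC"), 50 * 7200, tolerance = 1e-8)
  expect_equal(as.numeric(f), 7e-5 * 50 * 7200 / 1e4, tolerance = 1e-8)
  expect_equal(100 * as.numeric(f), 0.252, tolerance = 1e-8)

  # all-zero series: no exposure
  z <- aqueous_dataset(c(0, 100, 200), c(0, 0, 0))
  expect_equal(as.numeric(compute_bioavailability(z, 7e-5, 1e4)), 0)

  # proportionality: doubling the dose halves F
  f2 <- compute_bioavailability(d, Q_Aq = 7e-5, M_Released = 2e4)
  expect_equal(as.numeric(f2), as.numeric(f) / 2, tolerance = 1e-10)

  # growing series has no positive decay constant
  g <- aqueous_dataset(c(0, 100, 200, 300), c(1, 2, 4, 8))
  expect_error(compute_bioavailability(g, 7e-5, 1e4), "not positive")

  # inconsistent inputs warn
  big <- generate_aqueous_data(50, 7200, n_points = 10, noise = "none")
  expect_warning(compute_bioavailability(big, 1, 1), "exceeds 1")
})

test_that("F computed from a simulated trajectory recovers the input F", {
  p <- fixture_release()
  tr <- simulate_eye(p)
  days <- seq(86400, 604800, by = 86400)
  idx <- vapply(days, function(t) which.min(abs(tr$time_s - t)),
                integer(1))
  aq <- aqueous_dataset(tr$time_s[idx], tr$C_Aq[idx])
  f <- compute_bioavailability(aq, p$physiology$Q_Aq,
                               p$release$M_Released)
  expect_equal(as.numeric(f), p$drug$F, tolerance = 0.05)
})
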