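make_traj <- function(times, values) {
  df <- data.frame(time_s = times, C_t = values, C_ScCh = 0, C_Ret = 0,
                   C_Vit = 0, C_Aq = 0, C_Ep = NA_real_)
  class(df) <- c("eye_trajectory", "data.frame")
  df
}

test_that("exposure metrics follow the trapezoid and grid maximum", {
  m <- compute_metrics(make_traj(seq(0, 100, 10), rep(5, 11)))
  expect_equal(m$auc[m$compartment == "C_t"], 500)
  expect_equal(m$cmax[m$compartment == "C_t"], 5)

  m2 <- compute_metrics(make_traj(0:10, 0:10))
  expect_equal(m2$auc[m2$compartment == "C_t"], 50)
  expect_equal(m2$cmax[m2$compartment == "C_t"], 10)
  expect_equal(m2$t_cmax[m2$compartment == "C_t"], 10)

  m3 <- compute_metrics(make_traj(0:10, rep(0, 11)))
  expect_true(all(m3$auc == 0))
  expect_true(all(m3$cmax == 0))
})

test_that("mass audit catches a dropped sink", {
  p <- fixture_release()
  tr <- simulate_eye(p, t_end = 259200)
  expect_lt(mass_balance_residual(tr), 1e-3)

  # fault injection: erase the largest sink and expect its share back
  sinks <- tr[nrow(tr), grep("^sink_", names(tr), value = TRUE)]
  biggest <- names(sinks)[which.max(unlist(sinks))]
  broken <- tr
  broken[[biggest]] <- 0
  delivered <- p$release$M_Released *
    (1 - exp(-max(tr$time_s) / p$release$T))
  share <- unlist(sinks)[biggest] / delivered
  expect_equal(mass_balance_residual(broken), unname(share),
               tolerance = 1e-6)
})

test_that("closed-system runs leave nothing unaccounted", {
  p <- closed_system_params()
  tr <- simulate_eye(p, t_end = 20 * 3600, output_step = 3600)
  expect_lt(mass_balance_residual(tr), 1e-6)
})

test_that("local sensitivity rejects a zero perturbation and reports both directions", {
  p <- fixture_release()
  expect_error(local_sensitivity(p, perturbation = 0), "nonzero")

  s <- local_sensitivity(p, parameters = c("M_Released"))
  expect_setequal(s$direction, c("+10%", "-10%"))
  expect_identical(nrow(s), 10L)  # 2 directions x 5 compartments
  # source-strength linearity: +1 for +10%, -1 for -10%
  expect_equal(s$d_auc_pct_per_pct[s$direction == "+10%"], rep(1, 5),
               tolerance = 1e-4)
  expect_equal(s$d_auc_pct_per_pct[s$direction == "-10%"], rep(-1, 5),
               tolerance = 1e-4)
  expect_equal(abs(s$d_cmax_pct_per_pct), rep(1, 10), tolerance = 1e-4)
})

test_that("sensitivity coefficients match a direct finite-difference", {
  p <- fixture_release()
  p$solver$t_end <- 86400
  p$solver$output_step <- 1200
  s <- local_sensitivity(p, parameters = "Clearance_ScCh")

  # independent recomputation outside the framework
  base <- compute_metrics(simulate_eye(p))
  up <- p
  up$physiology$Clearance_ScCh <- 1.1 * p$physiology$Clearance_ScCh
  pert <- compute_metrics(simulate_eye(up))
  for (cc in c("C_ScCh", "C_Ret", "C_Vit")) {
    expected <- 100 * (pert$auc[pert$compartment == cc] /
                         base$auc[base$compartment == cc] - 1) / 10
    got <- s$d_auc_pct_per_pct[s$direction == "+10%" &
                                 s$compartment == cc]
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("a failing perturbed run is flagged without spoiling the table", {
  p <- fixture_release()
  p$solver$t_end <- 7200
  p$solver$output_step <- 1200
  # perturbing F beyond 1 makes validation fail for the +10% row only
  p$drug$F <- 0.95
  s <- local_sensitivity(p, parameters = c("F", "Q_Drain"))
  expect_true(all(s$failed[s$parameter == "F" & s$direction == "+10%"]))
  expect_false(any(s$failed[s$parameter == "Q_Drain"]))
  expect_false(any(is.na(s$d_auc_pct_per_pct[!s$failed])))
})

test_that("uncertainty ensembles are seeded, bracketed and degenerate at range 0", {
  p <- fixture_release()
  p$solver$t_end <- 43200
  p$solver$output_step <- 3600

  e0 <- uncertainty_cloud(p, n_runs = 5, range = 0, seed = 11)
  for (cc in names(e0$summary)) {
    expect_equal(e0$summary[[cc]][, "min"], e0$summary[[cc]][, "max"])
    expect_equal(e0$summary[[cc]][, "min"], e0$summary[[cc]][, "nominal"])
  }

  e1 <- uncertainty_cloud(p, n_runs = 8, range = 0.1, seed = 42)
  e2 <- uncertainty_cloud(p, n_runs = 8, range = 0.1, seed = 42)
  expect_identical(e1$summary, e2$summary)
  e3 <- uncertainty_cloud(p, n_runs = 8, range = 0.1, seed = 43)
  expect_false(identical(e1$summary, e3$summary))

  # nominal curve is an interior point of the sampled box
  for (cc in names(e1$summary)) {
    s <- e1$summary[[cc]]
    expect_true(all(s[, "nominal"] >= s[, "min"] - 1e-12))
    expect_true(all(s[, "nominal"] <= s[, "max"] + 1e-12))
    expect_true(all(s[, "p2_5"] >= s[, "min"] - 1e-12))
    expect_true(all(s[, "p97_5"] <= s[, "max"] + 1e-12))
  }
  expect_identical(e1$n_failed, 0L)
})
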