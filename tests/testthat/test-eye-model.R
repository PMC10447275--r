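state0 <- c(C_t = 0, C_ScCh = 0, C_Ret = 0, C_Vit = 0, C_Aq = 0)

test_that("release-mode balances implement the transport arrows", {
  p <- fixture_release()

  # all-zero state with a dead source: zero derivative
  p0 <- p
  p0$release$M_Released <- 1e-300
  d <- rhs_release(state0, t = 0, params = p0)
  expect_equal(unname(d$dC), rep(0, 5), tolerance = 1e-290)

  # equilibrated tears / sclera-choroid: bulbar exchange term vanishes,
  # so the sclera-choroid balance reduces to its own sinks
  st <- state0
  st["C_t"] <- 3
  st["C_ScCh"] <- 3 * p$drug$K_ScCh / p$drug$K_t
  d2 <- rhs_release(st, t = 1e12, params = p)  # source fully decayed
  expected <- -(p$physiology$Q_UvSc * st[["C_ScCh"]] / p$drug$K_ScCh +
                  p$physiology$Clearance_ScCh * st[["C_ScCh"]] +
                  p$anatomy$A_Globe * p$drug$P_ScCh_Ret *
                    st[["C_ScCh"]] / p$drug$K_ScCh) / p$anatomy$V_ScCh
  expect_equal(d2$dC[["C_ScCh"]], expected)

  # single-term check of the vitreous -> aqueous coupling
  p3 <- p
  p3$physiology$Q_Vit_Aq <- 1.9e-3
  st3 <- state0
  st3["C_Vit"] <- 10
  d3 <- rhs_release(st3, t = 1e12, params = p3)
  expect_equal(d3$dC[["C_Aq"]], 10 * 1.9e-3 / 0.325)

  # F splits the source between tears and aqueous humor
  pF1 <- p
  pF1$drug$F <- 1
  dF1 <- rhs_release(state0, t = 0, params = pF1)
  expect_equal(dF1$dC[["C_t"]], 0)
  expect_gt(dF1$dC[["C_Aq"]], 0)
  pF0 <- p
  pF0$drug$F <- 0
  dF0 <- rhs_release(state0, t = 0, params = pF0)
  expect_equal(dF0$dC[["C_Aq"]], 0)
  expect_gt(dF0$dC[["C_t"]], 0)

  # source vanishes as the release completes
  dInf <- rhs_release(state0, t = 500 * p$release$T, params = p)
  expect_equal(unname(dInf$dC), rep(0, 5), tolerance = 1e-200)

  expect_error(rhs_release(state0, 0, fixture_diffusion()),
               "release-mode")
  expect_error(rhs_diffusion(state0, NULL, p), "diffusion-mode")
})

test_that("epithelium concentration is the partition-weighted mean", {
  p <- fixture_release()
  p$drug$K_Ep_Aq <- 2
  p$drug$K_Ep_t <- 3
  expect_equal(epithelium_concentration(0, 0, p), 0)
  expect_equal(epithelium_concentration(10, 4, p), (2 * 10 + 3 * 4) / 2)
  p$drug$K_Ep_Aq <- 1
  p$drug$K_Ep_t <- 1
  expect_equal(epithelium_concentration(10, 4, p), 7)
  # missing coefficients give a missing diagnostic series
  expect_true(all(is.na(epithelium_concentration(1:3, 1:3,
                                                 fixture_release()))))
})

test_that("zero source gives an identically zero trajectory", {
  p <- closed_system_params()
  p$release$M_Released <- .Machine$double.xmin
  tr <- simulate_eye(p, t_end = 3600, output_step = 600)
  expect_lt(max(abs(as.matrix(tr[c("C_t", "C_ScCh", "C_Ret", "C_Vit",
                                   "C_Aq")]))), 1e-250)
})

test_that("the release-mode mass budget closes at every output time", {
  p <- fixture_release()
  tr <- simulate_eye(p)
  M <- p$release$M_Released
  delivered <- M * (1 - exp(-tr$time_s / p$release$T))
  closure <- abs(stored_mass(tr, p) + sink_mass(tr) - delivered) / M
  expect_lt(max(closure), 1e-3)
  expect_lt(mass_balance_residual(tr), 1e-3)
  # sink accumulators never decrease
  for (s in grep("^sink_", names(tr), value = TRUE)) {
    expect_true(all(diff(tr[[s]]) >= -1e-9 * max(tr[[s]])))
  }
})

test_that("the diffusion-mode mass budget closes at every output time", {
  p <- fixture_diffusion()
  tr <- simulate_eye(p)
  closure <- abs(tr$lens_mass + stored_mass(tr, p) + sink_mass(tr) -
                   tr$lens_mass[1]) / tr$lens_mass[1]
  expect_lt(max(closure), 1e-3)
  expect_lt(mass_balance_residual(tr), 1e-3)
})

test_that("the system is linear in the source strength", {
  p <- fixture_release()
  p$solver$t_end <- 86400
  tr1 <- simulate_eye(p)
  p2 <- p
  p2$release$M_Released <- 3 * p$release$M_Released
  tr2 <- simulate_eye(p2)
  for (cc in c("C_t", "C_ScCh", "C_Ret", "C_Vit", "C_Aq")) {
    i <- tr1[[cc]] > 1e-6 * max(tr1[[cc]])
    expect_lt(max(abs(tr2[[cc]][i] / tr1[[cc]][i] - 3)), 1e-6)
  }
})

test_that("concentrations stay non-negative for non-negative inputs", {
  for (p in list(fixture_release(), fixture_diffusion())) {
    tr <- simulate_eye(p, t_end = 172800)
    low <- min(as.matrix(tr[c("C_t", "C_ScCh", "C_Ret", "C_Vit",
                              "C_Aq")]))
    expect_gte(low, -10 * p$solver$abs_tol)
  }
})

test_that("choroidal clearance monotonically suppresses posterior exposure", {
  p <- fixture_release()
  p$solver$t_end <- 259200
  aucs <- sapply(c(0.5, 1, 1.5), function(s) {
    ps <- p
    ps$physiology$Clearance_ScCh <- s * p$physiology$Clearance_ScCh
    m <- compute_metrics(simulate_eye(ps))
    m$auc[match(c("C_ScCh", "C_Ret", "C_Vit"), m$compartment)]
  })
  # each row (compartment) strictly decreasing in clearance
  expect_true(all(aucs[, 1] > aucs[, 2]))
  expect_true(all(aucs[, 2] > aucs[, 3]))
})

test_that("lens-only parameters are inert in release mode", {
  p <- fixture_release()
  p$solver$t_end <- 86400
  tr <- simulate_eye(p)
  p2 <- p
  p2$drug$K_SCL <- 123
  p2$drug$P_t_Aq <- 9e-9
  tr2 <- simulate_eye(p2)
  expect_identical(as.matrix(as.data.frame(tr)),
                   as.matrix(as.data.frame(tr2)))
})

test_that("closed conservative system equilibrates to M over total volume", {
  p <- closed_system_params(T_release = 3600)
  sumV <- total_volume(p)
  g_bulb <- p$drug$P_Conj * p$anatomy$A_Bulb
  tau <- (sumV - p$anatomy$V_Aq - p$anatomy$V_t) / g_bulb
  tr <- simulate_eye(p, t_end = 100 * tau, output_step = tau)
  eq <- p$release$M_Released / sumV
  last <- tr[nrow(tr), ]
  for (cc in c("C_t", "C_ScCh", "C_Ret", "C_Vit", "C_Aq")) {
    expect_equal(last[[cc]], eq, tolerance = 5e-3)
  }
})
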