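test_that("unit normalization converts printed units to {cm, mL, s, ng}", {
  p <- fixture_release()
  # flows printed in uL/min and mL/min
  expect_equal(p$physiology$Q_Aq, 4.2 / 1000 / 60)
  expect_equal(p$physiology$Q_UvSc, 0.176 / 1000 / 60)
  expect_equal(p$physiology$Clearance_ScCh, 1 / 60)
  # percent stored as fraction
  expect_equal(p$drug$F, 0.0208)
  # release time constant in seconds
  expect_equal(p$release$T, 2 * 86400)

  # assorted unit tags across kinds
  q <- normalize_units(c(as.list(params_to_raw(p)),
                         list(Q_Aq = "0.252 mL/h", mode = "release")))
  expect_equal(q$physiology$Q_Aq, 0.252 / 3600)
})

test_that("normalize_units is idempotent and rejects bad input", {
  p <- fixture_release()
  raw <- params_to_raw(p)          # numeric, already internal
  p2 <- normalize_units(c(as.list(raw), list(mode = "release")))
  expect_equal(flatten_params_list(p2), flatten_params_list(p))

  expect_error(
    normalize_units(list(V_t = "7 furlongs", mode = "release")),
    "unknown unit tag.*V_t")
  expect_error(
    normalize_units(list(V_t = "7e-3 mL", mode = "release")),
    "missing required key")
  bad <- c(as.list(raw), list(Nonsense = 1, mode = "release"))
  expect_error(normalize_units(bad), "unrecognized parameter key")
})

test_that("rendering back to printed units reproduces the reference table", {
  printed <- params_as_printed(fixture_release())
  get <- function(k) printed$value[printed$key == k]
  expect_equal(signif(get("V_Vit"), 4), 1.7)
  expect_equal(signif(get("V_t"), 4), 7e-3)
  expect_equal(signif(get("Q_Aq"), 4), 4.2)        # uL/min
  expect_equal(signif(get("Q_UvSc"), 4), 0.176)    # uL/min
  expect_equal(signif(get("Q_Drain"), 4), 0.5)
  expect_equal(signif(get("Clearance_ScCh"), 4), 1)  # mL/min
  expect_equal(signif(get("P_Conj"), 4), 2.5e-6)   # cm/s
  expect_equal(signif(get("K_ScCh"), 4), 15)
  expect_equal(signif(get("F"), 4), 2.08)          # percent
})

test_that("reference parameter set has the literature values", {
  p <- fixture_release()
  expect_identical(p$anatomy$V_Vit, 1.7)
  expect_identical(p$anatomy$V_ScCh, 0.361)
  expect_identical(p$anatomy$V_Ret, 0.086)
  expect_identical(p$anatomy$A_Globe, 8.6)
  expect_identical(p$drug$K_ScCh, 15)
  expect_identical(p$drug$K_Ret, 10)
  expect_identical(p$drug$P_Conj, 2.5e-6)
  expect_identical(p$drug$P_ScCh_Ret, 1e-5)
  # ILM permeability is 30% above the RPE permeability
  expect_equal(p$drug$P_Ret_Vit, ilm_permeability(p$drug$P_ScCh_Ret))
  expect_equal(p$drug$P_Ret_Vit, 13e-6)
  # bit-identical across calls
  expect_identical(fixture_release(), fixture_release())
})

test_that("validation distinguishes fatal errors from warnings", {
  p <- fixture_release()
  expect_identical(nrow(validate_params(p)), 0L)

  p_bad <- p
  p_bad$anatomy$V_Aq <- -1
  d <- validate_params(p_bad)
  expect_true(any(d$severity == "fatal" & d$key == "V_Aq"))
  expect_error(simulate_eye(p_bad), "V_Aq")

  p_warn <- p
  p_warn$physiology$Q_UvSc <- 2 * p$physiology$Q_Aq
  d <- validate_params(p_warn)
  expect_true(all(d$severity == "warning"))
  expect_true(any(d$key == "Q_UvSc"))

  p_frac <- p
  p_frac$drug$F <- 1.5
  expect_true(any(validate_params(p_frac)$severity == "fatal"))
})

test_that("mode constraints are enforced at construction", {
  p <- fixture_release()
  expect_error(
    ocular_params(p$anatomy, p$physiology, p$drug, mode = "release"),
    "release fit")
  drug_no_f <- p$drug
  drug_no_f$F <- NA_real_
  expect_error(
    ocular_params(p$anatomy, p$physiology, drug_no_f,
                  release = p$release, mode = "release"),
    "F")
  expect_error(
    ocular_params(p$anatomy, p$physiology, p$drug, mode = "diffusion"),
    "lens")
})
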