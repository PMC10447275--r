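#' Model parameter bundle
#'
#' Container for the full set of anatomical, physiological, drug-specific,
#' lens-specific and numerical settings of the ocular pharmacokinetic model,
#' in the internal unit system {cm, mL, s, ng}. Two source modes exist:
#'
#' * `"diffusion"`: the lens is an explicit one-dimensional diffusion domain
#'   (thickness `H`, diffusivity `D_SCL`, uniform initial loading `C0_SCL`,
#'   partition coefficient `K_SCL`), coupled to the tears at its anterior
#'   face and to the aqueous humor across the corneal epithelium at its
#'   posterior face.
#' * `"release"`: the lens is replaced by an empirical exponential release
#'   rate R(t) fitted to in vitro data; a fraction `F` of the released drug
#'   enters the aqueous humor and `1 - F` enters the tears.
#'
#' @param anatomy named list of volumes (mL) and areas (cm^2): `V_t`,
#'   `V_Vit`, `V_ScCh`, `V_Ret`, `V_Aq`, `A_Globe`, `A_Palp`, `A_Bulb`, and
#'   (diffusion mode) `A_Cornea`, `A_SCL`.
#' @param physiology named list of flows (mL/s): `Q_UvSc`, `Q_Vit_Aq`,
#'   `Q_Aq`, `Q_Drain`, `Clearance_ScCh`.
#' @param drug named list of partition coefficients `K_*` (dimensionless),
#'   permeabilities `P_*` (cm/s) and aqueous bioavailability `F` (fraction).
#' @param lens named list `H` (cm), `D_SCL` (cm^2/s), `C0_SCL` (ng/mL),
#'   `n_nodes` (integer); required in diffusion mode, NULL otherwise.
#' @param release a [release_fit] object; required in release mode.
#' @param mode `"diffusion"` or `"release"`.
#' @param solver named list `t_end`, `output_step` (s), `rel_tol`, `abs_tol`,
#'   `seed`.
#' @return object of class `ocular_params`.
#' @export
ocular_params <- function(anatomy, physiology, drug, lens = NULL,
                          release = NULL,
                          mode = c("diffusion", "release"),
                          solver = list()) {
  mode <- match.arg(mode)
  solver <- utils::modifyList(
    list(t_end = 604800, output_step = 600, rel_tol = 1e-8,
         abs_tol = 1e-12, seed = 1L),
    solver)
  if (mode == "diffusion") {
    if (is.null(lens) || is.null(drug$K_SCL) || is.na(drug$K_SCL)) {
      stop("diffusion mode requires lens parameters and K_SCL",
           call. = FALSE)
    }
    if (is.null(lens$n_nodes)) lens$n_nodes <- 50L
    lens$n_nodes <- as.integer(lens$n_nodes)
  } else {
    if (is.null(release)) {
      stop("release mode requires a release fit (M_Released, T)",
           call. = FALSE)
    }
    if (is.null(drug$F) || is.na(drug$F)) {
      stop("release mode requires the aqueous bioavailability F",
           call. = FALSE)
    }
    lens <- NULL
  }
  structure(
    list(anatomy = anatomy, physiology = physiology, drug = drug,
         lens = lens, release = release, mode = mode, solver = solver),
    class = "ocular_params")
}

#' @export
print.ocular_params <- function(x, ...) {
  cat("<ocular_params> mode =", x$mode, "\n")
  flat <- flatten_params(x)
  cat("  anatomy:   ",
      paste(names(x$anatomy), signif(unlist(x$anatomy), 4),
            sep = "=", collapse = " "), "\n")
  cat("  physiology:",
      paste(names(x$physiology), signif(unlist(x$physiology), 4),
            sep = "=", collapse = " "), "\n")
  drg <- x$drug[!vapply(x$drug, function(v) is.null(v) || all(is.na(v)),
                        logical(1))]
  cat("  drug:      ",
      paste(names(drg), signif(unlist(drg), 4), sep = "=", collapse = " "),
      "\n")
  if (!is.null(x$lens)) {
    cat("  lens:      ",
        paste(names(x$lens), signif(unlist(x$lens), 4), sep = "=",
              collapse = " "), "\n")
  }
  if (!is.null(x$release)) {
    cat("  release:    M_Released=", signif(x$release$M_Released, 4),
        " ng, T=", signif(x$release$T, 4), " s\n", sep = "")
  }
  cat("  solver:     t_end=", x$solver$t_end, "s output_step=",
      x$solver$output_step, "s rel_tol=", x$solver$rel_tol,
      " abs_tol=", x$solver$abs_tol, "\n")
  invisible(x)
}

#' Inner-limiting-membrane permeability from the RPE permeability
#'
#' The permeability of the inner limiting membrane (retina-vitreous barrier)
#' is taken 30% higher than the permeability of the retinal pigment
#' epithelium (sclera-choroid to retina barrier).
#'
#' @param P_ScCh_Ret RPE permeability (cm/s).
#' @return inner-limiting-membrane permeability `P_Ret_Vit` (cm/s).
#' @export
#' @examples
#' ilm_permeability(10e-6)  # 13e-6 cm/s
ilm_permeability <- function(P_ScCh_Ret) {
  stopifnot(is.numeric(P_ScCh_Ret), all(P_ScCh_Ret >= 0))
  1.3 * P_ScCh_Ret
}

#' Rabbit / dexamethasone parameter set
#'
#' The reference parameterization for dexamethasone delivery from a soft
#' contact lens to the rabbit eye: rabbit anatomy (tear, aqueous, vitreous,
#' retina and sclera-choroid volumes; globe, palpebral and bulbar
#' conjunctival areas), rabbit physiology (aqueous turnover, uveoscleral and
#' vitreous-aqueous flows, tear drainage, choroidal clearance) and
#' dexamethasone tissue partition coefficients and barrier permeabilities,
#' with `P_Ret_Vit = ` [ilm_permeability]`(P_ScCh_Ret)` and aqueous
#' bioavailability F = 2.08%.
#'
#' Quantities the literature set does not fix are package defaults flagged
#' in the vignette: corneal and lens areas (`A_Cornea` = 2.0 cm^2,
#' `A_SCL` = 2.27 cm^2), the in vitro release fit of the reference lens
#' (`M_Released` = 2e5 ng, `T` = 2 days, illustrative of week-scale
#' sustained release), and in diffusion mode the lens transport set
#' (`H` = 0.01 cm, `D_SCL` = 2e-10 cm^2/s, `C0_SCL` = 4.4e6 ng/mL,
#' `K_SCL` = 20) and corneal permeability `P_t_Aq` = 5e-6 cm/s. The
#' epithelium partition coefficients `K_Ep_Aq`, `K_Ep_t` have no published
#' values and default to `NA`, so the epithelium series is reported as
#' missing.
#'
#' @param mode `"release"` (the validation configuration, default) or
#'   `"diffusion"`.
#' @return an `ocular_params` object, bit-identical across calls.
#' @export
rabbit_dexamethasone_params <- function(mode = c("release", "diffusion")) {
  mode <- match.arg(mode)
  raw <- list(
    # anatomy (rabbit)
    V_t = "7e-3 mL", V_Vit = "1.7 mL", V_ScCh = "0.361 mL",
    V_Ret = "0.086 mL", V_Aq = "0.325 mL",
    A_Globe = "8.6 cm2", A_Palp = "14 cm2", A_Bulb = "3 cm2",
    # not fixed by the rabbit literature set; package defaults
    A_Cornea = "2.0 cm2", A_SCL = "2.27 cm2",
    # physiology (rabbit)
    Q_UvSc = "0.176 uL/min", Q_Vit_Aq = "0.19 uL/min",
    Q_Aq = "4.2 uL/min", Q_Drain = "0.5 uL/min",
    Clearance_ScCh = "1 mL/min",
    # drug (dexamethasone)
    K_t = 1, K_Aq = 1, K_Vit = 1, K_ScCh = 15, K_Ret = 10,
    P_Conj = "2.5e-6 cm/s", P_ScCh_Ret = "10e-6 cm/s",
    F = "2.08 %",
    mode = mode)
  raw$P_Ret_Vit <- ilm_permeability(.parse_quantity("P_ScCh_Ret",
                                                    raw$P_ScCh_Ret))
  if (mode == "release") {
    raw$M_Released <- "2e5 ng"
    raw$T <- "2 day"
  } else {
    raw$H <- "0.01 cm"
    raw$D_SCL <- "2e-10 cm2/s"
    raw$C0_SCL <- "4.4e6 ng/mL"
    raw$n_nodes <- 50
    raw$K_SCL <- 20
    raw$P_t_Aq <- "5e-6 cm/s"  # within the reported ex vivo corneal range
  }
  p <- normalize_units(raw)
  # epithelium partition coefficients are not published for dexamethasone
  p$drug$K_Ep_Aq <- NA_real_
  p$drug$K_Ep_t <- NA_real_
  p
}

.diag_row <- function(severity, key, message) {
  data.frame(severity = severity, key = key, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks sign constraints, range constraints and physiological plausibility.
#' Returns a data.frame of diagnostics with columns `severity`
#' (`"fatal"` / `"warning"`), `key` and `message`; a clean set yields a
#' zero-row frame. Plausibility checks (e.g. `Q_UvSc <= Q_Aq`,
#' `A_SCL >= A_Cornea`, `V_t < V_Aq < V_Vit`) only warn.
#'
#' @param params an `ocular_params` object (unit-normalized).
#' @return data.frame of diagnostics (zero rows if clean).
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "ocular_params"))
  d <- list()
  an <- params$anatomy
  ph <- params$physiology
  dr <- params$drug

  for (key in names(an)) {
    v <- an[[key]]
    if (!is.na(v) && v <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", key,
        paste0(key, " must be strictly positive, got ", v))
    }
  }
  for (key in names(ph)) {
    v <- ph[[key]]
    if (!is.na(v) && v < 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", key,
        paste0(key, " must be non-negative, got ", v))
    }
  }
  for (key in grep("^K_", names(dr), value = TRUE)) {
    v <- dr[[key]]
    if (!is.null(v) && !is.na(v) && v <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", key,
        paste0("partition coefficient ", key, " must be > 0, got ", v))
    }
  }
  for (key in grep("^P_", names(dr), value = TRUE)) {
    v <- dr[[key]]
    if (!is.null(v) && !is.na(v) && v < 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", key,
        paste0("permeability ", key, " must be >= 0, got ", v))
    }
  }
  if (!is.null(dr$F) && !is.na(dr$F) && (dr$F < 0 || dr$F > 1)) {
    d[[length(d) + 1L]] <- .diag_row("fatal", "F",
      paste0("bioavailability F must lie in [0, 1], got ", dr$F))
  }
  if (params$mode == "diffusion") {
    ln <- params$lens
    if (ln$H <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", "H", "lens thickness H must be > 0")
    }
    if (ln$D_SCL <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", "D_SCL", "lens diffusivity D_SCL must be > 0")
    }
    if (ln$n_nodes < 3L) {
      d[[length(d) + 1L]] <- .diag_row("fatal", "n_nodes", "n_nodes must be >= 3")
    }
    if (!is.null(ln$C0_SCL) && ln$C0_SCL < 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", "C0_SCL", "initial lens loading must be >= 0")
    }
  } else {
    rl <- params$release
    if (rl$M_Released <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", "M_Released", "M_Released must be > 0")
    }
    if (rl$T <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", "T", "release time constant T must be > 0")
    }
  }
  sv <- params$solver
  for (key in c("t_end", "output_step", "rel_tol", "abs_tol")) {
    if (sv[[key]] <= 0) {
      d[[length(d) + 1L]] <- .diag_row("fatal", key,
        paste0("solver setting ", key, " must be > 0"))
    }
  }

  # plausibility (warn-only)
  if (!is.na(ph$Q_UvSc) && !is.na(ph$Q_Aq) && ph$Q_UvSc > ph$Q_Aq) {
    d[[length(d) + 1L]] <- .diag_row("warning", "Q_UvSc",
      "uveoscleral outflow Q_UvSc exceeds total aqueous turnover Q_Aq")
  }
  if (!is.null(an$A_SCL) && !is.null(an$A_Cornea) &&
      !is.na(an$A_SCL) && !is.na(an$A_Cornea) &&
      an$A_SCL < an$A_Cornea) {
    d[[length(d) + 1L]] <- .diag_row("warning", "A_SCL",
      "lens area A_SCL is smaller than the corneal area A_Cornea")
  }
  if (all(!is.na(c(an$V_t, an$V_Aq, an$V_Vit))) &&
      !(an$V_t < an$V_Aq && an$V_Aq < an$V_Vit)) {
    d[[length(d) + 1L]] <- .diag_row("warning", "V_t",
      "expected V_t < V_Aq < V_Vit for a physiological eye")
  }
  if (length(d) == 0L) {
    return(data.frame(severity = character(0), key = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, d)
}

# stop if validate_params reports anything fatal
assert_valid_params <- function(params) {
  diags <- validate_params(params)
  fatal <- diags[diags$severity == "fatal", , drop = FALSE]
  if (nrow(fatal) > 0L) {
    stop("invalid parameters: ",
         paste(fatal$message, collapse = "; "), call. = FALSE)
  }
  invisible(params)
}

# set a named scalar parameter (searched across sub-lists), multiplicative
# scaling helper used by the sensitivity and uncertainty machinery
set_param <- function(params, name, value) {
  for (block in c("physiology", "drug", "anatomy", "lens")) {
    if (!is.null(params[[block]]) && name %in% names(params[[block]])) {
      params[[block]][[name]] <- value
      return(params)
    }
  }
  if (!is.null(params$release) && name %in% c("M_Released", "T")) {
    params$release[[name]] <- value
    return(params)
  }
  stop("unknown parameter: ", name, call. = FALSE)
}

get_param <- function(params, name) {
  for (block in c("physiology", "drug", "anatomy", "lens")) {
    if (!is.null(params[[block]]) && name %in% names(params[[block]])) {
      return(params[[block]][[name]])
    }
  }
  if (!is.null(params$release) && name %in% c("M_Released", "T")) {
    return(params$release[[name]])
  }
  stop("unknown parameter: ", name, call. = FALSE)
}
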