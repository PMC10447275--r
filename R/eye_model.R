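#' @title Compartmental eye model
#' @description Mass balances for the tears, sclera-choroid, retina,
#'   vitreous humor and aqueous humor, coupled either to the discretized
#'   lens diffusion domain (diffusion mode) or to the empirical exponential
#'   release rate (release mode). All balances are evaluated in the
#'   internal {cm, mL, s, ng} system; tissue densities are taken as 1 g/mL
#'   so ng/g and ng/mL coincide.
#' @name eye_model
NULL

.sink_names <- c("sink_drainage", "sink_palpebral", "sink_uveoscleral",
                 "sink_choroidal", "sink_aqueous")
.compartments <- c("C_t", "C_ScCh", "C_Ret", "C_Vit", "C_Aq")

# Shared compartmental balance. src_t / src_aq are the tears and aqueous
# source rates (ng/s): lens fluxes in diffusion mode, the (1-F)R / F R
# split in release mode. Returns concentration derivatives and sink rates.
# The aqueous renovation sink logs (Q_Aq - Q_UvSc) C_Aq because Q_Aq is the
# total turnover and the Q_UvSc share re-enters the sclera-choroid.
.compartment_derivs <- function(C_t, C_ScCh, C_Ret, C_Vit, C_Aq,
                                src_t, src_aq, cn) {
  bulbar <- cn$P_Conj * cn$A_Bulb * (C_t / cn$K_t - C_ScCh / cn$K_ScCh)
  rpe <- cn$A_Globe * cn$P_ScCh_Ret *
    (C_ScCh / cn$K_ScCh - C_Ret / cn$K_Ret)
  ilm <- cn$A_Globe * cn$P_Ret_Vit * (C_Ret / cn$K_Ret - C_Vit / cn$K_Vit)

  r_drain <- cn$Q_Drain * C_t
  r_palp <- cn$P_Conj * cn$A_Palp * C_t
  r_uvsc_out <- cn$Q_UvSc * C_ScCh / cn$K_ScCh
  r_chor <- cn$Clearance_ScCh * C_ScCh
  r_aq <- (cn$Q_Aq - cn$Q_UvSc) * C_Aq

  list(
    dC = c(
      C_t = (src_t - r_drain - r_palp - bulbar) / cn$V_t,
      C_ScCh = (cn$Q_UvSc * C_Aq - r_uvsc_out + bulbar - r_chor - rpe) /
        cn$V_ScCh,
      C_Ret = (rpe - ilm) / cn$V_Ret,
      C_Vit = (ilm - cn$Q_Vit_Aq * C_Vit) / cn$V_Vit,
      C_Aq = (cn$Q_Vit_Aq * C_Vit + src_aq - cn$Q_Aq * C_Aq) / cn$V_Aq),
    sink_rates = c(sink_drainage = r_drain, sink_palpebral = r_palp,
                   sink_uveoscleral = r_uvsc_out, sink_choroidal = r_chor,
                   sink_aqueous = r_aq))
}

# constants bundle used by the right-hand sides
.model_constants <- function(params) {
  c(params$anatomy, params$physiology, params$drug)
}

#' Release-mode right-hand side
#'
#' Time derivatives of the five tissue concentrations when the lens is
#' represented by the fitted exponential release rate R(t): the tears
#' receive `(1 - F) R(t)` and the aqueous humor receives `F R(t)`; all
#' other transport terms are identical to diffusion mode.
#'
#' @param state named numeric vector with entries `C_t`, `C_ScCh`, `C_Ret`,
#'   `C_Vit`, `C_Aq` (ng/mL).
#' @param t time (s).
#' @param params release-mode `ocular_params`.
#' @return list with `dC` (named concentration derivatives, ng/mL/s) and
#'   `sink_rates` (named removal rates, ng/s).
#' @export
rhs_release <- function(state, t, params) {
  if (params$mode != "release") {
    stop("rhs_release requires release-mode parameters", call. = FALSE)
  }
  R <- release_rate(t, params$release)
  F_aq <- params$drug$F
  .compartment_derivs(state[["C_t"]], state[["C_ScCh"]], state[["C_Ret"]],
                      state[["C_Vit"]], state[["C_Aq"]],
                      src_t = (1 - F_aq) * R, src_aq = F_aq * R,
                      cn = .model_constants(params))
}

#' Diffusion-mode right-hand side
#'
#' Time derivatives of the five tissue concentrations when the lens is an
#' explicit diffusion domain: the tears receive the anterior-face flux
#' ([front_flux]) and the aqueous humor the trans-corneal posterior-face
#' flux ([back_flux]).
#'
#' @param state named numeric vector with entries `C_t`, `C_ScCh`, `C_Ret`,
#'   `C_Vit`, `C_Aq` (ng/mL).
#' @param profile a [lens_profile] giving the current lens state.
#' @param params diffusion-mode `ocular_params`.
#' @return list with `dC`, `sink_rates`, `lens` (the [lens_rhs] output) and
#'   `front_flux` (ng/s).
#' @export
rhs_diffusion <- function(state, profile, params) {
  if (params$mode != "diffusion") {
    stop("rhs_diffusion requires diffusion-mode parameters", call. = FALSE)
  }
  lrhs <- lens_rhs(profile, state[["C_t"]], state[["C_Aq"]], params)
  prof2 <- profile
  prof2$C_SCL[1] <- lrhs$C_anterior
  ff <- front_flux(prof2, params)
  out <- .compartment_derivs(state[["C_t"]], state[["C_ScCh"]],
                             state[["C_Ret"]], state[["C_Vit"]],
                             state[["C_Aq"]],
                             src_t = ff, src_aq = lrhs$back_flux,
                             cn = .model_constants(params))
  out$lens <- lrhs
  out$front_flux <- ff
  out
}

#' Corneal epithelium concentration
#'
#' The epithelium is assumed to vary linearly across its thickness, in
#' equilibrium with the tears on one side and the aqueous humor on the
#' other: `C_Ep = (K_Ep_Aq * C_Aq + K_Ep_t * C_t) / 2`. Purely diagnostic;
#' it feeds back into no balance. If either partition coefficient is
#' missing the result is `NA`.
#'
#' @param C_Aq aqueous humor concentration (ng/mL), vectorized.
#' @param C_t tears concentration (ng/mL), vectorized.
#' @param params `ocular_params` supplying `K_Ep_Aq` and `K_Ep_t`.
#' @return epithelium concentration (ng/g).
#' @export
epithelium_concentration <- function(C_Aq, C_t, params) {
  k_aq <- params$drug$K_Ep_Aq
  k_t <- params$drug$K_Ep_t
  if (is.null(k_aq) || is.null(k_t) || is.na(k_aq) || is.na(k_t)) {
    return(rep(NA_real_, length(C_Aq)))
  }
  (k_aq * C_Aq + k_t * C_t) / 2
}

#' Simulate the coupled eye model
#'
#' Adaptive stiff integration (lsoda) of the selected mode's right-hand
#' side from `t = 0` (all tissues drug-free; in diffusion mode the lens is
#' uniformly loaded at `C0_SCL`) to `t_end`, with dense output every
#' `output_step`. Cumulative sink masses are integrated alongside the
#' concentrations for mass accounting; in diffusion mode the cumulative
#' anterior and posterior lens fluxes and the residual lens mass are also
#' reported. Deterministic for fixed parameters.
#'
#' @param params validated `ocular_params`.
#' @param t_end,output_step optional overrides of the solver settings (s).
#' @return an `eye_trajectory`: a data.frame with columns `time_s`, the five
#'   compartment concentrations, `C_Ep` (NA when the epithelium partition
#'   coefficients are absent), the five `sink_*` cumulative masses and, in
#'   diffusion mode, `lens_mass`, `cum_front_flux`, `cum_back_flux`;
#'   the generating parameters are attached as attribute `params`.
#' @export
simulate_eye <- function(params, t_end = NULL, output_step = NULL) {
  assert_valid_params(params)
  if (!is.null(t_end)) params$solver$t_end <- t_end
  if (!is.null(output_step)) params$solver$output_step <- output_step
  sv <- params$solver
  times <- seq(0, sv$t_end, by = sv$output_step)
  if (times[length(times)] < sv$t_end) times <- c(times, sv$t_end)
  cn <- .model_constants(params)

  if (params$mode == "release") {
    M <- params$release$M_Released
    Tc <- params$release$T
    F_aq <- params$drug$F
    rhs <- function(t, y, parms) {
      R <- (M / Tc) * exp(-t / Tc)
      d <- .compartment_derivs(y[1], y[2], y[3], y[4], y[5],
                               src_t = (1 - F_aq) * R, src_aq = F_aq * R,
                               cn = cn)
      list(c(d$dC, d$sink_rates))
    }
    y0 <- stats::setNames(numeric(10L), c(.compartments, .sink_names))
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = sv$rel_tol,
                        atol = sv$abs_tol)
    .check_integration(sol, sv)
    out <- as.data.frame(sol)
    names(out)[1] <- "time_s"
  } else {
    g <- lens_grid(params$lens$H, params$lens$n_nodes)
    n <- g$n_nodes
    dy <- g$dy
    D <- params$lens$D_SCL
    K_SCL <- params$drug$K_SCL
    A_SCL <- params$anatomy$A_SCL
    A_P <- params$anatomy$A_Cornea * params$drug$P_t_Aq
    n_lens <- n - 1L  # nodes 2..n; anterior node slaved to K_SCL * C_t
    # face half-cell in tears equilibrium acts as added tears capacitance;
    # accounting it keeps the discrete mass budget exact (see vignette)
    cap <- A_SCL * dy * K_SCL / 2
    V_t <- params$anatomy$V_t
    rhs <- function(t, y, parms) {
      Cl_int <- y[seq_len(n_lens)]
      yc <- y[n_lens + 1:5]
      C <- c(K_SCL * yc[1], Cl_int)
      J_back <- A_P * (C[n] / K_SCL - yc[5])
      dC_lens <- numeric(n_lens)
      if (n > 3L) {
        idx <- 2:(n - 1L)
        dC_lens[idx - 1L] <- D * (C[idx + 1L] - 2 * C[idx] + C[idx - 1L]) /
          dy^2
      }
      C_ghost <- C[n - 1L] - 2 * dy * J_back / (A_SCL * D)
      dC_lens[n_lens] <- D * (C_ghost - 2 * C[n] + C[n - 1L]) / dy^2
      ff <- D * A_SCL * (C[2] - C[1]) / dy
      d <- .compartment_derivs(yc[1], yc[2], yc[3], yc[4], yc[5],
                               src_t = ff, src_aq = J_back, cn = cn)
      dCt <- d$dC[["C_t"]] * V_t / (V_t + cap)
      d$dC[["C_t"]] <- dCt
      list(c(dC_lens, d$dC, d$sink_rates, ff - cap * dCt, J_back))
    }
    y0 <- c(rep(params$lens$C0_SCL, n_lens), numeric(12L))
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = sv$rel_tol,
                        atol = sv$abs_tol)
    .check_integration(sol, sv)
    lens_nodes <- sol[, 1L + seq_len(n_lens), drop = FALSE]
    comp <- sol[, 1L + n_lens + 1:12, drop = FALSE]
    colnames(comp) <- c(.compartments, .sink_names,
                        "cum_front_flux", "cum_back_flux")
    out <- data.frame(time_s = sol[, 1], comp, check.names = FALSE)
    # reconstruct the full profile (anterior node from the tears boundary)
    profiles <- cbind(K_SCL * out$C_t, lens_nodes)
    out$lens_mass <- A_SCL * dy *
      (rowSums(profiles) - (profiles[, 1] + profiles[, n]) / 2)
    attr(out, "lens_profiles") <- unname(profiles)
    attr(out, "lens_grid") <- g
  }

  out$C_Ep <- epithelium_concentration(out$C_Aq, out$C_t, params)
  neg <- min(vapply(out[.compartments], min, numeric(1)))
  if (neg < -10 * sv$abs_tol) {
    warning("negative concentration (", signif(neg, 3),
            " ng/mL) beyond -10 * abs_tol; tolerances may be ",
            "misconfigured", call. = FALSE)
  }
  attr(out, "params") <- params
  attr(out, "mode") <- params$mode
  class(out) <- c("eye_trajectory", "data.frame")
  out
}

.check_integration <- function(sol, sv) {
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    t_last <- sol[nrow(sol), 1]
    stop("stiff integration failed near t = ", signif(t_last, 6),
         " s (istate = ", istate, "); consider loosening tolerances",
         call. = FALSE)
  }
  if (anyNA(sol)) {
    stop("integration produced NA values", call. = FALSE)
  }
  invisible(sol)
}

#' @export
print.eye_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat("<eye_trajectory> mode =", attr(x, "mode"), "|", nrow(x),
      "output times over", x$time_s[nrow(x)], "s\n")
  peaks <- vapply(.compartments, function(cc) max(x[[cc]]), numeric(1))
  cat("  peak concentrations (ng/mL):",
      paste(.compartments, signif(peaks, 4), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
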