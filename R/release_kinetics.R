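#' Exponential release fit object
#'
#' First-order (single-exponential) cumulative release model
#' `f(t) = M_Released * (1 - exp(-t / T))`, with release rate
#' `R(t) = df/dt = (M_Released / T) * exp(-t / T)`.
#'
#' @param M_Released total releasable drug mass (ng), > 0.
#' @param T release time constant (s), > 0.
#' @param residual_norm residual norm of the fit (ng), if fitted.
#' @param n_points number of data points used, if fitted.
#' @return object of class `release_fit`.
#' @export
release_fit <- function(M_Released, T, residual_norm = NA_real_,
                        n_points = NA_integer_) {
  stopifnot(is.numeric(M_Released), length(M_Released) == 1L,
            is.numeric(T), length(T) == 1L)
  if (!is.na(M_Released) && M_Released <= 0) {
    stop("M_Released must be > 0", call. = FALSE)
  }
  if (!is.na(T) && T <= 0) {
    stop("release time constant T must be > 0", call. = FALSE)
  }
  structure(list(M_Released = M_Released, T = T,
                 residual_norm = residual_norm,
                 n_points = as.integer(n_points)),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat("<release_fit> f(t) = M * (1 - exp(-t/T))\n")
  cat(sprintf("  M_Released = %.6g ng\n  T          = %.6g s\n",
              x$M_Released, x$T))
  if (!is.na(x$residual_norm)) {
    cat(sprintf("  residual norm = %.4g ng on %d points\n",
                x$residual_norm, x$n_points))
  }
  invisible(x)
}

#' In vitro cumulative release dataset
#'
#' @param times sampling times (s), non-negative, strictly increasing.
#' @param cumulative_released cumulative released mass (ng).
#' @param uncertainty optional per-point uncertainty (ng) used to tolerate
#'   small non-monotonicities from measurement noise.
#' @return object of class `release_dataset` (a data.frame).
#' @export
release_dataset <- function(times, cumulative_released,
                            uncertainty = NULL) {
  stopifnot(length(times) == length(cumulative_released))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  # tolerate noise-level non-monotonicity: a drop larger than 3 combined
  # standard uncertainties of the two points is flagged
  tol <- if (is.null(uncertainty)) rep(0, length(times)) else uncertainty
  drops <- diff(cumulative_released)
  lim <- 3 * sqrt(utils::head(tol, -1)^2 + utils::tail(tol, -1)^2)
  bad <- drops < -(lim + sqrt(.Machine$double.eps))
  if (any(bad)) {
    warning("cumulative release decreases beyond stated uncertainty at ",
            sum(bad), " interval(s)", call. = FALSE)
  }
  out <- data.frame(time_s = times, cumulative_ng = cumulative_released)
  if (!is.null(uncertainty)) out$uncertainty_ng <- uncertainty
  class(out) <- c("release_dataset", "data.frame")
  out
}

#' Aqueous humor concentration-time dataset
#'
#' @param times sampling times (s), non-negative, strictly increasing.
#' @param C_Aq aqueous humor concentrations (ng/mL).
#' @param uncertainty optional per-point uncertainty (ng/mL).
#' @return object of class `aqueous_dataset` (a data.frame).
#' @export
aqueous_dataset <- function(times, C_Aq, uncertainty = NULL) {
  stopifnot(length(times) == length(C_Aq))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(time_s = times, C_Aq_ng_mL = C_Aq)
  if (!is.null(uncertainty)) out$uncertainty_ng_mL <- uncertainty
  class(out) <- c("aqueous_dataset", "data.frame")
  out
}

#' Fit the exponential release model to cumulative in vitro data
#'
#' Nonlinear least squares of `f(t) = M * (1 - exp(-t/T))` on the cumulative
#' release curve. Initialization is deterministic and scale-free:
#' `M0 = max(cumulative)`, `T0` = time at which the curve first reaches
#' 63.2% of `M0`, by linear interpolation.
#'
#' @param data a [release_dataset] (or data.frame with columns `time_s`,
#'   `cumulative_ng`).
#' @return a [release_fit] with residual norm and point count.
#' @export
#' @examples
#' t <- seq(0, 4 * 3600, length.out = 10)
#' d <- release_dataset(t, 500 * (1 - exp(-t / 3600)))
#' fit_exponential_release(d)  # recovers M = 500 ng, T = 3600 s
fit_exponential_release <- function(data) {
  times <- data$time_s
  y <- data$cumulative_ng
  if (length(times) < 3L) {
    stop("need at least 3 data points", call. = FALSE)
  }
  if (all(y <= 0)) {
    stop("no release signal: all cumulative values are zero", call. = FALSE)
  }
  if (!any(times > 0 & y > 0)) {
    stop("no release signal at positive time", call. = FALSE)
  }
  M0 <- max(y)
  target <- (1 - exp(-1)) * M0
  T0 <- if (any(y >= target & times > 0)) {
    stats::approx(y, times, xout = target, ties = "ordered")$y
  } else {
    max(times[y > 0])
  }
  if (!is.finite(T0) || T0 <= 0) T0 <- max(times) / 3
  df <- data.frame(t = times, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ M * (1 - exp(-t / Tc)), data = df,
      start = list(M = M0, Tc = T0),
      lower = c(M = .Machine$double.xmin, Tc = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) {
      stop("release fit did not converge (last start M=", signif(M0, 6),
           ", T=", signif(T0, 6), "): ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  release_fit(M_Released = unname(cf["M"]), T = unname(cf["Tc"]),
              residual_norm = sqrt(sum(stats::resid(fit)^2)),
              n_points = length(times))
}

#' Instantaneous release rate of the exponential model
#'
#' `R(t) = (M_Released / T) * exp(-t / T)`; integrates to `M_Released`
#' over `[0, Inf)`.
#'
#' @param t time (s), `>= 0` (vectorized).
#' @param fit a [release_fit].
#' @return release rate (ng/s).
#' @export
release_rate <- function(t, fit) {
  stopifnot(inherits(fit, "release_fit"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  (fit$M_Released / fit$T) * exp(-t / fit$T)
}

#' Aqueous bioavailability from in vivo aqueous concentrations
#'
#' Computes the fraction F of the released dose that reached the aqueous
#' humor, `F = Q_Aq * AUC(C_Aq) / M_Released`. The AUC is obtained by
#' fitting a single exponential decay `C_Aq(t) = C0 * exp(-t / tau)` to the
#' data and integrating its closed form to infinity (i.e. down to zero
#' concentration), `AUC = C0 * tau`.
#'
#' @param aq an [aqueous_dataset] (or data.frame with columns `time_s`,
#'   `C_Aq_ng_mL`).
#' @param Q_Aq aqueous humor renovation rate (mL/s), > 0.
#' @param M_Released total released mass (ng), > 0.
#' @return bioavailability as a fraction in `[0, 1]` (a warning is raised if
#'   it exceeds 1), with attributes `C0`, `tau` and `AUC` describing the
#'   fitted exponential.
#' @export
compute_bioavailability <- function(aq, Q_Aq, M_Released) {
  stopifnot(is.numeric(Q_Aq), Q_Aq > 0, is.numeric(M_Released),
            M_Released > 0)
  times <- aq$time_s
  y <- aq$C_Aq_ng_mL
  if (length(times) < 3L) {
    stop("need at least 3 data points", call. = FALSE)
  }
  if (all(y == 0)) {
    out <- 0
    attr(out, "C0") <- 0
    attr(out, "tau") <- NA_real_
    attr(out, "AUC") <- 0
    return(out)
  }
  C0_init <- max(y)
  # crude log-linear slope for the initialization; a non-decaying series
  # has no positive decay constant and cannot be integrated to zero
  pos <- y > 0
  sl <- if (sum(pos) >= 2L) {
    unname(stats::coef(stats::lm(log(y[pos]) ~ times[pos]))[2])
  } else {
    NA_real_
  }
  if (is.finite(sl) && sl >= 0) {
    stop("fitted decay time constant is not positive; cannot integrate ",
         "to zero concentration", call. = FALSE)
  }
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else
    diff(range(times)) / 2
  df <- data.frame(t = times, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ C0 * exp(-t / tau), data = df,
      start = list(C0 = C0_init, tau = tau0),
      lower = c(C0 = 0, tau = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) {
      stop("aqueous exponential fit did not converge: ",
           conditionMessage(e), call. = FALSE)
    })
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  C0 <- unname(cf["C0"])
  if (!is.finite(tau) || tau <= 0) {
    stop("fitted decay time constant is not positive; cannot integrate to ",
         "zero concentration", call. = FALSE)
  }
  auc <- C0 * tau
  F_val <- Q_Aq * auc / M_Released
  if (F_val > 1) {
    warning("computed bioavailability exceeds 1; inputs are inconsistent",
            call. = FALSE)
  }
  out <- F_val
  attr(out, "C0") <- C0
  attr(out, "tau") <- tau
  attr(out, "AUC") <- auc
  out
}
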