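#' Exposure metrics of a trajectory
#'
#' AUC by trapezoidal quadrature over the full output grid, plus the grid
#' maximum concentration and its time, for each compartment (and the
#' epithelium series when present).
#'
#' @param traj an `eye_trajectory`.
#' @return data.frame with columns `compartment`, `auc` (ng s/mL), `cmax`
#'   (ng/mL), `t_cmax` (s).
#' @export
compute_metrics <- function(traj) {
  stopifnot(nrow(traj) > 0L)
  tt <- traj$time_s
  series <- .compartments
  if ("C_Ep" %in% names(traj) && !all(is.na(traj$C_Ep))) {
    series <- c(series, "C_Ep")
  }
  rows <- lapply(series, function(cc) {
    y <- traj[[cc]]
    i <- which.max(y)
    data.frame(compartment = cc, auc = .trapz(tt, y), cmax = y[i],
               t_cmax = tt[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Mass-balance residual of a trajectory
#'
#' Audits conservation at the final output time:
#' `|stored + removed - delivered| / delivered`, where stored is the sum of
#' compartment concentration times volume, removed is the sum of the sink
#' accumulators, and delivered is the cumulative release `f(t_end)` in
#' release mode or the lens mass lost since `t = 0` in diffusion mode.
#'
#' @param traj an `eye_trajectory` carrying sink accumulators.
#' @param params the generating parameters; defaults to the trajectory's
#'   `params` attribute.
#' @return fraction of delivered mass unaccounted for.
#' @export
mass_balance_residual <- function(traj, params = attr(traj, "params")) {
  stopifnot(!is.null(params))
  last <- traj[nrow(traj), , drop = FALSE]
  an <- params$anatomy
  vols <- c(an$V_t, an$V_ScCh, an$V_Ret, an$V_Vit, an$V_Aq)
  stored <- sum(unlist(last[.compartments]) * vols)
  removed <- sum(unlist(last[.sink_names]))
  if (params$mode == "release") {
    delivered <- params$release$M_Released *
      (1 - exp(-last$time_s / params$release$T))
  } else {
    delivered <- traj$lens_mass[1] - last$lens_mass
  }
  if (delivered == 0) {
    return(if (stored + removed == 0) 0 else Inf)
  }
  abs(stored + removed - delivered) / delivered
}

#' Default parameter list for the one-at-a-time sensitivity analysis
#'
#' The barrier properties (permeabilities), physiological transport
#' pathways (flows and clearance), tissue partition coefficients and, in
#' release mode, the aqueous bioavailability F. Anatomical parameters are
#' held constant. Only parameters active in the given mode are listed
#' (e.g. `K_SCL` and `P_t_Aq` do not enter the release-mode equations).
#'
#' @param params an `ocular_params`.
#' @return character vector of parameter names.
#' @export
default_sensitivity_parameters <- function(params) {
  common <- c("Q_UvSc", "Q_Vit_Aq", "Q_Aq", "Q_Drain", "Clearance_ScCh",
              "K_t", "K_Vit", "K_ScCh", "K_Ret",
              "P_Conj", "P_ScCh_Ret", "P_Ret_Vit")
  if (params$mode == "release") {
    c(common, "F")
  } else {
    c(common, "K_SCL", "P_t_Aq", "D_SCL")
  }
}

#' One-at-a-time local sensitivity analysis
#'
#' For each listed parameter and each direction, reruns the simulation with
#' that single parameter scaled by `1 + perturbation` (respectively
#' `1 - perturbation`), recomputes the exposure metrics, and reports the
#' normalized coefficients `dAUC(%) / |dparam(%)|` and
#' `dCmax(%) / |dparam(%)|` per compartment. Anatomical parameters are
#' excluded from the default list.
#'
#' @param params baseline `ocular_params` (its simulation must succeed).
#' @param perturbation relative perturbation, default 0.10; must be nonzero.
#' @param parameters character vector of parameter names; defaults to
#'   [default_sensitivity_parameters()]. Names like `M_Released` or `T` may
#'   be added explicitly.
#' @return object of class `sensitivity_table`: a data.frame with columns
#'   `parameter`, `direction` (`"+10%"` style labels), `compartment`,
#'   `d_auc_pct_per_pct`, `d_cmax_pct_per_pct`, `failed`.
#' @export
local_sensitivity <- function(params, perturbation = 0.10,
                              parameters = NULL) {
  if (!is.numeric(perturbation) || perturbation == 0) {
    stop("perturbation must be nonzero (zero denominator)", call. = FALSE)
  }
  if (is.null(parameters)) {
    parameters <- default_sensitivity_parameters(params)
  }
  base_traj <- simulate_eye(params)
  base_m <- compute_metrics(base_traj)
  base_m <- base_m[base_m$compartment %in% .compartments, ]

  pct <- abs(perturbation) * 100
  rows <- list()
  for (pname in parameters) {
    for (sgn in c(+1, -1)) {
      label <- sprintf("%+g%%", sgn * pct)
      nominal <- get_param(params, pname)
      p2 <- set_param(params, pname, nominal * (1 + sgn * perturbation))
      m2 <- tryCatch({
        tr <- simulate_eye(p2)
        mm <- compute_metrics(tr)
        mm[mm$compartment %in% .compartments, ]
      }, error = function(e) NULL)
      if (is.null(m2)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pname, direction = label,
          compartment = base_m$compartment,
          d_auc_pct_per_pct = NA_real_, d_cmax_pct_per_pct = NA_real_,
          failed = TRUE, stringsAsFactors = FALSE)
        next
      }
      d_auc <- 100 * (m2$auc - base_m$auc) / base_m$auc / pct
      d_cmax <- 100 * (m2$cmax - base_m$cmax) / base_m$cmax / pct
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pname, direction = label,
        compartment = base_m$compartment,
        d_auc_pct_per_pct = d_auc, d_cmax_pct_per_pct = d_cmax,
        failed = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "perturbation") <- perturbation
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Rank parameters by sensitivity magnitude for one compartment
#'
#' Averages `|d_auc_pct_per_pct|` (or the Cmax analogue) over the two
#' perturbation directions and sorts decreasingly.
#'
#' @param sens a `sensitivity_table`.
#' @param compartment one of `"C_t"`, `"C_ScCh"`, `"C_Ret"`, `"C_Vit"`,
#'   `"C_Aq"`.
#' @param metric `"auc"` or `"cmax"`.
#' @return data.frame with columns `parameter`, `coefficient` (mean
#'   absolute normalized coefficient), sorted decreasingly.
#' @export
rank_sensitivity <- function(sens, compartment, metric = c("auc", "cmax")) {
  metric <- match.arg(metric)
  col <- if (metric == "auc") "d_auc_pct_per_pct" else "d_cmax_pct_per_pct"
  sub <- sens[sens$compartment == compartment & !sens$failed, ]
  agg <- stats::aggregate(abs(sub[[col]]),
                          by = list(parameter = sub$parameter), FUN = mean)
  names(agg)[2] <- "coefficient"
  agg[order(-agg$coefficient), , drop = FALSE]
}

#' Randomized-parameter uncertainty ensemble
#'
#' Runs `n_runs` simulations with every non-anatomical input parameter
#' drawn independently and uniformly from `[1 - range, 1 + range]` times
#' its nominal value (in release mode this includes `M_Released`, `T` and
#' `F`), and summarizes the per-compartment concentration series by their
#' pointwise envelope (min/max) and 2.5/50/97.5 percentiles, alongside the
#' nominal curve. Fully reproducible for a fixed seed; failed runs are
#' recorded and excluded.
#'
#' @param params baseline `ocular_params`.
#' @param n_runs number of randomized runs (default 400).
#' @param range relative half-width of the sampling box (default 0.10).
#' @param seed integer seed for the parameter draws.
#' @param parameters names of parameters to randomize; defaults to the
#'   sensitivity list plus, in release mode, `M_Released` and `T`.
#' @param keep_runs keep the full per-run concentration arrays.
#' @return object of class `uncertainty_ensemble`: list with `times`,
#'   `nominal` (matrix time x compartment), `summary` (list per compartment
#'   of matrices with columns `nominal`, `min`, `p2_5`, `p50`, `p97_5`,
#'   `max`), `n_runs`, `n_failed`, `seed`, and optionally `runs`.
#' @export
uncertainty_cloud <- function(params, n_runs = 400L, range = 0.10,
                              seed = params$solver$seed,
                              parameters = NULL, keep_runs = FALSE) {
  stopifnot(n_runs >= 1L, range >= 0)
  if (is.null(parameters)) {
    parameters <- default_sensitivity_parameters(params)
    if (params$mode == "release") {
      parameters <- c(parameters, "M_Released", "T")
    }
  }
  nominal_traj <- simulate_eye(params)
  times <- nominal_traj$time_s
  nominal <- as.matrix(nominal_traj[.compartments])

  # draw all factors up front so the ensemble is a pure function of seed
  factors <- .with_seed(seed, {
    matrix(stats::runif(n_runs * length(parameters), 1 - range, 1 + range),
           nrow = n_runs, ncol = length(parameters),
           dimnames = list(NULL, parameters))
  })

  runs <- vector("list", n_runs)
  failed <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    p_i <- params
    for (pname in parameters) {
      p_i <- set_param(p_i, pname,
                       get_param(params, pname) * factors[i, pname])
    }
    runs[[i]] <- tryCatch(
      as.matrix(simulate_eye(p_i)[.compartments]),
      error = function(e) NULL)
    failed[i] <- is.null(runs[[i]])
  }
  ok <- which(!failed)
  if (length(ok) == 0L) stop("all ensemble runs failed", call. = FALSE)

  summary <- lapply(.compartments, function(cc) {
    mat <- vapply(ok, function(i) runs[[i]][, cc], numeric(length(times)))
    qs <- apply(mat, 1L, stats::quantile,
                probs = c(0, 0.025, 0.5, 0.975, 1), names = FALSE)
    out <- cbind(nominal = nominal[, cc], min = qs[1, ], p2_5 = qs[2, ],
                 p50 = qs[3, ], p97_5 = qs[4, ], max = qs[5, ])
    out
  })
  names(summary) <- .compartments

  structure(
    list(times = times, nominal = nominal, summary = summary,
         n_runs = n_runs, n_failed = sum(failed), seed = seed,
         range = range, parameters = parameters,
         runs = if (keep_runs) runs[ok] else NULL),
    class = "uncertainty_ensemble")
}

#' @export
print.uncertainty_ensemble <- function(x, ...) {
  cat("<uncertainty_ensemble>", x$n_runs, "runs (", x$n_failed,
      "failed ), +/-", x$range * 100, "% uniform, seed", x$seed, "\n")
  cat("  randomized:", paste(x$parameters, collapse = ", "), "\n")
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
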