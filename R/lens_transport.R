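#' Lens spatial grid
#'
#' Uniform one-dimensional grid across the lens thickness. `y = 0` is the
#' anterior, tears-facing face; `y = H` is the posterior, cornea-facing
#' face.
#'
#' @param H lens thickness (cm), > 0.
#' @param n_nodes number of nodes including both faces, >= 3.
#' @return object of class `lens_grid` with fields `n_nodes`, `y`, `dy`.
#' @export
lens_grid <- function(H, n_nodes = 50L) {
  stopifnot(H > 0, n_nodes >= 3L)
  n_nodes <- as.integer(n_nodes)
  structure(list(n_nodes = n_nodes,
                 y = seq(0, H, length.out = n_nodes),
                 dy = H / (n_nodes - 1L),
                 H = H),
            class = "lens_grid")
}

#' Uniformly loaded lens profile
#'
#' @param grid a [lens_grid].
#' @param C0 initial drug concentration in the lens (ng/mL), >= 0.
#' @return object of class `lens_profile` with fields `grid` and `C_SCL`.
#' @export
init_uniform_loading <- function(grid, C0) {
  stopifnot(inherits(grid, "lens_grid"), C0 >= 0)
  lens_profile(grid, rep(C0, grid$n_nodes))
}

#' Lens concentration profile
#'
#' @param grid a [lens_grid].
#' @param C_SCL drug concentration at each node (ng/mL), finite.
#' @return object of class `lens_profile`.
#' @export
lens_profile <- function(grid, C_SCL) {
  stopifnot(inherits(grid, "lens_grid"),
            length(C_SCL) == grid$n_nodes, all(is.finite(C_SCL)))
  structure(list(grid = grid, C_SCL = as.numeric(C_SCL)),
            class = "lens_profile")
}

#' @export
print.lens_profile <- function(x, ...) {
  cat("<lens_profile>", x$grid$n_nodes, "nodes over H =", x$grid$H, "cm;",
      "range", signif(min(x$C_SCL), 4), "-", signif(max(x$C_SCL), 4),
      "ng/mL\n")
  invisible(x)
}

.require_diffusion <- function(params) {
  if (params$mode != "diffusion") {
    stop("lens transport is undefined in release mode", call. = FALSE)
  }
  invisible(params)
}

#' Time derivative of the discretized lens diffusion equation
#'
#' Method-of-lines evaluation of the transverse diffusion equation
#' `dC/dt = D_SCL d2C/dy2` with a Dirichlet boundary at the anterior face
#' (tears equilibrium, `C(0) = K_SCL * C_t`; the face node is algebraically
#' slaved, its reported derivative is zero) and a flux-matching (Robin)
#' boundary at the posterior face, where the diffusive efflux from the lens
#' equals the trans-epithelial rate
#' `A_Cornea * P_t_Aq * (C(H)/K_SCL - C_Aq)`. Interior nodes use the
#' second-order central difference; the posterior node uses a ghost-node
#' elimination of the flux condition.
#'
#' @param profile a [lens_profile]; its anterior node is overwritten with
#'   `K_SCL * C_t` before differencing.
#' @param C_t tears concentration (ng/mL).
#' @param C_Aq aqueous humor concentration (ng/mL).
#' @param params diffusion-mode `ocular_params`.
#' @return list with `dCdt` (per-node derivative, ng/mL/s; zero at the
#'   anterior node), `C_anterior` (the imposed anterior value) and
#'   `back_flux` (ng/s into the aqueous humor).
#' @export
lens_rhs <- function(profile, C_t, C_Aq, params) {
  .require_diffusion(params)
  g <- profile$grid
  C <- profile$C_SCL
  n <- g$n_nodes
  dy <- g$dy
  D <- params$lens$D_SCL
  K_SCL <- params$drug$K_SCL
  A_SCL <- params$anatomy$A_SCL

  C[1] <- K_SCL * C_t
  J_back <- params$anatomy$A_Cornea * params$drug$P_t_Aq *
    (C[n] / K_SCL - C_Aq)

  dCdt <- numeric(n)
  idx <- 2:(n - 1L)
  dCdt[idx] <- D * (C[idx + 1L] - 2 * C[idx] + C[idx - 1L]) / dy^2
  # ghost node at y = H + dy from the total-rate flux match:
  # A_SCL * (-D dC/dy|_H) = J_back
  C_ghost <- C[n - 1L] - 2 * dy * J_back / (A_SCL * D)
  dCdt[n] <- D * (C_ghost - 2 * C[n] + C[n - 1L]) / dy^2

  list(dCdt = dCdt, C_anterior = C[1], back_flux = J_back)
}

#' Drug delivery rate from the anterior lens face into the tears
#'
#' `front_flux = D_SCL * A_SCL * (C[2] - C[1]) / dy`: the one-sided face
#' gradient, signed so that a lens richer than tears equilibrium yields a
#' positive rate into the tears. This is the discretely conservative form:
#' feeding it to the tears balance makes the cumulative mass entering the
#' tears equal (to within the moving-boundary half-cell term, which
#' vanishes with the tears concentration) the mass the discrete lens
#' actually loses through its anterior face, so the lens + tears budget
#' closes. Higher-order one-sided gradients are pointwise more accurate
#' for the continuous flux but overcount the cumulative efflux by the
#' anterior half-cell mass `A_SCL * dy * C0 / 2`, breaking the audit by
#' O(dy).
#'
#' @param profile a [lens_profile] (anterior node already at its boundary
#'   value).
#' @param params diffusion-mode `ocular_params`.
#' @return mass rate (ng/s) into the tears.
#' @export
front_flux <- function(profile, params) {
  .require_diffusion(params)
  C <- profile$C_SCL
  dy <- profile$grid$dy
  params$lens$D_SCL * params$anatomy$A_SCL * (C[2] - C[1]) / dy
}

#' Drug delivery rate across the cornea into the aqueous humor
#'
#' `back_flux = A_Cornea * P_t_Aq * (C_SCL(H)/K_SCL - C_Aq)`; negative when
#' the aqueous humor is richer than lens-face equilibrium (reverse flux).
#'
#' @param profile a [lens_profile].
#' @param C_Aq aqueous humor concentration (ng/mL).
#' @param params diffusion-mode `ocular_params`.
#' @return mass rate (ng/s) into the aqueous humor.
#' @export
back_flux <- function(profile, C_Aq, params) {
  .require_diffusion(params)
  C_H <- profile$C_SCL[profile$grid$n_nodes]
  params$anatomy$A_Cornea * params$drug$P_t_Aq *
    (C_H / params$drug$K_SCL - C_Aq)
}

#' Total drug mass held in the lens
#'
#' Trapezoidal quadrature of the concentration profile over `[0, H]` times
#' the lens area.
#'
#' @param profile a [lens_profile].
#' @param params diffusion-mode `ocular_params`.
#' @return mass (ng).
#' @export
lens_drug_mass <- function(profile, params) {
  .require_diffusion(params)
  C <- profile$C_SCL
  dy <- profile$grid$dy
  n <- length(C)
  params$anatomy$A_SCL * dy * (sum(C) - (C[1] + C[n]) / 2)
}

#' Solve the isolated lens slab with zero-concentration faces
#'
#' Verification harness for the spatial discretization: integrates the
#' method-of-lines system for a uniformly loaded slab with both faces
#' clamped at zero concentration (the limit of instantaneous removal at
#' both interfaces). The same central-difference kernel as [lens_rhs] is
#' used, so agreement with the classical Fourier-series slab solution
#' exercises the production discretization.
#'
#' @param H slab thickness (cm).
#' @param D diffusivity (cm^2/s).
#' @param C0 uniform initial concentration (ng/mL).
#' @param n_nodes grid size.
#' @param times output times (s), starting at 0.
#' @param rel_tol,abs_tol solver tolerances.
#' @return matrix of node concentrations, one row per output time, with the
#'   grid in attribute `"grid"`.
#' @export
solve_lens_slab <- function(H, D, C0, n_nodes, times,
                            rel_tol = 1e-10, abs_tol = 1e-12) {
  g <- lens_grid(H, n_nodes)
  n <- g$n_nodes
  dy <- g$dy
  rhs <- function(t, y, parms) {
    C <- c(0, y, 0)  # Dirichlet-0 faces
    idx <- 2:(n - 1L)
    list(D * (C[idx + 1L] - 2 * C[idx] + C[idx - 1L]) / dy^2)
  }
  sol <- deSolve::ode(y = rep(C0, n - 2L), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rel_tol, atol = abs_tol)
  out <- cbind(0, unname(sol[, -1, drop = FALSE]), 0)
  attr(out, "grid") <- g
  out
}

#' Analytic slab solution (Fourier series)
#'
#' Closed-form solution of `dC/dt = D d2C/dy2` on `[0, H]` with `C = 0` at
#' both faces and uniform initial concentration `C0`:
#' `C(y, t) = sum_{k odd} (4 C0 / (k pi)) sin(k pi y / H)
#' exp(-k^2 pi^2 D t / H^2)`.
#'
#' @param y positions (cm).
#' @param t time (s), scalar.
#' @param H slab thickness (cm).
#' @param D diffusivity (cm^2/s).
#' @param C0 initial concentration (ng/mL).
#' @param n_terms number of odd series terms.
#' @return concentrations at `y`.
#' @export
slab_fourier_solution <- function(y, t, H, D, C0, n_terms = 200L) {
  ks <- seq(1L, by = 2L, length.out = n_terms)
  out <- numeric(length(y))
  for (k in ks) {
    out <- out + (4 * C0 / (k * pi)) * sin(k * pi * y / H) *
      exp(-k^2 * pi^2 * D * t / H^2)
  }
  out
}
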