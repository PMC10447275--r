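# Shared fixtures built in code.

fixture_release <- function() rabbit_dexamethasone_params("release")
fixture_diffusion <- function() rabbit_dexamethasone_params("diffusion")

# Conservative closed-system variant: no flows, no clearance, unit
# partition coefficients, no palpebral sink. The aqueous humor is coupled
# to the rest only through the source split, so the common equilibrium
# M/sum(V) requires F = V_Aq / sum(V).
closed_system_params <- function(T_release = 3600) {
  p <- fixture_release()
  an <- p$anatomy
  sumV <- an$V_t + an$V_ScCh + an$V_Ret + an$V_Vit + an$V_Aq
  p$anatomy$A_Palp <- 1e-30
  p$physiology <- lapply(p$physiology, function(x) 0)
  for (k in c("K_t", "K_Aq", "K_Vit", "K_ScCh", "K_Ret")) {
    p$drug[[k]] <- 1
  }
  p$drug$F <- an$V_Aq / sumV
  p$release$T <- T_release
  p
}

# total volume of the five compartments (mL)
total_volume <- function(p) {
  with(p$anatomy, V_t + V_ScCh + V_Ret + V_Vit + V_Aq)
}

# stored drug mass (ng) at each output time of a trajectory
stored_mass <- function(traj, p) {
  vols <- with(p$anatomy, c(V_t, V_ScCh, V_Ret, V_Vit, V_Aq))
  as.matrix(traj[c("C_t", "C_ScCh", "C_Ret", "C_Vit", "C_Aq")]) %*% vols
}

sink_mass <- function(traj) {
  rowSums(traj[grep("^sink_", names(traj), value = TRUE)])
}

# named numeric vector of all scalar parameters (internal units)
params_to_raw <- function(p) {
  v <- ocupk:::flatten_params(p)
  v[!vapply(v, is.na, logical(1))]
}

flatten_params_list <- function(p) {
  v <- ocupk:::flatten_params(p)
  v[!vapply(v, is.na, logical(1))]
}
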