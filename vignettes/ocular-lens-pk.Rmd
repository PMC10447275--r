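---
title: "A physiology-based model of drug delivery from contact lenses to the back of the eye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiology-based model of drug delivery from contact lenses to the back of the eye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocupk)
```

## The problem

Drug-eluting soft contact lenses (SCLs) deliver drug to the tear film in a
sustained fashion, and animal studies have found therapeutic drug levels not
only in the anterior chamber but also in the choroid, retina and vitreous
after lens wear. `ocupk` implements a mechanistic, physiology-based model of
that process for the rabbit eye: a one-dimensional diffusion equation across
the lens thickness coupled to lumped mass balances for the tears,
sclera–choroid, retina, vitreous humor and aqueous humor, with the corneal
epithelium evaluated as an equilibrium diagnostic.

Two delivery routes connect the lens to the posterior segment:

* **non-corneal**: lens → tears → bulbar conjunctiva → sclera–choroid →
  retina → vitreous;
* **transcorneal**: lens → cornea → aqueous humor → uveoscleral outflow →
  sclera–choroid.

## Model structure

Concentrations are denoted `C_x` with `x` one of `SCL` (lens, spatially
resolved), `t` (tears), `ScCh` (sclera–choroid), `Ret` (retina), `Vit`
(vitreous), `Aq` (aqueous humor), `Ep` (corneal epithelium). Transport
across a membrane is `area × permeability × driving force`, with driving
forces expressed on the free-buffer scale `C/K` using tissue/buffer
partition coefficients `K`. Bulk flows `Q` carry drug at the local
concentration.

In **diffusion mode** the lens obeys `∂C_SCL/∂t = D_SCL ∂²C_SCL/∂y²` on
`y ∈ [0, H]`, with the anterior face (`y = 0`) in instantaneous equilibrium
with the tears (`C_SCL(0) = K_SCL C_t`) and the posterior face exchanging
with the aqueous humor across the corneal epithelium at total rate
`A_Cornea P_t_Aq (C_SCL(H)/K_SCL − C_Aq)`. The tears balance receives the
anterior-face flux; it loses drug to drainage (`Q_Drain C_t`), to the
palpebral conjunctiva (`P_Conj A_Palp C_t`, a one-way sink into the lid
vasculature) and exchanges with the sclera–choroid across the bulbar
conjunctiva (`P_Conj A_Bulb (C_t/K_t − C_ScCh/K_ScCh)`). The
sclera–choroid receives the uveoscleral inflow `Q_UvSc C_Aq`, loses
`Q_UvSc C_ScCh/K_ScCh` to orbital seepage and `Clearance_ScCh C_ScCh` to
the choroidal circulation, and exchanges with the retina across the
retinal pigment epithelium (`A_Globe P_ScCh_Ret`). The retina exchanges
with the vitreous across the inner limiting membrane (`A_Globe
P_Ret_Vit`), the vitreous drains into the aqueous (`Q_Vit_Aq C_Vit`), and
the aqueous turns over at `Q_Aq` (total turnover, of which the `Q_UvSc`
share re-enters the sclera–choroid). The epithelium is diagnostic:
`C_Ep = (K_Ep_Aq C_Aq + K_Ep_t C_t)/2`, with no feedback.

In **release mode** the explicit lens is replaced by an empirical
first-order release rate `R(t) = (M_Released/T) e^{−t/T}` fitted to in
vitro data; a fraction `F` (the aqueous bioavailability) enters the
aqueous humor directly and `1 − F` enters the tears. This is the
configuration used for the reference rabbit/dexamethasone validation
setup, because the reference lens is a sandwich device whose film
degradation is not modelled mechanistically.

All state equations are linear in concentration, so every output scales
exactly with `C0_SCL` (or `M_Released`) — a property the test-suite checks
and the sensitivity analysis reproduces as a normalized coefficient of
exactly 1 for the released amount.

## Parameters, units and the reference configuration

Everything is computed in the internal unit system `{cm, mL, s, ng}`;
`normalize_units()` converts printed-unit strings (`"4.2 uL/min"`,
`"2.08 %"`) on input and `params_as_printed()` renders them back. Tissue
densities are taken as 1 g/mL, so ng/g and ng/mL interconvert directly.
`F` is stored as a fraction and rendered as percent only at the I/O layer.

`rabbit_dexamethasone_params()` carries the literature rabbit anatomy
(`V_t = 7e−3`, `V_Aq = 0.325`, `V_Vit = 1.7`, `V_ScCh = 0.361`,
`V_Ret = 0.086` mL; `A_Globe = 8.6`, `A_Palp = 14`, `A_Bulb = 3` cm²),
rabbit physiology (`Q_Aq = 4.2`, `Q_Drain = 0.5`, `Q_UvSc = 0.176`,
`Q_Vit_Aq = 0.19` µl/min; `Clearance_ScCh = 1` mL/min) and dexamethasone
barrier properties (`P_Conj = 2.5e−6`, `P_ScCh_Ret = 10e−6` cm/s;
`K_ScCh = 15`, `K_Ret = 10`; `K_t = K_Aq = K_Vit = 1`; `F = 2.08%`). The
inner-limiting-membrane permeability is derived as 30% above the RPE
value, `ilm_permeability(P_ScCh_Ret) = 13e−6` cm/s.

Quantities the literature set does not fix are package defaults, chosen
once on physiological grounds and flagged here:

* `A_Cornea = 2.0` cm², `A_SCL = 2.27` cm² (typical rabbit cornea and a
  14-mm lens);
* the reference release kinetics `M_Released = 2e5` ng, `T = 2` days —
  illustrative of a week-scale sustained-release lens; every property
  checked on the fixture (mass balance, linearity, rankings, envelope
  shape) is invariant to this scale or insensitive to `T`;
* diffusion-mode lens transport: `H = 0.01` cm, `D_SCL = 2e−10` cm²/s
  (release time scale `H²/D ≈ 5.8` days), `C0_SCL = 4.4e6` ng/mL
  (≈100 µg load), `K_SCL = 20`, and `P_t_Aq = 5e−6` cm/s, inside the
  2–25 × 10⁻⁶ cm/s range reported ex vivo for dexamethasone across the
  cornea;
* `K_Ep_Aq`, `K_Ep_t` have no published values for dexamethasone and
  default to `NA`; the `C_Ep` series is then reported as missing rather
  than zero, so its absence cannot be mistaken for absence of drug.

## Numerical treatment

**Discretization.** The lens uses a uniform grid (`n_nodes = 50` by
default) with second-order central differences. The anterior node is
algebraically slaved to `K_SCL C_t` (Dirichlet elimination) instead of
being integrated through an artificial relaxation constant; the posterior
Robin condition is imposed through a ghost node. The analytic check
against the slab Fourier series shows a relative error of ~7.6e−6 at
`t = 0.1 H²/D` with 50 nodes and clean second-order convergence
(error ratios ≈ 4 per grid halving).

**Boundary-flux bookkeeping.** The boundary condition equates a flux
density on the lens side with a total trans-corneal rate; the only
dimensionally consistent, mass-conserving reading is to treat both
boundary exchanges as *total* rates, `A_SCL (−D ∂C/∂y|_H) = A_Cornea
P_t_Aq (C_SCL(H)/K_SCL − C_Aq)`, and that is what the ghost-node
elimination implements. At the anterior face the tears source uses the
conservative face gradient `D A_SCL (C₂ − C₁)/dy`: formally higher-order
one-sided gradients overcount the cumulative efflux by the anterior
half-cell mass `A_SCL dy C0/2` (≈1% at 50 nodes), which would break the
mass audit. The half-cell adjacent to the anterior face is in
instantaneous equilibrium with the tears, so its drug content
(`A_SCL dy K_SCL/2` of effective volume) is lumped with the tears
capacitance during integration and the moving-boundary term is charged to
the cumulative anterior flux. With these choices the discrete budget
(lens mass + tissue mass + sink accumulators = initial load) closes to
machine precision at every output time, and the audit tolerance of 0.1%
is limited only by solver tolerances.

**Stiffness.** The tears compartment (7 µl turning over in minutes) and
the sclera–choroid (cleared in ~20 s) sit against a 7-day horizon, a
stiffness ratio of ~10⁴. `simulate_eye()` integrates with `deSolve`'s
`lsoda` (adaptive, switches to BDF when stiff) at `rel_tol = 1e−8`,
`abs_tol = 1e−12` ng/mL, with dense output every 600 s over a 604800-s
(7-day) default horizon. Cumulative sink masses are integrated alongside
the states so that mass auditing does not rely on output-grid quadrature.

**Degenerate inputs.** Zero loading gives an identically zero trajectory;
negative concentrations beyond `−10 abs_tol` raise a diagnostic
(tolerance misconfiguration); solver step-size collapse aborts with the
failure time; reverse fluxes (aqueous richer than the lens face) are
permitted.

## Release fitting and bioavailability

`fit_exponential_release()` performs unweighted nonlinear least squares of
the cumulative curve `f(t) = M_Released (1 − e^{−t/T})` — fitting the
cumulative data directly rather than numerically differentiated rates,
which would amplify noise. Initialization is deterministic and
scale-free: `M₀ = max(cumulative)` and `T₀` the time the curve first
reaches 63.2% of `M₀` (linear interpolation), so the fit is reproducible
given the data.

`compute_bioavailability()` implements `F = Q_Aq · AUC(C_Aq) /
M_Released`, with the AUC obtained by fitting a single exponential decay
to the aqueous series and integrating its closed form to infinity
("down to zero concentration") rather than trapezoiding the raw points.
Closing the loop — simulating with a known `F`, sampling the aqueous curve
daily for a week and recomputing — recovers `F` within ~3%; the residual
reflects the single-exponential approximation of a multi-compartment
curve (the rise phase of `C_Aq`, time constant `V_Aq/Q_Aq ≈ 1.3 h`,
is below the fitted pure decay).

## Sensitivity analysis and uncertainty propagation

`local_sensitivity()` perturbs one parameter at a time by ±10% and
reports `ΔAUC(%)/|Δparam(%)|` and `ΔCmax(%)/|Δparam(%)|` per compartment,
with both directions kept as separate rows (no symmetrization is
assumed). The default parameter list contains the barrier permeabilities,
the physiological flows and clearance, the partition coefficients and, in
release mode, `F`; anatomical parameters are held constant. `M_Released`
and `T` are not in the default one-at-a-time list (they are release-curve
descriptors rather than barrier/transport/partition properties) but can
be requested explicitly — the linearity check does exactly that.

`uncertainty_cloud()` randomizes every non-anatomical input — including
`M_Released`, `T` and `F` in release mode — independently and uniformly
on ±10% of nominal (uniform being the minimal-assumption reading of "a
±10% range"), runs `N = 400` simulations by default, and keeps the
pointwise envelope plus the 2.5/50/97.5 percentiles per compartment; all
draws derive from one seed, so ensembles are bit-reproducible. On the
reference configuration the envelope is widest near each compartment's
concentration peak and ~20–30× narrower by day 7: parameter uncertainty
does not accumulate over time in this model.

On the reference configuration the computed AUC ranking is led, for the
posterior tissues, by `Clearance_ScCh` and `K_ScCh` (coefficients ≈ ±1),
followed by `K_Ret`/`K_Vit` and `K_t` (≈ 0.85 through the bulbar driving
force `C_t/K_t`), with `P_Conj` and `Q_Drain` at ≈ ±0.16. Two structural
features explain this: the choroidal clearance acts on the *total*
sclera–choroid concentration, so the quasi-steady tissue level is
influx/clearance and `K_ScCh` cancels out of its own compartment while
setting the free concentration `C_ScCh/K_ScCh` that feeds the retina and
vitreous (coefficient −1 there); and the conjunctival coefficient is
capped at `Q_Drain/(Q_Drain + P_Conj(A_Palp + A_Bulb)) ≈ 0.16`, because
the palpebral conjunctiva — not drainage — dominates tear clearance at
these parameter values, so increasing `P_Conj` raises the posterior
influx and the tear loss almost proportionally.

## Synthetic data

The generators produce release and aqueous datasets from the exact closed
forms with optional multiplicative Gaussian noise (assay errors scale
with signal; CV defaults to 10%, echoing the large variability of in
vivo ocular measurements), clip negative draws to zero with a count, and
attach the ground truth; they are pure functions of their seed and leave
the global RNG stream untouched. The default release sampling schedule
follows standard in vitro practice: half the samples packed into the
early rise (up to 16% of the span), the rest confirming the plateau over
its final 30%. This design matters for the prescribed unweighted fit:
under multiplicative noise the plateau points carry the largest absolute
noise, and equally spaced designs inflate the spread of the recovered
time constant (CV(T) ≈ 18% versus ≈ 12% here at n = 10, CV = 10%).

What the generators deliberately do not emulate: inter-animal random
effects, tissue-extraction bias, correlated assay errors, or
multi-exponential/Weibull release shapes. Passing the recovery tests
therefore demonstrates correctness of the fitting machinery under the
stated noise model, not robustness to real-world model misspecification.

## Verification choices worth knowing about

* **Closed-system equilibrium.** The conservative variant used in testing
  sets all flows and clearances to zero, all `K = 1`, and removes the
  palpebral sink. Because the aqueous humor is then coupled to the rest
  only through the source split, the unique source fraction under which
  all five compartments share the equilibrium `M_Released/ΣV` is
  `F = V_Aq/ΣV ≈ 0.131`; the test constructs exactly that system and
  integrates to 100× the slowest exchange time constant (the posterior
  pool charging through the bulbar conductance, ≈ 3.3 days).
* **Problem sizes.** The shipped checks use the 7-day fixture horizon at
  600-s output (1009 points), 50 lens nodes with refinements to 101,
  200 fit replicates, and the full 400-run ensemble.
* **Determinism.** Simulations are deterministic given parameters; only
  the generators and the ensemble consume randomness, always through an
  explicit seed.

## Limitations

Tissue concentrations are well-mixed (no spatial gradients outside the
lens); corneal endothelium resistance, retinal metabolism and active
transport are not modelled — a known cause of long-term overprediction of
retinal levels; the epithelium output is unavailable without user-supplied
`K_Ep` values; release mode assumes the lens is fully described by
`(M_Released, T, F)` with no tear-side feedback; macromolecules,
permeability enhancers, prodrugs and nanocarriers are out of scope, as is
a human-eye preset.
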