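# ocupk

Physiology-based ocular pharmacokinetics of drug-eluting soft contact
lenses (SCLs), for the rabbit eye.

Therapeutic contact lenses deliver drug to the tear film over hours to
weeks, and measurable drug reaches not just the aqueous humor but the
choroid, retina and vitreous — opening a non-invasive route to the back of
the eye. `ocupk` is for pharmacokinetic modellers and ocular drug-delivery
researchers who want to simulate that process mechanistically, audit its
mass balance, and ask which tissue and transport parameters actually
control exposure.

## The model

Seven compartments: the lens (spatially resolved), tears, sclera–choroid,
retina, vitreous humor, aqueous humor, and a diagnostic corneal
epithelium. Drug moves along two routes — non-corneal (tears → bulbar
conjunctiva → sclera–choroid → retina → vitreous) and transcorneal (cornea
→ aqueous → uveoscleral outflow → sclera–choroid). Membrane transport is
`A · P · (C_i/K_i − C_j/K_j)`; bulk flows `Q` carry drug at the local
concentration.

In **diffusion mode** the lens obeys the transverse diffusion equation
`∂C_SCL/∂t = D_SCL ∂²C_SCL/∂y²` with tears equilibrium at the anterior
face (`C_SCL(0) = K_SCL C_t`) and a trans-corneal flux match at the
posterior face, solved by the method of lines coupled to the tissue
balances. In **release mode** the lens is replaced by a fitted first-order
release rate `R(t) = (M_Released/T) e^(−t/T)`, split between tears
(`1 − F`) and aqueous humor (`F`, the aqueous bioavailability
`F = Q_Aq · AUC(C_Aq) / M_Released`).

On top of the simulator: exponential release-curve fitting, bioavailability
computation from aqueous concentration series, AUC/Cmax exposure metrics,
mass-balance audits, ±10% one-at-a-time local sensitivity analysis,
randomized-parameter uncertainty ensembles (N = 400), and seeded
synthetic-data generators. The methods vignette
(`vignettes/ocular-lens-pk.Rmd`) documents the equations, units,
numerical choices and limitations.

## Worked example

Simulate a week of dexamethasone delivery on the built-in rabbit
parameter set (release mode):

```r
library(ocupk)
p <- rabbit_dexamethasone_params()
tr <- simulate_eye(p)
tr
#> <eye_trajectory> mode = release | 1009 output times over 604800 s
#>   peak concentrations (ng/mL): C_t=22150 C_ScCh=9.981 C_Ret=4.31 C_Vit=0.4094 C_Aq=311.2
print(compute_metrics(tr), digits = 4)
#>   compartment       auc      cmax t_cmax
#> 1         C_t 3.732e+09 2.215e+04   1200
#> 2      C_ScCh 1.690e+06 9.981e+00   1200
#> 3       C_Ret 1.082e+06 4.310e+00  59400
#> 4       C_Vit 1.048e+05 4.094e-01  78600
#> 5        C_Aq 5.759e+07 3.112e+02  17400
mass_balance_residual(tr)
#> [1] 1.410473e-12
```

Tears peak within minutes of lens application and the aqueous humor within
hours, while the retina and vitreous peak after ~17 and ~22 hours — the
posterior segment charges slowly through the conjunctival-scleral route.
AUCs are in ng·s/mL, Cmax in ng/mL (≡ ng/g at unit tissue density), t_cmax
in seconds. The mass audit confirms that stored plus cleared drug accounts
for everything released, to solver precision.

Fit an in vitro cumulative release curve (here synthetic, 10% noise):

```r
d <- generate_release_data(500, 3600, n_points = 10,
                           noise = "multiplicative-gaussian",
                           cv = 0.1, seed = 42)
fit_exponential_release(d)
#> <release_fit> f(t) = M * (1 - exp(-t/T))
#>   M_Released = 543.896 ng
#>   T          = 3873.5 s
#>   residual norm = 94.65 ng on 10 points
```

A thin command-line wrapper (`inst/cli/ocupk`) exposes `simulate`,
`fit-release`, `bioavailability`, `sensitivity`, `uncertainty` and `synth`
subcommands over the same functions, e.g.

```sh
Rscript inst/cli/ocupk simulate --preset rabbit-dexamethasone --out traj.csv
```

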