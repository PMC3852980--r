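# freesolvent

Free-solvent thermodynamics of concentrated macromolecule solutions:
predict osmotic pressure and the activity coefficient of free-solvent for
globular-protein (and small-solute) aqueous solutions up to
near-saturation, from three independently measurable quantities — solution
composition, hydration derived from solvent-accessible surface area
(SASA), and protein–ion binding — with no adjustable parameters.

It is aimed at people who work with crowded or concentrated protein
solutions: membrane osmometry, ultrafiltration, protein formulation, and
macromolecular-crowding modelling.

## The model

The protein plus its bound water and bound ions is treated as a single
*hydrated macromolecule*; the remaining **free solvent** is then ideal.
With chamber II the protein solution and chamber I the protein-free
dialysate of a membrane osmometer, the free-water mole fraction in
chamber II is

```
x̂₁ = (N₁ − Σⱼ ν₁ⱼNⱼ) / [ (N₁ − Σⱼ ν₁ⱼNⱼ) + Σⱼ Nⱼ + Σₖ dₖ·(Nₖ − Σⱼ νₖⱼNⱼ) ]
```

(ν₁ⱼ = hydration, νₖⱼ = salt binding in formula units, dₖ = dissociation
count), the osmotic pressure is `π = −(RT/V̄₁)·ln(x̂₁ᴵᴵ/x̂₁ᴵ)`, and the
activity coefficient of free-solvent follows in closed form as

```
γ₁ᴵᴵ = (x̂₁ᴵᴵ/x₁ᴵᴵ) · (x₁ᴵ/x̂₁ᴵ)
```

where x₁ is the ordinary (total-water) mole fraction. Inverting the
non-ideal pressure relation, `γ₁ᴵᴵ = (x₁ᴵ/x₁ᴵᴵ)·exp(−πV̄₁/RT)`
back-calculates γ from measured pressures. Hydration comes from a SASA
monolayer at 15.2 waters/nm²: `ν₁₂ = SASA[Å²]/100 × 15.2` mol/mol.

The package provides the forward predictions, both γ routes, bounded
nonlinear least-squares regression of (ν₁₂, ν₃₂) from osmometry data, a
seeded synthetic osmometry generator, preset literature systems
(BSA/NaCl at three pH values, hemoglobin/KCl, sucrose/water), YAML/JSON
configs, CSV datasets, and a command-line interface. See the methods
vignette (`vignettes/free-solvent-model.Rmd`) for assumptions, numerical
choices and limitations.

## Worked example

```r
library(freesolvent)

# BSA hydration from the homology-model SASA (GETAREA)
hydration_from_sasa(27746, molar_mass = 66430)
#> <fs_hydration> SASA 27746 A^2 @ 15.2 /nm^2 -> 4217.39 mol/mol = 1.1437 g/g

# concentrated BSA in 0.15 M NaCl at pH 4.5 (ion binding 11.59 mol/mol)
sys <- fs_scenario("bsa_ph4.5", hydration_g_per_g = 1.144)
predict_osmotic_pressure(sys, c(100, 300, 450))
#>   conc   pressure
#> 1  100   69899.31
#> 2  300  390180.12
#> 3  450 1651024.54

activity_curve(sys, conc = c(0, 150, 300, 450))
#>   conc     gamma      mode
#> 1    0 1.0000000 predicted
#> 2  150 0.9998472 predicted
#> 3  300 0.9987792 predicted
#> 4  450 0.9908392 predicted
```

Pressures are in Pa (390 kPa ≈ 3.85 atm at 300 g/L); γ falls from unity
as crowding grows — a 1% departure of the *solvent* activity coefficient
already corresponds to a very large osmotic non-ideality at these
concentrations.

Fitting the two binding parameters back from noisy synthetic osmometry:

```r
d <- generate_osmotic_dataset(sys, conc = seq(50, 450, length.out = 15),
       noise = noise_model("multiplicative_gaussian", 0.02, seed = 7))
fit_binding_parameters(d, sys, init = c(hydration = 3000, ion_binding = 5))
#> <fs_fit> bounded nonlinear least squares
#>   hydration            4238.88  (se 20)
#>   ion_binding          11.5095  (se 0.151)
#>   hydration_g_per_g    1.14953
#>   rmse 10610.5 Pa, converged: TRUE, 85 evaluations
```

The true values were 4218.48 mol/mol (1.144 g/g) and 11.59 mol/mol: both
recovered within one standard error under 2% measurement noise.

## Command line

```sh
Rscript inst/scripts/freesolvent.R convert-hydration --sasa 27746 --molar-mass 66430
Rscript inst/scripts/freesolvent.R simulate --scenario bsa_ph7.4 --noise 0.02 --seed 17 --out sim.csv
Rscript inst/scripts/freesolvent.R fit --config inst/extdata/bsa_ph4.5.yaml --data sim.csv --out fit.json
```

Subcommands: `convert-hydration`, `predict-pressure`, `predict-gamma`,
`gamma-from-data`, `fit`, `simulate`; every error exits nonzero with a
one-line diagnostic.

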