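# celldose

Cellular dosimetry for Lutetium-177 radiopharmaceutical in vitro
experiments.

Clonogenic assays with beta-emitting radiopharmaceuticals such as
¹⁷⁷Lu-DOTATATE usually report survival against the *added* activity
(MBq/ml). To compare exposures across compounds — or against external-beam
irradiation — one needs the absorbed dose the cell nucleus actually
received, which depends strongly on cell morphology, on where the
radionuclide sits (medium, membrane, cytoplasm, Golgi), and on how colonies
grow during the follow-up. `celldose` implements that conversion for a 4-h
uptake plus 6-day colony-forming experiment on adherent cell monolayers
(the reference system is U2OS cells expressing the somatostatin receptor
SST₂), and correlates the resulting doses with clonogenic survival.

The absorbed dose to the nucleus follows the MIRD formalism,

    D(N) = Ã_M · S(N←M) + Ã_CS · S(N←CS) + Ã_C · S(N←C)

with cumulated activities `Ã` (Bq·s) per compartment and interval

    Ã = f · A₀ · (e^(−λₚT₁) − e^(−λₚT₂)) / λₚ

and cellular S values `S(N←X)` (Gy per Bq·s) computed by a straight-line
continuous-slowing-down (CSDA) Monte Carlo electron-transport engine over
spherical, truncated-cone (frustum + ellipsoid nucleus + half-torus Golgi)
and watertight polygonal-mesh cell geometries — for single cells
(self-dose), hexagonal monolayers and growing colony clusters (cross-dose),
and the medium-filled culture well. Survival is fitted as
`SF = exp(−αD − βD²)` with AIC selection between the linear and
linear-quadratic models.

## Worked example

From emission physics to a dose–response fit, on synthetic measurements:

```r
library(celldose)

spectrum <- load_emission_spectrum()
spectrum
#> <emission_spectrum> 3 beta branch(es), 10 discrete line(s)
#>   cutoff 3.80 keV | yield above cutoff 1.164 e-/decay | mean energy Delta = 146.8 keV/decay

cell <- tc_cell()          # average-volume adherent truncated-cone cell
cell
#> <cell_model> truncated_cone: V_cell = 3482, V_N = 1045, V_G = 59.7 um^3

self_s_value(cell, "cytoplasm", n_histories = 1e5, seed = 1)
#> <s_value> N <- cytoplasm: 9.089e-05 +/- 1e-06 Gy/(Bq s)  [100000 histories]
```

`9.1e-5` Gy/(Bq·s) is the self-dose to this cell's nucleus per decay in its
own cytoplasm — between the published polygonal-mesh average (5.84e-5) and
the equal-volume sphere (1.4e-4), as expected for the intermediate
truncated-cone representation.

```r
cfg  <- synthetic_config()                      # study-design defaults
ds   <- generate_uptake_dataset(cfg, seed = 1)  # gamma-counter tables + truth
cum  <- pipeline_cumulated(ds, activity = 2.5)  # fit TACs, cumulate per interval
dose <- compute_absorbed_dose(cum, ref_monolayer_s(), internalized = "cytoplasm")
dose
#> <dose_result> polygonal_mesh(cytoplasm): D(N) = 1.78 +/- 0.58 Gy (A0 = 2.5e+06 Bq)
#>  interval dose_membrane dose_internalized dose_medium dose_total dose_sd
#>    uptake       0.01917           0.12243       0.336    0.47759 0.15706
#>      day1       0.08146           0.60329       0.000    0.68475 0.22519
#>      day2       0.04748           0.36225       0.000    0.40973 0.13474
#>      day3       0.01668           0.11845       0.000    0.13514 0.04444
#>      day4       0.00463           0.04214       0.000    0.04677 0.01538
#>      day5       0.00237           0.01451       0.000    0.01688 0.00555
#>      day6       0.00040           0.00376       0.000    0.00416 0.00137
```

The 2.5 MBq/ml exposure delivers 1.78 Gy to the nucleus over the week: the
internalized fraction dominates, and the unbound medium contributes only
during the uptake phase (here 0.34 Gy ≈ 17% of the total). Feeding the
per-activity doses into the survival fit:

```r
doses <- vapply(cfg$activities, function(a)
  compute_absorbed_dose(pipeline_cumulated(ds, a),
                        ref_monolayer_s(), "cytoplasm")$total_Gy, 0)
sv <- generate_survival_dataset(cfg$alpha_true, doses, replicates = 3,
                                noise_cv = 0.1, seed = 2)
sf <- aggregate(sf ~ dose_Gy, sv, mean)
sel <- model_select_aic(list(fit_dose_response(sf$dose_Gy, sf$sf, "linear"),
                             fit_dose_response(sf$dose_Gy, sf$sf, "LQ")))
sel$chosen
#> <dose_response_fit> linear: alpha = 0.303 +/- 0.017 /Gy, R2 = 0.970, AIC = -35.79 (n = 5)
sel$linear_regime
#> [1] TRUE
```

AIC prefers the linear model (the radiopharmaceutical's protracted low
dose-rate regime, α/β > 100 Gy) and recovers the generating α = 0.33 within
its uncertainty.

See the vignette (`vignettes/cellular-dosimetry.Rmd`) for the transport
model, geometry parameterisations, kinetics conventions, and known
limitations — in particular that straight-line CSDA transport overstates
the absolute cross-dose of touching monolayers while reproducing the
relative proximity effects.

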