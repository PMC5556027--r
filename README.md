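# frackill

Dynamical modelling of cisplatin-induced **fractional killing**: why, in a
population of genetically similar tumour cells under a uniform drug dose,
some cells die while others survive — and what kinds of interventions can
change that fraction.

The package is aimed at systems biologists studying apoptosis and
drug-response heterogeneity. It implements a hybrid ODE model coupling:

- a **mass-action apoptosis switch** — free BH3 proteins activate
  mitochondrial BAX (BAXm), BCL sequesters both into inert dimers, and the
  mutual liberation of free BH3 and BAXm forms a positive feedback that
  makes BAXm activation bistable and hysteretic; BAXm accumulation is the
  death indicator,
- a **generic-formula p53/Mdm2 module** — each activity ratio relaxes to a
  sigmoidal target, `dX/dt = τ(1/(1+e^{−σW}) − X)`, with p53 positive
  feedback and Mdm2-mediated negative feedback; cisplatin relieves the
  Mdm2 repression of p53,
- an **incoherent feedforward loop** — the same drug also induces CIAP,
  which suppresses Caspase8 and thereby BH3 synthesis, raising the
  apoptosis threshold over time.

Cell fate is the race between these arms: in the (p53, CIAP) control
plane, the saddle-node folds of the BAXm switch trace an activation
threshold θ_act(CIAP) and an inactivation threshold θ_inact(CIAP); a cell
dies iff its (p53(t), CIAP(t)) trajectory reaches the apoptosis region
while the threshold is still low. Interventions are classified by whether
they reshape the threshold curves (**BG**, bifurcation geometry), redirect
the trajectories (**CT**), or both (**AB**).

## Worked example

Simulate a seeded heterogeneous population of 300 virtual cells (each
parameter of the p53/Mdm2 module, the CIAP degradation rate and the
per-cell drug-effect strength scaled to 70–120% of basal) at a low and a
high cisplatin dose, and score the hallmark features of fractional
killing:

```r
library(frackill)

p     <- fk_params()                       # calibrated "table1_basal" defaults
cells <- sample_population(p, heterogeneity_spec(n_cells = 300, seed = 1))
low   <- run_population(cells, fk_protocol(drug = 0.45))
high  <- run_population(cells, fk_protocol(drug = 1))

low
#> <fk_population> 300 cells at drug = 0.45
#>   fraction apoptotic: 0.503

feature_report(low, high)
#> <fk_features> hallmark features of fractional killing
#>                          feature pass statistic
#>                similar_p53_peaks TRUE    0.0423
#>       dispersed_activation_times TRUE    4.2600
#>            early_activation_dies TRUE   -4.3300
#>  survivors_higher_integrated_p53 TRUE   20.7000
#>       higher_dose_more_apoptosis TRUE    0.0933
```

About half the cells die at the low dose. Apoptotic and surviving cells
reach similar p53 peaks (4% relative median difference), activation times
are dispersed (IQR 4.3 time units), apoptotic cells activate p53 earlier
(median 4.3 units before survivors), survivors accumulate more integrated
p53 (their p53 keeps integrating to the end of the run, while apoptotic
cells lose theirs at death), and the higher dose kills 9 percentage
points more of the same cells.

The bistable switch behind the fate decision:

```r
one_param_scurve(p)      # BAXm equilibria vs p53 at basal CIAP
#> <fk_scurve> control: p53  cIAP = 0.01
#>   theta_inact = 0.52908  theta_act = 0.70242
```

Screening the canonical anti-fractional-killing strategies on a shared
100-cell seeded population:

```r
screen_strategies(p, spec = heterogeneity_spec(n_cells = 100, seed = 1))
#>               strategy kill_fraction_baseline kill_fraction_intervention
#>          increase_drug                   0.57                       0.62
#>        ciap_inhibition                   0.57                       0.89
#>         bcl_inhibition                   0.57                       0.89
#>                 nutlin                   0.57                       0.59
#>  ciap_bcl_coinhibition                   0.57                       0.98
#>       casp8_activation                   0.57                       0.89
#>  geometry_delta trajectory_delta category expected match
#>           0.000         7.22e-01       CT       CT  TRUE
#>           0.000         8.84e-01       CT       CT  TRUE
#>           0.353         3.99e-07       BG       BG  TRUE
#>           0.000         7.20e-01       CT       CT  TRUE
#>           0.353         8.84e-01       AB       AB  TRUE
#>           0.300         6.46e-07       BG       BG  TRUE
```

Raising the dose, inhibiting CIAP and adding Nutlin-3 move the cell
trajectories (CT); inhibiting BCL or activating Caspase8 move the
threshold curves (BG); co-inhibiting CIAP and BCL does both (AB) and
kills more cells than either single inhibition.

A command-line wrapper over the same functions is installed at
`system.file("cli", "frackill.R", package = "frackill")` with subcommands
`simulate-cell`, `simulate-population`, `features`, `scurve`,
`thresholds`, `overlay`, `strategies` and `calibrate`.

See the methods vignette (`vignettes/fractional-killing-model.Rmd`) for
the model equations, the calibration of the open parameters, and the
equilibrium- vs treatment-path threshold constructions.

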