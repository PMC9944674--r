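# ocupbpk

Physiologically based pharmacokinetic (PBPK) simulation of topical
ophthalmic solutions, with parameter estimation from sparse ocular tissue
data and rabbit-to-human exposure extrapolation.

## The problem

Ophthalmic drugs act locally: an eye drop reaches its site of action
before — and mostly instead of — the systemic circulation, so plasma
pharmacokinetics cannot stand in for ocular exposure, and sampling human
ocular tissues is only possible opportunistically during surgery. Rabbit
eyes are anatomically close to human eyes and are the standard preclinical
model. This package implements the workflow that bridges the two species:

1. build a compartmental ocular absorption/disposition model for the
   rabbit eye and estimate the few drug-specific parameters that cannot be
   measured (tissue permeabilities, systemic absorption rates, the melanin
   unbound fraction) from rabbit tissue concentration–time data;
2. extrapolate to human by swapping in the human ocular physiology while
   holding every drug-specific parameter fixed.

Three fluoroquinolones — levofloxacin, moxifloxacin, gatifloxacin — ship
as fully transcribed parameter records.

## The model

The pre-cornea (tear film) compartment receives each instilled drop,
capped at the conjunctival-sac capacity (35 µL rabbit / 37 µL human) with
the excess spilled; the fluid volume then relaxes to the physiological
tear volume (5 / ≈7 µL) by first-order nasolacrimal drainage
(k = 1 min⁻¹), carrying dissolved drug to the gut:

    dV/dt = -k_drain (V - V_tear)

Ten ocular compartments (pre-cornea → cornea epithelium/stroma → aqueous
humor → iris–ciliary body → vitreous, and pre-cornea → conjunctiva →
sclera → choroid → retina → vitreous) exchange drug passively,
`Perm · SA · (Cu_outer − Cu_inner)`, where `Cu = fu_melanin · C` in
melanin-containing tissues of pigmented species. Aqueous turnover and
first-order systemic absorption rates (SAR) move drug into a reduced
perfusion-limited whole-body PBPK model (mechanistic tissue/plasma
partition coefficients, renal clearance as a fraction of kidney blood
flow, well-stirred-type hepatic clearance, first-order gut absorption of
drained drug), and unbound plasma drug partitions back into the
vascularized eye tissues. Fitting minimizes summed squared log residuals
with one-sided handling of below-LOQ records, in log-parameter space,
with at most four free parameters per stage.

See `vignettes/ocular-pbpk-methods.Rmd` for assumptions, parameter
provenance, numerical choices and limitations.

## Worked example

```r
library(ocupbpk)

lev <- load_drug("levofloxacin")          # shipped parameter record
ph  <- get_physiology("NZ_rabbit")        # albino rabbit physiology
reg <- dose_regimen(0, drop_volume_uL = 30, strength_pct = 0.5)

sim <- simulate_ocular(lev, ph$ocular, ph$systemic, reg,
                       t_grid = c(0.25, 0.5, 1, 2, 4, 8, 24))
round(sim$conc[-1, c("precornea", "cornea_epi", "conjunctiva", "AH", "ICB")], 4)
#>      precornea cornea_epi conjunctiva     AH    ICB
#> [1,] 2042.6078    47.9358     35.9453 0.1444 0.1065
#> [2,]  885.7235    34.0065     35.1492 0.4925 0.3933
#> [3,]  179.0292    17.8907     19.6715 0.9807 0.8282
#> [4,]   14.8385     7.7558     7.5236  0.9059 0.7891
#> [5,]    3.4568     2.0181     3.1117  0.3384 0.3099
#> [6,]    0.7455     0.2316     0.6917  0.0971 0.1012
#> [7,]    0.0126     0.0275     0.0112  0.0252 0.0273
```

Concentrations are µg/mL at 0.25–24 h. The tear film starts at
150 µg / 35 µL (a 30 µL drop of 0.5% w/v exactly fills the rabbit
pre-cornea cap) and is cleared within the first hour by drainage; aqueous
humor peaks near 1 µg/mL at 1–2 h. `mass_balance(sim)` audits
conservation (here ~3e-15).

Extrapolation changes only the species physiology:

```r
sc <- extrapolate_to_human(lev, reg, t_grid = c(0.25, 0.5, 1, 2, 4, 8, 24))
subset(sc$nca, tissue %in% c("AH", "cornea"))
#>    tissue       cmax tmax        auc
#> 5      AH  0.2794617    1  0.8484015
#> 11 cornea 15.1133839    1 45.2275517
sc$drug_diff                # character(0): no drug parameter moved
```

Reduced tear flow (e.g. under surgical anesthesia) raises aqueous humor
exposure:

```r
tear_flow_sensitivity(lev, "human", reg,
                      t_grid = c(0.25, 0.5, 1, 2, 4, 8, 12, 24))
#>   reduction   ah_cmax    ah_auc
#> 1       0.0 0.2794617 0.8195943
#> 2       0.6 0.3021865 0.8873442
#> 3       0.8 0.3353290 0.9901410
```

Synthetic study data (destructive rabbit cohorts or single-sample
surgical designs, lognormal residual error) come from
`protocol_library()` / `generate_study()`; parameter estimation from
`fit_parameters()` / `melanin_fit()`. Config-driven pipelines
(`run_simulation_config()`, `run_fit_config()`,
`run_extrapolation_config()`) and a thin CLI (`inst/cli/ocupbpk.R`) tie
the stages together; schedule strings follow the grammar documented in
`?expand_regimen` (`"single"`, `"q15minx3"`, `"QIDx3d"`), and regimens
are also accepted as CSV (`time_h, volume_uL, strength_pct`).

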