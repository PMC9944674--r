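---
title: "Methods: ocular PBPK simulation and rabbit-to-human extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular PBPK simulation and rabbit-to-human extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocupbpk)
```

## Scope and model structure

`ocupbpk` simulates the ocular pharmacokinetics of topically instilled
ophthalmic solutions (fluoroquinolone eye drops are the shipped test set)
and extrapolates exposure from rabbit to human by exchanging physiology
while holding every drug-specific parameter fixed. Three coupled pieces
make up the model:

1. **Tear-film (pre-cornea) dynamics.** An instilled drop mixes
   instantaneously with the resident tear fluid; volume is capped at the
   conjunctival-sac maximum (35 µL rabbit, 37 µL human) and the excess is
   spilled at the mixed concentration. Afterwards the fluid volume relaxes
   to the physiological tear volume (5 µL rabbit, ≈7 µL human) by
   first-order nasolacrimal drainage, `dV/dt = -k_drain (V - V_tear)` with
   `k_drain = 1 min⁻¹` (aqueous, water-like viscosity). Drug leaves with
   the drained fluid at the current concentration, so with all
   permeabilities zeroed the pre-cornea amount follows the closed form
   `A(t) = A₀ V(t)/V₀` — used as an integration oracle in the tests.
   Evaporation and transconjunctival tear absorption are taken as
   negligible.

2. **Ocular tissue network.** Ten compartments (pre-cornea, cornea
   epithelium and stroma, conjunctiva, aqueous humor (AH), iris–ciliary
   body (ICB), sclera, choroid, retina, vitreous humor (VH)) exchange drug
   passively across ten interfaces with flux
   `Perm · SA · (Cu_outer - Cu_inner)`. `Cu` is the melanin-unbound
   concentration, `fu_melanin · C`, in pigmented tissues (ICB, retina,
   choroid, sclera of the pigmented rabbit and human) and the total
   concentration elsewhere. Aqueous turnover removes drug from the AH into
   venous blood; first-order systemic absorption rate constants (SAR)
   drain the vascularized tissues (conjunctiva, ICB, choroid, retina) into
   venous blood, and unbound plasma drug re-enters those tissues through
   the same rate constants (`flux_in = SAR · V_tissue · fu_plasma ·
   C_plasma`), making the ocular–systemic exchange bidirectional.

3. **Reduced whole-body PBPK.** Eleven perfusion-limited tissues plus
   venous and arterial blood. Partition coefficients come from a
   mechanistic tissue-composition calculation (below), renal elimination
   is a fixed fraction of kidney blood flow applied to arterial blood,
   hepatic elimination is intrinsic clearance acting on unbound liver
   concentration (venous-equilibration behaviour), and drained tear fluid
   enters a single gut-lumen compartment absorbed first-order with
   `ka [1/h] = 2·10⁴ · Peff [cm/s]` against a 0.25 h⁻¹ unabsorbed-loss
   rate — a deliberate single-stage reduction of intestinal transit,
   adequate because swallowed lacrimal drug is a minor pathway for these
   doses.

### Interface permeability assignment

Published parameter sets of this kind name one permeability per tissue,
not per interface. We assign interface permeabilities by a uniform
*inner-tissue rule*: the permeability named for a tissue governs exchange
across its outer-facing interface(s) (pre-cornea→cornea epithelium uses
the cornea-epithelium permeability, stroma→AH uses the AH permeability,
AH→ICB uses the ICB permeability, and the VH permeability serves both of
the vitreous entry routes from ICB and retina). The rule covers all ten
interfaces with the nine tissue permeabilities without special cases,
makes the AH permeability directly identifiable from AH data, and routes
the main AH elimination pathway through the ICB (ICB permeability × the
ICB systemic absorption rate), which is what lets the ICB absorption rate
constant set the AH elimination slope. The topology lives in one
declarative table (`ocular_topology()`) so it can be revised without
touching the solver.

### What the melanin model does and does not capture

Binding is linear: a single unbound fraction per drug, shared by all four
pigmented tissues, no capacity limit, no melanosome pH trapping. Because
passive fluxes are driven by the unbound concentration while the SAR
routes act on total amount, lowering `fu_melanin` raises the peak
pigmented-tissue concentration (less unbound back-flux out of the ICB)
and steepens total anterior-segment elimination. Saturable binding and
pH-partitioning into melanosomes are documented non-goals.

## Physiology and parameter provenance

The three printed tear-dynamics constants (1 min⁻¹ drainage; 5/7 µL tear
volume; 35/37 µL pre-cornea cap) are carried verbatim in the shipped
physiology files. Compartment volumes, exchange surface areas, aqueous
turnover and the systemic tissue volumes/flows are not printed in the
source parameterization (they are simulator defaults there); the shipped
YAML files populate them from standard ocular-anatomy and reference-PBPK
literature with a provenance note on every entry. All downstream
quantitative checks are deliberately *self-consistent* — parameters are
recovered from data the model itself generated — so none of them depends
on the accuracy of these anatomical stand-ins; they set the scale of the
simulated profiles, not the identifiability structure. The albino and
pigmented rabbit physiologies are identical except for the pigmentation
flags (enforced by test).

Units are normalized once at ingestion: amounts µg, volumes mL, time h,
concentrations µg/mL (tissue density 1 g/mL, so µg/g ≡ µg/mL);
percent fields become fractions; scale prefixes (10⁻⁷ cm/s and the like)
are resolved by the loader. Per-species parameter entries (blood/plasma
ratio, intestinal permeability, renal fraction, intrinsic clearance)
resolve to explicit rabbit/human pairs, with a single printed value
applying to both species.

The levofloxacin ICB absorption rate constant is stored at its
full-precision reported value (1.246·10⁻³ s⁻¹) rather than the
three-significant-figure table rounding (1.25·10⁻³).

## Partition coefficients

Perfusion-limited Kp values use a mechanistic tissue-composition equation
family: the fully uncharged microspecies equilibrates across membranes;
ionization (independent-site Henderson–Hasselbalch over the macroscopic
pKa set — the standard convention when only macroscopic constants are
known) is re-established at extracellular pH 7.4 and intracellular pH
7.0; neutral-lipid partitioning scales with `P = 10^logP` and neutral
phospholipid with `0.3 P + 0.7`:

`Kpu = f_ew + f_iw · X_iw/X_p + (P f_nl + (0.3P + 0.7) f_np)/X_p`, with
`X = 1/(fraction uncharged)` and `Kp = fu_plasma · Kpu`.

Acidic-phospholipid association of strong bases and plasma lipoprotein
binding are omitted from this reduction; a full per-tissue user override
is exposed (`calc_kp(..., override = )`) and recorded in the result, so
no downstream result is hostage to the Kp method choice.

## Dosing

The instilled amount is `drop volume (µL) × strength (% w/v) × 10` µg.
Whether an overflowing drop spills pre-mix or post-mix fluid is not
observable from the published description; we default to instantaneous
mixing followed by overflow at the mixed concentration (the conservative,
symmetric choice) and expose `mix = FALSE` to spill pure drop fluid
instead. Daily schedules ("four times daily") spread doses evenly over a
16-hour waking window starting at t = 0, because clinical reports rarely
state clock times; the window is a parameter.

## Numerics

`deSolve::lsoda` integrates the coupled system at `rtol 1e-8 / atol
1e-10` with a hard restart at every instillation event (the drop is an
instantaneous state update, not a forcing function). The tolerances are
deliberately tight: the tear film drains at 60 h⁻¹ next to tissue
exchange time-scales of hours, and the acceptance surface demands mass
conservation to 1e-6 and parameter recovery to 1%. Mass balance is audited
at every output point (compartments + terminal ledgers vs cumulative
instilled dose). Negative states beyond 100×atol raise an error rather
than being clipped. Halving the tolerances moves Cmax/AUC by far less
than 0.1% (tested).

## Parameter estimation

The objective is the sum of squared log residuals, `Σ (log(pred+ε) −
log(obs+ε))²` with `ε = LOQ/2`, because tissue concentrations span three
or more orders of magnitude across compartments; below-LOQ records
contribute one-sidedly, `max(0, log(pred) − log(LOQ))²`. Optimization is
in log10-parameter space (Brent for one parameter, Nelder-Mead with a
polish restart otherwise), multi-start (first start at the user's
initial values, the rest log-uniform in the bounds, seeded), at most four
free parameters per stage — mirroring the minimal-subset fitting
philosophy of the staged workflow: albino-rabbit permeabilities first,
then the melanin unbound fraction alone on pigmented-rabbit data with
everything else frozen. A sensitivity-correlation matrix is reported and
pairs with |r| > 0.98 flagged as a collinearity guard. The objective's
exact form inside the original commercial workflow is not disclosed;
recovery of the reported estimates from self-generated data is
independent of that choice.

## Synthetic data generator

`generate_study()` emulates the two designs behind published ocular
tissue PK: destructive rabbit sampling (a cohort per time point; mean ±
SD of n animals) and surgical human sampling (one specimen per subject at
the surgery time; individual values). Residual error is multiplicative
lognormal with `sdlog = sqrt(log(1+CV²))` — tissue PK dispersions are
reported as CV% — with an additive option deliberately left out of scope.
Default CVs (30% rabbit tissues, 50% surgical sampling, 95.3% for the
conjunctival-biopsy template, matching the dispersion reported for that
design) are stated assumptions: true inter-animal CVs per tissue are not
published in the main sources. An optional per-study lognormal multiplier
on the drainage rate constant (CV 30%, off by default) reproduces the
several-fold between-study spread of observed Cmax. The generator shares
the simulator with the fitting pipeline, so recovery tests demonstrate
*internal* consistency — estimator correctness, identifiability of the
chosen parameter subsets, seeded reproducibility — and say nothing about
model misspecification against real tissue data.

## Extrapolation and scenario analysis

`extrapolate_to_human()` re-runs the simulation with the human physiology
and verifies with a parameter diff that nothing drug-specific moved; with
the rabbit physiology swapped back it reproduces the rabbit run
bit-for-bit (tested). Exposure summaries are non-compartmental: linear
trapezoid AUC to the last grid point (no terminal extrapolation, since
ocular profiles are reported to finite horizons), Cmax with earliest-time
tie-breaking. Disease states are represented only as scenario labels plus
an optional tear-flow multiplier: `tear_flow_sensitivity()` scales the
drainage rate constant by `1 − reduction` over a grid (default {0, 0.6,
0.8}, the range relevant to anesthetic-induced tear-flow suppression
during ocular surgery), and AH exposure increases monotonically with the
reduction.

## Problem sizes

The shipped recovery suite uses single-drop studies sampled at 7 points
(0.25–24 h; 8 points to 48 h for the pigmented-rabbit melanin stage),
1–2 tissues, noise-free, with two-parameter refits started at 5× (10× for
the melanin fraction) the recorded values — the smallest designs on which
all fitted parameters are cleanly identifiable, which keeps a full
recovery run to minutes on one CPU. The synthetic-CV check uses 1000
subjects at one time point.

## Known limitations

- Interface surface areas and compartment volumes are literature
  stand-ins, not the original simulator's defaults; absolute predicted
  concentrations should be calibrated against observed data before any
  quantitative use.
- Lens is omitted (no published permeability parameter for it);
  suspensions/ointments, intraocular injections, protein binding in
  tears, saturable melanin binding and age/disease physiologies are out
  of scope.
- The systemic model is a reduced single-gut-stage PBPK intended to close
  the mass balance and supply plasma back-partitioning, not to reproduce
  every published IV/oral study.
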