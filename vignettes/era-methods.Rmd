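---
title: "Methods: tiered environmental risk assessment of veterinary medicinal products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered environmental risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetera)
```

## The problem

Veterinary antibiotics administered to intensively reared livestock are
excreted with manure, spread on arable land, and can move from soil into
groundwater, surface water and sediment. Regulatory assessment asks a
yes/no question per environmental compartment: does the predicted
concentration (PEC) stay below the concentration at which no adverse
ecosystem effect is expected (PNEC)? `vetera` implements that tiered
decision tree end to end for the manure-spreading exposure route, together
with the calibration arithmetic needed to compare the predictions with
LC-MS/MS surface-water measurements.

## Phase I exposure model and its assumptions

Phase I uses the *total-residue approach*: the entire administered dose is
assumed excreted unmetabolized and to survive manure storage — a deliberate
worst case that requires no substance-specific fate data. Manure is applied
up to the EU nitrogen ceiling and mixed into the plough layer:

$$PEC_{soil} = \frac{D \cdot A_d \cdot F_h \cdot H \cdot lr_N \cdot 1000}
{\rho_b \cdot A \cdot d}$$

| symbol | meaning | default | unit |
|---|---|---|---|
| $D$ | daily dose | scenario input | mg/kg bw/day |
| $A_d$ | treatment duration | scenario input | days |
| $F_h$ | fraction of herd treated | 1 (worst case) | — |
| $H$ | composite husbandry factor | registry | kg bw·cycles / kg N |
| $lr_N$ | nitrogen ceiling | 170 | kg N/ha |
| $\rho_b$ | dry soil bulk density | 1500 | kg/m³ |
| $A$ | reference area | 10000 | m² |
| $d$ | mixing depth | 0.05 | m |

$H = BW \cdot N_{cycles} / N_y$ collapses the guideline's per-species
husbandry defaults (body weight, production cycles per place-year, nitrogen
excreted per place-year) into one scalar, so the Phase I formula needs no
further animal inputs. The shipped registry covers piglets, chickens and
turkeys with factors *back-derived* from published worst-case soil PECs for
a 250 mg/g benzylpenicillin product (the inverse formula is exposed as
`derive_husbandry_factor()` and re-checked by the test suite at 4
significant figures). Users assessing other species must supply their own
$H$ or the $BW/N_{cycles}/N_y$ triple via `composite_husbandry_factor()` —
the registry refuses unknown species rather than guessing.

Two resolutions of ambiguity are fixed here and not revisited: a labelled
"3–4 consecutive days" regimen is shipped as $A_d = 4$ (worst case,
configurable per regimen), and $F_h$ defaults to 1, consistent with the
total-residue philosophy. The decomposition of the shipped $H$ values into
their husbandry triple is not recoverable from the published chain and is
not claimed.

If every species' $PEC_{soil}$ is at or below 100 µg/kg the assessment
stops at Phase I. The trigger is **strict** (`> 100`): the governing text
says "greater than", and the boundary case is resolved in favour of
stopping.

## Phase II Tier A partitioning

With the linear soil–water partition factor
$f = 0.1176 + 0.01764 \cdot K_{oc}$ (L/kg):

- groundwater takes the residue rediluted over the 20 cm layer:
  $PEC_{gw} = (PEC_{soil} \cdot 5/20)/f$;
- surface water takes pore water of the 5 cm layer diluted 3-fold:
  $PEC_{sw} = (PEC_{soil}/f)/3$;
- sediment accumulates from surface water by the suspended-matter factor:
  $PEC_{sed} = PEC_{sw} \cdot (0.783 + 0.0217 \cdot K_{oc})$.

The 20 cm/5 cm assignment is the only one consistent with both published
water figures of the worked example (28.24 and 37.66), and implies the
identity $PEC_{sw} = PEC_{gw} \cdot 4/3$ under default depths — kept as a
property test. Molar mass, solubility and vapor pressure are stored and
reported but enter no Tier A equation; they are metadata for this chain.

**The partition-factor override.** The worked example's published chain is
internally consistent only with $f = 7.69$ L/kg, while its stated
$K_{oc} = 421$ evaluates to $7.544$ (the sediment factor, by contrast,
matches $K_{oc} \approx 421$). Rather than silently adopting either number,
`substance_properties()` carries an optional `partition_factor_override`
used verbatim when present; the worked-example fixture sets 7.69, new
substances default to the computed value. The inconsistency is recorded,
not resolved.

**The stored sediment value.** The worked example's sediment PEC
(1721 µg/kg) is about 4.6× what the suspended-matter formula yields and its
derivation is not reconstructable; it is therefore carried as an explicit
`sediment_override`, never guessed at. Inside the species matrix the
override acts as an effective accumulation factor
(override / worst-case $PEC_{sw}$) applied to every species, which keeps
the matrix homogeneous of degree one in dose — the property tests rely on
that.

Units are fixed per compartment (µg/kg dry weight for soil and sediment,
µg/L for waters); conversions are centralized in `convert_unit()`, which
refuses cross-dimension conversions. Rounding happens only when rendering
reports (2 decimals for concentrations, 3 for risk quotients); stored
values keep full precision.

## Effects: PNEC derivation

The assessment-factor route divides each experimental endpoint by its AF
and takes the minimum per compartment. AFs are **data** on the endpoint
rows, not hard-coded logic; when a row omits its AF a conventional ladder
fills it (10 for a chronic NOEC, 1000 for a single acute EC50/LC50) — the
shipped fixture rows all carry explicit AFs (10 for the algae NOEC, 100 for
the activated-sludge EC50 and the earthworm NOEC).

The equilibrium-partitioning route translates the water PNEC to solids:
$PNEC_{soil} = f \cdot PNEC_{water}$ and
$PNEC_{sed} = (0.783 + 0.0217 K_{oc}) \cdot PNEC_{water}$. Where both
routes produce a candidate the **lower** is selected; where a compartment
has no experimental endpoint (sediment, in the worked example) the
equilibrium value stands alone. A published statement that the sediment
AF-route PNEC "is 1 mg/kg" is read here as the water PNEC restated — no
sediment organism data exist in the input table — hence the EP-only rule
for that case; supplying a sediment endpoint row switches the compartment
to the min rule automatically.

Highly sensitive endpoints quoted in the literature around the worked
example (blue-green algae NOEC 0.78 mg/L; insensitive species at 300 mg/L)
are *not* in the active fixture because they enter no published
calculation; adding the 0.78 row would lower the water PNEC to 0.078 mg/L
and is exactly the kind of sensitivity a user can explore by editing
`endpoints.csv`.

## Risk engine

$R = PEC/PNEC$ after unit harmonisation, per species × compartment.
Conclusions: `phase1_stop` (no species triggers), `acceptable_R_lt_1` (all
quotients below 1), else the refinement path. Refinement multiplies the
total-residue exposure by three fractions in (0, 1] — excreted
unmetabolized, remaining after manure degradation, remaining after soil
degradation — with identity defaults, so an unrefined run is untouched.
If refined quotients all fall below 1 the conclusion is `refine_pec`;
otherwise `refine_pnec` marks that effect refinement would be required
next. The refinement branch is implemented as these parametric hooks only:
the worked example never exercises it, and no degradation kinetics are
modelled.

Every intermediate (Phase I PECs, trigger flags, partition factor, Tier A
PECs, each PNEC candidate and selection, each quotient, refined quotients)
is appended to an ordered trace with its conventional symbol; the test
suite checks that every number in the rendered tables appears in the trace.

## Calibration and quantification

`fit_calibration()` is unweighted ordinary least squares of peak area on
concentration — the source states no weighting, so none is the default —
with 1/x and 1/x² weighting available because a 4–5000 ng/L range would
normally warrant it. $\sigma$ is the residual standard deviation of the
areas with the $n-2$ denominator; with exactly two points the fit is
saturated, $\sigma = 0$ by convention and the fit is flagged. "Correlation
coefficient $R^2$" in method-validation prose conflates $r$ and $R^2$; the
coefficient of determination is implemented. $LOD = 3.3\sigma/p$ and
$LOQ = 10\sigma/p$ take $\sigma$ as an explicit input, because whether a
published $\sigma$ comes from the full curve or from low-level replicates
is often unstated — the formula is applied as written.

Back-calculation inverts the line; results are classified `not_detected`
below LOD, `detected_not_quantifiable` in [LOD, LOQ), `quantified` at or
above LOQ. The worked example's calibration intercept is not published; the
shipped 239.0 is back-derived from its printed (area 1748, 32.452 ng/L)
pair and that derivation is frozen as a test oracle.

## What the synthetic generator emulates — and does not

`simulate_calibration()` draws replicate areas from the stated validation
design: 10 injections at each of 4, 20, 100, 500 and 5000 ng/L on the line
$area = 46.5 \cdot c + 239$ with homoscedastic Gaussian noise of SD 0.43
(the published residual SD). Real LC-MS/MS calibrations are
heteroscedastic over such a range, show occasional carry-over and drift,
and their low-level replicates dominate the practical detection limit; none
of that is emulated. A green parameter-recovery test therefore establishes
that the OLS/LOD/LOQ arithmetic is correct, not that the instrument method
itself would validate. The monitoring fixture (three non-detects and one
quantified sample) is likewise a constructed stand-in for real
chromatograms: peak detection and integration are out of scope, areas are
taken as given.

## Numerical conventions

- No rounding inside computations; rendering rounds concentrations to 2
  decimals and quotients to 3.
- Ties for the worst-case species break by declaration order, recorded in
  the trace.
- Degenerate inputs fail loudly: zero/negative partition factor, PNEC ≤ 0,
  unknown species, unit/dimension mismatches, identical calibration levels.
- The fixture generator is deterministic per seed and restores the
  caller's RNG state.

## Known limitations

- Only the manure-to-arable-land route: no pasture/direct excretion, no
  aquaculture branch, no DT50 degradation kinetics, no groundwater
  0.1 µg/L pesticide-style threshold, no antimicrobial-resistance risk.
- Tier A only; Tier B study designs are not modelled.
- The husbandry registry ships three species; everything else requires
  user-supplied factors.
- The two worked-example overrides (7.69 L/kg; 1721 µg/kg) reproduce a
  published chain whose internal inconsistencies they deliberately leave
  visible rather than repair.
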