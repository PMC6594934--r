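---
title: "A box-model account of why a warmer ocean can end up with more oxygen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A box-model account of why a warmer ocean can end up with more oxygen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mechanism

Warming lowers oxygen solubility, so the intuitive long-term outcome of a
warmer ocean is deoxygenation. `oxybox` implements, at box-model scale, the
counterintuitive alternative: when expanding oxygen-deficient waters shift
part of the ocean's respiration from oxygen to nitrate (denitrification),
every mole of nitrate lost spares the oxygen that aerobic respiration of
the same organic matter would have consumed. If nitrogen fixation does not
promptly replace the lost nitrate, the accumulated fixed-nitrogen deficit
is, mole for mole, an *oxygen gain* — large enough, over millennia, to
overcompensate the solubility loss.

The oxidant bookkeeping is fixed by the organic-matter stoichiometry
C:N:P:-O~2~ = 112:16:1:169.6. Aerobic remineralisation consumes 169.6 mol
O~2~ per mol P, i.e. 10.6 per mol organic N; denitrification of the same
material consumes 119.68 mol NO~3~ per mol P (7.48 per mol organic N) and
no oxygen. Hence each mole of nitrate lost spares
169.6 / 119.68 ≈ 1.417 ≈ 1.4 mol O~2~, and a nitrate-inventory loss of,
say, 6.2 Pmol is equivalent to an 8.8 Pmol oxygen gain. These four numbers
are `o2_demand_per_orgN()`, `no3_demand_per_orgN()`, `o2_per_no3_lost()`
and `o2_equivalent_of_nitrate_loss()`.

Two accounting choices make this bookkeeping close *exactly* in the model,
not just approximately:

* During denitrification the 119.68 mol NO~3~ per mol P is the gross
  electron-acceptor consumption and the organic nitrogen is returned to
  the fixed pool, so the nitrate tracer loses 119.68 − 16 = 103.68 at the
  remineralisation step and the full production-to-denitrification cycle
  (production consumed 16 mol NO~3~ that is never returned) loses exactly
  119.68 per mol P. This is also electron-exact: oxidising one P of
  organic matter to CO~2~ and nitrate transfers 4 × 169.6 = 678.4
  electrons, and with the organic N retained as fixed N the nitrate demand
  is 678.4 − 80 = 598.4 electrons at 5 per NO~3~, i.e. 119.68.
* Ordinary (nitrate-fuelled) production releases the full 169.6 mol O~2~
  per mol P, so the aerobic loop is oxygen-neutral. Diazotroph production
  releases 169.6 − 16 × 1.417 ≈ 146.9: the newly fixed nitrogen still has
  to be oxidised to nitrate, at the same 1.417 mol O~2~ per mol N
  bookkeeping rate. Nitrogen fixation is therefore a net oceanic oxygen
  sink of ≈ 1.4 mol O~2~ per mol N fixed — the mirror image of the
  denitrification source.

With these two choices the model satisfies, pathwise and at machine
precision, the two budget identities the diagnostics report:

1. ΔO~2~ inventory = cumulative air–sea flux + 1.417 × (net NO~3~ loss)
   (`decompose_budget()$residual_primary`, typically 1e−12 Pmol over a
   6000-year run), and
2. d(NO~3~ inventory)/dt = fixation − denitrification, exactly as
   accumulated by the flux integrals.

## Geometry and circulation

The default geometry has six boxes (volumes summing to 1.3 × 10^18^ m³):
three surface boxes — a warm low-latitude surface (22 °C) where nitrogen
fixers can grow, a cold Southern Ocean surface (4 °C), and a northern
surface (8 °C) — and three interior boxes: a poorly ventilated OMZ core
(0.9 × 10^17^ m³) that is suboxic with active denitrification already in
the control climate, a surrounding thermocline (1.65 × 10^17^ m³) that is
oxic in the control climate, and the deep ocean (0.99 × 10^18^ m³). An
overturning loop (25 Sv) runs low-latitude surface → Southern Ocean
surface → deep → thermocline, i.e. deep water forms at the cold southern
surface; bilateral mixing ventilates the OMZ core from the low-latitude
surface and connects the remaining neighbours.

This is the smallest topology on which the full mechanism can be *seen*:

* the OMZ core hosts control-climate denitrification;
* the thermocline box can cross below the 5 mmol m⁻³ threshold under
  warming, which is how a box model expresses a spatially expanding
  suboxic volume (a single OMZ box is either suboxic or not — its volume
  cannot grow);
* the cold southern surface is below the 15 °C diazotroph cutoff, so
  nitrate-deficient water upwelled there is subducted into the deep ocean
  without meeting nitrogen fixation — the loophole that lets deficits
  escape the fixation feedback.

With two potential suboxic boxes the warming experiment expands the
time-mean suboxic volume by a factor ≈ 2.7.

## Ecosystem closure

Biology is deliberately not prognostic. Production is
`mu_max × min(Monod terms) × biomass_proxy`, a nutrient-restoring-like
closure: the inventory-level mechanism needs realistic nutrient drawdown
and export, not plankton dynamics. Ordinary phytoplankton take the Liebig
minimum of NO~3~ (k = 1.6 mmol m⁻³) and PO~4~ (k = 0.1) limitation;
diazotrophs are phosphate-only (k = 2.5, a deliberately poor affinity:
they are excluded while ordinary producers keep phosphate low), grow at
most at 18 yr⁻¹ against 40 yr⁻¹ (the model enforces the less-than-half
constraint), and not at all below 15 °C (a hard step, as specified, not a
ramp). A per-box production efficiency (1.0 / 0.15 / 0.5 for the three
surface boxes) stands in for the light and micronutrient limitations a
box model cannot resolve; the low Southern Ocean value is what keeps that
box nutrient-rich and biologically inefficient.

The stabilising feedback that sets the control steady state runs through
phosphate: more nitrate → stronger (N-limited) ordinary production →
lower surface phosphate → less fixation; meanwhile more export → more
OMZ oxygen demand → more denitrification. The spun-up state settles with
fixation = denitrification ≈ 9 Tmol N yr⁻¹ (≈ 23% of the 38 Tmol N yr⁻¹
NCP in nitrogen units), surface phosphate ≈ 1 mmol m⁻³ and strongly
negative deep N* ≈ −16 mmol m⁻³ — the stored signature of past
denitrification.

Export is remineralised instantaneously in the interior boxes it is routed
to (default low-latitude partition 0.22 / 0.45 / 0.33 to OMZ core,
thermocline, deep). Remineralisation is aerobic at or above
5 mmol O~2~ m⁻³ and uses nitrate strictly below; at exactly the threshold
the pathway is aerobic. Within a step, aerobic consumption is additionally
capped by the oxygen the box holds and denitrification by its nitrate;
organic matter that finds neither oxidant cascades to the next deeper box
and is ultimately returned to the deep phosphate pool without oxidant
demand — the run aborts if this remainder ever exceeds 1% of export,
because systematic nitrate exhaustion would invalidate the budget
accounting (in the default runs the remainder is zero).

Faster, and hence shallower, remineralisation in a warmer ocean is
represented by a single sensitivity: the low-latitude export partition
shifts toward the thermocline box by 0.015 per °C of local surface
warming. This mechanism measurably deepens the simulated TOU decline — it
is one of the two drivers (with the overturning recovery) of the stored
respiratory deficit shrinking — and is on by default because the study
this model dissects identifies it as an operating mechanism; setting
`remin_t_sens = 0` turns it off.

## Tracers and the budget decomposition

Four idealised tracers carry the accounting. *Ideal age* ages at
1 yr yr⁻¹ in the interior and is held at zero at the surface; on a
two-box reduction its steady state is exactly V/ψ, one of the test-suite
oracles. *Abiotic O~2~* feels only transport, solubility and gas exchange
— its decline isolates the solubility component (−27.1 Pmol in the
default warming run). *Preformed PO~4~* is set identical to PO~4~ in the
surface boxes at the end of every step and is otherwise passive. *TOU*,
the true oxygen utilisation, is 169.6 × (PO~4~ − preformed PO~4~): the
oxygen equivalent of regenerated phosphate, free of the
surface-disequilibrium bias of AOU (which the package also computes, for
comparison only). TOU is pathway-blind — denitrified regeneration raises
it without any oxygen having been spent — and that is precisely why the
fixed-nitrogen loss appears as an interior oxygen source in the budget.

The per-step order of operations is fixed: transport → biology → gas
exchange → preformed reset. Gas exchange uses an exact within-step
relaxation toward saturation (Garcia–Gordon fit at fixed salinity 35, in
a fixed-atmosphere approximation: the air holds two orders of magnitude
more oxygen than the sea), which keeps the piston-velocity → ∞ limit
well-posed; the realised concentration change, not a quadrature, is
accumulated into the cumulative flux integral, so budget closure is exact
bookkeeping.

The secondary identity — cumulative flux ≈ Δ(abiotic) + Δ(−TOU) — holds
approximately on any run and becomes exact in the infinite-piston-velocity
limit *in a purely aerobic ocean*. With denitrification active the
identity carries a structural transient term (TOU's pathway blindness
again), which is why the test suite checks the limit on an aerobic
configuration and merely reports the residual for the warming run.

## The warming scenario

Emissions and climate dynamics are out of scope; the experiment prescribes
what the mechanism actually feels. Per-box temperature anomalies are
lagged logistics (surface midpoints near year 2150, deep near 2800), zero
at 1850 by construction and rescaled by a single factor so the
volume-weighted mean anomaly is exactly 3.1 °C at year 3380. The
amplitude pattern keeps the Southern Ocean surface below 15 °C throughout,
preserving the loophole. The overturning factor dips to ≈ 0.6 around year
2150, recovers through a maximum near year 3080 and levels off at 1.05.
The generator is deterministic (a seed is consumed only if forcing noise
is explicitly enabled) and forcing round-trips through CSV so external
trajectories can be swapped in.

## What the default experiment shows

```{r}
library(oxybox)
cfg <- ox_config()
state <- spinup(cfg)
warm <- run_simulation(cfg, state, make_warming_scenario(geometry = cfg$geometry))
ctrl <- run_simulation(cfg, state, make_control_scenario(geometry = cfg$geometry))
report(warm, ctrl)
```

From the spun-up state (O~2~ inventory 148.7 Pmol, NO~3~ 24.4 Pmol), the
warming run first loses 8.6 Pmol of oxygen (minimum near year 2600), then
recovers and ends 4.2 Pmol *above* pre-industrial. The decomposition over
the full run: abiotic O~2~ −27.1 Pmol (solubility), TOU −31.0 Pmol
(smaller stored respiratory deficit), cumulative air–sea flux −1.3 Pmol,
and +5.5 Pmol from the 3.9 Pmol net nitrate loss at 1.417 mol O~2~ per mol
NO~3~ — with a closure residual of order 10⁻¹² Pmol. Denitrification
roughly doubles at its peak; fixation begins its sustained rise about
300 years later (onset-to-onset, see below), because the nitrogen deficit
must first upwell into warm, fixation-capable water; NCP dips ≈ 16% during
the overturning minimum and recovers; the time-mean suboxic volume expands
2.7-fold as the thermocline box crosses the threshold; deep N* drops by a
further 3 mmol m⁻³.

The counterfactual (`instant_fixation_config()`) makes the diazotroph
community effectively unlimited: any step-level imbalance between
denitrification and prognostic fixation is topped up immediately as a
uniform (volume-weighted, hence mostly deep) nitrate increment, with the
nitrification-equivalent oxygen cost paid through the surface. Its nitrate
inventory is conserved to 10⁻¹³ Pmol, its oxygen change is flux-only, and
the difference between the two runs' interior-gained oxygen
(ΔO~2~ − flux) equals the default run's nitrate-loss equivalent to
machine precision — the cleanest statement that the oxygen excess is
bought with fixed nitrogen. (A counterfactual built instead by handing the
default diazotroph parameters their structural maxima equilibrates to a
visibly different control ocean and muddles this comparison; that is why
the compensation mode exists.)

## Numerical choices and their consequences

* **Forward Euler at dt = 0.05 yr** with exact flux bookkeeping. The
  budget identities are then bookkeeping identities, not quadrature
  approximations; halving dt moves the decomposition by < 0.05 Pmol.
* **The hard suboxic switch makes the steady state statistical.** The OMZ
  core flickers in an O(dt) band just below the threshold
  (4.92–5.00 mmol m⁻³ at dt = 0.05): an aerobic burst at the threshold
  overshoots it by one step's consumption, then supply rebuilds. Spin-up
  convergence is therefore measured on consecutive 500-year chunk-*mean*
  states (default tolerance 10⁻⁶ yr⁻¹, reached after ≈ 8000 years); a
  raw-tendency criterion would never converge below ≈ 10⁻⁵ yr⁻¹. For the
  same reason annual denitrification rates are bursty, and the
  onset-detection rule (first exceedance of the control mean + 2 σ
  sustained 10 years) operates on 21-year running means, with the
  threshold offset floored at 5% of the control mean so that a
  noise-free control series cannot flag infinitesimal drift.
* **Tie-breaks and floors.** At exactly 5 mmol m⁻³ remineralisation is
  aerobic; uptake and remineralisation are capped so no tracer is driven
  negative within a step; any residual negative concentration from
  transport is clipped to zero and logged (the default runs clip nothing).
* **Problem sizes.** The shipped analyses use the 6-box geometry, 6150-year
  scenarios at dt = 0.05 (annual output) and a spin-up of ≈ 8000 years —
  sizes chosen so the full pipeline (spin-up plus three scenario runs)
  completes in a few minutes on a single core while keeping the flicker
  band an order of magnitude below any quantity the diagnostics compare.

## What the model does and does not show

Passing runs demonstrate the *mechanism*: exact oxidant bookkeeping, the
sign pattern (transient deoxygenation, then overshoot; net fixed-N loss;
lagged fixation; expanding suboxia) and the budget decomposition that
attributes the gain. Box-scale magnitudes are not the 3D ocean's: a
six-box ocean has residence times, nutrient inventories and
denitrification throughput on its own scales, so headline 3D numbers
(total inventories, percent changes, the 25-year lag) are reproduced in
sign and ordering, not in value. Also absent, deliberately: sediments and
weathering (phosphorus is strictly conserved), iron, the sulfur cycle,
variable stoichiometry, carbonate chemistry, seasonal cycles, and any
feedback of oceanic oxygen on the (fixed) atmosphere.
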