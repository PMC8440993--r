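---
title: "Modelling blood and tissue gas dynamics in diving sea turtles"
author: "gasdive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blood and tissue gas dynamics in diving sea turtles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasdive)
```

## The problem

Air-breathing marine vertebrates load nitrogen into blood and tissue while
submerged; if dissolved gas comes back out of solution faster than the
circulation can return it to the lung, intravascular bubbles form (gas
embolism, GE).  Sea turtles caught at depth in fishing gear show exactly this
pathology.  `gasdive` implements a baseline compartmental model of N~2~, O~2~
and CO~2~ exchange in loggerhead, leatherback and green turtles, driven by
time-depth-recorder (TDR) dive profiles, so that end-dive mixed venous
N~2~ tension — the conventional index of decompression stress — can be
estimated for routine diving and for perturbations of body condition and
cardiac output.

## Model structure

The body is a lung plus four perfusion-limited compartments — brain,
fat/bone, central circulation (heart, kidney, liver, gut), and muscle (muscle
plus skin, connective tissue and everything else) — linked by arterial and
mixed venous blood.  Gas moves only down partial-pressure gradients.

**Surface (breathing).**  Breathing starts the instant depth reaches 0 m.
Arterial and faveolar tensions snap to the surface constants
$P_{N_2} = 0.741$, $P_{O_2} = 0.164$, $P_{CO_2} = 0.033$ ATA (water vapor
0.062 ATA; the four sum to 1 ATA), and each compartment relaxes toward them.
While breathing, ventilation is assumed to match metabolism, so surface
equilibrium is an exact fixed point of the integrator — a property the test
suite checks to machine precision.

**Diving.**  At each descent the lung holds the diving lung volume
(DLV, a fraction of total lung capacity TLC, default 1) at surface
composition.  At ambient pressure $P$ (1 ATA + 1 ATA per 10 m):

* the total lung gas volume follows Boyle's law at the dry-gas pressure,
  $V_{tot} = S_{tot}/(P - P_{H_2O})$, with $S_{tot}$ the current gas store;
* the conducting-airway dead space (7 % of TLC at the surface for all three
  species) compresses as
  $V_D(P) = V_{D0}\,[r + (1-r)\,(1 + (P-1)/|K_p|)^{-n}]$ with $K_p = -6.44$,
  $n = 0.74$ and a rigid, cartilage-supported fraction $r$;
* the faveolar (gas-exchanging) volume is the remainder,
  $V_{fA} = \min(V_{fA,max},\,\max(0, V_{tot} - V_D))$, and gas exchange
  stops the moment $V_{fA} = 0$;
* the pulmonary shunt is
  $s = s_0 + (1-s_0)(1 - V_{fA}/V_{fA,max})^{\gamma}$, reaching 1 at
  collapse;
* arterial tension per gas is the shunt-weighted mix
  $P_a = (1-s)\,P_{fav} + s\,P_{\bar v}$;
* each compartment $i$ receives the phase's flow fraction $f_i$ of total
  cardiac output $\dot Q_{tot}$ and relaxes toward arterial with rate
  $k_i = \dot Q_i\,\beta_b / (V_i\,\beta_i)$ (solubility-weighted
  perfusion), consuming O~2~ and producing CO~2~ at the diving metabolic
  rate;
* mixed venous tension is the flow-weighted mean of the compartment
  (venous-equilibrated) tensions.

Blood is a transit medium: arterial and mixed venous tensions are
instantaneous mixes, and the conserved whole-body inventory is the lung
store plus the tissue stores (dissolved everywhere, plus myoglobin-bound
O~2~ in muscle).  The lung store is debited by the exact tissue store
changes each step, so a sealed, non-collapsed submergence conserves each
gas inventory to numerical round-off (the suite requires
< 0.01 % drift per hour and observes ~10^-13^).  During full collapse the
flow-weighted redistribution of gas between compartments leaves a
negligible bookkeeping residual in that inventory; the lung itself is
frozen, and arterial equals mixed venous.

O~2~ is carried in blood as Hill-saturated hemoglobin plus dissolved gas,
$C_{O_2}(P) = 1.34\,[Hb]\,P^{h}/(P_{50}^{h}+P^{h}) + \beta_{O_2} P$ with
$h = 2.7$ for all species; muscle additionally stores O~2~ on myoglobin with
a hyperbolic curve.  If a compartment exhausts its O~2~, the tension floors
at zero, the sample is flagged as an event, and the run continues.

## Parameters

Species physiology (`speciesParams()`): mass-specific TLC is 64 ml kg^-1^
(leatherback), 115 (green) and allometric
$(113.6\,M^{0.923})/M$ (loggerhead); [Hb] 0.156/0.098/0.088 g ml^-1^,
P~50~ 40/47/25 mmHg, [Mb] 4.9/2.9/2.9 g kg^-1^ muscle.  Two unit
interpretations are deliberate and recorded in every run manifest: printed
hemoglobin figures of order 0.1 "g/dl" are read as g ml^-1^ (a tenth of a
gram per decilitre of blood would be two orders of magnitude below any
vertebrate), and P~50~ is taken in mmHg and converted to ATA by /760.

Body composition (`bodyComposition()`): control 7 % blood, 0.06 % brain,
30 % fat/bone, 9 % central circulation, 53.94 % muscle; the obese and
emaciated variants move fat/bone to 40 % and 20 %.  Muscle is always the
residual compartment so the five fractions sum to exactly 100 % — the
printed emaciated muscle figure does not close its row, and the residual
rule (61.934 %) is used instead.

Circulation (`surfaceSqtot()`, `turtleConfig()`): surface mass-specific
cardiac output scales allometrically from 8.4 ml min^-1^ in a 1.2 kg
reference animal, $s\dot Q_{tot} = (8.4/1.2)(M/1.2)^{-0.25}$, i.e.
7 ml min^-1^ kg^-1^ at the reference mass.  Diving cardiac output is 5 % of
surface.  Flow splits are 60/34/4/2 % (central/muscle/brain/fat-bone) at the
surface and 92.8/5.0/2.0/0.2 % while diving.  Metabolic rate is
4.23 ml O~2~ min^-1^ kg^-1^ at the surface and 5 % of that (0.21) while
diving, applied mass-specifically per compartment.

Gas solubilities (`gasConstants()`) are literature-standard Ostwald
coefficients — N~2~ 0.0144 ml ml^-1^ ATA^-1^ in lean tissue and blood,
0.067 in fat, O~2~ dissolved 0.0236, CO~2~ effective 0.47 (no full
dissociation curve) — all configurable.  The respiratory quotient defaults
to 1 and the myoglobin half-saturation tension to 3 mmHg; both are exposed
in `turtleConfig()`.

The seven configurations of the experiment suite change exactly one knob
each: body condition (obese / emaciated), surface cardiac output (10 or
2.5 ml min^-1^ kg^-1^), or the diving fraction (3.3 % `dive_high`, 10 %
`dive_low`; the labels name the direction of nitrogen-risk contrast, not of
flow, so the numeric fraction is always stored alongside).

## Lung-mechanics calibration

The compression model's two shape constants were fixed once, against the
stated physiology rather than any field outcome, and are not tuned
per-run:

* **Rigid airway fraction $r = 0.25$.**  With a fully compliant dead space
  the faveolar volume never reaches zero (total lung volume, falling as
  $1/P$, can never be overtaken by a dead space falling to zero), so no
  collapse depth exists; with too stiff an airway, collapse is implausibly
  shallow.  $r = 0.25$ puts the half-lung green-turtle collapse at
  `r round(10 * (collapsePressure(lungGeometry("green", 70, dlvFraction = 0.5)) - 1))` m,
  squarely consistent with forced-submergence observations that lung
  diffusion is essentially absent beyond 90 m yet barely impaired at 30 m:
  at 30 m a majority (~52 %) of the remaining lung gas still sits in the
  faveoli, while at 90 m the faveolar volume is ~0.2 % of maximum.
  The inverse-power form of the compliant decay keeps $V_{fA}$ continuous
  and monotone in pressure (a clipped power law that lets the airway volume
  vanish at finite pressure would make the faveoli spuriously re-expand).
* **Shunt exponent $\gamma = 12$.**  Chosen so that on a full lung the
  shunt is below 10 % at 30 m but dominant near a 19.4 ATA forced-dive
  apex, reproducing the observed shape of arterial PN~2~ under step-wise
  compression: a rise during early descent and a plateau once the collapsed
  lung drops out of the circuit (`forcedDiveScenario()` packages this run).

The faveolar pressure-volume constants $a = 1.04$, $b = 0.20$, $c = 1.21$
of the human-alveolus parameterization are carried in `lungGeometry()` and
in manifests for provenance; the condensed realization above does not need
them.

## Numerical choices

The integrator advances each compartment and gas with the exact exponential
solution of the linear relaxation over each step (piecewise-constant
coefficients), so it is unconditionally stable at the native 1 Hz step and
exactly reproduces the closed-form single-compartment response — the test
suite verifies agreement to well within 0.1 %, and halving the step changes
end-dive mixed venous PN~2~ by far less than 0.5 %.  For O~2~ the blood
content slope is taken as the secant of the Hill-plus-dissolved content
curve between arterial and tissue tension (the exact flux coefficient), and
the muscle capacitance includes the local myoglobin slope.  Tensions and
stores are floored at zero with flagged events rather than allowed to go
negative.  Depth 0 is the surface by definition; the dive/surface phase is
decided per sample.

Dive records are linearly interpolated to 1 Hz, then a 2 m offset is
subtracted and depths clamp at 0, so that every breathing event sits at the
surface; clamping after subtraction is immaterial for linear interpolation
but is the documented order.  A dive is any maximal run of samples with
depth > 0 — no minimum-depth threshold — and runs touching the record edges
are flagged truncated and excluded from end-dive metrics.  Depth bins use
the operational boundaries shallow < 30 m ≤ medium ≤ 90 m < deep.

End-dive PN~2~ is the arithmetic mean of mixed venous PN~2~ over the final
5 s of each dive (a configurable window; shorter dives use all samples and
are flagged).  Variant effects are $100\,(variant - control)/control$ per
bin, for the mean and the maximum.  The supersaturation ratio defaults to
the surface-referenced reading $P_{N_2}/0.741$, which reproduces the
published M-ratios (12.7, 8.3, 6.8 from the species maxima 9.40, 6.17,
5.03 ATA); the ambient-referenced field $(P_{N_2}-P_{amb})/P_{amb}$ is
computed alongside.

## The synthetic dive-bout generator

No TDR records ship with the package, so `generateBout()` emulates them:
each dive draws a depth bin from the spec's proportions, a duration and a
maximum depth from truncated normals (durations truncated at 10 s, depths
at 1 m and at the bin boundaries, so every dive realizes its drawn bin),
and is shaped as a descent-bottom-ascent trapezoid with 40 % bottom time
and a brief 15 s pause at 15 m on deeper ascents — mirroring the ascent
pause seen in all three species.  Surface intervals are truncated normal
with mean 120 s, SD 60 s; they are not recoverable from published
summaries, and the choice is declared, not inferred.  Sampling is by
inversion, so a spec's seed fixes the series exactly and the caller's RNG
state is untouched.  Specs mirroring the thirteen published individuals
(Dc1-Dc6, Cc1-Cc3, Cm1-Cm4) ship as YAML (`referenceBoutSpecs()`).

Where the published mean is small relative to its SD (e.g. shallow-bin
durations of 209 ± 251 s), left-truncation at 10 s necessarily raises the
realized mean above the nominal one — no truncated normal attains such
moments.  The generator therefore converges to the *analytic
truncated-normal* mean, which the property tests check; real dive-duration
distributions are strongly right-skewed, and a skewed family would be the
natural refinement.  The generator also makes no attempt at behavioural
dive-shape taxonomy (U/V/W dives), seasonality, or depth-dependent surface
intervals; passing its tests shows the pipeline handles realistically
*structured* records, not that it reproduces any individual animal.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes the package chooses: the qualitative field-result checks use one
600-dive bout (200 dives per depth bin, matched 600 ± 100 s durations so
the bin contrast isolates depth, 300 s surface intervals for clear washout
between dives), a 12 h constant-depth submergence for the compartment
half-time ordering, hour-scale runs for the conservation and fixed-point
checks, and 500-2000-dive bouts for generator fidelity.  A day-long 1 Hz
simulation takes well under a second.

## Known limitations

* Blood has no standing volume in the dynamics; arterial and venous pools
  are instantaneous mixes.  The 33/67 % arterial/venous split is carried in
  the configuration for store accounting and reporting only.
* With the default 120 s surface intervals, long repeated dives accumulate
  an O~2~ debt in muscle (delivery while diving is a fraction of demand and
  surface intervals are short); the model flags the resulting tension
  floors as events.  N~2~ kinetics — the quantity of interest — are
  unaffected.
* Tissue N~2~ loading under the published diving circulation is slow
  (central-circulation time constants of hours), so desk-scale synthetic
  bouts yield modest absolute supersaturations; the package's checks are
  therefore directional (bin ordering, variant signs, kinetic ordering of
  compartments) rather than magnitude reproductions of field-scale
  results, which depend on the original multi-week TDR records.
* Temperature is ignored: solubilities, metabolic rates and the ectotherm's
  thermal behaviour are fixed at their reference values.
* The right-to-left intracardiac shunt of sea turtles is folded into the
  pulmonary shunt rather than modelled as a separate pathway.
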