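# gasdive

Compartmental blood and tissue gas dynamics for breath-hold diving sea
turtles.

Sea turtles incidentally caught at depth in fishing gear frequently surface
with gas embolism (GE) — intravascular bubbles formed when dissolved
nitrogen comes out of solution faster than the circulation can off-load it
to the lungs. Understanding that pathology requires knowing what blood and
tissue gas tensions look like during *routine* diving. `gasdive` implements
a baseline perfusion-limited model of N₂/O₂/CO₂ exchange for loggerhead
(*Caretta caretta*), leatherback (*Dermochelys coriacea*) and green
(*Chelonia mydas*) turtles, driven by arbitrary 1 Hz time-depth profiles.
It is written for comparative diving physiologists and for fisheries /
conservation modellers who need an end-dive nitrogen-supersaturation index
per dive, per animal, under perturbations of body condition and cardiac
output.

## The model

Four perfusion-limited compartments — brain, fat/bone, central circulation,
muscle — exchange gas with arterial blood, and their venous outflows merge
into mixed venous blood returning to the lung. Per gas and compartment *i*,

P̂ᵢ′(t) = Q̇ᵢ βᵦ / (Vᵢ βᵢ) · (Pₐ − Pᵢ)  ± metabolism,

with Q̇ᵢ the compartment blood flow, βᵦ/βᵢ blood and tissue solubilities,
and arterial tension the pulmonary-shunt-weighted mix
Pₐ = (1−s) P_fav + s P_v̄. The lung compresses with depth (Boyle's-law
total volume, compliant conducting-airway dead space); the shunt
s = (1 − V_fA/V_fA,max)^γ rises as the faveoli compress and reaches 1 at
collapse, sealing the lung. Blood O₂ follows a Hill curve (h = 2.7) plus a
dissolved term; muscle holds additional O₂ on myoglobin. At the surface,
breathing is instantaneous: arterial tensions snap to 0.741/0.164/0.033 ATA
(water vapor 0.062 ATA) and the lung refills to the diving lung volume.

Dive records are regularized to 1 Hz, offset by 2 m (so breathing events
sit at 0 m), and segmented into dives; per-dive end-dive mixed venous PN₂
(mean of the final 5 s) is aggregated by depth bin (shallow < 30 m, medium
30–90 m, deep > 90 m) and compared across the control model and six
single-knob variants (obese/emaciated body condition, surface cardiac
output 10/2.5 ml·min⁻¹·kg⁻¹, diving cardiac output 10 %/3.3 % of surface).
A seeded synthetic dive-bout generator emulates published per-individual
dive summaries, so the full pipeline runs without any field data.

See the vignette (`vignettes/gas-dynamics-model.Rmd`) for the complete
model description, parameter provenance and calibration rationale.

## Worked example

Generate a synthetic green-turtle bout from the published Cm1 dive summary,
run the control model plus all six variants, and inspect the end-dive
metrics:

```r
library(gasdive)

spec   <- referenceBoutSpecs("Cm1", nDives = 60, seed = 7)
series <- generateBout(spec)
series
#> DepthSeries 'Cm1': 57532 samples @ 1 Hz (16.0 h), green, 71.0 kg
#>   offset applied: 0 m; max depth 98.2 m; 85.4% submerged

head(segmentDives(series), 3)
#>   start  end duration  maxDepth meanDepth     bin truncated
#> 1    10 2341     2331 98.143986 68.510995    deep     FALSE
#> 2  2506 3057      551  4.852185  3.403131 shallow     FALSE
#> 3  3203 3558      355  4.366500  3.065577 shallow     FALSE

suite <- runSuite(series, turtleConfig("green", 71))
suite
#> gasdive suite: 60 dives, 7 variant(s)
#>   control end-dive mixed venous PN2: mean 1.134, max 1.449 ATA
#>   obese         mean   +1.3%  max   +4.0%
#>   emaciated     mean   -1.3%  max   -3.4%
#>   surface_high  mean   +9.6%  max  +59.3%
#>   surface_low   mean   -0.1%  max   -0.3%
#>   dive_high     mean  -10.2%  max  -15.1%
#>   dive_low      mean  +23.2%  max  +37.4%
```

The control row says this simulated animal ends its dives with mixed venous
PN₂ up to 1.449 ATA — about twice the 0.741 ATA surface equilibrium, i.e. a
surface-referenced supersaturation ratio of ~2. The variant rows show the
model's central qualitative result: diving cardiac output is the strongest
lever on nitrogen loading (raising it to 10 % of surface raises mean
end-dive PN₂ by ~23 %, lowering it to 3.3 % drops it by ~10 %), while body
condition mainly moves the deep-dive maxima.

The conventional M-ratios follow directly from end-dive tensions:

```r
round(supersaturationRatio(c(9.40, 6.17, 5.03)), 1)
#> [1] 12.7  8.3  6.8
```

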