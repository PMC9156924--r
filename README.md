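# broilerland

Steady-state demographics and land-use scenarios for US broiler chicken
production.

US chicken meat comes almost entirely from one fast-growing breed (Ross
308) raised in confined grow-out houses (CAFOs). Welfare programmes push
toward slower-growing breeds (Ranger Classic, Ranger Gold, Rowan Ranger)
and more spacious housing (outdoor access, pasture). Because slower
breeds are lighter at slaughter and live longer before it, keeping
national meat output constant changes the standing population, the
annual slaughter rate, and the land needed directly (housing, pasture)
and indirectly (feed cropland). `broilerland` is for researchers and
analysts who want those country-scale trade-offs as a tested, scriptable
model rather than a spreadsheet.

## The model in brief

The national flock is two boxes at steady state, so each standing
population is throughput × residence time, *p = τ f* (1.19 billion
fattening birds from 9.25 × 10⁹ yr⁻¹ × 47/365; 75 million hens from
98 × 10⁶ yr⁻¹ × 0.767 yr). A breed matches today's dressed output
*W = f w* ≈ 20.06 × 10⁹ kg yr⁻¹ when its slaughter rate is *W / w*breed;
the package stores this as a slaughter-rate multiplier (1.1922, 1.35,
1.272 for RC, RG, RR). Direct land is population × stocking rate
(0.0743 m²/bird CAFO, +75% outdoor run, 10.12 m²/bird pasture);
indirect land converts feed mass through the 60.3/26.8/12.9%
maize/soy/other mix and FAO yields (4.802 and 1.403 t/acre). Holding
total land at the conventional cap *L₀* ≈ 75.6 thousand km² caps
consumption at *W · L₀ / L*scenario — exact, because every land term is
linear in flock size. A calibration module derives breed parameters
from breeder performance-objective tables via top-down weight and
performance scale factors, and a synthetic generator produces such
tables with known ground truth for end-to-end testing.

## Worked example

```r
library(broilerland)
res <- run_all()    # 12 breed x management constant-land scenarios
res
```

```
Constant-land scenario set: 12 scenarios, cap 75573 km2
   breed management max_consumption_mmt_yr slaughter_billion_yr population_billion
 Ross308       cafo                   20.1                 9.25               1.19
 Ross308    outdoor                   20.0                 9.24               1.19
 Ross308    pasture                   17.3                 7.99               1.03
      RC       cafo                   16.6                 9.12               1.42
      RC    outdoor                   16.6                 9.11               1.42
      RC    pasture                   13.9                 7.67               1.20
      RG       cafo                   16.7                10.40               1.63
      RG    outdoor                   16.7                10.40               1.63
      RG    pasture                   13.8                 8.57               1.34
      RR       cafo                   15.4                 9.01               1.70
      RR    outdoor                   15.3                 9.00               1.70
      RR    pasture                   12.5                 7.35               1.39
```

Each row is one scenario at today's land footprint: the maximum
consumption (MMT dressed meat per year), and the slaughter rate and
standing population that production level implies. The first row is the
identity scenario (today's system). The starkest trade-off:

```r
res[["RR:pasture"]]
```

```
Scenario 'RR' / pasture (land cap 75573 km2):
  full-consumption land : 121030 km2 (scale factor 0.6244)
  max consumption       : 12.52 MMT/yr (-7.53 MMT, -37.6%)
  at cap: 7.35e+09 slaughtered/yr, population 1.39e+09
```

Raising the slow-growing breed on pasture at today's land budget means
37.6% less chicken and fewer birds slaughtered per year — yet a *larger*
standing population than today's 1.19 billion, because each bird lives
69 rather than 47 days. `summary(res)` prints the full-consumption land
ranges over the alternative breeds by management; `as.data.frame(res)`
and `write_scenario_report(res, dir)` export everything with
unit-suffixed columns.

Lower-level pieces are exported too: `breed_flock()`, `direct_land()`,
`feed_demand()`, `footprint()`, `calibrate_breed()`,
`generate_performance_table()`. Command-line wrappers live in
`inst/scripts/` (`broilerland-run.R`, `broilerland-synth.R`).

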