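---
title: "A steady-state box model of US broiler demographics and land use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state box model of US broiler demographics and land use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilerland)
```

## The problem

Commercial US chicken-meat production relies almost entirely on one
fast-growing breed (Ross 308) raised in confined grow-out houses
(CAFOs). Animal-welfare programmes advocate slower-growing breeds
(Ranger Classic, Ranger Gold, Rowan Ranger) and more spacious housing
(outdoor access, pasture). Because slower breeds reach lower slaughter
weights and live longer before slaughter, holding national meat output
constant while switching breed or housing changes three things at once:
the number of birds alive at any moment, the number slaughtered per
year, and the land needed both directly (housing, pasture) and
indirectly (feed cropland). `broilerland` quantifies those trade-offs at
the country scale and answers the inverse question: if total land use
may not grow, how much less chicken can be produced under each
alternative?

## The model

**Demographics.** The national flock is two well-mixed boxes at steady
state: a breeding flock of hens and a much larger fattening flock.
Steady state means placements equal departures, so each standing
population is throughput times mean residence time,

$$p = \tau \, f,$$

with $\tau = 47/365$ yr for conventional fattening birds and
$\tau = 0.767$ yr (a 40-week laying cycle) for hens. With the national
slaughter rate $f = 9.25\times10^9$ birds yr$^{-1}$ and pullet
placements of $98.0\times10^6$ hens yr$^{-1}$, the standing populations
are about 1.19 billion broilers and 75 million hens. Mortality during
grow-out and carcass condemnation are deliberately not modelled; the
single averaged slaughter-rate constant absorbs the difference between
reported placements and slaughters.

**Equal production across breeds.** Annual dressed production is
$W = f \cdot w_{\text{dressed}}$, about $20.06\times10^9$ kg for the
baseline (2.93 kg live, 74% dressing). A breed matches that output when
its slaughter rate is $W / w_{\text{dressed,breed}}$. The package's
canonical parameterization stores this directly as a *slaughter
multiplier* relative to the baseline rate (1.1922, 1.35, 1.272 for RC,
RG, RR); an alternative *weight mode* derives the same rate from a
scaled live slaughter weight and the breed's 76% dressing fraction. The
two modes are exact algebraic inverses, which the test suite asserts.
We chose the multiplier as canonical because the published per-breed
weight deltas are not mutually consistent with the published multipliers,
while the multipliers, residence times and population increases form a
closed, self-consistent set ($\text{population factor} =
\text{multiplier} \times \tau_{\text{breed}}/47$: 1.446, 1.637, 1.868).
The breeding flock scales proportionally with the fattening flock, and
pullet placements follow from the hen residence time.

**Residence times.** RC and RG use 57-day grow-outs. For RR we use 69
days: it is the breed's commonly stated average market age and it is the
only value that reproduces the published 86.8% population increase
together with the 1.272 multiplier ($1.272 \times 69/47 = 1.867$); the
alternative reading of "12 days longer than conventional" (59 days)
reproduces neither.

**Direct land.** CAFO housing uses 0.0743 m$^2$ per bird (20 000 birds
per 1486 m$^2$ house). Outdoor access *adds* an outdoor run of at least
75% of the indoor floor area — it never substitutes for indoor space —
so outdoor direct land is 1.75 times the CAFO figure. Pasture uses
10.12 m$^2$ per bird (0.0101 km$^2$ per 1000 birds). Only the fattening
flock's land is counted; breeder housing is excluded, matching the
accounting the national figures are built on.

**Indirect land.** Feed demand is slaughter rate times per-bird feed
over the grow-out. The mix is 60.3% maize, 26.8% soybeans, 12.9% other;
"other" feed (largely mined minerals and fish by-products) is
conservatively assigned zero cropland. Cropland is mass over yield
(4.802 t/ac maize, 1.403 t/ac soy, international acre = 4046.8564
m$^2$). For the *baseline* system the reported national crop masses
(35.56 and 15.78 MMT) are used directly rather than composition × 58.1
MMT: the two routes disagree by about 1.4% because the published
composition percentages are themselves rounded, and the reported-mass
route reproduces the published 75 488 km$^2$ to 0.005%. Alternative
breeds, whose feed is modelled rather than observed, use the
composition route.

**Effective per-bird feed.** The conventional per-bird feed is the
top-down national ratio $58.1\times10^9\,\text{kg} / 9.25\times10^9 =
6.281$ kg. For the slower breeds the package ships *effective* defaults
(6.457, 5.653, 6.536 kg for RC, RG, RR) obtained by inverting the
published national indirect-land totals through the cropland equations —
a one-time back-derivation, frozen as constants. The breeder
performance tables from which those totals were originally built are
distributed only as a study supplement, so the effective values are the
reproducible defaults; when performance tables *are* available, the
calibration module recomputes per-bird feed from them.

**Calibration.** Breeder "performance objectives" tables overstate
field performance. Two top-down factors correct them: a *weight scale
factor* (national 2.93 kg over the table's conventional-breed weight at
day 47) applied to table weights, and a *performance scale factor*
(national 6.281 kg feed per bird over the table's cumulative feed at day
47, roughly 1.35 for published objectives) applied to table feed.
Calibrating the conventional table against itself reproduces the
national statistics exactly — a fixed point the tests assert.
Interpolation between table ages is linear; at the daily resolution
breeders publish, the choice is benign (thinning a table to every third
day moves both factors by well under 0.5%, which is tested).

**Constant-land scenarios.** Every land component is linear in flock
size, so the consumption that holds total land at the baseline cap
$L_0$ (direct + indirect of the conventional system, 75 573 km$^2$ as
computed here against the published 75 577) is simply

$$W_{\text{scenario}} = \frac{L_0}{L_{\text{scenario}}} \, W,$$

and the capped slaughter rate and population scale by the same factor.
The solver is exact, not iterative; its defining fixed point (re-running
the footprint on the capped flock returns the cap) is property-tested.

## Worked example

```{r}
params <- load_parameters(NULL)   # full published defaults
res <- run_all(baseline = params$baseline, breeds = params$breeds,
               managements = params$managements, feed = params$feed)
res
summary(res)
```

Switching entirely to the slow-growing RR breed on pasture, for
example, caps consumption near 12.5 MMT yr$^{-1}$ — a reduction of
about 37.6% — while the standing population still rises relative to
today because each bird lives 69 rather than 47 days:

```{r}
run_all()[["RR:pasture"]]
```

## The synthetic-data generator

`generator_spec()` emulates breeder performance-objective tables so
calibration and the full pipeline run with no external download. Growth
is a Gompertz curve $W(t) = W_\infty e^{-e^{-k(t - t_i)}}$ — saturating,
smooth and monotone like real objectives — with the asymptote derived
from an anchor (weight at slaughter age), so the noise-free curve passes
through its anchor exactly. Cumulative feed is a feed-conversion ratio
linear in age times weight, anchored the same way. Only pointwise values
at slaughter age enter the model, so the functional form matters for
realism, not correctness. Default anchors put the conventional table at
3.35 kg and 4.653 kg cumulative feed at day 47, making the true scale
factors 0.8746 and 1.3499; the slower breeds' anchors are placed so
calibration recovers the package's effective defaults. Measurement
noise is multiplicative lognormal with a running-maximum repair to keep
curves monotone; the default is zero noise, because real performance
objectives are deterministic published curves — the noise switch exists
to test calibration robustness, not to model the study conditions. All
randomness flows from the single seed through a saved-and-restored RNG
state, so generation never perturbs the session's random stream.

What the generator does *not* emulate: sex-split curves (as-hatched
averages only), seasonal or farm-level variation, mortality, and any
feedback between management and feed conversion. Passing tests on
synthetic tables therefore show that the calibration arithmetic and the
pipeline plumbing are correct, not that breeder tables themselves are
accurate.

## Numerical choices and degenerate inputs

- A year is 365 days everywhere; 0.129 and 0.767 yr are accepted as
  roundings of 47/365 and the 40-week cycle.
- Internal values keep full double precision; published-style roundings
  (1.19 billion, 2.17 kg, 20.0 MMT) appear only at presentation time.
- Zero placement rates, zero-population flocks and zero crop masses are
  valid and propagate zeros; zero yields, fractions outside their
  ranges, both-or-neither breed parameterizations, and performance
  tables not covering the evaluation age raise informative errors.
- Config round-trips are exact: YAML is written with 17 significant
  digits, enough to reproduce any double bit-identically.

## Problem sizes

Everything is desk-scale: 12 scenarios, tables of at most ~80 daily
rows, and closed-form arithmetic throughout. The full test suite,
including property-style loops (25 random flocks for the steady-state
identity, 10 for linearity and ordering, 5 noisy generator seeds), runs
in a few seconds.

## Known limitations

- Mortality during grow-out and carcass rejection at slaughter are
  excluded by design, as in the national accounting the model mirrors.
- No land is counted for breeder housing or breeder feed, for "other"
  feed ingredients, or for land quality, carbon and biodiversity.
- Feed requirements are management-invariant: pasture foraging intake
  and activity-driven feed-conversion penalties are not modelled, so
  pasture scenarios inherit CAFO feed demand.
- The published scenario table chains rounded intermediates; recomputed
  values can differ from printed ones by a few tenths of a percent, and
  one printed slaughter rate (intermediate RG on pasture) is internally
  inconsistent with the other printed figures. Golden tests use a 0.5%
  relative tolerance and exclude that single entry.
- Single-breed scenarios only: no mixed portfolios or partial
  transitions, though users can encode custom breed shares as custom
  `breed_spec` records.
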