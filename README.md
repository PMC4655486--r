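# neophron

An individual-based stochastic population model of Egyptian vultures
(*Neophron percnopterus*) in a Mediterranean protected area, for
conservation ecologists asking what happens to a threatened scavenger when
its keystone food resource — wild-rabbit (*Oryctolagus cuniculus*)
carcasses — collapses and a dominant competitor (the griffon vulture,
*Gyps fulvus*) expands. The package calibrates the model to stated vital
rates, hindcasts the 1980–2013 decline, projects 35-year futures under
food-recovery and competitor scenarios, fits Box-Behnken/factorial
response surfaces over management factors, and measures parameter
sensitivity with paired common-random-number ensembles.

## The model

One simulated female = one breeding territory. For each of the 6 months
the species spends in the study area, five synchronized process modules
run on a daily/monthly/annual calendar:

1. **Natural mortality** (monthly): survival `(1 - m)^(1/6)`, with
   annual `m` = 2% for breeders and 10% for non-breeders.
2. **Feeding** (daily): the month's rabbit-carcass biomass arrives as
   1-kg units spread over 30 days; each unit is intercepted by griffons
   with probability `min(1, kappa G)` (`G` = griffon abundance index), and
   the rest is allocated to the birds in random order up to each bird's
   daily intake. Birds left short are *unfed*.
3. **Exit accounting** (daily): an unfed breeder forages outside the
   protected area that day; a fed breeder does so with probability 0.20
   (the observed pre-crash fraction of outside trips).
4. **Poisoning mortality** (monthly): a breeder with `e` exit-days dies
   with probability `1 - (1 - p)^e`; the per-exit hazard `p` is zero
   before the 1990 rabbit-hemorrhagic-disease crash and calibrated so
   post-crash overall breeder mortality is 17%/yr.
5. **Reproduction** (annual): a surviving breeder fledges a chick with
   probability `clamp(a - b e/180)`, the line through productivity 0.4 at
   the pre-crash exit fraction (0.20) and 0.2 at the post-crash one
   (~0.8). Fledglings recruit to territories in their eighth year.

Exogenous drivers: pre-crash carcass biomass `R0` (sized to the pre-era
population's demand), a crash to 10% of `R0` in 1990, scenario-controlled
recovery `f` in [0, 1] afterwards; griffon pairs growing exponentially
from 1 (1990) to 85 (2013), then stable or linearly doubling over 35
years.

## Worked example

```r
library(neophron)

cal <- calibrate_params(ev_params(), seed = 42)   # ~45 s: pilot ensembles
calibration_report(cal)
#> # A tibble: 6 x 4
#>   quantity                   target achieved    residual
#>   <chr>                       <dbl>    <dbl>       <dbl>
#> 1 pre-era breeder mortality    0.02   0.0183 -0.00169
#> 2 post-era breeder mortality   0.17   0.165  -0.00546
#> 3 pre-era exit fraction        0.2    0.200   0.00000973
#> 4 pre-era productivity         0.4    0.403   0.00256
#> 5 post-era productivity        0.2    0.199  -0.00118
#> 6 2013 griffon share           0.27   0.269  -0.000560
```

The calibration solves the poisoning hazard, the interception coefficient
`kappa`, the food constant `R0` and the reproduction line so the simulator
reproduces the stated era rates; residuals are Monte-Carlo verification on
a fresh seed.

```r
hind <- run_hindcast(cal, n_reps = 100, seed = 7)
dplyr::filter(hind$summary, variable == "pairs", year == 2013)
#> # A tibble: 1 x 6
#>    year variable  mean  lo95  hi95 n_reps
#>   <int> <chr>    <dbl> <dbl> <dbl>  <int>
#> 1  2013 pairs     25.0    16  33.5    100
```

The hindcast declines from the 50 territories of 1980 to an ensemble mean
of 25.0 pairs in 2013 (the observed 23 active pairs lie inside the 95%
band), and in 2013 the two species split the consumed rabbit carrion
73%/27%:

```r
consumption_shares(hind) |> dplyr::filter(year == 2013)
#> # A tibble: 1 x 3
#>    year ev_share gv_share
#>   <int>    <dbl>    <dbl>
#> 1  2013    0.731    0.269

proj <- run_projection(cal, hind, n_years = 35, seed = 11,
                       griffon_scenario = "doubling")
consumption_shares(proj) |> dplyr::slice_tail(n = 1)
#> # A tibble: 1 x 3
#>    year ev_share gv_share
#>   <int>    <dbl>    <dbl>
#> 1  2048    0.460    0.540
```

Under a doubling griffon population the competitor ends up consuming ~54%
of the rabbit carrion — the competitive exclusion that drives the focal
population down. `recovery_threshold()` bisects the rabbit-recovery
fraction at which the breeding-population trend turns positive, and
`sensitivity_analysis()` gives the paired +1% effects of food, poisoning
and natural mortality on the number of females 35 years out.

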