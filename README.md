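# mangroflux

Mangroves capture atmospheric carbon while transpiring remarkably little
freshwater: their canopy transpiration (*E*<sub>c</sub>) is only about 43% of
the evapotranspiration (*ET*) of the 1-km² cells they occupy — rising toward
57% only if porewaters freshen — whereas the terrestrial ecoregions adjacent
to mangroves transpire 47–70% of *ET*. `mangroflux` implements the full
scaling chain behind that comparison, from leaf gas exchange to a global
water budget, for coastal ecohydrologists and blue-carbon analysts who want
the arithmetic reproducible, testable and extensible.

The package covers five linked pieces:

* **Leaf level.** Intrinsic water-use efficiency
  (WUE<sub>int</sub> = *P*<sub>n</sub>/*g*<sub>w</sub>, µmol CO₂ (mol H₂O)⁻¹)
  and instantaneous water-use efficiency
  (WUE<sub>ins</sub> = *P*<sub>n</sub>/*T*<sub>r</sub>, mmol CO₂ (mol H₂O)⁻¹),
  distribution summaries, and the OLS response of WUE<sub>int</sub> to
  porewater salinity that motivates the low-salinity "potential" scenario.
* **Canopy level.** The molar unit chain converting transpiration to carbon
  (NPP = *E*<sub>c</sub> · 55.51 · (WUE<sub>ins</sub>/1000) · 44.01 · 0.273 / 1000)
  and the calibrated linear model
  *E*<sub>c</sub> = 384.59 · NPP + 33.56 (mm H₂O yr⁻¹), plus sap-flow
  per-dbh regression and flux-tower cross-check arithmetic.
* **Landscape level.** Extraction of gridded annual *ET* for study sites
  with a Moore-neighborhood rule that excludes open-water cells, and
  *E*<sub>c</sub>-to-*ET* ratio summaries.
* **Global accounting.** The ecoregional water account: per-area reductions
  (mm yr⁻¹ and kL ha⁻¹ yr⁻¹ = 10 × mm) scaled by mangrove-adjacent area to
  GL yr⁻¹, the oil-palm conversion scenario, and virtual-water valuation
  (USD per mm of transpired water).
* **Individual trees.** A BETTINA-style simulator in which a tree is four
  geometric measures, water uptake follows the soil-to-leaf water-potential
  gradient through a resistance network, and biomass allocation adapts to
  water versus light limitation — reproducing shorter, thicker-stemmed,
  far thriftier trees at high salinity.

A synthetic-data generator emulates the statistical structure of all
literature inputs (salinity-dependent leaf records, a 71-site two-region NPP
table, a water-masked ET grid, linear sap-flow records), so the entire
pipeline runs and is tested without any download.

## A worked example

```r
library(mangroflux)

# Global account from the packaged ecoregion table
acct <- build_account()
acct[acct$name == "Tropical rainforest",
     c("reduction_avg_mm", "reduction_avg_klha", "global_avg_gl")]
#> # A tibble: 1 × 3
#>   reduction_avg_mm reduction_avg_klha global_avg_gl
#>              <dbl>              <dbl>         <dbl>
#> 1             291.              2905.        32635.

glance(acct)
#> # A tibble: 1 × 2
#>   total_avg_gl total_pot_gl
#>          <dbl>        <dbl>
#> 1       34714.       16161.
```

A tropical rainforest transpires 27 percentage points more of its *ET* than
mangroves do; over its 1076 mm yr⁻¹ of *ET* that is 290.52 mm yr⁻¹, i.e.
2905 kL ha⁻¹ yr⁻¹, and about 32,600 GL yr⁻¹ over the 11.2 Mha of mangroves
adjacent to that ecoregion (32,632.42 GL when the display-rounded
2905 kL ha⁻¹ is scaled, 32,635 GL unrounded). Summed over all seven ecoregions, mangroves use
~34.7 TL yr⁻¹ less water than comparable vegetation would (16.2 TL yr⁻¹
under the low-salinity potential scenario).

```r
# End-to-end synthetic pipeline, one seed
report <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))

# Tree-level salinity response
sweep <- salinity_sweep(seq(0, 80, by = 10))
round(sweep$uptake_l_day, 1)
#> [1] 389.7 342.7 294.8 246.3 197.4 148.6 100.7  55.4  17.2
```

A simulated 200-year-old tree at 70 psu uses ~14% of the water of the same
tree grown at 0 psu; `autoplot(sweep)` draws the gradient.

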