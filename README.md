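# isoflux

Nitrogen fuels most marine primary production, and coastal waters around
Cape Hatteras — where the Mid-Atlantic Bight (MAB) shelf, the Slope Sea,
the South Atlantic Bight (SAB) shelf and the Gulf Stream converge — host
strongly contrasting microbial communities and nutrient regimes.
`isoflux` is an R package for the desk-side analysis of multi-substrate
¹⁵N tracer cruises in such systems: it turns short deck-board incubation
records into uptake rates for six nitrogen substrates (nitrate, nitrite,
ammonium, urea, cyanate, dissolved free amino acids), classifies samples
into water masses, decomposes HPLC pigment profiles into nine
phytoplankton groups, and links rates, environment and community with
regional and multivariate statistics. A synthetic cruise generator with
known ground truth validates every stage.

## The core calculations

**Isotope mixing model.** An incubation spikes a water sample with a
highly enriched ¹⁵N substrate; uptake transfers label into particulate
nitrogen (PN). With a₀/a_f the initial/final atom% ¹⁵N of PN, a_src the
source-pool enrichment after the spike, and t the duration:

    ρ = (a_f − a₀)/(a_src − a₀) × PN̄ / t     [µmol N L⁻¹ h⁻¹]
    v = (a_f − a₀)/(a_src − a₀) / t          [h⁻¹]

with PN̄ the mean of initial and final PN. Source pools follow the
field's rules (nitrate δ¹⁵N = 6‰ below 0.5 µmol L⁻¹ ambient, 2.5‰ above;
natural abundance otherwise; below-detection ambient pools are
spike-dominated). Detection limits are evaluated per experiment from the
mass spectrometer's atom% resolution (0.0018 atom%), and experiments in
which ≥ 50% of the added substrate was consumed are excluded.

**Water masses.** Salinity bands north of Cape Hatteras (MAB < 34.5 ≤
Slope Sea < 36 ≤ front < 36.5 ≤ Gulf Stream); south of the cape the
shelf out to the 200 m isobath is SAB water. Derived indices:
Chl = 0.55·FL − 0.19 from CTD fluorescence, and the excess-phosphate
index P\* = [PO₄] − [NO₃]/16.

**Pigment unmixing.** A CHEMTAX-style decomposition: non-negative least
squares of each 15-channel pigment profile on a 9-group ratio matrix
(divinyl-Chl a attributable only to *Prochlorococcus*), plus a monotone
coordinate-descent optimization of the ratio matrix within bounds.

**Statistics.** Regional summaries with substrate fractions of total
uptake, Mann–Whitney U (exact by enumeration for small samples),
pairwise-complete Pearson correlation matrices, and redundancy analysis
(RDA) of the rate matrix on environment + community composition.

## Worked example

```r
library(isoflux)

cruise <- generate_cruise(cruise_config(n_stations_per_regime = 2,
                                        noise_cv = 0.05, seed = 42))
rates <- compute_uptake_rates(cruise$incubations)
head(rates[, c("substrate", "rate_umolN_L_h", "rate_sd", "flags")], 4)
#>   substrate rate_umolN_L_h  rate_sd                          flags
#> 1   cyanate        0.00495 0.000144                  OVER_ENRICHED
#> 2      DFAA        0.00936 0.001084                  OVER_ENRICHED
#> 3       NH4        0.01314 0.000663 AMBIENT_BELOW_DL;OVER_ENRICHED
#> 4       NO2        0.00731 0.000567 AMBIENT_BELOW_DL;OVER_ENRICHED

cl <- classify_hydro(cruise$hydro)
regional_summary(rates, unique(cl[, c("station_id", "water_mass")]))$totals
#>       region mean_total_umolN_L_h min_total max_total n_sets
#> 1 GulfStream               0.0588    0.0572    0.0603      6
#> 2        MAB               0.3178    0.3106    0.3242      6
#> 3        SAB               0.1246    0.1229    0.1271      6
#> 4   SlopeSea               0.2135    0.2097    0.2195      6

comp <- unmix_pigments(cruise$pigments)
head(comp[, c("station_id", "depth_id", "Diat", "Proc", "Syne", "picoeuk")], 3)
#>   station_id      depth_id Diat  Proc Syne picoeuk
#> 1     MAB_01       surface 0.47 0.016 0.13    0.33
#> 2     MAB_01 above_chl_max 0.45 0.021 0.13    0.34
#> 3     MAB_01       chl_max 0.47 0.020 0.12    0.34
```

The first rows are Gulf Stream experiments: rates of a few nmol N L⁻¹
h⁻¹, flagged over-enriched because the spike dominates the tiny ambient
pools (these are potential rates), with ammonium and nitrite ambient
concentrations below their method detection limits. The regional totals
recover the built-in shelf-to-stream gradient (MAB > Slope Sea > SAB >
Gulf Stream), and the pigment decomposition shows the diatom-dominated
MAB community with a small *Prochlorococcus* share.

The full pipeline — ingestion, rates, classification, unmixing,
statistics, recovery report and run manifest — runs from CSV inputs via
`run_pipeline(pipeline_config(in_dir, out_dir))`, or from a shell with
the thin wrapper `inst/exec/isoflux` (`isoflux simulate`, `isoflux run`).

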