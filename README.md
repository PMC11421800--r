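# stormtracer

Stream microbial communities as hydrologic tracers of storm response.

## The problem

When a storm hits a catchment, stream discharge can rise several-fold while
stable water isotopes barely move — the classic signature of an event fed
mostly by "old" water stored in the catchment before the rain. Isotopes
quantify *how much* old water is flowing but not *where* it was stored.
Stream bacteria can: every daily water sample carries hundreds of 16S
amplicon sequence variants (ASVs) washed in from soils, biofilms, sediments
and groundwater, and the way each taxon's abundance tracks discharge, plus
its likely source environment, encodes flowpath information.

stormtracer is for hydrologists and microbial ecologists with a daily
ASV-by-day count table spanning a storm, matching discharge/precipitation
and (optionally) stream isotope series. It packages the full analysis:

* **Diversity and ordination** — rarefaction to even depth, richness and
  base-2 Shannon entropy, Bray–Curtis dissimilarity
  `BC(u,v) = Σ|n_iu − n_iv| / Σ(n_iu + n_iv)`, mean distance from the
  pre-event baseline, and principal coordinates analysis (classical scaling).
* **Discharge reconstruction** — OLS of daily discharge on the first *p*
  principal coordinates (with the r²-vs-*p* profile and adjusted r²) and on
  alpha diversity and isotopes.
* **cQ classification** (the core statistic) — for each ASV detected on ≥ 3
  days, a linear regression of rarefied counts on discharge over the whole
  record labels it *mobilized* (slope > 0, p < 0.1), *diluted* (slope < 0,
  p < 0.1), *static*, or *uncharacterized* (< 3 detections); group-level
  class fractions are tested against 1,000 shuffled surrogates that permute
  counts within each day and permute the day–discharge alignment, flagging
  fractions outside the surrogate 5th–95th percentile band (p < 0.05).
* **Source attribution** — habitat hits per ASV collapsed onto eight source
  environments, abundance-weighted daily community composition, and exact
  Mann–Whitney contrasts of storm periods against the pre-event baseline.
* **Isotope tools** — deuterium excess (δ²H − 8 δ¹⁸O) and two-component
  hydrograph separation `f_new = (c_stream − c_old)/(c_new − c_old)`.
* **A synthetic generator** — hydrograph, coupled ASV counts, isotopes and
  habitat profiles with known ground truth, used throughout the test suite.

The central container is `StormExperiment`, a `SummarizedExperiment` of
ASV-by-day counts with the hydrograph and isotope series in `colData`.

## Worked example

```r
library(stormtracer)

# simulate a 17-day storm record with known ground truth
sim <- simulateStormExperiment(simulationConfig(rng_seed = 7))

# run the full analysis (rarefy to 4000, classify, 1000 surrogates,
# source attribution, isotope separation)
bundle <- runPipeline(sim$experiment, list(n_surrogates = 1000),
                      habitatProfiles = sim$habitatProfiles)
cat(stormReport(bundle), sep = "\n")
```

```
# Storm-tracer analysis summary

- Richness 89 to 187; Shannon 4.75 to 5.30 bits (peak on 2020-10-14).
- Discharge vs first 4 principal coordinates: r2 = 0.998 (adjusted 0.998).
- Taxa: 98 mobilized, 40 diluted, 72 static, 49 uncharacterized.
- Significant group-class fractions (surrogate test): Cyanobacteria/mobilized (33.3%); Alphaproteobacteria/mobilized (66.0%); Actinobacteriota/diluted (65.9%); Bacteroidota/diluted (80.0%); ...
- Source-environment shifts (Mann-Whitney, p < 0.1): sediment decrease in early_event (p = 0.057); groundwater decrease in early_event (p = 0.029); freshwater decrease in post_event (p = 0.007); soil increase in post_event (p = 0.007); ...
- Discharge 0.25 to 1.80 CMS (+620%), peak on 2020-10-13.
- Event water at peak: fraction 0.125 (0.22 CMS); old water 0.875.
```

Reading the summary: the community's ordination reconstructs the hydrograph
almost perfectly (adjusted r² ≈ 1 under strong simulated coupling); richness
spikes with the storm; Alphaproteobacteria are disproportionately mobilized
while Gammaproteobacteria and Bacteroidota are disproportionately diluted;
soil- and biofilm-associated taxa gain representation during and after the
event while freshwater/sediment taxa lose it; and the isotope mass balance
says ~87% of peak flow was old water. Per-taxon detail lives in
`bundle$classification` (asv_id, label, slope, p_value, n_detections).

File-based inputs work the same way: `readStormExperiment()` assembles
counts.tsv, taxonomy.tsv, hydro.csv and isotopes.csv, and
`inst/scripts/stormtracer.R` wraps `simulate` / `run` / `report` for shell
use with a YAML config.

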