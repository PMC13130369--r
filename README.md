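# ampliconbench

Benchmarking and optimization toolkit for 16S rRNA metabarcoding taxonomic
classifiers, written for researchers who need to know — before trusting a
pipeline on complex environmental samples such as wastewater — how well it
detects the organisms actually present, how much of the read signal lands on
them, and how badly its abundance and diversity estimates are distorted by
false positives.

The package provides, end to end and with no external pipelines required:

* **Tiered mock communities** (`design_community()`): 15 species per site in
  three abundance tiers (5 x 15% "main" with three strain variants each,
  5 x 4.5% "mid", 5 x 0.5% "rare"), with analytic diversity
  (Shannon *H* = −Σ *p*ᵢ ln *p*ᵢ = 2.25, Pielou *J* = *H*/ln 15 = 0.83) and a
  per-variant abundance configuration for external read simulators.
* **Readers/writers** for Kraken 2 reports, Bracken species tables, tabular
  BLAST hit files (best hit per query by bitscore, deterministic
  tie-breaking), generic taxon/count TSVs, and FASTA/FASTQ subsampling.
* **Detection metrics** (`detection_report()`): taxa/read sensitivity and
  selectivity plus the composite surveillance score
  (ts·tsel + rs·rsel)/200.
* **Mapping-error family** (`mapping_error()`): SAE and RMSE, their
  read-normalized forms (nSAE, nRMSE) and false-negative-weighted forms
  (wnSAE = w·U + O with under-detection mass U and over-detection mass O;
  wnRMSE), with exact FN/FP decomposition, a 6 x 6 modelling grid and
  Type I/II correlation analysis (`modelling_grid()`, `grid_correlations()`).
* **Diversity scoring**: richness, bias-corrected Chao1, Shannon, Pielou,
  Bray–Curtis, the composite diversity score
  (100 − mean |percent error| over four estimates) and the replicate/site
  precision ratio.
* **Selectivity filters** (`zscore_filter()`, `fraction_filter()`): remove
  taxa with fewer reads than μ − 0.25σ, or than 0.4% of total reads, with
  truth-aware diagnostics and threshold sweeps.
* **A classifier simulator** (`simulate_classification()`): multinomial
  reads through a confusion channel with dropout and a Zipf-tailed
  false-positive pool, reproducing the empirical regularity that
  false-positive taxa attract far fewer reads than true taxa.

All user-facing functions take and return tibbles, chain with the pipe, and
come with `tidy()`/`glance()`/`autoplot()` methods. A thin command-line
front end ships in `inst/cli/ampliconbench.R` (subcommands `design`,
`simulate`, `filter`, `evaluate`, `diversity`, `model-error`, `report`).

## Worked example

Design a wastewater-like community, simulate a mid-quality classifier on a
175k-read set, score it, then optimize selectivity with the 0.4% filter:

```r
library(ampliconbench)

truth <- design_community(c(
  "Acinetobacter johnsonii", "Acidovorax temperans", "Thermomonas carbonis",
  "Aeromonas caviae", "Cloacibacterium normanense",
  "Arcobacter cryaerophilus", "Pseudarcobacter defluvii", "Tolumonas auensis",
  "Hydrogenophaga intermedia", "Simplicispira suum",
  "Flavobacterium lindanitolerans", "Paludibacter propionicigenes",
  "Macellibacteroides fermentans", "Zoogloea ramigera", "Sphaerotilus natans"
), site_id = "west_bank")

round(c(shannon = shannon(truth$abundance_pct),
        pielou = pielou(truth$abundance_pct)), 2)
#> shannon  pielou
#>    2.25    0.83

sim <- simulate_classification(truth, n_reads = 175000,
                               params = confusion_params(seed = 101))
tidy(detection_report(sim, truth))
#> # A tibble: 6 × 2
#>   metric                value
#>   <chr>                 <dbl>
#> 1 taxa_sensitivity       93.3
#> 2 taxa_selectivity       31.8
#> 3 read_sensitivity       81.2
#> 4 read_selectivity       85.3
#> 5 false_positivity_rate  68.2
#> 6 surveillance_score     49.5
```

The classifier finds 14 of 15 community members (93.3% sensitivity) but its
output is two-thirds false positives (31.8% selectivity). The error panel
shows where the damage is — the weighted nSAE of 51.6 decomposes into an
under-detection component of 18.8 percent-abundance points (doubled by the
FN weight) plus 14.0 points sitting on false positives:

```r
print(as.data.frame(mapping_error_all(sim, truth))[, 1:4], digits = 4)
#>   metric     value fn_component fp_component
#> 1    SAE 57431.000    32874.000    24557.000
#> 2   nSAE    32.818       18.785       14.033
#> 3  wnSAE    51.603       18.785       14.033
#> 4   RMSE  2532.653     1789.740     1791.972
#> 5  nRMSE     1.447        1.023        1.024
#> 6 wnRMSE     1.772        1.023        1.024

dplyr::glimpse(filter_diagnostics(sim, truth, "fraction", 0.004))
#> Rows: 1
#> Columns: 12
#> $ method                  <chr> "fraction"
#> $ cutoff                  <dbl> 0.004
#> $ threshold_reads         <dbl> 700
#> $ n_removed               <int> 24
#> $ n_removed_fp            <int> 24
#> $ fp_rate_below_cutoff    <dbl> 100
#> $ read_correct_pct_before <dbl> 85.26724
#> $ read_correct_pct_after  <dbl> 87.6823
#> $ taxa_sensitivity_before <dbl> 93.33333
#> $ taxa_sensitivity_after  <dbl> 93.33333
#> $ taxa_selectivity_before <dbl> 31.81818
#> $ taxa_selectivity_after  <dbl> 70
```

The 700-read threshold (0.4% of 175k) sits below the ~875 reads expected on
a rare-tier taxon, so it strips 24 false positives while keeping sensitivity
untouched — selectivity more than doubles. Alpha diversity of the filtered
profile (richness 20 vs true 15; Chao1 equals richness because no
singleton/doubleton taxa survive the filter):

```r
print(as.data.frame(alpha_report(fraction_filter(sim, 0.004)$profile)), digits = 3)
#>   sample_id richness chao1 shannon pielou
#> 1 west_bank       20    20    2.44  0.813
```

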