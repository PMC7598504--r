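# topoquant

Quantitative analysis of bacterial DNA supercoiling from
agarose/chloroquine gel densitometry, for microbiologists studying how
growth conditions and small metabolites (polyamines, Mg²⁺) shift the
supercoiling set point of plasmid reporters.

Covalently closed plasmids run on an intercalator gel as a ladder of
topoisomers differing by integer apparent linking number (Lk). `topoquant`
turns a digitized lane profile into that ladder and summarizes it as the
intensity-weighted mean linking number,

    Lk̄ = Σᵢ Iᵢ·Lkᵢ / Σᵢ Iᵢ ,

with the topmost band assigned Lk = 0. Because apparent Lk shifts from gel
to gel, lanes are normalized to **Relative Supercoiling Units** against two
reference lanes run on every gel:

    RSU = (Lk̄ − Lk̄_ref0) / (Lk̄_ref1 − Lk̄_ref0) ,

so ref0 ≡ 0 RSU, ref1 ≡ 1 RSU, and with references ~0.5 Lk apart a full
linking-number change converts to ~2 RSU. On top of this sit DNA-gyrase
activity scoring (ΔLk̄/hour, percent variation versus a no-polyamine
baseline), group statistics (Student/Welch t-tests; Tukey's HSD with a
compact letter display built on the package's own studentized-range
distribution), HPLC polyamine quantitation (standard curves, intracellular
concentration from CFU and a 4 μm³ cell volume, free-fraction estimates,
0.2 mM detection-limit censoring), and log₂ fold-change analysis of an
FPKM expression table. A seeded synthetic gel generator with ground-truth
manifests makes every stage testable without laboratory data.

## Worked example

Simulate a wild-type lane, quantify it, and normalize a scenario to RSU:

```r
library(topoquant)

d    <- topoisomer_distribution(2, sd = 1.35, half_support = 6)
geom <- gel_geometry(origin_px = 150, spacing_px = 30, band_sigma_px = 5,
                     length_px = 480)
lane <- render_lane(d, geom, noise_model(2, 0.002, 0.01, seed = 1),
                    total_intensity = 1000, lane_id = "WT_HH")
fit  <- quantify_lane(lane, background_window_px = 91,
                      background_fit = "linear",
                      min_separation_px = 10, smooth_px = 5)
fit
#> Lane 'WT_HH': 7 bands, weighted mean Lk = 3.022
#>  lane_id lk_index center_px integrated_intensity
#>    WT_HH        0       120             17.79760
#>    WT_HH        1       150             88.78567
#>    WT_HH        2       180            217.16223
#>    WT_HH        3       210            288.07874
#>    WT_HH        4       240            216.71750
#>    WT_HH        5       271             92.77721
#>    WT_HH        6       300             22.04956
```

Seven bands, indexed 0–6 from the top of the gel; the weighted mean of
3.02 sits within 0.03 of the simulated truth (mean Lk 2 on the lane's own
index scale, which places index 0 at the band three spacings above the
mode). The full pipeline renders the default scenario (ref0/ref1 separated
by 0.5 Lk, one sample lane offset a full linking number from ref0),
quantifies all lanes on a shared index scale, and normalizes:

```r
res <- run_pipeline(default_run_config(seed = 1), quiet = TRUE)
res$supercoiling
#>      lane_id weighted_lk   rsu ref0_lane ref1_lane true_mean_lk
#> 1       ref0       3.011 0.000      ref0      ref1          2.0
#> 2       ref1       3.508 1.000      ref0      ref1          2.5
#> 3 sample_1lk       3.997 1.984      ref0      ref1          3.0
```

The one-Lk offset lane quantifies to 1.98 RSU — the "one linking number ≈
2 RSU" conversion recovered by measurement rather than by construction.
Group comparisons print compact letter displays:

```r
compare_groups(list(wt = c(0.98, 1.05), mutant = c(2.31, 2.25)),
               method = "student_t")
#> Group comparison (student_t, alpha = 0.05)
#>   group n  mean      sd letters
#>  mutant 2 2.280 0.04243       a
#>      wt 2 1.015 0.04950       b
#> Pairwise:
#>  group1 group2  diff    p_adj significant
#>  mutant     wt 1.265 0.001325        TRUE
```

Polyamine arithmetic is one-liners: `free_concentration(20, "putrescine")`
gives 8 mM free putrescine, and
`flag_differential(read_expression_table(system.file("extdata",
"table1_expression.tsv", package = "topoquant")))` flags 16 of 32 genes as
differential at q < 0.05.

## Package layout

- `R/topoisomer.R`, `R/gel-sim.R` — topoisomer distributions, synthetic
  lane rendering, scenario generator with ground-truth manifest
- `R/densitometry.R` — profile I/O, background subtraction, band
  detection, Lk assignment, `quantify_lane()`
- `R/scstats.R`, `R/tukey.R` — RSU, gyrase activity, group comparisons,
  studentized-range distribution, compact letter display
- `R/polyamine.R` — standard curves, intracellular/free concentrations,
  detection-limit censoring
- `R/expression.R` — FPKM fold changes and differential flagging
  (fixture: `inst/extdata/table1_expression.tsv`)
- `R/pipeline.R` — `run_pipeline()`, configuration, provenance
- `vignettes/supercoiling-quantification.Rmd` — the methods vignette
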