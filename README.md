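# tjperm

Spatially resolved quantification of transendothelial permeability at
tricellular junctions.

Macromolecules cross an endothelial monolayer mostly between cells, and
the points where three or more cells meet — **tricellular junctions** —
are candidate hot spots for this paracellular leak. In the spatially
resolved permeability assay, a fluorescent tracer (e.g. FITC-avidin)
binds a biotinylated substrate the moment it crosses the monolayer, so
bound-fluorescence spots mark *where* transport happened, while a
VE-cadherin immunostain shows the cell borders. `tjperm` is for
researchers running or evaluating this assay: it turns the two channels
into per-image permeability metrics and condition-level statistics, and it
ships a synthetic monolayer-image generator with exact ground truth so
every stage of the analysis can be validated by parameter recovery.

## The analysis

For junction centroids *c<sub>j</sub>* and tracer spots *S<sub>k</sub>*
(8-connected components of the adaptively thresholded tracer channel),
junction *j* is **permeable** iff

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>k</sub> min<sub>p ∈ S<sub>k</sub></sub> ‖c<sub>j</sub> − p‖ ≤ 2 px,

and each spot within 2 px of a junction is assigned to its nearest
junction only. Per image the package reports the four assay metrics:

- fraction of permeable tricellular junctions, *n*<sub>perm</sub>/*n*<sub>TJ</sub>;
- total tracer accumulation Σ *I*(p) over the thresholded foreground (RFU);
- junction-associated share of accumulation, Σ<sub>assigned spots</sub> *I* / Σ *I*;
- mean accumulation per permeable junction.

Junction centroids come from either a trainable multi-resolution residual
segmentation network (soft-Dice objective 1 − (2Σpg + 1)/(Σp + Σg + 1),
watershed post-processing to split merged detections) or a deterministic
skeleton-based detector. Condition summaries average images within
replicate (donor) first, report mean ± SEM across replicates, and compare
conditions with the pooled-variance unpaired Student t test.

## Worked example

```r
library(tjperm)

# a synthetic 512x512 monolayer of ~100 cells, untreated-like tracer
sim <- simulate_monolayer(field_spec(512, 512, 100, rng_seed = 3),
                          tracer = condition_preset("untreated"))

# detect junctions from the border channel and quantify the tracer channel
junctions <- geometric_detector(sim$border)
q <- quantify_image(sim$tracer, junctions)
q$report
#> <permeability_report> 67/168 junctions permeable (39.9%); total 395.0 RFU,
#> 85.4% via tricellular junctions; 5.03 RFU per permeable junction

# ground truth realised by the generator, for comparison
sim$truth
#> <tracer_truth> 64/168 junctions permeable, 75 spots, realised TJ share 0.840
```

About 40% of detected junctions are called permeable against a generated
38% (the 2-px rule also catches junctions adjacent to a spotted
neighbour), and 85% of all thresholded tracer signal is attributed to
tricellular junctions against a generated 84% — the junction-dominated
transport pattern the assay is designed to expose.

A full condition contrast, with replicate-level statistics:

```r
df <- simulate_condition_study(conditions = c("untreated", "s1p", "thrombin"),
                               junction_source = "geometric", seed = 5)
cc <- compare_conditions(df, pairs = list(c("untreated", "s1p")),
                         metrics = "total_accumulation")
cc$comparisons[c("metric", "percent_change", "t", "p", "stars")]
#>               metric percent_change        t            p stars
#> 1 total_accumulation      -45.00478 37.45217 3.035163e-06   ***
```

A command-line front end over the same functions is installed at
`inst/scripts/tjperm.R` (subcommands `simulate`, `train`, `segment`,
`quantify`, `summarize`, `compare`, `run`).

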