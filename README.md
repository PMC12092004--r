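# tfLC3quant

Neuron-level quantification of autophagic–lysosomal vesicle subtypes from
confocal images of the tandem fluorescent mRFP–eGFP–LC3 (tfLC3) autophagy
reporter combined with a cathepsin D (CTSD) immunolabel.

## The problem

The tfLC3 probe reports autophagy flux ratiometrically: autophagosomes (AP)
have a neutral lumen and carry both eGFP and mRFP signal (yellow), while in
acidic autolysosomes (AL) eGFP is quenched, leaving mRFP; a far-red CTSD
immunolabel (rendered blue) marks lysosomal compartments. Four organelle
classes follow from the channel combinations:

| subtype | meaning | channels | color |
|---|---|---|---|
| AP | autophagosome | eGFP + mRFP | yellow |
| AL | autolysosome | mRFP + CTSD | purple |
| pa-AL | poorly acidified AL | all three | white |
| LY | lysosome | CTSD only | blue |

Each segmented vesicle's mean channel intensities (R = mRFP, G = eGFP,
B = CTSD) are converted to a hue angle

```
hue = atan2( sqrt(3) (G - B), 2R - G - B ) in degrees, mapped to [0, 360)
```

and a saturation percentage `(max - min) / (max + min) x 100` on
normalized intensities (valid while lightness < 1). Vesicles are classified
by hue sector and channel presence — white (low-saturation, all channels
present) takes priority, then yellow, purple, blue — and counted per neuron
("Vesicle #/Neuron"). The package also partitions a fourth immunoreactivity
(IR) channel (e.g. mutant huntingtin, p62, ubiquitin) into AV-associated
and AV-unassociated area per cell by overlap with mRFP puncta, computes
integrated densities with low-staining region exclusion, converts raw
electron-microscopy tallies into rates per 100 neurons, and runs the group
statistics used with such data (unpaired two-tailed t-tests; one-way ANOVA
with Sidak-adjusted selected comparisons).

Because confocal source images for such studies are rarely deposited, the
package ships a synthetic scene simulator that renders 1024 x 1024 px
fields (212.34 x 212.34 µm) of neuronal somata with punctate vesicles
following the reporter logic, plus per-vesicle ground truth, so the whole
pipeline is testable end to end.

## Worked example

```r
library(tfLC3quant)

# a synthetic field: 10 neurons x (5 AP + 5 AL + 2 pa-AL + 8 LY)
scene <- generateScene(SceneConfig(seed = 42L))
res   <- processField(scene$field, scene$mask, thresholdSeed = 42L)

head(res$profiles[, c("neuron_id", "AP", "AL", "PA_AL", "LY", "total")])
#>   neuron_id AP AL PA_AL LY total
#> 1         1  5  5     2  8    20
#> 2         2  4  5     2  8    19
#> 3         3  5  5     2  7    19
#> 4         4  5  5     2  7    19
#> 5         5  5  5     2  8    20
#> 6         6  5  5     2  8    20

m <- matchToGroundTruth(res$vesicles, res$segmentation$labels, scene$groundTruth)
classificationAccuracy(m)
#> [1] 0.98

countRatePer100(113, 420)$rate_per_100_rounded   # granules per 100 neurons
#> [1] 27
```

Per-neuron subtype counts closely recover the simulated composition
(occasional merged doublets drop a count by one); 98 % of the
200 ground-truth vesicles receive their true subtype at the default
signal-to-noise level, and the tally helper reproduces the standard
per-100-neuron rate construction.

A full multi-group experiment (simulation, segmentation, classification,
statistics, CSV tables and a provenance record) runs from one JSON
configuration:

```r
runPipeline("config.json", "out/")   # or an equivalent R list
```

A thin command-line wrapper is provided in
`inst/scripts/run-pipeline.R` (`--config`, `--out`, `--seed`).

## Layout

- `R/` — S4 classes (`MultiChannelField`, `ROILabelMask`, `SceneConfig`,
  `SceneGroundTruth`, `ChannelThresholds`) and the analysis modules:
  image I/O, scene simulation, segmentation, hue classification,
  IR quantification, statistics, pipeline orchestration.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
- `vignettes/tfLC3quant-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
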