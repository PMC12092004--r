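---
title: "Hue-angle quantification of tfLC3 reporter images: methods and design"
author: "tfLC3quant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue-angle quantification of tfLC3 reporter images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfLC3quant)
```

## The measurement model

The tandem fluorescent mRFP–eGFP–LC3 (tfLC3) reporter exploits the pH
sensitivity of eGFP: autophagosomes (AP) have a near-neutral lumen and emit
both eGFP and mRFP, whereas fusion with a lysosome acidifies the lumen and
quenches eGFP, leaving mRFP. Adding a far-red cathepsin D (CTSD)
immunolabel — rendered as the blue channel — distinguishes lysosomal
compartments. Four organelle classes follow: AP (eGFP + mRFP, yellow),
autolysosome AL (mRFP + CTSD, purple), poorly acidified AL (all three,
white) and lysosome LY (CTSD only, blue).

The classifier operates on each segmented vesicle's mean channel
intensities $(R, G, B)$, where $R$ is mRFP–LC3, $G$ is eGFP–LC3 and $B$ is
CTSD. The hue angle is the direction of the chromatic opponent vector,

$$\mathrm{hue} = \operatorname{atan2}\!\big(\sqrt{3}\,(G - B),\; 2R - G - B\big)
\cdot \tfrac{180}{\pi},$$

mapped into $[0, 360)$ by adding $360^\circ$ to negative values; it is
undefined (achromatic) when both components vanish. One convention trap is
worth spelling out: spreadsheet `ATAN2(x, y)` takes the *x*-component
first, while the C/R `atan2(y, x)` convention takes the *y*-component
first. A silent mismatch reflects every hue; the red/green/blue axis
identities ($0^\circ$, $120^\circ$, $240^\circ$) pin the convention down,
and the test suite locks them. On the six canonical axes this circular hue
coincides with the familiar hexcone (HSL) hue; away from the axes the two
definitions differ by up to a degree or so, and the circular form — the
angle actually computed by the formula above — is the one used throughout.

Saturation is
$\mathrm{sat} = (\max - \min)/(\max + \min) \times 100$
on intensities normalised to $[0,1]$ by the full scale $2^{\mathrm{bit}}-1$.
The formula is valid provided lightness $(\max+\min)/2 < 1$; pixels at full
lightness are flagged saturated-white and assigned saturation 0, and an
all-zero vesicle yields 0 rather than 0/0.

### Classification rules

Rules are evaluated in a fixed priority order on hue, saturation and
channel presence (mean intensity strictly greater than the channel
threshold):

1. **pa-AL** — all three channels present and saturation below 25 %
   ("white" wins first, because a white vesicle also lies in some hue
   sector);
2. **AP** — hue in $[30^\circ, 90^\circ)$ with R and G present;
3. **AL** — hue in $[270^\circ, 330^\circ)$ with R and B present;
4. **LY** — hue in $[210^\circ, 270^\circ)$ with only B present;
5. otherwise **UNCLASSIFIED**.

The numeric hue boundaries are not dictated by the reporter logic (only
the colors are); the defaults centre on the canonical color axes (yellow
60°, blue 240°, magenta 300°) with ±30° sectors and are configuration
overrides, as is the 25 % white cutoff. Overlapping user-supplied sectors
are rejected at construction time. Red-only vesicles (mRFP present, CTSD
absent, hue near 0°) are UNCLASSIFIED by default since the AL definition
here is CTSD-coincident; a flag counts them as CTSD-negative AL instead.
Classification is invariant under positive intensity rescaling that
preserves the presence flags — which is why native integer units are used
throughout and only the lightness guard needs the bit depth.

## Segmentation

The segmentation sequence mirrors the standard interactive workflow, made
deterministic and parameterised:

- **Thresholds.** Each channel's threshold is the mean over sampled
  neuronal perikarya of that ROI's mean intensity in the channel
  (20 perikarya by default, sampled without replacement under a seed; all
  of them, with a warning, when fewer exist). Comparison is strictly
  greater-than, so ties are excluded deterministically.
- **Puncta mask.** Per-channel masks are unioned. Thresholding per channel
  before the union (rather than after) is a documented choice; both orders
  are defensible and the union is what the vesicle extractor sees.
- **Watershed.** Clumped vesicles are split on the smoothed summed-channel
  intensity landscape restricted to the mask: local maxima seed basins
  (neighbourhood radius `ext = 2` px, matching a ~2 px minimum peak
  separation after `sigma = 1` px smoothing), and a `tolerance` of 80
  native units (~2 % of the 12-bit scale) merges sub-peaks shallower than
  camera noise. Every mask pixel gets exactly one label, so pixel area is
  conserved; doublets with centers ≥ 2 spot-sigmas apart split reliably
  (a seeded property test covers 20 random doublets).
- **Size exclusion.** Labels below 3 px (~0.13 µm² at the default scale)
  are removed as background specks; no upper bound by default. Both bounds
  are configuration keys.
- **Neuron assignment.** A vesicle belongs to the neuron owning the
  plurality of its pixels; background-majority vesicles get id 0 and are
  excluded from per-neuron counts. Ties between a neuron and background go
  to the neuron, between neurons to the lower id — arbitrary but
  deterministic.

Pixel indexing follows R's native 1-based row/column convention.

## The synthetic scene simulator

No confocal source images are publicly deposited for this kind of study,
so validation rests on simulated scenes with known truth. The simulator
renders what the acquisition produces: a 1024 × 1024 px field covering
212.34 × 212.34 µm (the 40× raster, ~0.2074 µm/px, 12-bit), circular
somata (radius 8 µm, a medium spiny neuron perikaryon) with diffuse
cytosolic reporter signal (6 % of full scale in mRFP and eGFP, 2 % in
CTSD), and vesicles as isotropic 2-D Gaussian spots (amplitude = subtype
signature × full scale, σ = radius/2, radii uniform in 0.3–1.0 µm). The
subtype signatures put 80 % of full scale in each "present" channel and 0
in absent ones; the pa-AL signature uses equal R, G, B peaks so its
rendered saturation is near zero. After spot rendering the field is
blurred with a Gaussian PSF (σ = 0.15 µm, roughly diffraction-limited),
then Poisson photon noise and Gaussian read noise (σ = 0.5 % of full
scale) are applied on a 2 % background. Ten percent of vesicles are placed
as touching same-neuron doublets to exercise the watershed.

Default per-neuron composition is 5 AP + 5 AL + 2 pa-AL + 8 LY = 20
vesicles — an LY-rich, moderately loaded soma. Counts are exact by default
("fixed" mode); experiment simulations switch to Poisson-distributed
counts per neuron so neurons vary. All randomness flows from one seed
through R's Mersenne-Twister; the caller's RNG state is restored on exit,
and identical seeds give bit-identical scenes.

What the simulator deliberately does *not* emulate: lipofuscin
autofluorescence spectra, photobleaching, 3-D optics and z-stacks,
chromatic aberration, irregular soma shapes, and spatially varying
background. Passing tests therefore demonstrate that the algorithmic chain
is correct and well-calibrated on data obeying the forward model — not
that real tissue images of arbitrary quality will classify at the same
accuracy. At the default signal-to-noise level ≥ 95 % of vesicles recover
their true subtype; doubling the noise degrades accuracy gracefully rather
than catastrophically, which is the intended failure mode.

The immunoreactivity overlay adds a fourth channel of Gaussian blobs: a
configurable fraction is centered (with sub-radius jitter) on distinct
mRFP-positive vesicles, the remainder placed clear of all somata; spacing
is enforced on the above-threshold footprints (~1.4× the nominal radius)
so objects segment as discrete components. Per-object true association is
recorded, making the object-level association rule testable to binomial
tolerance (0.40 ± 0.02 at 500 objects).

## Immunoreactivity quantification

An IR object is AV-associated when at least one of its pixels overlaps the
mRFP puncta mask — association against the mRFP channel specifically,
since that is the signal identifying autophagic vacuoles — and its whole
area then counts to the associated form. The legend-level notion of a
stained structure being "associated" is categorical, so object-level
attribution is the default; a pixel-level mode (the overlap area itself)
exists for sensitivity analysis. In both modes total = associated +
unassociated holds exactly, per neuron, to the last pixel. Since it is not
stated whether per-cell areas were normalised, the partition reports both
absolute µm² and the fraction of the cell's area.

Integrated density sums a channel over the field after excluding
minimally stained regions (e.g. striatal fiber bundles) with intensity at
or below a cutoff; both included and excluded areas are reported, and the
quantity is additive over disjoint included regions. Raw
electron-microscopy tallies convert to rates per 100 neurons
(`countRatePer100`), reported unrounded and rounded.

## Statistics

The unit of analysis is the neuron, matching the per-neuron *n* such
figure legends quote; this treats neurons from one animal as independent,
which overstates the effective sample size — per-animal aggregation is
available by grouping the profile table on a mouse column, and no
mixed-effects modelling is attempted. Two-group comparisons use Student's
pooled-variance two-tailed t-test (the common Prism default; Welch by
flag), cross-checked against `t.test` to 1e-12. Multi-group designs use
one-way ANOVA with pairwise comparisons on the pooled error term and Sidak
adjustment $1-(1-p)^m$ over the $m$ *requested* comparisons (the
"selected comparisons" convention, with $m$ recorded). Degenerate inputs
(zero variance everywhere) yield $t = 0$, $p = 1$ and a flag rather than
an error. Type-I calibration is verified by simulation (10,000 null pairs
at $n = 50$, rejection rate 0.05 ± 0.005).

The effect-recovery experiment simulates a disease pattern — AL up 30 %,
pa-AL doubled, LY down 25 %, AP unchanged — at 100 neurons per group
(20 fields of 5 neurons, 512 × 512 px each, chosen to keep a full run in
tens of seconds while preserving the per-neuron unit). The magnitudes are
the simulator's own choices: the direction pattern is what matters, and
these sizes give clearly directional, well-powered effects without being
trivially large.

## Numerical and degenerate-input choices

- Achromatic triples have undefined hue (`NA`), not 0: a grey vesicle has
  no hue sector and must not fall into the red sector by accident.
- `max + min = 0` yields saturation 0; full-lightness white is flagged and
  zeroed under the lightness guard.
- Thresholding is strict (`>`), so a pixel exactly at threshold is
  background; raising any threshold can only shrink the mask (tested as a
  monotonicity property).
- Watershed tolerance and the local-maximum radius are configuration keys;
  the defaults (80 units, 2 px) were set from the noise scale and spot
  geometry of the forward model, not tuned per dataset.
- Tables are written with '#'-prefixed metadata headers (effective rules,
  seeds, thresholds) and full-precision numerics so they round-trip
  losslessly; images round-trip as 16-bit TIFF.
- Pipeline runs are deterministic: per-field seeds derive from the master
  seed, and provenance (config, seeds, rules, package version) is written
  alongside the tables with no timestamps, so identical configurations
  produce byte-identical outputs.

## Known limitations

- Hue sector boundaries and the white cutoff are assumptions standing in
  for an interactively calibrated workflow; they are exposed in
  configuration and echoed into output metadata precisely because a real
  dataset may need different values.
- Neuron/perikaryon masks are inputs; the package does not segment somata.
- Heavily merged clumps (more than two touching vesicles, or doublet
  centers well under two sigmas apart) may under-split, which shows up as
  slightly low per-neuron totals rather than misclassification.
- Neuron-level statistics inherit the pseudo-replication caveat above.
- Classification accuracy quoted anywhere in this package refers to
  simulated scenes under the stated forward model.
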