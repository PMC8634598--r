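---
title: "Quantifying exosome release and autophagosome puncta at the NMJ: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exosome release and autophagosome puncta at the NMJ: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjquant)
```

## The two measurements

At the *Drosophila* larval neuromuscular junction, a motor-neuron terminal
forms a chain of rounded boutons (2–5 µm diameter) embedded in the folded
postsynaptic muscle membrane (the subsynaptic reticulum, roughly 1 µm
thick). Two cell-biological readouts are commonly scored on two-channel
confocal images of this synapse:

1. **Exosome release**: a tagged transmembrane cargo (Evi-GFP) that leaves
   the bouton in exosomes accumulates in the subsynaptic reticulum. The
   quantity of interest is the protein signal in a calibrated shell around
   the bouton, normalized by the neuronal-membrane (HRP) signal in the same
   shell.
2. **Autophagosome abundance**: Atg8-mCherry (LC3) concentrates in
   sub-micron puncta. The quantity of interest is the number of such
   puncta inside the synaptic compartment traced by a surrounding marker
   (DLG).

Both were originally scored with interactive ImageJ macros. This package
reimplements the measurement logic as deterministic functions so that the
same image and parameters always produce the same numbers.

## Pipeline definitions

### Segmentation shared by both pipelines

The mask channel is thresholded with Otsu's criterion: the threshold
maximizes the between-class variance of a 256-bin histogram. The histogram
always spans the full nominal bit-depth range (0–4095 for 12-bit data, in
bins of width 16), not the per-image min–max. Two images acquired with
identical settings therefore see identical bin boundaries, which keeps
thresholds and 8-bit conversions comparable across a dataset — the same
reason acquisition settings must be held constant in the first place.
Foreground is *strictly above* the threshold. A constant image (a single
occupied bin) has no threshold and raises an error.

The interactive wand-tool click is replaced by `select_component()`: the
8-connected component under an explicit seed pixel, or the largest
component (ties broken by reading order of the first pixel). 8-connectivity
matches the wand's behavior on thresholded images and is used for every
component operation in the package.

### Exoquant

Given bouton set $B$ and its Euclidean enlargement $B_d$ by $d$ µm
(default $d = 1$, the subsynaptic-reticulum thickness):

* rows 1–2: both full channels;
* rows 3–4: both channels over $B$;
* rows 5–6: both channels over $B_d$ *after* $B$ is set to zero;
* rows 7–8: both cleared channels over the full frame.

Because clearing precedes measurement, the raw integrated densities of
rows 5–6 contain shell signal only, and rows 7/8 equal rows 1/2 minus
rows 3/4 as exact integer identities — a useful internal check that is
asserted on every run of the test suite. The *means* of rows 5–6 are
diluted by the zeroed interior; this is faithful to the original macro's
measurement region. An optional annulus-only measurement
(`exoquant_config(annulus = TRUE)`) is provided for users who want
undiluted shell means; the release index uses raw integrated density and is
identical either way.

The release index is row 6 / row 5 raw integrated density (shell protein
over shell membrane marker). The historical inside/outside ratio (shell
protein over bouton-interior protein) is available via
`index_mode = "inside-outside"`; it is more sensitive to expression-level
differences between genotypes, which is why the shell-normalized form is
the default. Integrated density, not mean, feeds the index because the
readout is the *amount* of released protein, not its concentration, and
integrated density is insensitive to the zero-dilution choice above.

### Autophagoquant

The protein channel is linearly converted to 8-bit over the full nominal
range, median-filtered with a Euclidean disk of radius 1 px (the pixel and
its 4 edge neighbors; borders use the available neighborhood only), and
thresholded at `mean + 4·SD` of the filtered ROI. The mean/SD come from the
filtered ROI (results row 2) because the filter is applied before the
threshold is derived; `threshold_source = "unfiltered"` switches to row 3.
Candidate pixels must exceed the threshold strictly, so a zero-variance ROI
detects nothing rather than everything.

8-connected candidate components are filtered on calibrated area
(0.09–0.5 µm² by default — the empirical window for Atg8 puncta) and
circularity ($4\pi A / P^2$, capped at 1; floor 0 by default because puncta
circularity is inconsistent). The perimeter is the outer-boundary chain
code: edge steps count one pixel, diagonal steps $\sqrt 2$. On digital
rasters this perimeter is short enough that compact particles exceed
circularity 1 before capping; the cap, not the raw value, is reported.

Surviving dots are merged iteratively: the closest centroid pair at
distance ≤ 0.5 µm merges into the union of pixel sets, the union's
centroid is recomputed (area-weighted, as the centroid of a pixel union
must be), and the procedure repeats, so chains can collapse through
intermediate merges. Ties on distance resolve toward the pair whose
centroids come first in reading order. One consequence worth knowing:
three *equal-mass* collinear dots at 0.4/0.4 µm spacings stabilize at two
objects (the first union's centroid lies 0.6 µm from the third dot);
chained collapse to a single object requires the middle dot to carry about
3× the mass, which the test suite demonstrates explicitly. Merged dots are
not re-filtered on size, since filtering precedes merging. Edge-to-edge
distance is available via `merge_metric = "edge"`.

Results row 4 ("above-threshold area of the protein channel") is
constructed from the protein channel's own Otsu threshold within the ROI;
`row4_mode = "detection"` substitutes the mean+4·SD detection set for users
who prefer the detection-consistent definition. The summary table is
computed over the 0/255 binarized detection image restricted to dot pixels,
which is why its mode and median are 255 whenever at least one dot exists.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `shell_distance_um` | 1.0 | µm | extracellular quantification band (SSR thickness) |
| `k_sd` | 4 | – | detection threshold in ROI standard deviations |
| `median_radius_px` | 1 | px | disk radius of the noise filter |
| `size_min_um2`, `size_max_um2` | 0.09, 0.5 | µm² | particle size window |
| `circ_min`, `circ_max` | 0, 1 | – | circularity window |
| `merge_distance_um` | 0.5 | µm | centroid distance below which clusters merge |
| `pixel_size_um` | required | µm/px | spatial calibration |

The size window is interpreted in µm² (the particle analyzer's native
unit). Because size calibration is sometimes done by measuring the base of
a fluorescence profile — a *diameter* — `size_unit = "um-diameter"`
converts a diameter window to an area window via $\pi (d/2)^2$.

Pixel size is a required input: none of the calibrated defaults can be
applied without it, and it is deliberately never guessed from image
content. It is read from TIFF resolution tags when present and must be
supplied otherwise. Anisotropic pixels are rejected.

## The synthetic generator

`make_exo_stack()` renders a filled-disk bouton (default radius 2 µm at
0.1 µm/px on a 256×256 frame, 12-bit) over a dimmer SSR-like shell in the
mask channel, and a diffuse interior level plus single-pixel shell plants
in the protein channel. Single-pixel plants make the planted shell sums
`S` and `M` exact, so noise-free pipeline output can be compared without
tolerance: `release_index == S/M`. `make_auto_stack()` renders a DLG-like
disk and compact (optionally elliptical) puncta of calibrated area, with
pairwise separation and size-window preconditions enforced, and records
each spot's pixel set plus the object count expected after merging.

What the generator emulates: calibrated two-channel geometry, a clear
Otsu gap between structure and background, diffuse-plus-punctate protein
distributions, additive Gaussian (optionally Poisson) noise, optional
Gaussian blur. What it does not emulate: realistic point-spread functions,
multi-bouton chains, SSR texture, staining artifacts, or neighboring
structures (trachea, nerves) that the original workflow advises screening
out by eye. Passing tests therefore demonstrate algorithmic correctness on
images satisfying the pipelines' assumptions, not robustness to
low-quality acquisitions — images with low signal-to-noise or saturated
regions still need human screening, and the package warns when saturated
pixels are present.

Default noise-free fixtures are 256×256 px; tests that need statistics use
100 seeded replicates at noise σ equal to one tenth of the spot
peak-minus-background contrast, and oracle comparisons (all-pairs
enlargement, exhaustive Otsu search) run on grids up to 32×32 where the
brute force is exact and fast. These sizes were chosen to keep the whole
suite under a minute while leaving every code path exercised at realistic
geometry (a 2 µm bouton at 0.1 µm/px is a typical acquisition scale).

## Numerical conventions

* Statistics are population moments (÷ n); excess kurtosis; skewness and
  kurtosis of a zero-variance region are reported as 0 by convention.
* The mode takes the smallest value on ties; the median of an even-count
  region takes the lower middle. Both mirror ImageJ's measurement
  definitions so results tables are stable and comparable.
* The median *filter* likewise takes the lower middle on even-count border
  neighborhoods, keeping integer images integer.
* Raw integrated density is an exact integer sum (stored as double; image
  sums stay far below 2^53).
* Enlargement uses an exact Euclidean distance transform
  (squared-distance lower-envelope algorithm) with the comparison
  `d² ≤ (distance/pixel_size)²`, not iterated structuring-element
  dilation; this is exactly reproducible by an all-pairs oracle.
* 8-bit conversion rounds half-up on the full nominal range; it is
  monotone and endpoint-exact (0 → 0, 4095 → 255).
* Saturated pixels trigger a warning but do not stop quantification.
* Degenerate inputs are errors with stable messages: constant images for
  Otsu ("degenerate histogram"), empty masks, seeds on background, empty
  regions. A flat protein channel in Autophagoquant yields zero dots and
  an undefined row 4 rather than an error, since that is a legitimate
  biological outcome (no puncta).

## Known limitations

* 2D single-plane images only; no z-stacks or time series.
* One ROI per run: batch images should contain one bouton of interest, or
  a seed pixel must be supplied per image.
* The merge rule is centroid-based by default; for elongated touching
  clusters edge-to-edge merging may be more appropriate.
* The release index is undefined (NA with a warning) when the shell
  membrane signal is zero — possible on masks that fill the frame or with
  a zero shell distance.
* Group-level statistics (normality tests, t-tests) are out of scope; the
  package emits tidy per-image tables for downstream analysis, plus
  `normalize_to_control()` for the customary wild-type rescaling.
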