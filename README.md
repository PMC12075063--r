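# mnmorph

3D morphometry of spinal motoneurons (MNs) from cleared-tissue
fluorescence stacks, for anatomists and imaging scientists quantifying
motoneuron development: instance segmentation of densely packed somata,
soma-volume statistics with clearing-expansion correction, size-based
classification of putative γ versus α motoneurons, and dendritic-arbor
extraction and metrics from sparsely labelled neurons. A synthetic-data
generator provides ground-truthed phantoms, so the whole pipeline is
testable without microscope data.

## The methods at its core

**Soma chain.** A stack is median-filtered (erasing neurites), binarised
by hysteresis thresholding (or any injected mask, e.g. from a trained
network), and split into instances by marker-based watershed of the
Gaussian-gradient magnitude inside the mask, with seeds taken as the
h-maxima of the anisotropy-aware Euclidean distance transform. Per-soma
volumes are measured in the cleared frame and corrected by the cube of the
linear expansion factor: for the default 1.2× isotropic expansion,

  V_real = V_measured / 1.2³ = V_measured / 1.728.

Volumes are binned on the standard 0–38 000 µm³ grid (1 000 µm³ bins) and
fitted with one or two Gaussian curves A·exp(−(x−µ)²/2σ²) by
Levenberg–Marquardt least squares on the counts. With two components, the
x-coordinate of the intersection of the fitted curves defines the size
threshold: somata below it are putative γMNs, above it putative αMNs.

**Dendrite chain.** Rod- and ball-model Hessian structure enhancement
(Frangi-type vesselness at 1–3 µm scales; blobness at 4–8 µm) are fused
and thresholded into one soma-plus-dendrites mask, labelled per neuron by
watershed, thinned topologically to a centerline, and rooted at the soma
to a SWC tree with centrifugal branch orders (root-attached = order 1).
Metrics: 3D Sholl profiles (crossings of concentric spheres around the
soma), crossings per branch order, per-order branch lengths (mean ± SEM),
and tortuosity = curve length / chord length ≥ 1.

## Worked example

Segment a synthetic crowded field and measure somata:

```r
library(mnmorph)

spec <- soma_field_spec(grid_shape = c(128, 128, 128), spacing_um = 1.5,
                        n_somata = 10, min_gap_um = 25, seed = 31)
sim <- generate_soma_field(spec)

labels <- segment_somata(sim$stack)
labels
#> <label_volume> 128x128x128 voxels, 10 instances

somas <- measure_somas(labels, expansion_spec(1.2))
head(somas[, c("id", "voxel_count", "volume_raw_um3", "volume_um3")], 4)
#>   id voxel_count volume_raw_um3 volume_um3
#> 1  1         868        2929.50   1695.313
#> 2  2        2838        9578.25   5542.969
#> 3  3        4548       15349.50   8882.813
#> 4  4        3182       10739.25   6214.844
```

All ten somata are recovered; `volume_um3` is `volume_raw_um3 / 1.728`,
the soma size in the un-expanded tissue frame.

Classify a realistic-size sample (889 somata, 32.6 % drawn from the
small-soma component) by the histogram fit and intersection threshold:

```r
draws <- sample_volume_mixture(889, list(w = 0.326, mean1 = 4000, sd1 = 1200,
                                         mean2 = 15000, sd2 = 4000), seed = 7)
fit <- fit_gaussians(histogram_volumes(draws$volume_um3), 2)
fit
#> <mixture_fit> 2 component(s)
#>   A=85.8 mu=4156 sigma=1429
#>   A=55.2 mu=14703 sigma=4162
#>   threshold = 7093.5 um3

cl <- classify_somas(data.frame(volume_um3 = draws$volume_um3),
                     fit$threshold_um3)
100 * cl$small_fraction
#> [1] 36.3
```

The fitted means and SDs track the generating mixture, the threshold falls
between the component means, and 36.3 % of this replicate is called
putative γ — close to the 32.6 % generating weight (single replicates
scatter by a few points; the averaged recovery is within ±2 points).

For dendrites: `generate_neuron_stack()` renders a ground-truthed neuron,
`trace_neuron()` returns its rooted skeleton, and `sholl()`,
`branch_lengths_by_order()` and `neuron_report()` produce the metric
tables; `write_swc()`/`read_swc()` are the interface for externally edited
reconstructions. `run_pipeline(pipeline_config(...))` drives the whole
chain from a config and writes a manifest with per-file checksums. A thin
command-line dispatcher over these functions is installed at
`inst/cli/mnmorph.R`.

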