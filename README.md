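# clonecortex

Clonal analysis of combinatorially labeled cells in the cerebral cortex.

Combinatorial fluorophore labeling (CLoNe-style lineage tracing) gives every
labeled progenitor a random combination of fluorophore expression levels;
all cells of a clone inherit that combination. `clonecortex` implements the
computational pipeline that turns multichannel confocal images of such
tissue into clonal statistics, for developmental neurobiologists analyzing
progenitor lineages in laminated cortex:

* **Segmentation** — iterative histogram-based multi-level thresholding of
  each 8-bit channel, with the number of thresholds *n* selected by the PSNR
  elbow (`select_thresholds()`, `choose_optimal_n()`), and cell extraction
  as connected components with centroids and per-channel mean intensities
  (`detect_cells()`).
* **Decoding** — quantization of mean intensities into five 51-point levels
  (ℓ = ⌊I/51⌋ on the 0–255 scale), concatenated into a per-cell *code*;
  cells sharing a code within a section form one clone (`encode_cells()`,
  `group_clones()`, `clone_size_histogram()`).
* **Statistics** — pairwise distances of clonally related vs unrelated
  cells stratified by cortical layer with exact/approximate Mann–Whitney
  tests (`pair_distances()`, `summarize_dispersion()`, `mann_whitney()`),
  Sidak-corrected layer-wise Welch comparisons (`compare_layer_counts()`,
  `sidak_adjust()`), laminar contribution fractions
  (`laminar_contribution()`), and the conversion of an all-cells lineage
  fraction into an excitatory-neuron fraction
  f / (p_neuron · (1 − p_interneuron)) (`excitatory_fraction()`).
* **Synthetic data** — a seeded generator of ground-truthed coded clones in
  a laminated slab, rendered as multichannel 8-bit TIFFs
  (`simulate_clones()`, `render_image()`), so the whole chain is testable
  without microscopy data.

`run_pipeline()` chains simulate → segment → decode → stats on one seeded
configuration and writes a manifest with checksums;
`inst/scripts/clonepipe.R` is a thin command-line wrapper with the same
subcommands. The methods vignette (`vignettes/clonal-analysis.Rmd`)
documents the model, parameter choices and limitations.

## Worked example

Simulate 50 clones at zero intensity noise, render, and run the full
analysis:

```r
library(clonecortex)

model  <- default_cortical_model()          # L1..L6 + SP, 1000 um deep
params <- sim_params(n_clones = 50, noise_sd = 0, seed = 11)
sim    <- simulate_clones(model, params)
sim
#> Simulated clones: 50 clones, 942 labeled cells, 0 unlabeled cells

img <- render_image(sim$cells, render_config())
img
#> Multichannel 8-bit image: 1001 x 2000 px, 4 channels, 1 um/px

cells <- detect_cells(img)                  # thresholds chosen per channel
cells$layer <- layer_of(model, cells$y_um)
clones <- group_clones(encode_cells(cells))
clones
#> Clone partition: 50 clones over 942 labeled cells ( 0 unlabeled)

clone_size_histogram(clones)
#> Clone sizes (50 clones):
#>   [1,8)  [8,16) [16,32]
#>       6      15      29
#> unrepresented sizes: 2, 3, 6, 7, 10, 13, 16, 24, 25, 26

summarize_dispersion(pair_distances(clones$cells))
#> Pairwise distance dispersion (um):
#>  relatedness layer_class      n mean_um sd_um
#>      related        same   5032    85.6  79.1
#>    unrelated        same  89543   723.0 475.3
#>      related   different   5429   161.4  78.2
#>    unrelated   different 343207   818.2 429.7
#>      related       total  10461   124.9  87.3
#>    unrelated       total 432750   798.5 441.2
#> Mann-Whitney related vs unrelated:
#>  layer_class         U p_value
#>         same  19234206       0
#>    different  52738642       0
#>        total 143481738       0

excitatory_fraction(0.30, 0.64, 0.25)
#> [1] 0.625
```

Reading the output: all 942 rendered cells are recovered and decode to the
generated clone partition exactly (zero noise, bin-centered intensities);
clone sizes fall in the configured classes with the largest class most
frequent; clonally related cells lie far closer together (e.g. 161 µm
across layers) than unrelated cross-clone pairs (818 µm), with vanishing
Mann–Whitney p — the hallmark signature of genuine clones. The last line is
the bookkeeping that converts a lineage contributing 30% of all cortical
cells (64% of cells neuronal, 25% of neurons interneurons) into 62.5% of
excitatory neurons.

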