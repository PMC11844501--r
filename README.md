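# punctamap

Quantification of punctate neuropeptide innervation in layered brain
tissue, for neuroanatomists quantifying immunohistochemistry in
multichannel confocal images. The package grew out of the analysis
problem posed by hypothalamic orexin-A and MCH axons innervating the
mouse olfactory bulb (OB): sparse, punctate immunoreactive processes
spread across four nested layers (GL, EPL, MCL, GCL), where the
questions are *how dense is the innervation per layer*, *which processes
are axon terminals rather than fibers of passage*, and *which terminals
co-express a vesicular glutamate transporter (VGLUT1/VGLUT2)*.

Every stage is implemented against a seeded synthetic-scene generator
that renders calibrated multichannel stacks with exhaustive ground
truth, so the whole pipeline can be validated end to end on scenes whose
correct answer is known.

## What it computes

1. **Segmentation + size filter.** A per-pixel foreground mask (Otsu by
   default; fixed-threshold and a trainable scribble-based classifier
   are provided), then 8-connected particle extraction keeping only
   components of more than 2 pixels — at the 0.65 µm tiled pixel size,
   a 0.845 µm² floor.
2. **Layer density.** Each particle is assigned to the layer polygon
   containing its centroid (even-odd rule, boundary-inclusive), and
   density is `count / layer area` (processes/mm²), with
   anterior–posterior profiles summarised as mean ± SEM across
   preparations.
3. **Nucleator morphometry.** For each process, the largest
   cross-section within a ≤ 2 µm z-window is measured with the
   nucleator probe: 6 equally spaced rays from the centroid,
   `A = π r̄²` with `r̄` the mean centre-to-edge distance.
4. **Size-transition detection.** Areas are sorted and adjacent
   differences ("the derivative of the sorted size distribution")
   scanned for the first jump at least `k = 3` times the mean
   difference; the transition point is the midpoint of the two flanking
   areas. Processes strictly above the threshold are putative axon
   terminals; the rest are fibers of passage.
5. **Object-based co-localization.** Each terminal footprint is scored
   against each VGLUT channel by overlap fraction (≥ θ = 0.5) and
   morphology similarity (IoU against the best-matching marker
   component, ≥ s_min = 0.3), yielding the four-way categories
   `1-/2-`, `1+/2-`, `1-/2+`, `1+/2+`, summarised per image and pooled.
6. **Statistics.** N-way ANOVA (type-II sums of squares), Tukey HSD with
   significance stars, mean ± SEM summaries, and a deterministic
   markdown report.

## Worked example

Render one orexin-A-like high-resolution field (0.1 µm pixels, 0.2 µm
z-steps) and run the morphometry + co-localization pipeline:

```r
library(punctamap)

spec  <- highres_scene_spec(n_terminals = 30, profile = "orexin", seed = 42)
scene <- render_section(spec)
scene
#> <scene> <section_stack 708 x 708 px, 5 z-slices, channels: NP, VGLUT1, VGLUT2, DAPI; 0.1 um/px, 0.2 um z-step>
#>   64 ground-truth objects (38 terminals, 26 fibers)

res <- analyze_coloc_section(scene$stack, scene$layers, pipeline_config())
res$size_threshold
#> <size_threshold: 1.2490 um^2 (peak 0.9894 = 7.9 x mean derivative, n = 64)>

summarize_proportions(res$records)
#> <proportion_table: 38 terminals over 1 images>
#> # A tibble: 4 x 6
#>   category mean_pct sem_pct n_images n_terminals pooled_pct
#>   <fct>       <dbl>   <dbl>    <int>       <int>      <dbl>
#> 1 1-/2-       39.5       NA        1          15      39.5
#> 2 1+/2-        5.26      NA        1           2       5.26
#> 3 1-/2+       36.8       NA        1          14      36.8
#> 4 1+/2+       18.4       NA        1           7      18.4
```

The 64 measured processes split at a detected size transition of
1.25 µm² (the measured fiber/terminal gap of this image; measured areas
scale with the segmentation threshold, so the transition sits above the
generative gap midpoint while separating the two classes exactly). The
38 supra-threshold terminals are then scored against both VGLUT
channels; here 36.8% overlap VGLUT2 alone, close to the generative
mixture value of 39.4% for a single ~40-terminal field. Pooling many
fields tightens the estimate — that is what the acceptance script does.

`plot_density_map()`, `plot_layer_density()`, `autoplot()` on
size-threshold and proportion objects, and `tidy()`/`glance()` methods
are provided for figures and tabular export. A thin command-line
wrapper lives at `inst/scripts/punctamap.R`
(`simulate` / `run` subcommands).

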