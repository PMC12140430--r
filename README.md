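# omnicyte

Quantitative analysis of time-lapse microscopy of bacterial microcolonies:
from raw per-frame images to registered, segmented, linked and quantified
single-cell trajectories.

Rod-shaped bacteria such as *E. coli* grown on agarose pads proliferate from
a single progenitor into a monolayer microcolony of touching cells. Turning
such a movie into biology requires a chain of steps — drift removal,
instance segmentation with contact-tolerant masks, frame-to-frame linking
with division detection, and per-cell cytometry — and an error anywhere in
the chain corrupts everything downstream. `omnicyte` implements that chain
as composable R functions, together with the two evaluation metrics that
matter for this kind of pipeline and an agent-based colony simulator that
provides exact ground truth, so every stage is testable without any
external dataset.

## What is in the package

* **Synthetic microcolonies** (`simulate_colony()`): spherocylindrical cells
  with exponential length growth L(t) = L₀·e^{gt}, stochastic division
  length, slightly asymmetric binary fission, and mechanical relaxation
  keeping the colony a monolayer of touching, non-overlapping rods.
  Ground-truth label masks, lineage and focus tables come for free, and
  `render_modality()` draws the colony in phase-contrast, under/over/in-focus
  brightfield, cytoplasmic- or membrane-fluorescence contrast.
* **Dataset I/O** (`discover_dataset()`, `read_mask_png()` /
  `write_mask_png()`, frame/cell files): the
  `<base>_t<T>xy<P>c<C>.tif` filename dialect, editable 16-bit PNG cell
  masks, and per-frame / per-cell / per-position output slicings.
* **Registration** (`estimate_shift()`, `register_stack()`): stage-drift
  removal by windowed cross-correlation with matrix-multiply DFT
  upsampling; sub-pixel to 1/upsample px.
* **Segmentation** (`baseline_segment()`, `import_masks()`,
  `clean_mask()`): a classical seeded-propagation baseline plus an import
  path for externally generated (e.g. learned) masks, with contact-tolerant
  instance-label semantics — touching cells, distinct labels, no background
  gap. `mask_boundary_recession_loss()` quantifies the area a
  gap-requiring segmenter loses per cell.
* **Linking** (`track_cells()` = `enforce_temporal_consistency()` +
  `assign_cell_ids()`): greedy maximum-overlap assignment with explicit
  division detection, suppression of 1→2→1 division flicker, persistent
  cell IDs, lineage trees, and re-import of hand-corrected track tables.
* **Cytometry** (`compute_frame_metrics()`, `assemble_clist()`,
  `export_clist()`): medial-axis length and width, per-channel
  fluorescence, diffraction-limited focus detection with long-axis
  coordinates, exponential elongation-rate fits, and a registry-validated
  clist (≥ 80 per-cell descriptors, ≥ 20 per-cell-per-frame quantities)
  exported as CSV or XLSX.
* **Evaluation** (`width_from_contact()`, `count_fatal_errors()`): the true
  cell width inferred from stacks of k side-by-side touching cells
  (span/k), bias/σ summaries, and cumulative fatal-error curves with the
  division-timing exemption.
* **Visualization** (`frame_mosaic()`, `kymograph()`, `cell_tower()`,
  `plot_lineage_tree()`, `extract_outline()`): mosaics with vector cell
  outlines, time × long-axis kymographs, axis-aligned cell towers, and
  lineage trees.

## Worked example

```r
library(omnicyte)

p   <- sim_params(n_frames = 40, seed = 3)   # 3 min/frame, 100 nm/px
sim <- simulate_colony(p)
sim
#> colony_sim: 40 frames, 31 cells total, 16 alive at end

res <- track_cells(sim$masks)                # link + divisions + IDs
fm  <- lapply(seq_len(sim$n_frames), function(t)
  compute_frame_metrics(sim$masks[[t]], list(), frame = t))
cl  <- assemble_clist(res, fm)
cl
#> clist: 31 cells, 66 per-cell descriptors; 226 cell-frames, 19 per-frame quantities

width_from_contact(sim$masks[[40]], p$pixel_size)$width_um
#> 1.020   # um; the simulated width is 1.0

fe <- count_fatal_errors(res$masks, sim$masks, sim$lineage,
                         pred_tracks = res$tracks)
fe$n_total
#> 0       # lineage recovered without a single over-/under-segmentation
          # or linking error

rates <- cl$cells$elongation_rate_per_min[cl$cells$lifetime_frames >= 8]
round(c(mean = mean(rates), true = p$growth_rate), 5)
#>    mean    true
#> 0.02743 0.02773
```

The width-from-contact estimate (1.020 µm against a true 1.0 µm) divides
the perpendicular span across stacks of touching cells by the number of
cells crossed, which cancels the per-boundary segmentation bias that a
direct per-cell width measurement would carry. The zero fatal-error count
says the recovered lineage needed no hand correction; the elongation-rate
fit recovers the simulated growth rate to about 1%. With fluorescence
channels and focus detection enabled the clist grows to 89 per-cell and 34
per-frame quantities (see `descriptor_registry()`).

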