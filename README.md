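# rhizotrack

Quantitative analysis of *Rhizobium leguminosarum* motility and symbiosis
phenotypes. Soil rhizobia reach legume roots by run-and-tumble swimming —
near-straight runs interrupted by brief flagellar reorientations — and their
chemotaxis systems shape both free-living motility and the later stages of
nodule symbiosis. Characterising those phenotypes takes four measurement
chains, all of which this package implements as tested, reusable R code:

1. **Single-cell motility tracking** — detect bacteria as subpixel spots in
   capillary video frames, link them into per-cell trajectories by optimal
   gated assignment, and estimate each track's mean swimming speed (um/s)
   and tumble rate (events/s).
2. **Swimming-halo dose-response** — fit halo diameter versus carbon
   concentration with four-parameter log-logistic curves
   `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))` or a line, select
   between them by small-sample corrected information criterion, and
   estimate the maximum non-motile baseline (control mean + 2 SD).
3. **Flow-cytometry gating** — classify nodule-content events into
   undifferentiated bacteria versus bacteroids with an explicit fluorescence
   threshold plus linear scatter gate, and scale counts to cells per gram of
   nodule.
4. **Nodule counting** — segment X-gal-like or Magenta-GlcA-like stained
   nodules in root photographs by colour thresholding, 8-connected
   labelling and watershed splitting.

Because the raw videos and photographs behind such studies are not
deposited, the package carries a first-class synthetic-data generator for
each input type (run-and-tumble swimmers rendered as noisy frame stacks,
sigmoidal halo tables, bivariate scatter mixtures, stained-root images) and
validates every chain by parameter recovery against known ground truth. The
published wildtype motility statistics — mean speed 44, 38, 41 um/s and
tumble rate 0.11, 0.14, 0.08 /s on glucose, pyruvate and succinate — serve
as the generative parameter sets (`rlv_motility_params()`).

## Worked example

Simulate wildtype-glucose swimmers, render them to frames, and run the full
tracking pipeline:

```r
library(rhizotrack)

sw <- swimmer_params(n_cells = 12, mean_speed = 44, speed_sd = 7,
                     tumble_rate = 0.11, duration = 3, seed = 1100)
im <- imaging_params(frame_width = 512, frame_height = 512)
res <- track_motility_experiment(sw, im, n_batches = 200)
res$summary
```

```
  group n_tracks speed_mean speed_sd tumble_mean tumble_sd
1   all     1367   43.04452 6.737502   0.1095235   0.46621
```

The recovered population speed (43.0 um/s) sits within ~2% of the
generative 44 um/s, and the pooled tumble rate (0.110 /s) within ~1% of the
generative 0.11 /s; the large per-track SD of the tumble rate is the
expected zero-inflation when rate x track length < 1 event. The `analysis/`
directory holds numbered drivers that run each assay end-to-end and write
tidy tables under `results/`:

```sh
Rscript analysis/01_motility_recovery.R   # tracking recovery, 3 conditions
Rscript analysis/02_halo_models.R         # dose-response fits + baseline
Rscript analysis/03_cytometry_gating.R    # bacteria/bacteroid gating
Rscript analysis/04_nodule_counts.R       # stained-nodule counting
```

For example, `02_halo_models.R` prints the selected model per strain and
carbon source (the non-motile fliG-like control sets a 9.1 mm baseline),
`03_cytometry_gating.R` recovers a 29.9% bacteroid deficit from a cohort
generated with 30% fewer bacteroids, and `04_nodule_counts.R` counts 60
synthetic root images with 100% of counts within 1 nodule of truth.

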