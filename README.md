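# scaffoldtrack

Quantitative image analysis of 3D cancer-cell migration and hydrogel
microarchitecture in microfluidic devices.

Microfluidic chips filled with collagen or collagen–Matrigel hydrogels are
a standard platform for watching tumor cells migrate through matrices that
mimic the invasion front. Turning those experiments into numbers requires
four separate image pipelines, which this package implements for R users
(biologists and image analysts running migration assays):

* **Cell tracking** — fluorescence time-lapse frames are contrast-enhanced
  (CLAHE), segmented by minimizing the two-phase Chan–Vese energy
  *E(S) = λ₁ Σ_{p∈S} (I_p−c₁)² + λ₂ Σ_{p∉S} (I_p−c₂)² + μ·Per(S)*
  **exactly** via graph min-cut (compiled Dinic max-flow on the pixel
  lattice), labeled, and linked across frames by gated one-to-one
  nearest-neighbour association.
* **Migration statistics** — per-track accumulated distance, mean
  accumulated distance (MAD, pooled and replica-pondered), average speed
  (µm/hr), and the velocity-SVD polarity profile with an anisotropy index
  that separates isotropic/persistent random walks from anisotropic ones.
* **Fiber networks (confocal reflection)** — steerable-filter ridge
  enhancement, local Otsu binarization, FIRE-style medial-axis fiber
  tracing with junction splitting, per-fiber length and worm-like-chain
  persistence length (fit of E[cos Δθ(s)] = e^(−s/2Lp)), and pore sizing
  by the covering radius transform over the liquid-phase medial axis.
* **SEM morphometry** — statistical-region-merging binarization, porosity
  %, pore count/area, and mean fiber diameter by the dual-centreline
  (axial thinning + medial axis) method with intersection correction.
* **Diffusion** — normalized ROI intensity curves against the 1D
  half-infinite solution C(x,t) = (C₀/2)·erfc(x/2√(Dt)), half-rise times
  and an effective-diffusivity fit.

A first-class synthetic-data generator reproduces every acquisition
modality with known ground truth (random-walk cells rendered as Gaussian
blobs, worm-like-chain fibers, two-phase textures, erfc diffusion
fronts), so the whole toolchain is testable without any microscopy data.

## Worked example

Simulate a 12-hour experiment (8 persistent walkers at the
serum-stimulated speed of 4.37 µm/hr, one frame per 15 min) and run the
full tracking pipeline:

```r
library(scaffoldtrack)

sv  <- synthetic_migration_video(8, seed = 42)
res <- run_cell_pipeline(sv, pixel_size = 1.3, frame_interval = 15,
                         params = chan_vese_params(mu = 0.05),
                         min_area = 10)
str(res$stats$summary)
#> List of 5
#>  $ mad_um                 : num 53.5
#>  $ mad_replica_pondered_um: num NA
#>  $ mean_speed_um_hr       : num 4.55
#>  $ n_tracks               : int 8
#>  $ duration_hr            : num 11.8
head(res$stats$per_track, 3)
#>   cell_id accumulated_distance_um average_speed_um_hr n_points
#> 1       1                   51.25               4.362       48
#> 2       2                   52.88               4.501       48
#> 3       3                   53.74               4.574       48
```

All 8 cells are recovered for all 48 frames. The estimated MAD of
53.5 µm sits just above the ground-truth path length of 51.3 µm (centroid
jitter adds a small positive bias), and the mean speed of 4.55 µm/hr
recovers the generator's 4.37 µm/hr. The polarity profile of the same
tracks is flat, as it must be for a persistent (direction-correlated but
orientation-isotropic) walk:

```r
polarity_profile(res$trackset, n_bins = 8)$anisotropy_index
#> [1] 1.082
```

An anisotropic walk with axis ratio 2 instead yields an index near 2.
The same style of round trip exists for the other modalities, e.g.:

```r
ch <- sample_fiber_chain(persistence_length = 10, contour_length = 40)
fiber_persistence(ch)          # recovers ~10 um

ds <- render_diffusion_series(D = 100, length_um = 400, pixel_size = 2,
                              dt_s = 5, n_frames = 400, n_rows = 8)
```

See the methods vignette (`vignettes/scaffoldtrack-methods.Rmd`) for the
models, conventions and tunable parameters of every stage.

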