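# cinemotility

Quantitative analysis of gastrointestinal motility from free-breathing
cine MRI, for imaging researchers studying gastric emptying and duodenal
peristalsis. The package turns a 2D+t image stack plus manually seeded wall
outlines into a small set of physiologically interpretable indices, and
ships a digital phantom generator with analytic ground truth so the whole
measurement chain is testable without patient data.

## What it computes

Given a cine series (40 frames at Δt = 0.656 s per plane in the target
protocol), the pipeline:

1. **Cancels respiratory motion** by exhaustive integer-shift minimization
   of the SSD energy over a region of interest χ,
   `E(b) = Σ_{x∈χ} (I_n(x) − I_{n+1}(x+b))² / |χ|`,
   chaining pairwise shifts so every frame aligns to the first.
2. **Resamples sparse manual seeds** (20 points for the gastric fundus, 30
   for the duodenum) into 100-point equal-arc-length closed contours via a
   periodic cubic spline, with normalized orientation and frame-to-frame
   point correspondence.
3. **Computes motility indices** per scan:
   - `DM(A)` = 100 · sd(area)/mean(area) (%), area variability;
   - `DM(G)` = centroid path length (mm), with the per-frame Y-trace
     `DG_Y(t) = G_y(t) − G_y(0)`;
   - `DM(V_N)`, `DM(V_T)` = mean absolute wall velocity (mm/s) along the
     inward normal and counterclockwise tangent (inward/ccw positive),
     from per-point displacements projected onto the later frame's
     contour frame — an exact decomposition, `V_N² + V_T² = |v|²`;
   - gastric residual volume index: summed frame-mean fundus area over
     planes P1–P4, as a percentage of the first motility scan (MS1 ≡ 100%).
4. **Compares conditions** across subjects with paired t-tests.

## Worked example

Render a peristalsis phantom — a C-shaped duodenal tube with a Gaussian
contraction ring travelling at 3 mm/s — then measure its wall velocities
through the full pipeline:

```r
library(cinemotility)

spec <- duodenum_spec(grid = c(80L, 80L), spacing = c(1.8, 1.8),
                      n_frames = 15L, depth = 0.5, ring_width = 8,
                      ring_speed = 3, ring_period = 10, noise_sd = 0.02,
                      seed = 3L)
phantom <- make_duodenum_phantom(spec)
phantom$stack
#> frame_stack: 15 frames of 80 x 80 px (1.8 x 1.8 mm/px), dt = 0.656 s, plane 1, MS1

series <- build_contour_series(phantom$seeds, n_points = 100,
                               frame_interval = spec$frame_interval)
series
#> contour_series: 15 frames x 100 points (duodenum), dt = 0.656 s

field <- wall_velocities(series)
round(dm_velocity(field), 4)
#>     vn     vt
#> 0.1714 0.2354

phantom$truth$dm_vn
#> [1] 0.1711935
```

The measured normal-velocity index `DM(V_N)` (0.1714 mm/s) agrees with the
phantom's analytic ground truth (0.1712 mm/s) to ~0.1%: a ring of depth 0.5
and width 8 mm on a 9 mm tube produces sub-mm/s mean wall speeds because
only the ring region moves at any instant. The tangential index also
absorbs correspondence slippage along the deforming wall, which is why
`DM(V_N)` is the primary contractility readout.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the study-style analysis on
synthetic data, writing tables and plots to `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_study.R` | render the 8-subject two-condition crossover study |
| `02_stabilization_check.R` | verify exact recovery of injected respiration |
| `03_subject_motility.R` | one subject: residual %, DM indices, DG_Y traces |
| `04_study_comparison.R` | paired t-tests per metric/scan, responder lines |
| `05_power_analysis.R` | power/size of the paired test at the design effect |

Run them in order from the repository root with `Rscript`.

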