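# htmotion

Parameter-free myocardial motion tracking and strain estimation for tagged
short-axis MR image sequences.

Regional myocardial strain is a clinically valuable measure of contractile
function, and tagged MRI makes it measurable: a periodic intensity grid is
imprinted on the tissue and deforms with it. The dominant way to recover the
motion — B-spline free-form deformation registration — depends on tunable
parameters (grid spacing, similarity measure, regularisation weights) whose
best values differ between image pairs of the same cardiac cycle. `htmotion`
implements a registration model with no regularisation functional and no
per-pair tuning:

* **Hierarchical template matching.** The moving image is decomposed into
  16 px templates, 8 px segments, 4 px chunks and 2 px windows; normalized
  cross-correlation (computed with running-sum local statistics, invariant
  to affine intensity change and hence to tag fading) matches each level
  inside the region found by the level above, with overlapping 14/12/10 and
  6 px refinement layers in between. Every 2 px window contributes one
  point correspondence, giving a dense uniform field of control points with
  sub-pixel localisation from the correlation-peak curvature.
* **Local Weighted Mean (LWM) transform.** A degree-2 polynomial is fitted
  around each control point over its `n − 1 = 11` nearest neighbours, and
  the mapping at any point is the blend of all polynomials whose compact
  support reaches it, weighted by `W(D) = 1 − 3D² + 2D³`. No global system
  of equations is solved; the transform is local, smooth and C¹.
* **Sequential tracking and Eulerian strain.** Consecutive pairs
  `I₁→I₂→…→I_T` are registered (forward and backward, for inverse
  consistency) and material points are carried through the fitted
  transforms. From the tracked trajectories: displacement gradient `∂U` by
  local least squares in deformed coordinates, deformation gradient
  `F = (I − ∂U)⁻¹`, Almansi strain `E = ½[I − (FFᵀ)⁻¹]`, projected into
  circumferential/radial components `E_cc`, `E_rr` and averaged over the
  six AHA sectors of the left-ventricular wall.

A synthetic tagged phantom with closed-form ground-truth motion and strain
(`tag_phantom()`), a target-registration-error harness (`tre()`) and a
paired model-comparison harness (`compare_models()`) make the whole pipeline
verifiable without any image data.

## Worked example

Generate a 19-phase contracting-and-twisting phantom, track its 18 withheld
landmarks plus a dense set of mid-wall points, and recover regional strain:

```r
library(htmotion)

cfg <- phantom_config()           # 128 x 128, 19 phases, contract + twist
ph  <- tag_phantom(cfg)

seeds <- rbind(ph$landmarks, phantom_wall_points(cfg))
traj  <- htm_track(ph$frames, seeds)
traj
#> HTM trajectories: 666 points over 19 frames (18 registrations)
#>   peak displacement from frame 0: 7.05 px; 0 extrapolated point-frames

tre(traj$positions[1:18, , ], ph$truth, pixel_size_mm = cfg$pixel_size_mm)
#> Target registration error over 18 landmarks, 18 frame pairs
#>   mean 0.2252 +/- 0.0776 px  =  0.3332 +/- 0.1149 mm (pixel 1.48 mm)
#>   worst frame: 0.3120 px

rs <- regional_strain(traj$positions[-(1:18), , ], centroid = cfg$center)
rs
#> Regional strain: 19 frames x 6 AHA regions
#>   peak strain per region:
#>     Anterior       Ecc -0.1838  Err -0.1822
#>     Anteroseptal   Ecc -0.1916  Err -0.2030
#>     Inferoseptal   Ecc -0.2042  Err -0.1932
#>     Inferior       Ecc -0.1822  Err -0.1953
#>     Inferolateral  Ecc -0.2057  Err -0.1991
#>     Anterolateral  Ecc -0.2050  Err -0.1768
plot(rs)                          # strain curves over the cycle
```

The landmarks are tracked to a worst-frame RMS error of 0.31 px (0.46 mm at
the phantom's 1.48 mm pixels) over the full cycle, and the recovered peak
circumferential strain of about −0.19 to −0.21 per region matches the
phantom's analytic ground truth (`phantom_strain()`), whose peak is −0.19
under 15 % radial contraction. Tracking error returns to ~0.03 px at the
final frame because the motion is cyclic and the registration chain is
inverse-consistent.

Single pairs can be registered directly; the result is a fitted transform
with the usual methods:

```r
reg <- htm_register(ph$frames[[9]], ph$frames[[10]])
summary(reg)
#> HTM registration of a 128 x 128 pair
#>   4096 window pairs: 255 ok, 3308 degenerate, 533 low-confidence; mean peak CC 0.9848
#> LWM transform: 255 control points, n = 12 (0 affine fallbacks)
#>   control-point residuals: RMS 0.03272 px, max 0.2107 px
#>   displacement: mean 0.147 px, max 0.660 px
predict(reg, cbind(60, 90))       # map a point from moving to reference
```

Flat blood-pool and background windows are flagged `degenerate`, and
windows whose match is ambiguous or whose cascade chain fell back are
`low_confidence`; only `ok` pairs become control points.

## Command line

A thin wrapper over the same functions lives in `inst/cli/htmotion.R`:

```sh
Rscript inst/cli/htmotion.R phantom  --out study --frames 19 --size 128
Rscript inst/cli/htmotion.R register --moving study/frame_000.png \
        --reference study/frame_001.png --out reg
Rscript inst/cli/htmotion.R track    --dir study --out results \
        --centroid 63.5,63.5 --seeds seeds.csv --plot
Rscript inst/cli/htmotion.R evaluate --tracked results/trajectories.csv \
        --truth study/truth_trajectories.csv --pixel-size 1.48 --out eval
```

Each run echoes its configuration into the output directory, so results are
reproducible from the outputs alone.

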