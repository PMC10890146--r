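# ppmap — Point Projection Mapping calibration and histology label transfer

`ppmap` is an R toolkit for validating point-based optical tissue
measurements (e.g. diffuse reflectance spectroscopy on surgical breast
specimens) against annotated histopathology. A projector–camera (PPM) rig
projects the chosen measurement locations as light dots onto the specimen;
after pathology processing, the snapshot must be deformably registered to
the H&E image so each measurement area can be read off the pathologist's
annotation. The package provides, without any hardware or patient data:

* **Base-plane calibration** — fit the work-surface plane
  `a·x + b·y + z + c = 0` to averaged depth frames by exact linear least
  squares on the vertical residual, and correct depth as
  `z_new = z + a·x + b·y + c` (0 on the surface, object height above it).
* **Projector calibration** — estimate the rigid camera→projector transform
  `P_p = R·P_c + T` from 3D checkerboard point pairs (closed-form
  Procrustes, optional derivative-free polish) and report its RMSE in mm.
* **Deformable registration** — estimate a dense displacement field φ
  (backward convention, `M(φ)(x) = M(x + φ(x))`) maximizing the mutual
  information `MI(F, M(φ)) − λ·smoothness` between the fixed histology
  image and the moving specimen snapshot on a 256×192 grid, via a
  coarse-to-fine control-grid optimizer; score alignment with MI (bits) and
  foreground-mask Dice `2|A∩B|/(|A|+|B|)`.
* **Label transfer** — detect projected POI dots, rasterize probe-sized
  disks, warp them into histology space with φ, and report per-POI tissue
  percentages that always sum to 100.
* **Synthetic phantoms** — deterministic generators for every stage (depth
  scenes, calibration pairs, deformed specimen/histology quartets) with
  recorded ground truth.

All images travel as plain-text rasters (ASCII PNM; depth as 16-bit ASCII
PGM in 0.1 mm steps), fields as a small text format, models as JSON — the
package runs in environments without binary image libraries. Coordinates
are 0-based `(x = column, y = row)` with pixel centers at integers.

## Worked example

```r
library(ppmap)

# one synthetic validation case: snapshot pair, histology, annotation, truth
ph <- generate_specimen_pair(phantom_spec(seed = 3))

# register specimen (saturation grayscale) to histology
res <- estimate_ddf(ph$h_o, to_saturation_gray(ph$s_o))
res
#> <registration_result: MI 0.791 -> 1.119 bits, Dice 0.957 -> 0.987>

# carry the measurement areas into histology space and label them
pois <- detect_pois(ph$s_poi, ph$s_o, radius = 5)
mask <- rasterize_poi_areas(pois, dim(ph$annotation$labels))
report <- extract_labels(warp_poi_mask(mask, res$field), ph$annotation)
subset(as.data.frame(report), poi_id == 1)
#>   poi_id      class percent
#> 1      1 background      20
#> 2      1        fat      80
#> 3      1 connective       0
#> 4      1      tumor       0
```

Reading: registration raised the shared information between the two
modalities from 0.79 to 1.12 bits and the foreground overlap from Dice
0.957 to 0.987. POI 1 (the first dot in raster order) lands, after warping
into histology space, with 80% of its measurement area on fat-analog
tissue and 20% just off the annotated specimen — its ground-truth label.
POIs whose area is *entirely* background are flagged in the report's
`flags` attribute rather than dropped.

Calibration side:

```r
sc  <- generate_depth_scene(phantom_spec(seed = 1), n_frames = 50)
pl  <- fit_base_plane(average_depth_frames(sc$frames))
cp  <- generate_calibration_pairs(phantom_spec(seed = 1), n_configs = 5)
t   <- estimate_transform(cp$pairs)
calibration_rmse(t, cp$pairs)   # ~1e-14 mm on noiseless pairs
```

## Command line

`exec/ppm` (installed under the package's `exec/` directory) exposes the
pipeline:

```sh
ppm make-phantom --preset specimen --seed 0 --out phantom/
ppm calibrate-plane --frames 'depth/*.pgm' --samples 10000 --seed 0 --out plane.json
ppm calibrate-projector --pairs pairs.csv --out transform.json --report rmse
ppm register --fixed HO.pgm --moving SO.ppm --out ddf.txt --metrics metrics.json
ppm extract-labels --spoi SPOI.ppm --so SO.ppm --ddf ddf.txt \
    --annotation HA.pgm --radius 5 --out labels.csv
ppm run --so SO.ppm --spoi SPOI.ppm --ho HO.pgm --annotation HA.pgm --out run/
ppm evaluate run1 run2 ... --out cohort.csv
```

Exit code 0 on success; failures name the failing stage.

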