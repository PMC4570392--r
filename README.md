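# uavweed

Can a farm skip the slow ultra-low-altitude UAV flights and still get
early-season weed maps good enough for site-specific herbicide spraying?
`uavweed` models the affirmative answer studied for sunflower row crops:
fly **once at 30 m** (1–2 cm/pixel), then produce the coarser images a 60 m
or 100 m flight would have delivered by **nearest-neighbour (NN) resampling**
of the 30 m ortho-mosaic — and verify, on fields with exact ground truth,
that the resampled product is as good as the real higher flight, both
**geometrically** (ASPRS 1990 horizontal accuracy classes, band-histogram
preservation) and **agronomically** (identical Treatment/No-Treatment
prescriptions from the derived weed maps).

Because paired real flight imagery is not redistributable, the package ships
a seeded **synthetic field generator** (crop rows + clustered inter-row weed
patches + 32 ground-truth sampling frames + ≥20 control-point markers, all
with known labels), so every stage is testable end to end:

| module | what it does |
|---|---|
| camera geometry | `camera_model()`, `gsd()`: altitude × pixel pitch / focal length |
| synthetic field | `field_scenario()`, `generate_scene()`, `render_image()` |
| NN resampler | `nn_resample()`, with an independent `striding_oracle()` cross-check |
| spatial quality | `measure_pairs()`, `asprs_test()`, `compare_stats()` |
| OBIA weed map | `run_obia()`: index → Otsu segmentation → row detection → crop/weed by position |
| SSWM assessment | `frame_covers()`, `treatment_decision()`, `concordance()` |
| orchestration | `full_run()`, YAML config, TIFF/PNG + world file + JSON I/O, CLI in `inst/cli/` |

## Worked example

```r
library(uavweed)

# the four reference resampling target pixel sizes, from the camera specs
gsd(flight_spec(60,  camera_preset("RGB")))   # 1.84 cm/px
gsd(flight_spec(100, camera_preset("TTC")))   # 5.42 cm/px

# a synthetic field with ground truth (default scenario, seed 42)
sc    <- field_scenario()
truth <- generate_scene(sc)
table(truth$frames$category)
#>  0  1  2  3
#>  8  8  8  8

# 30 m multispectral baseline (1.6 cm/px), degraded to the 60 m pixel size,
# and the "real" 60 m flight for comparison
base <- render_image(truth, sc, 1.6, "RNIR")
rs   <- nn_resample(base, resample_spec(1.6, 3.25))
uav  <- render_image(truth, sc, 3.25, "RNIR")

# spatial quality: ASPRS 1990 at 1:50 on the 20 rendered markers
pairs <- measure_pairs(uav, rs, truth$control_points)
asprs_test(pairs[!pairs$missing, ], 50)
#> <asprs_report> n = 20, RMSE X = 0.727 cm, Y = 0.514 cm (1:50, Class-1 limit 1.250 cm)
#>   achieved class: 1 (limiting axis X)

# weed maps and treatment concordance over the 32 frames
map_uav <- run_obia(uav)
map_rs  <- run_obia(rs)
concordance(frame_covers(map_uav, truth$frames),
            frame_covers(map_rs,  truth$frames))
#> <concordance_report> 32 frames
#>  threshold match_pct n_treat_a n_treat_b
#>        0.0       100        24        24
#>        2.5       100        24        24
#>        5.0       100        16        16
#>        7.5       100        16        16
#>       10.0       100        16        16
#>       12.5       100         8         8
#>       15.0       100         8         8
```

The resampled and the truly-flown 60 m map prescribe the same treatment in
every frame at every threshold — the resampling shortcut loses nothing for
SSWM on this field.

The whole campaign (2 fields × 2 cameras × {60, 100} m minus one excluded
flight = 7 resampled images, with quality reports, weed maps, per-frame
covers and concordances) runs as:

```r
report <- full_run(default_config(seed = 42), out_dir = "runs/demo")
```

or from the command line via `inst/cli/uavweed full-run --out runs/demo`.
Reports embed the fully resolved config and seeds; reruns are byte-identical.

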