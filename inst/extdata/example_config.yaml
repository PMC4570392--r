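# Example configuration for uavweed::full_run() / the `full-run` CLI command.
# Any omitted key falls back to default_config().
seed: 42
n_fields: 2
scenario:
  row_orientation: 0
  weed_cover_target: 0.08
cameras:
  altitudes: [60, 100]
  sensors: [RGB, TTC]
  gsd30:
    RGB: 1.07
    TTC: 1.6
# the one flight missing from the emulated campaign
exclude:
  - field: 1
    sensor: RGB
    altitude: 60
obia:
  min_object_area: 4
assessment:
  thresholds: [0, 2.5, 5, 7.5, 10, 12.5, 15]
  scale_denominator: 50
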