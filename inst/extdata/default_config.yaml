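# Default run configuration for the tsDCS volume-conductor pipeline.
# Every entry is optional; omitted values fall back to package defaults.

anatomy:
  preset: default        # "default" (2 mm) or "compact" (4 mm, small torso)
  # grid_resolution: 2
  # rng_seed: 0
  # jitter_mm: 0

tissues:
  wm_ratio: 10           # spinal white matter anisotropy (longitudinal:transverse)
  muscle_ratio: 5        # paravertebral muscle anisotropy
  # sigma:               # per-tissue overrides, S/m
  #   csf: 1.790

montage: T8-L2           # T8-L2 | pvT8R-pvL2L | pvT8L-pvL2R

session:
  current_mA: 4
  duration_s: 900
  electrode_area_cm2: 25

analysis:
  neuromodulation_threshold: 0.15   # V/m
  slice_thickness: 1                # mm (raised to the voxel size if coarser)
  drg_probe_radius: 2               # mm

solver:
  tol: 1.0e-8
  max_iter: 20000
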