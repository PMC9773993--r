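## Shared fixtures, memoized so expensive solves run once per test session.
## The "compact" anatomy preset (4 mm grid, small torso) keeps full-pipeline
## tests to a few seconds per montage.

.fixture_cache <- new.env(parent = emptyenv())

fix_anatomy <- function() {
  if (is.null(.fixture_cache$anatomy)) {
    .fixture_cache$anatomy <- build_anatomy(anatomy_params("compact"))
  }
  .fixture_cache$anatomy
}

fix_run <- function(montage = "T8-L2") {
  key <- paste0("run_", montage)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_simulation(anatomy = fix_anatomy(),
                                            montage = montage)
  }
  .fixture_cache[[key]]
}

## Default-anatomy runs (2 mm, ~1.7e6 unknowns, minutes per solve) are
## memoized in slimmed form: the conservation and current-balance checks are
## evaluated once here, and the bulky field/system arrays are dropped so
## three cached runs fit comfortably in memory.
fix_default_anatomy <- function() {
  if (is.null(.fixture_cache$default_anatomy)) {
    .fixture_cache$default_anatomy <- build_anatomy(anatomy_params("default"))
  }
  .fixture_cache$default_anatomy
}

fix_default_run <- function(montage = "T8-L2") {
  key <- paste0("default_run_", montage)
  if (is.null(.fixture_cache[[key]])) {
    run <- run_simulation(anatomy = fix_default_anatomy(), montage = montage)
    slim <- list(
      montage_name = run$montage_name,
      summary = run$summary,
      profile = run$profile,
      drg = run$drg,
      placed = list(montage = run$placed$montage),
      landmarks = run$anatomy$landmarks,
      conservation = conservation_check(run$field),
      electrode_currents = run$field$electrode_currents,
      injected_mA = run$field$injected_mA,
      anatomy_hash = run$anatomy_hash)
    rm(run); gc(verbose = FALSE)
    .fixture_cache[[key]] <- slim
  }
  .fixture_cache[[key]]
}

## A tiny synthetic field solution with a prescribed uniform E vector over a
## small grid whose central column is cord (WM with a GM core), for
## postprocessing tests that need exact expected values.
fake_field <- function(E = c(0, 0, -0.2), dims = c(5, 5, 12), h = 1) {
  lab <- array(TISSUE_LABELS_TEST[["csf"]], dims)
  lab[2:4, 2:4, ] <- TISSUE_LABELS_TEST[["wm"]]
  lab[3, 3, ] <- TISSUE_LABELS_TEST[["gm"]]
  mk <- function(v) array(v, dims)
  field <- structure(list(
    Ex = mk(E[1]), Ey = mk(E[2]), Ez = mk(E[3]),
    Enorm = mk(sqrt(sum(E^2)))), class = "field_solution")
  grid_meta <- list(origin = c(-dims[1] * h / 2, -dims[2] * h / 2, 0),
                    voxel_size = h)
  frame <- spinefield:::build_cord_frame(0, 0.5 * h, (dims[3] - 0.5) * h, h)
  list(field = field, labels = lab, grid_meta = grid_meta, frame = frame)
}

TISSUE_LABELS_TEST <- spinefield::tissue_labels()
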