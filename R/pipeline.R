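#' Run the full tsDCS simulation pipeline
#'
#' Convenience wrapper chaining the whole pipeline: build (or reuse) the
#' synthetic anatomy, validate it, assemble conductivity, place a montage,
#' solve the current-flow problem, rescale to the target current, and run
#' the cord analyses (component decomposition, slice profile, per-segment
#' maxima, suprathreshold regions, DRG probes).
#'
#' @param anatomy An `anatomy` from [build_anatomy()], or `NULL` to build
#'   one from `params`.
#' @param params An [anatomy_params()] (used when `anatomy` is `NULL`).
#' @param tissues A [tissue_table()].
#' @param montage A montage preset name or `montage_model`.
#' @param current_mA Target injected current (mA).
#' @param cfg An [analysis_config()]; its `slice_thickness` is raised to the
#'   voxel size when the grid is coarser.
#' @param tol,max_iter Solver tolerance and iteration cap.
#' @param validate Refuse to solve when the anatomy invariants fail
#'   (default `TRUE`).
#' @return A list of class `tsdcs_run`: `montage_name`, `field`,
#'   `components`, `profile`, `summary`, `threshold`, `drg`, `dosimetry`,
#'   `anatomy_hash`, plus the `anatomy` used.
#' @export
#' @examples
#' \donttest{
#' run <- run_simulation(params = anatomy_params("compact"),
#'                       montage = "T8-L2")
#' run$summary
#' }
run_simulation <- function(anatomy = NULL, params = anatomy_params(),
                           tissues = tissue_table(), montage = "T8-L2",
                           current_mA = 4, cfg = analysis_config(),
                           tol = 1e-8, max_iter = 20000L, validate = TRUE) {
  if (is.null(anatomy)) anatomy <- build_anatomy(params)
  if (validate) {
    rep <- validate_anatomy(anatomy$grid)
    if (!isTRUE(attr(rep, "ok"))) {
      bad <- paste(rep$check[!rep$pass], collapse = ", ")
      stop_spinefield(paste0("Anatomy invariants failed: ", bad,
                             "; refusing to solve."),
                      "spinefield_validation_error")
    }
  }
  placed <- place_montage(anatomy, montage)
  cond <- assemble_conductivity(placed$grid, tissues, anatomy$frame)
  sys <- assemble_system(cond, placed)
  pot <- solve_potential(sys, tol = tol, max_iter = max_iter)
  field <- compute_field(pot, cond, placed$grid$labels)
  field <- scale_to_current(field, current_mA)
  cfg$slice_thickness <- max(cfg$slice_thickness, anatomy$grid$voxel_size)
  cfg$drg_probe_radius <- max(cfg$drg_probe_radius, anatomy$grid$voxel_size)
  comp <- decompose_components(field, anatomy$frame, placed$grid$labels,
                               anatomy$grid)
  prof <- slice_profile(comp, cfg)
  summ <- segment_summary(prof, anatomy$landmarks)
  thr <- threshold_regions(comp, anatomy$landmarks, cfg)
  drg <- drg_probe(field, anatomy$landmarks, anatomy$grid, cfg)
  structure(list(
    montage_name = placed$montage$name,
    anatomy = anatomy,
    placed = placed,
    field = field,
    components = comp,
    profile = prof,
    summary = summ,
    threshold = thr,
    drg = drg,
    dosimetry = session_dosimetry(current_mA = current_mA),
    cfg = cfg,
    anatomy_hash = placed$anatomy_hash
  ), class = "tsdcs_run")
}

#' @export
print.tsdcs_run <- function(x, ...) {
  cat("<tsdcs_run> montage", x$montage_name, "at",
      signif(x$field$injected_mA, 4), "mA\n")
  best <- dplyr::slice_max(x$summary, .data$e_norm_max, n = 1)
  cat("  peak slice-mean |E|:", signif(best$e_norm_max[1], 3),
      "V/m in segment", best$segment[1], "(", best$tissue[1], ")\n")
  invisible(x)
}
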