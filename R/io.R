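## Export/import of the volumetric containers (NIfTI + JSON sidecars) and
## the YAML run configuration.

#' Write a label grid as NIfTI with a JSON label dictionary
#'
#' @param grid A `label_grid`.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`); the label dictionary
#'   is written next to it as `<path>.labels.json`.
#' @return `path`, invisibly.
#' @export
write_label_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$labels)
  h <- grid$voxel_size
  RNifti::pixdim(img) <- c(h, h, h)   # scale lives in pixdim; qform holds
  aff <- diag(c(h, h, h, 1))          # rotation + translation
  aff[1:3, 4] <- grid$origin + h / 2
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(grid$dict), paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label grid written by [write_label_grid()]
#'
#' @param path NIfTI path.
#' @return A `label_grid`.
#' @export
read_label_grid <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::pixdim(img)[1]
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4]) - h / 2
  new_label_grid(array(as.integer(img), dim(img)), h, origin)
}

#' Write a scalar component of a field solution as NIfTI
#'
#' @param field A `field_solution`.
#' @param what One of `"phi"`, `"Enorm"`, `"Ex"`, `"Ey"`, `"Ez"`, `"Jx"`,
#'   `"Jy"`, `"Jz"`.
#' @param path Output path.
#' @param grid_meta List with `origin` and `voxel_size`.
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(field, what, path, grid_meta) {
  stopifnot(what %in% c("phi", "Enorm", "Ex", "Ey", "Ez", "Jx", "Jy", "Jz"))
  a <- field[[what]]
  a[is.na(a)] <- 0
  img <- RNifti::asNifti(a)
  h <- grid_meta$voxel_size
  RNifti::pixdim(img) <- c(h, h, h)
  aff <- diag(c(h, h, h, 1))
  aff[1:3, 4] <- grid_meta$origin + h / 2
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write landmarks and cord frame as JSON
#'
#' @param anatomy An `anatomy`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(anatomy, path) {
  lm <- anatomy$landmarks
  fr <- anatomy$frame
  jsonlite::write_json(list(
    spinous_process_z = lm$spinous_process_z,
    interspinous_z = lm$interspinous_z,
    drg_centers = lm$drg_centers,
    root_axes = lm$root_axes,
    segment_z_ranges = lm$segment_z_ranges,
    cord_z = lm$cord_z,
    frame = list(z = fr$z, center = fr$center, t_hat = fr$t_hat,
                 v_hat = fr$v_hat, r_hat = fr$r_hat)
  ), path, digits = NA)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Sections `anatomy`, `tissues`, `montage`, `session`, `analysis`,
#' `solver` are mapped onto the corresponding constructors; missing
#' sections get defaults. See
#' `system.file("extdata", "default_config.yaml", package = "spinefield")`.
#'
#' @param path YAML file path.
#' @return A list: `params`, `tissues`, `montage` (name), `session`,
#'   `cfg`, `solver`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  an <- y$anatomy %||% list()
  preset <- an$preset %||% "default"
  an$preset <- NULL
  params <- do.call(anatomy_params, c(list(preset = preset), an))
  tis <- y$tissues %||% list()
  tissues <- tissue_table(wm_ratio = tis$wm_ratio %||% 10,
                          muscle_ratio = tis$muscle_ratio %||% 5)
  if (!is.null(tis$sigma)) {
    for (nm in names(tis$sigma)) {
      i <- which(tissues$tissue == nm)
      if (!length(i)) {
        stop_spinefield(paste0("Unknown tissue in config: ", nm),
                        "spinefield_lookup_error")
      }
      tissues$sigma[i] <- tis$sigma[[nm]]
    }
  }
  ses <- y$session %||% list()
  cfgl <- y$analysis %||% list()
  sol <- y$solver %||% list()
  list(
    params = params,
    tissues = tissues,
    montage = y$montage %||% "T8-L2",
    session = list(current_mA = ses$current_mA %||% 4,
                   duration_s = ses$duration_s %||% 900,
                   electrode_area_cm2 = ses$electrode_area_cm2 %||% 25),
    cfg = analysis_config(
      neuromodulation_threshold = cfgl$neuromodulation_threshold %||% 0.15,
      slice_thickness = cfgl$slice_thickness %||% 1,
      drg_probe_radius = cfgl$drg_probe_radius %||% 2),
    solver = list(tol = sol$tol %||% 1e-8, max_iter = sol$max_iter %||% 20000L)
  )
}

#' Write slice profiles / segment summaries as CSV
#'
#' @param x A `slice_profile` or `segment_summary` (any data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
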