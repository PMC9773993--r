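#' Parameters of the synthetic torso and spine anatomy
#'
#' Defines the parametric geometry from which [build_anatomy()] stamps the
#' labelled voxel model: a truncated elliptical torso with skin/fat/muscle
#' shells and single-blob thoracoabdominal organs, a vertebral column of
#' low-conductivity vertebrae (bodies, a bony ring around the spinal canal,
#' and spinous processes) separated by intervertebral disks, a spinal canal
#' with dura, CSF and a white/grey-matter cord ending at the conus, lateral
#' roots through the intervertebral foramina with dorsal root ganglia (DRG),
#' and a cauda equina bundle below the conus.
#'
#' All lengths are millimetres. The geometry is an artifact of this package:
#' dimensions are literature-typical adult values scaled to a desk-size
#' model, not measurements of any specific subject.
#'
#' @param preset `"default"` (2 mm grid, T5--L5 column plus sacrum) or
#'   `"compact"` (4 mm grid, smaller torso; coarse but fast, intended for
#'   examples and quick checks).
#' @param ... Named overrides of any parameter in the returned list.
#'
#' @details
#' Invariants enforced (violations raise an error naming the constraint):
#' * all lengths positive;
#' * `gm_semi_axes < cord_semi_axes < canal_radius - dura_thickness`
#'   componentwise, so the cord nests strictly inside the CSF;
#' * `grid_resolution <= min(dura_thickness, root_radius)`, so the thinnest
#'   stamped structures are resolvable;
#' * `levels` ordered rostral to caudal, ending with `"sacrum"`.
#'
#' `segment_map` is a data frame (`segment`, `length_mm`) ordered caudal to
#' rostral that places the spinal segments above the conus medullaris; the
#' conus sits at the L1--L2 disk, so lumbar segments lie adjacent to the
#' T11--L1 vertebral bodies, and the most rostral listed segment absorbs the
#' remaining cord up to the model truncation.
#'
#' @return A list of class `anatomy_params`.
#' @export
#' @examples
#' p <- anatomy_params("compact")
#' p$grid_resolution
anatomy_params <- function(preset = c("default", "compact"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "default") {
    list(
      grid_resolution        = 2,
      torso_height           = 400,
      torso_semi_axes        = c(125, 90),
      skin_thickness         = 4,
      fat_thickness          = 6,
      vertebral_body_radius  = 18,
      vertebral_body_height  = 20,
      disk_height            = 4,
      spinous_process_depth  = 22,
      canal_radius           = 9.5,
      canal_wall_thickness   = 6,
      dura_thickness         = 2,
      cord_semi_axes         = c(6.5, 4.5),
      gm_semi_axes           = c(3.5, 2.5),
      root_radius            = 2.5,
      drg_semi_axes          = c(4, 3, 3),
      levels                 = c("T5", "T6", "T7", "T8", "T9", "T10", "T11",
                                 "T12", "L1", "L2", "L3", "L4", "L5", "sacrum"),
      segment_map            = default_segment_map(),
      rng_seed               = 0L,
      jitter_mm              = 0
    )
  } else {
    list(
      grid_resolution        = 4,
      torso_height           = 360,
      torso_semi_axes        = c(80, 62),
      skin_thickness         = 4,
      fat_thickness          = 4,
      vertebral_body_radius  = 15,
      vertebral_body_height  = 18,
      disk_height            = 4,
      spinous_process_depth  = 16,
      canal_radius           = 14,
      canal_wall_thickness   = 5,
      dura_thickness         = 4,
      cord_semi_axes         = c(6, 5),
      gm_semi_axes           = c(3, 2.5),
      root_radius            = 4,
      drg_semi_axes          = c(5, 4, 4),
      levels                 = c("T6", "T7", "T8", "T9", "T10", "T11",
                                 "T12", "L1", "L2", "L3", "L4", "L5", "sacrum"),
      segment_map            = default_segment_map(),
      rng_seed               = 0L,
      jitter_mm              = 0
    )
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop_spinefield(paste0("Unknown anatomy parameter(s): ",
                           paste(unknown, collapse = ", ")),
                    "spinefield_param_error")
  }
  p[names(dots)] <- dots
  p$rng_seed <- as.integer(p$rng_seed)
  class(p) <- "anatomy_params"
  validate_anatomy_params(p)
  p
}

#' Default spinal-segment length table
#'
#' Caudal-to-rostral table of nominal segment lengths stacked upward from the
#' conus medullaris: coccygeal 5 mm, sacral 4 mm each, lumbar 10 mm each,
#' thoracic 20 mm each. These proportions reflect standard cord anatomy
#' (sacral segments compressed into the conus, thoracic segments longest);
#' the table is configuration, not hard-coded in the pipeline.
#'
#' @return A tibble with columns `segment`, `length_mm`.
#' @export
default_segment_map <- function() {
  tibble::tibble(
    segment = c("Co", paste0("S", 5:1), paste0("L", 5:1), paste0("T", 12:6)),
    length_mm = c(5, rep(4, 5), rep(10, 5), rep(20, 7))
  )
}

validate_anatomy_params <- function(p) {
  lens <- c(p$grid_resolution, p$torso_height, p$torso_semi_axes,
            p$skin_thickness, p$fat_thickness, p$vertebral_body_radius,
            p$vertebral_body_height, p$disk_height, p$spinous_process_depth,
            p$canal_radius, p$canal_wall_thickness, p$dura_thickness,
            p$cord_semi_axes, p$gm_semi_axes, p$root_radius, p$drg_semi_axes)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop_spinefield("All anatomy lengths must be positive and finite.",
                    "spinefield_param_error")
  }
  inner <- p$canal_radius - p$dura_thickness
  if (!all(p$gm_semi_axes < p$cord_semi_axes)) {
    stop_spinefield("Constraint violated: gm_semi_axes < cord_semi_axes.",
                    "spinefield_param_error")
  }
  if (!all(p$cord_semi_axes < inner)) {
    stop_spinefield(
      "Constraint violated: cord_semi_axes < canal_radius - dura_thickness.",
      "spinefield_param_error")
  }
  if (p$grid_resolution > min(p$dura_thickness, p$root_radius)) {
    stop_spinefield(paste0(
      "Constraint violated: grid_resolution (", p$grid_resolution,
      " mm) must not exceed min(dura_thickness, root_radius) = ",
      min(p$dura_thickness, p$root_radius),
      " mm; thin structures would be unresolvable."),
      "spinefield_resolution_error")
  }
  if (utils::tail(p$levels, 1) != "sacrum") {
    stop_spinefield("`levels` must end with \"sacrum\".", "spinefield_param_error")
  }
  vlv <- utils::head(p$levels, -1)
  ord <- vertebra_order(vlv)
  if (any(is.na(ord)) || any(diff(ord) != 1)) {
    stop_spinefield(
      "`levels` must be consecutive vertebral labels ordered rostral to caudal.",
      "spinefield_param_error")
  }
  sm <- p$segment_map
  if (!all(c("segment", "length_mm") %in% names(sm)) || any(sm$length_mm <= 0)) {
    stop_spinefield("`segment_map` needs columns segment, length_mm (> 0).",
                    "spinefield_param_error")
  }
  invisible(p)
}

## Linear ordering of vertebral labels, rostral (small) to caudal (large).
vertebra_order <- function(labels) {
  all_levels <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))
  match(labels, all_levels)
}

#' @export
print.anatomy_params <- function(x, ...) {
  cat("<anatomy_params>\n")
  cat("  grid resolution:", x$grid_resolution, "mm\n")
  cat("  torso:", x$torso_height, "mm tall, semi-axes",
      paste(x$torso_semi_axes, collapse = " x "), "mm\n")
  cat("  vertebral levels:", paste(x$levels, collapse = " "), "\n")
  invisible(x)
}
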