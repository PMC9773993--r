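#' Analysis configuration
#'
#' @param neuromodulation_threshold Field magnitude (V/m) above which
#'   neuromodulatory effects are considered possible (default 0.15, the
#'   value carried over from cortical DC-stimulation modelling).
#' @param slice_thickness Transverse slice thickness for profiles (mm);
#'   must be at least the voxel size of the grid it is applied to.
#' @param drg_probe_radius Radius (mm) of the spherical probe around each
#'   DRG landmark.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(neuromodulation_threshold = 0.15,
                            slice_thickness = 1,
                            drg_probe_radius = 2) {
  if (neuromodulation_threshold <= 0) {
    stop_spinefield("Threshold must be > 0.", "spinefield_param_error")
  }
  structure(list(neuromodulation_threshold = neuromodulation_threshold,
                 slice_thickness = slice_thickness,
                 drg_probe_radius = drg_probe_radius),
            class = "analysis_config")
}

#' Decompose the cord field into anatomical components
#'
#' Projects the electric field at every cord voxel (grey and white matter)
#' onto the local cord frame: `e_long` along the cord with positive =
#' rostral-to-caudal (the direction current takes from a rostral anode to a
#' lumbar cathode), `e_vd` positive dorsal-to-ventral, `e_rl` positive
#' right-to-left, and the magnitude `e_norm`. The triad is orthonormal, so
#' `e_long^2 + e_vd^2 + e_rl^2 = e_norm^2` voxelwise.
#'
#' @param field A `field_solution`.
#' @param frame A `cord_frame`.
#' @param labels Label array of the grid the field was solved on.
#' @param grid_meta A list with `origin` and `voxel_size` (a `label_grid`
#'   works).
#' @return A tibble of class `component_field`: one row per cord voxel with
#'   coordinates, `tissue` (`"gm"`/`"wm"`), `e_long`, `e_vd`, `e_rl`,
#'   `e_norm`.
#' @export
decompose_components <- function(field, frame, labels, grid_meta) {
  L <- TISSUE_LABELS
  vox <- which(labels == L[["gm"]] | labels == L[["wm"]])
  if (!length(vox)) {
    stop_spinefield("No cord (GM/WM) voxels in the grid.",
                    "spinefield_range_error")
  }
  dims <- dim(labels)
  h <- grid_meta$voxel_size
  org <- grid_meta$origin
  xi <- ((vox - 1L) %% dims[1]) + 1L
  yi <- (((vox - 1L) %/% dims[1]) %% dims[2]) + 1L
  zi <- ((vox - 1L) %/% (dims[1] * dims[2])) + 1L
  zv <- org[3] + (zi - 0.5) * h
  rng <- range(frame$z)
  if (any(zv < rng[1] - h | zv > rng[2] + h)) {
    stop_spinefield("Cord voxel without cord-frame coverage.",
                    "spinefield_range_error")
  }
  tr <- frame_at_z(frame, pmin(pmax(zv, rng[1]), rng[2]))
  Ex <- field$Ex[vox]; Ey <- field$Ey[vox]; Ez <- field$Ez[vox]
  ## t_hat points rostral; e_long is positive in the rostral->caudal direction.
  e_long <- -(Ex * tr$t_hat[, 1] + Ey * tr$t_hat[, 2] + Ez * tr$t_hat[, 3])
  e_vd <- Ex * tr$v_hat[, 1] + Ey * tr$v_hat[, 2] + Ez * tr$v_hat[, 3]
  e_rl <- Ex * tr$r_hat[, 1] + Ey * tr$r_hat[, 2] + Ez * tr$r_hat[, 3]
  out <- tibble::tibble(
    voxel = vox,
    x = org[1] + (xi - 0.5) * h,
    y = org[2] + (yi - 0.5) * h,
    z = zv,
    tissue = ifelse(labels[vox] == L[["gm"]], "gm", "wm"),
    e_long = e_long, e_vd = e_vd, e_rl = e_rl,
    e_norm = sqrt(Ex^2 + Ey^2 + Ez^2))
  class(out) <- c("component_field", class(out))
  attr(out, "voxel_size") <- h
  attr(out, "z0") <- org[3]
  out
}

#' Slice-averaged field profile along the cord
#'
#' Averages the component field in transverse slices along z, per tissue:
#' the magnitude as the mean of voxel magnitudes, the components as signed
#' means (so opposing directions cancel; absolute values are taken only at
#' the per-segment maximum step). Empty bins are kept as explicit missing
#' rows, never zero-filled.
#'
#' @param comp A `component_field`.
#' @param cfg An [analysis_config()]; `slice_thickness` must be >= the
#'   voxel size.
#' @return A tibble of class `slice_profile`: `z_mid`, `tissue`, `n_voxels`,
#'   `e_norm`, `e_long`, `e_vd`, `e_rl`.
#' @export
slice_profile <- function(comp, cfg = analysis_config()) {
  h <- attr(comp, "voxel_size")
  thick <- cfg$slice_thickness
  if (thick < h) {
    stop_spinefield(paste0("Slice thickness (", thick,
                           " mm) must be at least the voxel size (", h, " mm)."),
                    "spinefield_param_error")
  }
  if (nrow(comp) == 0) {
    stop_spinefield("Empty component field.", "spinefield_range_error")
  }
  z0 <- min(comp$z) - h / 2
  bins <- floor((comp$z - z0) / thick + 1e-9)
  out <- comp |>
    dplyr::mutate(bin = bins) |>
    dplyr::group_by(.data$bin, .data$tissue) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     e_norm = mean(.data$e_norm),
                     e_long = mean(.data$e_long),
                     e_vd = mean(.data$e_vd),
                     e_rl = mean(.data$e_rl), .groups = "drop") |>
    tidyr::complete(bin = seq(0, max(bins)),
                    tissue = unique(comp$tissue)) |>
    dplyr::mutate(z_mid = z0 + (.data$bin + 0.5) * thick,
                  n_voxels = tidyr::replace_na(.data$n_voxels, 0L)) |>
    dplyr::select("z_mid", "tissue", "n_voxels",
                  "e_norm", "e_long", "e_vd", "e_rl") |>
    dplyr::arrange(.data$tissue, .data$z_mid)
  class(out) <- c("slice_profile", class(out))
  attr(out, "slice_thickness") <- thick
  out
}

#' Per-spinal-segment maxima of the slice profile
#'
#' For each spinal segment and tissue, the maximum over the segment's slices
#' of the slice-mean magnitude and of the absolute slice-mean components,
#' with the arg-max slice position for the magnitude.
#'
#' @param profile A `slice_profile`.
#' @param landmarks A `landmarks` object whose segment map covers the
#'   profile extent.
#' @return A tibble of class `segment_summary`: `segment`, `tissue`,
#'   `e_norm_max`, `e_norm_argmax_z`, `e_long_max`, `e_vd_max`, `e_rl_max`.
#' @export
segment_summary <- function(profile, landmarks) {
  pr <- dplyr::filter(profile, .data$n_voxels > 0)
  pr$segment <- segment_for_z(pr$z_mid, landmarks)
  seg_order <- landmarks$segment_z_ranges$segment
  out <- pr |>
    dplyr::group_by(.data$segment, .data$tissue) |>
    dplyr::summarise(
      e_norm_max = max(.data$e_norm),
      e_norm_argmax_z = .data$z_mid[which.max(.data$e_norm)],
      e_long_max = max(abs(.data$e_long)),
      e_vd_max = max(abs(.data$e_vd)),
      e_rl_max = max(abs(.data$e_rl)),
      .groups = "drop") |>
    dplyr::arrange(match(.data$segment, seg_order), .data$tissue)
  class(out) <- c("segment_summary", class(out))
  out
}

#' Suprathreshold field regions in the cord
#'
#' Voxels whose field magnitude reaches the neuromodulation threshold
#' (inclusive comparison, `e_norm >= threshold`), with per-segment coverage
#' statistics.
#'
#' @param comp A `component_field`.
#' @param landmarks A `landmarks` object.
#' @param cfg An [analysis_config()].
#' @return A list: `mask` (the suprathreshold rows of `comp`), `stats`
#'   (tibble per segment and tissue: voxel count, volume in mm^3, coverage
#'   fraction of the segment's cord voxels).
#' @export
threshold_regions <- function(comp, landmarks, cfg = analysis_config()) {
  h <- attr(comp, "voxel_size")
  thr <- cfg$neuromodulation_threshold
  comp$segment <- segment_for_z(comp$z, landmarks)
  comp$above <- comp$e_norm >= thr
  stats <- comp |>
    dplyr::group_by(.data$segment, .data$tissue) |>
    dplyr::summarise(n_voxels = sum(.data$above),
                     volume_mm3 = sum(.data$above) * h^3,
                     coverage = mean(.data$above), .groups = "drop")
  list(mask = dplyr::filter(comp, .data$above),
       stats = dplyr::arrange(stats,
                              match(.data$segment,
                                    landmarks$segment_z_ranges$segment),
                              .data$tissue))
}

#' Probe the field at the dorsal root ganglia
#'
#' Samples the field in a sphere around each DRG landmark: the mean
#' magnitude and the signed projection of the mean field vector onto the
#' root axis (positive = directed from the cord towards the periphery).
#'
#' @param field A `field_solution`.
#' @param landmarks A `landmarks` object with DRG centres and root axes.
#' @param grid_meta A list with `origin` and `voxel_size`.
#' @param cfg An [analysis_config()].
#' @return A tibble of class `drg_report`: `level`, `side`, `n_voxels`,
#'   `mean_e_norm`, `root_projection`, `direction`
#'   (`"cord_to_periphery"`/`"periphery_to_cord"`), `missing`.
#' @export
drg_probe <- function(field, landmarks, grid_meta, cfg = analysis_config()) {
  h <- grid_meta$voxel_size
  org <- grid_meta$origin
  dims <- dim(field$Enorm)
  r <- cfg$drg_probe_radius
  drg <- dplyr::left_join(landmarks$drg_centers, landmarks$root_axes,
                          by = c("level", "side"))
  rows <- purrr::pmap(drg, function(level, side, x, y, z, ax, ay, az) {
    ir <- ceiling(r / h) + 1L
    ci <- coord_to_index(c(x, y, z), org, h)
    xs <- max(1L, ci[1] - ir):min(dims[1], ci[1] + ir)
    ys <- max(1L, ci[2] - ir):min(dims[2], ci[2] + ir)
    zs <- max(1L, ci[3] - ir):min(dims[3], ci[3] + ir)
    gg <- expand.grid(xi = xs, yi = ys, zi = zs)
    cx <- org[1] + (gg$xi - 0.5) * h
    cy <- org[2] + (gg$yi - 0.5) * h
    cz <- org[3] + (gg$zi - 0.5) * h
    keep <- (cx - x)^2 + (cy - y)^2 + (cz - z)^2 <= r^2
    vox <- gg$xi[keep] + (gg$yi[keep] - 1L) * dims[1] +
      (gg$zi[keep] - 1L) * dims[1] * dims[2]
    vox <- vox[!is.na(field$Enorm[vox])]
    if (!length(vox)) {
      return(tibble::tibble(level = level, side = side, n_voxels = 0L,
                            mean_e_norm = NA_real_,
                            root_projection = NA_real_,
                            direction = NA_character_, missing = TRUE))
    }
    mE <- c(mean(field$Ex[vox]), mean(field$Ey[vox]), mean(field$Ez[vox]))
    proj <- sum(mE * c(ax, ay, az))
    tibble::tibble(
      level = level, side = side, n_voxels = length(vox),
      mean_e_norm = mean(field$Enorm[vox]),
      root_projection = proj,
      direction = if (proj >= 0) "cord_to_periphery" else "periphery_to_cord",
      missing = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("drg_report", class(out))
  out
}

#' Rank montages by field delivered to a target
#'
#' Compares two or more runs (identical anatomy and injected current) by
#' the mean field magnitude over a stated target: a set of DRGs
#' (`target = list(type = "drg", levels = ..., sides = ...)`) or a set of
#' spinal segments (`target = list(type = "segments", segments = ...,
#' tissue = ...)`). Ties are broken lexicographically by montage name.
#'
#' @param runs A list of `tsdcs_run` objects (see [run_simulation()]), or a
#'   list of lists each with `montage_name`, `anatomy_hash`, `drg`
#'   (a `drg_report`) and `summary` (a `segment_summary`).
#' @param target Target specification (see Details above).
#' @return A tibble of class `montage_comparison` ranked best-first:
#'   `rank`, `montage`, `target_mean_e_norm`; attribute `winner`.
#' @export
compare_montages <- function(runs,
                             target = list(type = "drg",
                                           levels = c("L1", "L2", "L3", "L4", "L5"),
                                           sides = c("left", "right"))) {
  if (length(runs) < 2) {
    stop_spinefield("Montage comparison requires at least 2 runs.",
                    "spinefield_param_error")
  }
  hashes <- vapply(runs, function(r) r$anatomy_hash, character(1))
  if (length(unique(hashes)) != 1) {
    stop_spinefield("Runs were computed on different anatomies; refusing to compare.",
                    "spinefield_comparison_error")
  }
  score <- vapply(runs, function(r) {
    if (target$type == "drg") {
      d <- dplyr::filter(r$drg, .data$level %in% target$levels,
                         .data$side %in% (target$sides %||% c("left", "right")),
                         !.data$missing)
      mean(d$mean_e_norm)
    } else {
      s <- dplyr::filter(r$summary, .data$segment %in% target$segments,
                         .data$tissue %in% (target$tissue %||% c("gm", "wm")))
      mean(s$e_norm_max)
    }
  }, numeric(1))
  names_ <- vapply(runs, function(r) r$montage_name, character(1))
  ord <- order(-score, names_)
  out <- tibble::tibble(rank = seq_along(ord), montage = names_[ord],
                        target_mean_e_norm = score[ord])
  class(out) <- c("montage_comparison", class(out))
  attr(out, "winner") <- out$montage[1]
  out
}

#' Spinal segments lying between the electrodes
#'
#' The segments whose z-range falls entirely between the facing inner edges
#' of the two electrode footprints — the region where the induced field is
#' channelled along the canal (under the electrodes themselves it turns
#' radial).
#'
#' @param placed A `placed_montage`.
#' @param landmarks A `landmarks` object.
#' @return Character vector of segment labels.
#' @export
segments_between_electrodes <- function(placed, landmarks) {
  m <- placed$montage
  za <- anchor_z(m$anode$level_anchor, landmarks)
  zc <- anchor_z(m$cathode$level_anchor, landmarks)
  half <- c(anode = m$anode$gel_size[2] / 2, cathode = m$cathode$gel_size[2] / 2)
  lo <- min(za, zc) + if (za < zc) half[["anode"]] else half[["cathode"]]
  hi <- max(za, zc) - if (za > zc) half[["anode"]] else half[["cathode"]]
  seg <- landmarks$segment_z_ranges
  seg$segment[seg$z_min >= lo - 1e-9 & seg$z_max <= hi + 1e-9]
}
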