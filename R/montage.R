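#' Electrode specification
#'
#' One electrode of a trans-spinal DC montage: a conforming conductive-gel
#' layer (50 x 50 x 2.5 mm) against the skin, a conductive-rubber pad
#' (49 x 49 x 1 mm) on the gel, and a metallic connector disc (10 mm
#' diameter, 1 mm thick) on the pad, which the solver treats as the
#' isopotential current port.
#'
#' @param role `"anode"` or `"cathode"`.
#' @param level_anchor A spinous-process label (e.g. `"T8"`) or an
#'   interspinous pair (e.g. `"L1-L2"`) locating the electrode centre along z.
#' @param lateral_offset_mm Signed lateral offset of the centre (mm;
#'   positive = subject-left).
#' @param gel_size,pad_size Length-3 (x, z, thickness) extents in mm; the pad
#'   footprint must sit strictly inside the gel footprint.
#' @param connector_diameter_mm,connector_thickness_mm Connector disc size;
#'   the disc must sit strictly inside the pad footprint.
#' @return A list of class `electrode_spec`.
#' @export
electrode_spec <- function(role = c("cathode", "anode"), level_anchor,
                           lateral_offset_mm = 0,
                           gel_size = c(50, 50, 2.5),
                           pad_size = c(49, 49, 1),
                           connector_diameter_mm = 10,
                           connector_thickness_mm = 1) {
  role <- match.arg(role)
  if (!all(pad_size[1:2] < gel_size[1:2])) {
    stop_spinefield("Pad footprint must sit strictly inside the gel footprint.",
                    "spinefield_param_error")
  }
  if (connector_diameter_mm >= min(pad_size[1:2])) {
    stop_spinefield("Connector must sit strictly inside the pad.",
                    "spinefield_param_error")
  }
  structure(list(role = role, level_anchor = level_anchor,
                 lateral_offset_mm = lateral_offset_mm,
                 gel_size = gel_size, pad_size = pad_size,
                 connector_diameter_mm = connector_diameter_mm,
                 connector_thickness_mm = connector_thickness_mm),
            class = "electrode_spec")
}

MONTAGE_PRESETS <- c("T8-L2", "pvT8R-pvL2L", "pvT8L-pvL2R")

#' Preset electrode montages
#'
#' The three montages considered for lumbar tsDCS: anode over the T8 spinous
#' process and cathode between the L1 and L2 spinous processes, either both
#' on the midline (`"T8-L2"`) or offset 25 mm paravertebrally
#' (`"pvT8R-pvL2L"`: anode 25 mm right of T8, cathode 25 mm left of L1-L2;
#' `"pvT8L-pvL2R"` is its mirror). The cathode is always the lumbar (target)
#' electrode.
#'
#' @param name One of `"T8-L2"`, `"pvT8R-pvL2L"`, `"pvT8L-pvL2R"`.
#' @param landmarks A `landmarks` object (checked for anchor availability).
#' @return A list of class `montage_model` with elements `name`, `anode`,
#'   `cathode`.
#' @export
preset_montage <- function(name, landmarks) {
  if (!name %in% MONTAGE_PRESETS) {
    stop_spinefield(paste0("Unknown montage preset \"", name,
                           "\". Valid presets: ",
                           paste(MONTAGE_PRESETS, collapse = ", "), "."),
                    "spinefield_lookup_error")
  }
  ## +x is subject-left, so "25 mm right" is an offset of -25 mm.
  off <- switch(name,
    "T8-L2"       = c(anode = 0,   cathode = 0),
    "pvT8R-pvL2L" = c(anode = -25, cathode = 25),
    "pvT8L-pvL2R" = c(anode = 25,  cathode = -25))
  if (!"T8" %in% landmarks$spinous_process_z$level) {
    stop_spinefield("Landmarks lack a T8 spinous process for the anode anchor.",
                    "spinefield_lookup_error")
  }
  if (!"L1-L2" %in% landmarks$interspinous_z$pair) {
    stop_spinefield("Landmarks lack the L1-L2 interspinous anchor.",
                    "spinefield_lookup_error")
  }
  structure(list(
    name = name,
    anode = electrode_spec("anode", "T8", off[["anode"]]),
    cathode = electrode_spec("cathode", "L1-L2", off[["cathode"]])
  ), class = "montage_model")
}

## Resolve an anchor label to its z coordinate.
anchor_z <- function(anchor, landmarks) {
  if (grepl("-", anchor, fixed = TRUE)) {
    row <- which(landmarks$interspinous_z$pair == anchor)
    if (!length(row)) {
      stop_spinefield(paste0("Interspinous anchor \"", anchor, "\" not found."),
                      "spinefield_lookup_error")
    }
    landmarks$interspinous_z$z[row]
  } else {
    row <- which(landmarks$spinous_process_z$level == anchor)
    if (!length(row)) {
      stop_spinefield(paste0("Spinous-process anchor \"", anchor, "\" not found."),
                      "spinefield_lookup_error")
    }
    landmarks$spinous_process_z$z[row]
  }
}

#' Stamp an electrode stack onto the dorsal skin
#'
#' Places the gel/rubber/connector stack over the dorsal skin surface at the
#' electrode's anchor. The gel conforms to the curved skin: each column of
#' the footprint is filled from its local skin surface up to a common pad
#' plane, so there is no air gap. Rubber and connector are stamped above the
#' gel. Only background voxels are written (re-stamping the identical
#' electrode is a no-op); anything else in the way is a placement error.
#'
#' @param grid A `label_grid`.
#' @param landmarks A `landmarks` object.
#' @param spec An [electrode_spec()].
#' @return A list: `grid` (updated), `connector_voxels` (linear indices of
#'   the connector voxels of this electrode), `center` (x, z of the
#'   footprint centre), `role`.
#' @export
place_electrode <- function(grid, landmarks, spec) {
  lab <- grid$labels
  h <- grid$voxel_size
  d <- dim(lab)
  L <- TISSUE_LABELS
  z0 <- anchor_z(spec$level_anchor, landmarks)
  x0 <- spec$lateral_offset_mm

  gx <- spec$gel_size[1] / 2; gz <- spec$gel_size[2] / 2
  ix <- which(abs(axis_centers(d[1], grid$origin[1], h) - x0) <= gx)
  iz <- which(abs(axis_centers(d[3], grid$origin[3], h) - z0) <= gz)
  if (!length(ix) || !length(iz)) {
    stop_spinefield("Electrode footprint lies outside the grid.",
                    "spinefield_placement_error")
  }

  ## Dorsal skin surface per footprint column: topmost anatomy voxel in +y.
  tissue_max <- max(L[ANATOMY_LABELS])
  sub <- lab[ix, , iz, drop = FALSE]
  is_tissue <- sub >= L[["skin"]] & sub <= tissue_max
  ysurf <- apply(is_tissue, c(1, 3), function(col) {
    w <- which(col)
    if (length(w)) max(w) else NA_integer_
  })
  if (anyNA(ysurf)) {
    stop_spinefield(paste0(
      "Electrode footprint at anchor ", spec$level_anchor, " (offset ",
      spec$lateral_offset_mm, " mm) extends beyond the body surface."),
      "spinefield_placement_error")
  }
  top_lab <- lab[ix, , iz, drop = FALSE][cbind(
    rep(seq_along(ix), times = length(iz)), as.vector(ysurf),
    rep(seq_along(iz), each = length(ix)))]
  if (!all(top_lab == L[["skin"]])) {
    stop_spinefield("Electrode footprint is not entirely on skin.",
                    "spinefield_placement_error")
  }

  gel_layers <- max(1L, as.integer(round(spec$gel_size[3] / h)))
  pad_layers <- max(1L, as.integer(round(spec$pad_size[3] / h)))
  con_layers <- max(1L, as.integer(round(spec$connector_thickness_mm / h)))
  y_gel_top <- max(ysurf) + gel_layers
  y_pad_top <- y_gel_top + pad_layers
  y_con_top <- y_pad_top + con_layers
  if (y_con_top > d[2]) {
    stop_spinefield("Electrode stack exceeds the grid's dorsal extent.",
                    "spinefield_placement_error")
  }

  stamp <- function(lab, ixs, izs, y_from, y_to, value) {
    ## y_from may vary per column (gel); y_to is a common plane.
    for (a in seq_along(ixs)) for (b in seq_along(izs)) {
      yy <- y_from[a, b]:y_to
      cur <- lab[ixs[a], yy, izs[b]]
      conflict <- cur != L[["background"]] & cur != value
      if (any(conflict)) {
        stop_spinefield(paste0(
          "Electrode placement would overwrite tissue label ",
          names(L)[match(cur[conflict][1], L)], "."),
          "spinefield_placement_error")
      }
      lab[ixs[a], yy, izs[b]] <- value
    }
    lab
  }

  lab <- stamp(lab, ix, iz, ysurf + 1L,
               y_gel_top, L[["gel"]])

  px <- spec$pad_size[1] / 2; pz <- spec$pad_size[2] / 2
  ipx <- ix[abs(axis_centers(d[1], grid$origin[1], h)[ix] - x0) <= px]
  ipz <- iz[abs(axis_centers(d[3], grid$origin[3], h)[iz] - z0) <= pz]
  lab <- stamp(lab, ipx, ipz,
               matrix(y_gel_top + 1L, length(ipx), length(ipz)),
               y_pad_top, L[["rubber"]])

  rr <- spec$connector_diameter_mm / 2
  xc <- axis_centers(d[1], grid$origin[1], h)
  zc <- axis_centers(d[3], grid$origin[3], h)
  icx <- ix[abs(xc[ix] - x0) <= rr]
  icz <- iz[abs(zc[iz] - z0) <= rr]
  con_idx <- integer(0)
  for (a in icx) for (b in icz) {
    if ((xc[a] - x0)^2 + (zc[b] - z0)^2 > rr^2) next
    yy <- (y_pad_top + 1L):y_con_top
    cur <- lab[a, yy, b]
    if (any(cur != L[["background"]] & cur != L[["connector"]])) {
      stop_spinefield("Connector placement conflicts with existing labels.",
                      "spinefield_placement_error")
    }
    lab[a, yy, b] <- L[["connector"]]
    con_idx <- c(con_idx, a + (yy - 1L) * d[1] + (b - 1L) * d[1] * d[2])
  }
  grid$labels <- lab
  list(grid = grid, connector_voxels = sort(con_idx),
       center = c(x = x0, z = z0), role = spec$role)
}

#' Place a full montage on the anatomy
#'
#' @param anatomy An `anatomy` from [build_anatomy()].
#' @param montage A `montage_model` from [preset_montage()] (or a preset
#'   name).
#' @return A list of class `placed_montage`: `grid` (labels with both
#'   electrode stacks), `montage`, `electrodes` (per-role connector voxel
#'   indices and centres), `anatomy_hash`.
#' @export
place_montage <- function(anatomy, montage) {
  if (is.character(montage)) montage <- preset_montage(montage, anatomy$landmarks)
  a <- place_electrode(anatomy$grid, anatomy$landmarks, montage$anode)
  c_ <- place_electrode(a$grid, anatomy$landmarks, montage$cathode)
  structure(list(
    grid = c_$grid,
    montage = montage,
    electrodes = list(
      anode = list(connector_voxels = a$connector_voxels, center = a$center),
      cathode = list(connector_voxels = c_$connector_voxels, center = c_$center)),
    anatomy_hash = anatomy_hash(anatomy)
  ), class = "placed_montage")
}

anatomy_hash <- function(anatomy) {
  rlang::hash(list(anatomy$grid$labels, anatomy$grid$voxel_size,
                   anatomy$grid$origin))
}

#' Session parameters and dosimetry
#'
#' Computes the delivered charge density `I * t / A`, the mean electrode
#' current density `I / A`, and whether the current density is below the
#' 250 A/m^2 safety threshold for cutaneous and nervous tissue. The default
#' session (4 mA for 900 s through 25 cm^2 electrodes) delivers
#' 144 mC/cm^2 at 1.6 A/m^2.
#'
#' @param current_mA Injected current (mA, >= 0; 0 is a sham session).
#' @param duration_s Session duration (s, > 0).
#' @param electrode_area_cm2 Electrode contact area (cm^2, > 0).
#' @param safety_limit_A_m2 Current-density safety bound (A/m^2).
#' @return A one-row tibble: `current_mA`, `duration_s`, `area_cm2`,
#'   `current_density_A_m2`, `charge_density_mC_cm2`, `safe`.
#' @export
#' @examples
#' session_dosimetry()                 # 4 mA, 900 s, 25 cm^2 -> 144 mC/cm^2
#' session_dosimetry(current_mA = 0)   # sham
session_dosimetry <- function(current_mA = 4, duration_s = 900,
                              electrode_area_cm2 = 25,
                              safety_limit_A_m2 = 250) {
  if (current_mA < 0 || duration_s <= 0 || electrode_area_cm2 <= 0) {
    stop_spinefield("Need current >= 0, duration > 0, area > 0.",
                    "spinefield_param_error")
  }
  cd <- (current_mA * 1e-3) / (electrode_area_cm2 * 1e-4)   # A/m^2
  qd <- current_mA * duration_s / electrode_area_cm2        # mA*s/cm^2 = mC/cm^2
  tibble::tibble(
    current_mA = current_mA, duration_s = duration_s,
    area_cm2 = electrode_area_cm2,
    current_density_A_m2 = cd, charge_density_mC_cm2 = qd,
    safe = cd <= safety_limit_A_m2)
}
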