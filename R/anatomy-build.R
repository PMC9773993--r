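## Procedural stamping of the labelled voxel anatomy.
##
## The model is assembled back-to-front: torso shells, organ blobs, vertebral
## column, canal contents, roots/DRG, cord. Later stamps overwrite earlier
## ones, so ordering encodes containment (e.g. grey matter is stamped last
## and always sits inside white matter).

## ---- geometric mask primitives -------------------------------------------

## Elliptical-cylinder mask along z: ((x-cx)/a)^2 + ((y-cy)/b)^2 <= 1.
mask_ellipse_z <- function(cc, cx, cy, a, b, z0 = -Inf, z1 = Inf) {
  ((cc$x - cx) / a)^2 + ((cc$y - cy) / b)^2 <= 1 & cc$z >= z0 & cc$z <= z1
}

## Circular-cylinder mask along x (used for root channels).
mask_cylinder_x <- function(cc, cy, cz, r, x0 = -Inf, x1 = Inf) {
  (cc$y - cy)^2 + (cc$z - cz)^2 <= r^2 & cc$x >= x0 & cc$x <= x1
}

## Axis-aligned ellipsoid mask.
mask_ellipsoid <- function(cc, center, semi) {
  ((cc$x - center[1]) / semi[1])^2 +
    ((cc$y - center[2]) / semi[2])^2 +
    ((cc$z - center[3]) / semi[3])^2 <= 1
}

## Axis-aligned box mask.
mask_box <- function(cc, xr, yr, zr) {
  cc$x >= xr[1] & cc$x <= xr[2] &
    cc$y >= yr[1] & cc$y <= yr[2] &
    cc$z >= zr[1] & cc$z <= zr[2]
}

## ---- label grid container ------------------------------------------------

new_label_grid <- function(labels, voxel_size, origin) {
  structure(
    list(labels = labels, voxel_size = voxel_size, origin = origin,
         dict = TISSUE_LABELS),
    class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  d <- dim(x$labels)
  cat("<label_grid> ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_size, " mm\n", sep = "")
  tb <- table(factor(x$labels, levels = TISSUE_LABELS,
                     labels = names(TISSUE_LABELS)))
  present <- tb[tb > 0]
  cat("  labels: ", paste0(names(present), " (", present, ")",
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-tissue voxel counts of a label grid
#'
#' @param grid A `label_grid`.
#' @return A tibble with columns `tissue`, `label`, `n_voxels`, `volume_mm3`.
#' @export
label_counts <- function(grid) {
  tb <- tabulate(grid$labels + 1L, nbins = max(TISSUE_LABELS) + 1L)
  tibble::tibble(
    tissue = names(TISSUE_LABELS),
    label = unname(TISSUE_LABELS),
    n_voxels = tb[TISSUE_LABELS + 1L],
    volume_mm3 = tb[TISSUE_LABELS + 1L] * grid$voxel_size^3
  )
}

## ---- anatomy construction ------------------------------------------------

#' Build the synthetic labelled torso/spine model
#'
#' Stamps the parametric anatomy of an [anatomy_params()] set onto a uniform
#' voxel grid and derives the spinal-cord centreline frame and the anatomical
#' landmark tables (spinous processes, interspinous gaps, dorsal root
#' ganglia, spinal-segment z-ranges).
#'
#' Coordinate convention: +x subject-left, +y dorsal, +z rostral; physical
#' coordinate = origin + (0-based index + 0.5) * voxel size. The default
#' (jitter-free) anatomy is exactly mirror-symmetric about the mid-sagittal
#' plane x = 0. Torso truncation planes (rostral/caudal slabs) are capped
#' with skin so the skin shell is closed; beyond them lies background.
#'
#' The construction is deterministic for fixed parameters and seed.
#'
#' @param params An [anatomy_params()] object.
#' @return A list of class `anatomy` with elements `grid` (a `label_grid`),
#'   `frame` (cord centreline frame, see [frame_at_z()]), `landmarks`
#'   (landmark tables) and `params`.
#' @export
#' @examples
#' anat <- build_anatomy(anatomy_params("compact"))
#' label_counts(anat$grid)
build_anatomy <- function(params) {
  stopifnot(inherits(params, "anatomy_params"))
  validate_anatomy_params(params)
  p <- params
  h <- p$grid_resolution
  ax <- p$torso_semi_axes[1]; ay <- p$torso_semi_axes[2]

  ## Grid extents: x/y symmetric about 0 (even counts so mirror symmetry is
  ## exact); dorsal clearance for the electrode stack.
  clearance <- 16 + 2 * h
  nx <- 2L * as.integer(ceiling((ax + 2 * h) / h))
  ny <- 2L * as.integer(ceiling((ay + clearance) / h))
  nz <- as.integer(ceiling(p$torso_height / h))
  origin <- c(-nx * h / 2, -ny * h / 2, 0)
  dims <- c(nx, ny, nz)
  cc <- coord_arrays(dims, origin, h)
  lab <- array(TISSUE_LABELS[["background"]], dims)

  tskin <- p$skin_thickness; tfat <- p$fat_thickness
  z0t <- 2 * h; z1t <- p$torso_height - 2 * h

  ## Torso shells (skin closes the truncation planes as caps).
  lab[mask_ellipse_z(cc, 0, 0, ax, ay, z0t, z1t)] <- TISSUE_LABELS[["skin"]]
  lab[mask_ellipse_z(cc, 0, 0, ax - tskin, ay - tskin,
                     z0t + tskin, z1t - tskin)] <- TISSUE_LABELS[["fat"]]
  lab[mask_ellipse_z(cc, 0, 0, ax - tskin - tfat, ay - tskin - tfat,
                     z0t + tskin + tfat, z1t - tskin - tfat)] <-
    TISSUE_LABELS[["muscle"]]

  ## Column layout (bottom-up): sacrum block, then disk + body per level.
  ## The canal centre is snapped to a voxel-centre row so the cord/CSF/dura
  ## nesting survives discretization at coarse resolutions.
  yc <- ay - tskin - tfat - p$spinous_process_depth -
    p$canal_wall_thickness - p$canal_radius - 2
  yc <- origin[2] + (round((yc - origin[2]) / h - 0.5) + 0.5) * h
  y_body <- yc - p$canal_radius - p$canal_wall_thickness -
    p$vertebral_body_radius + 4
  sacrum_h <- 3 * p$vertebral_body_height
  col_z0 <- z0t + tskin + tfat + 6
  vlv <- rev(utils::head(p$levels, -1))      # caudal -> rostral vertebrae
  z <- col_z0 + sacrum_h
  body_range <- list(); disk_range <- list()
  below <- "sacrum"
  for (lv in vlv) {
    disk_range[[paste0(lv, "-", below)]] <- c(z, z + p$disk_height)
    z <- z + p$disk_height
    body_range[[lv]] <- c(z, z + p$vertebral_body_height)
    z <- z + p$vertebral_body_height
    below <- lv
  }
  col_top <- z
  ## Disk naming: the disk below vertebra V separates V from the level below;
  ## rename "L1-sacrum"-style keys to the conventional pair where applicable.
  names(disk_range) <- vapply(names(disk_range), function(nm) {
    parts <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (parts[2] == "sacrum") paste0(parts[1], "-S1") else nm
  }, character(1))

  ## Organ blobs (anterior, mirror-symmetric): lungs, heart, viscera.
  jit <- organ_jitter(p)
  lung_z <- col_top - 0.22 * (col_top - col_z0)
  lung_semi <- c(0.28 * ax, 0.30 * ay, 0.18 * (col_top - col_z0))
  for (s in c(-1, 1)) {
    lab[mask_ellipsoid(cc, c(s * 0.38 * ax, -0.25 * ay, lung_z) + jit$lung[[if (s > 0) 1 else 2]],
                       lung_semi) & lab == TISSUE_LABELS[["muscle"]]] <-
      TISSUE_LABELS[["lungs"]]
  }
  lab[mask_ellipsoid(cc, c(0, -0.38 * ay, lung_z - 1.2 * lung_semi[3]) + jit$heart,
                     c(0.20 * ax, 0.22 * ay, 0.6 * lung_semi[3])) &
        lab == TISSUE_LABELS[["muscle"]]] <- TISSUE_LABELS[["heart"]]
  lab[mask_ellipsoid(cc, c(0, -0.22 * ay, col_z0 + 0.30 * (col_top - col_z0)) + jit$viscera,
                     c(0.52 * ax, 0.36 * ay, 0.28 * (col_top - col_z0))) &
        lab == TISSUE_LABELS[["muscle"]]] <- TISSUE_LABELS[["viscera"]]

  ## Sacrum: fused block spanning body and posterior ring footprint.
  sac <- (mask_ellipse_z(cc, 0, y_body, 1.3 * p$vertebral_body_radius,
                         1.3 * p$vertebral_body_radius,
                         col_z0, col_z0 + sacrum_h) |
            mask_ellipse_z(cc, 0, yc,
                           p$canal_radius + p$canal_wall_thickness,
                           p$canal_radius + p$canal_wall_thickness,
                           col_z0, col_z0 + sacrum_h))
  lab[sac] <- TISSUE_LABELS[["bone"]]

  ## Vertebrae: body cylinder + ring around the canal + spinous process.
  ring_out <- p$canal_radius + p$canal_wall_thickness
  sp_w <- 4.5
  for (lv in vlv) {
    br <- body_range[[lv]]
    lab[mask_ellipse_z(cc, 0, y_body, p$vertebral_body_radius,
                       p$vertebral_body_radius, br[1], br[2])] <-
      TISSUE_LABELS[["bone"]]
    ring <- mask_ellipse_z(cc, 0, yc, ring_out, ring_out, br[1], br[2]) &
      !mask_ellipse_z(cc, 0, yc, p$canal_radius, p$canal_radius, br[1], br[2])
    lab[ring] <- TISSUE_LABELS[["bone"]]
    zmid <- mean(br)
    lab[mask_box(cc, c(-sp_w, sp_w),
                 c(yc + ring_out - 1, yc + ring_out + p$spinous_process_depth),
                 c(zmid - 0.35 * p$vertebral_body_height,
                   zmid + 0.35 * p$vertebral_body_height))] <-
      TISSUE_LABELS[["bone"]]
  }
  for (nm in names(disk_range)) {
    dr <- disk_range[[nm]]
    lab[mask_ellipse_z(cc, 0, y_body, p$vertebral_body_radius,
                       p$vertebral_body_radius, dr[1], dr[2])] <-
      TISSUE_LABELS[["disk"]]
  }

  ## Spinal canal contents: dura tube with end caps, CSF inside.
  canal_z0 <- col_z0 + sacrum_h / 2
  tdura <- p$dura_thickness
  in_canal <- mask_ellipse_z(cc, 0, yc, p$canal_radius, p$canal_radius,
                             canal_z0, col_top)
  lab[in_canal] <- TISSUE_LABELS[["dura"]]
  lab[mask_ellipse_z(cc, 0, yc, p$canal_radius - tdura, p$canal_radius - tdura,
                     canal_z0 + tdura, col_top - tdura)] <-
    TISSUE_LABELS[["csf"]]

  ## Roots through the intervertebral foramina (ring gaps at disk levels).
  conus_pair <- conus_disk_name(p$levels)
  conus_z <- mean(disk_range[[conus_pair]])
  x_out <- ring_out + 2
  for (nm in names(disk_range)) {
    dr <- disk_range[[nm]]
    zf <- mean(dr)
    if (zf <= canal_z0 + tdura) next
    ch <- mask_cylinder_x(cc, yc, zf, p$root_radius, -x_out, x_out) &
      cc$z > dr[1] - 1e-9 & cc$z < dr[2] + 1e-9 &
      lab != TISSUE_LABELS[["background"]] & lab != TISSUE_LABELS[["skin"]]
    lab[ch] <- TISSUE_LABELS[["roots"]]
  }

  ## Cauda equina bundle below the conus.
  cauda_r <- min(3, p$cord_semi_axes[2])
  lab[mask_ellipse_z(cc, 0, yc, cauda_r, cauda_r,
                     canal_z0 + tdura + h, conus_z) &
        lab == TISSUE_LABELS[["csf"]]] <- TISSUE_LABELS[["roots"]]

  ## Spinal cord: WM ellipse with GM core, conus to truncation. The GM core
  ## is inset one voxel at both cord ends so it stays strictly inside WM.
  cord_top <- col_top - tdura - h
  lab[mask_ellipse_z(cc, 0, yc, p$cord_semi_axes[1], p$cord_semi_axes[2],
                     conus_z, cord_top)] <- TISSUE_LABELS[["wm"]]
  lab[mask_ellipse_z(cc, 0, yc, p$gm_semi_axes[1], p$gm_semi_axes[2],
                     conus_z + h, cord_top - h)] <- TISSUE_LABELS[["gm"]]

  ## DRG ellipsoids in the foramina, T12..L5 bilaterally where present.
  x_drg <- p$canal_radius + p$canal_wall_thickness / 2 + 1
  drg_rows <- list()
  for (lv in intersect(c("T12", paste0("L", 1:5)), vlv)) {
    nm <- grep(paste0("^", lv, "-"), names(disk_range), value = TRUE)
    if (!length(nm)) next
    zf <- mean(disk_range[[nm[1]]])
    for (side in c("left", "right")) {
      s <- if (side == "left") 1 else -1
      ## jitter displaces the foraminal |x| only, mirrored left/right
      ctr <- c(s * (x_drg + jit$drg[[lv]]), yc, zf)
      lab[mask_ellipsoid(cc, ctr, p$drg_semi_axes)] <- TISSUE_LABELS[["roots"]]
      drg_rows[[paste(lv, side)]] <- tibble::tibble(
        level = lv, side = side, x = ctr[1], y = ctr[2], z = ctr[3])
    }
  }
  drg <- dplyr::bind_rows(drg_rows)

  ## Landmark tables.
  spinous <- tibble::tibble(
    level = vlv,
    z = vapply(body_range[vlv], mean, numeric(1)))
  inter <- tibble::tibble(
    pair = names(disk_range),
    z = vapply(disk_range, mean, numeric(1)))
  root_axes <- dplyr::mutate(
    drg,
    ax = ifelse(.data$side == "left", 1, -1), ay = 0, az = 0)[
      , c("level", "side", "ax", "ay", "az")]
  segments <- build_segment_ranges(p$segment_map, conus_z, cord_top)

  landmarks <- structure(list(
    spinous_process_z = spinous,
    interspinous_z = inter,
    drg_centers = drg,
    root_axes = root_axes,
    segment_z_ranges = segments,
    cord_z = c(conus_z, cord_top),
    canal_center = c(0, yc),
    conus_z = conus_z
  ), class = "landmarks")

  frame <- build_cord_frame(yc, conus_z, cord_top, h)

  structure(list(
    grid = new_label_grid(lab, h, origin),
    frame = frame,
    landmarks = landmarks,
    params = p
  ), class = "anatomy")
}

## Optional geometric jitter (seeded, off by default). Displacements are
## applied symmetrically so a jittered anatomy is still mirror-consistent in
## its left/right DRG placement; jitter models inter-subject variability in
## organ position and foraminal height, not asymmetry.
organ_jitter <- function(p) {
  lvls <- utils::head(p$levels, -1)
  if (p$jitter_mm <= 0) {
    return(list(
      lung = list(c(0, 0, 0), c(0, 0, 0)), heart = c(0, 0, 0),
      viscera = c(0, 0, 0),
      drg = stats::setNames(rep(0, length(lvls)), lvls)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(p$rng_seed)
  r <- function(n = 3) stats::rnorm(n, 0, p$jitter_mm)
  lj <- r()
  list(lung = list(lj, lj * c(-1, 1, 1)), heart = r() * c(0, 1, 1),
       viscera = r() * c(0, 1, 1),
       drg = stats::setNames(stats::rnorm(length(lvls), 0, p$jitter_mm), lvls))
}

conus_disk_name <- function(levels) {
  if ("L1" %in% levels && "L2" %in% levels) "L1-L2" else {
    stop_spinefield("Anatomy needs vertebrae L1 and L2 to place the conus.",
                    "spinefield_param_error")
  }
}

## Segment ranges tile [conus, cord_top]: stack the nominal lengths upward
## from the conus and let the most rostral listed segment absorb the rest.
build_segment_ranges <- function(segment_map, conus_z, cord_top) {
  zmin <- conus_z + c(0, cumsum(utils::head(segment_map$length_mm, -1)))
  zmax <- conus_z + cumsum(segment_map$length_mm)
  zmax[length(zmax)] <- max(zmax[length(zmax)], cord_top)
  keep <- zmin < cord_top
  out <- tibble::tibble(segment = segment_map$segment[keep],
                        z_min = zmin[keep], z_max = pmin(zmax[keep], cord_top))
  out
}

## ---- cord frame ----------------------------------------------------------

## The default cord is straight along z; the frame machinery still supports a
## curved centreline (tangent by finite differences, ventral reference vector
## re-orthogonalized per point).
build_cord_frame <- function(yc, z0, z1, h, centerline_x = NULL) {
  z <- seq(z0, z1, by = h)
  x <- if (is.null(centerline_x)) rep(0, length(z)) else centerline_x(z)
  y <- rep(yc, length(z))
  n <- length(z)
  tx <- c(diff(x), x[n] - x[n - 1]) ; tz <- rep(h, n)
  ty <- rep(0, n)
  nt <- sqrt(tx^2 + ty^2 + tz^2)
  t_hat <- cbind(tx, ty, tz) / nt           # points rostral (+z)
  ventral <- c(0, -1, 0)
  v_hat <- t(apply(t_hat, 1, function(t) {
    v <- ventral - sum(ventral * t) * t
    v / sqrt(sum(v^2))
  }))
  r_hat <- t(vapply(seq_len(n), function(i) {
    c(t_hat[i, 2] * v_hat[i, 3] - t_hat[i, 3] * v_hat[i, 2],
      t_hat[i, 3] * v_hat[i, 1] - t_hat[i, 1] * v_hat[i, 3],
      t_hat[i, 1] * v_hat[i, 2] - t_hat[i, 2] * v_hat[i, 1])
  }, numeric(3)))
  structure(list(
    z = z, center = cbind(x = x, y = y, z = z),
    t_hat = t_hat, v_hat = v_hat, r_hat = r_hat, h = h
  ), class = "cord_frame")
}

#' Cord frame triads at given z
#'
#' Returns the local orthonormal triad of the cord centreline frame at the
#' requested z positions (nearest centreline sample): `t_hat` the
#' longitudinal tangent pointing rostral, `v_hat` the dorsal-to-ventral
#' axis, `r_hat` the right-to-left axis.
#'
#' @param frame A `cord_frame` from [build_anatomy()].
#' @param z Numeric vector of z coordinates (mm) within the cord extent.
#' @return A list of matrices `t_hat`, `v_hat`, `r_hat` (one row per z).
#' @export
frame_at_z <- function(frame, z) {
  rng <- range(frame$z)
  if (any(z < rng[1] - frame$h / 2 | z > rng[2] + frame$h / 2)) {
    stop_spinefield("z outside the cord frame coverage.",
                    "spinefield_range_error")
  }
  i <- pmin(pmax(1L, as.integer(round((z - frame$z[1]) / frame$h)) + 1L),
            length(frame$z))
  list(t_hat = frame$t_hat[i, , drop = FALSE],
       v_hat = frame$v_hat[i, , drop = FALSE],
       r_hat = frame$r_hat[i, , drop = FALSE])
}

## ---- segment lookup ------------------------------------------------------

#' Spinal segment containing a z coordinate
#'
#' Piecewise-constant lookup of the spinal segment whose z-range contains
#' each `z`. A z exactly on a boundary between two ranges belongs to the
#' more caudal (lower) segment.
#'
#' @param z Numeric vector of z coordinates (mm).
#' @param landmarks A `landmarks` object from [build_anatomy()].
#' @return Character vector of segment labels.
#' @export
segment_for_z <- function(z, landmarks) {
  seg <- landmarks$segment_z_ranges
  breaks <- c(seg$z_min[1], seg$z_max)
  if (any(z < breaks[1] - 1e-9 | z > breaks[length(breaks)] + 1e-9)) {
    bad <- z[z < breaks[1] - 1e-9 | z > breaks[length(breaks)] + 1e-9][1]
    stop_spinefield(paste0("z = ", bad, " mm is outside the mapped cord extent [",
                           breaks[1], ", ", breaks[length(breaks)], "] mm."),
                    "spinefield_range_error")
  }
  k <- findInterval(z, breaks, left.open = TRUE)
  k[k == 0L] <- 1L                        # z exactly at the caudal end
  seg$segment[k]
}

## ---- validation ----------------------------------------------------------

#' Check the structural invariants of a label grid
#'
#' Reports, per invariant, pass/fail and the number of offending voxels:
#' all labels known; skin (with any mounted electrode stack) forms a closed
#' shell around the interior tissues (checked by axis-aligned ray casting
#' from all six directions); CSF is a single 26-connected component; grey
#' matter strictly inside white matter; white matter enclosed by GM/CSF/
#' roots; CSF enclosed by dura (up to root and cord contacts).
#'
#' @param grid A `label_grid`.
#' @return A tibble with columns `check`, `pass`, `n_offending`, `detail`;
#'   attribute `ok` is `TRUE` iff all checks pass.
#' @export
validate_anatomy <- function(grid) {
  lab <- grid$labels
  L <- TISSUE_LABELS
  rows <- list()

  known <- lab %in% unname(L)
  rows$known_labels <- check_row("known_labels", all(known), sum(!known),
                                 "every voxel maps to a known tissue")

  ## Closed shell: along each axis direction, the first non-background voxel
  ## of every ray must be skin or electrode material.
  allowed_first <- unname(L[c("skin", ELECTRODE_LABELS)])
  breach <- NULL; n_breach <- 0L
  for (axis in 1:3) for (from_end in c(FALSE, TRUE)) {
    fh <- first_hit_labels(lab, axis, from_end)
    bad <- which(!is.na(fh$label) & !(fh$label %in% allowed_first), arr.ind = TRUE)
    n_breach <- n_breach + nrow(bad)
    if (is.null(breach) && nrow(bad) > 0) {
      hit <- fh$label[bad[1, 1], bad[1, 2]]
      breach <- paste0("first breach: axis ", axis,
                       ifelse(from_end, " (from high)", " (from low)"),
                       " at line index (", bad[1, 1], ",", bad[1, 2],
                       "), exposed label ", names(L)[match(hit, L)])
    }
  }
  rows$skin_closed <- check_row("skin_closed_shell", n_breach == 0L, n_breach,
                                breach %||% "skin/electrode first along every ray")

  csf <- lab == L[["csf"]]
  ncomp <- if (any(csf)) max(cc_label(csf, 26L)) else 0L
  rows$csf_connected <- check_row(
    "csf_single_component", ncomp == 1L, max(0L, ncomp - 1L),
    paste0("26-connected CSF components: ", ncomp))

  rows$gm_in_wm <- neighbour_check(lab, "gm", c("gm", "wm"),
                                   "gm_inside_wm")
  rows$wm_enclosed <- neighbour_check(lab, "wm", c("wm", "gm", "csf", "roots"),
                                      "wm_inside_csf")
  rows$csf_in_dura <- neighbour_check(lab, "csf",
                                      c("csf", "dura", "wm", "gm", "roots"),
                                      "csf_inside_dura")

  out <- dplyr::bind_rows(rows)
  attr(out, "ok") <- all(out$pass)
  out
}

check_row <- function(check, pass, n, detail) {
  tibble::tibble(check = check, pass = pass, n_offending = as.integer(n),
                 detail = detail)
}

## First non-background label along each axis-aligned ray.
first_hit_labels <- function(lab, axis, from_end) {
  bg <- TISSUE_LABELS[["background"]]
  perm <- switch(axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2), `3` = c(1, 2, 3))
  a <- aperm(lab, perm)                  # scan along the 3rd dim
  d <- dim(a)
  if (from_end) a <- a[, , rev(seq_len(d[3])), drop = FALSE]
  m <- a != bg
  flat <- matrix(m, nrow = d[1] * d[2])
  first <- max.col(cbind(flat, TRUE), ties.method = "first")  # index of first TRUE
  has <- first <= d[3]
  lf <- matrix(a, nrow = d[1] * d[2])
  labf <- rep(NA_integer_, d[1] * d[2])
  labf[has] <- lf[cbind(which(has), first[has])]
  list(label = matrix(labf, d[1], d[2]))
}

neighbour_check <- function(lab, tissue, allowed, name) {
  L <- TISSUE_LABELS
  target <- lab == L[[tissue]]
  if (!any(target)) {
    return(check_row(name, FALSE, 0L, paste0("no ", tissue, " voxels present")))
  }
  allowed_l <- unname(L[allowed])
  bad <- array(FALSE, dim(lab))
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    nb <- shift_array(lab, axis, s, fill = NA_integer_)
    bad <- bad | (target & !is.na(nb) & !(nb %in% allowed_l))
    bad <- bad | (target & is.na(nb))    # tissue at the grid border
  }
  check_row(name, !any(bad), sum(bad),
            paste0(tissue, " touches only {", paste(allowed, collapse = ", "), "}"))
}

## 26- or 6-connected component labelling (Rcpp kernel).
cc_label <- function(mask, connectivity = 26L) {
  cc_label_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
}
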