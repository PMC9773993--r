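#' Tissue conductivity table
#'
#' The default DC conductivities of the 13 model tissues plus the electrode
#' materials. Muscle and spinal white matter are anisotropic: their
#' conductivity tensors are built from the isotropic reference value and an
#' eigenvalue ratio under the volume constraint (the product of eigenvalues
#' is kept equal to the isotropic value cubed), with muscle fibres along the
#' body axis and white-matter fibres along the local cord tangent.
#'
#' The anisotropy ratios are configurable; the defaults (white matter 10,
#' muscle 5) are common literature values for fibrous tissue.
#'
#' @param wm_ratio,muscle_ratio Longitudinal:transverse eigenvalue ratios
#'   (>= 1) for spinal white matter and muscle. Set to 1 for a fully
#'   isotropic model.
#' @return A tibble with columns `tissue`, `label`, `sigma` (S/m),
#'   `anisotropic`, `ratio`, `fiber_rule` (`"cord_tangent"`, `"body_axis"`
#'   or `"none"`).
#' @export
#' @examples
#' tissue_table()
#' sigma_for_tissue("CSF")
tissue_table <- function(wm_ratio = 10, muscle_ratio = 5) {
  if (wm_ratio < 1 || muscle_ratio < 1) {
    stop_spinefield("Anisotropy ratios must be >= 1.", "spinefield_param_error")
  }
  tb <- tibble::tibble(
    tissue = c("skin", "fat", "muscle", "lungs", "heart", "viscera", "bone",
               "disk", "dura", "csf", "roots", "wm", "gm",
               "gel", "rubber", "connector"),
    sigma = c(0.435, 0.040, 0.355, 0.046, 0.535, 0.123, 0.006,
              0.200, 0.030, 1.790, 0.154, 0.143, 0.333,
              4, 44, 5.96e7),
    anisotropic = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                    FALSE, FALSE, FALSE),
    ratio = c(1, 1, muscle_ratio, 1, 1, 1, 1,
              1, 1, 1, 1, wm_ratio, 1,
              1, 1, 1),
    fiber_rule = c("none", "none", "body_axis", "none", "none", "none", "none",
                   "none", "none", "none", "none", "cord_tangent", "none",
                   "none", "none", "none")
  )
  tb$label <- unname(TISSUE_LABELS[tb$tissue])
  tb$anisotropic <- tb$anisotropic & tb$ratio > 1
  tb[, c("tissue", "label", "sigma", "anisotropic", "ratio", "fiber_rule")]
}

## Alternative names accepted by sigma_for_tissue(), as they appear in the
## source conductivity compilations.
TISSUE_ALIASES <- c(
  "vertebrae/bone" = "bone", "vertebrae" = "bone", "bone" = "bone",
  "intervertebral disks" = "disk", "disks" = "disk", "disk" = "disk",
  "dura mater" = "dura",
  "brainstem/spinal roots" = "roots", "spinal roots" = "roots",
  "spinal-wm" = "wm", "spinal wm" = "wm", "white matter" = "wm",
  "spinal-gm" = "gm", "spinal gm" = "gm", "grey matter" = "gm",
  "gray matter" = "gm",
  "muscle (isotropic)" = "muscle"
)

#' Isotropic conductivity of a tissue
#'
#' @param name Tissue name (case-insensitive; common aliases such as
#'   `"Vertebrae/Bone"` or `"Spinal-WM"` are accepted).
#' @param table A [tissue_table()].
#' @return The scalar conductivity in S/m.
#' @export
sigma_for_tissue <- function(name, table = tissue_table()) {
  key <- tolower(trimws(name))
  canon <- if (key %in% names(TISSUE_ALIASES)) TISSUE_ALIASES[[key]] else key
  row <- which(table$tissue == canon)
  if (length(row) != 1) {
    stop_spinefield(paste0("Unknown tissue: \"", name, "\"."),
                    "spinefield_lookup_error")
  }
  table$sigma[row]
}

#' Volume-constrained anisotropic conductivity tensor
#'
#' Builds the symmetric 3x3 conductivity tensor with longitudinal eigenvalue
#' `sigma_iso * r^(2/3)` along `direction` and transverse eigenvalues
#' `sigma_iso * r^(-1/3)` (twice), so that the determinant equals
#' `sigma_iso^3` for any ratio `r`: the tensor-ellipsoid volume is preserved
#' relative to the isotropic tissue.
#'
#' @param sigma_iso Isotropic reference conductivity (S/m, > 0).
#' @param direction Unit fibre direction (length-3, |d| = 1 within 1e-9).
#' @param r Longitudinal:transverse eigenvalue ratio (>= 1).
#' @return A symmetric positive-definite 3x3 matrix (S/m).
#' @export
#' @examples
#' s <- build_anisotropic_tensor(0.143, c(0, 0, 1), 10)
#' det(s) / 0.143^3   # 1 by construction
build_anisotropic_tensor <- function(sigma_iso, direction, r) {
  if (!is.numeric(sigma_iso) || sigma_iso <= 0) {
    stop_spinefield("sigma_iso must be > 0.", "spinefield_param_error")
  }
  if (r < 1) {
    stop_spinefield("Anisotropy ratio r must be >= 1.", "spinefield_param_error")
  }
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    stop_spinefield("`direction` must be a unit vector (|d| = 1 within 1e-9).",
                    "spinefield_param_error")
  }
  s_long <- sigma_iso * r^(2 / 3)
  s_trans <- sigma_iso * r^(-1 / 3)
  d <- as.numeric(direction)
  s_trans * diag(3) + (s_long - s_trans) * tcrossprod(d)
}

#' Assemble the per-voxel conductivity tensor field
#'
#' Maps tissue labels to conductivities: isotropic tissues get
#' `sigma * Identity`; anisotropic tissues get volume-constrained tensors
#' with the principal axis set by their fibre rule (`body_axis`: global +z;
#' `cord_tangent`: local cord tangent from the centreline frame).
#'
#' @param grid A `label_grid`.
#' @param table A [tissue_table()].
#' @param frame A `cord_frame` covering the cord extent (required whenever a
#'   `cord_tangent` tissue is anisotropic).
#' @return A `conductivity_field`: arrays `xx`, `yy`, `zz` (and `xy`, `xz`,
#'   `yz` when any tensor has off-diagonal terms), logical array
#'   `anisotropic`, plus grid metadata.
#' @export
assemble_conductivity <- function(grid, table = tissue_table(), frame = NULL) {
  lab <- grid$labels
  dims <- dim(lab)
  sig_by_label <- rep(0, max(TISSUE_LABELS) + 1L)
  sig_by_label[table$label + 1L] <- table$sigma
  iso <- array(sig_by_label[lab + 1L], dims)

  f <- list(xx = iso, yy = iso, zz = iso, xy = NULL, xz = NULL, yz = NULL,
            anisotropic = array(FALSE, dims),
            voxel_size = grid$voxel_size, origin = grid$origin)

  for (row in which(table$anisotropic)) {
    tlab <- table$label[row]
    r <- table$ratio[row]
    vox <- which(lab == tlab)
    if (!length(vox)) next
    s_iso <- table$sigma[row]
    s_long <- s_iso * r^(2 / 3)
    s_trans <- s_iso * r^(-1 / 3)
    f$anisotropic[vox] <- TRUE
    rule <- table$fiber_rule[row]
    if (rule == "body_axis") {
      f$xx[vox] <- s_trans; f$yy[vox] <- s_trans; f$zz[vox] <- s_long
    } else if (rule == "cord_tangent") {
      if (is.null(frame)) {
        stop_spinefield("A cord frame is required for cord_tangent anisotropy.",
                        "spinefield_param_error")
      }
      zc <- axis_centers(dims[3], grid$origin[3], grid$voxel_size)
      zi <- ((vox - 1L) %/% (dims[1] * dims[2])) + 1L
      zv <- zc[zi]
      rng <- range(frame$z)
      if (any(zv < rng[1] - grid$voxel_size | zv > rng[2] + grid$voxel_size)) {
        stop_spinefield("Cord voxel outside the cord frame coverage.",
                        "spinefield_range_error")
      }
      tr <- frame_at_z(frame, pmin(pmax(zv, rng[1]), rng[2]))$t_hat
      dx <- tr[, 1]; dy <- tr[, 2]; dz <- tr[, 3]
      dd <- s_long - s_trans
      f$xx[vox] <- s_trans + dd * dx * dx
      f$yy[vox] <- s_trans + dd * dy * dy
      f$zz[vox] <- s_trans + dd * dz * dz
      oxy <- dd * dx * dy; oxz <- dd * dx * dz; oyz <- dd * dy * dz
      if (any(abs(c(oxy, oxz, oyz)) > 1e-14)) {
        if (is.null(f$xy)) {
          f$xy <- array(0, dims); f$xz <- array(0, dims); f$yz <- array(0, dims)
        }
        f$xy[vox] <- oxy; f$xz[vox] <- oxz; f$yz[vox] <- oyz
      }
    }
  }
  structure(f, class = "conductivity_field")
}

#' @export
print.conductivity_field <- function(x, ...) {
  cat("<conductivity_field> ", paste(dim(x$xx), collapse = " x "),
      " voxels; ", sum(x$anisotropic), " anisotropic; off-diagonals ",
      if (is.null(x$xy)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

## Determinant of the per-voxel tensors at the given voxel indices.
tensor_det <- function(cond, vox) {
  xx <- cond$xx[vox]; yy <- cond$yy[vox]; zz <- cond$zz[vox]
  if (is.null(cond$xy)) return(xx * yy * zz)
  xy <- cond$xy[vox]; xz <- cond$xz[vox]; yz <- cond$yz[vox]
  xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) + xz * (xy * yz - yy * xz)
}
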