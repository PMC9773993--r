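## Cell-centred finite-volume discretization of div(sigma grad phi) = 0 on
## the uniform voxel grid.
##
## Diagonal tensor entries give the 7-point stencil with harmonic face
## averaging of sigma (exact for 1-D layered media with face-aligned
## interfaces); off-diagonal tensor entries add symmetric couplings to the
## in-plane edge-diagonal neighbours (arithmetic averaging), extending the
## stencil towards the 27-point form. All couplings are written as pairwise
## conductances g_ij (Siemens) so that row sums over {phi_i - phi_j}
## vanish on constants, the matrix is symmetric by construction, and the
## current through any voxel interface is g_ij (phi_i - phi_j) in amperes.
##
## Electrode model: connector voxels are eliminated as Dirichlet cells at
## +0.5 V (anode) and -0.5 V (cathode); by linearity the solution is then
## rescaled so the measured electrode current equals the requested value.
## Background voxels carry no equation: faces towards them are insulating
## (zero normal current), which implements the truncation of the model.

#' Assemble the finite-volume system for a placed montage
#'
#' @param cond A `conductivity_field` from [assemble_conductivity()].
#' @param placed A `placed_montage` from [place_montage()] (or any list with
#'   a `grid` and `electrodes` entry).
#' @param anode_V,cathode_V Dirichlet potentials applied to the connector
#'   voxels before rescaling.
#' @return An `fv_system`: sparse SPD matrix `A` (dgCMatrix), right-hand
#'   side `b`, unknown-index array, Dirichlet data, and the per-electrode
#'   coupling table used to measure electrode currents.
#' @export
assemble_system <- function(cond, placed, anode_V = 0.5, cathode_V = -0.5) {
  dir_val <- numeric(0)
  dir_idx <- integer(0)
  for (role in names(placed$electrodes)) {
    v <- placed$electrodes[[role]]$connector_voxels
    dir_idx <- c(dir_idx, v)
    dir_val <- c(dir_val, rep(if (role == "anode") anode_V else cathode_V,
                              length(v)))
  }
  elec_id <- rep(names(placed$electrodes),
                 vapply(placed$electrodes, function(e)
                   length(e$connector_voxels), integer(1)))
  fv_assemble(cond, placed$grid$labels > 0L, dir_idx, dir_val, elec_id)
}

## Core assembly. `mask`: conductive voxels (including Dirichlet cells);
## `dir_idx`: linear indices of Dirichlet cells; `dir_val`: their potentials;
## `elec_id`: electrode membership of each Dirichlet cell (for current
## measurement).
fv_assemble <- function(cond, mask, dir_idx, dir_val, elec_id = NULL) {
  dims <- dim(cond$xx)
  h <- cond$voxel_size
  hm <- h * 1e-3                               # mm -> m
  mask <- array(mask, dims)
  if (!length(dir_idx)) {
    stop_spinefield("No Dirichlet (connector) voxels supplied.",
                    "spinefield_assembly_error")
  }
  if (any(!mask[dir_idx])) {
    stop_spinefield("Dirichlet voxels must be conductive.",
                    "spinefield_assembly_error")
  }

  ## Prune conductive islands with no path to an electrode (6-connectivity,
  ## matching the face-coupling stencil).
  comp <- array(cc_label(mask, 6L), dims)
  elec_comps <- unique(comp[dir_idx])
  if (!is.null(elec_id)) {
    by_elec <- split(comp[dir_idx], elec_id)
    shared <- Reduce(intersect, lapply(by_elec, unique))
    if (!length(shared)) {
      stop_spinefield(
        "Electrodes are not connected through the conductive domain.",
        "spinefield_assembly_error")
    }
  }
  island <- mask & !(comp %in% elec_comps)
  if (any(island)) {
    rlang::warn(paste0("Pruned ", sum(island),
                       " conductive voxel(s) with no path to an electrode."))
    mask[island] <- FALSE
  }

  dirich <- array(FALSE, dims)
  dirich[dir_idx] <- TRUE
  phi_d <- array(0, dims)
  phi_d[dir_idx] <- dir_val
  unknown <- mask & !dirich
  n <- sum(unknown)
  idx <- array(0L, dims)
  idx[unknown] <- seq_len(n)                   # column-major, deterministic

  ti <- vector("list", 0); tj <- vector("list", 0); tx <- vector("list", 0)
  bi <- vector("list", 0); bx <- vector("list", 0)
  elec_i <- vector("list", 0); elec_g <- vector("list", 0)
  elec_phi <- vector("list", 0); elec_lab <- vector("list", 0)
  elec_v <- vector("list", 0)
  elec_of <- array("", dims)
  if (!is.null(elec_id)) elec_of[dir_idx] <- elec_id

  push_pair <- function(g, ia, ib, da, db, pa, pb, ea, eb, va, vb) {
    ## ia/ib: unknown numbering (0 if Dirichlet); da/db: is-Dirichlet flags.
    uu <- !da & !db
    if (any(uu)) {
      ti[[length(ti) + 1]] <<- c(ia[uu], ib[uu], ia[uu], ib[uu])
      tj[[length(tj) + 1]] <<- c(ib[uu], ia[uu], ia[uu], ib[uu])
      tx[[length(tx) + 1]] <<- c(-g[uu], -g[uu], g[uu], g[uu])
    }
    ud <- !da & db                              # a unknown, b Dirichlet
    if (any(ud)) {
      ti[[length(ti) + 1]] <<- c(ia[ud]); tj[[length(tj) + 1]] <<- c(ia[ud])
      tx[[length(tx) + 1]] <<- g[ud]
      bi[[length(bi) + 1]] <<- ia[ud]; bx[[length(bx) + 1]] <<- g[ud] * pb[ud]
      elec_i[[length(elec_i) + 1]] <<- ia[ud]
      elec_g[[length(elec_g) + 1]] <<- g[ud]
      elec_phi[[length(elec_phi) + 1]] <<- pb[ud]
      elec_lab[[length(elec_lab) + 1]] <<- eb[ud]
      elec_v[[length(elec_v) + 1]] <<- vb[ud]
    }
    du <- da & !db
    if (any(du)) {
      ti[[length(ti) + 1]] <<- c(ib[du]); tj[[length(tj) + 1]] <<- c(ib[du])
      tx[[length(tx) + 1]] <<- g[du]
      bi[[length(bi) + 1]] <<- ib[du]; bx[[length(bx) + 1]] <<- g[du] * pa[du]
      elec_i[[length(elec_i) + 1]] <<- ib[du]
      elec_g[[length(elec_g) + 1]] <<- g[du]
      elec_phi[[length(elec_phi) + 1]] <<- pa[du]
      elec_lab[[length(elec_lab) + 1]] <<- ea[du]
      elec_v[[length(elec_v) + 1]] <<- va[du]
    }
  }

  comps <- list(`1` = cond$xx, `2` = cond$yy, `3` = cond$zz)
  for (axis in 1:3) {
    nb_mask <- shift_array(mask, axis, -1, fill = FALSE)   # neighbour at +axis
    both <- mask & nb_mask
    if (!any(both)) next
    sig <- comps[[axis]]
    sig_nb <- shift_array(sig, axis, -1, fill = 0)
    w <- which(both)
    g <- hm * 2 / (1 / sig[w] + 1 / sig_nb[w])              # harmonic face mean
    stride <- c(1L, dims[1], dims[1] * dims[2])[axis]
    wn <- w + stride
    push_pair(g, idx[w], idx[wn], dirich[w], dirich[wn],
              phi_d[w], phi_d[wn], elec_of[w], elec_of[wn], w, wn)
  }

  ## Mixed (off-diagonal) tensor couplings to edge-diagonal neighbours.
  if (!is.null(cond$xy)) {
    mixed <- list(list(a = 1L, b = 2L, s = cond$xy),
                  list(a = 1L, b = 3L, s = cond$xz),
                  list(a = 2L, b = 3L, s = cond$yz))
    strides <- c(1L, dims[1], dims[1] * dims[2])
    for (m in mixed) {
      if (!any(m$s != 0)) next
      for (sb in c(1L, -1L)) {
        ## neighbour offset +e_a + sb*e_b
        nb <- shift_array(shift_array(mask, m$a, -1, fill = FALSE),
                          m$b, -sb, fill = FALSE)
        both <- mask & nb
        if (!any(both)) next
        s_nb <- shift_array(shift_array(m$s, m$a, -1, fill = 0),
                            m$b, -sb, fill = 0)
        w <- which(both)
        g <- sb * (m$s[w] + s_nb[w]) / 2 * hm / 2
        keep <- g != 0
        if (!any(keep)) next
        w <- w[keep]; g <- g[keep]
        wn <- w + strides[m$a] + sb * strides[m$b]
        push_pair(g, idx[w], idx[wn], dirich[w], dirich[wn],
                  phi_d[w], phi_d[wn], elec_of[w], elec_of[wn], w, wn)
      }
    }
  }

  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, n), repr = "C")
  b <- numeric(n)
  if (length(bi)) {
    bsum <- rowsum(unlist(bx), unlist(bi))
    b[as.integer(rownames(bsum))] <- bsum[, 1]
  }
  elec_tbl <- if (length(elec_i)) {
    tibble::tibble(unknown = unlist(elec_i), g = unlist(elec_g),
                   phi_d = unlist(elec_phi), dir_voxel = unlist(elec_v),
                   electrode = unlist(elec_lab))
  } else {
    tibble::tibble(unknown = integer(), g = numeric(), phi_d = numeric(),
                   dir_voxel = integer(), electrode = character())
  }
  if (!is.null(elec_id)) {
    missing_e <- setdiff(unique(elec_id), unique(elec_tbl$electrode))
    if (length(missing_e)) {
      stop_spinefield(paste0("Electrode(s) ", paste(missing_e, collapse = ", "),
                             " have no conductive coupling to the domain."),
                      "spinefield_assembly_error")
    }
  }
  structure(list(
    A = A, b = b, idx = idx, unknown = unknown, dirichlet = dirich,
    phi_dirichlet = phi_d, electrode_couplings = elec_tbl,
    voxel_size = h, dims = dims, mask = mask,
    n_pruned = sum(island)
  ), class = "fv_system")
}

#' @export
print.fv_system <- function(x, ...) {
  cat("<fv_system> ", length(x$b), " unknowns, ",
      length(x$A@x), " nonzeros\n", sep = "")
  invisible(x)
}

#' Solve the assembled potential problem
#'
#' Conjugate gradients with an IC(0) incomplete-Cholesky preconditioner;
#' serial with a fixed ordering, hence deterministic for fixed inputs.
#'
#' @param system An `fv_system`.
#' @param tol Relative residual tolerance.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   achieved residual.
#' @return A `potential_field`: array `phi` (volts; `NA` outside the
#'   conductive domain, Dirichlet values filled in) plus solver metadata.
#' @export
solve_potential <- function(system, tol = 1e-8, max_iter = 20000L) {
  A <- system$A
  res <- ic0_pcg_cpp(A@p, A@i, A@x, system$b, tol, as.integer(max_iter))
  if (!res$converged) {
    stop_spinefield(paste0("PCG did not converge in ", max_iter,
                           " iterations (achieved relative residual ",
                           signif(res$relres, 3), ", tolerance ", tol, ")."),
                    "spinefield_convergence_error")
  }
  phi <- array(NA_real_, system$dims)
  phi[system$unknown] <- res$x
  phi[system$dirichlet] <- system$phi_dirichlet[system$dirichlet]
  structure(list(
    phi = phi, system = system,
    relres = res$relres, iterations = res$iterations, tol = tol,
    ic0_shift = res$shift,
    voxel_size = system$voxel_size
  ), class = "potential_field")
}

#' Electrode currents of a solved potential
#'
#' Sums the discrete fluxes `g * (phi_electrode - phi_neighbour)` over every
#' coupling between an electrode's connector voxels and the domain: the net
#' current injected by each electrode (mA, positive out of the electrode).
#' Anode and cathode magnitudes must agree; a mismatch beyond 1% signals a
#' discretization/conservation bug and raises an error.
#'
#' @param sol A `potential_field`.
#' @return A tibble with columns `electrode`, `current_mA`.
#' @export
electrode_current <- function(sol) {
  cur <- electrode_current_raw(sol)
  if (nrow(cur) == 2) {
    mags <- abs(cur$current_mA)
    mismatch <- abs(diff(mags)) / mean(mags)
    if (is.finite(mismatch) && mismatch > 0.01) {
      stop_spinefield(paste0(
        "Electrode current conservation failure: anode/cathode magnitudes ",
        "differ by ", signif(100 * mismatch, 3),
        "% (> 1%); the discretization or solve is inconsistent."),
        "spinefield_conservation_error")
    }
  }
  cur
}

## Unguarded electrode-current measurement: discrete fluxes between each
## electrode's connector voxels and the domain, read from the solution's phi
## array so rescaled solutions re-measure consistently.
electrode_current_raw <- function(sol) {
  ec <- sol$system$electrode_couplings
  phi_u <- sol$phi[sol$system$unknown]
  phid_now <- sol$phi[ec$dir_voxel]
  dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(ec, flux = .data$g * (phid_now - phi_u[.data$unknown])),
      .data$electrode),
    current_mA = sum(.data$flux) * 1e3, .groups = "drop")
}

#' Derive the electric field and current density from a potential
#'
#' E = -grad(phi) by central differences within same-tissue runs and
#' one-sided differences at tissue interfaces (so interface jumps in |E| are
#' not smeared); J = sigma E voxelwise with the full tensor.
#'
#' @param sol A `potential_field`.
#' @param cond The `conductivity_field` the system was assembled from.
#' @param labels Label array of the (electrode-stamped) grid, used to detect
#'   tissue interfaces.
#' @return A `field_solution`: arrays `Ex`, `Ey`, `Ez`, `Enorm` (V/m),
#'   `Jx`, `Jy`, `Jz` (A/m^2), electrode currents, injected current.
#' @export
compute_field <- function(sol, cond, labels) {
  phi <- sol$phi
  h_m <- sol$voxel_size * 1e-3
  dims <- dim(phi)
  E <- list()
  for (axis in 1:3) {
    up <- shift_array(phi, axis, -1)             # neighbour at +axis
    dn <- shift_array(phi, axis, +1)
    lab_up <- shift_array(labels, axis, -1, fill = -1L)
    lab_dn <- shift_array(labels, axis, +1, fill = -1L)
    same_up <- !is.na(up) & lab_up == labels
    same_dn <- !is.na(dn) & lab_dn == labels
    any_up <- !is.na(up)
    any_dn <- !is.na(dn)
    g <- array(0, dims)
    ## preferred: central within same tissue, one-sided at interfaces;
    ## fall back to across-label differences when a tissue is one voxel thin.
    use_c  <- same_up & same_dn
    use_u  <- same_up & !use_c
    use_d  <- same_dn & !use_c & !use_u
    rest   <- !(use_c | use_u | use_d)
    fb_c   <- rest & any_up & any_dn
    fb_u   <- rest & any_up & !any_dn
    fb_d   <- rest & any_dn & !any_up
    g[use_c | fb_c] <- (up[use_c | fb_c] - dn[use_c | fb_c]) / (2 * h_m)
    g[use_u | fb_u] <- (up[use_u | fb_u] - phi[use_u | fb_u]) / h_m
    g[use_d | fb_d] <- (phi[use_d | fb_d] - dn[use_d | fb_d]) / h_m
    g[is.na(phi)] <- NA_real_
    E[[axis]] <- -g
  }
  Ex <- E[[1]]; Ey <- E[[2]]; Ez <- E[[3]]
  if (is.null(cond$xy)) {
    Jx <- cond$xx * Ex; Jy <- cond$yy * Ey; Jz <- cond$zz * Ez
  } else {
    Jx <- cond$xx * Ex + cond$xy * Ey + cond$xz * Ez
    Jy <- cond$xy * Ex + cond$yy * Ey + cond$yz * Ez
    Jz <- cond$xz * Ex + cond$yz * Ey + cond$zz * Ez
  }
  cur <- electrode_current(sol)
  structure(list(
    Ex = Ex, Ey = Ey, Ez = Ez,
    Enorm = sqrt(Ex^2 + Ey^2 + Ez^2),
    Jx = Jx, Jy = Jy, Jz = Jz,
    phi = phi,
    electrode_currents = cur,
    injected_mA = cur$current_mA[cur$electrode == "anode"],
    voxel_size = sol$voxel_size,
    solver = list(relres = sol$relres, iterations = sol$iterations,
                  tol = sol$tol),
    system = sol$system
  ), class = "field_solution")
}

#' Rescale a field solution to a target injected current
#'
#' The problem is linear, so all fields scale with the injected current;
#' this multiplies phi, E and J by `I_target / I_computed` so the electrode
#' current equals the target exactly. A target of 0 mA (sham) zeroes the
#' fields.
#'
#' @param field A `field_solution`.
#' @param I_target_mA Target injected current (mA).
#' @return The rescaled `field_solution` (with `injected_mA = I_target_mA`).
#' @export
scale_to_current <- function(field, I_target_mA = 4) {
  I0 <- field$injected_mA
  if (!is.finite(I0) || I0 == 0) {
    stop_spinefield("Computed electrode current is zero; degenerate montage.",
                    "spinefield_assembly_error")
  }
  s <- I_target_mA / I0
  for (nm in c("Ex", "Ey", "Ez", "Enorm", "Jx", "Jy", "Jz", "phi")) {
    field[[nm]] <- field[[nm]] * s
  }
  field$electrode_currents$current_mA <- field$electrode_currents$current_mA * s
  field$injected_mA <- I_target_mA
  field$scale_factor <- s
  field
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> I =", signif(x$injected_mA, 4), "mA;",
      x$solver$iterations, "PCG iterations, relative residual",
      signif(x$solver$relres, 3), "\n")
  invisible(x)
}

#' Interior conservation residual of a solved system
#'
#' Maximum net current flux out of any interior control volume, relative to
#' the injected current: `max |A phi - b| / I`. For the conservative
#' finite-volume scheme this is bounded by the solver residual; the check
#' passes when it does not exceed 1e-6.
#'
#' @param field A `field_solution` (or `potential_field`).
#' @return A one-row tibble: `max_residual_A`, `injected_mA`,
#'   `relative_residual`, `pass`.
#' @export
conservation_check <- function(field) {
  sys <- field$system
  phi_u <- field$phi[sys$unknown]
  if (!is.null(field$scale_factor)) {
    ## residual of the scaled solution against the scaled rhs
    b <- sys$b * field$scale_factor
  } else {
    b <- sys$b
  }
  r <- as.numeric(sys$A %*% phi_u - b)
  I_A <- abs(if (!is.null(field$injected_mA)) field$injected_mA else {
    cur <- electrode_current_raw(field)
    mean(abs(cur$current_mA))
  }) * 1e-3
  mr <- max(abs(r))
  rel <- if (I_A > 0) mr / I_A else 0
  tibble::tibble(max_residual_A = mr, injected_mA = I_A * 1e3,
                 relative_residual = rel, pass = rel <= 1e-6)
}
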