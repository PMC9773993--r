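## Analytic verification harness: bar and slab geometries with closed-form
## potentials make the solver testable without any external data. The 1-D
## current flow between full-face end electrodes gives
##   phi(z) linear (piecewise linear across a conductivity interface),
##   E = dV / L, and I = sigma A dV / L (Ohm's law),
## with the series-resistor form for layered slabs and the longitudinal
## eigenvalue sigma_iso * r^(2/3) for a volume-constrained anisotropic bar.

#' Define an analytic oracle case
#'
#' @param name `"homogeneous_bar"`, `"layered_slab"` or `"anisotropic_bar"`.
#' @param sigma Conductivity (S/m): scalar for the bar; length-2
#'   `c(lower, upper)` for the slab.
#' @param width_mm Bar cross-section edge (square cross-section).
#' @param length_mm Conductive length between the electrode faces.
#' @param interface_mm Position of the conductivity interface measured from
#'   the caudal electrode face (slab only). Choose a multiple of the voxel
#'   size for an exactly representable interface, or a non-multiple to
#'   exercise the staircase discretization error.
#' @param delta_V Potential difference across the bar (V).
#' @param ratio Anisotropy ratio r for the anisotropic bar (fibres along z).
#' @return A list of class `oracle_case` with the geometry and closed forms
#'   `phi_exact(z)`, `E_exact` (V/m, z-component) and `I_exact_mA`.
#' @export
#' @examples
#' oc <- oracle_case("homogeneous_bar", sigma = 0.355, length_mm = 50)
#' oc$E_exact   # 20 V/m for 1 V over 50 mm
oracle_case <- function(name = c("homogeneous_bar", "layered_slab",
                                 "anisotropic_bar"),
                        sigma = 1, width_mm = 10, length_mm = 50,
                        interface_mm = length_mm / 2, delta_V = 1,
                        ratio = 10) {
  name <- match.arg(name)
  A_m2 <- (width_mm * 1e-3)^2
  L_m <- length_mm * 1e-3
  case <- list(name = name, sigma = sigma, width_mm = width_mm,
               length_mm = length_mm, interface_mm = interface_mm,
               delta_V = delta_V, ratio = ratio)
  if (name == "homogeneous_bar") {
    stopifnot(length(sigma) == 1)
    case$phi_exact <- function(z) delta_V / 2 - delta_V * z / length_mm
    case$E_exact <- delta_V / L_m
    case$I_exact_mA <- sigma * A_m2 * delta_V / L_m * 1e3
  } else if (name == "layered_slab") {
    stopifnot(length(sigma) == 2)
    L1 <- interface_mm * 1e-3; L2 <- L_m - L1
    R <- L1 / (sigma[1] * A_m2) + L2 / (sigma[2] * A_m2)
    I <- delta_V / R
    E1 <- I / (sigma[1] * A_m2); E2 <- I / (sigma[2] * A_m2)  # V/m
    case$phi_exact <- function(z) {
      zl <- pmin(z, interface_mm); zu <- pmax(z - interface_mm, 0)
      delta_V / 2 - (E1 * zl + E2 * zu) * 1e-3
    }
    case$E_exact <- c(lower = E1, upper = E2)
    case$I_exact_mA <- I * 1e3
  } else {
    stopifnot(length(sigma) == 1)
    s_long <- sigma * ratio^(2 / 3)
    case$sigma_long <- s_long
    case$phi_exact <- function(z) delta_V / 2 - delta_V * z / length_mm
    case$E_exact <- delta_V / L_m
    case$I_exact_mA <- s_long * A_m2 * delta_V / L_m * 1e3
  }
  class(case) <- "oracle_case"
  case
}

## Build the voxel model of an oracle case: a conductive box of
## width x width cross-section with one-voxel Dirichlet end layers whose
## cell centres sit exactly at z = 0 and z = length, so the discrete
## resistor chain between the electrode centres spans the nominal length
## and the closed-form potential is exact at every cell centre (for a
## face-centred conductivity interface).
oracle_grid <- function(case, resolution) {
  h <- resolution
  nxy <- as.integer(round(case$width_mm / h))
  nzc <- as.integer(round(case$length_mm / h))
  stopifnot(nxy >= 1, nzc >= 2)
  dims <- c(nxy, nxy, nzc + 1L)
  zc <- (seq_len(dims[3]) - 1) * h           # electrode centres at 0 and L
  sig <- array(0, dims)
  for (k in seq_len(dims[3])) {
    s <- if (case$name == "layered_slab") {
      if (zc[k] < case$interface_mm) case$sigma[1] else case$sigma[2]
    } else if (case$name == "anisotropic_bar") case$sigma else case$sigma
    sig[, , k] <- s
  }
  cond <- list(xx = sig, yy = sig, zz = sig, xy = NULL, xz = NULL, yz = NULL,
               voxel_size = h, origin = c(0, 0, -h / 2))
  if (case$name == "anisotropic_bar") {
    r <- case$ratio
    cond$xx <- sig * r^(-1 / 3); cond$yy <- sig * r^(-1 / 3)
    cond$zz <- sig * r^(2 / 3)
  }
  class(cond) <- "conductivity_field"
  mask <- array(TRUE, dims)
  lin <- function(k) {
    as.vector(outer(seq_len(nxy), (seq_len(nxy) - 1L) * nxy, "+")) +
      (k - 1L) * nxy * nxy
  }
  dir_idx <- c(lin(1L), lin(dims[3]))
  dir_val <- c(rep(case$delta_V / 2, nxy * nxy),
               rep(-case$delta_V / 2, nxy * nxy))
  elec_id <- c(rep("anode", nxy * nxy), rep("cathode", nxy * nxy))
  list(cond = cond, mask = mask, dir_idx = dir_idx, dir_val = dir_val,
       elec_id = elec_id, dims = dims, zc = zc, h = h)
}

## Solve an oracle case at a resolution; returns the field solution plus
## the grid description.
solve_oracle <- function(case, resolution, tol = 1e-10) {
  og <- oracle_grid(case, resolution)
  sys <- fv_assemble(og$cond, og$mask, og$dir_idx, og$dir_val, og$elec_id)
  pot <- solve_potential(sys, tol = tol, max_iter = 50000L)
  labels <- array(1L, og$dims)        # homogeneous labelling: gradients are
  if (case$name == "layered_slab") {  # one-sided at the sigma interface
    for (k in seq_len(og$dims[3])) {
      labels[, , k] <- if (og$zc[k] < case$interface_mm) 1L else 2L
    }
  }
  field <- compute_field(pot, og$cond, labels)
  list(field = field, og = og, pot = pot)
}

#' Run an analytic oracle case and report numeric-vs-exact errors
#'
#' Solves the case's voxel model and compares against the closed forms:
#' the maximum potential error, the maximum relative error of the field
#' z-component away from the electrode layers, and the relative error of
#' the measured electrode current.
#'
#' @param case An [oracle_case()].
#' @param resolution Voxel edge (mm).
#' @param tol Solver tolerance.
#' @return A one-row tibble: `case`, `resolution_mm`, `max_phi_error_V`,
#'   `max_E_rel_error`, `I_rel_error`, `I_mA`, `iterations`.
#' @export
run_oracle <- function(case, resolution, tol = 1e-10) {
  so <- solve_oracle(case, resolution, tol)
  og <- so$og; field <- so$field
  dims <- og$dims
  interior <- 2:(dims[3] - 1L)
  phi_err <- 0
  E_rel <- 0
  for (k in interior) {
    exact_phi <- case$phi_exact(og$zc[k])
    phi_err <- max(phi_err, max(abs(so$pot$phi[, , k] - exact_phi)))
    E_exact_k <- if (case$name == "layered_slab") {
      if (og$zc[k] < case$interface_mm) case$E_exact[["lower"]]
      else case$E_exact[["upper"]]
    } else case$E_exact
    E_rel <- max(E_rel, max(abs(field$Ez[, , k] - E_exact_k)) / abs(E_exact_k))
  }
  I <- field$electrode_currents$current_mA[
    field$electrode_currents$electrode == "anode"]
  I_rel <- abs(I - case$I_exact_mA) / abs(case$I_exact_mA)
  tibble::tibble(
    case = case$name, resolution_mm = resolution,
    max_phi_error_V = phi_err, max_E_rel_error = E_rel,
    I_rel_error = I_rel,
    I_mA = I, iterations = field$solver$iterations)
}

#' Grid-refinement convergence study on an oracle case
#'
#' Richardson estimate of the observed convergence order from the maximum
#' potential errors at three or more resolutions. When the errors are not
#' monotone, or all sit at round-off, the order cannot be established and
#' is reported as `NA` with a warning.
#'
#' @param case An [oracle_case()].
#' @param resolutions Numeric vector of voxel edges (mm), at least 3,
#'   coarse to fine.
#' @return A list of class `convergence_study`: `errors` (tibble), `order`
#'   (estimated p, `NA` when not established), `established`.
#' @export
convergence_study <- function(case, resolutions = c(4, 2, 1)) {
  if (length(resolutions) < 3) {
    stop_spinefield("A convergence study needs at least 3 resolutions.",
                    "spinefield_param_error")
  }
  resolutions <- sort(resolutions, decreasing = TRUE)
  errs <- dplyr::bind_rows(lapply(resolutions, function(h) {
    run_oracle(case, h)
  }))
  e <- errs$max_phi_error_V
  established <- TRUE
  if (all(e < 1e-9)) {
    rlang::warn("Errors at round-off level; convergence order not established.")
    established <- FALSE
  } else if (any(diff(e) >= 0)) {
    rlang::warn("Errors are not monotone; convergence order not established.")
    established <- FALSE
  }
  p <- if (established) {
    mean(log(e[-length(e)] / e[-1]) /
           log(resolutions[-length(resolutions)] / resolutions[-1]))
  } else NA_real_
  structure(list(errors = errs, order = p, established = established),
            class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  print(x$errors)
  cat("observed order:",
      if (x$established) signif(x$order, 3) else "not established", "\n")
  invisible(x)
}
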