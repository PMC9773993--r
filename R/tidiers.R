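#' Tidy a simulation run
#'
#' Returns the per-segment maxima table (the Table-2-style summary) of a
#' [run_simulation()] result, one row per spinal segment and tissue.
#'
#' @param x A `tsdcs_run`.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy tsdcs_run
#' @export
tidy.tsdcs_run <- function(x, ...) {
  dplyr::mutate(x$summary, montage = x$montage_name, .before = 1)
}

#' One-row summary of a simulation run
#'
#' @param x A `tsdcs_run`.
#' @param ... Ignored.
#' @return A one-row tibble: montage, injected current, problem size,
#'   solver iterations and residual, peak slice-mean field magnitude in GM
#'   and WM, and the session charge density.
#' @method glance tsdcs_run
#' @export
glance.tsdcs_run <- function(x, ...) {
  peak <- function(t) {
    s <- dplyr::filter(x$summary, .data$tissue == t)
    if (nrow(s)) max(s$e_norm_max) else NA_real_
  }
  tibble::tibble(
    montage = x$montage_name,
    current_mA = x$field$injected_mA,
    n_unknowns = length(x$field$system$b),
    iterations = x$field$solver$iterations,
    relres = x$field$solver$relres,
    peak_e_norm_gm = peak("gm"),
    peak_e_norm_wm = peak("wm"),
    charge_density_mC_cm2 = x$dosimetry$charge_density_mC_cm2)
}

#' Tidy a convergence study
#'
#' @param x A `convergence_study`.
#' @param ... Ignored.
#' @return The per-resolution error tibble.
#' @method tidy convergence_study
#' @export
tidy.convergence_study <- function(x, ...) x$errors

#' One-row summary of a convergence study
#'
#' @param x A `convergence_study`.
#' @param ... Ignored.
#' @return A one-row tibble: `order`, `established`.
#' @method glance convergence_study
#' @export
glance.convergence_study <- function(x, ...) {
  tibble::tibble(order = x$order, established = x$established)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
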