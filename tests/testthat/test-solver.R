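## Direct checks of the finite-volume discretization and PCG solve on small
## grids with closed-form solutions.

test_that("homogeneous bar: potential linear in z, Ohm's-law current", {
  ## sigma = 1 S/m, A = 100 mm^2, L = 50 mm, dV = 1 V -> I = sigma A dV / L = 2 mA
  case <- oracle_case("homogeneous_bar", sigma = 1, width_mm = 10,
                      length_mm = 50, delta_V = 1)
  expect_equal(case$I_exact_mA, 2)
  so <- spinefield:::solve_oracle(case, 2)
  zc <- so$og$zc
  for (k in c(2, 10, 20)) {
    expect_lt(max(abs(so$pot$phi[, , k] - case$phi_exact(zc[k]))), 1e-6)
  }
  cur <- so$field$electrode_currents
  expect_equal(cur$current_mA[cur$electrode == "anode"], 2, tolerance = 1e-6)
  ## anode and cathode currents: equal magnitude, opposite sign
  expect_equal(sum(cur$current_mA), 0, tolerance = 1e-9)
  ## E uniform at dV/L = 20 V/m away from the electrodes
  expect_lt(max(abs(so$field$Ez[, , 5:20] - 20)) / 20, 1e-6)

  ## doubling dV doubles I
  case2 <- oracle_case("homogeneous_bar", sigma = 1, width_mm = 10,
                       length_mm = 50, delta_V = 2)
  so2 <- spinefield:::solve_oracle(case2, 2)
  cur2 <- so2$field$electrode_currents
  expect_equal(cur2$current_mA[cur2$electrode == "anode"], 4, tolerance = 1e-6)
})

test_that("layered slab: piecewise slopes with continuous normal current", {
  ## face-centred interface (odd multiple of h/2) makes the discrete
  ## solution exact: E ratio between layers = sigma2 : sigma1
  case <- oracle_case("layered_slab", sigma = c(0.435, 0.006),
                      width_mm = 8, length_mm = 40, interface_mm = 21)
  so <- spinefield:::solve_oracle(case, 2)
  E1 <- mean(so$field$Ez[, , 4:8])     # inside lower layer
  E2 <- mean(so$field$Ez[, , 14:18])   # inside upper layer
  expect_equal(E1 / E2, 0.006 / 0.435, tolerance = 1e-6)
  ## |J_z| continuous across the interface within 1%
  Jlow <- mean(so$field$Jz[, , 10])
  Jup <- mean(so$field$Jz[, , 12])
  expect_lt(abs(Jlow / Jup - 1), 0.01)
})

test_that("the assembled matrix is symmetric, also with full tensors", {
  case <- oracle_case("homogeneous_bar", sigma = 0.355, width_mm = 8,
                      length_mm = 24)
  og <- spinefield:::oracle_grid(case, 2)
  sys <- spinefield:::fv_assemble(og$cond, og$mask, og$dir_idx, og$dir_val,
                                  og$elec_id)
  expect_equal(Matrix::norm(sys$A - Matrix::t(sys$A), "M"), 0)

  ## full tensor with off-diagonals
  S <- build_anisotropic_tensor(0.2, c(1, 1, 1) / sqrt(3), 5)
  cond <- og$cond
  dims <- dim(cond$xx)
  cond$xx <- array(S[1, 1], dims); cond$yy <- array(S[2, 2], dims)
  cond$zz <- array(S[3, 3], dims)
  cond$xy <- array(S[1, 2], dims); cond$xz <- array(S[1, 3], dims)
  cond$yz <- array(S[2, 3], dims)
  sys2 <- spinefield:::fv_assemble(cond, og$mask, og$dir_idx, og$dir_val,
                                   og$elec_id)
  expect_equal(Matrix::norm(sys2$A - Matrix::t(sys2$A), "M"), 0)
})

test_that("full-tensor stencil reproduces linear potentials exactly", {
  ## Dirichlet boundary data from a linear potential: with any uniform SPD
  ## tensor, div(sigma grad phi) = 0 exactly, so the interior solve must
  ## return the same linear function (consistency of the mixed terms).
  dims <- c(8, 8, 8); h <- 2
  S <- build_anisotropic_tensor(0.3, c(2, -1, 2) / 3, 8)
  mk <- function(v) array(v, dims)
  cond <- structure(list(xx = mk(S[1, 1]), yy = mk(S[2, 2]), zz = mk(S[3, 3]),
                         xy = mk(S[1, 2]), xz = mk(S[1, 3]), yz = mk(S[2, 3]),
                         voxel_size = h, origin = c(0, 0, 0)),
                    class = "conductivity_field")
  cc <- spinefield:::coord_arrays(dims, c(0, 0, 0), h)
  phi_lin <- 0.03 * cc$x - 0.02 * cc$y + 0.011 * cc$z
  boundary <- array(FALSE, dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE
  sys <- spinefield:::fv_assemble(cond, array(TRUE, dims),
                                  which(boundary), phi_lin[boundary])
  pot <- solve_potential(sys, tol = 1e-12)
  expect_lt(max(abs(pot$phi - phi_lin)), 1e-9)
})

test_that("swapping Dirichlet signs negates the potential bitwise", {
  case <- oracle_case("homogeneous_bar", sigma = 0.5, width_mm = 8,
                      length_mm = 24)
  og <- spinefield:::oracle_grid(case, 2)
  s1 <- spinefield:::fv_assemble(og$cond, og$mask, og$dir_idx, og$dir_val,
                                 og$elec_id)
  s2 <- spinefield:::fv_assemble(og$cond, og$mask, og$dir_idx, -og$dir_val,
                                 og$elec_id)
  p1 <- solve_potential(s1, tol = 1e-10)
  p2 <- solve_potential(s2, tol = 1e-10)
  expect_identical(p2$phi, -p1$phi)
})

test_that("rescaling to a target current is exact and linear", {
  case <- oracle_case("homogeneous_bar", sigma = 1, width_mm = 10,
                      length_mm = 50)
  so <- spinefield:::solve_oracle(case, 2)
  f4 <- scale_to_current(so$field, 4)
  expect_equal(f4$injected_mA, 4)
  cur <- electrode_current(f4)        # re-measure the rescaled solution
  expect_equal(abs(cur$current_mA), c(4, 4), tolerance = 1e-3, ignore_attr = TRUE)
  ## I = 8 mA equals 2x the 4 mA solution bitwise
  f8 <- scale_to_current(so$field, 8)
  expect_identical(f8$Ez, 2 * f4$Ez)
  ## sham: zero target zeroes the fields
  f0 <- scale_to_current(so$field, 0)
  expect_true(all(f0$Enorm == 0, na.rm = TRUE))
})

test_that("discrete maximum principle holds for the 7-point stencil", {
  case <- oracle_case("layered_slab", sigma = c(1.79, 0.006), width_mm = 8,
                      length_mm = 40, interface_mm = 21)
  so <- spinefield:::solve_oracle(case, 2)
  expect_true(all(so$pot$phi <= 0.5 + 1e-9))
  expect_true(all(so$pot$phi >= -0.5 - 1e-9))
})

test_that("conductive islands are pruned with a warning", {
  case <- oracle_case("homogeneous_bar", sigma = 1, width_mm = 12,
                      length_mm = 24)
  og <- spinefield:::oracle_grid(case, 2)
  ## isolate the corner column (1,1,3:11) by insulating all its neighbours
  mask <- og$mask
  mask[1, 1, c(2, 12)] <- FALSE
  mask[2, 1, 3:11] <- FALSE
  mask[1, 2, 3:11] <- FALSE
  expect_warning(
    sys <- spinefield:::fv_assemble(og$cond, mask, og$dir_idx, og$dir_val),
    "no path to an electrode")
  expect_true(sys$n_pruned >= 9)
})

test_that("electrodes without a conductive path refuse to assemble", {
  case <- oracle_case("homogeneous_bar", sigma = 1, width_mm = 8,
                      length_mm = 24)
  og <- spinefield:::oracle_grid(case, 2)
  mask <- og$mask
  mask[, , 6] <- FALSE                 # cut the bar in two
  expect_error(
    suppressWarnings(
      spinefield:::fv_assemble(og$cond, mask, og$dir_idx, og$dir_val,
                               og$elec_id)),
    class = "spinefield_assembly_error")
})

test_that("non-convergence raises an error reporting the residual", {
  case <- oracle_case("layered_slab", sigma = c(1.79, 0.006), width_mm = 8,
                      length_mm = 40, interface_mm = 21)
  og <- spinefield:::oracle_grid(case, 2)
  sys <- spinefield:::fv_assemble(og$cond, og$mask, og$dir_idx, og$dir_val)
  expect_error(solve_potential(sys, tol = 1e-14, max_iter = 2L),
               "residual", class = "spinefield_convergence_error")
})
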