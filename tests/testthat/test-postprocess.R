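test_that("component decomposition projects onto the cord triad", {
  ## uniform caudally-directed field: e_long = +|E| (rostral->caudal positive)
  fx <- fake_field(E = c(0, 0, -0.2))
  comp <- decompose_components(fx$field, fx$frame, fx$labels, fx$grid_meta)
  expect_true(all(abs(comp$e_long - 0.2) < 1e-12))
  expect_true(all(abs(comp$e_vd) < 1e-12))
  expect_true(all(abs(comp$e_rl) < 1e-12))

  ## dorsal->ventral field (-y): e_vd positive; left-pointing (+x): e_rl positive
  c2 <- decompose_components(fake_field(E = c(0, -0.1, 0))$field, fx$frame,
                             fx$labels, fx$grid_meta)
  expect_true(all(abs(c2$e_vd - 0.1) < 1e-12))
  c3 <- decompose_components(fake_field(E = c(0.3, 0, 0))$field, fx$frame,
                             fx$labels, fx$grid_meta)
  expect_true(all(abs(c3$e_rl - 0.3) < 1e-12))

  ## Parseval on an oblique field
  c4 <- decompose_components(fake_field(E = c(0.1, -0.05, 0.2))$field,
                             fx$frame, fx$labels, fx$grid_meta)
  expect_lt(max(abs(c4$e_long^2 + c4$e_vd^2 + c4$e_rl^2 - c4$e_norm^2) /
                  c4$e_norm^2), 1e-9)
})

test_that("Parseval holds voxelwise on a real solved field", {
  run <- fix_run("T8-L2")
  comp <- run$components
  expect_lt(max(abs(comp$e_long^2 + comp$e_vd^2 + comp$e_rl^2 - comp$e_norm^2) /
                  comp$e_norm^2), 1e-9)
})

test_that("slice means average magnitude unsigned and components signed", {
  fx <- fake_field(E = c(0, 0, -0.2))
  comp <- decompose_components(fx$field, fx$frame, fx$labels, fx$grid_meta)
  ## flip the sign of e_long for exactly half the WM voxels of one slice
  ## (profiles are per tissue, and the WM slice has an even voxel count)
  z1 <- sort(unique(comp$z))[1]
  in_slice <- which(comp$z == z1 & comp$tissue == "wm")
  expect_equal(length(in_slice) %% 2, 0)
  flip <- in_slice[seq_len(length(in_slice) / 2)]
  comp$e_long[flip] <- -comp$e_long[flip]
  prof <- slice_profile(comp, analysis_config(slice_thickness = 1))
  sl <- prof[abs(prof$z_mid - z1) < 0.5 & prof$tissue == "wm" &
               prof$n_voxels > 0, ]
  expect_true(all(abs(sl$e_long) < 1e-12))      # signed mean cancels
  expect_true(all(abs(sl$e_norm - 0.2) < 1e-12)) # magnitude mean does not
  other <- prof[abs(prof$z_mid - z1) >= 0.5 & prof$n_voxels > 0, ]
  expect_true(all(abs(other$e_long - 0.2) < 1e-12))
})

test_that("voxel-weighted slice means reproduce the global tissue mean", {
  run <- fix_run("T8-L2")
  prof <- dplyr::filter(run$profile, .data$n_voxels > 0)
  by_slice <- prof |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(m = sum(.data$e_norm * .data$n_voxels) / sum(.data$n_voxels))
  direct <- run$components |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(m = mean(.data$e_norm))
  expect_equal(by_slice$m, direct$m, tolerance = 1e-9)
})

test_that("slice thickness below the voxel size is a config error", {
  run <- fix_run("T8-L2")
  expect_error(slice_profile(run$components,
                             analysis_config(slice_thickness = 1)),
               class = "spinefield_param_error")
})

test_that("segment summary finds the arg-max segment of a constructed peak", {
  lm <- fix_anatomy()$landmarks
  l1 <- lm$segment_z_ranges[lm$segment_z_ranges$segment == "L1", ]
  fx <- fake_field()
  ## place cord voxels across the mapped extent with a peak inside L1
  z <- seq(lm$cord_z[1] + 0.5, lm$cord_z[2] - 0.5, by = 1)
  peak_z <- mean(c(l1$z_min, l1$z_max))
  comp <- tibble::tibble(
    voxel = seq_along(z), x = 0, y = 0, z = z, tissue = "gm",
    e_long = 0.1 + 0.2 * exp(-((z - peak_z) / 4)^2),
    e_vd = 0, e_rl = 0)
  comp$e_norm <- abs(comp$e_long)
  class(comp) <- c("component_field", class(comp))
  attr(comp, "voxel_size") <- 1
  prof <- slice_profile(comp, analysis_config(slice_thickness = 1))
  summ <- segment_summary(prof, lm)
  expect_equal(summ$segment[which.max(summ$e_norm_max)], "L1")
  ## per row: magnitude max dominates every component max
  expect_true(all(summ$e_norm_max >= summ$e_long_max - 1e-12))
  expect_true(all(summ$e_norm_max >= summ$e_vd_max - 1e-12))
  expect_true(all(summ$e_norm_max >= summ$e_rl_max - 1e-12))
})

test_that("uniform profiles give every segment the same maximum", {
  lm <- fix_anatomy()$landmarks
  z <- seq(lm$cord_z[1] + 0.5, lm$cord_z[2] - 0.5, by = 1)
  comp <- tibble::tibble(voxel = seq_along(z), x = 0, y = 0, z = z,
                         tissue = "wm", e_long = 0.2, e_vd = 0, e_rl = 0,
                         e_norm = 0.2)
  class(comp) <- c("component_field", class(comp))
  attr(comp, "voxel_size") <- 1
  summ <- segment_summary(slice_profile(comp, analysis_config()), lm)
  expect_true(all(abs(summ$e_norm_max - 0.2) < 1e-12))
})

test_that("threshold regions use an inclusive >= comparison", {
  fx <- fake_field(E = c(0, 0, -0.1))
  lm <- NULL
  mk_comp <- function(val) {
    z <- seq(fix_anatomy()$landmarks$cord_z[1] + 0.5,
             fix_anatomy()$landmarks$cord_z[2] - 0.5, by = 2)
    comp <- tibble::tibble(voxel = seq_along(z), x = 0, y = 0, z = z,
                           tissue = "gm", e_long = val, e_vd = 0, e_rl = 0,
                           e_norm = val)
    class(comp) <- c("component_field", class(comp))
    attr(comp, "voxel_size") <- 2
    comp
  }
  lm <- fix_anatomy()$landmarks
  r_low <- threshold_regions(mk_comp(0.1), lm)
  expect_equal(nrow(r_low$mask), 0)
  expect_true(all(r_low$stats$coverage == 0))
  r_high <- threshold_regions(mk_comp(0.2), lm)
  expect_true(all(r_high$stats$coverage == 1))
  r_eq <- threshold_regions(mk_comp(0.15), lm)
  expect_true(all(r_eq$stats$coverage == 1))   # exactly 0.15 is included
})

test_that("DRG probes report field direction along the root axes", {
  an <- fix_anatomy()
  ## uniform left-pointing field: left root (axis +x) sees cord->periphery,
  ## right root (axis -x) periphery->cord
  dims <- dim(an$grid$labels)
  mk <- function(v) array(v, dims)
  f <- structure(list(Ex = mk(0.5), Ey = mk(0), Ez = mk(0),
                      Enorm = mk(0.5)), class = "field_solution")
  rep <- drg_probe(f, an$landmarks, an$grid,
                   analysis_config(drg_probe_radius = 4))
  rep <- rep[!rep$missing, ]
  expect_true(all(rep$direction[rep$side == "left"] == "cord_to_periphery"))
  expect_true(all(rep$direction[rep$side == "right"] == "periphery_to_cord"))
  expect_true(all(abs(abs(rep$root_projection) - 0.5) < 1e-12))

  ## field orthogonal to the root axes: zero projection
  f2 <- structure(list(Ex = mk(0), Ey = mk(0), Ez = mk(0.3),
                       Enorm = mk(0.3)), class = "field_solution")
  rep2 <- drg_probe(f2, an$landmarks, an$grid,
                    analysis_config(drg_probe_radius = 4))
  expect_true(all(abs(rep2$root_projection[!rep2$missing]) < 1e-12))
})

test_that("montage comparison ranks by target field with stated tie-breaks", {
  r1 <- fix_run("T8-L2")
  ## two identical runs tie and break lexicographically by name
  r1b <- r1
  r1b$montage_name <- "zz-copy"
  cmp <- compare_montages(list(r1b, r1))
  expect_equal(cmp$montage, c("T8-L2", "zz-copy"))
  expect_equal(attr(cmp, "winner"), "T8-L2")

  expect_error(compare_montages(list(r1)), class = "spinefield_param_error")

  r2 <- r1
  r2$anatomy_hash <- "different"
  expect_error(compare_montages(list(r1, r2)),
               class = "spinefield_comparison_error")
})

test_that("cathode-side paravertebral montage wins the left-lumbar-DRG target", {
  rs <- list(fix_run("T8-L2"), fix_run("pvT8R-pvL2L"))
  cmp <- compare_montages(rs, target = list(type = "drg",
                                            levels = paste0("L", 1:5),
                                            sides = "left"))
  expect_equal(attr(cmp, "winner"), "pvT8R-pvL2L")
})
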