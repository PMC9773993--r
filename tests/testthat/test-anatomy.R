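test_that("parameter invariants are enforced with named errors", {
  expect_error(anatomy_params("compact", cord_semi_axes = c(20, 20)),
               "canal_radius - dura_thickness", fixed = TRUE)
  expect_error(anatomy_params("compact", gm_semi_axes = c(10, 10)),
               "gm_semi_axes < cord_semi_axes", fixed = TRUE)
  expect_error(anatomy_params("compact", grid_resolution = 8),
               class = "spinefield_resolution_error")
  expect_error(anatomy_params("compact", skin_thickness = -1),
               class = "spinefield_param_error")
  expect_error(anatomy_params("compact", levels = c("T8", "T6", "sacrum")),
               class = "spinefield_param_error")
})

test_that("the built anatomy contains all 13 tissues and is deterministic", {
  an <- fix_anatomy()
  counts <- label_counts(an$grid)
  anatomical <- counts[!counts$tissue %in%
                         c("background", "gel", "rubber", "connector"), ]
  expect_equal(nrow(anatomical), 13L)
  expect_true(all(anatomical$n_voxels > 0))
  an2 <- build_anatomy(anatomy_params("compact"))
  expect_identical(an$grid$labels, an2$grid$labels)
  ## DRG landmarks exist bilaterally for the T12..L5 levels present
  drg <- an$landmarks$drg_centers
  for (lv in intersect(c("T12", paste0("L", 1:5)), an$params$levels)) {
    expect_setequal(drg$side[drg$level == lv], c("left", "right"))
  }
})

test_that("the default (jitter-free) anatomy is mirror-symmetric about x = 0", {
  lab <- fix_anatomy()$grid$labels
  expect_identical(lab, spinefield:::mirror_x(lab))
})

test_that("CSF forms a single 26-connected component", {
  an <- fix_anatomy()
  csf <- an$grid$labels == tissue_labels()[["csf"]]
  comp <- spinefield:::cc_label(csf, 26L)
  expect_equal(max(comp), 1L)
})

test_that("cord frame triads are orthonormal with continuous tangents", {
  fr <- fix_anatomy()$frame
  n <- length(fr$z)
  for (i in c(1L, n %/% 2L, n)) {
    M <- rbind(fr$t_hat[i, ], fr$v_hat[i, ], fr$r_hat[i, ])
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-12)
  }
  dots <- rowSums(fr$t_hat[-1, , drop = FALSE] * fr$t_hat[-n, , drop = FALSE])
  expect_true(all(dots > cos(10 * pi / 180)))
})

test_that("stamped primitive volumes match analytic volumes within 10% at 1 mm", {
  dims <- c(60, 60, 60)
  cc <- spinefield:::coord_arrays(dims, c(-30, -30, -30), 1)
  vol_ell <- sum(spinefield:::mask_ellipsoid(cc, c(0, 0, 0), c(12, 9, 15)))
  expect_lt(abs(vol_ell / (4 / 3 * pi * 12 * 9 * 15) - 1), 0.10)
  vol_cyl <- sum(spinefield:::mask_ellipse_z(cc, 0, 0, 10, 7, -20, 20))
  expect_lt(abs(vol_cyl / (pi * 10 * 7 * 40) - 1), 0.10)
  vol_cx <- sum(spinefield:::mask_cylinder_x(cc, 0, 0, 8, -15, 15))
  expect_lt(abs(vol_cx / (pi * 8^2 * 30) - 1), 0.10)
})

test_that("segment lookup is piecewise-constant with a caudal tie-break", {
  lm <- fix_anatomy()$landmarks
  seg <- lm$segment_z_ranges
  l1 <- seg[seg$segment == "L1", ]
  expect_equal(segment_for_z(mean(c(l1$z_min, l1$z_max)), lm), "L1")
  ## boundary between L2 and L1 belongs to the more caudal L2
  expect_equal(segment_for_z(l1$z_min, lm), "L2")
  expect_equal(segment_for_z(seg$z_min[1], lm), seg$segment[1])
  expect_error(segment_for_z(max(seg$z_max) + 5, lm),
               class = "spinefield_range_error")
  expect_error(segment_for_z(seg$z_min[1] - 5, lm),
               class = "spinefield_range_error")
  ## vectorized, piecewise-constant inside a segment
  zs <- seq(l1$z_min + 0.5, l1$z_max - 0.5, length.out = 7)
  expect_true(all(segment_for_z(zs, lm) == "L1"))
})

test_that("segment ranges tile the cord extent without overlap", {
  lm <- fix_anatomy()$landmarks
  seg <- lm$segment_z_ranges
  expect_equal(seg$z_min[-1], seg$z_max[-nrow(seg)])
  expect_equal(seg$z_min[1], lm$cord_z[1])
  expect_equal(max(seg$z_max), lm$cord_z[2])
})

test_that("validate_anatomy passes on the built grid and catches defects", {
  an <- fix_anatomy()
  rep0 <- validate_anatomy(an$grid)
  expect_true(attr(rep0, "ok"))

  ## Deleting one skin voxel breaches the closed shell: pick the dorsal-most
  ## skin voxel of a mid-torso column (away from the thick z-caps), which
  ## has fat directly beneath it
  g <- an$grid
  L <- tissue_labels()
  d <- dim(g$labels)
  zmid <- round(d[3] / 2); xmid <- round(d[1] / 2)
  ytop <- max(which(g$labels[xmid, , zmid] == L[["skin"]]))
  expect_true(g$labels[xmid, ytop - 1L, zmid] != L[["skin"]])
  g$labels[xmid, ytop, zmid] <- L[["background"]]
  rep1 <- validate_anatomy(g)
  row <- rep1[rep1$check == "skin_closed_shell", ]
  expect_false(row$pass)
  expect_gt(row$n_offending, 0)
  expect_match(row$detail, "breach")

  ## Splitting the CSF reports two components
  g2 <- an$grid
  csf <- g2$labels == L[["csf"]]
  zcut <- round(dim(csf)[3] / 2)
  g2$labels[, , zcut][csf[, , zcut]] <- L[["dura"]]
  rep2 <- validate_anatomy(g2)
  row2 <- rep2[rep2$check == "csf_single_component", ]
  expect_false(row2$pass)
  expect_match(row2$detail, "2")
})

test_that("geometric jitter is seeded and leaves DRG placement mirrored", {
  p <- anatomy_params("compact", jitter_mm = 1)
  a1 <- build_anatomy(p)
  a2 <- build_anatomy(p)
  expect_identical(a1$grid$labels, a2$grid$labels)
  expect_false(identical(a1$grid$labels, fix_anatomy()$grid$labels))
  drg <- a1$landmarks$drg_centers
  left <- drg[drg$side == "left", ]
  right <- drg[drg$side == "right", ]
  expect_equal(left$x, -right$x)
})
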