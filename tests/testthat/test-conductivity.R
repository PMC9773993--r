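test_that("the tissue table reproduces the reference conductivities", {
  tb <- tissue_table()
  expect_equal(sigma_for_tissue("CSF", tb), 1.790)
  expect_equal(sigma_for_tissue("Vertebrae/Bone", tb), 0.006)
  expect_equal(sigma_for_tissue("gel", tb), 4)
  expect_equal(sigma_for_tissue("rubber", tb), 44)
  expect_equal(sigma_for_tissue("Spinal-WM", tb), 0.143)
  expect_equal(sigma_for_tissue("Spinal-GM", tb), 0.333)
  expect_equal(sigma_for_tissue("skin", tb), 0.435)
  expect_equal(sigma_for_tissue("fat", tb), 0.040)
  expect_equal(sigma_for_tissue("Muscle (isotropic)", tb), 0.355)
  expect_equal(sigma_for_tissue("lungs", tb), 0.046)
  expect_equal(sigma_for_tissue("heart", tb), 0.535)
  expect_equal(sigma_for_tissue("viscera", tb), 0.123)
  expect_equal(sigma_for_tissue("Intervertebral disks", tb), 0.200)
  expect_equal(sigma_for_tissue("Dura mater", tb), 0.030)
  expect_equal(sigma_for_tissue("Brainstem/spinal roots", tb), 0.154)
  expect_error(sigma_for_tissue("cartilage", tb), "cartilage",
               class = "spinefield_lookup_error")
})

test_that("anisotropic tensors satisfy the volume constraint closed form", {
  ## r = 10 along z: eigenvalues sigma*r^(2/3) once, sigma*r^(-1/3) twice
  s <- build_anisotropic_tensor(0.143, c(0, 0, 1), 10)
  expect_equal(diag(s), c(0.143 * 10^(-1 / 3), 0.143 * 10^(-1 / 3),
                          0.143 * 10^(2 / 3)))
  expect_equal(s[upper.tri(s)], rep(0, 3))
  ## independent oracle: numeric eigendecomposition + determinant
  ev <- eigen(s, symmetric = TRUE)$values
  expect_equal(sort(ev), sort(c(0.143 * 10^(2 / 3), rep(0.143 * 10^(-1 / 3), 2))))
  expect_lt(abs(det(s) / 0.143^3 - 1), 1e-12)

  ## r = 1 is the isotropic limit
  expect_equal(build_anisotropic_tensor(0.5, c(1, 0, 0), 1), 0.5 * diag(3))

  ## oblique direction: symmetric, SPD, volume-constrained for several r
  d <- c(1, 2, -2) / 3
  for (r in c(1, 2, 5, 10)) {
    s2 <- build_anisotropic_tensor(0.355, d, r)
    expect_equal(s2, t(s2))
    expect_true(all(eigen(s2, symmetric = TRUE)$values > 0))
    expect_lt(abs(det(s2) / 0.355^3 - 1), 1e-10)
  }

  expect_error(build_anisotropic_tensor(0.1, c(1, 1, 0), 10),
               class = "spinefield_param_error")
  expect_error(build_anisotropic_tensor(0.1, c(0, 0, 1), 0.5),
               class = "spinefield_param_error")
})

test_that("field assembly maps labels to tensors with the right fibre axes", {
  an <- fix_anatomy()
  tb <- tissue_table()
  cond <- assemble_conductivity(an$grid, tb, an$frame)
  L <- tissue_labels()
  lab <- an$grid$labels

  ## isotropic tissue: sigma * Identity
  v_csf <- which(lab == L[["csf"]])[1]
  expect_equal(cond$xx[v_csf], 1.790)
  expect_equal(cond$yy[v_csf], 1.790)
  expect_equal(cond$zz[v_csf], 1.790)
  expect_false(cond$anisotropic[v_csf])

  ## straight vertical cord: WM principal axis is exactly z
  wm <- which(lab == L[["wm"]])
  expect_true(all(abs(cond$zz[wm] - 0.143 * 10^(2 / 3)) < 1e-12))
  expect_true(all(abs(cond$xx[wm] - 0.143 * 10^(-1 / 3)) < 1e-12))
  ## muscle fibres along the body axis
  mus <- which(lab == L[["muscle"]])
  expect_true(all(abs(cond$zz[mus] - 0.355 * 5^(2 / 3)) < 1e-12))

  ## no off-diagonal terms arise for axis-aligned fibres
  expect_null(cond$xy)

  ## volume constraint holds on every anisotropic voxel
  vox <- which(cond$anisotropic)
  sig_iso <- ifelse(lab[vox] == L[["wm"]], 0.143, 0.355)
  dets <- spinefield:::tensor_det(cond, vox)
  expect_lt(max(abs(dets / sig_iso^3 - 1)), 1e-10)
})

test_that("r -> 1 reproduces the isotropic assembly bitwise", {
  an <- fix_anatomy()
  iso1 <- assemble_conductivity(an$grid, tissue_table(1, 1), an$frame)
  expect_false(any(iso1$anisotropic))
  expect_identical(iso1$xx, iso1$zz)
  v <- which(an$grid$labels == tissue_labels()[["wm"]])[1]
  expect_identical(iso1$zz[v], 0.143)
})

test_that("a curved cord produces unit-determinant full tensors", {
  ## curved centreline: tangent has x and z components -> off-diagonals
  fr <- spinefield:::build_cord_frame(0, 0, 40, 2,
                                      centerline_x = function(z) 5 * sin(z / 15))
  dims <- c(5, 5, 21)
  lab <- array(tissue_labels()[["wm"]], dims)
  grid <- structure(list(labels = lab, voxel_size = 2, origin = c(-5, -5, -1),
                         dict = tissue_labels()), class = "label_grid")
  cond <- assemble_conductivity(grid, tissue_table(), fr)
  expect_false(is.null(cond$xy))
  dets <- spinefield:::tensor_det(cond, seq_along(lab))
  expect_lt(max(abs(dets / 0.143^3 - 1)), 1e-10)
})
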