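test_that("spherical phantom volume approaches the analytic sphere volume", {
  ph <- make_spherical_phantom(0.5, 1.5, 0.05)
  expect_equal(ph$tumor_volume, 4 / 3 * pi * 0.5^3, tolerance = 0.05)
  # first-order convergence: finer grid at least as accurate
  ph2 <- make_spherical_phantom(0.5, 1.5, 0.1)
  err_fine <- abs(ph$tumor_volume - 4 / 3 * pi * 0.5^3)
  err_coarse <- abs(ph2$tumor_volume - 4 / 3 * pi * 0.5^3)
  expect_lt(err_fine, err_coarse + 1e-12)
  # tumor strictly inside: no tumor voxel on the boundary faces
  lab <- ph$labels; d <- dim(lab)
  expect_false(any(lab[c(1, d[1]), , ] == 2L) || any(lab[, c(1, d[2]), ] == 2L) ||
                 any(lab[, , c(1, d[3])] == 2L))
})

test_that("phantom constructors enforce their geometric guards", {
  expect_error(make_spherical_phantom(0.5, 1.5, 0.2),
               class = "psmatrans_phantom_error")  # spacing > radius/5
  expect_error(make_spherical_phantom(0.5, 0.4, 0.05),
               class = "psmatrans_phantom_error")  # tumor larger than domain
  expect_error(make_spherical_phantom(0, 1, 0.01))
})

test_that("lobed ellipsoid phantoms are deterministic, connected, near the ellipsoid volume", {
  a <- make_ellipsoidal_phantom(c(0.6, 0.5, 0.4), 1.0, 0.05, seed = 7, lobedness = 0.2)
  b <- make_ellipsoidal_phantom(c(0.6, 0.5, 0.4), 1.0, 0.05, seed = 7, lobedness = 0.2)
  expect_identical(a$labels, b$labels)
  expect_true(psmatrans:::.single_connected_component(a$labels, 2L))
  vol_ell <- 4 / 3 * pi * 0.6 * 0.5 * 0.4
  expect_equal(a$tumor_volume, vol_ell, tolerance = 0.25)
  # degenerate case: zero lobedness gives the exact ellipsoid
  e <- make_ellipsoidal_phantom(c(0.6, 0.5, 0.4), 1.0, 0.05, seed = 1, lobedness = 0)
  expect_equal(e$tumor_volume, vol_ell, tolerance = 0.05)
})

test_that("NIfTI mask round trip preserves labels, spacing and origin", {
  ph <- make_spherical_phantom(0.3, 0.8, 0.05)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(ph, f)
  ph2 <- read_mask(f)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$spacing, ph$spacing, tolerance = 1e-6)
  expect_equal(ph2$origin, ph$origin, tolerance = 1e-5)
  expect_equal(ph2$tumor_volume, ph$tumor_volume, tolerance = 1e-6)
})

test_that("anisotropic MRI-style spacing survives the mask round trip", {
  lab <- array(1L, dim = c(8, 8, 6)); lab[4:5, 4:5, 3:4] <- 2L
  ph <- psmatrans:::.new_phantom(lab, c(0.0859, 0.0859, 0.4), c(0, 0, 0),
                                 "synthetic anisotropic case")
  f <- withr::local_tempfile(fileext = ".nii")
  write_mask(ph, f)
  ph2 <- read_mask(f)
  expect_equal(ph2$spacing, c(0.0859, 0.0859, 0.4), tolerance = 1e-6)
  expect_identical(ph2$labels, lab)
})

test_that("masks with labels outside {0,1,2} are rejected", {
  img <- RNifti::asNifti(array(3L, dim = c(4, 4, 4)), datatype = "int16")
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_error(read_mask(f), class = "psmatrans_format_error")
})
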