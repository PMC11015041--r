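test_that("a deep single-tissue domain relaxes to the Starling equilibrium pressure", {
  # far from the Dirichlet boundary the pressure must plateau at
  # p_e = p_B - sigma_s (pi_B - pi_i) and the velocity must vanish
  ps <- load_parameters()
  ph <- uniform_box_phantom(n = 21L, spacing = 0.1, label = 2L)
  fl <- solve_ifp(ph, ps)
  pe_t <- (15.6 - 0.82 * 5) * 133.322
  ctr <- fl$p_i[11, 11, 11]
  expect_equal(ctr, pe_t, tolerance = 1e-6)
  speed <- psmatrans:::.cell_speed(fl)
  expect_lt(speed[11, 11, 11], 1e-12)
})

test_that("Starling field evaluation matches direct arithmetic", {
  ps <- load_parameters()
  ph <- make_spherical_phantom(0.3, 0.8, 0.05)
  pe_t <- (15.6 - 0.82 * 5) * 133.322
  # at the equilibrium pressure the capillary source vanishes
  st <- starling_fields(array(pe_t, dim(ph$labels)), ps, ph)
  expect_equal(max(abs(st$phi_B[ph$labels == 2L])), 0, tolerance = 1e-18)
  # at p_i = p_L the lymphatic sink vanishes
  st0 <- starling_fields(array(0, dim(ph$labels)), ps, ph)
  expect_equal(max(abs(st0$phi_L)), 0)
  expect_true(all(st0$phi_L[ph$labels == 2L] == 0))
  # tumor voxel at the validation pressure: phi_B = Lp S/V (p_e - p_i)
  st1 <- starling_fields(array(1490.8, dim(ph$labels)), ps, ph)
  phiB_expect <- (2.8e-7 / 133.322) * 200 * (pe_t - 1490.8)
  expect_equal(st1$phi_B[ph$labels == 2L][1], phiB_expect, tolerance = 1e-12)
  expect_equal(phiB_expect, 1.781e-5, tolerance = 2e-3)  # ~1.78e-5 1/s
})

test_that("spherical-tumor pressure matches the closed-form radial solution", {
  ps <- load_parameters()
  ph <- make_spherical_phantom(0.5, 1.0, 0.1)
  fl <- solve_ifp(ph, ps)
  ctr <- ceiling(dim(ph$labels) / 2)
  p_num <- fl$p_i[ctr[1], ctr[2], ctr[3]]
  p_ana <- radial_two_region_pressure(ps, R = 0.5, R_out = 1.0, r = 0)
  expect_equal(p_num, p_ana, tolerance = 0.02)
  # lymphatic sink restricted to normal tissue
  expect_true(all(fl$phi_L[ph$labels == 2L] == 0))
})

test_that("discrete fluid mass balance and maximum principle hold", {
  ps <- load_parameters()
  ph <- make_spherical_phantom(0.5, 1.0, 0.1)
  fl <- solve_ifp(ph, ps)
  expect_lt(fl$fluid_balance$rel_error, 0.005)
  ft <- tissue_flow_table(ps)
  expect_true(all(fl$p_i[ph$labels > 0] <= max(ft$p_e) + 1e-9))
  expect_true(all(fl$p_i[ph$labels > 0] >= 0 - 1e-9))
})

test_that("IFP is highest in the tumor core and velocity peaks at the interface", {
  ps <- load_parameters()
  ph <- make_spherical_phantom(0.5, 1.0, 0.1)
  fl <- solve_ifp(ph, ps)
  prof <- radial_profile(fl, n_bins = 15)
  core_p <- prof$p_i[1]
  # plateau in the core (flat to within solver noise), monotone drop outside
  expect_gt(core_p, max(prof$p_i) - 1)  # Pa
  # velocity maximal near the tumor-normal interface (r ~ 0.5 cm)
  r_vmax <- prof$r[which.max(prof$v_mag)]
  expect_lt(abs(r_vmax - 0.5), 0.15)
  expect_gt(core_p, mean(fl$p_i[ph$labels == 1L]))
})

test_that("grid refinement changes the central tumor IFP by less than 3 percent", {
  ps <- load_parameters()
  p_c <- vapply(c(0.1, 0.05), function(h) {
    ph <- make_spherical_phantom(0.5, 1.0, h)
    fl <- solve_ifp(ph, ps)
    ctr <- ceiling(dim(ph$labels) / 2)
    fl$p_i[ctr[1], ctr[2], ctr[3]]
  }, numeric(1))
  expect_lt(abs(p_c[2] - p_c[1]) / p_c[2], 0.03)
})

test_that("disconnected tissue is rejected", {
  lab <- array(0L, dim = c(7, 7, 7))
  lab[2, 2, 2] <- 1L
  lab[6, 6, 6] <- 1L
  ph <- psmatrans:::.new_phantom(lab, rep(0.1, 3), rep(0, 3), "disconnected")
  expect_error(solve_ifp(ph, load_parameters()), class = "psmatrans_flow_error")
})
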