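test_that("receptor RHS reduces to synthesis minus endocytosis with no ligand", {
  ps <- load_parameters()
  DR <- receptor_density(ps, "tumor")
  st <- list(F_s = DR, F_e = 0, RP_s = 0, RP_e = 0)
  d <- receptor_rhs(st, 0, 0, ps)
  v <- ps$values
  expect_equal(d$F_s, v$V_r - v$k_ec * DR)
  expect_equal(d$F_e, v$k_ec * DR)
  expect_equal(d$RP_s, 0)
  expect_equal(d$RP_e, 0)
  expect_error(receptor_rhs(list(F_s = -1, F_e = 0, RP_s = 0, RP_e = 0), 0, 0, ps),
               class = "psmatrans_validation_error")
})

test_that("ligand-free steady state matches the analytic balance and long integration", {
  # hold F_s* = 50 by supplying the required synthesis rate, then verify the
  # pools stay put under a high-accuracy integration with no ligand
  ps0 <- load_parameters()
  ss <- receptor_steady_state(ps0, F_s_star = 50)
  v <- ps0$values
  denom <- (1 - v$f2) * v$k_rec + v$f2 * v$k_deg
  expect_equal(ss$F_e, v$k_ec * 50 / denom)
  expect_equal(ss$V_r_required, v$k_ec * 50 * v$f2 * v$k_deg / denom)
  ps <- load_parameters(list(V_r = ss$V_r_required / 1e6))  # nmol/L/s -> mol/m^3/s
  prot <- administration_protocol(1e-12, 0.1)  # effectively no ligand
  ref <- make_reaction_reference(ps, prot, t_grid = c(0, 3000), D_R = 50,
                                 init = c(F_e = ss$F_e))
  expect_equal(ref$F_s[2], 50, tolerance = 1e-6)
  expect_equal(ref$F_e[2], ss$F_e, tolerance = 1e-6)
})

test_that("with no ligand and vanishing synthesis the total receptor pool decays monotonically", {
  ps <- load_parameters()
  prot <- administration_protocol(1e-12, 0.1)
  ref <- make_reaction_reference(ps, prot, t_grid = seq(0, 3000, by = 100), D_R = 50)
  tot <- ref$F_s + ref$F_e + ref$RP_s + ref$RP_e
  expect_true(all(diff(tot) < 0))
  expect_true(all(ref$F_s >= 0 & ref$F_e >= 0 & ref$RP_s >= 0 & ref$RP_e >= 0))
})

test_that("receptor bookkeeping matches the term-by-term sum with no degradation routing", {
  # with f1 = f2 = 0 nothing is routed to degradation, so the total pool
  # changes exactly by V_r + k_syn RP_s (every other term transfers between
  # pools); assert the symbolic sum of the four derivatives equals it
  ps <- load_parameters(list(f1 = 0, f2 = 0))
  st <- list(F_s = 30, F_e = 5, RP_s = 12, RP_e = 2)
  d <- receptor_rhs(st, C_F = 3, C_FU = 27, ps)
  v <- ps$values
  total_change <- d$F_s + d$F_e + d$RP_s + d$RP_e
  expect_equal(total_change, v$V_r + v$k_syn * st$RP_s, tolerance = 1e-12)
})

test_that("sustained exposure yields quasi-steady surface receptors increasing in k_rec", {
  # short high-accuracy integrations under a constant-rate infusion
  fs_end <- vapply(c(1e-4, 1e-2, 1e-1), function(kr) {
    ps <- load_parameters(list(k_rec = kr))
    prot <- administration_protocol(100, 0.1, mode = "infusion",
                                    infusion_duration = 600)
    ref <- make_reaction_reference(ps, prot, t_grid = c(0, 600), D_R = 50)
    ref$F_s[2]
  }, numeric(1))
  expect_true(all(diff(fs_end) > 0))
})

test_that("the stepping kernel is stiff-safe: dt 0.1 min and 0.01 min agree on all pools", {
  ps <- load_parameters()
  prot <- administration_protocol(100, 0.1)
  a <- run_zero_d(ps, prot, t_end_h = 6, dt_min = 0.1)
  b <- run_zero_d(ps, prot, t_end_h = 6, dt_min = 0.01)
  for (f in c("F_s", "F_e", "RP_s", "RP_e", "C_F", "C_B", "C_I")) {
    ta <- a$ts$tumor[, f]; tb <- b$ts$tumor[, f]
    expect_lt(max(abs(ta - tb)) / max(abs(tb)), 0.005)
  }
})

test_that("kernel trajectories track the independent adaptive-integrator reference", {
  ps <- load_parameters()
  prot <- administration_protocol(100, 0.1)
  sim <- run_zero_d(ps, prot, t_end_h = 24, dt_min = 0.1, out_every_min = 60)
  ref <- make_reaction_reference(ps, prot, t_grid = seq(0, 24 * 60, by = 60),
                                 D_R = 50)
  for (f in c("C_F", "C_B", "C_I", "C_FU", "C_BU", "C_IU", "F_s", "RP_s")) {
    dev <- max(abs(sim$ts$tumor[, f] - ref[[f]])) / max(abs(ref[[f]]))
    expect_lt(dev, 0.005)
  }
})
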