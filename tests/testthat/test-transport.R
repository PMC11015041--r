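test_that("solute exchange reduces to pure diffusion as the wall Peclet vanishes", {
  ps <- load_parameters()
  ph <- uniform_box_phantom(n = 3L, label = 2L)
  fl <- uniform_flow(ph, phi_B = 0)
  C_F <- array(2, dim(ph$labels)); C_FU <- array(5, dim(ph$labels))
  ex <- solute_exchange(C_F, C_FU, 10, 90, fl, ps, ph)
  PSV <- ps$values$P * ps$values$S_V_tumor
  expect_equal(ex$phi_B_solute[2, 2, 2], PSV * (10 - 2), tolerance = 1e-12)
  expect_equal(ex$phi_BU_solute[2, 2, 2], PSV * (90 - 5), tolerance = 1e-12)
  expect_equal(max(abs(ex$Pe_transcap)), 0)
  # equal plasma and tissue concentration with no filtration: no net flux
  ex0 <- solute_exchange(C_F, C_FU, 2, 5, fl, ps, ph)
  expect_equal(max(abs(ex0$phi_B_solute)), 0)
})

test_that("the trans-capillary Peclet number is small (diffusion-dominated wall exchange)", {
  ps <- load_parameters()
  ph <- uniform_box_phantom(n = 3L, label = 2L)
  # Starling flux for a tumor voxel at ~1500 Pa
  pe_t <- (15.6 - 0.82 * 5) * 133.322
  phiB <- (2.8e-7 / 133.322) * 200 * (pe_t - 1500)
  fl <- uniform_flow(ph, phi_B = phiB)
  ex <- solute_exchange(array(0, dim(ph$labels)), array(0, dim(ph$labels)),
                        1, 9, fl, ps, ph)
  pe <- ex$Pe_transcap[2, 2, 2]
  expect_gt(pe, 1e-6)
  expect_lt(pe, 1e-3)  # order 1e-5..1e-4: exchange is diffusion-dominated
  expect_equal(sign(pe), sign(phiB))
})

test_that("radioactive decay cancels pairwise in the hot+cold sums of the discrete RHS", {
  ps_a <- load_parameters()                      # lambda as tabulated
  ps_b <- load_parameters(list(lambda_lu177 = 7.15e-2))  # 1000x decay
  ph <- make_spherical_phantom(0.3, 0.6, 0.06)
  fl <- solve_ifp(ph, ps_a)
  set.seed(42)
  d <- dim(ph$labels)
  mkf <- function() array(runif(prod(d)), d) * (ph$labels > 0)
  st <- list(C_F = mkf(), C_B = mkf(), C_I = mkf(),
             C_FU = mkf(), C_BU = mkf(), C_IU = mkf())
  rec <- initial_receptor_state(ph, ps_a)
  ex <- solute_exchange(st$C_F, st$C_FU, 3, 27, fl, ps_a, ph)
  ra <- transport_rhs(st, rec, ex, fl, ps_a, ph)
  rb <- transport_rhs(st, rec, ex, fl, ps_b, ph)
  for (pair in list(c("C_F", "C_FU"), c("C_B", "C_BU"), c("C_I", "C_IU"))) {
    sa <- ra[[pair[1]]] + ra[[pair[2]]]
    sb <- rb[[pair[1]]] + rb[[pair[2]]]
    expect_equal(sa, sb, tolerance = 1e-10)
  }
})

test_that("internalization conserves ligand amount through the volume-fraction factor", {
  # FV_i * (loss of bound concentration to internalization) must equal
  # FV_c * (gain of intracellular concentration), exactly
  ps <- load_parameters()
  v <- ps$values
  C_B <- 7.3
  loss_amount <- v$FVi * v$k_int * C_B
  gain_amount <- v$FVc * (v$FVi / v$FVc * v$k_int * C_B)
  expect_identical(loss_amount, gain_amount)
})

test_that("compiled kernel and reference RHS agree on a tiny step", {
  ps <- load_parameters()
  ph <- make_spherical_phantom(0.25, 0.45, 0.05)
  fl <- solve_ifp(ph, ps)
  d <- dim(ph$labels)
  inside <- ph$labels > 0L
  set.seed(7)
  smooth_field <- function(amp) {
    ax <- seq(0, pi, length.out = d[1])
    amp * outer(outer(sin(ax), sin(ax)), sin(ax)) * inside
  }
  st <- list(C_F = smooth_field(2), C_B = smooth_field(1), C_I = smooth_field(0.5),
             C_FU = smooth_field(20), C_BU = smooth_field(10), C_IU = smooth_field(5))
  rec <- initial_receptor_state(ph, ps)
  prot <- administration_protocol(100, 0.1)
  dtm <- 1e-5  # min; makes the one-step splitting error negligible
  sim <- run_simulation(ph, ps, prot, t_end_h = dtm / 60, dt_min = dtm,
                        out_every_min = dtm, flow = fl,
                        init = list(species = st, receptors = rec))
  cp <- plasma_concentration(prot, dtm / 2)
  ex <- solute_exchange(st$C_F, st$C_FU, cp$labeled, cp$unlabeled, fl, ps, ph)
  rhs <- transport_rhs(st, rec, ex, fl, ps, ph)
  rrhs <- receptor_rhs(rec, st$C_F, st$C_FU, ps)
  dt_s <- dtm * 60
  for (f in names(st)) {
    num <- (sim$final_species[[f]] - st[[f]]) / dt_s
    scale <- max(abs(rhs[[f]]))
    expect_lt(max(abs(num - rhs[[f]])[inside]) / scale, 1e-3)
  }
  scale_rec <- max(vapply(rrhs, function(a) max(abs(a)), numeric(1)))
  for (f in names(rec)) {
    num <- (sim$final_receptors[[f]] - rec[[f]]) / dt_s
    expect_lt(max(abs(num - rrhs[[f]])[inside]) / scale_rec, 1e-3)
  }
})

test_that("a Gaussian blob under pure diffusion-decay follows the heat kernel", {
  ps <- load_parameters(list(P = 1e-30))  # switch off transvascular exchange
  n <- 64L; h <- 0.0125; s0 <- 0.08
  ph <- uniform_box_phantom(n = n, spacing = h, label = 2L)
  fl <- uniform_flow(ph, phi_B = 0)
  ax <- (seq_len(n) - (n + 1) / 2) * h
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  st <- initial_species_state(ph)
  st$C_F <- exp(-r2 / (2 * s0^2))
  rec <- initial_receptor_state(ph, ps)
  rec$F_s <- array(0, dim(ph$labels))  # no receptors: no binding
  prot <- administration_protocol(1e-12, 0.1)
  t_min <- 10
  sim <- run_simulation(ph, ps, prot, t_end_h = t_min / 60, dt_min = 0.1,
                        out_every_min = t_min, flow = fl,
                        init = list(species = st, receptors = rec))
  v <- ps$values
  exact <- gaussian_diffusion_decay(r2, t_min * 60, s0, v$D_eff, v$lambda_lu177)
  err <- max(abs(sim$final_species$C_F - exact)) / max(exact)
  expect_lt(err, 0.01)
  # and the decayed fraction reappears in the cold field
  expect_equal(max(sim$final_species$C_FU) / max(sim$final_species$C_F),
               expm1(v$lambda_lu177 * t_min * 60), tolerance = 0.01)
})

test_that("a zero-amount protocol leaves every field identically zero", {
  ps <- load_parameters()
  prot <- administration_protocol(0, 0.1)
  sim <- run_zero_d(ps, prot, t_end_h = 1, dt_min = 0.1, out_every_min = 30)
  for (f in c("C_F", "C_B", "C_I", "C_FU", "C_BU", "C_IU")) {
    expect_equal(max(abs(sim$ts$tumor[, f])), 0)
  }
})
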