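# Independent oracles used by the test suite. These are deliberately
# separate implementations from the package's solvers: the radial solution
# is the closed-form two-region sphere solution of the Darcy-Starling
# problem, the heat kernel is the analytic free-space diffusion solution,
# and reference reaction trajectories come from deSolve at tight tolerance
# (via make_reaction_reference, which the simulation kernel never calls).

# Closed-form pressure for a spherical tumor (radius R) inside a spherical
# normal shell (outer radius R_out, p = 0 there), with Starling source in
# both tissues and lymphatic sink in the normal shell only.
# In each region p(r) = p_inf + u(r)/r with u'' = u / l^2:
#   tumor:  p = pe_t + A sinh(r/lt)/r
#   normal: p = peq_n + (B exp(r/ln) + C exp(-r/ln))/r
# Unknowns (A, B, C) from continuity of p and K p' at R, and p(R_out) = 0.
radial_two_region_pressure <- function(params, R, R_out, r) {
  ft <- tissue_flow_table(params)
  tt <- ft[ft$tissue == "tumor", ]
  nn <- ft[ft$tissue == "normal", ]
  s_t <- tt$Lp * tt$S_V
  s_n <- nn$Lp * nn$S_V + nn$LpL_SL_V
  pe_t <- tt$p_e
  peq_n <- (nn$Lp * nn$S_V * nn$p_e + nn$LpL_SL_V * nn$p_L) / s_n
  lt <- sqrt(tt$K / s_t)
  ln <- sqrt(nn$K / s_n)
  # basis u/r and d/dr(u/r); scale normal exponentials by exp(-R/ln) etc.
  # to keep the linear system well conditioned
  f_t  <- function(r) sinh(r / lt) / r
  df_t <- function(r) cosh(r / lt) / (lt * r) - sinh(r / lt) / r^2
  f_p  <- function(r) exp((r - R_out) / ln) / r
  df_p <- function(r) f_p(r) * (1 / ln - 1 / r)
  f_m  <- function(r) exp(-(r - R) / ln) / r
  df_m <- function(r) f_m(r) * (-1 / ln - 1 / r)
  M <- rbind(
    c(f_t(R), -f_p(R), -f_m(R)),                      # p continuity at R
    c(tt$K * df_t(R), -nn$K * df_p(R), -nn$K * df_m(R)),  # flux continuity
    c(0, f_p(R_out), f_m(R_out))                      # outer Dirichlet
  )
  rhs <- c(peq_n - pe_t, 0, -peq_n)
  abc <- solve(M, rhs)
  vapply(r, function(ri) {
    if (ri < 1e-12) {
      pe_t + abc[1] / lt  # limit sinh(r/l)/r -> 1/l
    } else if (ri <= R) {
      pe_t + abc[1] * f_t(ri)
    } else {
      peq_n + abc[2] * f_p(ri) + abc[3] * f_m(ri)
    }
  }, numeric(1))
}

# Analytic solution of pure diffusion + decay for a Gaussian initial blob:
# C0 = exp(-|x|^2 / (2 s0^2))  ->
# C(x,t) = (s0^2/st^2)^{3/2} exp(-|x|^2/(2 st^2)) exp(-lambda t),
# st^2 = s0^2 + 2 D t.
gaussian_diffusion_decay <- function(r2, t_s, s0, D, lambda) {
  st2 <- s0^2 + 2 * D * t_s
  (s0^2 / st2)^1.5 * exp(-r2 / (2 * st2)) * exp(-lambda * t_s)
}

# A uniform zero-velocity flow field on a phantom, with prescribed Starling
# source/sink levels; used to reduce the kernel to its reaction subsystem.
uniform_flow <- function(phantom, phi_B = 1.775e-5, phi_L = 0) {
  d <- dim(phantom$labels)
  inside <- phantom$labels > 0L
  structure(list(
    p_i = array(NA_real_, d),
    vx = array(0, d + c(1, 0, 0)), vy = array(0, d + c(0, 1, 0)),
    vz = array(0, d + c(0, 0, 1)),
    phi_B = array(phi_B * inside, d), phi_L = array(phi_L * inside, d),
    residual_norm = 0, iterations = 0L,
    fluid_balance = list(production = 0, outflow = 0, rel_error = 0),
    phantom = phantom), class = "psma_flow")
}

# single-tissue box phantoms built through the internal constructor
uniform_box_phantom <- function(n = 3L, spacing = 0.1, label = 2L) {
  lab <- array(label, dim = rep(n, 3))
  psmatrans:::.new_phantom(lab, rep(spacing, 3), rep(0, 3),
                           "uniform single-tissue test box")
}

# 0-D style simulation on a uniform box with a hand-built flow field
run_zero_d <- function(params, protocol, t_end_h, dt_min = 0.1,
                       out_every_min = 30, phi_B = 1.775e-5, phi_L = 0,
                       n = 3L, label = 2L, init = NULL) {
  ph <- uniform_box_phantom(n = n, label = label)
  fl <- uniform_flow(ph, phi_B = phi_B, phi_L = phi_L)
  run_simulation(ph, params, protocol, t_end_h = t_end_h, dt_min = dt_min,
                 out_every_min = out_every_min, flow = fl, init = init)
}
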