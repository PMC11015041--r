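#' Manufactured solution for the Darcy-Starling problem
#'
#' Builds a verification case with a prescribed smooth pressure field and
#' the forcing that makes it the exact solution of
#' `-div(K grad p) + s_B p + s_L p = s_B p_e + s_L p_L + f` on a
#' single-tissue cube, so the finite-volume solver must recover it. The
#' default field `p = amp * prod(sin(pi x_k / L))` vanishes on the outer
#' boundary, matching the solver's Dirichlet condition; the corresponding
#' forcing is `f = (K pi^2 sum(1/L_k^2) + s) p - s p_eq`.
#'
#' @param phantom A single-tissue `psma_phantom` (labels all 1 or all 2 are
#'   both accepted; the matching tissue parameters are used).
#' @param params A `psma_params`.
#' @param amp Amplitude of the manufactured pressure, Pa.
#' @return List with the exact solution array `p_exact` (Pa), the `forcing`
#'   array (1/s) for [solve_ifp()], and the grid spec.
#' @export
make_manufactured_darcy <- function(phantom, params, amp = 100) {
  lab <- phantom$labels
  tiss <- if (all(lab[lab > 0] == 2L)) "tumor" else "normal"
  if (!all(lab %in% if (tiss == "tumor") c(0L, 2L) else c(0L, 1L))) {
    rlang::abort("Manufactured cases require a single-tissue phantom.")
  }
  ft <- tissue_flow_table(params)
  row <- ft[ft$tissue == tiss, ]
  s <- row$Lp * row$S_V + row$LpL_SL_V
  rhs0 <- row$Lp * row$S_V * row$p_e + row$LpL_SL_V * row$p_L
  d <- dim(lab)
  ax <- .axis_coords(phantom)
  L <- vapply(1:3, function(a) d[a] * phantom$spacing[a], numeric(1))
  # x measured from the domain face (voxel centers at (i - 1/2) h)
  xs <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * phantom$spacing[a])
  p <- amp * outer(outer(sin(pi * xs[[1]] / L[1]), sin(pi * xs[[2]] / L[2])),
                   sin(pi * xs[[3]] / L[3]))
  dim(p) <- d
  f <- (row$K * pi^2 * sum(1 / L^2) + s) * p - rhs0
  list(p_exact = p, forcing = f, spacing = phantom$spacing, tissue = tiss)
}

#' High-accuracy reference trajectories of the reaction system
#'
#' Integrates the spatially uniform (zero-dimensional) coupled
#' ligand/receptor reaction system — binding, internalization, release,
#' decay, trafficking and transvascular exchange, with transport switched
#' off — using a tight-tolerance adaptive integrator (deSolve `lsoda`,
#' rtol/atol 1e-12). The production kernel never calls this code path, so
#' these trajectories serve as independent ground truth for the stepping
#' scheme.
#'
#' @param params A `psma_params`.
#' @param protocol An [administration_protocol()] (the plasma forcing).
#' @param t_grid Output times, min.
#' @param D_R Initial free-surface receptor density, nmol/L.
#' @param phi_B Starling fluid source, 1/s (tumor-core magnitude by
#'   default).
#' @param phi_L Lymphatic sink, 1/s (0 = tumor voxel).
#' @param S_V Vessel surface density, 1/cm.
#' @param init Optional named numeric vector of the ten initial values.
#' @return Tibble: `t` (min) and the ten state variables (nmol/L).
#' @export
make_reaction_reference <- function(params, protocol, t_grid, D_R = 50,
                                    phi_B = 1.775e-5, phi_L = 0,
                                    S_V = NULL, init = NULL) {
  v <- params$values
  if (is.null(S_V)) S_V <- v$S_V_tumor
  PSV <- v$P * S_V
  conv <- phi_B * (1 - v$sigma_f)
  Pe <- if (PSV > 0) conv / PSV else 0
  PeF <- if (abs(Pe) < 1e-8) 1 - Pe / 2 else Pe / expm1(Pe)
  a_min <- protocol$alpha / 60
  cp_tot <- function(t_min) {
    A <- protocol$amount_total; V <- protocol$plasma_volume
    if (A <= 0) return(0)
    if (protocol$mode == "bolus") return(A / V * exp(-a_min * t_min))
    Td <- protocol$infusion_duration
    if (t_min < Td) A / (V * a_min * Td) * (1 - exp(-a_min * t_min))
    else A / (V * a_min * Td) * (exp(a_min * Td) - 1) * exp(-a_min * t_min)
  }
  y0 <- c(C_F = 0, C_B = 0, C_I = 0, C_FU = 0, C_BU = 0, C_IU = 0,
          F_s = D_R, F_e = 0, RP_s = 0, RP_e = 0)
  if (!is.null(init)) y0[names(init)] <- init
  g <- v$FVi / v$FVc
  rhs <- function(t, y, parms) {
    # t in seconds (canonical); plasma evaluated in minutes
    cpt <- cp_tot(t / 60)
    cpl <- protocol$labeled_fraction * cpt
    cpu <- cpt - cpl
    ex_l <- conv * cpl + PSV * PeF * (cpl - y["C_F"])
    ex_u <- conv * cpu + PSV * PeF * (cpu - y["C_FU"])
    C <- y["C_F"] + y["C_FU"]
    with(v, {
      dCF <- -lambda_lu177 * y["C_F"] - k_on * y["F_s"] * y["C_F"] +
        k_off * y["C_B"] + ex_l - phi_L * y["C_F"]
      dCB <- -lambda_lu177 * y["C_B"] + k_on * y["F_s"] * y["C_F"] -
        (k_off + k_int) * y["C_B"]
      dCI <- -lambda_lu177 * y["C_I"] - k_rel * y["C_I"] + g * k_int * y["C_B"]
      dCFU <- lambda_lu177 * y["C_F"] - k_on * y["F_s"] * y["C_FU"] +
        k_off * y["C_BU"] + ex_u - phi_L * y["C_FU"]
      dCBU <- lambda_lu177 * y["C_B"] + k_on * y["F_s"] * y["C_FU"] -
        (k_off + k_int) * y["C_BU"]
      dCIU <- lambda_lu177 * y["C_I"] - k_rel * y["C_IU"] + g * k_int * y["C_BU"]
      dFs <- -k_on * y["F_s"] * C + V_r + (k_syn + k_off) * y["RP_s"] -
        k_ec * y["F_s"] + (1 - f2) * k_rec * y["F_e"]
      dFe <- k_ec * y["F_s"] - ((1 - f2) * k_rec + f2 * k_deg) * y["F_e"]
      dRPs <- k_on * y["F_s"] * C + (1 - f1) * k_rec * y["RP_e"] -
        (k_off + k_int) * y["RP_s"]
      dRPe <- -((1 - f1) * k_rec + f1 * k_deg) * y["RP_e"] + k_int * y["RP_s"]
      list(c(dCF, dCB, dCI, dCFU, dCBU, dCIU, dFs, dFe, dRPs, dRPe))
    })
  }
  out <- deSolve::lsoda(y0, times = t_grid * 60, func = rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-12, maxsteps = 500000)
  out <- as.data.frame(out)
  out$time <- out$time / 60
  names(out)[1] <- "t"
  as_tibble(out)
}
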