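#' Transvascular solute exchange terms
#'
#' Capillary source and lymphatic sink of free ligand per voxel. The
#' capillary source combines convective extravasation with the Starling
#' fluid flux `phi_B` and diffusive exchange across the vessel wall,
#' `phi_B (1 - sigma_f) C_p + (P S/V)(C_p - C) Pe/(exp(Pe) - 1)`, where the
#' trans-capillary Peclet number is `Pe = phi_B (1 - sigma_f) / (P S/V)`.
#' As `Pe -> 0` the correction factor tends to 1 and exchange reduces to
#' pure diffusion. The lymphatic sink is `phi_L C` and is identically zero
#' in tumor voxels (no functional tumor lymphatics).
#'
#' @param C_F,C_FU Free labeled / unlabeled concentration arrays, nmol/L.
#' @param C_p_labeled,C_p_unlabeled Scalar plasma concentrations, nmol/L.
#' @param flow A [solve_ifp()] `psma_flow`.
#' @param params A `psma_params`.
#' @param phantom The `psma_phantom`.
#' @return List of arrays: `phi_B_solute`, `phi_BU_solute` (sources,
#'   nmol/L/s), `phi_L_solute`, `phi_LU_solute` (sinks, nmol/L/s) and
#'   `Pe_transcap` (dimensionless).
#' @export
solute_exchange <- function(C_F, C_FU, C_p_labeled, C_p_unlabeled, flow,
                            params, phantom) {
  v <- params$values
  lab <- phantom$labels
  PSV <- array(0, dim(lab))
  PSV[lab == 1L] <- v$P * v$S_V_normal
  PSV[lab == 2L] <- v$P * v$S_V_tumor
  conv <- flow$phi_B * (1 - v$sigma_f)
  Pe <- ifelse(PSV > 0, conv / PSV, 0)
  PeF <- ifelse(abs(Pe) < 1e-8, 1 - Pe / 2, Pe / expm1(Pe))
  inside <- lab > 0L
  src_l <- array(0, dim(lab)); src_u <- array(0, dim(lab))
  src_l[inside] <- conv[inside] * C_p_labeled +
    (PSV * PeF)[inside] * (C_p_labeled - C_F[inside])
  src_u[inside] <- conv[inside] * C_p_unlabeled +
    (PSV * PeF)[inside] * (C_p_unlabeled - C_FU[inside])
  list(phi_B_solute = src_l, phi_BU_solute = src_u,
       phi_L_solute = flow$phi_L * C_F, phi_LU_solute = flow$phi_L * C_FU,
       Pe_transcap = Pe)
}

# upwind advection + central diffusion divergence for one field (reference
# implementation; the production path is the compiled kernel)
.conv_diff_rhs <- function(C, flow, params, phantom) {
  v <- params$values
  lab <- phantom$labels
  d <- dim(lab)
  h <- phantom$spacing
  inside <- lab > 0L
  C0 <- ifelse(inside, C, 0)
  acc <- array(0, d)
  for (axis in 1:3) {
    vel <- list(flow$vx, flow$vy, flow$vz)[[axis]]
    n <- d[axis]
    idx <- function(a, i) {
      switch(axis,
             a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    }
    asn <- function(a, i, val) {
      switch(axis,
             { a[i, , ] <- val; a }, { a[, i, ] <- val; a }, { a[, , i] <- val; a })
    }
    flux_at <- function(f) {
      # advective flux in +axis direction at face f (1..n+1)
      vf <- idx(vel, f)
      cl <- if (f >= 2) idx(C0, f - 1) else array(0, dim(vf))
      il <- if (f >= 2) idx(inside, f - 1) else array(FALSE, dim(vf))
      cr <- if (f <= n) idx(C0, f) else array(0, dim(vf))
      ir <- if (f <= n) idx(inside, f) else array(FALSE, dim(vf))
      up <- ifelse(vf > 0, ifelse(il, cl, 0), ifelse(ir, cr, 0))
      v$R_f * vf * up
    }
    for (cell in seq_len(n)) {
      Flo <- flux_at(cell)
      Fhi <- flux_at(cell + 1)
      contrib <- (Flo - Fhi) / h[axis]
      # diffusion with zero-flux closure at domain boundary
      here <- idx(C0, cell); ihere <- idx(inside, cell)
      if (cell >= 2) {
        nb <- idx(C0, cell - 1); inb <- idx(inside, cell - 1)
        contrib <- contrib + ifelse(ihere & inb, v$D_eff * (nb - here) / h[axis]^2, 0)
      }
      if (cell <= n - 1) {
        nb <- idx(C0, cell + 1); inb <- idx(inside, cell + 1)
        contrib <- contrib + ifelse(ihere & inb, v$D_eff * (nb - here) / h[axis]^2, 0)
      }
      acc <- asn(acc, cell, idx(acc, cell) + ifelse(ihere, contrib, 0))
    }
  }
  acc
}

#' Right-hand side of the six coupled ligand fields
#'
#' Reference (pure R) evaluation of the convection-diffusion-reaction system
#' for labeled (hot) and unlabeled (cold) ligand in free, receptor-bound and
#' internalized compartments. Free fields are advected on the steady Darcy
#' velocity (retardation `R_f`), diffuse with `D_eff`, exchange with plasma
#' and lymph, and bind to free surface receptors (`k_on F_s C_F`, reversed
#' by `k_off`); bound ligand internalizes at `k_int` with the volume-ratio
#' factor `FV_i/FV_c` on the intracellular gain; internalized ligand is
#' released (lost) at `k_rel`. Radioactive decay moves every hot species
#' into its cold counterpart at `lambda_lu177`, so hot+cold sums are
#' decay-free.
#'
#' @param state List of six arrays `C_F`, `C_B`, `C_I`, `C_FU`, `C_BU`,
#'   `C_IU` (nmol/L).
#' @param receptors Receptor state list (only `F_s` enters the binding term).
#' @param exchange Output of [solute_exchange()].
#' @param flow A `psma_flow`.
#' @param params A `psma_params`.
#' @param phantom The `psma_phantom`.
#' @return List of six arrays of time derivatives, nmol/L/s.
#' @export
transport_rhs <- function(state, receptors, exchange, flow, params, phantom) {
  v <- params$values
  lam <- v$lambda_lu177
  Fs <- receptors$F_s
  g <- v$FVi / v$FVc
  adv_F <- .conv_diff_rhs(state$C_F, flow, params, phantom)
  adv_FU <- .conv_diff_rhs(state$C_FU, flow, params, phantom)
  list(
    C_F = adv_F - lam * state$C_F - v$k_on * Fs * state$C_F +
      v$k_off * state$C_B + exchange$phi_B_solute - exchange$phi_L_solute,
    C_B = -lam * state$C_B + v$k_on * Fs * state$C_F -
      (v$k_off + v$k_int) * state$C_B,
    C_I = -lam * state$C_I - v$k_rel * state$C_I + g * v$k_int * state$C_B,
    C_FU = adv_FU + lam * state$C_F - v$k_on * Fs * state$C_FU +
      v$k_off * state$C_BU + exchange$phi_BU_solute - exchange$phi_LU_solute,
    C_BU = lam * state$C_B + v$k_on * Fs * state$C_FU -
      (v$k_off + v$k_int) * state$C_BU,
    C_IU = lam * state$C_I - v$k_rel * state$C_IU + g * v$k_int * state$C_BU
  )
}

#' Zeroed species state on a phantom
#'
#' @param phantom A `psma_phantom`.
#' @return List of six zero arrays (the model's initial condition: no drug
#'   in tissue).
#' @export
initial_species_state <- function(phantom) {
  z <- array(0, dim(phantom$labels))
  list(C_F = z, C_B = z, C_I = z, C_FU = z, C_BU = z, C_IU = z)
}

#' Run the coupled transport + receptor simulation
#'
#' Advances the six ligand fields and four receptor pools on the steady
#' Darcy flow field with the compiled operator-splitting kernel: explicit
#' upwind/central convection-diffusion for the free fields, an L-stable
#' implicit (TR-BDF2) update of the stiff binding/exchange pairs, and
#' sub-stepped explicit midpoint integration of the receptor pools. The
#' default time step is 0.1 min and the default horizon 50 h; region-averaged
#' time series are recorded every `out_every_min` minutes.
#'
#' @param phantom A `psma_phantom`.
#' @param params A `psma_params`.
#' @param protocol An [administration_protocol()]. Its `plasma_volume` and
#'   `alpha` default from `params` if `NULL`.
#' @param t_end_h Simulated physical time, hours.
#' @param dt_min Time step, minutes.
#' @param out_every_min Output sampling interval, minutes.
#' @param flow Optional precomputed [solve_ifp()] result (reused across
#'   sweep members); solved here when `NULL`.
#' @param init Optional list with elements `species` and `receptors` for a
#'   warm start; defaults to drug-free tissue and surface receptors at the
#'   tissue density.
#' @return A `psma_sim` object; see [tidy.psma_sim()], [glance.psma_sim()],
#'   [compute_tia()].
#' @export
run_simulation <- function(phantom, params, protocol, t_end_h = 50,
                           dt_min = 0.1, out_every_min = 5, flow = NULL,
                           init = NULL) {
  stopifnot(inherits(phantom, "psma_phantom"), inherits(params, "psma_params"),
            inherits(protocol, "administration_protocol"))
  if (is.null(flow)) flow <- solve_ifp(phantom, params)
  v <- params$values
  lab <- phantom$labels
  PSV <- array(0, dim(lab))
  PSV[lab == 1L] <- v$P * v$S_V_normal
  PSV[lab == 2L] <- v$P * v$S_V_tumor

  species <- if (is.null(init)) initial_species_state(phantom) else init$species
  receptors <- if (is.null(init)) initial_receptor_state(phantom, params) else init$receptors

  pars_vec <- c(D_eff = v$D_eff, R_f = v$R_f, lambda_lu177 = v$lambda_lu177,
                k_on = v$k_on, k_off = v$k_off, k_int = v$k_int,
                k_rel = v$k_rel, k_deg = v$k_deg, k_ec = v$k_ec,
                k_rec = v$k_rec, k_syn = v$k_syn, f1 = v$f1, f2 = v$f2,
                FVi = v$FVi, FVc = v$FVc, V_r = v$V_r, sigma_f = v$sigma_f)
  plasma <- list(mode = if (protocol$mode == "bolus") 0L else 1L,
                 A = protocol$amount_total, V = protocol$plasma_volume,
                 alpha = protocol$alpha / 3600,            # 1/h -> 1/s
                 T = protocol$infusion_duration * 60,      # min -> s
                 frac = protocol$labeled_fraction)
  init_vec <- list(C_F = as.numeric(species$C_F), C_B = as.numeric(species$C_B),
                   C_I = as.numeric(species$C_I), C_FU = as.numeric(species$C_FU),
                   C_BU = as.numeric(species$C_BU), C_IU = as.numeric(species$C_IU),
                   F_s = as.numeric(receptors$F_s), F_e = as.numeric(receptors$F_e),
                   RP_s = as.numeric(receptors$RP_s), RP_e = as.numeric(receptors$RP_e))
  out_every <- max(1L, as.integer(round(out_every_min / dt_min)))
  res <- run_kernel_cpp(dims = dim(lab), spacing = phantom$spacing,
                        labels = as.integer(lab),
                        vx = flow$vx, vy = flow$vy, vz = flow$vz,
                        phi_B = flow$phi_B, phi_L = flow$phi_L,
                        PSV = PSV, pars_in = pars_vec, plasma = plasma,
                        init = init_vec,
                        t_end = t_end_h * 3600, dt = dt_min * 60,
                        out_every = out_every)
  fields <- c("C_F", "C_B", "C_I", "C_FU", "C_BU", "C_IU",
              "F_s", "F_e", "RP_s", "RP_e")
  colnames(res$ts_tumor) <- fields
  colnames(res$ts_normal) <- fields
  final_state <- lapply(res$final_state, function(x) array(x, dim(lab)))
  structure(list(
    times_min = res$times_min,
    ts = list(tumor = res$ts_tumor, normal = res$ts_normal),
    amounts = tibble(t = res$times_min,
                     labeled_tumor = res$amounts[, 1],
                     labeled_normal = res$amounts[, 2],
                     unlabeled_tumor = res$amounts[, 3],
                     unlabeled_normal = res$amounts[, 4]),
    final_species = final_state[1:6],
    final_receptors = final_state[7:10],
    diagnostics = list(rp_discrepancy = res$rp_discrepancy,
                       clip_count = res$clip_count,
                       substeps_mean = res$substeps_mean),
    phantom = phantom, params = params, protocol = protocol,
    flow = flow, dt_min = dt_min, t_end_h = t_end_h),
    class = "psma_sim")
}

#' @export
print.psma_sim <- function(x, ...) {
  cat("<psma_sim> ", x$protocol$amount_total, " nmol ", x$protocol$mode,
      " (", 100 * x$protocol$labeled_fraction, "% labeled), ",
      x$t_end_h, " h at dt = ", x$dt_min, " min\n", sep = "")
  tia <- compute_tia(x)
  cat("  tumor TIA:", signif(tia$tia[tia$region == "tumor"], 5), "MBq min;",
      "normal TIA:", signif(tia$tia[tia$region == "normal"], 5), "MBq min\n")
  invisible(x)
}

#' Region-averaged concentration time series of a simulation
#'
#' @param x A `psma_sim`.
#' @param ... Unused.
#' @return A long tibble: `t` (min), `region`, `species`, `concentration`
#'   (nmol/L; receptor pools included).
#' @method tidy psma_sim
#' @export
tidy.psma_sim <- function(x, ...) {
  purrr::map_dfr(c("tumor", "normal"), function(reg) {
    m <- x$ts[[reg]]
    as_tibble(m) |>
      mutate(t = x$times_min, region = reg) |>
      tidyr::pivot_longer(cols = -c("t", "region"), names_to = "species",
                          values_to = "concentration")
  })
}

#' One-row summary of a simulation
#'
#' @param x A `psma_sim`.
#' @param ... Unused.
#' @return Tibble with tumor/normal TIA, labeled AUC, peak free/bound/
#'   internalized times in the tumor and solver diagnostics.
#' @method glance psma_sim
#' @export
glance.psma_sim <- function(x, ...) {
  tia <- compute_tia(x)
  pk <- peak_times(x)
  tibble(
    tia_tumor = tia$tia[tia$region == "tumor"],
    tia_normal = tia$tia[tia$region == "normal"],
    peak_C_F = pk$t_peak[pk$species == "C_F" & pk$region == "tumor"],
    peak_C_B = pk$t_peak[pk$species == "C_B" & pk$region == "tumor"],
    peak_C_I = pk$t_peak[pk$species == "C_I" & pk$region == "tumor"],
    clip_count = x$diagnostics$clip_count,
    substeps_mean = x$diagnostics$substeps_mean
  )
}

#' Plot region-averaged ligand concentrations
#'
#' @param object A `psma_sim`.
#' @param species Species to show.
#' @param ... Unused.
#' @return A ggplot, faceted by region.
#' @method autoplot psma_sim
#' @export
autoplot.psma_sim <- function(object, species = c("C_F", "C_B", "C_I"), ...) {
  df <- tidy(object) |> filter(.data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 60, y = .data$concentration,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = "concentration [nmol/L]")
}
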