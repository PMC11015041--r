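#' Receptor trafficking right-hand side
#'
#' Per-voxel mass-balance ODEs of the four PSMA receptor pools: free surface
#' receptors `F_s`, free endosomal receptors `F_e`, occupied surface
#' receptors `RP_s` and occupied endosomal receptors `RP_e` (all nmol/L).
#' Free surface receptors bind extracellular ligand (labeled plus unlabeled)
#' at `k_on`, are endocytosed constitutively at `k_ec` and replenished by
#' constitutive synthesis `V_r`, ligand-induced synthesis `k_syn * RP_s`,
#' dissociation `k_off * RP_s` and recycling `(1 - f2) k_rec * F_e`.
#' Endosomal pools either recycle or are degraded (`k_deg`), with sorting
#' fractions `f1` (occupied) and `f2` (free); occupied surface receptors
#' internalize at `k_int`. Receptors are cell-bound: there are no transport
#' terms, so the system is integrated voxel-by-voxel.
#'
#' @param state List with numeric fields `F_s`, `F_e`, `RP_s`, `RP_e`
#'   (arrays or vectors, nmol/L).
#' @param C_F,C_FU Free labeled / unlabeled ligand concentration fields
#'   (same shape, nmol/L).
#' @param params A `psma_params`.
#' @return List of time derivatives `F_s`, `F_e`, `RP_s`, `RP_e`
#'   (nmol/L/s).
#' @export
receptor_rhs <- function(state, C_F, C_FU, params) {
  v <- params$values
  if (any(state$F_s < 0, state$F_e < 0, state$RP_s < 0, state$RP_e < 0)) {
    rlang::abort("Receptor pools must be nonnegative.",
                 class = "psmatrans_validation_error")
  }
  C <- C_F + C_FU
  with(v, {
    list(
      F_s  = -k_on * state$F_s * C + V_r + (k_syn + k_off) * state$RP_s -
        k_ec * state$F_s + (1 - f2) * k_rec * state$F_e,
      F_e  = k_ec * state$F_s - ((1 - f2) * k_rec + f2 * k_deg) * state$F_e,
      RP_s = k_on * state$F_s * C + (1 - f1) * k_rec * state$RP_e -
        (k_off + k_int) * state$RP_s,
      RP_e = -((1 - f1) * k_rec + f1 * k_deg) * state$RP_e + k_int * state$RP_s
    )
  })
}

#' Initial receptor state for a phantom
#'
#' Free surface receptors start at the tissue receptor density (tumor
#' density in tumor voxels, one tenth of it in normal tissue by default);
#' all other pools start empty.
#'
#' @param phantom A `psma_phantom`.
#' @param params A `psma_params`.
#' @return List of four arrays on the phantom grid (nmol/L).
#' @export
initial_receptor_state <- function(phantom, params) {
  lab <- phantom$labels
  F_s <- array(0, dim(lab))
  F_s[lab == 2L] <- receptor_density(params, "tumor")
  F_s[lab == 1L] <- receptor_density(params, "normal")
  z <- array(0, dim(lab))
  list(F_s = F_s, F_e = z, RP_s = z, RP_e = z)
}

#' Ligand-free receptor steady state
#'
#' With no ligand, setting the free-pool equations to zero gives
#' `F_e* = k_ec F_s* / ((1 - f2) k_rec + f2 k_deg)` and the synthesis rate
#' needed to hold a surface density `F_s*`:
#' `V_r = k_ec F_s* f2 k_deg / ((1 - f2) k_rec + f2 k_deg)`.
#' Useful as an analytic cross-check of the trafficking kinetics.
#'
#' @param params A `psma_params`.
#' @param F_s_star Surface density to support, nmol/L.
#' @return Tibble with `F_s`, `F_e` and the required `V_r` (nmol/L/s).
#' @export
receptor_steady_state <- function(params, F_s_star) {
  v <- params$values
  denom <- (1 - v$f2) * v$k_rec + v$f2 * v$k_deg
  tibble(F_s = F_s_star,
         F_e = v$k_ec * F_s_star / denom,
         V_r_required = v$k_ec * F_s_star * v$f2 * v$k_deg / denom)
}
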