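# Avogadro constant, 1/mol
.N_AVOGADRO <- 6.02214076e23

# activity of 1 nmol of carrier-free Lu-177, MBq, given the decay rate in 1/s
.mbq_per_nmol <- function(lambda_s) 1e-9 * .N_AVOGADRO * lambda_s / 1e6

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Time-integrated activity of a simulation
#'
#' Activity is the labeled ligand amount in a region (free + bound weighted
#' by the interstitial volume fraction, internalized by the cellular
#' fraction) converted from nmol to molecules times the physical decay rate;
#' TIA is its time integral over the simulated horizon (trapezoid on the
#' output grid), in MBq min. Absolute values scale with the phantom's tumor
#' volume; ratios between runs on the same phantom do not.
#'
#' @param sim A `psma_sim`.
#' @return Tibble with columns `region`, `tia` (MBq min) and
#'   `labeled_amount_auc` (nmol min).
#' @export
compute_tia <- function(sim) {
  conv <- .mbq_per_nmol(sim$params$values$lambda_lu177)
  t <- sim$amounts$t
  tibble(
    region = c("tumor", "normal"),
    tia = c(conv * .trapz(t, sim$amounts$labeled_tumor),
            conv * .trapz(t, sim$amounts$labeled_normal)),
    labeled_amount_auc = c(.trapz(t, sim$amounts$labeled_tumor),
                           .trapz(t, sim$amounts$labeled_normal))
  )
}

#' Concentration AUCs by species
#'
#' @param sim A `psma_sim`.
#' @param region `"tumor"` or `"normal"`.
#' @return Tibble `species`, `auc` (nmol/L min) for the six ligand fields
#'   plus labeled/unlabeled/overall totals.
#' @export
auc_by_species <- function(sim, region = c("tumor", "normal")) {
  region <- match.arg(region)
  m <- sim$ts[[region]]
  t <- sim$times_min
  sp <- c("C_F", "C_B", "C_I", "C_FU", "C_BU", "C_IU")
  aucs <- vapply(sp, function(s) .trapz(t, m[, s]), numeric(1))
  tot_l <- .trapz(t, m[, "C_F"] + m[, "C_B"] + m[, "C_I"])
  tot_u <- .trapz(t, m[, "C_FU"] + m[, "C_BU"] + m[, "C_IU"])
  bind_rows(tibble(species = sp, auc = unname(aucs)),
            tibble(species = c("total_labeled", "total_unlabeled", "total"),
                   auc = c(tot_l, tot_u, tot_l + tot_u)))
}

#' Peak times of the region-averaged concentration curves
#'
#' @param sim A `psma_sim`.
#' @return Tibble `region`, `species`, `t_peak` (min), `c_peak` (nmol/L).
#' @export
peak_times <- function(sim) {
  purrr::map_dfr(c("tumor", "normal"), function(reg) {
    m <- sim$ts[[reg]]
    purrr::map_dfr(colnames(m), function(s) {
      i <- which.max(m[, s])
      tibble(region = reg, species = s, t_peak = sim$times_min[i],
             c_peak = m[i, s])
    })
  })
}

#' Concentrations normalized by the initial plasma concentration
#'
#' Non-dimensionalizes the tidy time series by `C_P0 = A/V`, the plasma
#' concentration an instantaneous bolus of the protocol's amount would
#' produce.
#'
#' @param sim A `psma_sim`.
#' @return The [tidy.psma_sim()] tibble with an extra column
#'   `concentration_norm`.
#' @export
normalize_by_cp0 <- function(sim) {
  cp0 <- sim$protocol$amount_total / sim$protocol$plasma_volume
  tidy(sim) |> mutate(concentration_norm = .data$concentration / cp0)
}
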