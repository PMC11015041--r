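#' Spherical surrogate phantom for a tumor scenario
#'
#' The desk-scale stand-in geometry used by the sweep experiments: a
#' 0.5 cm-radius spherical tumor centered in a 1 cm half-width cube of
#' normal tissue at 0.1 cm voxel spacing (8000 voxels). Sweep
#' conclusions are ratio/ordering claims that are insensitive to the exact
#' tumor shape; the scenario only sets the receptor density via
#' [load_parameters()].
#'
#' @param radius Tumor radius, cm.
#' @param half_width Normal-tissue half-width, cm.
#' @param spacing Voxel edge, cm.
#' @return A `psma_phantom`.
#' @export
surrogate_phantom <- function(radius = 0.5, half_width = 1.0, spacing = 0.1) {
  make_spherical_phantom(radius, half_width, spacing)
}

#' Run one named scenario end to end
#'
#' Convenience wrapper: parameters for the scenario (plus overrides), a
#' bolus/infusion protocol, flow solve and coupled simulation.
#'
#' @param scenario `"tumor1"`, `"tumor2"` or `"tumor3"`.
#' @param overrides Named list of parameter overrides (input units).
#' @param amount_total Injected amount, nmol.
#' @param labeled_fraction Labeled fraction.
#' @param mode `"bolus"` or `"infusion"`.
#' @param infusion_duration Infusion duration, min.
#' @param phantom Optional phantom (default [surrogate_phantom()]).
#' @param flow Optional precomputed flow field.
#' @param ... Passed to [run_simulation()].
#' @return A `psma_sim`.
#' @export
run_scenario <- function(scenario = "tumor1", overrides = list(),
                         amount_total = 100, labeled_fraction = 0.10,
                         mode = "bolus", infusion_duration = 60,
                         phantom = NULL, flow = NULL, ...) {
  params <- load_parameters(overrides, scenario = scenario)
  if (is.null(phantom)) phantom <- surrogate_phantom()
  protocol <- administration_protocol(
    amount_total, labeled_fraction, mode = mode,
    infusion_duration = infusion_duration,
    plasma_volume = params$values$plasma_volume,
    alpha = params$values$alpha * 3600)
  run_simulation(phantom, params, protocol, flow = flow, ...)
}

#' Sweep one model variable and tabulate TIA
#'
#' Runs the full coupled simulation for each value of the swept variable on
#' a shared phantom and flow solve, and tabulates tumor/normal TIA, labeled
#' AUC and tumor peak times. Supported variables: `receptor_density`
#' (nmol/L), `k_rec` (1/min), `amount_total` (nmol), `labeled_fraction`
#' (fraction) and `mode` (`"bolus"`/`"infusion"`).
#'
#' @param variable Swept variable name.
#' @param values Vector of values (units above).
#' @param scenario Tumor scenario for the non-swept receptor density.
#' @param overrides Fixed parameter overrides applied to every member.
#' @param amount_total,labeled_fraction Protocol settings for members that
#'   do not sweep them.
#' @param phantom Optional phantom; default [surrogate_phantom()].
#' @param ... Passed to [run_simulation()] (e.g. `t_end_h`, `dt_min`).
#' @return A `psma_sweep` tibble: one row per member with columns `variable`,
#'   `value`, `tia_tumor`, `tia_normal`, `auc_labeled_tumor`, peak times and
#'   diagnostics. Failures of individual members are recorded in an `error`
#'   column instead of aborting the sweep.
#' @export
run_sweep <- function(variable = c("receptor_density", "k_rec", "amount_total",
                                   "labeled_fraction", "mode"),
                      values, scenario = "tumor1", overrides = list(),
                      amount_total = 100, labeled_fraction = 0.10,
                      phantom = NULL, ...) {
  variable <- match.arg(variable)
  if (is.null(phantom)) phantom <- surrogate_phantom()
  base_params <- load_parameters(overrides, scenario = scenario)
  flow <- solve_ifp(phantom, base_params)  # flow is independent of all swept variables
  rows <- purrr::map(values, function(val) {
    ov <- overrides
    amt <- amount_total; frac <- labeled_fraction; mode <- "bolus"
    if (variable == "receptor_density") ov$receptor_density_tumor <- val
    if (variable == "k_rec") ov$k_rec <- val
    if (variable == "amount_total") amt <- val
    if (variable == "labeled_fraction") frac <- val
    if (variable == "mode") mode <- as.character(val)
    out <- tryCatch({
      sim <- run_scenario(scenario = scenario, overrides = ov,
                          amount_total = amt, labeled_fraction = frac,
                          mode = mode, phantom = phantom, flow = flow, ...)
      g <- glance(sim)
      tibble(variable = variable,
             value = if (variable == "mode") NA_real_ else as.numeric(val),
             mode = mode,
             tia_tumor = g$tia_tumor, tia_normal = g$tia_normal,
             auc_labeled_tumor = auc_by_species(sim, "tumor") |>
               filter(.data$species == "total_labeled") |> pull("auc"),
             peak_C_F = g$peak_C_F, peak_C_I = g$peak_C_I,
             clip_count = g$clip_count, error = NA_character_)
    }, error = function(e) {
      tibble(variable = variable,
             value = if (variable == "mode") NA_real_ else as.numeric(val),
             mode = NA_character_, tia_tumor = NA_real_, tia_normal = NA_real_,
             auc_labeled_tumor = NA_real_, peak_C_F = NA_real_,
             peak_C_I = NA_real_, clip_count = NA_real_,
             error = conditionMessage(e))
    })
    out
  })
  out <- bind_rows(rows)
  class(out) <- c("psma_sweep", class(out))
  out
}

#' Summarize a sweep: argmax and fold change
#'
#' @param sweep A [run_sweep()] result.
#' @return One-row tibble with the swept variable, the value maximizing
#'   tumor TIA, and the fold change between the extreme swept values
#'   (`tia(max value) / tia(min value)`).
#' @export
sweep_summary <- function(sweep) {
  ok <- filter(sweep, is.na(.data$error))
  imax <- which.max(ok$tia_tumor)
  lo <- which.min(ok$value); hi <- which.max(ok$value)
  tibble(variable = ok$variable[1],
         argmax_value = ok$value[imax],
         tia_at_argmax = ok$tia_tumor[imax],
         fold_extremes = ok$tia_tumor[hi] / ok$tia_tumor[lo])
}

#' @method autoplot psma_sweep
#' @export
autoplot.psma_sweep <- function(object, ...) {
  df <- filter(object, is.na(.data$error))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$tia_tumor)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = df$variable[1], y = "tumor TIA [MBq min]")
}

#' Compare bolus and continuous-infusion administration
#'
#' Runs the identical protocol twice (same amount, labeled fraction,
#' phantom, flow) as a bolus and as a constant infusion, and reports TIA
#' and per-compartment peak concentrations in tumor and normal tissue.
#'
#' @param amount_total Injected amount, nmol.
#' @param labeled_fraction Labeled fraction.
#' @param infusion_duration Infusion duration, min (default 60).
#' @param scenario,overrides,phantom,... As in [run_sweep()].
#' @return List with `summary` (tibble: mode x region TIA), `peaks`
#'   (tibble: mode, region, species, peak time and value) and the two
#'   `psma_sim` objects.
#' @export
compare_bolus_infusion <- function(amount_total = 100, labeled_fraction = 0.10,
                                   infusion_duration = 60, scenario = "tumor1",
                                   overrides = list(), phantom = NULL, ...) {
  if (is.null(phantom)) phantom <- surrogate_phantom()
  params <- load_parameters(overrides, scenario = scenario)
  flow <- solve_ifp(phantom, params)
  sims <- purrr::map(c("bolus", "infusion"), function(md) {
    run_scenario(scenario = scenario, overrides = overrides,
                 amount_total = amount_total,
                 labeled_fraction = labeled_fraction, mode = md,
                 infusion_duration = infusion_duration,
                 phantom = phantom, flow = flow, ...)
  })
  names(sims) <- c("bolus", "infusion")
  summary <- purrr::map_dfr(names(sims), function(md) {
    compute_tia(sims[[md]]) |> mutate(mode = md, .before = 1)
  })
  peaks <- purrr::map_dfr(names(sims), function(md) {
    peak_times(sims[[md]]) |> mutate(mode = md, .before = 1)
  })
  list(summary = summary, peaks = peaks, sims = sims)
}

#' Labeled-only versus carrier-added administration
#'
#' Named experiment: a fixed labeled amount given alone versus the same
#' labeled amount co-injected with unlabeled carrier. Reports tumor TIA for
#' both and the relative change; absolute TIA values scale with the phantom
#' volume, so only the relative reduction is comparable across geometries.
#'
#' @param labeled_amount Labeled ligand amount, nmol (default 10).
#' @param carrier_amount Additional unlabeled amount, nmol (default 100).
#' @param scenario,overrides,phantom,... As in [run_sweep()].
#' @return Tibble with the two arms' tumor TIA and the relative change.
#' @export
carrier_competition_experiment <- function(labeled_amount = 10,
                                           carrier_amount = 100,
                                           scenario = "tumor1",
                                           overrides = list(), phantom = NULL,
                                           ...) {
  if (is.null(phantom)) phantom <- surrogate_phantom()
  params <- load_parameters(overrides, scenario = scenario)
  flow <- solve_ifp(phantom, params)
  pure <- run_scenario(scenario = scenario, overrides = overrides,
                       amount_total = labeled_amount, labeled_fraction = 1.0,
                       phantom = phantom, flow = flow, ...)
  mixed <- run_scenario(scenario = scenario, overrides = overrides,
                        amount_total = labeled_amount + carrier_amount,
                        labeled_fraction = labeled_amount /
                          (labeled_amount + carrier_amount),
                        phantom = phantom, flow = flow, ...)
  tia_p <- glance(pure)$tia_tumor
  tia_m <- glance(mixed)$tia_tumor
  tibble(arm = c("labeled_only", "with_carrier"),
         tia_tumor = c(tia_p, tia_m),
         relative_change = c(0, (tia_m - tia_p) / tia_p))
}
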