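#' @useDynLib psmatrans, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort
#' @import tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup slice_max pull left_join
#' @importFrom stats setNames
NULL

# Pa per mmHg, exact by definition of the conversion used throughout
.PA_PER_MMHG <- 133.322

# Registry of every user-settable parameter: the unit it is quoted in
# (configuration files and overrides use these units), the multiplier to the
# package's canonical unit system (length cm, time s, pressure Pa,
# concentration nmol/L), the canonical unit tag, and validation bounds.
.param_registry <- function() {
  mm <- .PA_PER_MMHG
  tribble(
    ~key,                              ~input_unit,      ~to_canonical, ~canonical_unit, ~lower, ~lower_open, ~upper,
    "D_eff",                           "cm^2/s",         1,             "cm^2/s",        0,      TRUE,  Inf,
    "receptor_density_tumor",          "nmol/L",         1,             "nmol/L",        0,      TRUE,  Inf,
    "receptor_density_normal_factor",  "1",              1,             "1",             0,      TRUE,  Inf,
    "f1",                              "1",              1,             "1",             0,      FALSE, 1,
    "f2",                              "1",              1,             "1",             0,      FALSE, 1,
    "FVc",                             "1",              1,             "1",             0,      TRUE,  1,
    "FVi",                             "1",              1,             "1",             0,      TRUE,  1,
    "alpha",                           "1/h",            1 / 3600,      "1/s",           0,      TRUE,  Inf,
    "lambda_lu177",                    "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "k_int",                           "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "k_on",                            "L/nmol/min",     1 / 60,        "L/nmol/s",      0,      TRUE,  Inf,
    "k_off",                           "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "k_rel",                           "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "k_deg",                           "1/s",            1,             "1/s",           0,      TRUE,  Inf,
    "k_ec",                            "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "k_rec",                           "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "k_syn",                           "1/min",          1 / 60,        "1/s",           0,      TRUE,  Inf,
    "P",                               "cm/s",           1,             "cm/s",          0,      TRUE,  Inf,
    "R_f",                             "1",              1,             "1",             0,      TRUE,  Inf,
    "V_r",                             "mol/m^3/s",      1e6,           "nmol/L/s",      0,      TRUE,  Inf,
    "sigma_f",                         "1",              1,             "1",             0,      FALSE, 1,
    "plasma_volume",                   "L",              1,             "L",             0,      TRUE,  Inf,
    "K_normal",                        "cm^2/mmHg/s",    1 / mm,        "cm^2/Pa/s",     0,      TRUE,  Inf,
    "K_tumor",                         "cm^2/mmHg/s",    1 / mm,        "cm^2/Pa/s",     0,      TRUE,  Inf,
    "Lp_normal",                       "cm/mmHg/s",      1 / mm,        "cm/Pa/s",       0,      TRUE,  Inf,
    "Lp_tumor",                        "cm/mmHg/s",      1 / mm,        "cm/Pa/s",       0,      TRUE,  Inf,
    "LpL_SL_V_normal",                 "1/mmHg/s",       1 / mm,        "1/Pa/s",        0,      TRUE,  Inf,
    "p_B",                             "mmHg",           mm,            "Pa",            0,      TRUE,  Inf,
    "p_L_normal",                      "mmHg",           mm,            "Pa",            0,      FALSE, Inf,
    "S_V_normal",                      "1/cm",           1,             "1/cm",          0,      TRUE,  Inf,
    "S_V_tumor",                       "1/cm",           1,             "1/cm",          0,      TRUE,  Inf,
    "pi_B",                            "mmHg",           mm,            "Pa",            0,      TRUE,  Inf,
    "pi_i_normal",                     "mmHg",           mm,            "Pa",            0,      TRUE,  Inf,
    "pi_i_tumor",                      "mmHg",           mm,            "Pa",            0,      TRUE,  Inf,
    "sigma_s_normal",                  "1",              1,             "1",             0,      FALSE, 1,
    "sigma_s_tumor",                   "1",              1,             "1",             0,      FALSE, 1
  )
}

# Defaults in *input* units (the units of the registry above). Receptor
# density is scenario dependent and filled in by load_parameters().
.param_defaults <- function() {
  list(
    D_eff = 8.7e-7,
    receptor_density_normal_factor = 0.1,
    f1 = 0.5, f2 = 0.5,
    FVc = 0.61, FVi = 0.39,
    alpha = 0.0521,
    lambda_lu177 = 7.15e-5,
    k_int = 0.001,
    k_on = 0.046,
    k_off = 0.046,
    k_rel = 2e-4,
    k_deg = 2.9891e-4,
    k_ec = 0.007,
    k_rec = 0.15,
    k_syn = 0.0118,
    P = 3.3e-4,
    R_f = 1,
    V_r = 1.2e-22,
    sigma_f = 0.9,
    plasma_volume = 3.0,
    K_normal = 8.53e-9, K_tumor = 4.13e-8,
    Lp_normal = 0.36e-7, Lp_tumor = 2.80e-7,
    LpL_SL_V_normal = 1.33e-5,
    p_B = 15.6,
    p_L_normal = 0,
    S_V_normal = 70, S_V_tumor = 200,
    pi_B = 20,
    pi_i_normal = 10, pi_i_tumor = 15,
    sigma_s_normal = 0.91, sigma_s_tumor = 0.82
  )
}

.scenario_receptor_density <- c(tumor1 = 50, tumor2 = 500, tumor3 = 200)

#' Load a model parameter set
#'
#' Builds the full physiological/kinetic parameter set of the transport model:
#' ligand kinetics (binding, internalization, release, decay), receptor
#' trafficking rates, transvascular exchange constants and the per-tissue
#' interstitial-flow block. Values not overridden take the model defaults;
#' the `scenario` selects the tumor receptor density (50, 500 or 200 nmol/L
#' for `"tumor1"`, `"tumor2"`, `"tumor3"`). All values are converted once,
#' at load time, into a canonical unit system (length cm, time s, pressure
#' Pa, concentration nmol/L) and carry unit tags.
#'
#' @param config Named list of overrides, or path to a YAML file with such a
#'   list. Keys must be known parameter names (see [parameter_registry()]);
#'   values are given in the quoted input units (e.g. rates in 1/min,
#'   pressures in mmHg).
#' @param scenario One of `"tumor1"`, `"tumor2"`, `"tumor3"` or `"custom"`.
#'   For `"custom"`, `receptor_density_tumor` must be supplied in `config`.
#' @return An object of class `psma_params`: a list with canonical `values`,
#'   `units` tags, and the `scenario` label.
#' @examples
#' ps <- load_parameters(scenario = "tumor2")
#' ps$values$receptor_density_tumor   # 500 nmol/L
#' ps2 <- load_parameters(list(k_rec = 1e-4), scenario = "tumor1")
#' @export
load_parameters <- function(config = list(), scenario = c("tumor1", "tumor2", "tumor3", "custom")) {
  scenario <- match.arg(scenario)
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  reg <- .param_registry()
  vals_in <- .param_defaults()
  if (scenario != "custom") {
    vals_in$receptor_density_tumor <- unname(.scenario_receptor_density[scenario])
  }
  unknown <- setdiff(names(config), reg$key)
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter key(s): ", paste(unknown, collapse = ", "),
                 ". Known keys are listed by parameter_registry()."),
          class = "psmatrans_config_error")
  }
  for (k in names(config)) vals_in[[k]] <- config[[k]]
  if (is.null(vals_in$receptor_density_tumor)) {
    abort("scenario = 'custom' requires a 'receptor_density_tumor' entry in config.",
          class = "psmatrans_config_error")
  }
  # validate in input units, then convert
  for (i in seq_len(nrow(reg))) {
    k <- reg$key[i]
    v <- vals_in[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("Parameter '", k, "' must be a single finite number."),
            class = "psmatrans_validation_error")
    }
    bad_low <- if (reg$lower_open[i]) v <= reg$lower[i] else v < reg$lower[i]
    if (bad_low || v > reg$upper[i]) {
      abort(paste0("Parameter '", k, "' = ", v, " ", reg$input_unit[i],
                   " violates its admissible range (",
                   if (reg$lower_open[i]) "(" else "[", reg$lower[i], ", ",
                   reg$upper[i], "])."),
            class = "psmatrans_validation_error")
    }
  }
  if (abs(vals_in$FVc + vals_in$FVi - 1) > 1e-12) {
    abort(paste0("FVc + FVi must equal 1 (got ", vals_in$FVc + vals_in$FVi, ")."),
          class = "psmatrans_validation_error")
  }
  values <- setNames(
    lapply(reg$key, function(k) vals_in[[k]] * reg$to_canonical[reg$key == k]),
    reg$key
  )
  units <- setNames(reg$canonical_unit, reg$key)
  structure(list(values = values, units = units, scenario = scenario),
            class = "psma_params")
}

#' Registry of model parameters
#'
#' @return A tibble with one row per settable parameter: key, input unit
#'   (the unit used in configuration files), canonical unit and admissible
#'   range.
#' @export
parameter_registry <- function() {
  .param_registry() |>
    select("key", "input_unit", "canonical_unit", "lower", "upper")
}

#' Fetch a parameter value with an explicit unit check
#'
#' Guards against silent unit mixing: the caller states the unit it expects
#' and an error is raised unless it matches the stored canonical unit tag.
#'
#' @param params A `psma_params` object.
#' @param key Parameter name.
#' @param unit Expected canonical unit string (e.g. `"1/s"`, `"Pa"`).
#' @return The numeric value in canonical units.
#' @export
param_value <- function(params, key, unit) {
  stopifnot(inherits(params, "psma_params"))
  if (!key %in% names(params$values)) {
    abort(paste0("Unknown parameter key: ", key), class = "psmatrans_config_error")
  }
  if (!identical(unname(params$units[[key]]), unit)) {
    abort(paste0("Unit mismatch for '", key, "': stored as ", params$units[[key]],
                 ", requested as ", unit, ". Convert explicitly."),
          class = "psmatrans_unit_error")
  }
  params$values[[key]]
}

#' Per-tissue interstitial-flow parameter block
#'
#' @param params A `psma_params` object.
#' @return A tibble with rows `normal` and `tumor` and canonical-unit columns
#'   `K` (cm^2/Pa/s), `Lp` (cm/Pa/s), `LpL_SL_V` (1/Pa/s; 0 in tumor — the
#'   tumor has no functional lymphatics), `p_B`, `p_L`, `pi_B`, `pi_i` (Pa),
#'   `S_V` (1/cm), `sigma_s`, and the Starling equilibrium pressure
#'   `p_e = p_B - sigma_s * (pi_B - pi_i)`.
#' @export
tissue_flow_table <- function(params) {
  v <- params$values
  tb <- tibble(
    tissue   = c("normal", "tumor"),
    K        = c(v$K_normal, v$K_tumor),
    Lp       = c(v$Lp_normal, v$Lp_tumor),
    S_V      = c(v$S_V_normal, v$S_V_tumor),
    LpL_SL_V = c(v$LpL_SL_V_normal, 0),
    p_B      = c(v$p_B, v$p_B),
    p_L      = c(v$p_L_normal, 0),
    pi_B     = c(v$pi_B, v$pi_B),
    pi_i     = c(v$pi_i_normal, v$pi_i_tumor),
    sigma_s  = c(v$sigma_s_normal, v$sigma_s_tumor)
  )
  mutate(tb, p_e = .data$p_B - .data$sigma_s * (.data$pi_B - .data$pi_i))
}

#' Receptor density by tissue
#'
#' Normal tissue expresses the receptor at one tenth (by default) of the
#' tumor density.
#'
#' @param params A `psma_params` object.
#' @param tissue `"tumor"` or `"normal"`.
#' @return Density in nmol/L.
#' @export
receptor_density <- function(params, tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  d <- params$values$receptor_density_tumor
  if (tissue == "normal") d <- d * params$values$receptor_density_normal_factor
  d
}

#' Convert pressures between Pa and mmHg
#'
#' Exact linear conversion with 1 mmHg = 133.322 Pa.
#'
#' @param value Numeric pressure value(s).
#' @param from,to `"Pa"` or `"mmHg"`.
#' @return Converted value(s).
#' @examples
#' convert_pressure(15.6, "mmHg", "Pa")  # 2079.8 Pa
#' @export
convert_pressure <- function(value, from, to) {
  ok <- c("Pa", "mmHg")
  if (!(from %in% ok) || !(to %in% ok)) {
    abort(paste0("Unknown pressure unit; use one of: ", paste(ok, collapse = ", ")),
          class = "psmatrans_unit_error")
  }
  if (from == to) return(value)
  if (from == "mmHg") value * .PA_PER_MMHG else value / .PA_PER_MMHG
}

#' @export
print.psma_params <- function(x, ...) {
  cat("<psma_params> scenario:", x$scenario, "\n")
  cat("  receptor density (tumor):", x$values$receptor_density_tumor, "nmol/L;",
      "normal factor:", x$values$receptor_density_normal_factor, "\n")
  cat("  canonical units: cm, s, Pa, nmol/L;",
      length(x$values), "parameters (see parameter_registry()).\n")
  invisible(x)
}
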