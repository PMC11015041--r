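#' Define an administration protocol
#'
#' The vascular input of the model: a total ligand amount of which a fraction
#' is radiolabeled, delivered either as an instantaneous bolus or as a
#' constant-rate infusion over `infusion_duration` minutes. Plasma
#' concentration then follows a mono-exponential clearance with rate `alpha`.
#'
#' @param amount_total Total injected ligand amount, nmol (labeled + unlabeled).
#' @param labeled_fraction Fraction of the amount that is radiolabeled,
#'   in (0, 1]. Default 0.10 (the clinical 10% hot / 90% cold composition).
#' @param mode `"bolus"` or `"infusion"`.
#' @param infusion_duration Infusion duration, min (only for `mode = "infusion"`;
#'   default 60 min).
#' @param plasma_volume Compartmental plasma volume, L.
#' @param alpha Compartmental clearance rate, 1/h.
#' @return An `administration_protocol` object.
#' @examples
#' administration_protocol(100, mode = "bolus")
#' @export
administration_protocol <- function(amount_total, labeled_fraction = 0.10,
                                    mode = c("bolus", "infusion"),
                                    infusion_duration = 60,
                                    plasma_volume = 3.0, alpha = 0.0521) {
  mode <- match.arg(mode)
  stopifnot(amount_total >= 0, labeled_fraction > 0, labeled_fraction <= 1,
            plasma_volume > 0, alpha > 0)
  if (mode == "infusion" && !(infusion_duration > 0)) {
    rlang::abort("infusion_duration must be positive for mode = 'infusion'.",
                 class = "psmatrans_validation_error")
  }
  structure(list(amount_total = amount_total, labeled_fraction = labeled_fraction,
                 mode = mode, infusion_duration = infusion_duration,
                 plasma_volume = plasma_volume, alpha = alpha),
            class = "administration_protocol")
}

#' @export
print.administration_protocol <- function(x, ...) {
  cat("<administration_protocol> ", x$amount_total, " nmol (",
      100 * x$labeled_fraction, "% labeled), ", x$mode, sep = "")
  if (x$mode == "infusion") cat(" over ", x$infusion_duration, " min", sep = "")
  cat("; V =", x$plasma_volume, "L, alpha =", x$alpha, "/h\n")
  invisible(x)
}

#' Plasma concentration over time
#'
#' For a bolus, `C_p(t) = (A/V) exp(-alpha t)`. For a constant infusion of
#' duration `T`, `C_p(t) = A/(V alpha T) (1 - exp(-alpha t))` while `t < T`
#' and `C_p(t) = A/(V alpha T) (exp(alpha T) - 1) exp(-alpha t)` afterwards;
#' the profile is continuous at `t = T` and both modes integrate to
#' `A / (V alpha)`.
#'
#' @param protocol An [administration_protocol()].
#' @param t Time(s) since administration, min. Must be nonnegative.
#' @return A tibble with columns `t` (min), `labeled`, `unlabeled` and
#'   `total` plasma concentrations (nmol/L).
#' @examples
#' p <- administration_protocol(100)
#' plasma_concentration(p, c(0, 60, 24 * 60))
#' @export
plasma_concentration <- function(protocol, t) {
  stopifnot(inherits(protocol, "administration_protocol"))
  if (any(t < 0)) {
    rlang::abort("t must be nonnegative.", class = "psmatrans_validation_error")
  }
  a_min <- protocol$alpha / 60  # 1/h -> 1/min
  A <- protocol$amount_total
  V <- protocol$plasma_volume
  cp <- if (protocol$mode == "bolus") {
    (A / V) * exp(-a_min * t)
  } else {
    Td <- protocol$infusion_duration
    ifelse(t < Td,
           A / (V * a_min * Td) * (1 - exp(-a_min * t)),
           A / (V * a_min * Td) * (exp(a_min * Td) - 1) * exp(-a_min * t))
  }
  tibble(t = t, labeled = protocol$labeled_fraction * cp,
         unlabeled = (1 - protocol$labeled_fraction) * cp, total = cp)
}
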