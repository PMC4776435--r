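# Boltzmann temperature correction and ln-normalization of routine
# metabolic rates.

#' Boltzmann correction parameters
#'
#' Activation energy of metabolic processes E (eV) and Boltzmann's constant
#' k (eV K^-1). The defaults, E = 0.65 eV and k = 8.62e-5 eV K^-1, are the
#' standard values of metabolic theory.
#'
#' @param E activation energy in eV; must be >= 0.
#' @param k Boltzmann constant in eV per Kelvin; must be > 0.
#' @return A `boltzmann_params` list.
#' @export
boltzmann_params <- function(E = 0.65, k = 8.62e-5) {
  stopifnot(is.numeric(E), length(E) == 1L, E >= 0,
            is.numeric(k), length(k) == 1L, k > 0)
  structure(list(E = E, k = k), class = "boltzmann_params")
}

# Celsius-to-Kelvin offset; the conversion constant is fixed at 273.15.
.KELVIN_OFFSET <- 273.15

#' Temperature-correct a mass-specific metabolic rate
#'
#' Applies the Boltzmann factor MR = MR0 * exp(E / (k * T)) with T the
#' absolute assay temperature, and returns the corrected rate together with
#' its natural log, ln(MR) = ln(MR0) + E/(kT). The raw factor is used (no
#' reference-temperature rescaling): the corrected values live on the
#' e^(E/kT) scale, so ln(MR) is typically around 30 for teleost routine
#' rates.
#'
#' @param mr0 raw mass-specific routine metabolic rate(s),
#'   mg O2 kg^-1 h^-1; must be > 0.
#' @param temperature_celsius assay temperature(s) in degrees Celsius;
#'   values outside -2..45 degrees C trigger a plausibility warning.
#' @param params a [boltzmann_params()] object.
#' @return data.frame with columns `mr0`, `T` (Kelvin), `mr_corrected`,
#'   `ln_mr`.
#' @examples
#' boltzmann_correct(1, 25)$ln_mr  # = 0.65 / (8.62e-5 * 298.15)
#' @export
boltzmann_correct <- function(mr0, temperature_celsius,
                              params = boltzmann_params()) {
  stopifnot(inherits(params, "boltzmann_params"))
  mr0 <- as.numeric(mr0)
  temperature_celsius <- as.numeric(temperature_celsius)
  if (any(!is.finite(mr0)) || any(mr0 <= 0)) {
    stop("mr0 must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(temperature_celsius))) {
    stop("assay temperature must be finite", call. = FALSE)
  }
  if (any(temperature_celsius < -2 | temperature_celsius > 45)) {
    warning("assay temperature outside the physiologically plausible ",
            "range -2..45 degrees C", call. = FALSE)
  }
  T_kelvin <- temperature_celsius + .KELVIN_OFFSET
  if (any(params$k * T_kelvin <= 0)) {
    stop("k * T must be positive", call. = FALSE)
  }
  factor_exp <- params$E / (params$k * T_kelvin)
  data.frame(
    mr0 = mr0,
    T = T_kelvin,
    mr_corrected = mr0 * exp(factor_exp),
    ln_mr = log(mr0) + factor_exp
  )
}

#' Boltzmann-correct and ln-normalize a metabolic-rate dataset
#'
#' Replaces each record's trait value with ln(MR) = ln(MR0) + E/(kT); the
#' raw rate and assay temperature are preserved in the provenance columns
#' `mr0_raw` and `temperature`. No body-mass scaling is applied: the input
#' rates are already mass-specific. A mass-scaling hook (`mass_exponent`)
#' exists for users with whole-animal rates but is off (`NULL`) by default.
#'
#' @param dataset a `trait_dataset` with `variable == "MR"`; every record
#'   must carry an assay temperature.
#' @param params a [boltzmann_params()] object.
#' @param mass_exponent optional allometric exponent; if non-`NULL` the
#'   records must carry a `mass` column and mr0 is divided by
#'   `mass^mass_exponent` before correction.
#' @return The dataset with `value` holding ln(MR).
#' @export
normalize_mr <- function(dataset, params = boltzmann_params(),
                         mass_exponent = NULL) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (dataset$variable != "MR") {
    stop("normalize_mr applies only to MR datasets", call. = FALSE)
  }
  rec <- dataset$records
  if (is.null(rec$temperature) || any(!is.finite(rec$temperature))) {
    bad <- if (is.null(rec$temperature)) rec$species else
      rec$species[!is.finite(rec$temperature)]
    stop("missing assay temperature for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mr0 <- rec$value
  if (!is.null(mass_exponent)) {
    if (is.null(rec$mass)) {
      stop("mass_exponent given but no 'mass' column present", call. = FALSE)
    }
    mr0 <- mr0 / rec$mass^mass_exponent
  }
  corr <- boltzmann_correct(mr0, rec$temperature, params)
  rec$mr0_raw <- rec$value
  rec$value <- corr$ln_mr
  dataset$records <- rec
  attr(dataset, "normalized") <- TRUE
  dataset
}
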