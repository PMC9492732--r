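#' @title Metabolic model of leaf trait rates
#' @description
#' The core model expresses a mass-specific leaf metabolic rate (light-saturated
#' photosynthetic capacity, nmol g^-1 s^-1, or specific leaf area, cm^2 g^-1)
#' as a product of a Michaelis-Menten hydration response and a
#' Boltzmann-Arrhenius temperature factor:
#'
#'   B_s = g * exp(k1 * S / (K1 + S)) * exp(-E / (k * T))
#'
#' where S is the dry-mass-based leaf water content (g water per g dry mass),
#' T is absolute temperature (K), E an activation energy (eV) and k the
#' Boltzmann constant. On the natural-log scale the model is the sum of
#' ln(g), the saturating water term, and minus the Arrhenius exponent.
#' @name core_model
NULL

#' Boltzmann constant in electron-volt per Kelvin
#'
#' The fixed physical constant used in the Arrhenius factor `exp(-E/(k*T))`,
#' following the metabolic-theory convention of expressing activation
#' energies in eV.
#'
#' @format A single numeric value, 8.617e-5 eV K^-1.
#' @export
boltzmann_ev <- 8.617e-5

#' Model parameters for the saturation-times-Arrhenius rate model
#'
#' Bundles the constants of the leaf metabolic rate model. The same structure
#' serves the photosynthesis model (normalisation `g` in nmol g^-1 s^-1) and
#' the specific leaf area model (`g` in cm^2 g^-1).
#'
#' @param g Normalisation constant, in the rate units of the modelled trait.
#'   Must be positive.
#' @param k1 Maximum increase of the log rate from full hydration
#'   (dimensionless). Must be non-negative. Note the model does not constrain
#'   `k1 <= 1`; empirical fits tend to land near 1.
#' @param K1 Half-saturation water content (g water g^-1 dry mass), the LWC at
#'   which the hydration term reaches `k1/2`. Must be positive.
#' @param E Activation energy in eV. May be negative (an apparent decline of
#'   the trait with temperature); zero switches the temperature factor off.
#' @param boltzmann_k Boltzmann constant (eV K^-1); fixed physical constant,
#'   exposed only so that printed parameter sets are self-describing.
#'
#' @return An object of class `"model_params"`: a named list with elements
#'   `g`, `k1`, `K1`, `E`, `boltzmann_k`.
#' @examples
#' p <- model_params(g = 240, k1 = 1, K1 = 0.6, E = 0.03)
#' water_saturation_term(1.5, p)
#' @export
model_params <- function(g, k1, K1, E = 0, boltzmann_k = boltzmann_ev) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(K1), length(K1) == 1L, is.finite(K1),
            is.numeric(E), length(E) == 1L, is.finite(E))
  if (g <= 0) stop("'g' must be positive", call. = FALSE)
  if (k1 < 0) stop("'k1' must be non-negative", call. = FALSE)
  if (K1 <= 0) stop("'K1' must be positive", call. = FALSE)
  if (boltzmann_k <= 0) stop("'boltzmann_k' must be positive", call. = FALSE)
  structure(list(g = g, k1 = k1, K1 = K1, E = E, boltzmann_k = boltzmann_k),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Saturation-Arrhenius model parameters\n")
  cat(sprintf("  g  (normalisation)      : %.6g\n", x$g))
  cat(sprintf("  k1 (max hydration gain) : %.6g\n", x$k1))
  cat(sprintf("  K1 (half-saturation LWC): %.6g g g^-1\n", x$K1))
  cat(sprintf("  E  (activation energy)  : %.6g eV\n", x$E))
  cat(sprintf("  k  (Boltzmann)          : %.4g eV K^-1\n", x$boltzmann_k))
  invisible(x)
}

#' Convert Celsius to Kelvin
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' Michaelis-Menten hydration term of the rate model
#'
#' Computes `k1 * lwc / (K1 + lwc)`: the saturating contribution of leaf
#' water content to the natural-log metabolic rate. Monotone non-decreasing
#' in `lwc`, bounded above by `k1`, and equal to `k1/2` at `lwc = K1`.
#'
#' @param lwc Leaf water content, dry-mass basis (g water g^-1 dry mass);
#'   non-negative, vectorised.
#' @param params A [model_params()] object.
#' @return Dimensionless numeric vector, same length as `lwc`.
#' @export
water_saturation_term <- function(lwc, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(lwc))
  if (any(lwc < 0, na.rm = TRUE)) {
    stop("'lwc' must be non-negative (dry-mass-based water content)",
         call. = FALSE)
  }
  params$k1 * lwc / (params$K1 + lwc)
}

#' Magnitude of the Boltzmann temperature exponent
#'
#' Computes `E / (k * T)` for absolute temperature `T` in Kelvin. The forward
#' model multiplies rates by `exp(-E/(k*T))`; this function returns the
#' exponent magnitude used by both the forward model and the corrections.
#'
#' @param temperature_k Absolute temperature in Kelvin; strictly positive,
#'   vectorised. Use [celsius_to_kelvin()] for field temperatures in Celsius.
#' @param params A [model_params()] object.
#' @return Dimensionless numeric vector.
#' @export
arrhenius_exponent <- function(temperature_k, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(temperature_k))
  if (any(temperature_k <= 0, na.rm = TRUE)) {
    stop("'temperature_k' must be positive Kelvin temperatures", call. = FALSE)
  }
  params$E / (params$boltzmann_k * temperature_k)
}

#' Predicted natural-log mass-specific rate
#'
#' The forward model on the log scale:
#' `ln(rate) = ln(g) + k1*lwc/(K1+lwc) - E/(k*T)`. Instantiated with the
#' photosynthesis parameter set it predicts ln of mass-specific photosynthetic
#' capacity; with the leaf-area set, ln of specific leaf area.
#'
#' @inheritParams water_saturation_term
#' @inheritParams arrhenius_exponent
#' @return Numeric vector of natural-log rates.
#' @export
predict_log_rate <- function(lwc, temperature_k, params) {
  log(params$g) + water_saturation_term(lwc, params) -
    arrhenius_exponent(temperature_k, params)
}

#' Temperature-correct a trait value
#'
#' Moves the Boltzmann factor to the left-hand side of the model:
#' returns `value * exp(E/(k*T))`. With `E = 0` this is the identity;
#' dividing the result by `exp(E/(k*T))` recovers the input exactly.
#' Applied to mass-specific photosynthesis it yields the temperature-corrected
#' capacity whose log is predicted to follow the hydration term alone; the
#' same operation applied to SLA yields temperature-corrected SLA.
#'
#' @param value Positive trait value(s) (e.g. nmol g^-1 s^-1 or cm^2 g^-1).
#' @inheritParams arrhenius_exponent
#' @return Corrected trait values: original units times a dimensionless factor.
#' @export
temperature_correct <- function(value, temperature_k, params) {
  stopifnot(is.numeric(value))
  if (any(value <= 0, na.rm = TRUE)) {
    stop("'value' must be positive to be temperature-corrected", call. = FALSE)
  }
  value * exp(arrhenius_exponent(temperature_k, params))
}

#' Temperature- and water-content-correct a whole-leaf trait
#'
#' Moves both the hydration term and the Boltzmann factor to the left-hand
#' side: returns `value * exp(-k1*lwc/(K1+lwc)) * exp(E/(k*T))`. For a
#' whole-leaf trait generated exactly by the model (rate times dry mass),
#' the result equals `g * M_L`: the corrected trait scales isometrically
#' with leaf dry mass.
#'
#' @param value Positive whole-leaf trait value(s) (e.g. whole-leaf
#'   photosynthesis in nmol s^-1, or leaf area in cm^2).
#' @inheritParams water_saturation_term
#' @inheritParams arrhenius_exponent
#' @return Corrected trait values: original units times a dimensionless factor.
#' @export
full_correct <- function(value, lwc, temperature_k, params) {
  stopifnot(is.numeric(value))
  if (any(value <= 0, na.rm = TRUE)) {
    stop("'value' must be positive to be corrected", call. = FALSE)
  }
  value * exp(-water_saturation_term(lwc, params)) *
    exp(arrhenius_exponent(temperature_k, params))
}
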