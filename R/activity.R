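#' Davies activity model
#'
#' Parameters of the Davies extension of Debye-Hueckel theory used to move
#' stability constants between ionic strengths.  `A` is the Debye-Hueckel
#' solvent coefficient (0.51 for water at 298.1 K), `b` the empirical linear
#' term (canonical Davies value 0.3), and `I_validity_max` the ionic strength
#' (mol/dm^3) above which a warning is emitted: the Davies form is usually
#' considered reliable only up to about 0.5 mol/dm^3.
#'
#' @param A Debye-Hueckel coefficient (> 0).
#' @param b linear-term coefficient (dimensionless).
#' @param I_validity_max warning threshold on ionic strength (mol/dm^3).
#' @return an object of class `activity_model`.
#' @export
activity_model <- function(A = 0.51, b = 0.3, I_validity_max = 0.5) {
  stopifnot(is.numeric(A), length(A) == 1L, A > 0,
            is.numeric(b), length(b) == 1L,
            is.numeric(I_validity_max), I_validity_max > 0)
  structure(list(A = A, b = b, I_validity_max = I_validity_max),
            class = "activity_model")
}

#' Davies log10 activity coefficient
#'
#' log10 gamma = -A z^2 (sqrt(I)/(1 + sqrt(I)) - b I).  Neutral species have
#' log gamma = 0 at all ionic strengths.
#'
#' @param z signed integer charge (vectorised).
#' @param I ionic strength, mol/dm^3 (scalar, >= 0).
#' @param model an [activity_model()].
#' @return log10 activity coefficient(s), same length as `z`.
#' @export
davies_log_gamma <- function(z, I, model = activity_model()) {
  if (!is.numeric(I) || length(I) != 1L || is.na(I) || I < 0)
    stop("ionic strength `I` must be a single non-negative number")
  if (I > model$I_validity_max)
    warning(sprintf(
      "I = %g mol/dm^3 exceeds the Davies validity limit (%g mol/dm^3)",
      I, model$I_validity_max))
  -model$A * z^2 * (sqrt(I) / (1 + sqrt(I)) - model$b * I)
}

# Davies ionic-strength function f(I); log10 gamma(z) = -A z^2 f(I).
davies_f <- function(I, model = activity_model()) {
  sqrt(I) / (1 + sqrt(I)) - model$b * I
}

#' Convert a conditional formation constant to its intrinsic (I = 0) value
#'
#' A cumulative formation constant measured at ionic strength `I_ref`
#' (concentration quotient) is extrapolated to infinite dilution:
#' log beta0 = log beta_cond - A f(I_ref) (z_species^2 - sum nu_i z_i^2),
#' i.e. the activity-coefficient quotient of the formation reaction is
#' removed.  `delta_z2` is z^2 of the species minus the stoichiometry-weighted
#' sum of squared component charges (water contributes zero; hydroxo species
#' encoded as -H carry nu = -1 for the proton).
#'
#' @param logK_cond conditional log10 constant at `I_ref`.
#' @param delta_z2 z^2(species) - sum(nu * z^2(components)).
#' @param I_ref ionic strength of the measurement, mol/dm^3.
#' @param model an [activity_model()].
#' @return log10 constant at I = 0.
#' @seealso [intrinsic_to_conditional()] for the inverse.
#' @export
conditional_to_intrinsic <- function(logK_cond, delta_z2, I_ref,
                                     model = activity_model()) {
  logK_cond - model$A * davies_f(I_ref, model) * delta_z2
}

#' @rdname conditional_to_intrinsic
#' @param logK0 intrinsic log10 constant (I = 0).
#' @param I target ionic strength, mol/dm^3.
#' @export
intrinsic_to_conditional <- function(logK0, delta_z2, I,
                                     model = activity_model()) {
  logK0 + model$A * davies_f(I, model) * delta_z2
}

# delta z^2 of a formation reaction from a named stoichiometry vector and
# component charges: z_sp^2 - sum(nu_i z_i^2).
reaction_delta_z2 <- function(charge_species, stoich, comp_charge) {
  charge_species^2 - sum(stoich * comp_charge[names(stoich)]^2)
}

#' Redox potential / electron activity conversion
#'
#' pe = Eh F / (ln(10) R T) with Eh supplied in millivolts.  At 298.15 K one
#' pe unit corresponds to 59.16 mV.
#'
#' @param Eh_mV redox potential in millivolts.
#' @param T_K temperature in kelvin (> 0).
#' @return pe (dimensionless negative log10 electron activity).
#' @export
eh_to_pe <- function(Eh_mV, T_K = 298.15) {
  stopifnot(is.numeric(T_K), T_K > 0)
  (Eh_mV / 1000) * .FARADAY / (log(10) * .RGAS * T_K)
}

#' @rdname eh_to_pe
#' @param pe dimensionless redox intensity.
#' @export
pe_to_eh <- function(pe, T_K = 298.15) {
  pe * log(10) * .RGAS * T_K / .FARADAY * 1000
}

.FARADAY <- 96485.33212   # C/mol
.RGAS <- 8.31446          # J/(mol K)

# Nernst slope in mV/decade at T kelvin.
nernst_slope_mV <- function(T_K = 298.1) log(10) * .RGAS * T_K / .FARADAY * 1000

#' Cumulative formation constants from stepwise metal-complex constants
#'
#' Potentiometric work reports stepwise constants for the reactions
#' M + L = ML, ML + H = MHL and ML + H2O = ML(OH) + H.  On the component
#' basis (M, L, H) the cumulative constants are log-additive:
#' beta(ML) = K_ML, beta(MHL) = K_ML * K_MHL, beta(MLOH) = K_ML * K_MLOH.
#'
#' @param reactions a list of `list(type =, logK =)` entries with
#'   `type` one of `"ML"`, `"MHL"`, `"MLOH"`.
#' @return named numeric vector of cumulative log10 beta values.
#' @examples
#' stepwise_to_cumulative(list(list(type = "ML", logK = 11.48),
#'                             list(type = "MLOH", logK = -9.69)))
#' @export
stepwise_to_cumulative <- function(reactions) {
  types <- vapply(reactions, function(r) as.character(r$type), character(1))
  logK <- vapply(reactions, function(r) as.numeric(r$logK), numeric(1))
  if (anyDuplicated(types)) stop("duplicate reaction types")
  bad <- setdiff(types, c("ML", "MHL", "MLOH"))
  if (length(bad)) stop("unknown reaction type: ", paste(bad, collapse = ", "))
  if (!"ML" %in% types && length(types))
    stop("MHL/MLOH stepwise constants require an ML entry")
  k <- stats::setNames(logK, types)
  out <- c(ML = unname(k["ML"]))
  if ("MHL" %in% types) out["MHL"] <- k[["ML"]] + k[["MHL"]]
  if ("MLOH" %in% types) out["MLOH"] <- k[["ML"]] + k[["MLOH"]]
  out
}
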