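#' Parameters for forward-simulated gas-exchange/isotope records
#'
#' Describes a steady cuvette state with a known true mesophyll conductance.
#' CO2 concentrations must satisfy `Ce > Ca >= Cs >= Ci > GammaStar` for a
#' transpiring, assimilating leaf. The tank air isotope ratio (`d13Ce`) is
#' strongly depleted (-32 to -37 per mil is typical of cylinder CO2);
#' greenhouse atmospheric CO2 is taken as -8 per mil unless overridden.
#' Measurement noise is i.i.d. Gaussian on the sampled `d13Ca`.
#'
#' @param gm True mesophyll conductance (mol CO2 m-2 s-1, > 0).
#' @param An Net assimilation (umol m-2 s-1).
#' @param E Transpiration (mol m-2 s-1).
#' @param g_act Combined boundary-layer + stomatal conductance to CO2
#'   (mol m-2 s-1).
#' @param Ca,Cs,Ci,Ce CO2 concentrations (umol mol-1).
#' @param Rd Day respiration (umol m-2 s-1).
#' @param GammaStar Photocompensation point (umol mol-1).
#' @param d13Ce,d13Catm Isotope ratios of tank and atmospheric CO2 (per mil).
#' @param noise_sd Gaussian SD added to d13Ca (per mil).
#' @param n Number of replicate records.
#' @param seed Integer seed.
#' @return An object of class `isotope_sim_params`.
#' @export
isotope_sim_params <- function(gm = 0.15, An = 14, E = 0.002, g_act = 0.25,
                               Ca = 400, Cs = 390, Ci = 280, Ce = 455,
                               Rd = 1.5, GammaStar = 40,
                               d13Ce = -35, d13Catm = -8,
                               noise_sd = 0.1, n = 1L, seed = 1L) {
  if (gm <= 0) stop("true gm must be > 0")
  if (!(Ce > Ca && Ca >= Cs && Cs >= Ci && Ci > GammaStar))
    stop("require Ce > Ca >= Cs >= Ci > GammaStar for an assimilating leaf")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (An + Rd <= 0) stop("An + Rd must be > 0")
  structure(list(gm = gm, An = An, E = E, g_act = g_act,
                 Ca = Ca, Cs = Cs, Ci = Ci, Ce = Ce,
                 Rd = Rd, GammaStar = GammaStar,
                 d13Ce = d13Ce, d13Catm = d13Catm,
                 noise_sd = noise_sd, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "isotope_sim_params")
}

#' Forward-simulate gas-exchange/isotope records from a known gm
#'
#' Runs the discrimination model forward: predicted discrimination and the
#' respiratory/photorespiratory components are computed from the cuvette
#' state; the mesophyll-conductance component follows from the true `gm`;
#' their difference gives the observed discrimination, which is inverted for
#' the cuvette-air isotope ratio `d13Ca` consistent with the tank `d13Ce`.
#' Gaussian noise is then added to `d13Ca` per replicate. With zero noise,
#' [estimate_gm()] applied to a simulated record returns the true `gm`
#' exactly (to floating-point roundoff).
#'
#' @param params An [isotope_sim_params()].
#' @param constants [isotope_constants()].
#' @return Record table in the documented CSV layout
#'   (`An,E_mmol,gact,Ca,Cs,Ci,Ce,Rd,GammaStar,d13Ca,d13Ce,d13Catm`) plus a
#'   `true_gm` column for recovery tests.
#' @export
generate_isotope_records <- function(params, constants = isotope_constants()) {
  stopifnot(inherits(params, "isotope_sim_params"))
  p <- params
  z <- zeta(p$Ce, p$Ca)
  a_prime <- combined_fractionation(p$Ca, p$Cs, p$Ci, constants)
  t <- ternary_t(a_prime, p$E, p$g_act)
  delta_i <- predicted_discrimination(t, a_prime, p$Ci, p$Ca, constants)
  nr <- nonrubisco_discriminations(
    t, list(d13Ce = p$d13Ce, d13Catm = p$d13Catm, Rd = p$Rd, An = p$An,
            Ca = p$Ca, Ci = p$Ci, GammaStar = p$GammaStar), constants)
  delta_gm <- (1 + t) / (1 - t) *
    (constants$b - constants$ai - nr$e * p$Rd / (p$An + p$Rd)) *
    (p$An / (p$gm * p$Ca))
  delta_o <- delta_i - delta_gm - nr$delta_e - nr$delta_f

  # invert the observed-discrimination relation for d13Ca
  denom <- z * (delta_o + 1000) - delta_o
  if (denom <= 0)
    stop("simulation not invertible: zeta*(Do+1000) - Do <= 0")
  d13Ca_clean <- (1000 * delta_o + z * p$d13Ce * (delta_o + 1000)) / denom

  with_seed(p$seed, {
    noise <- stats::rnorm(p$n, sd = p$noise_sd)
    data.frame(An = p$An, E_mmol = p$E * 1000, gact = p$g_act,
               Ca = p$Ca, Cs = p$Cs, Ci = p$Ci, Ce = p$Ce,
               Rd = p$Rd, GammaStar = p$GammaStar,
               d13Ca = d13Ca_clean + noise, d13Ce = p$d13Ce,
               d13Catm = p$d13Catm, true_gm = p$gm)
  })
}
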