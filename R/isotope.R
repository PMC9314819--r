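#' Isotopic fractionation constants for discrimination calculations
#'
#' Fractionation factors (per mil) used throughout the discrimination model:
#' diffusion across the stomata (`a`), through the boundary layer (`ab`),
#' dissolution plus liquid-phase diffusion at 25 C (`ai`), Rubisco
#' carboxylation (`b`), and photorespiration (`f`). `b` and `f` are stored as
#' positive magnitudes: the discrimination equations take them with positive
#' sign so that predicted discrimination and the photorespiratory term come
#' out positive, as observed. The respiratory fractionation `e` is not a
#' constant; it is computed per record as the offset between the tank and
#' atmospheric carbon isotope ratios.
#'
#' @param a,ab,ai,b,f Fractionations in per mil (all > 0).
#' @return Named list of constants.
#' @export
isotope_constants <- function(a = 4.4, ab = 2.9, ai = 1.8, b = 29, f = 11.6) {
  k <- list(a = a, ab = ab, ai = ai, b = b, f = f)
  if (any(unlist(k) <= 0)) stop("all fractionation magnitudes must be > 0")
  k
}

#' CO2 drawdown ratio of the open cuvette
#'
#' The ratio of the reference CO2 concentration entering the cuvette to the
#' net amount consumed by the leaf, `zeta = Ce / (Ce - Ca)`.
#'
#' @param Ce Reference (entering) CO2 (umol mol-1).
#' @param Ca CO2 leaving the cuvette after consumption (umol mol-1).
#' @return zeta (dimensionless).
#' @export
zeta <- function(Ce, Ca) {
  if (any(Ce == Ca))
    stop("Ce equals Ca: no net CO2 drawdown, reference/plant pair is degenerate")
  Ce / (Ce - Ca)
}

#' Observed photosynthetic 13C discrimination
#'
#' Computed from the carbon isotope ratios of air entering (`d13Ce`) and
#' leaving (`d13Ca`) the cuvette and the drawdown ratio zeta.
#'
#' @param d13Ca,d13Ce Isotope ratios (per mil) of unconsumed and reference CO2.
#' @param zeta Drawdown ratio from [zeta()].
#' @return Observed discrimination (per mil).
#' @export
observed_discrimination <- function(d13Ca, d13Ce, zeta) {
  denom <- 1000 + d13Ca - zeta * (d13Ca - d13Ce)
  if (any(denom <= 0))
    stop("implausible isotope pair: nonpositive denominator in observed discrimination")
  1000 * zeta * (d13Ca - d13Ce) / denom
}

#' Combined diffusional fractionation through boundary layer and stomata
#'
#' Weighted by the CO2 gradients across each segment of the diffusion path:
#' `a' = (ab (Ca - Cs) + a (Cs - Ci)) / (Ca - Ci)`.
#'
#' @param Ca,Cs,Ci CO2 at ambient, leaf surface, and substomatal cavity
#'   (umol mol-1).
#' @param constants [isotope_constants()].
#' @return a-prime (per mil).
#' @export
combined_fractionation <- function(Ca, Cs, Ci, constants = isotope_constants()) {
  if (any(Ca == Ci)) stop("Ca equals Ci: no diffusion gradient, a' undefined")
  (constants$ab * (Ca - Cs) + constants$a * (Cs - Ci)) / (Ca - Ci)
}

#' Ternary correction factor
#'
#' Accounts for the interaction of the transpiration flux with CO2 diffusion:
#' `t = (1 + a'/1000) E / (2 g_act)`, with a-prime converted from per mil to
#' fractional form.
#'
#' @param a_prime Combined diffusional fractionation (per mil).
#' @param E Transpiration rate (mol m-2 s-1).
#' @param g_act Combined boundary-layer and stomatal conductance to CO2
#'   (mol m-2 s-1).
#' @return t (dimensionless).
#' @export
ternary_t <- function(a_prime, E, g_act) {
  if (any(g_act <= 0)) stop("g_act must be > 0")
  if (any(E < 0)) stop("E must be >= 0")
  (1 + a_prime / 1000) * E / (2 * g_act)
}

#' Predicted discrimination from the Ca -> Ci gradient
#'
#' Discrimination expected if the only CO2 drawdown were across the boundary
#' layer and stomata:
#' `Di = a'/(1-t) + ((1+t) b - a') / (1-t) * Ci/Ca`.
#'
#' @param t Ternary correction from [ternary_t()].
#' @param a_prime Combined diffusional fractionation (per mil).
#' @param Ci,Ca Substomatal and ambient CO2 (umol mol-1).
#' @param constants [isotope_constants()].
#' @return Predicted discrimination (per mil).
#' @export
predicted_discrimination <- function(t, a_prime, Ci, Ca,
                                     constants = isotope_constants()) {
  if (any(t >= 1)) stop("ternary correction t must be < 1")
  (1 / (1 - t)) * a_prime +
    (1 / (1 - t)) * ((1 + t) * constants$b - a_prime) * (Ci / Ca)
}

#' Respiratory and photorespiratory discrimination components
#'
#' `e = d13Ce - d13Catm` (respired carbon carries the signature of carbon
#' fixed from tank air rather than greenhouse air);
#' `De = (1+t)/(1-t) * e Rd / ((An + Rd) Ca) * (Ci - GammaStar)`;
#' `Df = (1+t)/(1-t) * f GammaStar / Ca`.
#'
#' @param t Ternary correction factor.
#' @param record List or one-row data frame with fields `d13Ce`, `d13Catm`,
#'   `Rd`, `An`, `Ca`, `Ci`, `GammaStar`.
#' @param constants [isotope_constants()].
#' @return List with `delta_e`, `delta_f`, `e` (per mil).
#' @export
nonrubisco_discriminations <- function(t, record,
                                       constants = isotope_constants()) {
  r <- as.list(record)
  if (any(r$An + r$Rd == 0)) stop("An + Rd is zero: respiratory term undefined")
  if (any(r$Ca <= 0)) stop("Ca must be > 0")
  e <- r$d13Ce - r$d13Catm
  tf <- (1 + t) / (1 - t)
  delta_e <- tf * (e * r$Rd / ((r$An + r$Rd) * r$Ca)) * (r$Ci - r$GammaStar)
  delta_f <- tf * constants$f * r$GammaStar / r$Ca
  list(delta_e = delta_e, delta_f = delta_f, e = e)
}

#' Mesophyll conductance from combined gas exchange and 13C discrimination
#'
#' Compares predicted discrimination (diffusion down to Ci only) with the
#' observed discrimination; the shortfall, after removing respiratory and
#' photorespiratory components, is attributed to the Ci -> Cc drawdown and
#' inverted for mesophyll conductance:
#' `gm = (1+t)/(1-t) [b - ai - e Rd/(An+Rd)] (An/Ca) / (Di - Do - De - Df)`.
#' The chloroplast CO2 concentration follows as `Cc = Ci - An/gm`.
#'
#' @param record List or one-row data frame with fields `An`, `E`
#'   (mol m-2 s-1), `gact`, `Ca`, `Cs`, `Ci`, `Ce`, `Rd`, `GammaStar`,
#'   `d13Ca`, `d13Ce`, and optionally `d13Catm` (default -8).
#' @param constants [isotope_constants()].
#' @return A `discrimination_result` list: `zeta`, `a_prime`, `t`, `delta_o`,
#'   `delta_i`, `delta_e`, `delta_f`, `delta_gm`, `e`, `gm`
#'   (mol CO2 m-2 s-1), `Cc` (umol mol-1), and `flag` (`"ok"`,
#'   `"gm_unresolvable"` when the residual drawdown is nonpositive, or
#'   `"Cc_negative"`).
#' @export
estimate_gm <- function(record, constants = isotope_constants()) {
  r <- as.list(record)
  if (is.null(r$d13Catm)) r$d13Catm <- -8
  z <- zeta(r$Ce, r$Ca)
  a_prime <- combined_fractionation(r$Ca, r$Cs, r$Ci, constants)
  t <- ternary_t(a_prime, r$E, r$gact)
  delta_o <- observed_discrimination(r$d13Ca, r$d13Ce, z)
  delta_i <- predicted_discrimination(t, a_prime, r$Ci, r$Ca, constants)
  nr <- nonrubisco_discriminations(t, r, constants)
  delta_gm <- delta_i - delta_o - nr$delta_e - nr$delta_f

  num <- (1 + t) / (1 - t) *
    (constants$b - constants$ai - nr$e * r$Rd / (r$An + r$Rd)) *
    (r$An / r$Ca)
  if (delta_gm <= 0) {
    gm <- NA_real_
    Cc <- NA_real_
    flag <- "gm_unresolvable"
  } else {
    gm <- num / delta_gm
    Cc <- chloroplast_co2(r$Ci, r$An, gm)
    flag <- if (!is.na(Cc) && Cc < 0) "Cc_negative" else "ok"
  }
  structure(list(zeta = z, a_prime = a_prime, t = t,
                 delta_o = delta_o, delta_i = delta_i,
                 delta_e = nr$delta_e, delta_f = nr$delta_f,
                 delta_gm = delta_gm, e = nr$e,
                 gm = gm, Cc = Cc, flag = flag),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "<discrimination_result> gm = %.4g mol m-2 s-1, Cc = %.4g umol mol-1 [%s]\n",
    x$gm, x$Cc, x$flag))
  cat(sprintf("  Do %.3f | Di %.3f | De %.4f | Df %.4f | Dgm %.3f permil\n",
              x$delta_o, x$delta_i, x$delta_e, x$delta_f, x$delta_gm))
  invisible(x)
}

#' Chloroplast CO2 concentration
#'
#' `Cc = Ci - An / gm`. A negative result (possible with noisy inputs) is
#' returned as-is; callers flag it.
#'
#' @param Ci Substomatal CO2 (umol mol-1).
#' @param An Net assimilation (umol m-2 s-1).
#' @param gm Mesophyll conductance (mol m-2 s-1, > 0).
#' @return Cc (umol mol-1).
#' @export
chloroplast_co2 <- function(Ci, An, gm) {
  if (any(gm <= 0)) stop("gm must be > 0")
  Ci - An / gm
}

#' Estimate mesophyll conductance for a table of records
#'
#' Applies [estimate_gm()] row-wise to a record table using the documented
#' CSV header (`An,E_mmol,gact,Ca,Cs,Ci,Ce,Rd,GammaStar,d13Ca,d13Ce` and
#' optionally `d13Catm`). Transpiration is accepted in mmol m-2 s-1, as
#' gas-exchange systems report it, and converted internally.
#'
#' @param records Data frame with the columns above.
#' @param constants [isotope_constants()].
#' @return The input with appended columns `zeta`, `a_prime`, `t`, `delta_o`,
#'   `delta_i`, `delta_e`, `delta_f`, `delta_gm`, `gm`, `Cc`, `flag`.
#' @export
estimate_gm_batch <- function(records, constants = isotope_constants()) {
  need <- c("An", "E_mmol", "gact", "Ca", "Cs", "Ci", "Ce", "Rd",
            "GammaStar", "d13Ca", "d13Ce")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- as.list(records[i, ])
    r$E <- r$E_mmol / 1000
    res <- estimate_gm(r, constants)
    out[[i]] <- data.frame(zeta = res$zeta, a_prime = res$a_prime, t = res$t,
                           delta_o = res$delta_o, delta_i = res$delta_i,
                           delta_e = res$delta_e, delta_f = res$delta_f,
                           delta_gm = res$delta_gm, gm = res$gm, Cc = res$Cc,
                           flag = res$flag)
  }
  cbind(records, do.call(rbind, out))
}

#' Pair plant samples with bracketing reference samples
#'
#' In open-cuvette sampling, reference (empty-chamber) vials alternate with
#' plant vials. Each plant sample's reference isotope ratio is taken as the
#' mean of its two bracketing reference samples, falling back to the single
#' neighbor at sequence ends.
#'
#' @param d13C Isotope ratios (per mil) in sampling order.
#' @param is_reference Logical, `TRUE` for reference samples.
#' @return Numeric vector, one entry per plant sample: the bracketing-mean
#'   reference value (named by plant sample position in the sequence).
#' @export
average_bracketing_refs <- function(d13C, is_reference) {
  stopifnot(length(d13C) == length(is_reference))
  refs <- which(is_reference)
  if (!length(refs)) stop("no reference samples in sequence")
  plants <- which(!is_reference)
  out <- vapply(plants, function(i) {
    before <- refs[refs < i]
    after <- refs[refs > i]
    nb <- c(if (length(before)) max(before), if (length(after)) min(after))
    mean(d13C[nb])
  }, numeric(1))
  stats::setNames(out, plants)
}

#' Read a gas-exchange/isotope record table from CSV
#'
#' Expects the documented header used by [estimate_gm_batch()].
#'
#' @param path CSV file path.
#' @return Data frame of records.
#' @export
read_isotope_records <- function(path) {
  df <- utils::read.csv(path)
  need <- c("An", "E_mmol", "gact", "Ca", "Cs", "Ci", "Ce", "Rd",
            "GammaStar", "d13Ca", "d13Ce")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("record CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}
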