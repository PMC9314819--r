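# Leaflet hydraulics, stomatal anatomy, FvCB A-Ci fitting and the
# divided-alpha pairwise testing convention.

#' Leaflet hydraulic conductance by the evaporative flux method
#'
#' `K_leaflet = E / (Psi_bagged - Psi_unbagged)`: transpiration divided by
#' the water-potential drop between a non-transpiring (bagged, equilibrated)
#' leaflet and a transpiring one on the same leaf. The bagged leaflet of a
#' transpiring plant is the less negative of the pair.
#'
#' @param E Transpiration rate (mmol m-2 s-1).
#' @param psi_bagged,psi_unbagged Water potentials (MPa).
#' @return K_leaflet (mmol m-2 s-1 MPa-1). A negative driving gradient
#'   (bagged more negative than unbagged) yields a negative value with a
#'   warning so the record can be screened.
#' @export
k_leaflet <- function(E, psi_bagged, psi_unbagged) {
  dpsi <- psi_bagged - psi_unbagged
  if (any(dpsi == 0))
    stop("zero water-potential difference: conductance undefined")
  if (any(dpsi < 0))
    warning("negative driving gradient (bagged more negative than unbagged); ",
            "flagging by returning negative conductance")
  E / dpsi
}

#' Stomatal anatomy metrics and anatomical maximum conductance
#'
#' Aperture ratio (inner pore width / inner pore length), stomate size
#' (guard-cell length x guard-cell pair total width), and the anatomical
#' maximum stomatal conductance to water vapor
#' `g_smax = (d_w / v) SD a_max / (l + (pi/2) sqrt(a_max / pi))`,
#' where `a_max` is the elliptical maximal pore area from the inner pore
#' axes, `l` the pore depth (taken as the width of a single guard cell,
#' i.e. half the pair width), `SD` the stomatal density, `d_w` the
#' diffusivity of water vapor in air and `v` the molar volume of air.
#'
#' @param pore_length_um,pore_width_um Inner pore axes (um, > 0).
#' @param gc_length_um Guard-cell length (um, > 0).
#' @param gc_pair_width_um Total width of the closed guard-cell pair (um).
#' @param density_mm2 Stomatal density (mm-2, > 0 for `g_smax`).
#' @param d_w Water-vapor diffusivity (m2 s-1).
#' @param v_air Molar volume of air (m3 mol-1).
#' @return Named list: `aperture_ratio`, `size_um2`, `a_max_um2`,
#'   `pore_depth_um`, `g_smax` (mol m-2 s-1).
#' @export
stomatal_metrics <- function(pore_length_um, pore_width_um, gc_length_um,
                             gc_pair_width_um, density_mm2,
                             d_w = 2.49e-5, v_air = 0.0224) {
  if (any(c(pore_length_um, pore_width_um, gc_length_um,
            gc_pair_width_um) <= 0))
    stop("all stomatal dimensions must be > 0")
  if (any(density_mm2 <= 0)) stop("stomatal density must be > 0")
  a_max_um2 <- pi * (pore_length_um / 2) * (pore_width_um / 2)
  pore_depth_um <- gc_pair_width_um / 2
  a_max <- a_max_um2 * 1e-12
  l <- pore_depth_um * 1e-6
  sd_m2 <- density_mm2 * 1e6
  list(aperture_ratio = pore_width_um / pore_length_um,
       size_um2 = gc_length_um * gc_pair_width_um,
       a_max_um2 = a_max_um2,
       pore_depth_um = pore_depth_um,
       g_smax = (d_w / v_air) * sd_m2 * a_max / (l + (pi / 2) * sqrt(a_max / pi)))
}

#' FvCB net assimilation
#'
#' Two-limitation Farquhar-von Caemmerer-Berry model:
#' `A = min(Wc, Wj) - Rd` with Rubisco-limited
#' `Wc = Vcmax (Ci - GammaStar) / (Ci + Km)` and RuBP-regeneration-limited
#' `Wj = J (Ci - GammaStar) / (4 Ci + 8 GammaStar)`.
#'
#' @param Ci Substomatal CO2 (umol mol-1).
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param J Electron transport rate (umol m-2 s-1).
#' @param Rd Day respiration (umol m-2 s-1).
#' @param GammaStar Photocompensation point (umol mol-1).
#' @param Km Effective Michaelis-Menten constant of Rubisco in air
#'   (umol mol-1); default `Kc (1 + O/Ko)` at 25 C.
#' @return Net assimilation (umol m-2 s-1).
#' @export
fvcb_assimilation <- function(Ci, Vcmax, J, Rd, GammaStar, Km = 710.3) {
  wc <- Vcmax * (Ci - GammaStar) / (Ci + Km)
  wj <- J * (Ci - GammaStar) / (4 * Ci + 8 * GammaStar)
  pmin(wc, wj) - Rd
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Joint least-squares fit of `A = min(Wc, Wj) - Rd` over the whole curve
#' (no pre-assignment of points to limitation regimes), followed by
#' per-point labelling by the smaller limitation at the optimum. `GammaStar`
#' and `Km` are fixed caller-supplied kinetics; `Vcmax`, `J` and `Rd` are
#' estimated on a log scale.
#'
#' @param data Data frame with columns `Ci` and `An` (>= 6 points spanning
#'   both limitation regimes for a fully identified fit).
#' @param GammaStar,Km Kinetic constants (umol mol-1).
#' @param start Optional named start values `Vcmax`, `J`, `Rd`.
#' @return An object of class `fvcb_fit`: `coefficients` (Vcmax, J, Rd),
#'   `A_max` (fitted A at Ci = 1500), `limitation` (per-point
#'   `"Rubisco"`/`"RuBP"`), `fitted`, `residuals`, `unidentified` (character
#'   vector of parameters with no points in their regime).
#' @export
fit_aci <- function(data, GammaStar = 40, Km = 710.3, start = NULL) {
  if (!all(c("Ci", "An") %in% names(data)))
    stop("data must have columns Ci and An")
  if (nrow(data) < 6) stop("need at least 6 A-Ci points")
  Ci <- data$Ci
  An <- data$An
  obj <- function(lp) {
    p <- exp(lp)
    sum((An - fvcb_assimilation(Ci, p[1], p[2], p[3], GammaStar, Km))^2)
  }
  starts <- if (!is.null(start)) {
    list(log(unname(start[c("Vcmax", "J", "Rd")])))
  } else {
    # seed the search over plausible day-respiration values: carboxylation
    # capacity from the low-CO2 arm, electron transport from the high arm
    lapply(unique(c(max(0.5, -min(An)), 1, 2, 4)), function(rd0) {
      lo <- Ci <= stats::quantile(Ci, 0.5)
      hi <- Ci >= 0.8 * max(Ci)
      v0 <- stats::median((An[lo] + rd0) * (Ci[lo] + Km) /
                            pmax(Ci[lo] - GammaStar, 1))
      j0 <- stats::median((An[hi] + rd0) * (4 * Ci[hi] + 8 * GammaStar) /
                            pmax(Ci[hi] - GammaStar, 1))
      log(c(max(v0, 5), max(j0, 5), rd0))
    })
  }
  # Nelder-Mead with restarts: robust to the kink of the two-limitation min
  best <- NULL
  for (s0 in starts) {
    cand <- stats::optim(s0, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
    cand <- stats::optim(cand$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  polish <- stats::nlminb(best$par, obj,
                          control = list(rel.tol = 1e-14, iter.max = 500))
  fit <- if (polish$objective < best$value)
    list(par = polish$par, value = polish$objective) else best
  p <- exp(fit$par)
  names(p) <- c("Vcmax", "J", "Rd")
  wc <- p[1] * (Ci - GammaStar) / (Ci + Km)
  wj <- p[2] * (Ci - GammaStar) / (4 * Ci + 8 * GammaStar)
  limitation <- ifelse(wc <= wj, "Rubisco", "RuBP")
  # a parameter whose regime claims at most one point is not identified
  unident <- c(if (sum(limitation == "Rubisco") <= 1) "Vcmax",
               if (sum(limitation == "RuBP") <= 1) "J")
  if (length(unident))
    warning("all points fall in one limitation regime; ",
            paste(unident, collapse = ", "), " not identified")
  fitted <- fvcb_assimilation(Ci, p[1], p[2], p[3], GammaStar, Km)
  structure(list(coefficients = p,
                 A_max = fvcb_assimilation(1500, p[1], p[2], p[3],
                                           GammaStar, Km),
                 GammaStar = GammaStar, Km = Km,
                 limitation = limitation, fitted = fitted,
                 residuals = An - fitted,
                 unidentified = unident %||% character(0)),
            class = "fvcb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fvcb_fit <- function(x, ...) {
  cat(sprintf(
    "<fvcb_fit> Vcmax = %.2f, J = %.2f, Rd = %.2f umol m-2 s-1; A_max = %.2f\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3], x$A_max))
  cat("  limitation:", paste(table(x$limitation), names(table(x$limitation)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Divided significance threshold for pairwise testing
#'
#' The comparison-wise threshold obtained by dividing the family alpha by
#' the number of mean pairs per test (a Bonferroni division). The raw
#' quotient is retained; the reported value is rounded to 4 decimals.
#'
#' @param alpha Family-wise significance level.
#' @param n_pairs Number of mean pairs (>= 1).
#' @return Object of class `adjusted_alpha`: list `alpha`, `n_pairs`, `raw`,
#'   `reported`.
#' @export
adjusted_alpha <- function(alpha = 0.05, n_pairs) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  raw <- alpha / n_pairs
  structure(list(alpha = alpha, n_pairs = n_pairs, raw = raw,
                 reported = round(raw, 4)),
            class = "adjusted_alpha")
}

#' @export
print.adjusted_alpha <- function(x, ...) {
  cat(sprintf("adjusted alpha = %g (%g / %d pairs; reported %.4f)\n",
              x$raw, x$alpha, x$n_pairs, x$reported))
  invisible(x)
}

#' Pairwise Welch comparisons across groups
#'
#' Welch two-sample t tests for every unordered pair of group levels, with
#' significance flagged at the divided threshold [adjusted_alpha()] for the
#' number of pairs actually tested. When a reference level is given (e.g.
#' the well-watered treatment), the percent change of each group mean
#' relative to the reference mean is attached.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param reference Optional reference level for percent change.
#' @param alpha Family-wise alpha.
#' @return Data frame with one row per pair: `group1`, `group2`, `mean1`,
#'   `mean2`, `n1`, `n2`, `p_value`, `significant`. Attributes:
#'   `adjusted_alpha` (the [adjusted_alpha()] object) and, when `reference`
#'   is set, `percent_change` (data frame `group`, `mean`, `pct_change`).
#' @export
pairwise_compare <- function(data, value, group, reference = NULL,
                             alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (is.null(v) || is.null(data[[group]]))
    stop("columns not found: ", value, " / ", group)
  lev <- levels(g)
  if (length(lev) < 2) stop("need at least two groups")
  pairs <- utils::combn(lev, 2)
  aa <- adjusted_alpha(alpha, ncol(pairs))
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- v[g == pairs[1, k]]
    b <- v[g == pairs[2, k]]
    if (length(a) < 2 || length(b) < 2) {
      warning("skipping pair ", pairs[1, k], " vs ", pairs[2, k],
              ": fewer than 2 observations in a group")
      rows[[k]] <- data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                              mean1 = mean(a), mean2 = mean(b),
                              n1 = length(a), n2 = length(b),
                              p_value = NA_real_, significant = NA)
      next
    }
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
             mean(a) == mean(b)) 1 else
      stats::t.test(a, b, var.equal = FALSE)$p.value
    rows[[k]] <- data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                            mean1 = mean(a), mean2 = mean(b),
                            n1 = length(a), n2 = length(b),
                            p_value = p, significant = p < aa$raw)
  }
  out <- do.call(rbind, rows)
  attr(out, "adjusted_alpha") <- aa
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference level not found: ", reference)
    mref <- mean(v[g == reference])
    means <- tapply(v, g, mean)
    attr(out, "percent_change") <-
      data.frame(group = lev, mean = as.numeric(means),
                 pct_change = 100 * (as.numeric(means) - mref) / mref)
  }
  out
}

#' Simulate an A-Ci curve from known FvCB parameters
#'
#' Evaluates [fvcb_assimilation()] on a Ci grid spanning sub- and
#' supra-ambient CO2 and adds Gaussian noise. The true parameters travel
#' with the table (as attributes) for recovery tests.
#'
#' @param Vcmax,J,Rd,GammaStar,Km FvCB parameters (all > 0).
#' @param Ci_grid CO2 grid (umol mol-1); default mirrors a standard
#'   50-1500 ppm protocol.
#' @param noise_sd Gaussian SD on A (umol m-2 s-1).
#' @param seed Integer seed.
#' @return Data frame `Ci`, `An` with attributes `true_pars` (named vector)
#'   and `GammaStar`, `Km`.
#' @export
generate_aci_curve <- function(Vcmax = 100, J = 150, Rd = 1.5,
                               GammaStar = 40, Km = 710.3,
                               Ci_grid = c(50, 80, 100, 150, 200, 400, 600,
                                           800, 1000, 1200, 1500),
                               noise_sd = 0, seed = 1L) {
  if (any(c(Vcmax, J, Rd, GammaStar, Km) <= 0))
    stop("all FvCB parameters must be > 0")
  with_seed(seed, {
    An <- fvcb_assimilation(Ci_grid, Vcmax, J, Rd, GammaStar, Km) +
      stats::rnorm(length(Ci_grid), sd = noise_sd)
    out <- data.frame(Ci = Ci_grid, An = An)
    attr(out, "true_pars") <- c(Vcmax = Vcmax, J = J, Rd = Rd)
    attr(out, "GammaStar") <- GammaStar
    attr(out, "Km") <- Km
    out
  })
}
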