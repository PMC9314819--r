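# Stomate-seeded distance fields, tortuosity, lateral path lengthening and
# intercellular-airspace conductance.

R_GAS <- 8.31446261815324  # J mol-1 K-1

lin_index <- function(d, zyx) {
  # 1-based (z,y,x) matrix -> 1-based linear index into a (nz,ny,nx) array
  (zyx[, 3] - 1L) * d[1] * d[2] + (zyx[, 2] - 1L) * d[1] + zyx[, 1]
}

#' Detect stomata as airspace perforations of the abaxial epidermis
#'
#' A stomate appears in a segmented stack as IAS-labelled voxels inside the
#' abaxial epidermis that are face-adjacent to the background outside the
#' leaf. All such pore-mouth voxels are returned as seeds, so a wide pore
#' contributes several seed voxels.
#'
#' @param volume A [labeled_volume()].
#' @return Integer matrix with columns `z`, `y`, `x` (1-based voxel
#'   coordinates).
#' @export
detect_stomata <- function(volume) {
  lab <- volume$labels
  d <- dim(lab)
  iasm <- tissue_mask(volume, "ias")
  bg <- tissue_mask(volume, "background")
  touch <- iasm & (shift3(bg, c(1L, 0L, 0L)) | shift3(bg, c(-1L, 0L, 0L)) |
                     shift3(bg, c(0L, 1L, 0L)) | shift3(bg, c(0L, -1L, 0L)) |
                     shift3(bg, c(0L, 0L, 1L)) | shift3(bg, c(0L, 0L, -1L)))
  idx <- which(touch)
  if (!length(idx))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  z <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  y <- rest %% d[2] + 1L
  x <- rest %/% d[2] + 1L
  # keep abaxial-side perforations only (below the leaf mid-depth)
  leaf_z <- range(which(apply(!bg, 1, any)))
  keep <- z > mean(leaf_z)
  cbind(z = z[keep], y = y[keep], x = x[keep])
}

#' Stomate-seeded distance fields over the airspace
#'
#' Computes the three distance maps underlying tortuosity and lateral path
#' lengthening: `L_geo`, the within-airspace geodesic distance from the
#' nearest stomate (shortest-path propagation restricted to IAS voxels over
#' a quasi-Euclidean move neighborhood); `L_Euc`, the unobstructed
#' straight-line distance from the nearest stomate (exact Euclidean distance
#' transform); and `L_epi`, the straight-line distance to the abaxial
#' epidermis layer (its voxels plus the stomatal pores that perforate it).
#' Because the stomata are part of the epidermis-layer seed set,
#' `L_Euc >= L_epi` holds everywhere by construction, and because each
#' geodesic step weight equals its Euclidean length, `L_geo >= L_Euc`.
#'
#' IAS voxels not connected to any stomate keep `L_geo = Inf`; their
#' fraction is reported as `1 - reachable_fraction`.
#'
#' @param volume A [labeled_volume()].
#' @param stomata Optional integer matrix of seed voxels (columns `z,y,x`,
#'   1-based); defaults to [detect_stomata()]. Every seed must be an IAS
#'   voxel.
#' @param nb_order Geodesic move-neighborhood half-width: 1 gives the
#'   26-neighbor (1, sqrt 2, sqrt 3) chamfer metric; higher orders add longer
#'   primitive moves with line-of-sight checks, shrinking the free-space
#'   metric overestimate to well under 1% on average (the default).
#' @return An object of class `distance_fields`: arrays `L_geo`, `L_Euc`,
#'   `L_epi` (um, volume-shaped), the `stomata` seed matrix, `voxel_um`,
#'   `nb_order` and `reachable_fraction`.
#' @export
distance_fields <- function(volume, stomata = NULL, nb_order = 4L) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (is.null(stomata)) stomata <- detect_stomata(volume)
  stomata <- as.matrix(stomata)
  if (nrow(stomata) == 0)
    stop("no stomata: supply seed coordinates or use a volume with ",
         "abaxial perforations")
  d <- dim(volume$labels)
  iasm <- tissue_mask(volume, "ias")
  seeds_lin <- lin_index(d, stomata)
  bad <- which(!iasm[seeds_lin])
  if (length(bad))
    stop("stomate seed(s) not inside the airspace (rows ",
         paste(bad, collapse = ", "), ")")

  h <- volume$voxel_um
  lg <- cpp_geodesic(d, as.vector(iasm), as.integer(seeds_lin - 1L),
                     as.integer(nb_order))
  L_geo <- array(lg * h, d)

  seed_mask <- array(FALSE, d)
  seed_mask[seeds_lin] <- TRUE
  L_euc <- array(cpp_edt(d, as.vector(seed_mask)) * h, d)

  epi_mask <- tissue_mask(volume, "epidermis_abaxial")
  epi_mask[seeds_lin] <- TRUE
  L_epi <- array(cpp_edt(d, as.vector(epi_mask)) * h, d)

  structure(list(L_geo = L_geo, L_Euc = L_euc, L_epi = L_epi,
                 stomata = stomata, voxel_um = h,
                 nb_order = as.integer(nb_order),
                 reachable_fraction = mean(is.finite(L_geo[iasm]))),
            class = "distance_fields")
}

#' @export
print.distance_fields <- function(x, ...) {
  cat(sprintf(
    "<distance_fields> %s voxels, %d stomata, %.1f%% of IAS reachable\n",
    paste(dim(x$L_geo), collapse = " x "), nrow(x$stomata),
    100 * x$reachable_fraction))
  invisible(x)
}

# IAS voxels face-adjacent to mesophyll cells: the evaluation surface for
# tortuosity and path lengthening.
mesophyll_edge <- function(volume) {
  iasm <- tissue_mask(volume, "ias")
  cell <- tissue_mask(volume, "mesophyll_cell")
  iasm & (shift3(cell, c(1L, 0L, 0L)) | shift3(cell, c(-1L, 0L, 0L)) |
            shift3(cell, c(0L, 1L, 0L)) | shift3(cell, c(0L, -1L, 0L)) |
            shift3(cell, c(0L, 0L, 1L)) | shift3(cell, c(0L, 0L, -1L)))
}

#' Leaf-level diffusive tortuosity
#'
#' Per-voxel tortuosity `(L_geo / L_Euc)^2`, evaluated at airspace voxels
#' adjacent to mesophyll cells (the cell-surface edge of the airspace), and
#' averaged (voxel-weighted arithmetic mean). Voxels unreachable from any
#' stomate, and seed voxels where `L_Euc = 0`, are excluded.
#'
#' @param fields [distance_fields()] computed on `volume`.
#' @param volume The matching [labeled_volume()].
#' @return Tortuosity tau_leaf (m2 m-2, >= 1).
#' @export
leaf_tortuosity <- function(fields, volume) {
  edge <- mesophyll_edge(volume)
  ok <- edge & is.finite(fields$L_geo) & fields$L_Euc > 0
  if (!any(ok))
    stop("no reachable mesophyll-edge airspace voxels; tortuosity undefined")
  mean((fields$L_geo[ok] / fields$L_Euc[ok])^2)
}

#' Leaf-level lateral path lengthening
#'
#' Per-voxel ratio `L_Euc / L_epi` (straight-line distance to the nearest
#' stomate over perpendicular distance to the abaxial epidermis), averaged
#' over airspace voxels adjacent to mesophyll cells. Captures the extra
#' lateral distance imposed by discrete stomatal spacing. Voxels with
#' `L_epi = 0` are excluded.
#'
#' @inheritParams leaf_tortuosity
#' @return lambda_leaf (m m-1, >= 1).
#' @export
leaf_path_lengthening <- function(fields, volume) {
  edge <- mesophyll_edge(volume)
  ok <- edge & fields$L_epi > 0
  if (!any(ok))
    stop("no mesophyll-edge airspace voxels with positive epidermis distance")
  mean(fields$L_Euc[ok] / fields$L_epi[ok])
}

#' Intercellular airspace conductance
#'
#' Gas-phase conductance of the mesophyll airspace for a hypostomatous leaf,
#' `g_IAS = theta_IAS D_m / (0.5 L_mes tau_leaf lambda_leaf)`, with the
#' diffusion path length taken as half the mesophyll thickness. The velocity
#' form (m s-1) is converted to a molar flux basis by the ideal-gas molar
#' density `P / (R T)`, giving mol m-2 s-1 bar-1.
#'
#' @param theta_ias Mesophyll porosity (m3 m-3).
#' @param tau_leaf Tortuosity (>= 1).
#' @param lambda_leaf Lateral path lengthening (>= 1).
#' @param L_mes_m Mesophyll thickness in meters.
#' @param D_m Diffusivity of CO2 in air (m2 s-1); default 1.54e-5 at 25 C.
#' @param temperature Kelvin.
#' @param pressure Bar.
#' @return g_IAS (mol m-2 s-1 bar-1).
#' @export
g_ias <- function(theta_ias, tau_leaf, lambda_leaf, L_mes_m,
                  D_m = 1.54e-5, temperature = 298.15, pressure = 1) {
  vals <- c(theta_ias, tau_leaf, lambda_leaf, L_mes_m, D_m, temperature,
            pressure)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all g_IAS inputs must be positive and finite")
  vel <- theta_ias * D_m / (0.5 * L_mes_m * tau_leaf * lambda_leaf)
  vel * (pressure * 1e5) / (R_GAS * temperature)
}

#' Share of mesophyll resistance residing in the gas phase
#'
#' With the airspace conductance in series within total mesophyll
#' conductance, the gas-phase share of total resistance is
#' `(1/g_IAS) / (1/g_m) = g_m / g_IAS`.
#'
#' @param g_m Total mesophyll conductance (mol m-2 s-1, same basis as
#'   `g_IAS`).
#' @param g_IAS Airspace conductance (mol m-2 s-1).
#' @return Fraction in `(0, 1]`.
#' @export
gias_contribution <- function(g_m, g_IAS) {
  if (any(g_m <= 0) || any(g_IAS <= 0)) stop("conductances must be > 0")
  if (any(g_m > g_IAS))
    stop("g_m exceeds g_IAS: a series component cannot be smaller than ",
         "the total conductance")
  g_m / g_IAS
}

#' Full diffusion-trait pipeline for one volume
#'
#' Convenience wrapper: porosity, distance fields, tortuosity, lateral path
#' lengthening, mesophyll thickness and airspace conductance in one call.
#'
#' @param volume A [labeled_volume()].
#' @param stomata Optional seed matrix, as in [distance_fields()].
#' @param nb_order Geodesic neighborhood order (see [distance_fields()]).
#' @param D_m,temperature,pressure Passed to [g_ias()].
#' @return Named list: `theta_ias`, `tau_leaf`, `lambda_leaf`, `L_mes_um`,
#'   `g_ias`, `reachable_fraction`, plus the `fields` object.
#' @export
diffusion_traits <- function(volume, stomata = NULL, nb_order = 4L,
                             D_m = 1.54e-5, temperature = 298.15,
                             pressure = 1) {
  fields <- distance_fields(volume, stomata, nb_order)
  th <- thicknesses(volume)
  theta <- porosity(volume)
  tau <- leaf_tortuosity(fields, volume)
  lam <- leaf_path_lengthening(fields, volume)
  list(theta_ias = theta, tau_leaf = tau, lambda_leaf = lam,
       L_mes_um = th[["L_mes"]],
       g_ias = g_ias(theta, tau, lam, th[["L_mes"]] * 1e-6, D_m,
                     temperature, pressure),
       reachable_fraction = fields$reachable_fraction,
       fields = fields)
}
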