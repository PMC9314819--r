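# Scalar and depth-resolved anatomical traits from segmented leaf volumes.

# out[i] = a[i + s] with zero/FALSE fill; s = c(dz, dy, dx)
shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  idx <- vector("list", 3)
  src <- vector("list", 3)
  for (k in 1:3) {
    if (s[k] >= 0) {
      idx[[k]] <- seq_len(max(d[k] - s[k], 0))
    } else {
      idx[[k]] <- seq(1 - s[k], d[k])
    }
    src[[k]] <- idx[[k]] + s[k]
  }
  if (all(lengths(idx) > 0))
    out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mesophyll porosity
#'
#' Fraction of the mesophyll occupied by intercellular airspace:
#' `N_IAS / (N_IAS + N_mesophyll-cell)`. Bundle-sheath extensions and veins
#' are excluded from both numerator and denominator by default; pass their
#' tissue names in `denominator_extra` to count them as mesophyll area.
#'
#' @param volume A [labeled_volume()].
#' @param denominator_extra Additional tissue names counted in the
#'   denominator (e.g. `c("bse", "vein")`).
#' @return Porosity in `[0, 1]` (m3 m-3).
#' @export
porosity <- function(volume, denominator_extra = character()) {
  cnt <- tissue_counts(volume)
  n_ias <- cnt[["ias"]]
  denom <- n_ias + cnt[["mesophyll_cell"]] + sum(cnt[denominator_extra])
  if (denom == 0)
    stop("volume contains no mesophyll (no mesophyll-cell or IAS voxels)")
  n_ias / denom
}

#' Airspace to mesophyll-cell volume ratio
#'
#' `V_IAS / V_mes-cell`, equal to `theta / (1 - theta)` for porosity theta.
#'
#' @param volume A [labeled_volume()].
#' @return Ratio (m3 m-3).
#' @export
vias_to_vcell <- function(volume) {
  cnt <- tissue_counts(volume)
  if (cnt[["mesophyll_cell"]] == 0)
    stop("volume contains no mesophyll-cell voxels; ratio undefined")
  cnt[["ias"]] / cnt[["mesophyll_cell"]]
}

#' Mesophyll surface area exposed to airspace, per mesophyll volume
#'
#' Estimates the area of the mesophyll-cell/IAS interface with a
#' normal-weighted exposed-face method: each voxel face separating a cell
#' voxel from an IAS voxel contributes its face area weighted by
#' `1 / ||n||_1` of the local unit surface normal, estimated from the
#' gradient of a Gaussian-smoothed cell indicator. The weighting removes the
#' systematic overestimate (up to 50% on oblique surfaces) of naive face
#' counting; the estimator is exact for axis-aligned planes and accurate to
#' a few percent on curved interfaces at radii of tens of voxels. The
#' denominator is the total mesophyll volume (cells + airspace).
#'
#' @param volume A [labeled_volume()].
#' @param sigma_vox Smoothing scale for normal estimation (voxels).
#' @return SA_mes/V_mes in um2 um-3.
#' @export
sa_mes_per_vmes <- function(volume, sigma_vox = 1.5) {
  cell <- tissue_mask(volume, "mesophyll_cell")
  iasm <- tissue_mask(volume, "ias")
  n_cell <- sum(cell)
  n_ias <- sum(iasm)
  if (n_cell + n_ias == 0)
    stop("volume contains no mesophyll")
  if (n_cell == 0 || n_ias == 0) {
    warning("no mesophyll-cell/IAS interface (porosity 0 or 1); returning 0")
    return(0)
  }
  sm <- gauss_smooth3(cell * 1.0, sigma_vox)
  # replicate-edge central differences: constant directions keep zero gradient
  shift_clamp <- function(a, s) {
    d <- dim(a)
    ix <- lapply(1:3, function(k) pmin(pmax(seq_len(d[k]) + s[k], 1L), d[k]))
    a[ix[[1]], ix[[2]], ix[[3]]]
  }
  gz <- (shift_clamp(sm, c(1L, 0L, 0L)) - shift_clamp(sm, c(-1L, 0L, 0L))) / 2
  gy <- (shift_clamp(sm, c(0L, 1L, 0L)) - shift_clamp(sm, c(0L, -1L, 0L))) / 2
  gx <- (shift_clamp(sm, c(0L, 0L, 1L)) - shift_clamp(sm, c(0L, 0L, -1L))) / 2

  dirs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  area_w <- 0
  for (k in seq_len(nrow(dirs))) {
    s <- dirs[k, ]
    face <- cell & shift3(iasm, s)
    if (!any(face)) next
    nz <- (gz[face] + shift3(gz, s)[face]) / 2
    ny <- (gy[face] + shift3(gy, s)[face]) / 2
    nx <- (gx[face] + shift3(gx, s)[face]) / 2
    l2 <- sqrt(nz^2 + ny^2 + nx^2)
    l1 <- abs(nz) + abs(ny) + abs(nx)
    w <- ifelse(l1 > 1e-12, l2 / l1, 1)
    area_w <- area_w + sum(w)
  }
  h <- volume$voxel_um
  (area_w * h^2) / ((n_cell + n_ias) * h^3)
}

# per-column helper: (ny*nx) matrices of z-extent and counts
column_stats <- function(mask) {
  d <- dim(mask)
  mm <- matrix(mask, d[1])
  counts <- colSums(mm)
  zi <- row(mm)
  zmax <- apply(ifelse(mm, zi, -Inf), 2, max)
  zmin <- apply(ifelse(mm, zi, Inf), 2, min)
  list(counts = counts, zmin = zmin, zmax = zmax,
       extent = ifelse(counts > 0, zmax - zmin + 1, 0))
}

#' Leaf, mesophyll and epidermal thicknesses
#'
#' Axis-aligned per-column z-extents of each tissue, averaged over all
#' (y, x) columns that intersect the leaf, in micrometers. Leaf thickness is
#' the extent of all non-background labels; mesophyll thickness the extent
#' of mesophyll cells, airspace, BSEs and veins; epidermal thicknesses are
#' per-column voxel counts of each epidermis.
#'
#' @param volume A [labeled_volume()].
#' @return Named numeric: `L_leaf`, `L_mes`, `L_epi_adaxial`,
#'   `L_epi_abaxial` (um).
#' @export
thicknesses <- function(volume) {
  cnt <- tissue_counts(volume)
  if (cnt[["epidermis_adaxial"]] == 0 || cnt[["epidermis_abaxial"]] == 0)
    stop("both epidermes must be present to measure thicknesses")
  leaf <- !tissue_mask(volume, "background")
  mes <- tissue_mask(volume, c("mesophyll_cell", "ias", "bse", "vein"))
  ad <- tissue_mask(volume, "epidermis_adaxial")
  ab <- tissue_mask(volume, "epidermis_abaxial")
  sl <- column_stats(leaf)
  keep <- sl$counts > 0
  sm <- column_stats(mes)
  h <- volume$voxel_um
  c(L_leaf = mean(sl$extent[keep]) * h,
    L_mes = mean(sm$extent[keep]) * h,
    L_epi_adaxial = mean(colSums(matrix(ad, dim(ad)[1]))[keep]) * h,
    L_epi_abaxial = mean(colSums(matrix(ab, dim(ab)[1]))[keep]) * h)
}

#' Porosity profile across mesophyll depth
#'
#' Bins mesophyll voxels (cells + airspace; epidermes, BSEs and veins
#' excluded) by relative depth, normalized per column to that column's
#' mesophyll extent (0% = adaxial mesophyll edge, 100% = abaxial edge), and
#' reports the airspace fraction per bin. The voxel-weighted mean of the bin
#' porosities reproduces the scalar [porosity()] exactly.
#'
#' @param volume A [labeled_volume()].
#' @param n_bins Number of depth bins (>= 5).
#' @return Data frame `depth_pct` (bin centers), `porosity`, `n_vox`.
#' @export
porosity_depth_profile <- function(volume, n_bins = 20L) {
  if (n_bins < 5) stop("n_bins must be >= 5")
  lm <- volume$label_map
  lab <- volume$labels
  d <- dim(lab)
  mes <- lab == lm[["mesophyll_cell"]] | lab == lm[["ias"]]
  cs <- column_stats(mes)
  idx <- which(mes)
  z <- (idx - 1L) %% d[1] + 1L
  col <- (idx - 1L) %/% d[1] + 1L
  rel <- (z - cs$zmin[col] + 0.5) / cs$extent[col] * 100
  bin <- pmin(pmax(ceiling(rel / (100 / n_bins)), 1L), n_bins)
  is_ias <- lab[idx] == lm[["ias"]]
  n_vox <- tabulate(bin, n_bins)
  n_ias <- tabulate(bin[is_ias], n_bins)
  data.frame(depth_pct = (seq_len(n_bins) - 0.5) * 100 / n_bins,
             porosity = ifelse(n_vox > 0, n_ias / n_vox, NA_real_),
             n_vox = n_vox)
}

#' Bundle-sheath-extension area fraction
#'
#' Percentage of the mesophyll cross-sectional area occupied by
#' bundle-sheath extensions, `100 * BSE / (BSE + mesophyll cells + IAS)`,
#' computed per cross-section (slices along y) and averaged over sections
#' containing mesophyll. Veins are not counted as mesophyll area.
#'
#' @param volume A [labeled_volume()].
#' @return Percentage in `[0, 100]`.
#' @export
bse_area_fraction <- function(volume) {
  lm <- volume$label_map
  lab <- volume$labels
  d <- dim(lab)
  fr <- vapply(seq_len(d[2]), function(y) {
    sl <- lab[, y, ]
    n_bse <- sum(sl == lm[["bse"]])
    n_mes <- sum(sl == lm[["mesophyll_cell"]] | sl == lm[["ias"]])
    if (n_bse + n_mes == 0) NA_real_ else 100 * n_bse / (n_bse + n_mes)
  }, numeric(1))
  if (all(is.na(fr))) return(0)
  mean(fr, na.rm = TRUE)
}

#' Mean paradermal palisade cell diameter at chosen depths
#'
#' Extracts the paradermal (y, x) slice at each relative mesophyll depth
#' (measured from the adaxial mesophyll edge), labels in-plane connected
#' mesophyll-cell components (4-connectivity), and reports the mean
#' equivalent-circle diameter of components at least `min_area_vox` voxels
#' large that do not touch the slice border.
#'
#' @param volume A [labeled_volume()].
#' @param depth_fractions Depths in `(0, 1)` from the adaxial surface.
#' @param min_area_vox Minimum in-plane component area (voxels).
#' @return Data frame `depth_fraction`, `diameter_um`, `n_cells`.
#' @export
paradermal_palisade_diameter <- function(volume,
                                         depth_fractions = c(0.2, 0.4, 0.6),
                                         min_area_vox = 10L) {
  if (!length(depth_fractions))
    return(data.frame(depth_fraction = numeric(0), diameter_um = numeric(0),
                      n_cells = integer(0)))
  if (any(depth_fractions <= 0 | depth_fractions >= 1))
    stop("depth fractions must lie in (0, 1)")
  lm <- volume$label_map
  lab <- volume$labels
  d <- dim(lab)
  mes_z <- which(apply(lab == lm[["mesophyll_cell"]] | lab == lm[["ias"]],
                       1, any))
  if (!length(mes_z)) stop("volume contains no mesophyll")
  zmin <- min(mes_z); zmax <- max(mes_z)
  out <- lapply(depth_fractions, function(f) {
    z <- zmin + round(f * (zmax - zmin))
    mask <- lab[z, , ] == lm[["mesophyll_cell"]]
    if (!any(mask)) {
      warning(sprintf("no mesophyll cells in paradermal slice at %.0f%% depth",
                      100 * f))
      return(data.frame(depth_fraction = f, diameter_um = NA_real_,
                        n_cells = 0L))
    }
    cc <- cpp_label2d(mask)
    border <- unique(c(cc[1, ], cc[nrow(cc), ], cc[, 1], cc[, ncol(cc)]))
    keep <- setdiff(seq_len(max(cc)), c(0L, border))
    areas <- tabulate(cc, nbins = max(cc))[keep]
    areas <- areas[areas >= min_area_vox]
    if (!length(areas)) {
      warning(sprintf("no interior components >= %d voxels at %.0f%% depth",
                      min_area_vox, 100 * f))
      return(data.frame(depth_fraction = f, diameter_um = NA_real_,
                        n_cells = 0L))
    }
    data.frame(depth_fraction = f,
               diameter_um = mean(2 * sqrt(areas / pi)) * volume$voxel_um,
               n_cells = length(areas))
  })
  do.call(rbind, out)
}

#' All scalar anatomical traits of a volume
#'
#' Convenience wrapper bundling [porosity()], [vias_to_vcell()],
#' [sa_mes_per_vmes()], [thicknesses()] and [bse_area_fraction()].
#'
#' @param volume A [labeled_volume()].
#' @return Named list of traits.
#' @export
trait_set <- function(volume) {
  th <- thicknesses(volume)
  list(theta_ias = porosity(volume),
       vias_vcell = vias_to_vcell(volume),
       sa_mes_per_vmes = sa_mes_per_vmes(volume),
       L_leaf = th[["L_leaf"]], L_mes = th[["L_mes"]],
       L_epi_adaxial = th[["L_epi_adaxial"]],
       L_epi_abaxial = th[["L_epi_abaxial"]],
       bse_area_pct = bse_area_fraction(volume))
}
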