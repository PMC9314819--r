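#' Parameters for a synthetic segmented leaf volume
#'
#' Describes a layered hypostomatous leaf phantom: adaxial epidermis, palisade
#' mesophyll (close-packed vertical cylinders), spongy mesophyll (thresholded
#' correlated random field), abaxial epidermis perforated by stomata, plus
#' bundle-sheath-extension slabs joining vein cylinders to both epidermes.
#' Defaults reflect a walnut-like leaflet: ~215 um total thickness, dense
#' palisade over porous spongy tissue, ~60 stomata per mm2.
#'
#' @param shape Volume shape in voxels, `c(nz, ny, nx)` with z the
#'   adaxial->abaxial depth axis.
#' @param voxel_um Isotropic voxel pitch (um).
#' @param thickness_um Named layer thicknesses (um):
#'   `adaxial_epidermis`, `palisade`, `spongy`, `abaxial_epidermis`.
#' @param porosity_palisade,porosity_spongy Target IAS fraction per layer,
#'   in `[0, 1)`.
#' @param palisade_diameter_um Palisade cell (cylinder) diameter (um).
#' @param stomatal_density_mm2 Stomata per mm2 of abaxial surface.
#' @param pore_length_um,pore_width_um Stomatal pore axes (um).
#' @param bse_spacing_um,bse_width_um Spacing and width of
#'   bundle-sheath-extension slabs (um); `bse_spacing_um = 0` disables them.
#' @param vein_diameter_um Vein cylinder diameter (um).
#' @param spongy_blob_um Correlation length of the spongy airspace field (um).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `leaf_phantom_params`.
#' @export
leaf_phantom_params <- function(shape = c(180L, 96L, 96L),
                                voxel_um = 1.3,
                                thickness_um = c(adaxial_epidermis = 20,
                                                 palisade = 100,
                                                 spongy = 80,
                                                 abaxial_epidermis = 15),
                                porosity_palisade = 0.1,
                                porosity_spongy = 0.4,
                                palisade_diameter_um = 30,
                                stomatal_density_mm2 = 62,
                                pore_length_um = 20,
                                pore_width_um = 8,
                                bse_spacing_um = 60,
                                bse_width_um = 5,
                                vein_diameter_um = 20,
                                spongy_blob_um = 8,
                                seed = 1L) {
  need <- c("adaxial_epidermis", "palisade", "spongy", "abaxial_epidermis")
  if (!all(need %in% names(thickness_um)))
    stop("thickness_um must name: ", paste(need, collapse = ", "))
  thickness_um <- thickness_um[need]
  if (any(thickness_um <= 0)) stop("all layer thicknesses must be > 0")
  if (voxel_um <= 0) stop("voxel_um must be > 0")
  if (porosity_palisade < 0 || porosity_palisade >= 1 ||
      porosity_spongy < 0 || porosity_spongy >= 1)
    stop("layer porosities must lie in [0, 1)")
  if (sum(thickness_um) > shape[1] * voxel_um)
    stop("sum of layer thicknesses (", sum(thickness_um),
         " um) exceeds volume depth (", shape[1] * voxel_um, " um)")
  if (palisade_diameter_um > thickness_um[["palisade"]])
    stop("palisade cylinder diameter (", palisade_diameter_um,
         " um) exceeds the palisade layer thickness")
  if (stomatal_density_mm2 < 0) stop("stomatal_density_mm2 must be >= 0")
  structure(list(shape = as.integer(shape), voxel_um = voxel_um,
                 thickness_um = thickness_um,
                 porosity_palisade = porosity_palisade,
                 porosity_spongy = porosity_spongy,
                 palisade_diameter_um = palisade_diameter_um,
                 stomatal_density_mm2 = stomatal_density_mm2,
                 pore_length_um = pore_length_um,
                 pore_width_um = pore_width_um,
                 bse_spacing_um = bse_spacing_um,
                 bse_width_um = bse_width_um,
                 vein_diameter_um = vein_diameter_um,
                 spongy_blob_um = spongy_blob_um,
                 seed = as.integer(seed)),
            class = "leaf_phantom_params")
}

# Hexagonal-lattice disk coverage mask on an (ny, nx) grid.
# Returns logical matrix: TRUE inside some disk of radius r_vox.
hex_disk_mask <- function(ny, nx, spacing_vox, r_vox) {
  dy <- spacing_vox * sqrt(3) / 2
  rows <- seq(-r_vox - spacing_vox, ny + r_vox + spacing_vox, by = dy)
  mask <- matrix(FALSE, ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  for (i in seq_along(rows)) {
    off <- if (i %% 2 == 0) spacing_vox / 2 else 0
    cols <- seq(-r_vox - spacing_vox + off, nx + r_vox + spacing_vox,
                by = spacing_vox)
    for (cx in cols) {
      cy <- rows[i]
      lo_y <- max(1L, floor(cy - r_vox)); hi_y <- min(ny, ceiling(cy + r_vox))
      lo_x <- max(1L, floor(cx - r_vox)); hi_x <- min(nx, ceiling(cx + r_vox))
      if (lo_y > hi_y || lo_x > hi_x) next
      ys <- lo_y:hi_y; xs <- lo_x:hi_x
      sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r_vox^2
      mask[ys, xs] <- mask[ys, xs] | sub
    }
  }
  mask
}

# Choose the lattice spacing so the disk coverage hits 1 - porosity, by
# bisection (coverage is monotone decreasing in spacing).
palisade_section <- function(ny, nx, porosity, r_vox) {
  target_cover <- 1 - porosity
  ideal <- sqrt(2 * pi * r_vox^2 / (sqrt(3) * max(target_cover, 1e-6)))
  lo <- max(1.05 * r_vox, 2)
  hi <- max(4 * ideal, 4 * r_vox)
  cover <- function(s) mean(hex_disk_mask(ny, nx, s, r_vox))
  if (cover(lo) < target_cover) lo <- max(0.8 * r_vox, 1.5)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (cover(mid) >= target_cover) lo <- mid else hi <- mid
    if (hi - lo < 0.01) break
  }
  hex_disk_mask(ny, nx, (lo + hi) / 2, r_vox)
}

# Periodic separable Gaussian smoothing of a 3D array via FFT.
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  k1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(k1(d[1], sigma_vox), k1(d[2], sigma_vox)),
             k1(d[3], sigma_vox))
  dim(K) <- d
  Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
}

#' Generate a synthetic segmented leaf volume with known ground truth
#'
#' Builds the label stack described by [leaf_phantom_params()] and a truth
#' record whose every field is recomputable by direct voxel counting on the
#' emitted volume. Stomata are elliptical through-pores of the abaxial
#' epidermis (labelled as airspace), each connected upward to the spongy
#' airspace by a narrow channel so that stomate-seeded distance fields are
#' well defined.
#'
#' @param params A [leaf_phantom_params()].
#' @return A list with elements `volume` (a [labeled_volume()]) and `truth`
#'   (list: achieved layer porosities and whole-mesophyll porosity, layer
#'   thicknesses in um, BSE area fraction in percent, stomate center
#'   coordinates, and achieved palisade cylinder diameter in um).
#' @export
generate_leaf_volume <- function(params) {
  stopifnot(inherits(params, "leaf_phantom_params"))
  with_seed(params$seed, {
    p <- params
    nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
    vx <- p$voxel_um
    lm <- leaf_labels()
    lab <- array(lm[["background"]], dim = c(nz, ny, nx))

    tv <- pmax(1L, as.integer(round(p$thickness_um / vx)))  # layer voxels
    if (sum(tv) > nz) stop("layer thicknesses exceed volume depth in voxels")
    z0 <- max(0L, (nz - sum(tv)) %/% 2L)                    # background above
    z_ad <- z0 + seq_len(tv[1])
    z_pal <- z0 + tv[1] + seq_len(tv[2])
    z_sp <- z0 + tv[1] + tv[2] + seq_len(tv[3])
    z_ab <- z0 + tv[1] + tv[2] + tv[3] + seq_len(tv[4])

    lab[z_ad, , ] <- lm[["epidermis_adaxial"]]
    lab[z_ab, , ] <- lm[["epidermis_abaxial"]]

    # palisade: vertical cylinders on a hexagonal lattice
    r_vox <- p$palisade_diameter_um / 2 / vx
    if (p$porosity_palisade == 0) {
      pal2d <- matrix(TRUE, ny, nx)
    } else {
      pal2d <- palisade_section(ny, nx, p$porosity_palisade, r_vox)
    }
    pal_lab <- ifelse(pal2d, lm[["mesophyll_cell"]], lm[["ias"]])
    for (z in z_pal) lab[z, , ] <- pal_lab

    # spongy: correlated Gaussian field thresholded at the porosity quantile
    if (p$porosity_spongy == 0) {
      lab[z_sp, , ] <- lm[["mesophyll_cell"]]
    } else {
      field <- gauss_smooth3(array(stats::rnorm(length(z_sp) * ny * nx),
                                   dim = c(length(z_sp), ny, nx)),
                             p$spongy_blob_um / vx)
      thr <- stats::quantile(field, p$porosity_spongy)
      lab[z_sp, , ] <- ifelse(field < thr, lm[["ias"]], lm[["mesophyll_cell"]])
    }

    # BSE slabs + vein cylinders
    z_mes <- c(z_pal, z_sp)
    if (p$bse_spacing_um > 0 && p$bse_width_um > 0) {
      xs_um <- seq(p$bse_spacing_um / 2, nx * vx, by = p$bse_spacing_um)
      wv <- p$bse_width_um / vx
      rv <- p$vein_diameter_um / 2 / vx
      zc <- mean(range(z_mes))
      for (xc_um in xs_um) {
        xc <- xc_um / vx
        lo <- round(xc - wv / 2)
        xi <- max(1L, lo):min(nx, lo + max(1L, round(wv)) - 1L)
        lab[z_mes, , xi] <- lm[["bse"]]
        if (rv > 0) {
          zi <- max(1L, floor(zc - rv)):min(nz, ceiling(zc + rv))
          xv <- max(1L, floor(xc - rv)):min(nx, ceiling(xc + rv))
          circ <- outer((zi - zc)^2, (xv - xc)^2, "+") <= rv^2
          for (a in seq_along(zi)) for (b in seq_along(xv))
            if (circ[a, b]) lab[zi[a], , xv[b]] <- lm[["vein"]]
        }
      }
    }

    # stomata: elliptical through-pores of the abaxial epidermis
    area_mm2 <- (ny * vx / 1000) * (nx * vx / 1000)
    n_stom <- round(p$stomatal_density_mm2 * area_mm2)
    stomata <- NULL
    if (n_stom > 0) {
      k <- ceiling(sqrt(n_stom))
      cells <- expand.grid(gy = seq_len(k), gx = seq_len(k))
      cells <- cells[sample(nrow(cells), n_stom), , drop = FALSE]
      cy <- (cells$gy - stats::runif(n_stom)) / k * ny
      cx <- (cells$gx - stats::runif(n_stom)) / k * nx
      a <- max(p$pore_length_um / 2 / vx, 0.5)
      b <- max(p$pore_width_um / 2 / vx, 0.5)
      ias_code <- lm[["ias"]]
      for (s in seq_len(n_stom)) {
        ys <- max(1L, floor(cy[s] - a)):min(ny, ceiling(cy[s] + a))
        xs <- max(1L, floor(cx[s] - b)):min(nx, ceiling(cx[s] + b))
        ell <- outer(((ys - cy[s]) / a)^2, ((xs - cx[s]) / b)^2, "+") <= 1
        if (!any(ell)) {  # sub-voxel pore: open the nearest voxel
          ys <- max(1L, min(ny, round(cy[s]))); xs <- max(1L, min(nx, round(cx[s])))
          ell <- matrix(TRUE, 1, 1)
        }
        for (z in z_ab) {
          m <- matrix(lab[z, ys, xs], length(ys), length(xs))
          m[ell] <- ias_code
          lab[z, ys, xs] <- m
        }
        # connect the pore to the spongy airspace by a 1-voxel channel
        ych <- max(1L, min(ny, round(cy[s])))
        xch <- max(1L, min(nx, round(cx[s])))
        if (p$porosity_spongy > 0) {
          for (z in rev(z_sp)) {
            v <- lab[z, ych, xch]
            if (v == ias_code || v == lm[["vein"]]) break
            lab[z, ych, xch] <- ias_code
          }
        }
        stomata <- rbind(stomata, c(z = z_ab[1], y = ych, x = xch))
      }
    }

    vol <- labeled_volume(lab, voxel_um = vx)

    # truth by direct counting on the emitted stack
    count_por <- function(zr) {
      sl <- lab[zr, , ]
      n_ias <- sum(sl == lm[["ias"]]); n_cell <- sum(sl == lm[["mesophyll_cell"]])
      if (n_ias + n_cell == 0) NA_real_ else n_ias / (n_ias + n_cell)
    }
    # whole-volume counts so the truth matches porosity() exactly (stomatal
    # pore voxels within the abaxial epidermis are IAS too)
    n_ias <- sum(lab == lm[["ias"]]); n_cell <- sum(lab == lm[["mesophyll_cell"]])
    n_bse <- sum(lab == lm[["bse"]])
    pal_cc <- cpp_label2d(pal2d)
    interior <- setdiff(unique(as.vector(pal_cc)), c(0L,
      unique(c(pal_cc[1, ], pal_cc[ny, ], pal_cc[, 1], pal_cc[, nx]))))
    pal_diam <- if (length(interior)) {
      areas <- tabulate(pal_cc)[interior]
      mean(2 * sqrt(areas / pi)) * vx
    } else NA_real_

    truth <- list(
      layer_thickness_um = stats::setNames(tv * vx, names(p$thickness_um)),
      porosity_palisade = count_por(z_pal),
      porosity_spongy = count_por(z_sp),
      porosity_mesophyll = n_ias / (n_ias + n_cell),
      bse_area_fraction_pct = 100 * n_bse / (n_bse + n_cell + n_ias),
      stomata = stomata,
      palisade_diameter_um = pal_diam,
      palisade_diameter_nominal_um = p$palisade_diameter_um)
    list(volume = vol, truth = truth)
  })
}
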