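# Fixture builders (all volumes constructed in code) and the independent
# graph shortest-path oracle used to validate geodesic propagation.

# Layered slab leaf: adaxial epidermis / cell ceiling / open airspace /
# abaxial epidermis / background, with stomatal pores at given (y, x)
# positions. Voxel pitch 1 um.
make_slab_leaf <- function(nz = 60, ny = 48, nx = 48,
                           pores = cbind(y = ny %/% 2, x = nx %/% 2),
                           cell_rows = 6:10) {
  lm <- leaf_labels()
  stopifnot(nz >= 25)
  lab <- array(lm[["ias"]], c(nz, ny, nx))
  lab[1:5, , ] <- lm[["epidermis_adaxial"]]
  lab[cell_rows, , ] <- lm[["mesophyll_cell"]]
  abx <- (nz - 9):(nz - 5)
  lab[abx, , ] <- lm[["epidermis_abaxial"]]
  lab[(nz - 4):nz, , ] <- lm[["background"]]
  for (i in seq_len(nrow(pores)))
    lab[abx, pores[i, 1], pores[i, 2]] <- lm[["ias"]]
  list(volume = labeled_volume(lab, 1),
       stomata = cbind(z = abx[1], y = pores[, 1], x = pores[, 2]),
       abaxial_rows = abx)
}

# Exact Dijkstra over the 26-neighbor voxel graph restricted to open voxels,
# implemented with igraph: the independent oracle for cpp geodesic
# propagation at nb_order = 1. Returns distances in voxels (Inf where
# unreachable), shaped like `open`.
igraph_geodesic <- function(open, seeds_lin) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  d <- dim(open)
  n <- prod(d)
  node <- integer(n)
  open_idx <- which(open)
  node[open_idx] <- seq_along(open_idx)
  dirs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  edges <- list()
  wts <- list()
  zc <- (open_idx - 1L) %% d[1] + 1L
  rest <- (open_idx - 1L) %/% d[1]
  yc <- rest %% d[2] + 1L
  xc <- rest %/% d[2] + 1L
  for (r in seq_len(nrow(dirs))) {
    dz <- dirs[r, 1]; dy <- dirs[r, 2]; dx <- dirs[r, 3]
    z2 <- zc + dz; y2 <- yc + dy; x2 <- xc + dx
    okb <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] & x2 >= 1 & x2 <= d[3]
    lin2 <- (x2 - 1L) * d[1] * d[2] + (y2 - 1L) * d[1] + z2
    ok <- okb
    ok[okb] <- open[lin2[okb]]
    if (!any(ok)) next
    edges[[r]] <- rbind(node[open_idx[ok]], node[lin2[ok]])
    wts[[r]] <- rep(sqrt(dz^2 + dy^2 + dx^2), sum(ok))
  }
  edges <- edges[!vapply(edges, is.null, logical(1))]
  wts <- wts[!vapply(wts, is.null, logical(1))]
  g <- igraph::make_graph(as.vector(do.call(cbind, edges)),
                          n = length(open_idx), directed = TRUE)
  dm <- igraph::distances(g, v = node[seeds_lin], weights = unlist(wts),
                          mode = "out", algorithm = "dijkstra")
  dmin <- if (nrow(dm) == 1) as.numeric(dm) else apply(dm, 2, min)
  out <- array(Inf, d)
  out[open_idx] <- dmin
  out
}

# small random leaf phantom for property checks
random_phantom <- function(seed, shape = c(64L, 64L, 64L), voxel_um = 2,
                           bse = FALSE) {
  set.seed(seed)
  depth <- shape[1] * voxel_um
  leaf_phantom_params(
    shape = shape, voxel_um = voxel_um,
    thickness_um = c(adaxial_epidermis = 0.10, palisade = 0.42,
                     spongy = 0.36, abaxial_epidermis = 0.10) * depth,
    porosity_palisade = runif(1, 0.15, 0.35),
    porosity_spongy = runif(1, 0.3, 0.5),
    palisade_diameter_um = 16,
    stomatal_density_mm2 = runif(1, 60, 250),
    pore_length_um = 8, pore_width_um = 5,
    bse_spacing_um = if (bse) 45 else 0, bse_width_um = 4,
    vein_diameter_um = 10,
    spongy_blob_um = 6,
    seed = seed)
}
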