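#' Canonical tissue label map for segmented leaf volumes
#'
#' Segmented leaf microCT stacks carry seven voxel classes. The integer codes
#' below are the package convention; [labeled_volume()] accepts any map with
#' these seven tissue names.
#'
#' @return Named integer vector mapping tissue name to label code.
#' @export
leaf_labels <- function() {
  c(background = 0L,
    epidermis_adaxial = 1L,
    epidermis_abaxial = 2L,
    mesophyll_cell = 3L,
    ias = 4L,
    bse = 5L,
    vein = 6L)
}

#' Segmented leaf volume
#'
#' Container for a segmented 3D leaf stack: an integer label array with axes
#' `(z, y, x)` where z runs from the adaxial to the abaxial surface, the
#' isotropic voxel pitch in micrometers, and a label map.
#'
#' @param labels 3D integer array, axes `(z, y, x)`.
#' @param voxel_um Voxel edge length in micrometers (> 0).
#' @param label_map Named integer vector with the seven tissue names of
#'   [leaf_labels()].
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_um, label_map = leaf_labels()) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array (z, y, x)")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("`voxel_um` must be a single positive number")
  needed <- names(leaf_labels())
  if (!all(needed %in% names(label_map)))
    stop("`label_map` must name all tissues: ", paste(needed, collapse = ", "))
  storage.mode(labels) <- "integer"
  present <- unique(as.vector(labels))
  unknown <- setdiff(present, unname(label_map))
  if (length(unknown))
    stop("labels not in the declared map: ", paste(unknown, collapse = ", "))
  structure(list(labels = labels,
                 voxel_um = as.numeric(voxel_um),
                 label_map = label_map[needed]),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (z,y,x) @ %.3g um\n",
              d[1], d[2], d[3], x$voxel_um))
  cnt <- tissue_counts(x)
  for (nm in names(cnt))
    cat(sprintf("  %-18s %d\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Logical mask for one or more tissues
#'
#' @param volume A [labeled_volume()].
#' @param tissue Character vector of tissue names.
#' @return Logical array with the volume's dimensions.
#' @export
tissue_mask <- function(volume, tissue) {
  stopifnot(inherits(volume, "labeled_volume"))
  bad <- setdiff(tissue, names(volume$label_map))
  if (length(bad)) stop("unknown tissue: ", paste(bad, collapse = ", "))
  codes <- unname(volume$label_map[tissue])
  array(volume$labels %in% codes, dim = dim(volume$labels))
}

#' Voxel counts per tissue
#'
#' @param volume A [labeled_volume()].
#' @return Named integer vector of voxel counts, one per tissue.
#' @export
tissue_counts <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  tab <- tabulate(volume$labels + 1L, nbins = max(volume$label_map) + 1L)
  stats::setNames(tab[volume$label_map + 1L], names(volume$label_map))
}

#' Write a labeled volume as a multi-page TIFF plus JSON sidecar
#'
#' One 8-bit TIFF page per z-slice (values are the raw label codes), and a
#' sidecar recording the voxel pitch and the label map so the stack is
#' self-describing.
#'
#' @param volume A [labeled_volume()].
#' @param stack_path Output TIFF path.
#' @param sidecar_path Output JSON path; defaults to the stack path with a
#'   `.json` extension.
#' @return Invisibly, the two paths.
#' @export
write_label_volume <- function(volume, stack_path,
                               sidecar_path = sub("\\.tiff?$", ".json",
                                                  stack_path)) {
  stopifnot(inherits(volume, "labeled_volume"))
  d <- dim(volume$labels)
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(volume$labels[z, , ] / 255, nrow = d[2], ncol = d[3]))
  tiff::writeTIFF(pages, stack_path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxel_um = volume$voxel_um,
         axes = c("z", "y", "x"),
         labels = as.list(volume$label_map)),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(stack = stack_path, sidecar = sidecar_path))
}

#' Read a labeled volume written by [write_label_volume()]
#'
#' @param stack_path Multi-page TIFF of 8-bit label slices.
#' @param sidecar_path JSON sidecar with `voxel_um` and `labels`.
#' @return A [labeled_volume()].
#' @export
read_label_volume <- function(stack_path,
                              sidecar_path = sub("\\.tiff?$", ".json",
                                                 stack_path)) {
  pages <- tiff::readTIFF(stack_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  d2 <- dim(pages[[1]])
  arr <- array(0L, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages))
    arr[z, , ] <- as.integer(round(pages[[z]] * 255))
  label_map <- stats::setNames(as.integer(unlist(side$labels)),
                               names(side$labels))
  labeled_volume(arr, voxel_um = side$voxel_um, label_map = label_map)
}

# Evaluate a function with a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
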