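# Normalized chlorophyll-fluorescence depth profiles and BSE-proximity
# lateral profiles from leaf cross-section images.

#' Cross-section fluorescence image container
#'
#' A grayscale leaf cross-section with the adaxial edge at row 1, a pixel
#' pitch, and a mesophyll mask excluding non-photosynthetic structures
#' (epidermes, veins).
#'
#' @param image Numeric matrix of nonnegative intensities (rows = depth).
#' @param pixel_um Pixel pitch (um).
#' @param mask Logical matrix of the same shape; `TRUE` inside mesophyll.
#' @return Object of class `fluor_image`.
#' @export
fluor_image <- function(image, pixel_um, mask) {
  image <- as.matrix(image)
  if (any(image < 0)) stop("intensities must be >= 0")
  if (pixel_um <= 0) stop("pixel_um must be > 0")
  if (!identical(dim(mask), dim(image)))
    stop("mask must match the image dimensions")
  if (!any(mask)) stop("mesophyll mask is empty")
  structure(list(image = image, pixel_um = pixel_um, mask = mask),
            class = "fluor_image")
}

#' Read a grayscale TIFF or PNG cross-section as a fluorescence image
#'
#' @param path Image file (`.tif`/`.tiff` or `.png`); multi-channel images
#'   are averaged to grayscale.
#' @param pixel_um Pixel pitch (um).
#' @param mask Optional logical matrix; defaults to pixels with intensity
#'   above `mask_threshold` times the image maximum.
#' @param mask_threshold Relative threshold for the default mask.
#' @return A [fluor_image()].
#' @export
read_fluor_image <- function(path, pixel_um, mask = NULL,
                             mask_threshold = 0.02) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the png package")
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  if (is.null(mask)) mask <- img > mask_threshold * max(img)
  fluor_image(img, pixel_um, mask)
}

# bin means with neighbor interpolation of empty bins
bin_means <- function(bin, value, n_bins) {
  s <- tabulate(bin, n_bins)
  m <- rep(NA_real_, n_bins)
  agg <- vapply(split(value, factor(bin, levels = seq_len(n_bins))),
                function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  m[] <- agg
  if (anyNA(m)) {
    warning("empty profile bin(s) interpolated from neighbors")
    ok <- which(!is.na(m))
    if (!length(ok)) stop("all profile bins are empty")
    m <- stats::approx(ok, m[ok], xout = seq_len(n_bins), rule = 2)$y
  }
  list(mean = m, n = s)
}

#' Normalized fluorescence depth profile
#'
#' Averages masked intensity in a vertical strip by relative mesophyll
#' depth. Depth is normalized per column to that column's masked extent
#' (0% = adaxial mesophyll edge, 100% = abaxial edge), then the binned
#' profile is scaled so its maximum equals 100%. Only relative values are
#' reported: absolute fluorescence is not comparable across samples.
#'
#' @param img A [fluor_image()].
#' @param strip Optional integer range of columns to average over (default:
#'   a centered strip of `strip_width` columns).
#' @param strip_width Strip width in pixels when `strip` is not given.
#' @param n_bins Number of depth bins.
#' @return Data frame `depth_pct` (bin centers), `fluor_pct` (max = 100).
#' @export
depth_profile <- function(img, strip = NULL, strip_width = 75L,
                          n_bins = 20L) {
  stopifnot(inherits(img, "fluor_image"))
  nc <- ncol(img$image)
  if (is.null(strip)) {
    w <- min(strip_width, nc)
    lo <- max(1L, (nc - w) %/% 2L + 1L)
    strip <- lo:(lo + w - 1L)
  }
  if (any(strip < 1 | strip > nc)) stop("strip exceeds image width")
  bins <- integer(0)
  vals <- numeric(0)
  for (j in strip) {
    rows <- which(img$mask[, j])
    if (length(rows) < 2) next
    lo <- min(rows)
    ext <- max(rows) - lo + 1L
    rel <- (rows - lo + 0.5) / ext * 100
    b <- pmin(pmax(ceiling(rel / (100 / n_bins)), 1L), n_bins)
    bins <- c(bins, b)
    vals <- c(vals, img$image[rows, j])
  }
  if (!length(bins)) stop("mask has no usable columns in the strip")
  bm <- bin_means(bins, vals, n_bins)
  prof <- bm$mean / max(bm$mean) * 100
  data.frame(depth_pct = (seq_len(n_bins) - 0.5) * 100 / n_bins,
             fluor_pct = prof)
}

#' Normalized fluorescence vs lateral distance from bundle-sheath extensions
#'
#' Bins masked intensity by signed lateral distance from each BSE center
#' (negative = left, positive = right), averages the per-BSE profiles after
#' normalizing each to its own maximum (so bright and dim BSEs weigh
#' equally), and rescales the mean profile to a maximum of 100%.
#'
#' @param img A [fluor_image()].
#' @param bse_centers_px Column indices of BSE centers (>= 1 required).
#' @param half_window_um Half-width of the lateral window (um).
#' @param n_bins Number of distance bins (use an odd count to center a bin
#'   on the BSE).
#' @return Data frame `dist_um` (bin centers), `fluor_pct` (max = 100).
#' @export
bse_proximity_profile <- function(img, bse_centers_px, half_window_um,
                                  n_bins = 21L) {
  stopifnot(inherits(img, "fluor_image"))
  if (!length(bse_centers_px)) stop("at least one BSE center is required")
  nc <- ncol(img$image)
  hw_px <- half_window_um / img$pixel_um
  if (hw_px > (nc - 1) / 2)
    warning("lateral window exceeds the image; profile truncated at edges")
  edges <- seq(-half_window_um, half_window_um, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  acc <- matrix(NA_real_, length(bse_centers_px), n_bins)
  for (i in seq_along(bse_centers_px)) {
    c0 <- bse_centers_px[i]
    cols <- max(1L, ceiling(c0 - hw_px)):min(nc, floor(c0 + hw_px))
    dist_um <- (cols - c0) * img$pixel_um
    b <- findInterval(dist_um, edges, rightmost.closed = TRUE)
    b[b < 1 | b > n_bins] <- NA
    vals <- numeric(0)
    bins <- integer(0)
    for (k in seq_along(cols)) {
      if (is.na(b[k])) next
      rows <- which(img$mask[, cols[k]])
      if (!length(rows)) next
      vals <- c(vals, mean(img$image[rows, cols[k]]))
      bins <- c(bins, b[k])
    }
    if (!length(bins)) next
    m <- vapply(split(vals, factor(bins, levels = seq_len(n_bins))),
                function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
    acc[i, ] <- m / max(m, na.rm = TRUE) * 100
  }
  prof <- colMeans(acc, na.rm = TRUE)
  if (all(is.na(prof))) stop("no masked pixels inside the lateral window")
  prof <- prof / max(prof, na.rm = TRUE) * 100
  data.frame(dist_um = centers, fluor_pct = prof)
}

#' Generate a synthetic fluorescence cross-section image
#'
#' Builds a grayscale cross-section whose column-averaged masked intensity
#' follows a caller-supplied depth profile (a nonnegative function of
#' relative depth, 0-100%), optionally modulated laterally around
#' bundle-sheath-extension stripes, with i.i.d. Gaussian noise. The emitted
#' mask covers the mesophyll band between two epidermis margins.
#'
#' @param profile Function of relative depth (0-100) giving nonnegative
#'   intensity.
#' @param shape Image shape `c(rows, cols)`.
#' @param pixel_um Pixel pitch (um).
#' @param epidermis_px Rows of zero-intensity margin at top and bottom
#'   (excluded from the mask).
#' @param bse_centers_px Optional BSE stripe column centers.
#' @param lateral Optional function of signed lateral distance (um) from the
#'   nearest BSE center; its value multiplies the depth profile.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param seed Integer seed.
#' @return A [fluor_image()] with attribute `bse_centers_px`.
#' @export
generate_fluorescence_image <- function(profile, shape = c(220L, 300L),
                                        pixel_um = 1, epidermis_px = 15L,
                                        bse_centers_px = NULL,
                                        lateral = NULL, noise_sd = 0,
                                        seed = 1L) {
  nr <- shape[1]; nc <- shape[2]
  if (2 * epidermis_px >= nr) stop("epidermis margins exceed image height")
  rows_mes <- (epidermis_px + 1L):(nr - epidermis_px)
  rel <- (seq_along(rows_mes) - 0.5) / length(rows_mes) * 100
  base <- vapply(rel, profile, numeric(1))
  if (any(base < 0)) stop("profile must be nonnegative over 0-100% depth")
  img <- matrix(0, nr, nc)
  lat <- rep(1, nc)
  if (!is.null(bse_centers_px) && !is.null(lateral)) {
    dmat <- outer(seq_len(nc), bse_centers_px,
                  function(x, c0) (x - c0) * pixel_um)
    nearest <- apply(abs(dmat), 1, which.min)
    signed <- dmat[cbind(seq_len(nc), nearest)]
    lat <- vapply(signed, lateral, numeric(1))
    if (any(lat < 0)) stop("lateral modulation must be nonnegative")
  }
  img[rows_mes, ] <- outer(base, lat)
  with_seed(seed, {
    if (noise_sd > 0)
      img[rows_mes, ] <- pmax(img[rows_mes, ] +
                                stats::rnorm(length(rows_mes) * nc,
                                             sd = noise_sd), 0)
    mask <- matrix(FALSE, nr, nc)
    mask[rows_mes, ] <- TRUE
    out <- fluor_image(img, pixel_um, mask)
    attr(out, "bse_centers_px") <- bse_centers_px
    out
  })
}
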