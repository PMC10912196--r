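#' Canopy segmentation configuration
#'
#' HSV thresholds use the half-degree hue convention (H in [0, 180), S and
#' V in [0, 255]) common in computer-vision pipelines; the defaults keep
#' hues from 20 to 170 — green vegetation — and exclude brown soil.
#' Contrast-limited adaptive histogram equalization (CLAHE) is applied to
#' the brightness (value) channel before thresholding to even out
#' illumination differences between flights.
#'
#' @param hsv_lower,hsv_upper Length-3 \code{(H, S, V)} bounds; a pixel is
#'   canopy iff componentwise lower <= HSV <= upper.
#' @param clahe_clip_limit CLAHE clip limit (default 2).
#' @param clahe_tile_grid CLAHE tile grid \code{c(rows, cols)} (default 8x8).
#' @param exg_bands \code{"three"} for the standard excess-green
#'   \eqn{2g - r - b} on chromatic coordinates, \code{"two"} for the
#'   green-red variant \eqn{g - r}.
#' @return A \code{seg_config} list.
#' @export
seg_config <- function(hsv_lower = c(20, 0, 0), hsv_upper = c(170, 255, 255),
                       clahe_clip_limit = 2, clahe_tile_grid = c(8, 8),
                       exg_bands = c("three", "two")) {
  stopifnot(length(hsv_lower) == 3, length(hsv_upper) == 3,
            all(hsv_lower <= hsv_upper),
            hsv_lower[1] >= 0, hsv_upper[1] < 180,
            all(hsv_upper[2:3] <= 255), clahe_clip_limit > 0,
            length(clahe_tile_grid) == 2, all(clahe_tile_grid >= 1))
  structure(list(hsv_lower = hsv_lower, hsv_upper = hsv_upper,
                 hue_convention = "H in [0,180), S/V in [0,255]",
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = clahe_tile_grid,
                 exg_bands = match.arg(exg_bands)),
            class = "seg_config")
}

# RGB array (h x w x 3, values in [0,1]) -> HSV planes in the
# half-degree convention used by seg_config.
rgb_to_hsv_halfdeg <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  d <- dim(rgb)[1:2]
  m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
             as.vector(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 180, d[1], d[2]),
       s = matrix(hsv[2, ] * 255, d[1], d[2]),
       v = matrix(hsv[3, ] * 255, d[1], d[2]))
}

#' Equalize tile contrast with CLAHE on the brightness channel
#'
#' The RGB tile is converted to HSV, CLAHE is applied to the value channel
#' only (hue and saturation pass through, so the segmentation hue bounds
#' see the same colors), and the tile is converted back to RGB.
#'
#' @param rgb h x w x 3 array with values in [0, 1] (8-bit data scaled).
#' @param config A [seg_config()].
#' @return Equalized array, same shape and range.
#' @export
equalize_contrast <- function(rgb, config = seg_config()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (min(rgb) < 0 || max(rgb) > 1)
    stop("expected 8-bit image data scaled to [0, 1]")
  hsv <- rgb_to_hsv_halfdeg(rgb)
  v <- hsv$v / 255
  if (diff(range(v)) == 0) return(rgb)  # flat brightness: nothing to equalize
  # the equalizer needs dimensions divisible by the tile grid: pad by edge
  # replication, equalize, crop back
  nx <- config$clahe_tile_grid[2]; ny <- config$clahe_tile_grid[1]
  nr <- nrow(v); nc <- ncol(v)
  nr2 <- ceiling(nr / ny) * ny; nc2 <- ceiling(nc / nx) * nx
  vp <- v[c(seq_len(nr), rep(nr, nr2 - nr)), c(seq_len(nc), rep(nc, nc2 - nc)),
          drop = FALSE]
  veq <- EBImage::clahe(EBImage::Image(vp), nx = nx, ny = ny,
                        limit = config$clahe_clip_limit,
                        keep.range = TRUE)
  veq <- pmin(pmax(EBImage::imageData(veq), 0), 1)[seq_len(nr), seq_len(nc)]
  out <- grDevices::hsv(hsv$h / 180, hsv$s / 255, as.vector(veq))
  arr <- grDevices::col2rgb(out) / 255
  array(c(arr[1, ], arr[2, ], arr[3, ]), dim = dim(rgb))
}

#' Threshold a tile into a canopy mask
#'
#' A pixel is canopy (255) iff its HSV triple lies componentwise within
#' the configured bounds, else soil (0).
#'
#' @inheritParams equalize_contrast
#' @return Integer matrix of 0/255.
#' @export
mask_canopy <- function(rgb, config = seg_config()) {
  hsv <- rgb_to_hsv_halfdeg(rgb)
  lo <- config$hsv_lower; hi <- config$hsv_upper
  ok <- hsv$h >= lo[1] & hsv$h <= hi[1] &
        hsv$s >= lo[2] & hsv$s <= hi[2] &
        hsv$v >= lo[3] & hsv$v <= hi[3]
  m <- matrix(0L, nrow(ok), ncol(ok))
  m[ok] <- 255L
  m
}

#' Canopy cover from a mask
#'
#' @param mask 0/255 canopy mask.
#' @param aom_pixel_count Pixel count of the plot's area of measurement;
#'   defaults to the full mask.
#' @return Fraction of the plot covered by canopy, in [0, 1].
#' @export
canopy_cover <- function(mask, aom_pixel_count = length(mask)) {
  if (aom_pixel_count == 0) stop("empty area of measurement")
  sum(mask == 255) / aom_pixel_count
}

#' Canopy height statistics from a DEM and a canopy mask
#'
#' The DEM holds absolute elevation; plant height needs a ground baseline,
#' taken as the median elevation of the plot's soil (non-canopy) pixels,
#' falling back to the 5th percentile of the whole tile when no soil is
#' visible. Heights are clamped at 0. Percentiles use linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param dem Elevation matrix (meters), co-registered with \code{mask}.
#' @param mask 0/255 canopy mask of the same shape.
#' @return List: \code{CH} (mean height), \code{CH90} (90th percentile),
#'   \code{deciles} (10th..100th percentiles, diagnostics).
#' @export
canopy_height <- function(dem, mask) {
  if (!all(dim(dem) == dim(mask))) stop("DEM and mask shapes differ")
  canopy <- mask == 255
  if (!any(canopy))
    return(list(CH = 0, CH90 = 0, deciles = rep(0, 10)))
  ground <- if (any(!canopy)) stats::median(dem[!canopy])
            else stats::quantile(dem, 0.05, names = FALSE)
  h <- pmax(dem[canopy] - ground, 0)
  dec <- stats::quantile(h, seq(0.1, 1, by = 0.1), names = FALSE, type = 7)
  list(CH = mean(h), CH90 = dec[9], deciles = dec)
}

#' Mean excess-green index over canopy pixels
#'
#' Per pixel, RGB is reduced to chromatic coordinates
#' \eqn{r = R/(R+G+B)} etc., and ExG \eqn{= 2g - r - b} (or \eqn{g - r}
#' under the two-band variant). The mean over canopy pixels is returned,
#' un-normalized; see [normalize_exg()].
#'
#' @inheritParams equalize_contrast
#' @param mask 0/255 canopy mask.
#' @return Mean ExG, or \code{NA} for an empty mask.
#' @export
excess_green <- function(rgb, mask, config = seg_config()) {
  canopy <- mask == 255
  if (!any(canopy)) return(NA_real_)
  R <- rgb[, , 1][canopy]; G <- rgb[, , 2][canopy]; B <- rgb[, , 3][canopy]
  tot <- R + G + B
  tot[tot == 0] <- 1  # black pixel: all chromatic coords 0
  r <- R / tot; g <- G / tot; b <- B / tot
  vals <- if (config$exg_bands == "two") g - r else 2 * g - r - b
  mean(vals)
}

#' Min-max normalize raw ExG values to [0, 1]
#'
#' Scaling is over the processing batch supplied (conventionally one
#' year's extractions), mapping the batch minimum to 0 and maximum to 1.
#'
#' @param x Raw ExG values.
#' @return Values scaled to [0, 1]; an all-equal batch maps to 0.5 with a
#'   warning.
#' @export
normalize_exg <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("all ExG values equal; returning 0.5")
    return(ifelse(is.na(x), NA_real_, 0.5))
  }
  (x - rng[1]) / diff(rng)
}

#' Read a tile pair written by [write_tile_pair()]
#'
#' @param rgb_path PNG path; @param dem_path single-band TIFF path.
#' @return List with \code{rgb} array and \code{dem} matrix.
#' @export
read_tile_pair <- function(rgb_path, dem_path) {
  rgb <- png::readPNG(rgb_path)
  if (length(dim(rgb)) == 3 && dim(rgb)[3] == 4) rgb <- rgb[, , 1:3]
  dem <- tiff::readTIFF(dem_path)
  if (length(dim(dem)) == 3) dem <- dem[, , 1]
  list(rgb = rgb, dem = dem)
}

#' Extract the plot-by-date trait table from a tile manifest
#'
#' For each manifest row the RGB tile is contrast-equalized, segmented,
#' and reduced to canopy cover, canopy height statistics, canopy volume
#' (CV = CC x CH, CV90 = CC x CH90) and raw ExG; ExG is then min-max
#' normalized within each year. Rows whose files are missing are flagged
#' (\code{missing = TRUE}) rather than fatal.
#'
#' @param manifest Data frame with \code{plot_id}, \code{genotype},
#'   \code{year}, \code{dap}, \code{rgb_path}, \code{dem_path} (and
#'   optionally \code{rep}).
#' @param config A [seg_config()].
#' @param equalize Apply CLAHE before masking (default TRUE).
#' @return Trait table with one row per manifest entry.
#' @export
extract_trait_table <- function(manifest, config = seg_config(),
                                equalize = TRUE) {
  need <- c("plot_id", "genotype", "year", "dap", "rgb_path", "dem_path")
  stopifnot(all(need %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    base <- data.frame(plot_id = r$plot_id, genotype = r$genotype,
                       rep = if ("rep" %in% names(r)) r$rep else NA,
                       year = r$year, dap = r$dap, stringsAsFactors = FALSE)
    if (!file.exists(r$rgb_path) || !file.exists(r$dem_path)) {
      warning("missing tile(s) for plot ", r$plot_id, " DAP ", r$dap)
      return(cbind(base, CC = NA, CH = NA, CH90 = NA, CV = NA, CV90 = NA,
                   ExG_raw = NA, missing = TRUE))
    }
    tile <- read_tile_pair(r$rgb_path, r$dem_path)
    img <- if (equalize) equalize_contrast(tile$rgb, config) else tile$rgb
    mask <- mask_canopy(img, config)
    cc <- canopy_cover(mask)
    ch <- canopy_height(tile$dem, mask)
    exg <- excess_green(tile$rgb, mask, config)
    cbind(base, CC = cc, CH = ch$CH, CH90 = ch$CH90,
          CV = cc * ch$CH, CV90 = cc * ch$CH90,
          ExG_raw = exg, missing = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ExG <- NA_real_
  for (yr in unique(out$year)) {
    sel <- out$year == yr & !is.na(out$ExG_raw)
    if (sum(sel) >= 2) out$ExG[sel] <- normalize_exg(out$ExG_raw[sel])
  }
  out
}
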