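#' Multi-channel fluorescence image container
#'
#' Named 2D channels (`mito`, `ld`, `actin`) of equal dimension with a pixel
#' calibration in micrometres.
#'
#' @param mito,ld,actin numeric matrices of equal dimension with
#'   non-negative intensities.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(mito, ld, actin, pixel_size) {
  for (ch in list(mito, ld, actin)) .check_matrix(ch, "channel")
  .same_dim(mito, ld, "channels"); .same_dim(mito, actin, "channels")
  if (min(mito, ld, actin) < 0) .stopf("channel intensities must be >= 0")
  if (pixel_size <= 0) .stopf("pixel_size must be positive")
  structure(list(channels = list(mito = mito, ld = ld, actin = actin),
                 pixel_size = pixel_size, dim = dim(mito)),
            class = "multichannel_image")
}

# min-max scaling to [0, 1]; constant input maps to all zeros
.minmax <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(array(0, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Cell-guidance channel: actin plus Gaussian-blurred mitochondria
#'
#' Hepatocyte boundaries are marked by actin while the cytoplasm is filled
#' by the blurred mitochondrial signal; their sum guides cell segmentation.
#' Each channel is min-max scaled to \[0, 1\] before summation.
#'
#' @param actin,mito numeric matrices of equal dimension.
#' @param sigma_um Gaussian blur standard deviation in micrometres
#'   (default 2; 0 disables the blur).
#' @param pixel_size pixel edge length in micrometres.
#' @return A numeric matrix in \[0, 2\].
#' @export
build_cell_guidance_channel <- function(actin, mito, sigma_um = 2,
                                        pixel_size = 1) {
  .same_dim(actin, mito, "channels")
  if (sigma_um < 0) .stopf("sigma_um must be >= 0")
  blurred <- if (sigma_um > 0) {
    sigma <- sigma_um / pixel_size
    radius <- 2 * ceiling(3 * sigma) + 1
    cap <- min(dim(mito))
    if (cap %% 2 == 0) cap <- cap - 1
    as.matrix(EBImage::gblur(mito, sigma = sigma,
                             radius = min(radius, cap)))
  } else mito
  .minmax(actin) + .minmax(blurred)
}

# wrap a user backend so failures identify the backend
.run_backend <- function(backend, channel, name) {
  out <- tryCatch(backend(channel), error = function(e)
    .stopf("segmentation error in backend '%s': %s", name, conditionMessage(e)))
  lab <- matrix(as.integer(round(as.matrix(out))), nrow = nrow(channel))
  if (any(lab < 0)) .stopf("backend '%s' returned negative labels", name)
  lab
}

#' Segment hepatocytes from a guidance channel
#'
#' The segmentation backend is a contract: any function mapping a channel
#' matrix to an integer label matrix may be plugged in (for example a
#' learned model wrapper). The classical fallback smooths the guidance
#' channel, thresholds the bright cell-boundary ridges (Otsu unless an
#' absolute threshold is given), labels the connected interior regions, and
#' removes border-touching and small components.
#'
#' @param guidance numeric matrix from [build_cell_guidance_channel()].
#' @param backend optional backend function; `NULL` uses the fallback.
#' @param pixel_size pixel edge length in micrometres.
#' @param min_area_um2 minimum cell area kept (default 100).
#' @param smooth_sigma_px fallback pre-smoothing sigma in pixels (default 1).
#' @param threshold optional absolute ridge threshold on the smoothed,
#'   rescaled guidance channel; when given, interiors are the
#'   below-threshold connected components (with enclosed holes refilled).
#'   When `NULL` (default) the ridge criterion is thresholdless: a
#'   watershed on the inverted guidance, whose basin boundaries follow the
#'   bright actin ridges while `ridge_tolerance` merges shallow basins
#'   caused by organelle signal inside cells.
#' @param ridge_tolerance watershed merging tolerance on the \[0, 1\]
#'   rescaled guidance (default 0.3).
#' @param drop_border remove cells touching the image border (default TRUE).
#' @return Integer cell label matrix.
#' @export
segment_cells <- function(guidance, backend = NULL, pixel_size = 1,
                          min_area_um2 = 100, smooth_sigma_px = 1,
                          threshold = NULL, ridge_tolerance = 0.3,
                          drop_border = TRUE) {
  .check_matrix(guidance, "guidance")
  if (any(!is.finite(guidance))) .stopf("guidance channel must be finite")
  if (!is.null(backend)) {
    lab <- .run_backend(backend, guidance,
                        deparse(substitute(backend))[1])
  } else {
    g <- .minmax(if (smooth_sigma_px > 0)
      as.matrix(EBImage::gblur(guidance, sigma = smooth_sigma_px))
      else guidance)
    if (all(g == 0)) return(matrix(0L, nrow(guidance), ncol(guidance)))
    if (!is.null(threshold)) {
      interior <- g < threshold
      lab <- EBImage::bwlabel(interior)
      # organelle-dense patches can exceed the ridge threshold inside a
      # cell; refill such enclosed holes so interiors stay solid
      lab <- matrix(as.integer(EBImage::fillHull(lab)),
                    nrow = nrow(guidance))
    } else {
      w <- EBImage::watershed(EBImage::Image(max(g) - g),
                              tolerance = ridge_tolerance, ext = 1)
      lab <- matrix(as.integer(w), nrow = nrow(guidance))
    }
  }
  if (drop_border) lab <- exclude_border_objects(lab)
  filter_min_area(lab, min_area_um2, pixel_size)
}

#' Segment organelles from a single channel
#'
#' Same pluggable contract as [segment_cells()]; the classical fallback is a
#' per-image global Otsu threshold followed by connected-component labelling
#' and a minimum-area filter.
#'
#' @param channel numeric matrix (mitochondria or LD channel).
#' @param kind `"mito"` or `"ld"` (recorded as an attribute).
#' @param backend optional backend function; `NULL` uses the fallback.
#' @param pixel_size pixel edge length in micrometres.
#' @param min_area_um2 minimum object area kept (default 0.2).
#' @param threshold optional absolute intensity threshold; `NULL` uses Otsu.
#' @return Integer organelle label matrix with attribute `kind`.
#' @export
segment_organelles <- function(channel, kind = c("mito", "ld"),
                               backend = NULL, pixel_size = 1,
                               min_area_um2 = 0.2, threshold = NULL) {
  kind <- match.arg(kind)
  .check_matrix(channel, "channel")
  if (any(!is.finite(channel))) .stopf("channel must be finite")
  if (!is.null(backend)) {
    lab <- .run_backend(backend, channel, deparse(substitute(backend))[1])
  } else {
    g <- .minmax(channel)
    if (all(g == 0)) {
      lab <- matrix(0L, nrow(channel), ncol(channel))
    } else {
      thr <- threshold %||% EBImage::otsu(EBImage::Image(g), range = c(0, 1))
      lab <- matrix(as.integer(EBImage::bwlabel(g > thr)),
                    nrow = nrow(channel))
    }
  }
  lab <- filter_min_area(lab, min_area_um2, pixel_size)
  attr(lab, "kind") <- kind
  lab
}

#' Remove lipid-droplet segments below an intensity threshold
#'
#' False-positive LD segments are removed by thresholding the per-object
#' mean intensity in the LD channel. Remaining object ids are preserved and
#' the operation is idempotent at a fixed absolute threshold.
#'
#' @param ld_labels integer LD label matrix.
#' @param ld_channel LD intensity matrix of the same dimension.
#' @param threshold absolute mean-intensity threshold; `NULL` derives it as
#'   the `quantile` of per-object mean intensities.
#' @param quantile quantile used when `threshold` is `NULL` (default 0.25).
#' @return Filtered integer label matrix (ids preserved); the threshold used
#'   is attached as attribute `threshold`.
#' @export
filter_ld_by_intensity <- function(ld_labels, ld_channel, threshold = NULL,
                                   quantile = 0.25) {
  .same_dim(ld_labels, ld_channel, "labels and channel")
  storage.mode(ld_labels) <- "integer"
  ids <- sort(unique(ld_labels[ld_labels > 0]))
  if (length(ids) == 0L) return(ld_labels)
  pos <- which(ld_labels > 0)
  f <- factor(ld_labels[pos], levels = ids)
  means <- as.numeric(rowsum(ld_channel[pos], f) / tabulate(f, length(ids)))
  thr <- threshold %||% stats::quantile(means, quantile, names = FALSE)
  drop <- ids[means < thr]
  out <- ld_labels
  out[out %in% drop] <- 0L
  attr(out, "threshold") <- thr
  out
}

#' Remove objects touching the image border
#'
#' @param labels integer label matrix.
#' @return Label matrix with border-touching objects removed (ids of the
#'   survivors preserved).
#' @export
exclude_border_objects <- function(labels) {
  .check_matrix(labels, "labels")
  storage.mode(labels) <- "integer"
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- border[border > 0]
  if (length(border)) labels[labels %in% border] <- 0L
  labels
}

#' Remove objects below a minimum area
#'
#' @param labels integer label matrix.
#' @param min_area_um2 minimum retained object area in square micrometres.
#' @param pixel_size pixel edge length in micrometres.
#' @return Filtered label matrix (ids preserved).
#' @export
filter_min_area <- function(labels, min_area_um2, pixel_size = 1) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L || min_area_um2 <= 0) return(labels)
  f <- factor(labels[labels > 0], levels = ids)
  npx <- tabulate(f, length(ids))
  drop <- ids[npx * pixel_size^2 < min_area_um2]
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}
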