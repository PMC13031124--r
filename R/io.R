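# TIFF and config IO. Label maps travel as 16-bit single-channel TIFF;
# multi-channel images as multi-page float TIFF with a channel-name map.

#' Read a multi-channel TIFF as a named channel list
#'
#' @param path TIFF file with one page per channel.
#' @param channels channel names in page order
#'   (default `c("mito", "ld", "actin")`).
#' @param pixel_size pixel edge length in micrometres.
#' @return A [multichannel_image()] when the three standard channels are
#'   present, otherwise a named list of matrices.
#' @export
read_multichannel_tiff <- function(path, channels = c("mito", "ld", "actin"),
                                   pixel_size = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < length(channels))
    .stopf("expected %d channel pages, found %d", length(channels),
           length(pages))
  chans <- lapply(pages[seq_along(channels)], function(p)
    if (length(dim(p)) == 3L) p[, , 1] else p)
  names(chans) <- channels
  if (all(c("mito", "ld", "actin") %in% channels))
    multichannel_image(chans$mito, chans$ld, chans$actin, pixel_size)
  else chans
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' Channels are rescaled to \[0, 1\] floats for storage.
#'
#' @param img a [multichannel_image()] or named list of matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(img, path) {
  chans <- if (inherits(img, "multichannel_image")) img$channels else img
  pages <- lapply(chans, function(ch) {
    m <- pmax(ch, 0)
    if (max(m) > 1) m <- m / max(m)
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read an integer label map from a 16-bit TIFF
#'
#' @param path TIFF path written by [write_label_tiff()].
#' @return Integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write an integer label map as a 16-bit TIFF
#'
#' @param labels integer matrix, values in `0..65535`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) .stopf("labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with any of: `channels` (name map), `sigma_um`,
#' `ld_intensity_quantile`, `min_cell_area_um2`, `min_mito_area_um2`,
#' `min_ld_area_um2`, `pixel_size`, `n_bins`, `overlap_denominator`,
#' `backend`. Missing keys fall back to package defaults.
#'
#' @param path config file path; `NULL` returns the defaults.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    channels = list(mito = 1L, ld = 2L, actin = 3L),
    sigma_um = 2, ld_intensity_quantile = 0.25,
    min_cell_area_um2 = 100, min_mito_area_um2 = 0.2,
    min_ld_area_um2 = 0.2, pixel_size = 0.2, n_bins = 12L,
    overlap_denominator = "ld", backend = NULL)
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  }
  utils::modifyList(defaults, cfg)
}
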