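#' Vein annotation for one PP-PC axis
#'
#' Bundles the central-vein (CV) and portal-vein (PV) landmark masks of one
#' manually cropped porto-central axis together with the pixel calibration.
#' All downstream spatial coordinates (distance to the CV, normalized
#' position, zonal bin) are derived from this annotation.
#'
#' @param cv,pv binary or logical matrices of equal dimension marking the
#'   central-vein and portal-vein regions. Both must be non-empty and
#'   disjoint.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param axis_id identifier of the axis.
#' @return An object of class `vein_annotation`.
#' @seealso [veins_from_labels()], [measure_axis_length()]
#' @export
vein_annotation <- function(cv, pv, pixel_size, axis_id = "axis1") {
  .check_matrix(cv, "cv"); .check_matrix(pv, "pv")
  .same_dim(cv, pv, "vein masks")
  cv <- cv > 0; pv <- pv > 0
  if (!any(cv)) .stopf("annotation error: central-vein region is empty")
  if (!any(pv)) .stopf("annotation error: portal-vein region is empty")
  if (any(cv & pv)) .stopf("geometry error: CV and PV regions overlap")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    .stopf("pixel_size must be a single positive number (um per pixel)")
  structure(
    list(cv = cv, pv = pv, pixel_size = pixel_size,
         axis_id = as.character(axis_id), dim = dim(cv)),
    class = "vein_annotation"
  )
}

#' Build a vein annotation from an integer label map
#'
#' Label conventions follow the on-disk format: 1 = central vein, 2 = portal
#' vein, 0 = background.
#'
#' @param labels integer matrix with CV pixels labelled 1 and PV pixels 2.
#' @inheritParams vein_annotation
#' @return A `vein_annotation`.
#' @export
veins_from_labels <- function(labels, pixel_size, axis_id = "axis1") {
  .check_matrix(labels, "labels")
  vein_annotation(labels == 1, labels == 2, pixel_size, axis_id)
}

#' Build a vein annotation from polygon outlines
#'
#' Rasterizes CV/PV polygons (vertices in 0-based pixel coordinates,
#' columns x then y) onto a pixel grid of the given dimension. Pixel centres
#' inside the polygon are included.
#'
#' @param polygons a list with elements `cv` and `pv`, each an n x 2 matrix
#'   of polygon vertices, or a path to a JSON file holding the same.
#' @param dim image dimension `c(nrow, ncol)`.
#' @inheritParams vein_annotation
#' @return A `vein_annotation`.
#' @export
veins_from_polygons <- function(polygons, dim, pixel_size, axis_id = "axis1") {
  if (is.character(polygons))
    polygons <- jsonlite::read_json(polygons, simplifyVector = TRUE)
  if (!requireNamespace("mgcv", quietly = TRUE))
    .stopf("polygon rasterization requires the 'mgcv' package")
  rasterize <- function(poly) {
    poly <- as.matrix(poly)
    grid <- expand.grid(y = seq_len(dim[1]) - 1, x = seq_len(dim[2]) - 1)
    inside <- mgcv::in.out(rbind(poly, poly[1, ]),
                           cbind(grid$x, grid$y))
    matrix(inside, nrow = dim[1])
  }
  vein_annotation(rasterize(polygons$cv), rasterize(polygons$pv),
                  pixel_size, axis_id)
}

#' Measure the PP-PC axis length
#'
#' The axis length is the minimal boundary-to-boundary Euclidean distance
#' between the CV and PV regions of one cropped axis, in micrometres.
#' Distances are measured between pixel centres of the region boundaries.
#'
#' @param annotation a [vein_annotation()].
#' @return An object of class `axis_record` with fields `axis_id`,
#'   `length_um`, `length_px` and `endpoints` (2 x 2 matrix of 0-based
#'   (x, y) coordinates on the CV and PV boundaries, in that order).
#' @export
measure_axis_length <- function(annotation) {
  stopifnot(inherits(annotation, "vein_annotation"))
  cvb <- pixel_xy(mask_boundary(annotation$cv))
  pvb <- pixel_xy(mask_boundary(annotation$pv))
  hit <- min_cross_distance(cvb, pvb)
  if (!is.finite(hit$d) || hit$d <= 0)
    .stopf("geometry error: degenerate axis (CV/PV boundaries coincide)")
  endpoints <- rbind(cv = cvb[hit$i, ], pv = pvb[hit$j, ])
  axis_record(annotation$axis_id, hit$d * annotation$pixel_size,
              endpoints, length_px = hit$d)
}

#' Construct an axis record directly
#'
#' Used internally by [measure_axis_length()] and available as a polyline
#' override for curved axes whose length is measured manually.
#'
#' @param axis_id axis identifier.
#' @param length_um axis length in micrometres (> 0).
#' @param endpoints optional 2 x 2 matrix of (x, y) endpoints.
#' @param length_px optional axis length in pixels.
#' @return An `axis_record`.
#' @export
axis_record <- function(axis_id, length_um, endpoints = NULL,
                        length_px = NA_real_) {
  if (!is.numeric(length_um) || length_um <= 0)
    .stopf("geometry error: axis length must be positive")
  structure(list(axis_id = as.character(axis_id), length_um = length_um,
                 length_px = length_px, endpoints = endpoints),
            class = "axis_record")
}

#' Normalized porto-central coordinate of cell centroids
#'
#' Each centroid receives `d_cv_um`, its Euclidean distance to the nearest
#' central-vein boundary pixel, and `d_norm = d_cv_um / length_um` clamped
#' to \[0, 1\]. Cells whose raw ratio exceeds 1 (outside the cropped axis)
#' are clamped and flagged.
#'
#' @param centroids an n x 2 matrix or data frame of 0-based (x, y) pixel
#'   coordinates.
#' @param annotation a [vein_annotation()].
#' @param axis an `axis_record` for the same axis.
#' @return A data frame with columns `d_cv_um`, `d_norm` and `clamped`.
#' @export
compute_normalized_coordinate <- function(centroids, annotation, axis) {
  stopifnot(inherits(annotation, "vein_annotation"),
            inherits(axis, "axis_record"))
  if (axis$length_um <= 0) .stopf("geometry error: zero axis length")
  xy <- as.matrix(centroids[, 1:2, drop = FALSE])
  d <- dim(annotation$cv)
  if (any(xy[, 1] < 0 | xy[, 1] > d[2] - 1 | xy[, 2] < 0 | xy[, 2] > d[1] - 1))
    .stopf("centroid outside image bounds")
  cvb <- pixel_xy(mask_boundary(annotation$cv))
  d_cv <- min_dist_to_set(xy, cvb) * annotation$pixel_size
  raw <- d_cv / axis$length_um
  data.frame(d_cv_um = d_cv, d_norm = pmin(pmax(raw, 0), 1),
             clamped = raw > 1)
}

#' Assign zonal bins along the PP-PC axis
#'
#' The normalized coordinate (0 at the central vein, 1 at the portal vein)
#' is partitioned into `n_bins` half-open intervals. Bin `n_bins` is
#' adjacent to the central vein and bin 1 is adjacent to the portal
#' vessels, so `bin_index = n_bins - floor(d_norm * n_bins)` clamped to
#' `[1, n_bins]`.
#'
#' @param d_norm numeric vector of normalized coordinates in \[0, 1\].
#' @param n_bins number of bins (default 12).
#' @return Integer vector of bin indices in `1..n_bins`.
#' @export
assign_bin <- function(d_norm, n_bins = 12L) {
  if (n_bins < 1) .stopf("n_bins must be >= 1")
  if (any(!is.finite(d_norm)) || any(d_norm < 0 | d_norm > 1))
    .stopf("domain error: d_norm must lie in [0, 1]")
  as.integer(pmin(pmax(n_bins - floor(d_norm * n_bins), 1L), n_bins))
}

#' Locate segmented cells along the PP-PC axis
#'
#' Computes centroids and areas from a cell label map and derives the
#' normalized coordinate and zonal bin of every cell.
#'
#' @param cell_labels integer label matrix (0 = background).
#' @param annotation a [vein_annotation()].
#' @param axis an `axis_record`; measured from `annotation` when `NULL`.
#' @param n_bins number of zonal bins (default 12).
#' @param drop_clamped drop cells whose raw coordinate exceeded 1 instead of
#'   clamping them (default `FALSE`).
#' @return A data frame of cell records: `cell_id`, `x`, `y`, `area_um2`,
#'   `d_cv_um`, `d_norm`, `clamped`, `bin_index`, `axis_id`.
#' @export
locate_cells <- function(cell_labels, annotation, axis = NULL, n_bins = 12L,
                         drop_clamped = FALSE) {
  .check_matrix(cell_labels, "cell_labels")
  stopifnot(inherits(annotation, "vein_annotation"))
  .same_dim(cell_labels, annotation$cv, "cell labels and vein masks")
  if (is.null(axis)) axis <- measure_axis_length(annotation)
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                      area_um2 = numeric(), d_cv_um = numeric(),
                      d_norm = numeric(), clamped = logical(),
                      bin_index = integer(), axis_id = character()))
  idx <- which(cell_labels > 0, arr.ind = TRUE)
  lab <- cell_labels[cell_labels > 0]
  cx <- tapply(idx[, 2] - 1, lab, mean)[as.character(ids)]
  cy <- tapply(idx[, 1] - 1, lab, mean)[as.character(ids)]
  npx <- tapply(lab, lab, length)[as.character(ids)]
  pos <- compute_normalized_coordinate(cbind(cx, cy), annotation, axis)
  out <- data.frame(cell_id = as.integer(ids), x = as.numeric(cx),
                    y = as.numeric(cy),
                    area_um2 = as.numeric(npx) * annotation$pixel_size^2,
                    d_cv_um = pos$d_cv_um, d_norm = pos$d_norm,
                    clamped = pos$clamped,
                    bin_index = assign_bin(pos$d_norm, n_bins),
                    axis_id = annotation$axis_id,
                    row.names = NULL)
  if (drop_clamped) out <- out[!out$clamped, , drop = FALSE]
  out
}

#' Write cell records to CSV
#'
#' @param cells data frame from [locate_cells()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
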