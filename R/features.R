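#' Circularity (2D sphericity proxy)
#'
#' `4 * pi * area / perimeter^2`: 1 for an ideal disk, smaller for
#' elongated shapes. Reported for mitochondria as a 2D proxy of sphericity.
#'
#' @param area object area (any unit, squared length).
#' @param perimeter object perimeter (same length unit).
#' @return Numeric vector of circularity values.
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    .stopf("domain error: area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Per-object shape features of a label map
#'
#' One record per labelled object: area (pixel count x pixel_size^2),
#' perimeter (weighted boundary-step contour length: orthogonal steps weigh
#' 1 and diagonal steps sqrt(2)), circularity, eccentricity (from second
#' central moments), solidity (area over convex-hull area, hull taken over
#' pixel corners so solid convex objects score exactly 1), Feret diameter
#' (longest distance between any two boundary-pixel centres) and mean
#' intensity. Circularity is `NA` for degenerate single-pixel contours.
#'
#' @param labels integer label matrix (0 = background).
#' @param intensity optional intensity matrix of the same dimension.
#' @param pixel_size pixel edge length in micrometres.
#' @return A data frame with one row per object: `object_id`, `npx`,
#'   `area_um2`, `perimeter_um`, `circularity`, `eccentricity`, `solidity`,
#'   `feret_um`, `mean_intensity`, `centroid_x`, `centroid_y`.
#' @export
shape_features <- function(labels, intensity = NULL, pixel_size = 1) {
  .check_matrix(labels, "labels")
  storage.mode(labels) <- "integer"
  if (!is.null(intensity)) .same_dim(labels, intensity, "labels and intensity")
  ids <- sort(unique(labels[labels > 0]))
  empty <- data.frame(object_id = integer(), npx = integer(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      circularity = numeric(), eccentricity = numeric(),
                      solidity = numeric(), feret_um = numeric(),
                      mean_intensity = numeric(), centroid_x = numeric(),
                      centroid_y = numeric())
  if (length(ids) == 0L) return(empty)

  pos <- which(labels > 0)
  idx <- arrayInd(pos, dim(labels))
  lab <- labels[pos]
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  f <- factor(lab, levels = ids)
  npx <- as.integer(tabulate(f, nbins = length(ids)))
  sx <- rowsum(x, f); sy <- rowsum(y, f)
  cx <- sx / npx; cy <- sy / npx
  # second central moments for eccentricity (+1/12 point-spread of a pixel)
  dx <- x - cx[as.integer(f)]; dy <- y - cy[as.integer(f)]
  mu20 <- rowsum(dx * dx, f) / npx + 1 / 12
  mu02 <- rowsum(dy * dy, f) / npx + 1 / 12
  mu11 <- rowsum(dx * dy, f) / npx
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  ecc <- sqrt(pmax(1 - l2 / l1, 0))

  per_px <- cpp_label_perimeters(labels, as.integer(ids))

  bnd <- mask_boundary(labels > 0) & labels > 0
  # objects touching other objects keep their own boundary via per-object pass
  feret <- numeric(length(ids)); solidity <- numeric(length(ids))
  mean_int <- rep(NA_real_, length(ids))
  xs <- split(x, f); ys <- split(y, f)
  if (!is.null(intensity)) {
    ivals <- rowsum(intensity[pos], f)
    mean_int <- as.numeric(ivals) / npx
  }
  for (k in seq_along(ids)) {
    px <- xs[[k]]; py <- ys[[k]]
    feret[k] <- .feret_diameter(px, py)
    solidity[k] <- npx[k] / .corner_hull_area(px, py)
  }
  area <- npx * pixel_size^2
  per <- per_px * pixel_size
  circ <- ifelse(per > 0, 4 * pi * area / per^2, NA_real_)
  data.frame(object_id = as.integer(ids), npx = npx, area_um2 = area,
             perimeter_um = per, circularity = circ,
             eccentricity = as.numeric(ecc), solidity = solidity,
             feret_um = feret * pixel_size, mean_intensity = mean_int,
             centroid_x = as.numeric(cx), centroid_y = as.numeric(cy))
}

# centroids of labelled objects without the full feature pass
.label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    return(data.frame(object_id = integer(), centroid_x = numeric(),
                      centroid_y = numeric()))
  pos <- which(labels > 0)
  idx <- arrayInd(pos, dim(labels))
  f <- factor(labels[pos], levels = ids)
  npx <- tabulate(f, nbins = length(ids))
  data.frame(object_id = as.integer(ids),
             centroid_x = as.numeric(rowsum(idx[, 2] - 1, f) / npx),
             centroid_y = as.numeric(rowsum(idx[, 1] - 1, f) / npx))
}

# longest pairwise distance between pixel centres (via the convex hull,
# identical to the exhaustive boundary-pair maximum)
.feret_diameter <- function(px, py) {
  n <- length(px)
  if (n == 1L) return(0)
  pts <- cbind(px, py)
  h <- if (n > 3L) unique(pts[chull(pts), , drop = FALSE]) else pts
  dx <- outer(h[, 1], h[, 1], "-"); dy <- outer(h[, 2], h[, 2], "-")
  sqrt(max(dx * dx + dy * dy))
}

# convex-hull area over the 4 corners of every pixel (shoelace formula);
# always >= pixel count, so solidity <= 1
.corner_hull_area <- function(px, py) {
  corners <- cbind(c(px - 0.5, px + 0.5, px - 0.5, px + 0.5),
                   c(py - 0.5, py - 0.5, py + 0.5, py + 0.5))
  h <- corners[chull(corners), , drop = FALSE]
  n <- nrow(h)
  j <- c(2:n, 1)
  abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
}

#' Percent mitochondria/lipid-droplet pixel overlap
#'
#' The percentage of LD pixels that are also mitochondria pixels, optionally
#' restricted to a cell mask: `100 * |mito & ld & cell| / |ld & cell|`.
#' Defined as 0 when there are no LD pixels. `denominator = "mito"` switches
#' to the mitochondria-normalized variant.
#'
#' @param mito_mask,ld_mask,cell_mask binary masks of equal dimension;
#'   `cell_mask = NULL` uses the whole image.
#' @param denominator `"ld"` (default) or `"mito"`.
#' @return A list with `overlap_pct` and the raw `overlap_px` count.
#' @export
mito_ld_overlap <- function(mito_mask, ld_mask, cell_mask = NULL,
                            denominator = c("ld", "mito")) {
  denominator <- match.arg(denominator)
  .same_dim(mito_mask, ld_mask, "organelle masks")
  m <- mito_mask > 0; l <- ld_mask > 0
  if (!is.null(cell_mask)) {
    .same_dim(mito_mask, cell_mask, "organelle and cell masks")
    cc <- cell_mask > 0
    m <- m & cc; l <- l & cc
  }
  inter <- sum(m & l)
  denom <- if (denominator == "ld") sum(l) else sum(m)
  list(overlap_pct = if (denom == 0) 0 else 100 * inter / denom,
       overlap_px = inter)
}

#' Shortest mitochondria-to-lipid-droplet distances
#'
#' For each LD object, the minimal Euclidean pixel-centre distance from any
#' of its pixels to any mitochondria pixel (0 when the LD overlaps or
#' coincides with mitochondria). The per-cell summary value is the mean over
#' LDs ("average organelle min dist"); the minimum over LDs is also
#' returned. Distances are exact pixel-pair minima.
#'
#' @param mito_mask binary mitochondria mask.
#' @param ld binary LD mask or integer LD label matrix (labels preserve
#'   object identity; a plain mask is labelled by connected components).
#' @param cell_mask optional cell mask restricting both organelle sets.
#' @param pixel_size pixel edge length in micrometres.
#' @return A list: `per_ld` (data frame `ld_id`, `dist_um`),
#'   `avg_min_dist_um`, `min_dist_um` (both `NA` if no LDs, `Inf` if LDs
#'   present but no mitochondria).
#' @export
min_organelle_distance <- function(mito_mask, ld, cell_mask = NULL,
                                   pixel_size = 1) {
  .same_dim(mito_mask, ld, "organelle masks")
  m <- mito_mask > 0
  ld_lab <- if (any(ld > 1)) ld else EBImage::bwlabel(ld > 0)
  ld_lab <- matrix(as.integer(ld_lab), nrow = nrow(ld))
  if (!is.null(cell_mask)) {
    cc <- cell_mask > 0
    m <- m & cc
    ld_lab[!cc] <- 0L
  }
  ids <- sort(unique(ld_lab[ld_lab > 0]))
  if (length(ids) == 0L)
    return(list(per_ld = data.frame(ld_id = integer(), dist_um = numeric()),
                avg_min_dist_um = NA_real_, min_dist_um = NA_real_))
  mpx <- pixel_xy(m)
  dists <- vapply(ids, function(id) {
    lpx <- pixel_xy(ld_lab == id)
    if (nrow(mpx) == 0L) return(Inf)
    min(min_dist_to_set(lpx, mpx))
  }, numeric(1)) * pixel_size
  list(per_ld = data.frame(ld_id = as.integer(ids), dist_um = dists),
       avg_min_dist_um = mean(dists), min_dist_um = min(dists))
}

#' Assign organelle objects to cells by centroid containment
#'
#' An organelle belongs to the cell whose label covers its centroid pixel.
#' Centroids falling on background are reassigned to the nearest cell within
#' `max_dist_um`; otherwise the object is dropped (with a message).
#'
#' @param org_labels integer organelle label matrix.
#' @param cell_labels integer cell label matrix of the same dimension.
#' @param pixel_size pixel edge length in micrometres.
#' @param max_dist_um rescue radius for background centroids (default 2).
#' @return Data frame `object_id`, `cell_id` (dropped objects omitted).
#' @export
assign_organelles_to_cells <- function(org_labels, cell_labels,
                                       pixel_size = 1, max_dist_um = 2) {
  .same_dim(org_labels, cell_labels, "organelle and cell labels")
  feats <- .label_centroids(org_labels)
  if (nrow(feats) == 0L)
    return(data.frame(object_id = integer(), cell_id = integer()))
  r <- round(feats$centroid_y) + 1L
  c <- round(feats$centroid_x) + 1L
  cell <- cell_labels[cbind(r, c)]
  if (any(cell == 0L)) {
    max_px <- max_dist_um / pixel_size
    cpx <- pixel_xy(cell_labels > 0)
    clab <- cell_labels[cell_labels > 0]
    for (k in which(cell == 0L)) {
      d <- sqrt((cpx[, 1] - feats$centroid_x[k])^2 +
                (cpx[, 2] - feats$centroid_y[k])^2)
      j <- which.min(d)
      if (length(j) == 1L && d[j] <= max_px) cell[k] <- clab[j]
    }
    if (any(cell == 0L))
      message(sum(cell == 0L),
              " organelle(s) with background centroid beyond ",
              max_dist_um, " um of any cell were dropped")
  }
  keep <- cell > 0L
  data.frame(object_id = feats$object_id[keep], cell_id = as.integer(cell[keep]))
}

#' Per-cell organelle feature vectors
#'
#' Aggregates per-object shape features and contact metrics into one row per
#' cell: the 12 zonal profiling variables (counts, total area, average area,
#' perimeter, eccentricity, solidity, Feret, circularity, mean organelle
#' channel intensities, average mito-LD minimal distance, density) for
#' mitochondria and LDs, plus percent mito-LD overlap and raw overlapping
#' pixel counts. Density is the organelle area fraction of the cell area
#' (organelle pixels clipped to the cell); a count-per-area column is
#' exported alongside. Averages over zero objects are `NA`; overlap over
#' zero LD pixels is 0.
#'
#' @param cell_labels,mito_labels,ld_labels integer label matrices of equal
#'   dimension.
#' @param mito_channel,ld_channel optional intensity matrices.
#' @param geometry optional data frame from [locate_cells()]; joined by
#'   `cell_id` to attach `d_norm`, `bin_index` and `axis_id`.
#' @param pixel_size pixel edge length in micrometres.
#' @param overlap_denominator `"ld"` (default) or `"mito"`, see
#'   [mito_ld_overlap()].
#' @return A data frame, one row per cell.
#' @export
cell_feature_vectors <- function(cell_labels, mito_labels, ld_labels,
                                 mito_channel = NULL, ld_channel = NULL,
                                 geometry = NULL, pixel_size = 1,
                                 overlap_denominator = "ld") {
  .same_dim(cell_labels, mito_labels, "cell and mito labels")
  .same_dim(cell_labels, ld_labels, "cell and LD labels")
  storage.mode(cell_labels) <- "integer"
  storage.mode(mito_labels) <- "integer"
  storage.mode(ld_labels) <- "integer"
  cells <- shape_features(cell_labels, pixel_size = pixel_size)
  if (nrow(cells) == 0L) .stopf("no cells in cell_labels")
  mito <- shape_features(mito_labels, mito_channel, pixel_size)
  ld <- shape_features(ld_labels, ld_channel, pixel_size)
  mito_map <- assign_organelles_to_cells(mito_labels, cell_labels, pixel_size)
  ld_map <- assign_organelles_to_cells(ld_labels, cell_labels, pixel_size)

  agg_kind <- function(feats, map, prefix) {
    out <- data.frame(cell_id = cells$object_id)
    cols <- c(count = NA, total_area = NA, avg_area = NA, avg_perimeter = NA,
              avg_eccentricity = NA, avg_solidity = NA, avg_feret = NA,
              avg_circularity = NA, avg_int = NA)
    for (nm in names(cols)) out[[paste0(prefix, "_", nm)]] <- NA_real_
    out[[paste0(prefix, "_count")]] <- 0
    out[[paste0(prefix, "_total_area")]] <- 0
    for (i in seq_len(nrow(cells))) {
      cid <- cells$object_id[i]
      oid <- map$object_id[map$cell_id == cid]
      if (length(oid) == 0L) next
      f <- feats[match(oid, feats$object_id), , drop = FALSE]
      out[[paste0(prefix, "_count")]][i] <- nrow(f)
      out[[paste0(prefix, "_total_area")]][i] <- sum(f$area_um2)
      out[[paste0(prefix, "_avg_area")]][i] <- mean(f$area_um2)
      out[[paste0(prefix, "_avg_perimeter")]][i] <- mean(f$perimeter_um)
      out[[paste0(prefix, "_avg_eccentricity")]][i] <- mean(f$eccentricity)
      out[[paste0(prefix, "_avg_solidity")]][i] <- mean(f$solidity)
      out[[paste0(prefix, "_avg_feret")]][i] <- mean(f$feret_um)
      out[[paste0(prefix, "_avg_circularity")]][i] <-
        mean(f$circularity, na.rm = TRUE)
      out[[paste0(prefix, "_avg_int")]][i] <- mean(f$mean_intensity)
    }
    out
  }
  magg <- agg_kind(mito, mito_map, "mito")
  lagg <- agg_kind(ld, ld_map, "ld")

  n <- nrow(cells)
  res <- data.frame(cell_id = cells$object_id,
                    cell_area_um2 = cells$area_um2,
                    x = cells$centroid_x, y = cells$centroid_y)
  res <- cbind(res, magg[-1], lagg[-1])
  res$mito_density <- NA_real_; res$ld_density <- NA_real_
  res$mito_count_per_area <- NA_real_; res$ld_count_per_area <- NA_real_
  res$avg_min_dist_um <- NA_real_; res$min_dist_um <- NA_real_
  res$overlap_pct <- 0; res$overlap_px <- 0L

  for (i in seq_len(n)) {
    cid <- cells$object_id[i]
    cm <- cell_labels == cid
    # clip assigned organelle pixels to the cell for density/contact metrics
    mids <- mito_map$object_id[mito_map$cell_id == cid]
    lids <- ld_map$object_id[ld_map$cell_id == cid]
    mm <- matrix(mito_labels %in% mids, nrow = nrow(cm)) & cm
    ll <- ld_labels
    ll[!(cm & (ld_labels %in% lids))] <- 0L
    res$mito_density[i] <- sum(mm) / cells$npx[i]
    res$ld_density[i] <- sum(ll > 0) / cells$npx[i]
    res$mito_count_per_area[i] <- length(mids) / cells$area_um2[i]
    res$ld_count_per_area[i] <- length(lids) / cells$area_um2[i]
    ov <- mito_ld_overlap(mm, ll > 0, denominator = overlap_denominator)
    res$overlap_pct[i] <- ov$overlap_pct
    res$overlap_px[i] <- ov$overlap_px
    md <- min_organelle_distance(mm, ll, pixel_size = pixel_size)
    res$avg_min_dist_um[i] <- md$avg_min_dist_um
    res$min_dist_um[i] <- md$min_dist_um
  }
  if (!is.null(geometry)) {
    j <- match(res$cell_id, geometry$cell_id)
    for (col in intersect(c("d_cv_um", "d_norm", "bin_index", "axis_id"),
                          names(geometry)))
      res[[col]] <- geometry[[col]][j]
  }
  res
}

#' Write per-cell feature vectors to CSV
#'
#' @param features data frame from [cell_feature_vectors()].
#' @param path output file path.
#' @param condition optional condition label added as a column.
#' @return `path`, invisibly.
#' @export
write_cell_features <- function(features, path, condition = NULL) {
  if (!is.null(condition)) features$condition <- condition
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
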