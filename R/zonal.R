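# Zonal multivariate signatures: per-bin profiles, PCA, complete-linkage
# clustering, condition correlations, overlap heatmaps.

# the zonal profiling variables aggregated per bin, when present
.zonal_feature_cols <- function(cells) {
  drop <- c("cell_id", "x", "y", "bin_index", "axis_id", "condition",
            "clamped", "d_cv_um", "d_norm", "overlap_px")
  names(cells)[vapply(cells, is.numeric, logical(1)) &
                 !(names(cells) %in% drop)]
}

#' Aggregate per-cell features into per-bin zonal profiles
#'
#' Means, standard deviations and cell counts of every numeric feature per
#' zonal bin (R1..Rn). Empty bins are retained as `NA` rows and flagged.
#'
#' @param cells data frame of per-cell features carrying `bin_index`
#'   (from [cell_feature_vectors()] joined with [locate_cells()]).
#' @param features character vector of feature columns; `NULL` selects all
#'   numeric feature columns.
#' @param n_bins number of bins (default 12).
#' @param condition optional condition label stored with the profile.
#' @return An object of class `zonal_profile`: list with `mean`, `sd`
#'   (n_bins x features matrices), `n` (cells per bin), `condition`,
#'   `empty_bins`.
#' @export
aggregate_by_bin <- function(cells, features = NULL, n_bins = 12L,
                             condition = NULL) {
  if (!"bin_index" %in% names(cells))
    .stopf("cells must carry a 'bin_index' column")
  features <- features %||% .zonal_feature_cols(cells)
  bins <- factor(cells$bin_index, levels = seq_len(n_bins))
  mean_m <- sapply(features, function(f)
    tapply(cells[[f]], bins, mean, na.rm = TRUE))
  sd_m <- sapply(features, function(f)
    tapply(cells[[f]], bins, sd, na.rm = TRUE))
  n <- as.integer(tabulate(bins, n_bins))
  mean_m <- matrix(unlist(mean_m), nrow = n_bins,
                   dimnames = list(paste0("R", seq_len(n_bins)), features))
  sd_m <- matrix(unlist(sd_m), nrow = n_bins,
                 dimnames = dimnames(mean_m))
  sd_m[n == 1L, ] <- 0           # spread of a single cell is zero
  empty <- which(n == 0L)
  if (length(empty))
    warning("empty bins: ", paste0("R", empty, collapse = ", "))
  structure(list(mean = mean_m, sd = sd_m, n = n,
                 condition = condition, empty_bins = empty),
            class = "zonal_profile")
}

#' @export
print.zonal_profile <- function(x, ...) {
  cat("<zonal_profile>", nrow(x$mean), "bins x", ncol(x$mean), "features;",
      "condition:", x$condition %||% "<none>", "\n")
  invisible(x)
}

# coerce zonal_profile / matrix / stacked list to a plain matrix of means
.zonal_matrix <- function(x) {
  if (inherits(x, "zonal_profile")) {
    m <- x$mean
    if (length(x$empty_bins)) m <- m[-x$empty_bins, , drop = FALSE]
    return(m)
  }
  if (is.list(x) && !is.data.frame(x)) {
    mats <- lapply(x, .zonal_matrix)
    labels <- names(x) %||% seq_along(mats)
    for (i in seq_along(mats))
      rownames(mats[[i]]) <- paste(labels[i], rownames(mats[[i]]), sep = ".")
    return(do.call(rbind, mats))
  }
  as.matrix(x)
}

# z-score columns, dropping constant ones with a warning
.standardize <- function(m) {
  sds <- apply(m, 2, sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning("dropping constant feature(s): ",
            paste(colnames(m)[bad], collapse = ", "))
    m <- m[, !bad, drop = FALSE]
  }
  scale(m)
}

#' Principal component analysis of zonal feature profiles
#'
#' Features are z-score standardized before the decomposition; constant
#' columns are dropped with a warning. Component orientation is made
#' deterministic by forcing the largest-magnitude loading of each component
#' positive.
#'
#' @param x a `zonal_profile`, a bins x features matrix, or a named list of
#'   profiles (conditions stacked row-wise).
#' @param n_components number of components returned (2 or 3; default 3).
#' @return An object of class `zonal_pca`: list with `scores`, `loadings`,
#'   `explained` (variance fractions).
#' @export
zonal_pca <- function(x, n_components = 3L) {
  m <- .zonal_matrix(x)
  if (nrow(m) < 2L) .stopf("PCA needs at least 2 rows")
  if (!n_components %in% 2:3) .stopf("n_components must be 2 or 3")
  z <- .standardize(m)
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = rot,
                 explained = ev[seq_len(k)]),
            class = "zonal_pca")
}

#' Complete-linkage clustering of zonal profiles
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance) of bins and of features, both on z-score standardized values —
#' the ordering machinery behind dendrogram heatmaps.
#'
#' @param x a `zonal_profile`, matrix, or named list of profiles.
#' @return A list with `row_hclust`, `col_hclust`, `row_order`, `col_order`
#'   and the standardized matrix `z`.
#' @export
cluster_zones <- function(x) {
  m <- .zonal_matrix(x)
  if (nrow(m) < 2L) .stopf("clustering needs at least 2 rows")
  z <- .standardize(m)
  rh <- hclust(dist(z), method = "complete")
  ch <- if (ncol(z) >= 2L) hclust(dist(t(z)), method = "complete") else NULL
  list(row_hclust = rh, col_hclust = ch, row_order = rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(z)) else ch$order, z = z)
}

#' Pearson correlation between the zonal profiles of two conditions
#'
#' Both layouts of the comparison are produced: `bins` correlates the
#' feature vectors of each bin pair (standardized within condition so the
#' comparison is not dominated by feature scale), and `features` correlates
#' the bin-wise profile of each feature pair across the axis. Display
#' values are rounded to two decimals; raw values are retained.
#'
#' @param a,b `zonal_profile` objects (or matrices) with matching feature
#'   columns.
#' @return An object of class `condition_correlation`: list with `bins`,
#'   `features`, `bins_display`, `features_display`.
#' @export
condition_correlation <- function(a, b) {
  ma <- .zonal_matrix(a); mb <- .zonal_matrix(b)
  if (!identical(colnames(ma), colnames(mb)))
    .stopf("feature columns of the two conditions do not match")
  za <- scale(ma); zb <- scale(mb)
  keep <- apply(is.finite(za), 2, all) & apply(is.finite(zb), 2, all)
  za <- za[, keep, drop = FALSE]; zb <- zb[, keep, drop = FALSE]
  rb <- suppressWarnings(cor(t(za), t(zb)))
  rf <- suppressWarnings(cor(ma, mb))
  if (any(!is.finite(rb)) || any(!is.finite(rf)))
    warning("zero-variance vectors produced missing correlation entries")
  structure(list(bins = rb, features = rf,
                 bins_display = round(rb, 2),
                 features_display = round(rf, 2)),
            class = "condition_correlation")
}

#' Mito-LD overlap heatmap across bins and conditions
#'
#' Per bin x condition mean percent overlap and summed overlapping-pixel
#' counts, mirroring the R1-R12 x diet contact heatmaps.
#'
#' @param cells data frame of per-cell features with `bin_index`,
#'   `overlap_pct`, `overlap_px` and `condition` columns.
#' @param n_bins number of bins (default 12).
#' @return An object of class `overlap_heatmap`: list with `pct` and `px`
#'   (n_bins x conditions matrices).
#' @export
overlap_heatmap <- function(cells, n_bins = 12L) {
  need <- c("bin_index", "overlap_pct", "overlap_px", "condition")
  if (!all(need %in% names(cells)))
    .stopf("cells must carry columns: %s", paste(need, collapse = ", "))
  bins <- factor(cells$bin_index, levels = seq_len(n_bins))
  conds <- factor(cells$condition)
  pct <- tapply(cells$overlap_pct, list(bins, conds), mean)
  px <- tapply(cells$overlap_px, list(bins, conds), sum)
  dimnames(pct) <- dimnames(px) <-
    list(paste0("R", seq_len(n_bins)), levels(conds))
  structure(list(pct = pct, px = px), class = "overlap_heatmap")
}

#' Write zonal profile matrices to CSV
#'
#' @param x a `zonal_profile`, `zonal_pca`, `condition_correlation` or
#'   `overlap_heatmap`.
#' @param prefix output path prefix; one CSV per component matrix.
#' @return The written paths, invisibly.
#' @export
write_zonal_csv <- function(x, prefix) {
  mats <- if (inherits(x, "zonal_profile")) {
    list(mean = x$mean, sd = x$sd, n = matrix(x$n, ncol = 1,
         dimnames = list(rownames(x$mean), "n_cells")))
  } else if (inherits(x, "zonal_pca")) {
    list(scores = x$scores, loadings = x$loadings,
         explained = matrix(x$explained, ncol = 1,
                            dimnames = list(NULL, "explained")))
  } else if (inherits(x, "condition_correlation")) {
    list(bins = x$bins_display, features = x$features_display)
  } else if (inherits(x, "overlap_heatmap")) {
    list(overlap_pct = x$pct, overlap_px = x$px)
  } else .stopf("unsupported object")
  paths <- character(0)
  for (nm in names(mats)) {
    p <- paste0(prefix, "_", nm, ".csv")
    write.csv(as.data.frame(mats[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Heatmap of a zonal profile (optional plotting helper)
#'
#' Draws a dendrogram heatmap of the standardized bin x feature matrix via
#' pheatmap with complete-linkage clustering, matching [cluster_zones()].
#'
#' @param x a `zonal_profile`, matrix, or named list of profiles.
#' @param filename optional output file.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_zonal_heatmap <- function(x, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    .stopf("plotting requires the 'pheatmap' package")
  cl <- cluster_zones(x)
  ph <- pheatmap::pheatmap(cl$z, clustering_method = "complete",
                           filename = filename, ...)
  invisible(ph)
}
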