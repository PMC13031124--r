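# Zonal profiles: bin aggregation, PCA, clustering, correlations, heatmaps

make_cells <- function(bins, area) {
  data.frame(bin_index = bins, mito_total_area = area,
             ld_count = rev(area), overlap_pct = area / 10,
             overlap_px = as.integer(area), condition = "X")
}

test_that("bin aggregation reproduces means, sds and counts", {
  cells <- make_cells(c(1, 1, 2), c(10, 20, 7))
  prof <- suppressWarnings(aggregate_by_bin(cells, n_bins = 3))
  expect_equal(prof$mean["R1", "mito_total_area"], 15)
  expect_equal(prof$sd["R1", "mito_total_area"], sqrt(50))
  expect_equal(prof$n, c(2L, 1L, 0L))
  # a single cell per bin keeps its values with zero spread
  expect_equal(prof$mean["R2", "mito_total_area"], 7)
  expect_equal(prof$sd["R2", "mito_total_area"], 0)
  expect_equal(prof$empty_bins, 3L)
  expect_warning(aggregate_by_bin(cells, n_bins = 3), "empty")
})

test_that("toy three-bin profile matches direct recomputation", {
  set.seed(4)
  cells <- data.frame(bin_index = sample(1:3, 30, TRUE),
                      f1 = rnorm(30), f2 = runif(30))
  prof <- aggregate_by_bin(cells, features = c("f1", "f2"), n_bins = 3)
  for (b in 1:3) {
    sel <- cells$bin_index == b
    expect_equal(prof$mean[b, "f1"], mean(cells$f1[sel]))
    expect_equal(prof$sd[b, "f2"], sd(cells$f2[sel]))
  }
})

test_that("PCA is standardized, oriented and matches the eigen oracle", {
  set.seed(8)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- zonal_pca(m, n_components = 2)
  # oracle: eigendecomposition of the correlation matrix
  z <- scale(m)
  ev <- eigen(cor(m))
  expect_equal(abs(p$scores[, 1]), abs(as.vector(z %*% ev$vectors[, 1])),
               tolerance = 1e-8)
  expect_equal(p$explained[1:2], (ev$values / sum(ev$values))[1:2])
  # deterministic orientation: largest-magnitude loading positive
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # explained variance fractions are non-increasing and bounded
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
})

test_that("PCA handles rank-1 and duplicated-row structure", {
  v <- c(1, 2, 3, 4)
  m <- cbind(f1 = v, f2 = 2 * v, f3 = -v)
  p <- zonal_pca(m, n_components = 2)
  expect_equal(p$explained[1], 1)
  dup <- rbind(m, m[4, ])
  p2 <- zonal_pca(dup, n_components = 2)
  expect_equal(p2$scores[4, ], p2$scores[5, ])
  # constant columns are dropped with a warning
  expect_warning(zonal_pca(cbind(m, k = rep(1, 4))), "constant")
})

test_that("complete-linkage clustering matches the exhaustive oracle", {
  # two identical rows merge first at height 0
  m <- rbind(c(0, 0), c(0, 0), c(3, 4))
  cl <- hclust(dist(m), method = "complete")
  expect_equal(cl$height[1], 0)
  # 1D points {0, 1, 10}: complete linkage joins 10 at height 10
  x <- matrix(c(0, 1, 10), ncol = 1)
  heights <- hclust(dist(x), method = "complete")$height
  expect_equal(heights, c(1, 10))
  expect_equal(heights, oracle_complete_linkage_heights(x))
  # random 5-row toys against the exhaustive agglomeration oracle
  set.seed(12)
  for (rep in 1:5) {
    y <- matrix(rnorm(15), 5, 3)
    expect_equal(hclust(dist(y), method = "complete")$height,
                 oracle_complete_linkage_heights(y))
  }
  # cluster_zones wires the standardized matrix through hclust
  mm <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, letters[1:4]))
  cz <- cluster_zones(mm)
  expect_equal(cz$row_hclust$height,
               oracle_complete_linkage_heights(scale(mm)))
})

test_that("condition correlations are bounded, symmetric and rounded", {
  set.seed(3)
  m <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  self <- condition_correlation(m, m)
  expect_equal(unname(diag(self$bins)), rep(1, 12))
  expect_equal(self$bins, t(self$bins))
  expect_true(all(abs(self$bins) <= 1 + 1e-12))
  # one feature vector negated -> r = -1 on the feature layout diagonal
  neg <- m; neg[, "a"] <- -neg[, "a"]
  cc <- condition_correlation(m, neg)
  expect_equal(unname(cc$features["a", "a"]), -1)
  # display rounding to two decimals, raw retained
  expect_equal(cc$bins_display, round(cc$bins, 2))
  # toy pair against the direct covariance formula
  a <- m[, 1]; b2 <- neg[, 2]
  r_direct <- sum((a - mean(a)) * (b2 - mean(b2))) /
    sqrt(sum((a - mean(a))^2) * sum((b2 - mean(b2))^2))
  expect_equal(unname(cc$features["a", "b"]), r_direct)
})

test_that("overlap heatmap averages percents and sums pixel counts", {
  cells <- rbind(
    data.frame(bin_index = c(1, 1, 2), overlap_pct = c(10, 30, 0),
               overlap_px = c(5L, 10L, 0L), condition = "CNTR"),
    data.frame(bin_index = c(1, 2), overlap_pct = c(50, 50),
               overlap_px = c(20L, 25L), condition = "fasted"))
  hm <- overlap_heatmap(cells, n_bins = 2)
  expect_equal(hm$pct["R1", "CNTR"], 20)
  expect_equal(hm$pct["R1", "fasted"], 50)
  expect_equal(hm$px["R2", "fasted"], 25)
  # all-zero overlaps give a zero matrix
  z <- cells; z$overlap_pct <- 0; z$overlap_px <- 0L
  expect_true(all(overlap_heatmap(z, n_bins = 2)$pct == 0))
})

test_that("zonal CSV writers emit one file per component matrix", {
  set.seed(2)
  cells <- data.frame(bin_index = rep(1:12, 2), f1 = rnorm(24),
                      f2 = rnorm(24))
  prof <- aggregate_by_bin(cells, features = c("f1", "f2"))
  prefix <- tempfile()
  paths <- write_zonal_csv(prof, prefix)
  on.exit(unlink(paths))
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[grepl("mean", paths)], row.names = 1)
  expect_equal(as.matrix(back), prof$mean, ignore_attr = TRUE)
})
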