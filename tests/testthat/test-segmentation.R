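# Guidance channel, pluggable segmentation contract, label-map filters

test_that("guidance channel is the sum of min-max scaled inputs", {
  actin <- matrix(runif(100), 10, 10)
  zeros <- matrix(0, 10, 10)
  g <- build_cell_guidance_channel(actin, zeros, sigma_um = 0)
  expect_equal(g, (actin - min(actin)) / diff(range(actin)))
  # constant channels give constant output (blur invariance)
  g2 <- build_cell_guidance_channel(matrix(1, 5, 5), matrix(2, 5, 5),
                                    sigma_um = 1, pixel_size = 1)
  expect_true(all(g2 == g2[1]))
  expect_error(build_cell_guidance_channel(actin, matrix(0, 5, 5)), "dim")
})

test_that("Gaussian blur of an impulse matches dense convolution", {
  mito <- matrix(0, 9, 9); mito[5, 5] <- 1
  actin <- matrix(0, 9, 9)
  g <- build_cell_guidance_channel(actin, mito, sigma_um = 1, pixel_size = 1)
  # direct discrete Gaussian convolution oracle (normalized to peak 1 as the
  # guidance channel min-max rescales)
  k <- outer(-4:4, -4:4, function(i, j) exp(-(i^2 + j^2) / 2))
  k <- k / sum(k)
  expect_equal(g[5, 5], max(k) / max(k), tolerance = 1e-6)
  expect_equal(g[5, 6] / g[5, 5], k[5, 6] / k[5, 5], tolerance = 0.02)
})

test_that("blank and trivial images segment as expected", {
  blank <- matrix(0, 40, 40)
  expect_equal(max(segment_cells(blank)), 0)
  expect_equal(max(segment_organelles(blank, "mito")), 0)
  # two well-separated bright blobs
  ch <- matrix(0, 40, 40)
  ch[5:10, 5:10] <- 1; ch[25:32, 25:32] <- 1
  lab <- segment_organelles(ch, "ld", min_area_um2 = 0)
  expect_equal(length(unique(lab[lab > 0])), 2L)
  ch[15:18, 15:18] <- 1
  expect_equal(length(setdiff(unique(segment_organelles(ch, "ld",
    min_area_um2 = 0)), 0L)), 3L)
})

test_that("fallback cell segmentation recovers synthetic cells at IoU 0.5", {
  ax <- quiet_axis("CNTR", seed = 101, noise = 0.02)
  img <- ax$image
  g <- build_cell_guidance_channel(img$channels$actin, img$channels$mito,
                                   sigma_um = 2, pixel_size = img$pixel_size)
  seg <- segment_cells(g, pixel_size = img$pixel_size)
  expect_gte(match_fraction_iou(seg, ax$labels$cell, 0.5), 0.9)
})

test_that("fallback organelle segmentation counts match ground truth", {
  ax <- quiet_axis("CNTR", seed = 101, noise = 0.02)
  img <- ax$image
  lseg <- segment_organelles(img$channels$ld, "ld",
                             pixel_size = img$pixel_size)
  true_n <- length(unique(ax$labels$ld[ax$labels$ld > 0]))
  seg_n <- length(unique(lseg[lseg > 0]))
  expect_lte(abs(seg_n - true_n) / true_n, 0.1)
})

test_that("segmentation backend contract surfaces failures with identity", {
  bad_backend <- function(ch) stop("boom")
  expect_error(segment_cells(matrix(1, 5, 5), backend = bad_backend),
               "bad_backend")
  # a trivial custom backend flows through filtering untouched
  passthrough <- function(ch) matrix(rep(c(0L, 1L), each = 50), 10, 10)
  lab <- segment_cells(matrix(1, 10, 10), backend = passthrough,
                       min_area_um2 = 0, drop_border = FALSE)
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L))
})

test_that("LD intensity filter removes dim objects and is idempotent", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L; lab[7:8, 7:8] <- 2L
  ch <- matrix(0, 10, 10)
  ch[lab == 1L] <- 10; ch[lab == 2L] <- 50
  out <- filter_ld_by_intensity(lab, ch, threshold = 30)
  expect_identical(sort(unique(as.vector(out))), c(0L, 2L))  # ids preserved
  # idempotence at fixed threshold
  out2 <- filter_ld_by_intensity(out, ch, threshold = 30)
  expect_identical(as.vector(out2), as.vector(out))
  # threshold 0 is the identity; a threshold above max empties the map
  expect_identical(as.vector(filter_ld_by_intensity(lab, ch, threshold = 0)),
                   as.vector(lab))
  expect_equal(max(filter_ld_by_intensity(lab, ch, threshold = 100)), 0L)
  # quantile default drops the dimmest quarter
  outq <- filter_ld_by_intensity(lab, ch)
  expect_identical(sort(unique(as.vector(outq))), c(0L, 2L))
})

test_that("border-object exclusion matches a brute-force border scan", {
  lab <- matrix(0L, 10, 10)
  lab[3:5, 3:5] <- 1L          # interior: survives
  lab[1, 4:6] <- 2L            # touches top border
  lab[8:10, 8] <- 3L           # touches bottom border
  out <- exclude_border_objects(lab)
  expect_identical(sort(unique(out[out > 0])), 1L)
  # interior-only map is untouched; full-row object is removed
  expect_identical(exclude_border_objects(out), out)
  full <- matrix(0L, 5, 5); full[3, ] <- 1L
  expect_equal(max(exclude_border_objects(full)), 0L)
})

test_that("label operations never merge or negate ids", {
  ax <- quiet_axis("CNTR", seed = 101)
  lab <- ax$labels$ld
  ch <- ax$image$channels$ld
  out <- filter_ld_by_intensity(lab, ch, threshold = 0.1)
  expect_true(all(out >= 0))
  expect_true(all(unique(out[out > 0]) %in% unique(lab[lab > 0])))
})

test_that("label maps round-trip through 16-bit TIFF", {
  lab <- matrix(sample(0:5, 200, TRUE), 10, 20)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_label_tiff(lab, path)
  expect_identical(read_label_tiff(path), lab)
})

test_that("multi-channel images round-trip through TIFF", {
  ax <- quiet_axis("CNTR", seed = 101)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_multichannel_tiff(ax$image, path)
  back <- read_multichannel_tiff(path, pixel_size = ax$image$pixel_size)
  expect_s3_class(back, "multichannel_image")
  expect_equal(dim(back$channels$mito), dim(ax$image$channels$mito))
  # stored values are rescaled to [0, 1]; correlation must be preserved
  expect_gt(cor(as.vector(back$channels$ld),
                as.vector(ax$image$channels$ld)), 0.999)
})
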