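# Normalization, linear-model contrasts, empirical-Bayes moderation,
# BH adjustment and zonation calls

test_that("channel-loading normalization equalizes column sums", {
  x <- matrix(c(1, 1, 2, 2), 2, 2)
  out <- channel_loading_normalize(x)
  expect_equal(colSums(out), rep(3, 2))
  expect_equal(out[1, ] / out[2, ], x[1, ] / x[2, ])  # within-column ratios
  # already equal -> identity; scaling a column is undone up to the global
  # abundance scale (the target is the mean column sum)
  y <- matrix(runif(40, 1, 2), 10, 4)
  y <- sweep(y, 2, colSums(y), "/")
  expect_equal(channel_loading_normalize(y), y)
  y2 <- y; y2[, 3] <- y2[, 3] * 7
  a <- channel_loading_normalize(y2); b <- channel_loading_normalize(y)
  expect_equal(a / mean(a), b / mean(b))
  expect_error(channel_loading_normalize(cbind(y, 0)), "zero column")
})

test_that("pooled-reference normalization removes batch offsets", {
  set.seed(6)
  base <- matrix(rexp(10), 5, 2)
  # batch 2 carries a 2x global intensity offset; last column per batch pooled
  x <- cbind(base, base[, 1], 2 * base, 2 * base[, 1])
  batch <- rep(c("b1", "b2"), each = 3)
  pooled <- rep(c(FALSE, FALSE, TRUE), 2)
  out <- pooled_reference_normalize(x, batch, pooled)
  expect_equal(out[, 3], rep(1, 5))               # pooled columns become 1
  expect_equal(out[, 6], rep(1, 5))
  expect_equal(out[, 1:2], out[, 4:5], ignore_attr = TRUE)  # offset removed
  # hand-computed ratios on a toy two-batch table
  expect_equal(out[, 1], base[, 1] / base[, 1])
  expect_equal(out[, 2], base[, 2] / base[, 1])
  # single batch where pooled equals every sample -> all ratios 1
  z <- matrix(5, 4, 3)
  expect_true(all(pooled_reference_normalize(z, rep("b", 3),
                                             c(FALSE, FALSE, TRUE)) == 1))
  expect_error(pooled_reference_normalize(z, rep("b", 3), rep(FALSE, 3)),
               "pooled")
})

test_that("quantile normalization matches the stated rule and limma", {
  # identical columns -> identity
  x <- matrix(rep(c(3, 1, 2), 3), 3, 3)
  expect_equal(quantile_normalize(x), x)
  # permuted columns share sorted values afterwards
  set.seed(13)
  y <- cbind(sample(1:6), sample(1:6))
  out <- quantile_normalize(y)
  expect_equal(sort(out[, 1]), sort(out[, 2]))
  # 4x3 toy with a tie: hand calculation with the mean-tie rule
  z <- matrix(c(2, 2, 6, 8,
                1, 3, 5, 7,
                4, 4, 4, 12), 4, 3)
  expect_equal(quantile_normalize(z), oracle_quantile_normalize(z))
  skip_if_not_installed("limma")
  w <- matrix(rexp(60), 15, 4)      # tie-free: must agree with limma
  expect_equal(quantile_normalize(w), limma::normalizeQuantiles(w),
               ignore_attr = TRUE)
})

test_that("linear-model contrasts recover group differences", {
  grp <- factor(rep(c("A", "B"), each = 3))
  X <- stats::model.matrix(~ 0 + grp)
  y <- rbind(c(5, 5, 5, 7, 7, 7))
  fit <- fit_contrasts(rbind(y, y), X, c(-1, 1))
  expect_equal(unname(fit$coefficients[1, 1]), 2)       # log2FC -> FC 4
  expect_equal(unname(2^fit$coefficients[1, 1]), 4)
  expect_equal(fit$df_residual[1], 4)
  # difference-of-differences vanishes for identical WD effects
  cmat <- dietgeno_contrasts(c("Null", "KO"))
  g <- factor(rep(c("Null.CD", "Null.WD", "KO.CD", "KO.WD"), each = 2),
              levels = rownames(cmat))
  Xg <- stats::model.matrix(~ 0 + g); colnames(Xg) <- levels(g)
  yy <- rbind(rep(c(1, 3, 4, 6), each = 2))   # WD effect = 2 in both
  fitg <- fit_contrasts(yy, Xg[, rownames(cmat)], cmat)
  expect_equal(unname(fitg$coefficients[1, "KO_vs_Null_WDeffect"]), 0)
  expect_equal(unname(fitg$coefficients[1, "KO_WDeffect"]), 2)
  expect_error(fit_contrasts(rbind(y), cbind(X, X[, 1]), c(-1, 1, 0)),
               "rank-deficient")
})

test_that("OLS estimates match the normal-equations oracle on a 2x2 design", {
  set.seed(17)
  g <- rep(c("Null.CD", "Null.WD", "KO.CD", "KO.WD"), each = 2)
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- sub("^g", "", colnames(X))
  cmat <- dietgeno_contrasts(c("Null", "KO"))
  X <- X[, rownames(cmat)]
  y <- matrix(rnorm(8 * 8), 8, 8)
  fit <- fit_contrasts(y, X, cmat)
  beta_oracle <- t(solve(t(X) %*% X, t(X) %*% t(y)))
  expect_equal(unname(fit$coefficients), unname(beta_oracle %*% cmat))
  res <- y - beta_oracle %*% t(X)
  expect_equal(fit$sigma2, rowSums(res^2) / 4, ignore_attr = TRUE)
})

test_that("moderation interpolates between ordinary and pooled t", {
  set.seed(23)
  grp <- factor(rep(c("A", "B"), each = 4))
  X <- stats::model.matrix(~ 0 + grp)
  y <- matrix(rnorm(50 * 8), 50, 8)
  fit <- fit_contrasts(y, X, c(-1, 1))
  # d0 = 0: ordinary two-sample t
  m0 <- moderate(fit, d0 = 0, s02 = 1)
  tt <- apply(y, 1, function(r)
    t.test(r[5:8], r[1:4], var.equal = TRUE)$statistic)
  expect_equal(unname(m0$t[, 1]), unname(tt))
  # fixed hyperparameters: closed-form shrinkage oracle
  mfix <- moderate(fit, d0 = 4, s02 = 0.8)
  oracle <- oracle_moderated_t(fit$coefficients[, 1],
                               fit$stdev_unscaled[, 1],
                               fit$sigma2, fit$df_residual, 4, 0.8)
  expect_equal(unname(mfix$t[, 1]), unname(oracle))
  expect_equal(unname(mfix$p[, 1]),
               unname(2 * pt(-abs(oracle), df = fit$df_residual + 4)))
  # d0 = Inf pools the variance completely
  minf <- moderate(fit, d0 = Inf, s02 = 0.9)
  expect_equal(unname(minf$t[, 1]),
               unname(fit$coefficients[, 1] /
                        (fit$stdev_unscaled[, 1] * sqrt(0.9))))
  # identical residual variances stay unshrunk
  sfit <- fit
  sfit$sigma2 <- rep(1.3, 50)
  ms <- moderate(sfit, d0 = 7, s02 = 1.3)
  expect_equal(ms$s2_post, rep(1.3, 50))
  # posterior variance lies between prior and sample variance
  expect_true(all(mfix$s2_post >= pmin(0.8, fit$sigma2) - 1e-12 &
                  mfix$s2_post <= pmax(0.8, fit$sigma2) + 1e-12))
})

test_that("estimated hyperparameters reproduce the limma eBayes fit", {
  skip_if_not_installed("limma")
  set.seed(31)
  grp <- factor(rep(c("A", "B"), each = 4))
  X <- stats::model.matrix(~ 0 + grp)
  y <- matrix(rnorm(120 * 8, sd = sqrt(1 / rgamma(120, 4, 4))), 120, 8)
  fit <- fit_contrasts(y, X, c(-1, 1))
  mod <- moderate(fit)
  lf <- limma::contrasts.fit(limma::lmFit(y, X), c(-1, 1))
  eb <- limma::eBayes(lf)
  expect_equal(mod$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(mod$s02, eb$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$t[, 1]), unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(unname(mod$p[, 1]), unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(2)
  p <- runif(40)
  expect_equal(bh_adjust(p), oracle_bh(p))
  # order preservation (monotonicity)
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "domain")
})

test_that("zonation calls apply the P/FC thresholds under both rules", {
  tab <- data.frame(p = c(0.01, 0.2, 0.01, 0.2, 0.04, 0.001),
                    log2fc = c(log2(1.5), log2(1.5), 0.1, 0.05,
                               -log2(1.3), log2(1.19)),
                    q = c(0.04, 0.5, 0.04, 0.5, 0.1, 0.01))
  and_flags <- call_zonation(tab, rule = "AND")
  or_flags <- call_zonation(tab, rule = "OR")
  expect_identical(and_flags, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(or_flags, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  # direct threshold application oracle
  expect_identical(and_flags, tab$p < 0.05 & abs(tab$log2fc) >= log2(1.2))
  expect_identical(or_flags, tab$p < 0.05 | abs(tab$log2fc) >= log2(1.2))
  # q-based calls
  expect_identical(call_zonation(tab, use_q = TRUE),
                   tab$q < 0.05 & abs(tab$log2fc) >= log2(1.2))
  s <- zonation_summary(and_flags)
  expect_equal(s$n_zonated, 2L)
  expect_equal(s$fraction, 2 / 6)
})

test_that("simulated zonated features are detected with adequate power", {
  set.seed(41)
  grp <- factor(rep(c("A", "B"), each = 4))
  X <- stats::model.matrix(~ 0 + grp)
  hits <- replicate(60, {
    y <- matrix(rnorm(200 * 8, sd = 0.5), 200, 8)
    y[1:100, 5:8] <- y[1:100, 5:8] + 1       # log2FC = 1
    fit <- fit_contrasts(y, X, c(-1, 1))
    tab <- moderated_table(moderate(fit))
    mean(call_zonation(tab)[1:100])
  })
  expect_gte(mean(hits), 0.8)
})

test_that("BH keeps the empirical FDR at the nominal level", {
  set.seed(47)
  grp <- factor(rep(c("A", "B"), each = 4))
  X <- stats::model.matrix(~ 0 + grp)
  fdr <- replicate(200, {
    y <- matrix(rnorm(300 * 8, sd = 0.5), 300, 8)
    y[1:30, 5:8] <- y[1:30, 5:8] + 1.5       # 10% true effects
    fit <- fit_contrasts(y, X, c(-1, 1))
    mod <- moderate(fit)
    disc <- which(mod$q[, 1] < 0.05)
    if (!length(disc)) return(0)
    mean(disc > 30)
  })
  expect_lte(mean(fdr), 0.05)
})
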