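# Moderated-statistics workflow for zonation and diet-by-genotype
# contrasts: two-step reporter normalization (channel loading, pooled
# reference), quantile normalization, per-feature linear-model contrasts,
# empirical-Bayes variance shrinkage, BH adjustment and threshold-based
# zonation calls.

#' Equalize column sums (channel-loading normalization)
#'
#' Each sample column of a raw abundance matrix is scaled so all column
#' sums equal the mean column sum, accounting for equal peptide loading
#' across reporter channels.
#'
#' @param x features x samples matrix of positive abundances.
#' @return Matrix with equal column sums.
#' @export
channel_loading_normalize <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) .stopf("abundances must be non-negative")
  cs <- colSums(x, na.rm = TRUE)
  if (any(cs == 0)) .stopf("zero column sum in sample(s): %s",
                           paste(which(cs == 0), collapse = ", "))
  sweep(x, 2, mean(cs) / cs, "*")
}

#' Pooled-reference normalization across batches
#'
#' Every feature in every batch is divided by that batch's pooled-reference
#' abundance (ratio scale), removing the batch effect of multiplexed
#' experiments; the pooled columns become all ones. With several pooled
#' columns per batch their per-feature mean is the reference. Features with
#' a zero/missing pooled abundance are flagged `NA` in that batch.
#'
#' @param x features x samples matrix.
#' @param batch vector assigning each column to a batch.
#' @param pooled logical vector marking pooled-reference columns.
#' @param drop_pooled remove the pooled columns from the result
#'   (default `FALSE`).
#' @return Matrix of ratios to the pooled reference.
#' @export
pooled_reference_normalize <- function(x, batch, pooled,
                                       drop_pooled = FALSE) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(x) || length(pooled) != ncol(x))
    .stopf("batch and pooled must have one entry per column")
  out <- x
  for (b in unique(batch)) {
    sel <- batch == b
    ref_cols <- sel & pooled
    if (!any(ref_cols))
      .stopf("batch '%s' has no pooled-reference column", b)
    ref <- rowMeans(x[, ref_cols, drop = FALSE])
    ref[ref == 0 | !is.finite(ref)] <- NA_real_
    out[, sel] <- x[, sel, drop = FALSE] / ref
  }
  if (drop_pooled) out <- out[, !pooled, drop = FALSE]
  out
}

#' Quantile normalization
#'
#' Classic quantile normalization: within-column ranks are mapped to the
#' mean order statistics across columns; tied values receive the mean of
#' the quantiles they span.
#'
#' @param x features x samples matrix (>= 2 columns).
#' @return Quantile-normalized matrix; all columns share the same sorted
#'   values.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) .stopf("quantile normalization needs >= 2 samples")
  sorted <- apply(x, 2, sort)
  target <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    # integer ranks index the target directly; tied (fractional) ranks get
    # the mean of the two spanned order statistics
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

#' Per-feature linear-model contrasts
#'
#' Fits ordinary least squares row-wise on a log2 matrix under a shared
#' design matrix and evaluates linear contrasts of the coefficients,
#' returning the ingredients of moderated inference: contrast estimates
#' (log2 fold changes), unscaled standard errors, residual variances and
#' degrees of freedom. Supports both contrast families of the
#' diet-by-genotype workflow: within-genotype WD vs CD means, and
#' difference-of-differences against the Null genotype (see
#' [dietgeno_contrasts()]).
#'
#' @param y features x samples matrix of log2 values.
#' @param design samples x coefficients design matrix (full rank).
#' @param contrasts coefficients x contrasts matrix (or a single vector).
#' @return An object of class `zonation_fit`: list with `coefficients`
#'   (features x contrasts log2FC), `stdev_unscaled`, `sigma2`, `df_residual`.
#' @export
fit_contrasts <- function(y, design, contrasts) {
  y <- as.matrix(y)
  design <- as.matrix(design)
  if (nrow(design) != ncol(y))
    .stopf("design has %d rows but y has %d samples", nrow(design), ncol(y))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    .stopf("rank-deficient design; aliased term(s): %s",
           paste(aliased, collapse = ", "))
  }
  if (is.null(dim(contrasts)))
    contrasts <- matrix(contrasts, ncol = 1,
                        dimnames = list(NULL, "contrast"))
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != ncol(design))
    .stopf("contrast rows must match design coefficients")

  beta <- t(qr.coef(qrd, t(y)))               # features x coefficients
  fitted <- beta %*% t(design)
  res <- y - fitted
  df <- nrow(design) - qrd$rank
  if (df < 1L) .stopf("no residual degrees of freedom")
  sigma2 <- rowSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))[order(qrd$pivot), order(qrd$pivot),
                                 drop = FALSE]
  se_unscaled <- sqrt(diag(t(contrasts) %*% xtx_inv %*% contrasts))
  est <- beta %*% contrasts
  structure(list(coefficients = est,
                 stdev_unscaled = matrix(se_unscaled, nrow(y),
                                         ncol(contrasts), byrow = TRUE,
                                         dimnames = dimnames(est)),
                 sigma2 = sigma2, df_residual = rep(df, nrow(y)),
                 design = design, contrasts = contrasts),
            class = "zonation_fit")
}

#' Contrast matrices for the diet-by-genotype workflow
#'
#' For a one-way layout of genotype:diet group means (design columns named
#' `<genotype>.<diet>`), builds the two tested contrast families: the
#' within-genotype Western-diet effect (`WD - CD` per genotype) and the
#' difference-of-differences against the reference genotype
#' (`(WD - CD)_genotype - (WD - CD)_ref`).
#'
#' @param genotypes character vector of genotype levels.
#' @param ref reference (Null) genotype.
#' @param diets the two diet levels, control first (default
#'   `c("CD", "WD")`).
#' @return A coefficients x contrasts matrix whose rownames are the group
#'   design columns.
#' @export
dietgeno_contrasts <- function(genotypes, ref = genotypes[1],
                               diets = c("CD", "WD")) {
  groups <- as.vector(outer(genotypes, diets, paste, sep = "."))
  cmat <- NULL
  for (g in genotypes) {
    v <- setNames(numeric(length(groups)), groups)
    v[paste(g, diets[2], sep = ".")] <- 1
    v[paste(g, diets[1], sep = ".")] <- -1
    cmat <- cbind(cmat, v)
    colnames(cmat)[ncol(cmat)] <- paste0(g, "_WDeffect")
  }
  for (g in setdiff(genotypes, ref)) {
    v <- cmat[, paste0(g, "_WDeffect")] - cmat[, paste0(ref, "_WDeffect")]
    cmat <- cbind(cmat, v)
    colnames(cmat)[ncol(cmat)] <- paste0(g, "_vs_", ref, "_WDeffect")
  }
  cmat
}

# solve trigamma(x) = y by Newton iteration
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderation of contrast statistics
#'
#' Shrinks per-feature residual variances towards a common prior. The prior
#' degrees of freedom `d0` and prior variance `s0^2` are estimated by
#' moment matching on the log residual variances (digamma/trigamma
#' relations of the scaled-F model); the posterior variance is
#' `s_post^2 = (d0 s0^2 + d s^2) / (d0 + d)`, the moderated t is the
#' contrast estimate over `stdev_unscaled * s_post`, and p-values use
#' `d + d0` degrees of freedom. Passing `d0`/`s02` fixes the
#' hyperparameters instead of estimating them (`d0 = 0` reproduces the
#' ordinary t-test; `d0 = Inf` pools the variance entirely).
#'
#' @param fit a `zonation_fit` from [fit_contrasts()].
#' @param d0,s02 optional fixed prior degrees of freedom and variance.
#' @return An object of class `moderated_result`: list with matrices
#'   `log2fc`, `t`, `p`, `q` (BH within contrast), vectors `s2_post`,
#'   `df_total`, and hyperparameters `d0`, `s02`.
#' @export
moderate <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "zonation_fit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  ok <- is.finite(s2) & d > 0
  if (sum(ok) < 2L) .stopf("need >= 2 features with residual df")
  if (all(s2[ok] == 0)) .stopf("all residual variances are zero")
  if (is.null(d0) || is.null(s02)) {
    z <- log(pmax(s2[ok], 1e-300))
    e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
    evar <- var(e) - mean(trigamma(d[ok] / 2))
    if (is.finite(evar) && evar > 0) {
      d0_est <- 2 * .trigamma_inverse(evar)
      s02_est <- exp(mean(e) + digamma(d0_est / 2) - log(d0_est / 2))
    } else {
      d0_est <- Inf
      s02_est <- exp(mean(e))
    }
    d0 <- d0 %||% d0_est
    s02 <- s02 %||% s02_est
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + d * s2) / (d0 + d)
  tt <- fit$coefficients / (fit$stdev_unscaled * sqrt(s2_post))
  df_total <- d + d0
  pp <- 2 * pt(-abs(tt), df = df_total)
  qq <- apply(pp, 2, bh_adjust)
  if (is.null(dim(qq))) qq <- matrix(qq, nrow = nrow(pp),
                                     dimnames = dimnames(pp))
  structure(list(log2fc = fit$coefficients, t = tt, p = pp, q = qq,
                 s2_post = s2_post, df_total = df_total,
                 d0 = d0, s02 = s02),
            class = "moderated_result")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values (monotone step-up adjustment, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    .stopf("domain error: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Tidy per-feature table for one contrast
#'
#' @param mod a `moderated_result`.
#' @param contrast contrast name or index (default 1).
#' @return Data frame with `feature`, `log2fc`, `fc` (signed linear fold
#'   change), `t`, `p`, `q`.
#' @export
moderated_table <- function(mod, contrast = 1L) {
  stopifnot(inherits(mod, "moderated_result"))
  lfc <- mod$log2fc[, contrast]
  data.frame(feature = rownames(mod$log2fc) %||% seq_along(lfc),
             log2fc = lfc, fc = sign(lfc) * 2^abs(lfc),
             t = mod$t[, contrast], p = mod$p[, contrast],
             q = mod$q[, contrast], row.names = NULL)
}

#' Zonation/significance calls from thresholds
#'
#' Flags features as zonated using the p-value (default 0.05) and linear
#' fold-change (default 1.2) thresholds. The default rule is `AND`
#' (both conditions); `OR` (either) is available since the thresholds may
#' be combined either way. `use_q` applies the threshold to BH q-values
#' instead of raw p-values.
#'
#' @param tab data frame from [moderated_table()] (or any table with `p`,
#'   `q` and `log2fc` columns).
#' @param p_thr p-value threshold (default 0.05).
#' @param fc_thr linear fold-change threshold (default 1.2).
#' @param rule `"AND"` or `"OR"`.
#' @param use_q threshold q instead of p (default `FALSE`).
#' @return Logical vector of zonation flags.
#' @export
call_zonation <- function(tab, p_thr = 0.05, fc_thr = 1.2,
                          rule = c("AND", "OR"), use_q = FALSE) {
  rule <- match.arg(rule)
  pv <- if (use_q) tab$q else tab$p
  sig_p <- pv < p_thr
  sig_fc <- abs(tab$log2fc) >= log2(fc_thr)
  if (rule == "AND") sig_p & sig_fc else sig_p | sig_fc
}

#' Zonation summary counts
#'
#' @param flags logical vector from [call_zonation()].
#' @return Data frame with `n_features`, `n_zonated`, `fraction`.
#' @export
zonation_summary <- function(flags) {
  data.frame(n_features = length(flags), n_zonated = sum(flags),
             fraction = mean(flags))
}
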