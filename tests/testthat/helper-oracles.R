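# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's implementation paths.

# all (x, y) 0-based coordinates of positive pixels
oracle_xy <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# boundary pixels: positive pixels with a 4-neighbour outside the mask
oracle_boundary_xy <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  nr <- nrow(mask); nc <- ncol(mask)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    for (j in 1:4) {
      rr <- nb[j, 1]; cc <- nb[j, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || mask[rr, cc] <= 0) {
        keep[k] <- TRUE
        break
      }
    }
  }
  cbind(x = idx[keep, 2] - 1, y = idx[keep, 1] - 1)
}

# exhaustive minimal distance between two pixel-coordinate sets
oracle_min_pair_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  best
}

# exhaustive maximal pairwise distance within one pixel set (Feret)
oracle_feret <- function(xy) {
  if (nrow(xy) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(xy) - 1))
    for (j in (i + 1):nrow(xy)) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d > best) best <- d
    }
  best
}

# contour length of a CONVEX digital object: boundary pixel centres sorted
# by angle around the centroid form the contour polygon
oracle_convex_contour_length <- function(mask) {
  b <- oracle_boundary_xy(mask)
  ctr <- colMeans(oracle_xy(mask))
  o <- order(atan2(b[, 2] - ctr[2], b[, 1] - ctr[1]))
  p <- b[o, , drop = FALSE]
  p2 <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((p2 - p)^2)))
}

# random 4-connected polyomino of n pixels grown from a seed pixel
random_polyomino <- function(n, dim = c(12L, 12L)) {
  m <- matrix(0L, dim[1], dim[2])
  r <- sample(3:(dim[1] - 2), 1); c <- sample(3:(dim[2] - 2), 1)
  m[r, c] <- 1L
  frontier <- rbind(c(r, c))
  while (sum(m) < n) {
    k <- sample(nrow(frontier), 1)
    step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample(4, 1), ]
    nr <- frontier[k, 1] + step[1]; nc <- frontier[k, 2] + step[2]
    if (nr < 2 || nr > dim[1] - 1 || nc < 2 || nc > dim[2] - 1) next
    if (m[nr, nc] == 0L) {
      m[nr, nc] <- 1L
      frontier <- rbind(frontier, c(nr, nc))
    }
  }
  m
}

# hand implementation of the BH step-up adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# moderated t at FIXED hyperparameters from first principles
oracle_moderated_t <- function(est, se_unscaled, s2, d, d0, s02) {
  s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  est / (se_unscaled * sqrt(s2_post))
}

# quantile normalization by the stated rule: within-column ranks mapped to
# mean order statistics, fractional (tied) ranks averaging the two spanned
# order statistics
oracle_quantile_normalize <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- (target[floor(r)] + target[ceiling(r)]) / 2
  }
  out
}

# exhaustive complete-linkage agglomeration recording merge heights
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# fraction of ground-truth objects matched by a segmentation at IoU >= thr
match_fraction_iou <- function(seg, truth, thr = 0.5) {
  tids <- sort(unique(truth[truth > 0]))
  hit <- vapply(tids, function(id) {
    tm <- truth == id
    cand <- seg[tm]
    cand <- cand[cand > 0]
    if (!length(cand)) return(FALSE)
    best <- as.integer(names(sort(table(cand), decreasing = TRUE))[1])
    sm <- seg == best
    sum(tm & sm) / sum(tm | sm) >= thr
  }, logical(1))
  mean(hit)
}

# small synthetic axis shared across tests (noise-free, deterministic)
quiet_axis <- local({
  memo <- new.env()
  function(cond = "CNTR", seed = 101, noise = 0) {
    key <- paste(cond, seed, noise)
    if (is.null(memo[[key]])) {
      spec <- preset_condition(cond)
      spec$noise_sd <- noise
      memo[[key]] <- generate_axis(spec, seed = seed)
    }
    memo[[key]]
  }
})
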