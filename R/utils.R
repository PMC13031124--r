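# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) .stopf("'%s' must be a matrix", name)
  x
}

.same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) .stopf("%s must share dimensions", what)
  invisible(TRUE)
}

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 0-based (x, y) = (column, row) pixel-center coordinates of TRUE/positive
# entries of a matrix, as an n x 2 matrix
pixel_xy <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# boundary pixels of a binary mask: object pixels with at least one
# 4-neighbour outside the object (image edge counts as outside)
mask_boundary <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  up    <- rbind(FALSE, m[-nr, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, m[, -nc, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

# minimal Euclidean distance between two pixel-coordinate sets (n x 2),
# with the argmin pair; chunked to bound memory
min_cross_distance <- function(a, b, chunk = 2048L) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(list(d = Inf, i = NA_integer_, j = NA_integer_))
  best <- Inf; bi <- NA_integer_; bj <- NA_integer_
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    dx <- outer(a[s:e, 1], b[, 1], "-")
    dy <- outer(a[s:e, 2], b[, 2], "-")
    d2 <- dx * dx + dy * dy
    k <- which.min(d2)
    if (d2[k] < best * best) {
      best <- sqrt(d2[k])
      bi <- s + (k - 1L) %% (e - s + 1L)
      bj <- 1L + (k - 1L) %/% (e - s + 1L)
    }
  }
  list(d = best, i = bi, j = bj)
}

# per-row minimum distance from each point of `a` to the set `b`
min_dist_to_set <- function(a, b, chunk = 2048L) {
  if (nrow(b) == 0L) return(rep(Inf, nrow(a)))
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    dx <- outer(a[s:e, 1], b[, 1], "-")
    dy <- outer(a[s:e, 2], b[, 2], "-")
    out[s:e] <- sqrt(.rowMins(dx * dx + dy * dy))
  }
  out
}

.rowMins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
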