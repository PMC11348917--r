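# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit `seed`; the
#' caller's RNG state is left untouched.
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Deterministic expansion of one global seed into per-stage seeds so that
#' pipeline stages can be rerun independently. Kept below 2^31 - 1.
#' @noRd
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

#' Centered running mean with shrink-at-border averaging
#'
#' Window of `k` samples (forced odd); near the borders the window shrinks so
#' no padding value biases the estimate.
#' @noRd
runningMean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Column-wise running mean over a t x p matrix
#' @noRd
runningMeanMat <- function(m, k) {
  n <- nrow(m)
  if (k <= 1L || n == 0L) return(m)
  k <- as.integer(k); if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  cs <- rbind(0, apply(m, 2L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' 3x3 running-average filter with shrink-at-border behaviour
#' @noRd
meanFilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  w <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  w[2:(nr + 1L), 2:(nc + 1L)] <- 1
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    acc <- acc + p[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
    cnt <- cnt + w[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
  }
  acc / cnt
}

#' Seeded 8-connected flood fill on a logical matrix
#'
#' Returns the logical mask of the connected component of `mask` containing
#' the seed (row, col). Grids here are small (tens of pixels a side), so a
#' queue-based fill is adequate.
#' @noRd
connectedRegion <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  if (!mask[seed[1L], seed[2L]]) return(out)
  queue <- matrix(seed, ncol = 2L)
  out[seed[1L], seed[2L]] <- TRUE
  while (nrow(queue) > 0L) {
    cur <- queue[1L, , drop = FALSE]
    queue <- queue[-1L, , drop = FALSE]
    for (dy in -1:1) for (dx in -1:1) {
      y <- cur[1L] + dy; x <- cur[2L] + dx
      if (y >= 1L && y <= nr && x >= 1L && x <= nc && mask[y, x] && !out[y, x]) {
        out[y, x] <- TRUE
        queue <- rbind(queue, c(y, x))
      }
    }
  }
  out
}

#' Circular absolute difference
#' @noRd
circAbsDiff <- function(a, b, period) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertProbs <- function(p, what = "type_probs", tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(what, " must be finite and nonnegative")
  }
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  invisible(p)
}
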