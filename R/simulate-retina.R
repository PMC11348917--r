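# Phantom flat-mount retina stacks: two smooth ChAT-band surfaces plus
# dendritic arbors rendered at known strata, with full ground truth returned
# so the flattening and typing stages can be scored.

#' Configuration for a phantom flat-mount stack
#'
#' @param xySize xy extent in pixels (square field).
#' @param zSize number of z planes.
#' @param bandSep mean separation of the two ChAT bands, in planes.
#' @param curvatureAmp maximum band undulation, in planes.
#' @param cells list of cell specs, each a list with \code{soma} (xy pixel
#'   coordinates), \code{strata} (target strata in 1..10), and optional
#'   logical \code{asymmetry} and \code{cofasciculation} flags and
#'   \code{arborRadius} (pixels, default 10).
#' @param noiseSd additive Gaussian noise SD (intensity units; signal is 1).
#' @param seed integer seed.
#' @return A validated config (list) for \code{\link{simulateRetinaStack}}.
#' @export
retinaPhantomConfig <- function(xySize = 48, zSize = 36, bandSep = 8,
                                curvatureAmp = 2, cells = list(),
                                noiseSd = 0.02, seed = 1L) {
  lo <- 1 + 0.625 * bandSep + curvatureAmp
  hi <- zSize - 1.875 * bandSep - curvatureAmp
  if (lo > hi)
    stop("band curvature and separation exceed the z extent of the stack")
  for (cell in cells) {
    if (!all(cell$strata %in% 1:10)) stop("target strata must lie in 1..10")
    if (any(cell$soma < 1) || any(cell$soma > xySize))
      stop("soma must lie inside the field")
  }
  structure(list(xySize = as.integer(xySize), zSize = as.integer(zSize),
                 bandSep = bandSep, curvatureAmp = curvatureAmp,
                 cells = cells, noiseSd = noiseSd, seed = as.integer(seed),
                 offZ0 = (lo + hi) / 2),
            class = "RetinaPhantomConfig")
}

#' Generate a phantom two-channel flat-mount stack
#'
#' The ChAT channel holds two bright smooth surfaces (Gaussian z-profiles
#' around the true band surfaces); the RGC channel holds radial dendrite
#' renderings confined, via the true surfaces, to each cell's target strata.
#'
#' @param cfg a \code{\link{retinaPhantomConfig}}.
#' @return List with \code{chat} and \code{rgc} arrays (y, x, z), the
#'   ground-truth \code{surfaces} (\linkS4class{ChatBandSurfaces}), and
#'   \code{cells}: per cell its \code{somaXy}, target \code{strata}, xy
#'   \code{mask}, and rendered voxel table with true strata.
#' @export
simulateRetinaStack <- function(cfg) {
  stopifnot(inherits(cfg, "RetinaPhantomConfig"))
  n <- cfg$xySize; nz <- cfg$zSize
  withSeed(cfg$seed, {
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # col index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    und <- cfg$curvatureAmp *
      sin(2 * pi * xs / n + stats::runif(1, 0, 2 * pi)) *
      cos(2 * pi * ys / n + stats::runif(1, 0, 2 * pi))
    offZ <- cfg$offZ0 + und
    onZ <- offZ + cfg$bandSep
    sigma <- 0.8
    chat <- array(0, dim = c(n, n, nz))
    for (z in seq_len(nz)) {
      chat[, , z] <- exp(-(z - offZ)^2 / (2 * sigma^2)) +
                     exp(-(z - onZ)^2 / (2 * sigma^2))
    }
    rgc <- array(0, dim = c(n, n, nz))
    strataC <- 0.25 * (1:10 - 3)
    cellsOut <- vector("list", length(cfg$cells))
    for (ci in seq_along(cfg$cells)) {
      cell <- cfg$cells[[ci]]
      arbor <- cell$arborRadius %||% 10
      asym <- isTRUE(cell$asymmetry)
      nRays <- 10L
      angles <- if (asym) seq(-60, 60, length.out = nRays) * pi / 180
                else seq(0, 2 * pi, length.out = nRays + 1L)[-(nRays + 1L)]
      mask <- matrix(FALSE, n, n)
      vox <- list()
      for (k in cell$strata) {
        depth <- strataC[k]
        for (a in angles) {
          for (r in seq(1, arbor, by = 0.5)) {
            x <- round(cell$soma[1] + r * cos(a))
            y <- round(cell$soma[2] + r * sin(a))
            if (x < 1 || x > n || y < 1 || y > n) next
            d <- depth + stats::rnorm(1, 0, 0.02)
            zc <- offZ[y, x] + d * cfg$bandSep
            z0 <- floor(zc); w <- zc - z0
            if (z0 >= 1 && z0 <= nz) rgc[y, x, z0] <- max(rgc[y, x, z0], 1 - w)
            if (z0 + 1 >= 1 && z0 + 1 <= nz)
              rgc[y, x, z0 + 1] <- max(rgc[y, x, z0 + 1], w)
            mask[y, x] <- TRUE
            vox[[length(vox) + 1L]] <- c(y, x, zc, k)
          }
        }
      }
      mask[cell$soma[2], cell$soma[1]] <- TRUE
      voxels <- if (length(vox))
        stats::setNames(as.data.frame(do.call(rbind, vox)),
                        c("y", "x", "z", "stratum"))
      else data.frame(y = numeric(0), x = numeric(0), z = numeric(0),
                      stratum = numeric(0))
      cellsOut[[ci]] <- list(somaXy = cell$soma, strata = cell$strata,
                             asymmetry = asym, mask = mask, voxels = voxels)
    }
    if (cfg$noiseSd > 0) {
      chat <- chat + array(stats::rnorm(length(chat), 0, cfg$noiseSd), dim(chat))
      rgc <- rgc + array(stats::rnorm(length(rgc), 0, cfg$noiseSd), dim(rgc))
    }
    list(chat = chat, rgc = rgc,
         surfaces = new("ChatBandSurfaces", offZ = offZ, onZ = onZ),
         cells = cellsOut, config = cfg)
  })
}
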