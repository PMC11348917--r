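# Dendrite-versus-soma feature correspondence: 16-dimensional response-vector
# correlations versus Euclidean distance, distance-binned statistics,
# mono-exponential decay fits and circular angle differences.

#' 16-dimensional response vector of a ResponseMatrix at one speed
#'
#' Concatenates the 8 positive and 8 negative amplitudes at the given speed.
#'
#' @param resp a \linkS4class{ResponseMatrix}.
#' @param speedIdx speed index (1..3).
#' @return Numeric vector of length 16.
#' @export
responseVector16 <- function(resp, speedIdx) {
  c(resp@P[, speedIdx], resp@N[, speedIdx])
}

#' Speed evoking the maximum response (positive or negative)
#' @param resp a \linkS4class{ResponseMatrix}.
#' @return Speed index; ties broken toward the slowest speed.
#' @export
bestResponseSpeed <- function(resp) {
  as.integer(which.max(apply(pmax(resp@P, resp@N), 2L, max)))
}

#' Correlation of dendritic compartments with their soma
#'
#' Pearson correlation between each compartment's 16-dimensional response
#' vector (8 positive + 8 negative amplitudes) and the soma's, at the speed
#' that evoked the soma's maximum response (positive or negative).
#' Compartments failing the SNR gate are dropped; constant vectors yield NA
#' with a flag.
#'
#' @param somaResp \linkS4class{ResponseMatrix} of the soma.
#' @param compartmentResps list of \linkS4class{ResponseMatrix}, one per
#'   dendritic compartment.
#' @param distancesUm Euclidean distances between compartment and soma ROI
#'   centers (micrometer); a lower bound on path length.
#' @param snrGate inclusion gate (default 2.5) applied per compartment.
#' @return data.frame: compartment, distance_um, r, snr, included, degenerate.
#' @export
somaDendriteCorrelation <- function(somaResp, compartmentResps, distancesUm,
                                    snrGate = 2.5) {
  if (somaResp@snr <= snrGate)
    stop("soma fails the SNR gate (", format(somaResp@snr, digits = 3), ")")
  if (any(distancesUm < 0)) stop("distances must be >= 0")
  sp <- bestResponseSpeed(somaResp)
  sv <- responseVector16(somaResp, sp)
  out <- lapply(seq_along(compartmentResps), function(i) {
    cr <- compartmentResps[[i]]
    cv <- responseVector16(cr, sp)
    degen <- stats::sd(cv) == 0 || stats::sd(sv) == 0
    data.frame(compartment = i, distance_um = distancesUm[i],
               r = if (degen) NA_real_ else stats::cor(sv, cv),
               snr = cr@snr, included = cr@snr > snrGate,
               degenerate = degen)
  })
  do.call(rbind, out)
}

#' Distance-binned mean and SD
#'
#' Bin edges at 0, 50, 100, ... micrometer by default; empty bins are
#' reported as missing.
#'
#' @param values numeric values (e.g. correlations or indices).
#' @param distancesUm matching distances.
#' @param binWidthUm bin width (default 50).
#' @return data.frame: bin_lo, bin_hi, bin_mid, n, mean, sd.
#' @export
binnedStats <- function(values, distancesUm, binWidthUm = 50) {
  stopifnot(length(values) == length(distancesUm))
  bin <- floor(distancesUm / binWidthUm)
  out <- lapply(sort(unique(bin)), function(b) {
    v <- values[bin == b]
    data.frame(bin_lo = b * binWidthUm, bin_hi = (b + 1) * binWidthUm,
               bin_mid = (b + 0.5) * binWidthUm, n = length(v),
               mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  do.call(rbind, out)
}

#' Mono-exponential decay fit y = Delta * exp(-x / lambda) + y0
#'
#' Least-squares fit with multi-start initialization over a grid of length
#' constants (lambda bounded positive). Flat data converge to Delta near 0
#' with an unidentifiable lambda; such fits are flagged.
#'
#' @param x distances (must have positive spread; >= 4 points).
#' @param y index values.
#' @param lambdaStarts initial length constants tried (micrometer).
#' @param robust use Huber-type robust weighting (default FALSE, plain least
#'   squares).
#' @return List: delta, lambda, y0, rss, identifiable, fit (the nls object).
#' @export
expDecayFit <- function(x, y, lambdaStarts = c(10, 25, 50, 100, 200),
                        robust = FALSE) {
  if (length(x) < 4L) stop("need at least 4 points")
  if (max(x) - min(x) <= 0) stop("x must have positive spread")
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (l0 in lambdaStarts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ delta * exp(-x / lambda) + y0, data = dat,
        start = list(delta = max(y) - min(y), lambda = l0, y0 = min(y)),
        lower = c(-Inf, 1e-6, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (robust) {
      r <- stats::residuals(fit)
      s <- stats::mad(r) + .Machine$double.eps
      w <- pmin(1, 1.345 / abs(r / s))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ delta * exp(-x / lambda) + y0, data = dat,
                          start = as.list(stats::coef(fit)),
                          lower = c(-Inf, 1e-6, -Inf), weights = w),
        error = function(e) fit)
      rss <- sum(stats::residuals(fit)^2)
    }
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # essentially flat data: the decay amplitude is indistinguishable from 0
    # and lambda is unidentifiable; report the degenerate fit, flagged
    if (stats::sd(y) < 10 * (max(abs(y)) + 1) * .Machine$double.eps^0.25 ||
        stats::sd(y) < 0.05 * abs(mean(y)) + .Machine$double.eps) {
      return(list(delta = 0, lambda = NA_real_, y0 = mean(y),
                  rss = sum((y - mean(y))^2), identifiable = FALSE,
                  fit = NULL))
    }
    stop("exponential fit did not converge from any start")
  }
  co <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(Inf, 3))
  identifiable <- is.finite(se["lambda"]) &&
    abs(co["delta"]) > 2 * (stats::sd(y) / sqrt(length(y))) &&
    se["lambda"] < 2 * co["lambda"]
  list(delta = unname(co["delta"]), lambda = unname(co["lambda"]),
       y0 = unname(co["y0"]), rss = best$rss,
       identifiable = identifiable, fit = best$fit)
}

#' Circular absolute angle difference
#'
#' @param a,b angles in degrees.
#' @param mode \code{"direction"} (period 360, result in [0, 180]) or
#'   \code{"orientation"} (period 180, result in [0, 90]).
#' @return Absolute circular difference in degrees.
#' @examples
#' angularDifference(350, 10, "direction")   # 20
#' angularDifference(170, 10, "orientation") # 20
#' @export
angularDifference <- function(a, b, mode = c("direction", "orientation")) {
  mode <- match.arg(mode)
  circAbsDiff(a, b, if (mode == "direction") 360 else 180)
}
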