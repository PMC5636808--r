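## Watson-distributed fiber orientation dispersion.

#' Watson concentration from the dispersion half-angle
#'
#' The generator parameterises orientation dispersion by a half-angle
#' \code{thetaT} (degrees); the corresponding Watson concentration is
#' \code{kappa = 2 / sin^2(thetaT)}, strictly decreasing in \code{thetaT}.
#'
#' @param thetaT dispersion half-angle, degrees, in (0, 90].
#' @return The concentration parameter kappa (unitless).
#' @examples
#' watsonKappa(90)  # 2
#' watsonKappa(30)  # 8
#' @export
watsonKappa <- function(thetaT) {
    if (any(thetaT <= 0 | thetaT > 90))
        stop("'thetaT' must lie in (0, 90] degrees")
    2 / sin(thetaT * pi / 180)^2
}

#' Sample fiber axes from a Watson distribution
#'
#' Draws axes about \code{meanAxis} whose deviation angle theta follows the
#' solid-angle density proportional to \code{exp(-kappa * sin^2(theta)) *
#' sin(theta)} on the hemisphere of the mean axis, with uniform azimuth.
#' The sin(theta) Jacobian is included because the density lives on
#' orientations, not on the scalar angle. Sampling is by vectorised rejection
#' with uniform azimuth: writing w = 1 - cos(theta), the target density is
#' proportional to exp(-kappa * w * (2 - w)) on [0, 1], which is dominated by
#' the Exp(kappa) proposal with the exact acceptance ratio
#' exp(-kappa * w * (1 - w)) <= 1. Acceptance stays above ~50% for every
#' kappa, so the sampler remains practical in the near-degenerate
#' high-concentration regime.
#'
#' @param meanAxis mean orientation (3-vector, need not be unit).
#' @param kappa Watson concentration, > 0.
#' @param n number of axes to draw.
#' @param seed optional integer seed; when given the draw is reproducible.
#' @return an n x 3 matrix of unit axes, all on the hemisphere of
#'   \code{meanAxis}.
#' @examples
#' a <- sampleWatsonAxes(c(0, 0, 1), kappa = 8, n = 5, seed = 1)
#' @export
sampleWatsonAxes <- function(meanAxis, kappa, n, seed = NULL) {
    if (sqrt(sum(meanAxis^2)) == 0) stop("'meanAxis' must be non-zero")
    if (kappa <= 0) stop("'kappa' must be positive")
    if (n < 1) stop("'n' must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    meanAxis <- meanAxis / sqrt(sum(meanAxis^2))
    ct <- numeric(0)
    need <- n
    while (need > 0L) {
        m <- max(64L, ceiling(need * 2.5))
        w <- stats::rexp(m, rate = kappa)
        keep <- w <= 1
        w <- w[keep][stats::runif(sum(keep)) <
            exp(-kappa * w[keep] * (1 - w[keep]))]
        got <- 1 - w
        ct <- c(ct, got[seq_len(min(length(got), need))])
        need <- n - length(ct)
    }
    st <- sqrt(pmax(0, 1 - ct^2))
    phi <- stats::runif(n, 0, 2 * pi)
    local <- cbind(st * cos(phi), st * sin(phi), ct)
    R <- .rotationBetween(c(0, 0, 1), meanAxis)
    local %*% t(R)
}
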