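## q-space spherical patches: antipodal canonicalisation, azimuthal
## equidistant projection (AEP) to the unit disc, polar-grid resampling.

#' Map axes antipodally to a reference hemisphere
#'
#' Diffusion signals are antipodally symmetric, so every axis may be replaced
#' by its antipode. This flips each input axis, where needed, onto the
#' hemisphere of \code{reference} (non-negative dot product).
#'
#' @param axes matrix of unit axes (one per row) or a single 3-vector.
#' @param reference reference direction (non-zero 3-vector).
#' @return matrix of the same shape with all rows satisfying
#'   \code{row . reference >= 0}.
#' @examples
#' antipodalCanonicalize(rbind(c(0, 0, -1)), c(0, 0, 1))
#' @export
antipodalCanonicalize <- function(axes, reference) {
    if (sqrt(sum(reference^2)) == 0) stop("'reference' must be non-zero")
    axes <- if (is.null(dim(axes))) matrix(axes, 1L) else as.matrix(axes)
    s <- sign(drop(axes %*% reference))
    s[s == 0] <- 1
    axes * s
}

#' Azimuthal equidistant projection about a patch centre
#'
#' Projects axes (already canonicalised to the centre's hemisphere) to polar
#' coordinates (rho, theta) on the plane tangent at the centre: rho is the
#' great-circle angular distance to the centre (radians; preserved exactly by
#' this projection) and theta the azimuth computed from the
#' latitude/longitude spherical trigonometry of the projection, measured at
#' the centre. The centre itself maps to rho = 0 with theta set to 0 (its
#' azimuth is undefined).
#'
#' @param center unit centre direction.
#' @param axes matrix of unit axes on the centre's open hemisphere.
#' @return matrix with columns \code{rho} (radians) and \code{theta}
#'   (radians, in [0, 2*pi)).
#' @examples
#' aepProject(c(0, 0, 1), rbind(c(0, 0, 1), c(1, 0, 0)))
#' @export
aepProject <- function(center, axes) {
    axes <- if (is.null(dim(axes))) matrix(axes, 1L) else as.matrix(axes)
    dots <- drop(axes %*% center)
    if (any(dots <= -1 + 1e-12))
        stop("axis antipodal to the patch centre cannot be projected")
    c0 <- .cartToLatLon(matrix(center, 1L))
    ll <- .cartToLatLon(axes)
    phi0 <- c0[1, "phi"]; lam0 <- c0[1, "lambda"]
    phi <- ll[, "phi"]; dl <- ll[, "lambda"] - lam0
    rho <- acos(pmin(1, pmax(-1,
        sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl))))
    theta <- atan2(cos(phi) * sin(dl),
        cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
    theta <- ifelse(rho < 1e-12, 0, theta %% (2 * pi))
    cbind(rho = rho, theta = theta)
}

## Inverse AEP: directions at angular distance rho, azimuth theta from the
## centre, in the same convention as aepProject (verified by round-trip).
.aepInverse <- function(center, rho, theta) {
    c0 <- .cartToLatLon(matrix(center, 1L))
    phi0 <- c0[1, "phi"]; lam0 <- c0[1, "lambda"]
    phi <- asin(pmin(1, pmax(-1,
        cos(rho) * sin(phi0) + sin(rho) * cos(phi0) * cos(theta))))
    lam <- lam0 + atan2(sin(theta) * sin(rho),
        cos(rho) * cos(phi0) - sin(rho) * sin(phi0) * cos(theta))
    .latLonToCart(phi, lam)
}

#' Polar quadrature grid for disc moments
#'
#' Nodes at \code{nRings} equal-area ring radii (midpoints in rho^2) times
#' \code{nAngles} equally spaced angles, with uniform weights summing to 1
#' under the 1/pi-normalised disc measure.
#'
#' @param nRings,nAngles grid resolution; defaults 8 x 16 resolve the
#'   order-4 moment oscillations.
#' @return A [PolarGridSpec-class].
#' @export
polarGrid <- function(nRings = 8L, nAngles = 16L) {
    nRings <- as.integer(nRings); nAngles <- as.integer(nAngles)
    u <- (seq_len(nRings) - 0.5) / nRings
    th <- (seq_len(nAngles) - 0.5) / nAngles * 2 * pi
    g <- expand.grid(rho = sqrt(u), theta = th)
    new("PolarGridSpec", nRings = nRings, nAngles = nAngles,
        rho = g$rho, theta = g$theta,
        weights = rep(1 / (nRings * nAngles), nRings * nAngles))
}

#' Extract a spherical q-space patch
#'
#' Collects the scheme directions whose axis angle to the centre direction
#' (after antipodal canonicalisation) is at most \code{alphaP}.
#'
#' @param scheme a [GradientScheme-class].
#' @param centerIndex index of the centre direction.
#' @param alphaP patch angle, degrees, in (0, 90).
#' @return A [SphericalPatch-class]. A patch containing only its centre is
#'   allowed; a message flags it.
#' @examples
#' sch <- defaultScheme(20, seed = 1)
#' extractPatch(sch, 1, alphaP = 30)
#' @export
extractPatch <- function(scheme, centerIndex, alphaP = 30) {
    if (alphaP <= 0 || alphaP >= 90)
        stop("'alphaP' must lie in (0, 90) degrees")
    g <- directions(scheme)
    center <- g[centerIndex, ]
    ang <- acos(pmin(1, abs(drop(g %*% center)))) * 180 / pi
    members <- which(ang <= alphaP + 1e-12)
    if (length(members) == 1L)
        message("patch at direction ", centerIndex,
                " contains only its centre")
    new("SphericalPatch", centerIndex = as.integer(centerIndex),
        memberIndices = as.integer(members),
        memberAxes = antipodalCanonicalize(g[members, , drop = FALSE],
            center),
        center = center, alphaP = as.numeric(alphaP), scheme = scheme)
}

#' Resample a patch signal onto the polar grid
#'
#' Fits a real antipodally symmetric spherical-harmonic expansion (even
#' orders up to \code{shOrder}, Laplace-Beltrami regularisation
#' \code{shLambda}) to the full-shell signal and evaluates it at the sphere
#' directions obtained by inverse projection of the grid nodes about the
#' patch centre (grid radius 1 corresponds to the patch angle alphaP, so the
#' patch fills the unit disc the moment basis assumes).
#'
#' @param patch a [SphericalPatch-class].
#' @param signal full-shell signal vector (length = number of scheme
#'   directions).
#' @param grid a [PolarGridSpec-class].
#' @param shOrder even spherical-harmonic order.
#' @param shLambda Laplace-Beltrami regularisation weight.
#' @return A [ProjectedPatch-class] with member polar coordinates
#'   (rho normalised by alphaP) and the resampled grid signal.
#' @export
resampleToPolarGrid <- function(patch, signal, grid = polarGrid(),
                                shOrder = 8L, shLambda = 0.006) {
    g <- directions(patch@scheme)
    if (length(signal) != nrow(g))
        stop("'signal' length must match the scheme")
    pc <- aepProject(patch@center, patch@memberAxes)
    alphaRad <- patch@alphaP * pi / 180
    coef <- .shFitMatrix(g, shOrder, shLambda) %*% signal
    nodes <- .aepInverse(patch@center, grid@rho * alphaRad, grid@theta)
    gridSignal <- drop(.shBasis(nodes, shOrder) %*% coef)
    new("ProjectedPatch",
        polarCoords = cbind(rhoNorm = pc[, "rho"] / alphaRad,
            theta = pc[, "theta"]),
        memberSignals = as.numeric(signal[patch@memberIndices]),
        gridSignal = gridSignal, grid = grid)
}
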