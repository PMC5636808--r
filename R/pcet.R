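## Polar complex exponential transform (PCET) moments of projected patches
## and the rotation-invariant magnitude features used for patch matching.

#' PCET basis function
#'
#' \code{H[n, l](rho, theta) = exp(i 2 pi n rho^2) * exp(i l theta)}, a
#' unit-modulus complex exponential on the unit disc.
#'
#' @param n radial order (integer).
#' @param l angular repetition (integer).
#' @param rho radius in [0, 1] (vectorised).
#' @param theta angle in radians (vectorised).
#' @return complex values of modulus 1.
#' @examples
#' pcetBasis(1, 0, 1 / sqrt(2), 0)  # exp(i pi) = -1
#' @export
pcetBasis <- function(n, l, rho, theta) {
    exp(1i * (2 * pi * n * rho^2 + l * theta))
}

## lexicographic (n, l) table, both -m..m
.pcetIndex <- function(m) {
    as.matrix(expand.grid(l = -m:m, n = -m:m))[, c("n", "l")]
}

## Quadrature operator: rows = (n, l) lexicographic, columns = grid cells;
## moments = .pcetMatrix(grid, m) %*% gridSignal (implements the
## 1/pi-normalised disc integral with conjugated basis).
.pcetMatrix <- function(grid, m) {
    idx <- .pcetIndex(m)
    A <- matrix(0i, nrow(idx), length(grid@rho))
    for (j in seq_len(nrow(idx)))
        A[j, ] <- grid@weights *
            Conj(pcetBasis(idx[j, "n"], idx[j, "l"], grid@rho, grid@theta))
    A
}

#' PCET moments of a projected patch
#'
#' Computes the complex moments \code{M[n, l]} for \code{-m <= n, l <= m} by
#' quadrature over the patch's polar grid, and the magnitude feature vector
#' in lexicographic (n, l) order. Magnitudes are invariant to in-plane
#' rotation of the patch, which is what makes them usable for comparing
#' patches whose projections differ only by azimuth.
#'
#' @param patch a [ProjectedPatch-class] with a populated grid.
#' @param m maximum order.
#' @return A [PCETFeatures-class].
#' @export
pcetMoments <- function(patch, m = 4L) {
    m <- as.integer(m)
    if (length(patch@gridSignal) == 0L)
        stop("patch has an empty polar grid")
    M <- drop(.pcetMatrix(patch@grid, m) %*% patch@gridSignal)
    new("PCETFeatures",
        moments = matrix(M, 2L * m + 1L, 2L * m + 1L, byrow = TRUE,
            dimnames = list(n = -m:m, l = -m:m)),
        magnitudes = as.numeric(Mod(M)), order = m)
}

#' Squared distance between feature vectors
#'
#' Squared Euclidean distance between the magnitude vectors of two patches'
#' moment features; the quantity entering the matching kernel.
#'
#' @param a,b [PCETFeatures-class] objects of equal order.
#' @return non-negative scalar.
#' @export
featureDistance <- function(a, b) {
    if (momentOrder(a) != momentOrder(b))
        stop("feature orders differ (", momentOrder(a), " vs ",
             momentOrder(b), ")")
    sum((momentMagnitudes(a) - momentMagnitudes(b))^2)
}

## ---------------------------------------------------------------------------
## Fast feature bank
## ---------------------------------------------------------------------------

## Linear operator Phi mapping a full-shell signal s (length K) to the
## complex moments of all K patches at once: for centre k, M_k = A E_k C s
## where C is the SH fit operator, E_k evaluates the fit at the inverse-
## projected grid nodes of patch k and A is the moment quadrature. Phi is
## the (F*K) x K stack of A E_k C. Complex, built once per scheme/config
## pair. With dedup = TRUE only the 41 non-redundant rows are kept
## (|M(n,l)| = |M(-n,-l)| for real signals), the paired ones scaled by
## sqrt(2) so that magnitude-vector distances are preserved exactly.
.patchFeatureOperator <- function(scheme, m = 4L, alphaP = 30,
                                  grid = polarGrid(), shOrder = 8L,
                                  shLambda = 0.006, dedup = FALSE) {
    g <- directions(scheme)
    K <- nrow(g)
    A <- .pcetMatrix(grid, m)
    if (dedup) {
        idx <- .pcetIndex(m)
        keep <- idx[, "n"] > 0L | (idx[, "n"] == 0L & idx[, "l"] >= 0L)
        scale <- ifelse(idx[keep, "n"] == 0L & idx[keep, "l"] == 0L,
            1, sqrt(2))
        A <- A[keep, , drop = FALSE] * scale
    }
    C <- .shFitMatrix(g, shOrder, shLambda)
    alphaRad <- alphaP * pi / 180
    Fdim <- nrow(A)
    Phi <- matrix(0i, Fdim * K, K)
    for (k in seq_len(K)) {
        nodes <- .aepInverse(g[k, ], grid@rho * alphaRad, grid@theta)
        Phi[((k - 1L) * Fdim + 1L):(k * Fdim), ] <-
            (A %*% .shBasis(nodes, shOrder)) %*% C
    }
    Phi
}

## Magnitude features of all patches of all columns of S (K x n signal
## matrix): returns an array [F, K, n].
.featureBank <- function(Phi, S, Fdim) {
    K <- nrow(S)
    M <- Mod(Phi %*% S)
    dim(M) <- c(Fdim, K, ncol(S))
    M
}
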