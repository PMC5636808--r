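## Quasi-uniform gradient schemes by electrostatic repulsion.

## Energy and tangent gradient of the antipodally symmetric Coulomb energy
## E = sum_{i<j} 1/|p_i - p_j| + 1/|p_i + p_j| for unit points P (K x 3).
.repulsionEnergy <- function(P) {
    G <- tcrossprod(P)
    d1 <- sqrt(pmax(2 - 2 * G, 0))
    d2 <- sqrt(pmax(2 + 2 * G, 0))
    diag(d1) <- Inf
    diag(d2) <- Inf
    sum(1 / d1[upper.tri(d1)]) + sum(1 / d2[upper.tri(d2)])
}

.repulsionGradient <- function(P) {
    G <- tcrossprod(P)
    d1 <- sqrt(pmax(2 - 2 * G, 1e-300))
    d2 <- sqrt(pmax(2 + 2 * G, 1e-300))
    A <- 1 / d1^3
    B <- 1 / d2^3
    diag(A) <- 0
    diag(B) <- 0
    ## grad_i = p_i * (-sum_j A_ij - sum_j B_ij) + (A - B) %*% P
    g <- P * (-rowSums(A) - rowSums(B)) + (A - B) %*% P
    ## project onto the tangent space of the sphere
    g - P * rowSums(g * P)
}

.repulsionMinimize <- function(P, maxit = 2000L, tol = 1e-10) {
    e <- .repulsionEnergy(P)
    step <- 0.01
    for (it in seq_len(maxit)) {
        g <- .repulsionGradient(P)
        gn <- sqrt(sum(g^2))
        if (gn < tol) break
        repeat {
            Pn <- .unitize(P - step * g)
            en <- .repulsionEnergy(Pn)
            if (en < e || step < 1e-12) break
            step <- step / 2
        }
        if (en >= e) break
        P <- Pn
        de <- e - en
        e <- en
        step <- step * 1.2
        if (de < tol * max(1, abs(e))) break
    }
    list(points = P, energy = e)
}

#' Generate a quasi-uniform gradient scheme
#'
#' Places \code{K} axes on the hemisphere by minimising an antipodally
#' symmetric electrostatic (Coulomb) energy from a seeded random start,
#' emulating the common shell designs whose minimal angular separation at K =
#' 81 is around 15 degrees. Several restarts are run and the lowest-energy
#' configuration kept, so the result is deterministic given \code{seed}.
#'
#' @param K number of directions (>= 6).
#' @param bValue shell b-value, s/mm^2.
#' @param seed integer seed for the random starts.
#' @param nStarts number of seeded restarts.
#' @param maxit iteration cap per restart.
#' @return A [GradientScheme-class]; axes are canonicalised to the upper
#'   hemisphere and ordered by decreasing z.
#' @examples
#' sch <- defaultScheme(20, seed = 1)
#' minPairwiseAngle(sch)
#' @export
defaultScheme <- function(K = 81L, bValue = 3000, seed = 1L, nStarts = 3L,
                          maxit = 2000L) {
    K <- as.integer(K)
    if (K < 6L) stop("'K' must be at least 6")
    set.seed(seed)
    best <- NULL
    for (s in seq_len(nStarts)) {
        P0 <- .unitize(matrix(stats::rnorm(3L * K), K, 3L))
        res <- .repulsionMinimize(P0, maxit = maxit)
        if (is.null(best) || res$energy < best$energy) best <- res
    }
    P <- best$points
    flip <- P[, 3] < 0 | (P[, 3] == 0 & P[, 2] < 0) |
        (P[, 3] == 0 & P[, 2] == 0 & P[, 1] < 0)
    P[flip, ] <- -P[flip, , drop = FALSE]
    P <- P[order(-P[, 3], P[, 1], P[, 2]), , drop = FALSE]
    gradientScheme(P, bValue = bValue)
}
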