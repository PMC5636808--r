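## Real symmetric spherical harmonics (even orders), least-squares fitting
## with Laplace-Beltrami regularisation, and the Funk-Radon transform used
## for analytical Q-ball ODFs. Internal to the package.

## Associated Legendre P_l^m(x) for all l <= lmax, m <= l, standard
## (Condon-Shortley) recurrences. x: numeric vector. Returns a list indexed
## [[l + 1]][[m + 1]] of vectors.
.assocLegendre <- function(lmax, x) {
    out <- vector("list", lmax + 1L)
    for (l in 0:lmax) out[[l + 1L]] <- vector("list", l + 1L)
    out[[1L]][[1L]] <- rep(1, length(x))
    if (lmax == 0L) return(out)
    sx <- sqrt(pmax(0, 1 - x^2))
    for (m in 0:lmax) {
        if (m > 0L)
            out[[m + 1L]][[m + 1L]] <-
                (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * sx^m
        if (m < lmax)
            out[[m + 2L]][[m + 1L]] <- x * (2 * m + 1) * out[[m + 1L]][[m + 1L]]
        if (m + 2L <= lmax)
            for (l in (m + 2L):lmax)
                out[[l + 1L]][[m + 1L]] <-
                    ((2 * l - 1) * x * out[[l]][[m + 1L]] -
                     (l + m - 1) * out[[l - 1L]][[m + 1L]]) / (l - m)
    }
    out
}

## (l, m) index table for even orders up to lmax
.shIndex <- function(lmax) {
    ls <- seq(0L, lmax, by = 2L)
    do.call(rbind, lapply(ls, function(l) cbind(l = l, m = -l:l)))
}

## Real orthonormal symmetric SH design matrix: rows = directions, columns =
## (l, m) per .shIndex. m > 0 -> sqrt(2) N cos(m phi) P_l^m, m = 0 -> N P_l,
## m < 0 -> sqrt(2) N sin(|m| phi) P_l^|m|.
.shBasis <- function(dirs, lmax) {
    dirs <- as.matrix(dirs)
    ct <- pmin(1, pmax(-1, dirs[, 3]))
    phi <- atan2(dirs[, 2], dirs[, 1])
    P <- .assocLegendre(lmax, ct)
    idx <- .shIndex(lmax)
    B <- matrix(0, nrow(dirs), nrow(idx))
    for (j in seq_len(nrow(idx))) {
        l <- idx[j, "l"]; m <- idx[j, "m"]; am <- abs(m)
        N <- sqrt((2 * l + 1) / (4 * pi) *
            exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
        p <- P[[l + 1L]][[am + 1L]]
        B[, j] <- if (m > 0L) sqrt(2) * N * p * cos(am * phi)
            else if (m < 0L) sqrt(2) * N * p * sin(am * phi)
            else N * p
    }
    B
}

## Fit operator: coefficients = .shFitMatrix(...) %*% signal.
## Laplace-Beltrami penalty lambda * l^2 (l+1)^2 per coefficient.
.shFitMatrix <- function(dirs, lmax, lambda = 0.006) {
    B <- .shBasis(dirs, lmax)
    idx <- .shIndex(lmax)
    L <- diag(idx[, "l"]^2 * (idx[, "l"] + 1)^2, nrow(idx))
    A <- crossprod(B) + lambda * L
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev))
        stop("scheme too sparse for spherical-harmonic order ", lmax,
             ": rank-deficient fit")
    solve(A, t(B))
}

## Funk-Radon transform of an SH expansion: per-coefficient scaling
## 2 * pi * P_l(0), P_l(0) = (-1)^(l/2) (l-1)!! / l!! for even l.
.frtWeights <- function(lmax) {
    idx <- .shIndex(lmax)
    vapply(idx[, "l"], function(l) {
        if (l == 0L) return(2 * pi)
        k <- l / 2
        2 * pi * (-1)^k * prod(seq(1, l - 1, by = 2)) / prod(seq(2, l, by = 2))
    }, numeric(1))
}
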