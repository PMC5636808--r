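## Patch-matching weights, Rician-bias-corrected weighted means, the
## simple-averaging baseline and the mean-shift template estimator.

#' x-q space candidate neighbourhood
#'
#' All pairs (voxel j, direction l) with Euclidean voxel distance
#' \code{|x_i - x_j| <= rs} and axis angle \code{acos(|q_k . q_l|) <=
#' alphaS}; the target pair (i, k) is always included. The neighbourhood is
#' a Cartesian product of the spatial and angular balls, and the relation is
#' symmetric in (i, k) and (j, l).
#'
#' @param i,k target voxel index and direction index.
#' @param scheme a [GradientScheme-class].
#' @param coords voxel coordinate matrix (voxels x 3, voxel units).
#' @param rs spatial radius in voxels (>= 0).
#' @param alphaS angular radius in degrees (> 0).
#' @return list with \code{voxels}, \code{dirs} (index vectors), and
#'   \code{pairs}, the full candidate matrix with columns voxel/dir.
#' @export
buildNeighborhood <- function(i, k, scheme, coords, rs = 2, alphaS = 30) {
    if (rs < 0) stop("'rs' must be >= 0")
    if (alphaS <= 0) stop("'alphaS' must be positive")
    coords <- as.matrix(coords)
    d2 <- rowSums((coords - matrix(coords[i, ], nrow(coords), 3L,
        byrow = TRUE))^2)
    vox <- which(d2 <= rs^2 + 1e-12)
    g <- directions(scheme)
    ang <- acos(pmin(1, abs(drop(g %*% g[k, ])))) * 180 / pi
    dirs <- which(ang <= alphaS + 1e-12)
    list(voxels = vox, dirs = dirs,
         pairs = as.matrix(expand.grid(voxel = vox, dir = dirs)))
}

#' Feature-kernel bandwidth
#'
#' \code{h_M = sqrt(2 * beta * sigmaHat^2 * featureCount)}: the attenuation
#' of the patch-similarity kernel scales with the noise variance and the
#' length of the feature vector, following the non-local-means bandwidth
#' convention.
#'
#' @param beta kernel constant (> 0).
#' @param sigmaHat estimated Gaussian noise SD (>= 0).
#' @param featureCount length of the feature vector: the element count
#'   (2m+1)^2 by default, or its Euclidean norm under the alternative
#'   interpretation.
#' @return the bandwidth in signal units; 0 when \code{sigmaHat} is 0 (the
#'   caller must then treat the kernel as an exact-match indicator).
#' @examples
#' hM(0.1, 7.5, 81)
#' @export
hM <- function(beta, sigmaHat, featureCount) {
    if (beta <= 0) stop("'beta' must be positive")
    if (sigmaHat < 0) stop("'sigmaHat' must be >= 0")
    if (featureCount < 1) stop("'featureCount' must be >= 1")
    sqrt(2 * beta * sigmaHat^2 * featureCount)
}

#' Patch-matching weights for one target
#'
#' Unnormalised weights are the product of a feature kernel
#' \code{exp(-d_M^2 / h_M^2)} on the squared distance between magnitude
#' feature vectors and a spatial kernel \code{exp(-|x_i - x_j|^2 / h_x^2)},
#' then normalised to sum to one over all candidates. If every unnormalised
#' weight underflows to zero the weights fall back to uniform with a
#' warning. With \code{h_M = 0} (noise-free data) the kernel degenerates to
#' an indicator on exact feature matches.
#'
#' @param refFeatures magnitude feature vector of the reference patch.
#' @param candFeatures matrix of candidate magnitude features (one row per
#'   candidate).
#' @param refPosition,candPositions voxel coordinates of the reference and
#'   of each candidate (rows).
#' @param config a [FusionConfig-class]; \code{sigma} must be set.
#' @param patchSize number of q-space samples in the reference patch;
#'   required when \code{config@hMMode == "patch"}.
#' @return normalised weight vector (sums to 1).
#' @export
computeWeights <- function(refFeatures, candFeatures, refPosition,
                           candPositions, config, patchSize = NULL) {
    candFeatures <- as.matrix(candFeatures)
    if (ncol(candFeatures) != length(refFeatures))
        stop("candidate features must share the reference's order")
    sigma <- config@sigma
    if (is.na(sigma)) stop("'config@sigma' must be set")
    fc <- switch(config@hMMode,
        patch = {
            if (is.null(patchSize))
                stop("'patchSize' is required with hMMode = \"patch\"")
            patchSize
        },
        count = length(refFeatures),
        norm = sqrt(sum(refFeatures^2)))
    h <- hM(config@beta, sigma, max(fc, 1))
    d2 <- rowSums((candFeatures - matrix(refFeatures,
        nrow(candFeatures), length(refFeatures), byrow = TRUE))^2)
    dx2 <- rowSums((as.matrix(candPositions) - matrix(refPosition,
        nrow(candFeatures), 3L, byrow = TRUE))^2)
    hx2 <- 2 * config@sigmaX^2
    w <- if (h == 0)
        as.numeric(d2 <= 1e-8 * (sum(refFeatures^2) + 1)) * exp(-dx2 / hx2)
    else exp(-d2 / h^2 - dx2 / hx2)
    Z <- sum(w)
    if (Z == 0) {
        warning("all matching weights underflowed; using uniform weights")
        w <- rep(1 / length(w), length(w))
    } else {
        w <- w / Z
    }
    w
}

#' Bias-corrected weighted mean of signals
#'
#' \code{sqrt(sum(w * S^2) - 2 * sigma^2)}, clamped at zero when the Rician
#' bias correction drives the bracket negative. With uniform weights over
#' the D subjects' own signals this reduces exactly to the simple-averaging
#' estimator.
#'
#' @param weights normalised weights (sum to 1).
#' @param signals candidate signals, same length.
#' @param sigma Gaussian noise SD.
#' @return the fused scalar signal (>= 0).
#' @examples
#' weightedMeanSignal(c(0.25, 0.75), c(10, 20), 1)  # sqrt(323)
#' @export
weightedMeanSignal <- function(weights, signals, sigma = 0) {
    if (abs(sum(weights) - 1) > 1e-9)
        stop("'weights' must sum to 1")
    sqrt(max(0, sum(weights * signals^2) - 2 * sigma^2))
}

#' Simple-averaging template (baseline)
#'
#' Per voxel and direction, the square root of the mean squared signal over
#' subjects minus \code{2 * sigma^2} (Rician bias removal), clamped at zero.
#'
#' @param population a [DiffusionPopulation-class].
#' @param sigma Gaussian noise SD; defaults to the population's.
#' @return A [DiffusionTemplate-class] with \code{method = "average"}.
#' @export
simpleAverage <- function(population, sigma = noiseSigma(population)) {
    D <- nSubjects(population)
    S2 <- Reduce(`+`, lapply(seq_len(D),
        function(d) subjectSignals(population, d)^2)) / D
    sig <- sqrt(pmax(S2 - 2 * sigma^2, 0))
    new("DiffusionTemplate", signals = sig, scheme = scheme(population),
        coords = S4Vectors::DataFrame(voxelCoords(population)),
        trace = numeric(0), iterations = 0L, method = "average")
}

#' Mean-shift template fusion
#'
#' Seeks, at every point of the x-q space, the mode of the population's
#' signal distribution instead of its mean. Starting from the
#' simple-averaging template, each iteration (a) recomputes the
#' rotation-invariant patch features of the current template, (b) recomputes
#' the matching weights of every candidate subject patch in the local x-q
#' neighbourhood against the template patch, and (c) updates each template
#' value by the bias-corrected weighted mean. Iteration stops when the mean
#' absolute change drops below \code{gamma * sigma} (or below 1e-12 when
#' \code{sigma = 0}), or after \code{tMax} iterations.
#'
#' Candidate subject features never change and are computed once; only the
#' template's features are refreshed per iteration. Weights exist only while
#' a voxel is updated, keeping memory at O(K * candidates) per voxel.
#'
#' @param population a [DiffusionPopulation-class].
#' @param config a [FusionConfig-class]; when \code{config@sigma} is NA the
#'   population's known noise SD is used.
#' @param verbose print per-iteration tolerance against the stopping
#'   threshold.
#' @return A [DiffusionTemplate-class] with the per-iteration mean absolute
#'   change in \code{convergenceTrace()}.
#' @export
meanShiftFuse <- function(population, config = fusionConfig(),
                          verbose = FALSE) {
    stopifnot(is(population, "DiffusionPopulation"),
              is(config, "FusionConfig"))
    sch <- scheme(population)
    g <- directions(sch)
    K <- nrow(g)
    V <- nrow(population)
    D <- nSubjects(population)
    sigma <- if (is.na(config@sigma)) noiseSigma(population) else config@sigma
    coords <- voxelCoords(population)
    Fdim <- (2L * config@m + 1L)^2

    grid <- polarGrid(config@nRings, config@nAngles)
    Phi <- .patchFeatureOperator(sch, m = config@m, alphaP = config@alphaP,
        grid = grid, shOrder = config@shOrder, shLambda = config@shLambda,
        dedup = TRUE)
    Fb <- nrow(Phi) / K  # deduplicated feature rows; distances preserved

    ## candidate features as one Fb x (K * D * V) matrix, voxel-major:
    ## column of candidate (voxel j, subject d, direction l) is
    ## (j-1)*K*D + (d-1)*K + l. Squared signals share the (l; d, j) layout.
    CB <- matrix(0, Fb, K * D * V)
    S2c <- matrix(0, K, D * V)
    for (d in seq_len(D)) {
        S <- t(subjectSignals(population, d))  # K x V
        fb <- .featureBank(Phi, S, Fb)         # Fb, K, V
        for (v in seq_len(V))
            CB[, ((v - 1L) * K * D + (d - 1L) * K + 1L):
                  ((v - 1L) * K * D + d * K)] <- fb[, , v]
        S2c[, (seq_len(V) - 1L) * D + d] <- S^2
    }
    cn <- colSums(CB^2)

    ## neighbourhood structure: spatial ball per voxel, angular cone per
    ## direction (allowed candidate directions l for each target k)
    angK <- acos(pmin(abs(tcrossprod(g)), 1)) * 180 / pi
    allowedL <- lapply(seq_len(K), function(k)
        which(angK[k, ] <= config@alphaS + 1e-12))
    spatial <- lapply(seq_len(V), function(i) {
        d2 <- rowSums((coords - matrix(coords[i, ], V, 3L, byrow = TRUE))^2)
        j <- which(d2 <= config@rs^2 + 1e-12)
        list(j = j, w = exp(-d2[j] / (2 * config@sigmaX^2)))
    })
    ## per-voxel candidate gather: global column indices plus aligned
    ## candidate norms, spatial weights and squared signals
    gather <- lapply(seq_len(V), function(i) {
        nb <- spatial[[i]]
        cols <- unlist(lapply(nb$j, function(j)
            ((j - 1L) * K * D + 1L):(j * K * D)))
        list(nj = length(nb$j), cols = cols, cn = cn[cols],
             sw = rep(nb$w, each = K * D),
             s2 = as.vector(S2c[, rep((nb$j - 1L) * D, each = D) +
                 rep(seq_len(D), length(nb$j)), drop = FALSE]))
    })

    ## squared feature bandwidth per target direction k; "norm" mode is
    ## resolved per iteration from the reference feature norm
    patchSizes <- rowSums(angK <= config@alphaP + 1e-12)
    hm2Fixed <- switch(config@hMMode,
        patch = 2 * config@beta * sigma^2 * patchSizes,
        count = rep(2 * config@beta * sigma^2 * Fdim, K),
        norm = NULL)

    Scur <- templateSignals(simpleAverage(population, sigma = sigma))
    threshold <- if (sigma > 0) config@gamma * sigma else 1e-12
    trace <- numeric(0)

    for (t in seq_len(config@tMax)) {
        TF <- .featureBank(Phi, t(Scur), Fb)  # Fb, K, V
        Snew <- Scur
        for (i in seq_len(V)) {
            ga <- gather[[i]]
            R <- TF[, , i, drop = TRUE]
            dim(R) <- c(Fb, K)
            rn <- colSums(R^2)
            Dots <- crossprod(R, CB[, ga$cols, drop = FALSE])
            offs <- (seq_len(ga$nj * D) - 1L) * K
            hm2 <- if (is.null(hm2Fixed))
                2 * config@beta * sigma^2 * pmax(sqrt(rn), 1)
            else hm2Fixed
            for (k in seq_len(K)) {
                idxK <- as.vector(outer(allowedL[[k]], offs, `+`))
                d2 <- rn[k] + ga$cn[idxK] - 2 * Dots[k, idxK]
                ## sigma = 0 degenerates the kernel to an exact-match
                ## indicator; the tolerance is relative to the feature
                ## scale because d2 is computed with catastrophic
                ## cancellation for identical patches
                w <- if (sigma == 0)
                    as.numeric(d2 <= 1e-8 * (rn[k] + 1)) * ga$sw[idxK]
                    else exp(-d2 / hm2[k]) * ga$sw[idxK]
                Z <- sum(w)
                if (Z == 0) {          # kernel underflow: uniform fallback
                    w <- rep(1, length(w))
                    Z <- length(w)
                }
                Snew[i, k] <- sqrt(max(0,
                    sum(w * ga$s2[idxK]) / Z - 2 * sigma^2))
            }
        }
        tol <- mean(abs(Snew - Scur))
        trace <- c(trace, tol)
        Scur <- Snew
        if (verbose)
            message(sprintf("iteration %d: tol = %.6g (threshold %.6g)",
                t, tol, threshold))
        if (tol < threshold) break
    }

    new("DiffusionTemplate", signals = Scur, scheme = sch,
        coords = S4Vectors::DataFrame(voxelCoords(population)),
        trace = trace, iterations = length(trace), method = "meanshift")
}
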