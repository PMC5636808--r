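#' @include AllGenerics.R
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## GradientScheme
## ---------------------------------------------------------------------------

#' Single-shell gradient sampling scheme
#'
#' A set of unit diffusion-encoding directions (wavevector axes) shared by all
#' subjects of a population, together with the common b-value of the shell.
#' Directions are treated as axes: \code{g} and \code{-g} encode the same
#' measurement, and no two directions may be collinear as axes.
#'
#' @slot directions numeric matrix (K x 3), unit rows.
#' @slot bValue single non-negative number, s/mm^2.
#'
#' @seealso [gradientScheme()], [defaultScheme()]
#' @export
setClass("GradientScheme",
    representation(directions = "matrix", bValue = "numeric"))

setValidity("GradientScheme", function(object) {
    d <- object@directions
    if (!is.numeric(d) || ncol(d) != 3L)
        return("'directions' must be a numeric K x 3 matrix")
    if (length(object@bValue) != 1L || object@bValue < 0)
        return("'bValue' must be a single non-negative number")
    nrm <- sqrt(rowSums(d^2))
    if (any(abs(nrm - 1) > 1e-12))
        return("all directions must have unit norm (tolerance 1e-12)")
    if (nrow(d) > 1L) {
        ca <- abs(tcrossprod(d))
        diag(ca) <- 0
        if (any(ca >= 1 - 1e-12))
            return("directions must be pairwise non-collinear as axes")
    }
    TRUE
})

#' Construct a GradientScheme
#'
#' @param directions numeric K x 3 matrix of directions; rows are normalised
#'   to unit length.
#' @param bValue shell b-value in s/mm^2.
#' @return A [GradientScheme-class] object.
#' @examples
#' gradientScheme(diag(3), bValue = 3000)
#' @export
gradientScheme <- function(directions, bValue = 3000) {
    directions <- as.matrix(directions)
    storage.mode(directions) <- "double"
    nrm <- sqrt(rowSums(directions^2))
    if (any(nrm == 0))
        stop("zero direction vector in gradient scheme")
    new("GradientScheme", directions = directions / nrm, bValue = as.numeric(bValue))
}

#' @describeIn GradientScheme-class the K x 3 direction matrix.
#' @param x a \code{GradientScheme}.
#' @export
setMethod("directions", "GradientScheme", function(x) x@directions)

#' @describeIn GradientScheme-class the shell b-value (s/mm^2).
#' @export
setMethod("bValue", "GradientScheme", function(x) x@bValue)

#' @describeIn GradientScheme-class number of directions K.
#' @export
setMethod("nDirections", "GradientScheme", function(x) nrow(x@directions))

#' @describeIn GradientScheme-class smallest pairwise axis angle, degrees.
#' @export
setMethod("minPairwiseAngle", "GradientScheme", function(x) {
    ca <- abs(tcrossprod(x@directions))
    diag(ca) <- -1
    acos(pmin(1, max(ca))) * 180 / pi
})

setMethod("show", "GradientScheme", function(object) {
    cat("GradientScheme:", nDirections(object), "directions, b =",
        object@bValue, "s/mm^2\n")
    cat("  min pairwise axis angle:",
        format(minPairwiseAngle(object), digits = 4), "deg\n")
})

## ---------------------------------------------------------------------------
## FiberConfig
## ---------------------------------------------------------------------------

#' Fiber configuration of a synthetic voxel
#'
#' One or more fiber axes with positive volume fractions summing to one.
#' Used by the multi-tensor signal generator.
#'
#' @slot axes numeric matrix (one unit axis per row).
#' @slot weights positive fractions summing to 1.
#' @slot label short configuration name.
#' @seealso [fiberConfig()]
#' @export
setClass("FiberConfig",
    representation(axes = "matrix", weights = "numeric", label = "character"))

setValidity("FiberConfig", function(object) {
    if (nrow(object@axes) != length(object@weights))
        return("one weight per axis required")
    if (ncol(object@axes) != 3L)
        return("'axes' must have 3 columns")
    if (any(object@weights <= 0))
        return("weights must be strictly positive")
    if (abs(sum(object@weights) - 1) > 1e-12)
        return("weights must sum to 1 (tolerance 1e-12)")
    if (any(abs(sqrt(rowSums(object@axes^2)) - 1) > 1e-12))
        return("axes must be unit vectors")
    TRUE
})

#' @describeIn FiberConfig-class axis matrix (n x 3).
#' @param x a \code{FiberConfig}.
#' @export
setMethod("fiberAxes", "FiberConfig", function(x) x@axes)

#' @describeIn FiberConfig-class volume fractions.
#' @export
setMethod("fiberWeights", "FiberConfig", function(x) x@weights)

setMethod("show", "FiberConfig", function(object) {
    cat("FiberConfig '", object@label, "': ", nrow(object@axes),
        " fiber(s), weights ", paste(format(object@weights, digits = 3),
        collapse = "/"), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Settings of the dispersed-fiber benchmark generator
#'
#' Holds the Watson dispersion half-angle \code{thetaT} (degrees; the derived
#' concentration is \code{kappa = 2 / sin^2(thetaT)}), the Rician noise level
#' as a percentage \code{noisePercent} of the maximum signal \code{maxSignal},
#' the baseline signal \code{S0}, the axial/radial diffusivities of the tensor
#' model (mm^2/s) and the population size \code{populationSize}.
#'
#' @export
setClass("SimulationConfig",
    representation(thetaT = "numeric", noisePercent = "numeric",
        maxSignal = "numeric", S0 = "numeric",
        lambdaAxial = "numeric", lambdaRadial = "numeric",
        populationSize = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@thetaT < 0 || object@thetaT > 90)
        return("'thetaT' must lie in [0, 90] degrees")
    if (object@noisePercent < 0 || object@noisePercent >= 100)
        return("'noisePercent' must lie in [0, 100)")
    if (object@maxSignal <= 0 || object@S0 <= 0)
        return("'maxSignal' and 'S0' must be positive")
    if (object@lambdaRadial <= 0 || object@lambdaAxial < object@lambdaRadial)
        return("need lambdaAxial >= lambdaRadial > 0")
    if (object@populationSize < 1L)
        return("'populationSize' must be >= 1")
    TRUE
})

#' @param thetaT dispersion half-angle, degrees in [0, 90]; 0 disables
#'   dispersion (kappa infinite).
#' @param noisePercent Rician noise level p, percent of \code{maxSignal}.
#' @param maxSignal maximum possible signal value v (noise scale reference).
#' @param S0 non-diffusion-weighted baseline signal.
#' @param lambdaAxial,lambdaRadial tensor eigenvalues, mm^2/s.
#' @param populationSize number of subjects D.
#' @return A \code{SimulationConfig}.
#' @describeIn SimulationConfig-class constructor. Defaults reproduce the
#'   synthetic benchmark: S0 = v = 150 and standard white-matter
#'   diffusivities.
#' @examples
#' simulationConfig(thetaT = 30, noisePercent = 5)
#' @export
simulationConfig <- function(thetaT = 30, noisePercent = 5, maxSignal = 150,
                             S0 = 150, lambdaAxial = 1.7e-3,
                             lambdaRadial = 3e-4, populationSize = 20L) {
    new("SimulationConfig", thetaT = as.numeric(thetaT),
        noisePercent = as.numeric(noisePercent),
        maxSignal = as.numeric(maxSignal), S0 = as.numeric(S0),
        lambdaAxial = as.numeric(lambdaAxial),
        lambdaRadial = as.numeric(lambdaRadial),
        populationSize = as.integer(populationSize))
}

setMethod("show", "SimulationConfig", function(object) {
    kap <- if (object@thetaT == 0) Inf else watsonKappa(object@thetaT)
    cat("SimulationConfig: thetaT =", object@thetaT, "deg (kappa =",
        format(kap, digits = 5), "), noise =", object@noisePercent,
        "% of", object@maxSignal, ", D =", object@populationSize, "\n")
})

## ---------------------------------------------------------------------------
## FusionConfig
## ---------------------------------------------------------------------------

#' Mean-shift fusion parameters
#'
#' All defaults follow the method's reference setting: spatial search radius
#' \code{rs} = 2 voxels, kernel constant \code{beta} = 0.1, a 30-degree
#' q-space patch and search aperture, moment order \code{m} = 4 and stopping
#' factor \code{gamma} = 0.001 (iteration stops when the mean absolute
#' template change drops below \code{gamma * sigma}).
#'
#' The two q-space angles are stored as the thresholds the code applies:
#' \code{alphaP} is the patch radius (directions within \code{alphaP} of the
#' centre belong to the patch; 30 degrees keeps the two nearest direction
#' rings of an 81-direction shell, about 10 samples). \code{alphaS} is the
#' radius of the candidate search cone; its default 15 degrees realises a
#' 30-degree full search aperture (one direction ring), which is the reading
#' of the reference setting under which mode seeking beats plain averaging —
#' with a 30-degree search radius, rotation-invariant features cannot
#' separate second-ring candidates from genuine cross-subject matches and
#' the update blurs crossing profiles (see the methods vignette).
#'
#' @slot rs spatial search radius, voxels.
#' @slot alphaS q-space search radius, degrees (half the search aperture).
#' @slot alphaP q-space patch radius, degrees.
#' @slot beta feature-kernel bandwidth constant.
#' @slot m maximum moment order.
#' @slot gamma stopping-rule factor (threshold gamma * sigma).
#' @slot tMax iteration cap.
#' @slot sigma Gaussian noise SD in signal units; NA = take from the data.
#' @slot sigmaX spatial kernel scale, voxels (h_x = sqrt(2) * sigmaX).
#' @slot hMMode interpretation of the "vector length" in the bandwidth rule
#'   \code{h_M = sqrt(2 * beta * sigma^2 * length)}: \code{"patch"} (default)
#'   uses the patch cardinality (number of q-space samples within alphaP of
#'   the patch centre), matching the patch-size convention of the non-local
#'   means literature the rule is borrowed from; \code{"count"} uses the
#'   feature-vector element count (2m+1)^2; \code{"norm"} its Euclidean norm.
#' @slot shOrder,shLambda spherical-harmonic resampling settings.
#' @slot nRings,nAngles polar grid resolution for the disc moments.
#' @export
setClass("FusionConfig",
    representation(rs = "numeric", alphaS = "numeric", alphaP = "numeric",
        beta = "numeric", m = "integer", gamma = "numeric", tMax = "integer",
        sigma = "numeric", sigmaX = "numeric", hMMode = "character",
        shOrder = "integer", shLambda = "numeric",
        nRings = "integer", nAngles = "integer"))

setValidity("FusionConfig", function(object) {
    if (object@rs < 0) return("'rs' must be >= 0")
    if (object@alphaS <= 0 || object@alphaS > 90)
        return("'alphaS' must lie in (0, 90] degrees")
    if (object@alphaP <= 0 || object@alphaP >= 90)
        return("'alphaP' must lie in (0, 90) degrees")
    if (object@beta <= 0) return("'beta' must be positive")
    if (object@m < 0L) return("'m' must be >= 0")
    if (object@gamma <= 0) return("'gamma' must be positive")
    if (object@tMax < 1L) return("'tMax' must be >= 1")
    if (!is.na(object@sigma) && object@sigma < 0)
        return("'sigma' must be >= 0")
    if (object@sigmaX <= 0) return("'sigmaX' must be positive")
    if (!object@hMMode %in% c("patch", "count", "norm"))
        return("'hMMode' must be \"patch\", \"count\" or \"norm\"")
    TRUE
})

#' @param rs,alphaS,alphaP,beta,m,gamma,tMax,sigma,sigmaX,hMMode,shOrder,shLambda,nRings,nAngles
#'   see the class slots.
#' @return A \code{FusionConfig}.
#' @describeIn FusionConfig-class constructor with the reference defaults.
#' @examples
#' fusionConfig(rs = 0)  # q-space-only neighbourhood
#' @export
fusionConfig <- function(rs = 2, alphaS = 15, alphaP = 30, beta = 0.1,
                         m = 4L, gamma = 0.001, tMax = 10L, sigma = NA_real_,
                         sigmaX = 1.0, hMMode = "patch", shOrder = 8L,
                         shLambda = 0.006, nRings = 8L, nAngles = 16L) {
    new("FusionConfig", rs = as.numeric(rs), alphaS = as.numeric(alphaS),
        alphaP = as.numeric(alphaP), beta = as.numeric(beta),
        m = as.integer(m), gamma = as.numeric(gamma), tMax = as.integer(tMax),
        sigma = as.numeric(sigma), sigmaX = as.numeric(sigmaX),
        hMMode = hMMode, shOrder = as.integer(shOrder),
        shLambda = as.numeric(shLambda), nRings = as.integer(nRings),
        nAngles = as.integer(nAngles))
}

setMethod("show", "FusionConfig", function(object) {
    cat("FusionConfig: rs =", object@rs, "vox, alphaP/alphaS =",
        object@alphaP, "/", object@alphaS, "deg, beta =", object@beta,
        ", m =", object@m, ", gamma =", object@gamma,
        ", tMax =", object@tMax, "\n")
})

## ---------------------------------------------------------------------------
## DiffusionPopulation
## ---------------------------------------------------------------------------

#' Population of aligned diffusion signal sets
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are voxels
#' (with 0-based grid coordinates in \code{rowData}), columns are gradient
#' directions, and each assay holds one subject's voxel x direction signal
#' matrix. Populations produced by [makePopulation()] also carry the
#' noise-free dispersion-free ground-truth signals, the true fiber axes and
#' the Gaussian noise SD.
#'
#' @slot scheme the shared [GradientScheme-class].
#' @slot groundTruth voxel x direction noise-free reference signals.
#' @slot trueAxes matrix of true fiber axes (one per row).
#' @slot sigma Gaussian noise SD in signal units.
#' @export
setClass("DiffusionPopulation",
    contains = "SummarizedExperiment",
    representation(scheme = "GradientScheme", groundTruth = "matrix",
        trueAxes = "matrix", sigma = "numeric"))

setValidity("DiffusionPopulation", function(object) {
    K <- nDirections(object@scheme)
    if (ncol(object) != K)
        return("number of columns must equal the number of directions")
    for (a in as.list(assays(object)))
        if (any(a < 0)) return("magnitude signals must be non-negative")
    if (length(object@groundTruth) &&
        !all(dim(object@groundTruth) == c(nrow(object), K)))
        return("groundTruth must be voxels x directions")
    if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma < 0)
        return("'sigma' must be a single non-negative number")
    TRUE
})

#' @describeIn DiffusionPopulation-class number of subjects D.
#' @param x a \code{DiffusionPopulation}.
#' @export
setMethod("nSubjects", "DiffusionPopulation", function(x) length(assays(x)))

#' @describeIn DiffusionPopulation-class voxel x direction signal matrix of
#'   subject \code{d} (index or assay name).
#' @param d subject index or name.
#' @export
setMethod("subjectSignals", "DiffusionPopulation",
    function(x, d) as.matrix(assay(x, d)))

#' @describeIn DiffusionPopulation-class noise-free reference signals.
#' @export
setMethod("groundTruth", "DiffusionPopulation", function(x) x@groundTruth)

#' @describeIn DiffusionPopulation-class true fiber axes (rows).
#' @export
setMethod("trueAxes", "DiffusionPopulation", function(x) x@trueAxes)

#' @describeIn DiffusionPopulation-class Gaussian noise SD.
#' @export
setMethod("noiseSigma", "DiffusionPopulation", function(x) x@sigma)

#' @describeIn DiffusionPopulation-class the shared gradient scheme.
#' @export
setMethod("scheme", "DiffusionPopulation", function(x) x@scheme)

setMethod("show", "DiffusionPopulation", function(object) {
    cat("DiffusionPopulation:", nSubjects(object), "subjects,",
        nrow(object), "voxels x", ncol(object), "directions, b =",
        bValue(object@scheme), "s/mm^2, sigma =",
        format(object@sigma, digits = 4), "\n")
})

#' Voxel grid coordinates of a population
#'
#' @param x a \code{DiffusionPopulation} or \code{DiffusionTemplate}.
#' @return integer matrix (voxels x 3) of 0-based grid coordinates.
#' @export
voxelCoords <- function(x) {
    rd <- if (is(x, "DiffusionPopulation")) rowData(x) else x@coords
    as.matrix(rd[, c("vx", "vy", "vz")])
}

## ---------------------------------------------------------------------------
## DiffusionTemplate
## ---------------------------------------------------------------------------

#' Fused diffusion template
#'
#' The result of [meanShiftFuse()] or [simpleAverage()]: the fused signal
#' matrix over voxels x directions together with the per-iteration mean
#' absolute change trace of the mean-shift iteration.
#'
#' @slot signals voxel x direction fused signal matrix (non-negative).
#' @slot scheme the gradient scheme.
#' @slot coords voxel grid coordinates (\code{DataFrame} with vx, vy, vz).
#' @slot trace mean absolute change per completed iteration.
#' @slot iterations number of iterations performed (0 for simple averaging).
#' @slot method "meanshift" or "average".
#' @export
setClass("DiffusionTemplate",
    representation(signals = "matrix", scheme = "GradientScheme",
        coords = "DataFrame", trace = "numeric", iterations = "integer",
        method = "character"))

setValidity("DiffusionTemplate", function(object) {
    if (any(object@signals < 0))
        return("fused signals must be non-negative")
    if (ncol(object@signals) != nDirections(object@scheme))
        return("signal columns must match the number of directions")
    if (object@iterations > 0L &&
        length(object@trace) != object@iterations)
        return("trace must be recorded for every completed iteration")
    TRUE
})

#' @describeIn DiffusionTemplate-class fused voxel x direction signals.
#' @param x a \code{DiffusionTemplate}.
#' @export
setMethod("templateSignals", "DiffusionTemplate", function(x) x@signals)

#' @describeIn DiffusionTemplate-class per-iteration mean absolute change.
#' @export
setMethod("convergenceTrace", "DiffusionTemplate", function(x) x@trace)

#' @describeIn DiffusionTemplate-class number of mean-shift iterations run.
#' @export
setMethod("iterationsUsed", "DiffusionTemplate", function(x) x@iterations)

#' @describeIn DiffusionTemplate-class the gradient scheme.
#' @export
setMethod("scheme", "DiffusionTemplate", function(x) x@scheme)

setMethod("show", "DiffusionTemplate", function(object) {
    cat("DiffusionTemplate (", object@method, "): ", nrow(object@signals),
        " voxels x ", ncol(object@signals), " directions", sep = "")
    if (object@iterations > 0L)
        cat(", ", object@iterations, " iterations, final tol ",
            format(utils::tail(object@trace, 1), digits = 4), sep = "")
    cat("\n")
})

## ---------------------------------------------------------------------------
## Patch-level value classes
## ---------------------------------------------------------------------------

#' Polar quadrature grid on the unit disc
#'
#' Ring radii are midpoints in rho^2 (equal-area rings): under the
#' 1/pi-normalised disc measure the radial part of the moment integral then
#' becomes an exact discrete Fourier sum, so moments of a constant patch
#' vanish exactly for all basis indices resolved by the grid.
#'
#' @slot nRings,nAngles grid resolution.
#' @slot rho,theta node coordinates (length nRings * nAngles, ring-major).
#' @slot weights quadrature weights, summing to 1.
#' @seealso [polarGrid()]
#' @export
setClass("PolarGridSpec",
    representation(nRings = "integer", nAngles = "integer", rho = "numeric",
        theta = "numeric", weights = "numeric"))

setValidity("PolarGridSpec", function(object) {
    if (any(object@weights <= 0)) return("quadrature weights must be > 0")
    if (abs(sum(object@weights) - 1) > 1e-12)
        return("quadrature weights must sum to 1")
    TRUE
})

#' Spherical q-space patch
#'
#' The scheme directions (antipodally canonicalised to the centre's
#' hemisphere) that lie within the patch angle \code{alphaP} of a centre
#' direction.
#'
#' @slot centerIndex index of the centre direction in the scheme.
#' @slot memberIndices scheme indices of patch members (centre included).
#' @slot memberAxes canonicalised member axes, one per row.
#' @slot center the centre axis.
#' @slot alphaP patch angle, degrees.
#' @slot scheme the originating scheme (kept for resampling).
#' @seealso [extractPatch()]
#' @export
setClass("SphericalPatch",
    representation(centerIndex = "integer", memberIndices = "integer",
        memberAxes = "matrix", center = "numeric", alphaP = "numeric",
        scheme = "GradientScheme"))

setValidity("SphericalPatch", function(object) {
    if (!(object@centerIndex %in% object@memberIndices))
        return("the centre must be a patch member")
    ang <- acos(pmin(1, abs(drop(object@memberAxes %*% object@center)))) *
        180 / pi
    if (any(ang > object@alphaP + 1e-9))
        return("all members must lie within alphaP of the centre")
    TRUE
})

#' Patch projected to the unit disc
#'
#' Member axes mapped by azimuthal equidistant projection about the patch
#' centre, with the radial coordinate normalised by the patch angle so the
#' patch fills the unit disc, plus the patch signal resampled on a fixed
#' polar grid. The centre's azimuth is undefined and stored as 0.
#'
#' @slot polarCoords matrix with columns \code{rhoNorm} (in [0, 1]) and
#'   \code{theta} (in [0, 2*pi)).
#' @slot memberSignals signal at the member directions.
#' @slot gridSignal resampled signal at the grid nodes (ring-major).
#' @slot grid the [PolarGridSpec-class] used.
#' @seealso [resampleToPolarGrid()]
#' @export
setClass("ProjectedPatch",
    representation(polarCoords = "matrix", memberSignals = "numeric",
        gridSignal = "numeric", grid = "PolarGridSpec"))

setValidity("ProjectedPatch", function(object) {
    if (any(object@polarCoords[, "rhoNorm"] > 1 + 1e-9))
        return("normalised radius must not exceed 1")
    TRUE
})

#' Rotation-invariant disc moment features
#'
#' Complex polar exponential moments M[n, l] for -m <= n, l <= m and the
#' magnitude feature vector, concatenated in lexicographic (n, l) order.
#'
#' @slot moments complex (2m+1) x (2m+1) matrix, rows indexed by n, columns
#'   by l, both running -m..m.
#' @slot magnitudes numeric vector of length (2m+1)^2, |M[n, l]| in
#'   lexicographic (n, l) order.
#' @slot order the maximum order m.
#' @seealso [pcetMoments()], [featureDistance()]
#' @export
setClass("PCETFeatures",
    representation(moments = "matrix", magnitudes = "numeric",
        order = "integer"))

setValidity("PCETFeatures", function(object) {
    if (length(object@magnitudes) != (2L * object@order + 1L)^2)
        return("magnitude vector must have length (2m+1)^2")
    if (any(object@magnitudes < 0))
        return("magnitudes must be non-negative")
    TRUE
})

#' @describeIn PCETFeatures-class the magnitude feature vector.
#' @param x a \code{PCETFeatures}.
#' @export
setMethod("momentMagnitudes", "PCETFeatures", function(x) x@magnitudes)

#' @describeIn PCETFeatures-class the maximum order m.
#' @export
setMethod("momentOrder", "PCETFeatures", function(x) x@order)

## ---------------------------------------------------------------------------
## PeakSet
## ---------------------------------------------------------------------------

#' Extracted fiber orientation peaks
#'
#' Antipodal representatives of local ODF maxima, sorted by decreasing ODF
#' value.
#'
#' @slot axes unit axes, one per row.
#' @slot values ODF values at the peaks.
#' @seealso [estimatePeaks()], [orientationalDiscrepancy()]
#' @export
setClass("PeakSet",
    representation(axes = "matrix", values = "numeric"))

setValidity("PeakSet", function(object) {
    if (nrow(object@axes) < 1L) return("a peak set must be non-empty")
    if (nrow(object@axes) != length(object@values))
        return("one value per peak required")
    TRUE
})

#' @describeIn PeakSet-class peak axes (rows).
#' @param x a \code{PeakSet}.
#' @export
setMethod("peakAxes", "PeakSet", function(x) x@axes)

#' @describeIn PeakSet-class ODF values at the peaks.
#' @export
setMethod("peakValues", "PeakSet", function(x) x@values)

setMethod("show", "PeakSet", function(object) {
    cat("PeakSet:", nrow(object@axes), "peak(s)\n")
    for (i in seq_len(nrow(object@axes)))
        cat(sprintf("  [%d] (% .3f, % .3f, % .3f)  value %.4g\n", i,
            object@axes[i, 1], object@axes[i, 2], object@axes[i, 3],
            object@values[i]))
})
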