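## Dispersed-fiber synthetic benchmark: multi-tensor signals, Watson
## orientation dispersion across subjects, Rician noise.

#' Construct a fiber configuration
#'
#' Either give \code{axes}/\code{weights} explicitly or pick one of the four
#' benchmark presets: \code{"single"} (one fiber), \code{"cross90eq"} /
#' \code{"cross60eq"} (two equally weighted fibers 90 or 60 degrees apart)
#' and \code{"cross90uneq"} (two fibers 90 degrees apart, weights 0.65/0.35).
#'
#' @param preset preset name, ignored when \code{axes} is given.
#' @param axes matrix of fiber axes (one per row).
#' @param weights volume fractions, summing to 1.
#' @param label configuration label (defaults to the preset name).
#' @return A [FiberConfig-class].
#' @examples
#' fiberConfig("cross60eq")
#' @export
fiberConfig <- function(preset = c("single", "cross90eq", "cross60eq",
                                   "cross90uneq"),
                        axes = NULL, weights = NULL, label = NULL) {
    if (is.null(axes)) {
        preset <- match.arg(preset)
        axes <- switch(preset,
            single = rbind(c(1, 0, 0)),
            cross90eq = rbind(c(1, 0, 0), c(0, 1, 0)),
            cross60eq = rbind(c(1, 0, 0),
                c(cos(pi / 3), sin(pi / 3), 0)),
            cross90uneq = rbind(c(1, 0, 0), c(0, 1, 0)))
        weights <- switch(preset,
            single = 1,
            cross90eq = c(0.5, 0.5),
            cross60eq = c(0.5, 0.5),
            cross90uneq = c(0.65, 0.35))
        if (is.null(label)) label <- preset
    } else {
        axes <- .unitize(axes)
        if (is.null(weights)) weights <- rep(1 / nrow(axes), nrow(axes))
        if (is.null(label)) label <- "custom"
    }
    new("FiberConfig", axes = .unitize(axes), weights = as.numeric(weights),
        label = label)
}

#' Noise-free multi-tensor diffusion signal
#'
#' Evaluates \code{S(g) = S0 * sum_f w_f * exp(-b * g' D_f g)} over the
#' scheme directions, each tensor \code{D_f} axially symmetric about its
#' fiber axis with eigenvalues (lambdaAxial, lambdaRadial, lambdaRadial).
#'
#' @param config a [FiberConfig-class].
#' @param scheme a [GradientScheme-class].
#' @param S0 baseline signal.
#' @param lambdaAxial,lambdaRadial diffusivities, mm^2/s, with
#'   \code{lambdaAxial >= lambdaRadial > 0}.
#' @return numeric vector of length \code{nDirections(scheme)}, in (0, S0].
#' @examples
#' sch <- gradientScheme(diag(3), bValue = 3000)
#' multiTensorSignal(fiberConfig("single"), sch)
#' @export
multiTensorSignal <- function(config, scheme, S0 = 150,
                              lambdaAxial = 1.7e-3, lambdaRadial = 3e-4) {
    if (lambdaRadial <= 0 || lambdaAxial < lambdaRadial)
        stop("need lambdaAxial >= lambdaRadial > 0")
    g <- directions(scheme)
    b <- bValue(scheme)
    ## g' D g = lambdaRadial + (lambdaAxial - lambdaRadial) * (g . axis)^2
    ca2 <- (g %*% t(fiberAxes(config)))^2
    adc <- lambdaRadial + (lambdaAxial - lambdaRadial) * ca2
    drop(S0 * exp(-b * adc) %*% fiberWeights(config))
}

#' Add Rician noise to magnitude signals
#'
#' Gaussian noise of standard deviation \code{sigma = v * p / 100} is added
#' to the real and imaginary channels of the (real) signal and the magnitude
#' taken: \code{out = sqrt((S + n1)^2 + n2^2)}.
#'
#' @param signal numeric vector or matrix of noise-free magnitudes.
#' @param p noise level, percent of the maximum signal \code{v}.
#' @param v maximum possible signal value.
#' @param seed optional integer seed.
#' @return noisy magnitudes, same shape as \code{signal}.
#' @examples
#' addRicianNoise(rep(100, 5), p = 5, v = 150, seed = 1)
#' @export
addRicianNoise <- function(signal, p, v = 150, seed = NULL) {
    if (p < 0) stop("'p' must be >= 0")
    if (v <= 0) stop("'v' must be positive")
    if (p == 0) return(signal)
    if (!is.null(seed)) set.seed(seed)
    sigma <- v * p / 100
    n1 <- stats::rnorm(length(signal), 0, sigma)
    n2 <- stats::rnorm(length(signal), 0, sigma)
    out <- sqrt((signal + n1)^2 + n2^2)
    if (is.matrix(signal)) out <- matrix(out, nrow(signal), ncol(signal))
    out
}

#' Simulate a dispersed-fiber population
#'
#' Generates \code{populationSize} subjects on a small voxel grid. For every
#' subject and voxel, each fiber axis of \code{config} is independently
#' perturbed by a Watson draw with concentration \code{kappa =
#' 2 / sin^2(thetaT)} (no perturbation when \code{thetaT = 0}), the
#' multi-tensor signal is synthesised, and Rician noise at
#' \code{noisePercent} of \code{maxSignal} is added. Voxels are therefore
#' i.i.d. realisations of the same dispersed profile; the ground truth is
#' the unperturbed noise-free profile.
#'
#' One RNG stream drives the whole dataset: given the same \code{seed} the
#' returned population is bit-identical.
#'
#' @param sim a [SimulationConfig-class].
#' @param config a [FiberConfig-class].
#' @param scheme a [GradientScheme-class].
#' @param volumeDim integer grid dimensions, e.g. \code{c(3, 3, 3)}.
#' @param seed integer seed.
#' @return A [DiffusionPopulation-class] with per-subject assays, ground
#'   truth, true axes and \code{sigma = maxSignal * noisePercent / 100}.
#' @examples
#' sch <- defaultScheme(20, seed = 1)
#' pop <- makePopulation(simulationConfig(populationSize = 4),
#'                       fiberConfig("single"), sch,
#'                       volumeDim = c(2, 2, 1), seed = 1)
#' pop
#' @export
makePopulation <- function(sim, config, scheme, volumeDim = c(3L, 3L, 3L),
                           seed = 1L) {
    stopifnot(is(sim, "SimulationConfig"), is(config, "FiberConfig"),
              is(scheme, "GradientScheme"))
    volumeDim <- as.integer(volumeDim)
    V <- prod(volumeDim)
    K <- nDirections(scheme)
    D <- sim@populationSize
    nf <- nrow(fiberAxes(config))
    sigma <- sim@maxSignal * sim@noisePercent / 100
    kappa <- if (sim@thetaT == 0) Inf else watsonKappa(sim@thetaT)

    gt1 <- multiTensorSignal(config, scheme, S0 = sim@S0,
        lambdaAxial = sim@lambdaAxial, lambdaRadial = sim@lambdaRadial)
    gt <- matrix(gt1, V, K, byrow = TRUE)

    set.seed(seed)
    g <- directions(scheme)
    b <- bValue(scheme)
    w <- fiberWeights(config)
    assaysList <- vector("list", D)
    for (d in seq_len(D)) {
        S <- matrix(0, V, K)
        for (f in seq_len(nf)) {
            ax <- if (is.finite(kappa))
                sampleWatsonAxes(fiberAxes(config)[f, ], kappa, V)
            else
                matrix(fiberAxes(config)[f, ], V, 3L, byrow = TRUE)
            ca2 <- (g %*% t(ax))^2  # K x V
            adc <- sim@lambdaRadial +
                (sim@lambdaAxial - sim@lambdaRadial) * ca2
            S <- S + w[f] * sim@S0 * t(exp(-b * adc))
        }
        if (sim@noisePercent > 0)
            S <- addRicianNoise(S, p = sim@noisePercent, v = sim@maxSignal)
        assaysList[[d]] <- S
    }
    names(assaysList) <- sprintf("subject%02d", seq_len(D))

    coords <- as.matrix(expand.grid(vx = seq_len(volumeDim[1]) - 1L,
                                    vy = seq_len(volumeDim[2]) - 1L,
                                    vz = seq_len(volumeDim[3]) - 1L))
    se <- SummarizedExperiment(assays = assaysList,
        rowData = S4Vectors::DataFrame(coords),
        colData = S4Vectors::DataFrame(
            gx = directions(scheme)[, 1], gy = directions(scheme)[, 2],
            gz = directions(scheme)[, 3], bval = bValue(scheme)))
    S4Vectors::metadata(se) <- list(volumeDim = volumeDim,
        simulation = sim, configLabel = config@label, seed = seed)
    new("DiffusionPopulation", se, scheme = scheme, groundTruth = gt,
        trueAxes = fiberAxes(config), sigma = sigma)
}
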