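## Population-level input/output: per-subject 4D NIfTI volumes plus a shared
## gradient table, template writing with a JSON fusion report.

#' Write a simulated population to disk
#'
#' One 4D NIfTI per subject (X x Y x Z x K), a shared bvec/bval pair, the
#' ground-truth volume and a JSON sidecar with sigma, kappa and the true
#' axes.
#'
#' @param population a [DiffusionPopulation-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param gzip write .nii.gz instead of .nii.
#' @return named list of written paths, invisibly.
#' @export
writePopulation <- function(population, dir, prefix = "synthetic",
                            gzip = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    md <- S4Vectors::metadata(population)
    vd <- md$volumeDim
    K <- ncol(population)
    ext <- if (gzip) ".nii.gz" else ".nii"
    paths <- character(0)
    for (d in seq_len(nSubjects(population))) {
        p <- file.path(dir, sprintf("%s_subject%02d%s", prefix, d, ext))
        writeNifti(array(subjectSignals(population, d), c(vd, K)), p)
        paths <- c(paths, p)
    }
    gtPath <- file.path(dir, paste0(prefix, "_groundtruth", ext))
    writeNifti(array(groundTruth(population), c(vd, K)), gtPath)
    gtab <- writeGradientTable(scheme(population),
        file.path(dir, prefix))
    sim <- md$simulation
    side <- list(sigma = noiseSigma(population),
        thetaT = if (!is.null(sim)) sim@thetaT else NA,
        kappa = if (!is.null(sim) && sim@thetaT > 0)
            watsonKappa(sim@thetaT) else NA,
        noisePercent = if (!is.null(sim)) sim@noisePercent else NA,
        trueAxes = trueAxes(population),
        configLabel = md$configLabel, seed = md$seed,
        volumeDim = vd, bValue = bValue(scheme(population)))
    jsonPath <- file.path(dir, paste0(prefix, "_info.json"))
    jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(list(subjects = paths, groundTruth = gtPath,
        bvec = gtab[1], bval = gtab[2], sidecar = jsonPath))
}

#' Read an aligned population from disk
#'
#' Assembles subject 4D volumes sharing one gradient table into a
#' [DiffusionPopulation-class]. Entries with b-value below
#' \code{b0Threshold} are excluded from the shell with a message. When
#' several records carry their own bvec/bval the schemes must agree within
#' 1e-6 per axis.
#'
#' @param imagePaths character vector of subject 4D NIfTI paths.
#' @param bvecPath,bvalPath shared gradient table.
#' @param sigma Gaussian noise SD if known (default 0).
#' @param b0Threshold b-values below this (s/mm^2) are dropped from the
#'   shell.
#' @return A [DiffusionPopulation-class] (ground truth empty, axes unknown).
#' @export
readPopulation <- function(imagePaths, bvecPath, bvalPath, sigma = 0,
                           b0Threshold = 50) {
    gt <- readGradientTable(bvecPath, bvalPath)
    shell <- which(gt$bvals >= b0Threshold)
    if (length(shell) < length(gt$bvals))
        message("excluding ", length(gt$bvals) - length(shell),
                " low-b (b < ", b0Threshold, ") entries from the shell")
    sch <- gradientScheme(gt$directions[shell, , drop = FALSE],
        bValue = stats::median(gt$bvals[shell]))
    K <- length(shell)
    assaysList <- list()
    vd <- NULL
    for (p in imagePaths) {
        img <- readNifti(p)
        if (length(dim(img$data)) != 4L)
            stop("subject image is not 4D: ", p)
        if (dim(img$data)[4] != length(gt$bvals))
            stop("direction count mismatch between image and bvec for ", p)
        if (is.null(vd)) vd <- dim(img$data)[1:3]
        else if (!all(dim(img$data)[1:3] == vd))
            stop("voxel grid mismatch for ", p)
        S <- matrix(img$data, prod(vd), dim(img$data)[4])[, shell,
            drop = FALSE]
        assaysList[[length(assaysList) + 1L]] <- S
    }
    names(assaysList) <- sprintf("subject%02d", seq_along(assaysList))
    coords <- as.matrix(expand.grid(vx = seq_len(vd[1]) - 1L,
        vy = seq_len(vd[2]) - 1L, vz = seq_len(vd[3]) - 1L))
    se <- SummarizedExperiment(assays = assaysList,
        rowData = S4Vectors::DataFrame(coords),
        colData = S4Vectors::DataFrame(
            gx = directions(sch)[, 1], gy = directions(sch)[, 2],
            gz = directions(sch)[, 3], bval = bValue(sch)))
    S4Vectors::metadata(se) <- list(volumeDim = as.integer(vd))
    new("DiffusionPopulation", se, scheme = sch,
        groundTruth = matrix(numeric(0), 0, 0),
        trueAxes = matrix(numeric(0), 0, 3), sigma = as.numeric(sigma))
}

#' Write a fused template with its convergence report
#'
#' Writes the template as 4D NIfTI, the gradient table, and a JSON report
#' with the fusion settings, iterations used, the convergence trace and the
#' stopping threshold.
#'
#' @param template a [DiffusionTemplate-class].
#' @param prefix output path prefix.
#' @param volumeDim 3D grid dimensions of the template voxels.
#' @param config the [FusionConfig-class] used (echoed into the report).
#' @param sigma noise SD used (echoed; defines the gamma * sigma threshold).
#' @param gzip write .nii.gz instead of .nii.
#' @return named list of written paths, invisibly.
#' @export
writeTemplate <- function(template, prefix, volumeDim,
                          config = fusionConfig(), sigma = NA, gzip = FALSE) {
    if (any(!is.finite(templateSignals(template))))
        stop("template contains non-finite signals")
    ext <- if (gzip) ".nii.gz" else ".nii"
    imgPath <- paste0(prefix, "_template", ext)
    writeNifti(array(templateSignals(template), c(volumeDim,
        ncol(templateSignals(template)))), imgPath)
    gtab <- writeGradientTable(scheme(template), prefix)
    cfgList <- list(rs = config@rs, alphaS = config@alphaS,
        alphaP = config@alphaP, beta = config@beta, m = config@m,
        gamma = config@gamma, tMax = config@tMax, sigma = config@sigma,
        sigmaX = config@sigmaX, hMMode = config@hMMode,
        shOrder = config@shOrder, shLambda = config@shLambda,
        nRings = config@nRings, nAngles = config@nAngles)
    report <- list(method = template@method,
        iterationsUsed = iterationsUsed(template),
        trace = convergenceTrace(template),
        finalTol = if (length(convergenceTrace(template)))
            utils::tail(convergenceTrace(template), 1) else NA,
        stoppingThreshold = if (!is.na(sigma)) config@gamma * sigma else NA,
        sigma = sigma, config = cfgList,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonPath <- paste0(prefix, "_report.json")
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(list(image = imgPath, bvec = gtab[1], bval = gtab[2],
        report = jsonPath))
}
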