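## Shared fixtures. Scheme construction is the only expensive setup, so the
## two schemes used throughout are built once per test run.

.fixtures <- new.env(parent = emptyenv())

scheme81 <- function() {
    if (is.null(.fixtures$s81))
        .fixtures$s81 <- defaultScheme(81L, seed = 1L)
    .fixtures$s81
}

scheme20 <- function() {
    if (is.null(.fixtures$s20))
        .fixtures$s20 <- defaultScheme(20L, seed = 1L)
    .fixtures$s20
}

## Two-population contamination fixture: majority single-fiber subjects
## along the x axis, a minority along the orthogonal y axis, one voxel.
mixedPopulation <- function(seed, nMajor = 16L, nMinor = 4L, thetaT = 15,
                            noisePercent = 3) {
    sch <- scheme81()
    g <- directions(sch)
    pa <- makePopulation(
        simulationConfig(thetaT = thetaT, noisePercent = noisePercent,
            populationSize = nMajor),
        fiberConfig("single"), sch, volumeDim = c(1L, 1L, 1L), seed = seed)
    pb <- makePopulation(
        simulationConfig(thetaT = thetaT, noisePercent = noisePercent,
            populationSize = nMinor),
        fiberConfig(axes = rbind(c(0, 1, 0)), weights = 1,
            label = "minority"),
        sch, volumeDim = c(1L, 1L, 1L), seed = seed + 50000L)
    as_ <- c(lapply(seq_len(nMajor), function(d) subjectSignals(pa, d)),
             lapply(seq_len(nMinor), function(d) subjectSignals(pb, d)))
    names(as_) <- sprintf("s%02d", seq_along(as_))
    se <- SummarizedExperiment::SummarizedExperiment(assays = as_,
        rowData = S4Vectors::DataFrame(vx = 0L, vy = 0L, vz = 0L),
        colData = S4Vectors::DataFrame(gx = g[, 1], gy = g[, 2],
            gz = g[, 3], bval = bValue(sch)))
    methods::new("DiffusionPopulation", se, scheme = sch,
        groundTruth = groundTruth(pa), trueAxes = trueAxes(pa),
        sigma = noiseSigma(pa))
}
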