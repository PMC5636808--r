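test_that("fiberConfig presets satisfy their separation labels", {
    for (pre in c("cross90eq", "cross90uneq")) {
        ax <- fiberAxes(fiberConfig(pre))
        expect_equal(acos(abs(sum(ax[1, ] * ax[2, ]))) * 180 / pi, 90,
            tolerance = 1e-9)
    }
    ax <- fiberAxes(fiberConfig("cross60eq"))
    expect_equal(acos(abs(sum(ax[1, ] * ax[2, ]))) * 180 / pi, 60,
        tolerance = 1e-9)
    expect_equal(fiberWeights(fiberConfig("cross90uneq")), c(0.65, 0.35))
    expect_error(fiberConfig(axes = diag(3), weights = c(0.5, 0.5, 0.1)))
})

test_that("multi-tensor signal matches the closed forms", {
    sch0 <- gradientScheme(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
        bValue = 0)
    expect_equal(multiTensorSignal(fiberConfig("single"), sch0),
        rep(150, 3))

    b <- 3000
    sch <- gradientScheme(rbind(c(1, 0, 0), c(0, 1, 0)), bValue = b)
    s <- multiTensorSignal(fiberConfig("single"), sch, S0 = 150,
        lambdaAxial = 1.7e-3, lambdaRadial = 3e-4)
    expect_equal(s[1], 150 * exp(-b * 1.7e-3), tolerance = 1e-12)
    expect_equal(s[2], 150 * exp(-b * 3e-4), tolerance = 1e-12)

    full <- multiTensorSignal(fiberConfig("cross60eq"), scheme81())
    expect_true(all(full > 0 & full <= 150))
    expect_error(multiTensorSignal(fiberConfig("single"), sch,
        lambdaAxial = 1e-4, lambdaRadial = 3e-4))
})

test_that("noise-free signals are invariant under joint rotation", {
    sch <- scheme81()
    cfg <- fiberConfig("cross90eq")
    base <- multiTensorSignal(cfg, sch)
    set.seed(42)
    for (r in 1:10) {
        R <- qr.Q(qr(matrix(rnorm(9), 3)))
        if (det(R) < 0) R[, 1] <- -R[, 1]
        schR <- gradientScheme(directions(sch) %*% t(R), bValue(sch))
        cfgR <- fiberConfig(axes = fiberAxes(cfg) %*% t(R),
            weights = fiberWeights(cfg))
        expect_lt(max(abs(multiTensorSignal(cfgR, schR) - base)), 1e-10)
    }
})

test_that("Rician noise has the Rayleigh mean and second-moment identity", {
    expect_identical(addRicianNoise(c(1, 2, 3), p = 0), c(1, 2, 3))

    ## S = 0: output is Rayleigh with mean sigma * sqrt(pi / 2)
    out <- addRicianNoise(rep(0, 1e6), p = 5, v = 150, seed = 3)
    expect_equal(mean(out), 7.5 * sqrt(pi / 2), tolerance = 0.005)

    ## E[S_noisy^2] = S^2 + 2 sigma^2
    S <- 40
    out <- addRicianNoise(rep(S, 1e6), p = 5, v = 150, seed = 4)
    expect_equal(mean(out^2), S^2 + 2 * 7.5^2, tolerance = 0.005)

    expect_identical(addRicianNoise(rep(1, 5), p = 3, v = 150, seed = 9),
        addRicianNoise(rep(1, 5), p = 3, v = 150, seed = 9))
})

test_that("populations degenerate to ground truth and reproduce exactly", {
    sch <- scheme20()
    cfg <- fiberConfig("cross90eq")
    pop <- makePopulation(simulationConfig(thetaT = 0, noisePercent = 0,
        populationSize = 4), cfg, sch, volumeDim = c(2, 2, 1), seed = 5)
    for (d in 1:4)
        expect_equal(subjectSignals(pop, d), groundTruth(pop))

    p1 <- makePopulation(simulationConfig(populationSize = 3), cfg, sch,
        volumeDim = c(2, 1, 1), seed = 6)
    p2 <- makePopulation(simulationConfig(populationSize = 3), cfg, sch,
        volumeDim = c(2, 1, 1), seed = 6)
    expect_identical(lapply(1:3, function(d) subjectSignals(p1, d)),
                     lapply(1:3, function(d) subjectSignals(p2, d)))
    expect_equal(noiseSigma(p1), 150 * 5 / 100)
})

test_that("subject-mean squared signals carry the Rician bias term", {
    sch <- scheme20()
    pop <- makePopulation(simulationConfig(thetaT = 0, noisePercent = 5,
        populationSize = 1000), fiberConfig("single"), sch,
        volumeDim = c(1, 1, 1), seed = 8)
    m2 <- Reduce(`+`, lapply(seq_len(1000),
        function(d) subjectSignals(pop, d)^2)) / 1000
    expected <- groundTruth(pop)^2 + 2 * noiseSigma(pop)^2
    ## Monte-Carlo error of mean(S^2) at D = 1000 is ~3% of the expectation
    ## in the deep-attenuation directions (var = 4 S^2 sigma^2 + 4 sigma^4),
    ## so the per-direction bound is set at ~3 sd and the aggregate one
    ## tighter
    expect_lt(max(abs(m2 - expected) / expected), 0.10)
    expect_lt(sqrt(sum((m2 - expected)^2)) / sqrt(sum(expected^2)), 0.02)
})

test_that("the repulsion scheme is uniform, reproducible, near-optimal", {
    sch <- scheme81()
    expect_equal(nDirections(sch), 81L)
    expect_equal(sqrt(rowSums(directions(sch)^2)), rep(1, 81),
        tolerance = 1e-12)
    ## the paper-scale shell: minimal angular separation around 15 degrees
    expect_gt(minPairwiseAngle(sch), 12)
    expect_lt(minPairwiseAngle(sch), 18)

    s1 <- defaultScheme(20, seed = 3)
    s2 <- defaultScheme(20, seed = 3)
    expect_identical(directions(s1), directions(s2))

    ## K = 6: the icosahedral half-set is the optimal axis packing; the
    ## optimiser must reach its repulsion energy
    ico <- dmriTemplate:::.icosahedron()$vertices
    half <- ico[ico[, 3] > 0 | (ico[, 3] == 0 & ico[, 2] > 0) |
        (ico[, 3] == 0 & ico[, 2] == 0 & ico[, 1] > 0), ]
    expect_equal(nrow(half), 6L)
    eIco <- dmriTemplate:::.repulsionEnergy(half)
    eOpt <- dmriTemplate:::.repulsionEnergy(directions(defaultScheme(6,
        seed = 2)))
    expect_equal(eOpt, eIco, tolerance = 1e-3)
    expect_error(defaultScheme(5))
})
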