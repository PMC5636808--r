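test_that("x-q neighbourhoods match brute force and are symmetric", {
    sch <- scheme81()
    g <- directions(sch)
    dims <- c(5L, 5L, 5L)
    coords <- as.matrix(expand.grid(vx = 0:4, vy = 0:4, vz = 0:4))

    nb <- buildNeighborhood(1L, 1L, sch, coords, rs = 0,
        alphaS = 0.9 * minPairwiseAngle(sch))
    expect_identical(nb$pairs, cbind(voxel = 1L, dir = 1L))

    ## brute-force double loop over all (voxel, direction) pairs
    i <- 63L; k <- 40L
    nb <- buildNeighborhood(i, k, sch, coords, rs = 2, alphaS = 30)
    bf <- matrix(0L, 0L, 2L)
    for (j in seq_len(nrow(coords)))
        for (l in seq_len(81L))
            if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 2 &&
                acos(min(1, abs(sum(g[k, ] * g[l, ])))) * 180 / pi <= 30)
                bf <- rbind(bf, c(j, l))
    got <- nb$pairs[order(nb$pairs[, "dir"], nb$pairs[, "voxel"]), ]
    bf <- bf[order(bf[, 2], bf[, 1]), ]
    expect_equal(unname(as.matrix(got)), unname(bf))

    ## symmetry of the neighbourhood relation
    set.seed(5)
    for (r in 1:20) {
        i <- sample(125L, 1); j <- sample(125L, 1)
        k <- sample(81L, 1); l <- sample(81L, 1)
        inIJ <- any(buildNeighborhood(i, k, sch, coords)$pairs[, 1] == j &
                    buildNeighborhood(i, k, sch, coords)$pairs[, 2] == l)
        inJI <- any(buildNeighborhood(j, l, sch, coords)$pairs[, 1] == i &
                    buildNeighborhood(j, l, sch, coords)$pairs[, 2] == k)
        expect_identical(inIJ, inJI)
    }
})

test_that("the feature bandwidth follows the stated rule", {
    expect_equal(hM(0.5, 1, 1), 1.0)
    expect_equal(hM(0.1, 7.5, 81), sqrt(2 * 0.1 * 56.25 * 81))  # 30.186...
    expect_equal(hM(0.1, 0, 81), 0)
    expect_lt(hM(0.1, 7.5, 81), hM(0.2, 7.5, 81))
    expect_lt(hM(0.1, 7.5, 81), hM(0.1, 8, 81))
    expect_lt(hM(0.1, 7.5, 10), hM(0.1, 7.5, 81))
    expect_error(hM(0, 1, 1))
})

test_that("matching weights normalise, symmetrise, and fall back", {
    cfg <- fusionConfig(sigma = 7.5)
    ref <- rep(10, 81)
    expect_equal(computeWeights(ref, rbind(ref + 1), c(0, 0, 0),
        rbind(c(1, 0, 0)), cfg, patchSize = 10), 1)

    two <- rbind(ref + 2, ref - 2)
    w <- computeWeights(ref, two, c(0, 0, 0), rbind(c(1, 0, 0), c(0, 1, 0)),
        cfg, patchSize = 10)
    expect_equal(w, c(0.5, 0.5))

    ## three candidates with hand-set distances: softmax-style oracle
    cand <- rbind(ref, ref + 1, ref + 3)
    pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
    w <- unname(computeWeights(ref, cand, c(0, 0, 0), pos, cfg,
        patchSize = 10))
    h2 <- 2 * 0.1 * 7.5^2 * 10
    hx2 <- 2 * 1^2
    raw <- c(exp(0), exp(-81 / h2 - 1 / hx2), exp(-81 * 9 / h2 - 4 / hx2))
    expect_equal(w, raw / sum(raw), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)

    expect_warning(
        wU <- computeWeights(ref, rbind(ref + 1e6, ref - 1e6), c(0, 0, 0),
            pos[1:2, ], cfg, patchSize = 10),
        "underflow")
    expect_equal(wU, c(0.5, 0.5))
})

test_that("the bias-corrected weighted mean matches its closed forms", {
    expect_equal(weightedMeanSignal(rep(0.2, 5), rep(7, 5), 0), 7)
    expect_equal(weightedMeanSignal(c(0.25, 0.75), c(10, 20), 1),
        sqrt(323))  # 17.972...
    expect_equal(weightedMeanSignal(c(0.5, 0.5), c(1, 1), 50), 0)
    expect_error(weightedMeanSignal(c(0.5, 0.4), c(1, 1)))

    ## uniform weights over the subjects' own signals reduce to Eq-10
    ## simple averaging exactly
    set.seed(6)
    s <- runif(20, 0, 150)
    expect_equal(weightedMeanSignal(rep(1 / 20, 20), s, 7.5),
        sqrt(max(0, mean(s^2) - 2 * 7.5^2)), tolerance = 1e-12)
})

test_that("simple averaging handles degenerate populations", {
    sch <- scheme20()
    pop <- makePopulation(simulationConfig(thetaT = 0, noisePercent = 0,
        populationSize = 1), fiberConfig("single"), sch,
        volumeDim = c(2, 1, 1), seed = 7)
    expect_equal(templateSignals(simpleAverage(pop)),
        subjectSignals(pop, 1))

    pop4 <- makePopulation(simulationConfig(thetaT = 0, noisePercent = 0,
        populationSize = 4), fiberConfig("cross90eq"), sch,
        volumeDim = c(2, 1, 1), seed = 8)
    expect_equal(templateSignals(simpleAverage(pop4)), groundTruth(pop4))
})

test_that("mean shift reaches the fixed point of identical subjects", {
    sch <- scheme81()
    pop <- makePopulation(simulationConfig(thetaT = 0, noisePercent = 0,
        populationSize = 5), fiberConfig("cross90eq"), sch,
        volumeDim = c(2, 1, 1), seed = 9)
    tpl <- meanShiftFuse(pop, fusionConfig(rs = 1))
    expect_equal(templateSignals(tpl), groundTruth(pop), tolerance = 1e-9)
    expect_identical(iterationsUsed(tpl), 1L)
    expect_length(convergenceTrace(tpl), 1L)
    expect_lt(convergenceTrace(tpl)[1], 1e-12)
})

test_that("huge bandwidth reduces mean shift to simple averaging", {
    ## beta -> Inf makes every feature kernel 1; with a q-space cone that
    ## only contains the target direction and rs = 0, the update is exactly
    ## the Eq-10 estimator
    sch <- scheme81()
    pop <- makePopulation(simulationConfig(thetaT = 20, noisePercent = 5,
        populationSize = 6), fiberConfig("single"), sch,
        volumeDim = c(2, 1, 1), seed = 10)
    cfg <- fusionConfig(rs = 0, alphaS = 0.9 * minPairwiseAngle(sch),
        beta = 1e12, tMax = 3L)
    tpl <- meanShiftFuse(pop, cfg)
    expect_equal(templateSignals(tpl),
        templateSignals(simpleAverage(pop)), tolerance = 1e-9)
})

test_that("fused signals respect the neighbourhood maximum bound", {
    sch <- scheme81()
    pop <- makePopulation(simulationConfig(thetaT = 30, noisePercent = 5,
        populationSize = 8), fiberConfig("cross60eq"), sch,
        volumeDim = c(2, 2, 1), seed = 11)
    tpl <- meanShiftFuse(pop, fusionConfig(tMax = 3L))
    sig <- templateSignals(tpl)
    smax <- do.call(pmax, lapply(seq_len(8), function(d)
        subjectSignals(pop, d)))
    ## weighted quadratic mean over any neighbourhood cannot exceed the
    ## global maximum after bias removal
    bound <- sqrt(pmax(max(smax)^2 - 2 * noiseSigma(pop)^2, 0))
    expect_true(all(sig <= bound + 1e-9))
    expect_lte(iterationsUsed(tpl), 3L)
    expect_length(convergenceTrace(tpl), iterationsUsed(tpl))
})

test_that("mean shift seeks the mode of a contaminated population", {
    ## 80/20 mixture: the template must land nearer the majority profile
    ## than the average does (small-n version of the robustness criterion)
    wins <- 0L
    for (s in 1:5) {
        pop <- mixedPopulation(seed = 300 + s)
        maj <- groundTruth(pop)[1, ]
        dAvg <- sqrt(sum((templateSignals(simpleAverage(pop))[1, ] -
            maj)^2))
        dMS <- sqrt(sum((templateSignals(meanShiftFuse(pop,
            fusionConfig()))[1, ] - maj)^2))
        wins <- wins + (dMS < dAvg)
    }
    expect_gte(wins, 4L)
})
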