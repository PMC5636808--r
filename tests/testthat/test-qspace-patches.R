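test_that("antipodal canonicalisation flips onto the reference hemisphere", {
    ref <- c(0, 0, 1)
    expect_equal(unname(antipodalCanonicalize(c(0.1, 0.2, 0.9), ref)),
        rbind(c(0.1, 0.2, 0.9)))
    expect_equal(unname(antipodalCanonicalize(-ref, ref)),
        rbind(c(0, 0, 1)))
    set.seed(1)
    ax <- dmriTemplate:::.unitize(matrix(rnorm(300), 100))
    out <- antipodalCanonicalize(ax, c(1, -1, 2))
    expect_true(all(out %*% c(1, -1, 2) >= 0))
    expect_true(all(abs(out) == abs(ax)))
    expect_error(antipodalCanonicalize(ax, c(0, 0, 0)))
})

test_that("AEP preserves radial distance and reduces to longitude at the pole", {
    expect_equal(unname(aepProject(c(0, 0, 1), c(0, 0, 1))[1, "rho"]), 0)

    ## any axis 30 degrees from the centre projects to rho = pi/6
    ctr <- dmriTemplate:::.unitize(rbind(c(1, 1, 1)))[1, ]
    set.seed(2)
    for (i in 1:5) {
        perp <- rnorm(3); perp <- perp - sum(perp * ctr) * ctr
        perp <- perp / sqrt(sum(perp^2))
        ax <- cos(pi / 6) * ctr + sin(pi / 6) * perp
        expect_equal(unname(aepProject(ctr, ax)[1, "rho"]), pi / 6,
            tolerance = 1e-12)
    }

    ## centre at the north pole: the azimuth reduces to pi - longitude
    ## (independent simplification of the projection trigonometry)
    pole <- c(0, 0, 1)
    lam <- c(0.3, 1.2, -2.0, 2.9)
    phi <- c(0.5, 0.1, 1.0, -0.2)
    pts <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
    pts <- antipodalCanonicalize(pts, pole)
    pc <- aepProject(pole, pts)
    lamC <- atan2(pts[, 2], pts[, 1])
    expect_equal(pc[, "theta"], (pi - lamC) %% (2 * pi), tolerance = 1e-9)

    expect_error(aepProject(pole, rbind(c(0, 0, -1))))
})

test_that("AEP radial preservation and injectivity hold on scheme patches", {
    sch <- scheme81()
    g <- directions(sch)
    for (k in c(1L, 40L, 81L)) {
        p <- extractPatch(sch, k, alphaP = 30)
        pc <- aepProject(p@center, p@memberAxes)
        ## compared in the cosine domain: acos amplifies rounding near
        ## rho = 0 (the centre member) far beyond 1e-12
        expect_lt(max(abs(cos(pc[, "rho"]) -
            pmin(1, drop(p@memberAxes %*% p@center)))), 1e-12)
        ## injective: distinct members, distinct projected points
        pts <- cbind(pc[, "rho"] * cos(pc[, "theta"]),
                     pc[, "rho"] * sin(pc[, "theta"]))
        expect_equal(nrow(unique(round(pts, 9))), nrow(pts))
    }
})

test_that("patch membership matches brute force and flags singletons", {
    sch <- scheme81()
    g <- directions(sch)
    p <- extractPatch(sch, 10L, alphaP = 30)
    bf <- which(acos(pmin(1, abs(g %*% g[10, ]))) * 180 / pi <= 30 + 1e-12)
    expect_identical(p@memberIndices, as.integer(bf))
    expect_true(10L %in% p@memberIndices)

    expect_message(ps <- extractPatch(sch, 1L,
        alphaP = 0.5 * minPairwiseAngle(sch)), "only its centre")
    expect_identical(ps@memberIndices, 1L)
    expect_error(extractPatch(sch, 1L, alphaP = 95))

    ## membership is stable under global rotation of the scheme
    set.seed(3)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    schR <- gradientScheme(g %*% t(R), bValue(sch))
    pR <- extractPatch(schR, 10L, alphaP = 30)
    expect_identical(p@memberIndices, pR@memberIndices)
})

test_that("polar-grid resampling reproduces constants and SH functions", {
    sch <- scheme81()
    p <- extractPatch(sch, 5L, alphaP = 30)

    pr <- resampleToPolarGrid(p, rep(7.5, 81))
    expect_lt(max(abs(pr@gridSignal - 7.5)), 1e-9)
    expect_true(all(pr@polarCoords[, "rhoNorm"] <= 1 + 1e-12))

    ## an order-4 SH basis function sampled on the scheme must be
    ## reproduced at the grid nodes (analytic evaluation oracle);
    ## unregularised fit, since the Laplace-Beltrami penalty shrinks l = 4
    B <- dmriTemplate:::.shBasis(directions(sch), 8L)
    idx <- dmriTemplate:::.shIndex(8L)
    j <- which(idx[, "l"] == 4 & idx[, "m"] == 2)
    sig <- B[, j]
    pr <- resampleToPolarGrid(p, sig, shOrder = 8L, shLambda = 0)
    nodes <- dmriTemplate:::.aepInverse(p@center,
        pr@grid@rho * 30 * pi / 180, pr@grid@theta)
    analytic <- dmriTemplate:::.shBasis(nodes, 8L)[, j]
    expect_lt(max(abs(pr@gridSignal - analytic)), 1e-6)

    expect_error(resampleToPolarGrid(p, rep(1, 10)))
})

test_that("resampling is rotation-equivariant up to in-plane rotation", {
    ## a joint rotation of scheme + signal rotates the projected patch
    ## in-plane by a constant azimuth offset: the per-ring angular spectrum
    ## and the PCET magnitudes are the invariants that must match
    sch <- scheme81()
    g <- directions(sch)
    sig <- multiTensorSignal(fiberConfig("cross60eq"), sch)
    k <- 17L
    p <- extractPatch(sch, k, alphaP = 30)
    pr <- resampleToPolarGrid(p, sig)

    set.seed(4)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    schR <- gradientScheme(g %*% t(R), bValue(sch))
    pR <- extractPatch(schR, k, alphaP = 30)
    prR <- resampleToPolarGrid(pR, sig)

    nR <- pr@grid@nRings
    nA <- pr@grid@nAngles
    m1 <- matrix(pr@gridSignal, nR, nA)
    m2 <- matrix(prR@gridSignal, nR, nA)
    for (r in seq_len(nR))
        expect_equal(Mod(fft(m1[r, ])), Mod(fft(m2[r, ])),
            tolerance = 1e-6)

    f1 <- momentMagnitudes(pcetMoments(pr, 4L))
    f2 <- momentMagnitudes(pcetMoments(prR, 4L))
    expect_lt(max(abs(f1 - f2)), 1e-6 * max(1, max(f1)))
})
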