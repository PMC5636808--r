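test_that("the moment basis is unit modulus with the stated values", {
    expect_equal(pcetBasis(0, 0, 0.3, 1.1), 1 + 0i)
    expect_equal(pcetBasis(1, 0, 1 / sqrt(2), 0), -1 + 0i,
        tolerance = 1e-12)
    set.seed(1)
    for (i in 1:20) {
        h <- pcetBasis(sample(-4:4, 1), sample(-4:4, 1), runif(1),
            runif(1, 0, 2 * pi))
        expect_equal(Mod(h), 1, tolerance = 1e-12)
    }
})

## moments of analytically integrable patch signals, via a synthetic
## ProjectedPatch built directly on a grid
gridPatch <- function(values, grid = polarGrid()) {
    methods::new("ProjectedPatch",
        polarCoords = cbind(rhoNorm = 0, theta = 0),
        memberSignals = 0, gridSignal = values, grid = grid)
}

test_that("moments of constant and radial signals match closed forms", {
    g8 <- polarGrid(8, 16)
    f <- pcetMoments(gridPatch(rep(1, length(g8@rho)), g8), 4L)
    mags <- momentMagnitudes(f)
    expect_length(mags, 81L)
    i00 <- which(dmriTemplate:::.pcetIndex(4L)[, "n"] == 0 &
                 dmriTemplate:::.pcetIndex(4L)[, "l"] == 0)
    expect_equal(mags[i00], 1, tolerance = 1e-3)
    expect_lt(max(mags[-i00]), 1e-3)

    ## on a 64 x 128 grid the non-(0,0) moments vanish to 1e-6
    g64 <- polarGrid(64, 128)
    f64 <- pcetMoments(gridPatch(rep(1, length(g64@rho)), g64), 4L)
    expect_equal(momentMagnitudes(f64)[i00], 1, tolerance = 1e-6)
    expect_lt(max(momentMagnitudes(f64)[-i00]), 1e-6)

    ## S = rho^2: M00 = (1/pi) * 2 pi * int rho^3 = 1/2
    f2 <- pcetMoments(gridPatch(g8@rho^2, g8), 4L)
    expect_equal(momentMagnitudes(f2)[i00], 0.5, tolerance = 1e-3)

    ## real input: |M(n,l)| = |M(-n,-l)|
    set.seed(2)
    fr <- pcetMoments(gridPatch(runif(length(g8@rho)), g8), 4L)
    M <- fr@moments
    expect_equal(Mod(M), Mod(M[9:1, 9:1]), tolerance = 1e-9,
        ignore_attr = TRUE)

    expect_error(pcetMoments(gridPatch(numeric(0))))
})

test_that("the basis is orthonormal under the disc quadrature", {
    g <- polarGrid(64, 128)
    idx <- dmriTemplate:::.pcetIndex(4L)
    H <- sapply(seq_len(nrow(idx)), function(j)
        pcetBasis(idx[j, "n"], idx[j, "l"], g@rho, g@theta))
    gram <- t(Conj(H)) %*% (g@weights * H)
    expect_equal(gram, diag(nrow(idx)) + 0i, tolerance = 1e-9)
})

test_that("feature distance is a squared Euclidean metric on magnitudes", {
    sch <- scheme20()
    p <- extractPatch(sch, 3L, alphaP = 40)
    set.seed(3)
    fa <- pcetMoments(resampleToPolarGrid(p, runif(20, 0, 150),
        shOrder = 4L), 4L)
    fb <- pcetMoments(resampleToPolarGrid(p, runif(20, 0, 150),
        shOrder = 4L), 4L)
    expect_equal(featureDistance(fa, fa), 0)
    expect_equal(featureDistance(fa, fb), featureDistance(fb, fa))
    ## brute-force loop oracle
    acc <- 0
    for (i in seq_along(momentMagnitudes(fa)))
        acc <- acc + (momentMagnitudes(fa)[i] - momentMagnitudes(fb)[i])^2
    expect_equal(featureDistance(fa, fb), acc, tolerance = 1e-12)
    fc <- pcetMoments(resampleToPolarGrid(p, runif(20), shOrder = 4L), 3L)
    expect_error(featureDistance(fa, fc), "order")
})

test_that("magnitudes are invariant to in-plane rotation of the patch", {
    ## evaluate a smooth in-plane signal on the grid, then on the grid
    ## rotated by arbitrary angles; the magnitudes must agree within 1%
    g <- polarGrid()
    sig <- function(rho, theta) 60 * exp(-2 * rho^2) *
        (1 + 0.8 * cos(theta) + 0.3 * sin(2 * theta))
    f0 <- momentMagnitudes(pcetMoments(gridPatch(sig(g@rho, g@theta)), 4L))
    for (delta in c(0.21, 1.0, 2.6)) {
        fr <- momentMagnitudes(pcetMoments(gridPatch(
            sig(g@rho, (g@theta + delta) %% (2 * pi))), 4L))
        expect_lt(max(abs(fr - f0)) / max(f0), 0.01)
    }
    ## quadrature of the unit-modulus basis bounds each magnitude by max|S|
    expect_lt(max(f0), max(abs(sig(g@rho, g@theta))) + 1e-9)
})

test_that("the internal feature bank agrees with the public moment path", {
    sch <- scheme20()
    set.seed(4)
    sig <- runif(20, 0, 150)
    Phi <- dmriTemplate:::.patchFeatureOperator(sch, m = 4L, alphaP = 40,
        shOrder = 4L)
    bank <- dmriTemplate:::.featureBank(Phi, cbind(sig), 81L)
    for (k in c(1L, 11L)) {
        f <- pcetMoments(resampleToPolarGrid(extractPatch(sch, k,
            alphaP = 40), sig, shOrder = 4L), 4L)
        expect_equal(bank[, k, 1], momentMagnitudes(f), tolerance = 1e-9)
    }
    ## deduplicated bank preserves distances exactly
    PhiD <- dmriTemplate:::.patchFeatureOperator(sch, m = 4L, alphaP = 40,
        shOrder = 4L, dedup = TRUE)
    sig2 <- runif(20, 0, 150)
    bankD <- dmriTemplate:::.featureBank(PhiD, cbind(sig, sig2), 41L)
    bankF <- dmriTemplate:::.featureBank(Phi, cbind(sig, sig2), 81L)
    dF <- colSums((bankF[, , 1] - bankF[, , 2])^2)
    dD <- colSums((bankD[, , 1] - bankD[, , 2])^2)
    expect_equal(dD, dF, tolerance = 1e-9)
})
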