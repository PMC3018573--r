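test_that("the two-point estimator inverts the rational signal model exactly", {
    acq <- acquisitionParams()
    set.seed(11)
    pd <- runif(200, 0.5, 1.2)
    r1 <- runif(200, 0.2, 2)
    s1 <- rationalSignal(pd, r1, acq@alpha1, acq@tr1)
    s2 <- rationalSignal(pd, r1, acq@alpha2, acq@tr2)
    d <- c(10, 5, 4)
    S1 <- brainVolume(array(s1, dim = d)); S2 <- brainVolume(array(s2, dim = d))
    est <- volData(r1AppMap(S1, S2, acq)$r1app)
    expect_lt(max(abs(est - array(r1, dim = d)) / r1), 1e-12)
})

test_that("on full Ernst signals the estimator is accurate to 3% at protocol", {
    acq <- acquisitionParams()
    r1 <- seq(0.2, 2, by = 0.05)
    s1 <- ernstSignal(1, r1, acq@alpha1, acq@tr1)
    s2 <- ernstSignal(1, r1, acq@alpha2, acq@tr2)
    num <- 0.5 * (s2 * acq@alpha2 / acq@tr2 - s1 * acq@alpha1 / acq@tr1)
    den <- s1 / acq@alpha1 - s2 / acq@alpha2
    est <- num / den
    expect_lt(max(abs(est - r1) / r1), 0.03)
    # frozen spot value at R1 = 1/s: small underestimate from the
    # small-angle approximation
    expect_equal(est[which.min(abs(r1 - 1))], 0.989586, tolerance = 1e-5)
})

test_that("receive-coil scaling cancels in the estimator", {
    ds <- smallPhantom()
    acq <- acquisitionParams()
    a <- r1AppMap(ds$pdw, ds$t1w, acq)
    scale <- function(v, c) brainVolume(volData(v) * c, affine = volAffine(v))
    b <- r1AppMap(scale(ds$pdw, 3.7), scale(ds$t1w, 3.7), acq)
    expect_equal(volData(a$r1app), volData(b$r1app), tolerance = 1e-12)
    expect_identical(maskArray(a$valid), maskArray(b$valid))
})

test_that("invalid voxels are zeroed and flagged", {
    acq <- acquisitionParams()
    d <- c(4, 4, 4)
    s1 <- array(1, dim = d); s2 <- array(1, dim = d)
    # equal S/alpha ratios make the denominator vanish at one voxel
    s2[1] <- s1[1] * acq@alpha2 / acq@alpha1
    out <- r1AppMap(brainVolume(s1), brainVolume(s2), acq)
    expect_false(maskArray(out$valid)[1])
    expect_equal(volData(out$r1app)[1], 0)
})

test_that("measured-B1 correction applies the squared transmit ratio", {
    d <- c(4, 4, 4)
    r1 <- brainVolume(array(0.5, dim = d))
    psi <- brainVolume(array(1.2, dim = d))
    expect_equal(unique(as.vector(volData(correctWithB1(r1, psi)))), 0.72,
                 tolerance = 1e-12)
    one <- brainVolume(array(1, dim = d))
    expect_equal(volData(correctWithB1(r1, one)), volData(r1))
    expect_error(correctWithB1(r1, brainVolume(array(-1, dim = d))),
                 "positive")
})

test_that("correcting rational-model signals with true psi recovers truth", {
    spec <- smallSpec()
    geo <- makeGeometry(spec)
    psi <- makeB1Field(spec, geo$headMask)
    m <- maskArray(geo$headMask)
    acq <- acquisitionParams()
    r1t <- array(0, dim = spec@gridDims); r1t[m] <- 0.9
    pd <- array(0, dim = spec@gridDims); pd[m] <- 0.8
    mk <- function(alpha, tr) {
        s <- array(0, dim = spec@gridDims)
        s[m] <- rationalSignal(pd[m], r1t[m], volData(psi)[m] * alpha, tr)
        brainVolume(s, voxelSize = spec@voxelSize)
    }
    app <- r1AppMap(mk(acq@alpha1, acq@tr1), mk(acq@alpha2, acq@tr2), acq)
    rec <- correctWithB1(app$r1app, psi, geo$headMask)
    rel <- abs(volData(rec)[m] - r1t[m]) / r1t[m]
    expect_lt(max(rel), 1e-10)
})

test_that("histogram threshold isolates the head from the background mode", {
    # constructed case: background mode at 10, head block at 60 (60 > 5*10)
    d <- c(16, 16, 16)
    x <- array(10, dim = d)
    x[5:12, 5:12, 5:12] <- 60
    hm <- headMaskFromPDw(brainVolume(x), cleanup = FALSE)
    expect_identical(maskArray(hm), x == 60)

    expect_error(headMaskFromPDw(brainVolume(array(5, dim = d))),
                 "degenerate")
})

test_that("phantom head mask matches ground truth almost exactly", {
    ds <- refPhantom()
    hm <- headMaskFromPDw(ds$pdw)
    m <- maskArray(ds$truth@headMask)
    dice <- 2 * sum(maskArray(hm) & m) / (sum(maskArray(hm)) + sum(m))
    expect_gt(dice, 0.98)
})

test_that("largest-component cleanup removes disconnected islands", {
    d <- c(16, 16, 16)
    x <- array(10, dim = d)
    x[4:12, 4:12, 4:12] <- 60
    x[15, 15, 15] <- 60              # isolated bright voxel
    hm <- headMaskFromPDw(brainVolume(x), cleanup = TRUE)
    expect_false(maskArray(hm)[15, 15, 15])
    expect_true(all(maskArray(hm)[4:12, 4:12, 4:12]))
})

test_that("acquisition parameters convert console units and validate", {
    acq <- acquisitionParams(c(6, 20), c(23.7, 18.7))
    expect_equal(acq@alpha1, 6 * pi / 180)
    expect_equal(acq@tr2, 0.0187)
    acq2 <- acquisitionParams(c(0.2, 0.4), c(0.02, 0.02),
                              degrees = FALSE, milliseconds = FALSE)
    expect_equal(acq2@alpha2, 0.4)
    expect_error(acquisitionParams(c(6, 6), c(20, 20)), "differ")
    expect_error(acquisitionParams(c(-6, 20), c(23.7, 18.7)), "between")
})
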