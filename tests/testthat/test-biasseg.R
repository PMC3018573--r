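test_that("basis counts follow the smoothness cutoff rule", {
    # full 64^3 box at 3 mm: 192 mm extent -> floor(2*192/60)+1 = 7
    m <- headMask(array(TRUE, dim = c(64, 64, 64)))
    b <- buildCosineBasis(m, 3, 60)
    expect_equal(b@nBasis, rep(7L, 3))
    # fwhm beyond twice the extent: constant field only
    b1 <- buildCosineBasis(m, 3, 2 * 192 + 1)
    expect_equal(b1@nBasis, rep(1L, 3))
    # the bounding box tracks the mask, not the lattice
    m2arr <- array(FALSE, dim = c(64, 64, 64))
    m2arr[1:32, 1:64, 1:64] <- TRUE      # 96 mm extent along x
    b2 <- buildCosineBasis(headMask(m2arr), 3, 60)
    expect_equal(b2@nBasis[1], 4L)       # floor(2*96/60)+1
    expect_error(buildCosineBasis(m, 3, -1), "fwhm")
})

test_that("per-axis basis functions are orthogonal on the full grid", {
    m <- headMask(array(TRUE, dim = c(48, 40, 36)))
    b <- buildCosineBasis(m, 3, 40)
    for (a in 1:3) {
        G <- crossprod(b@B[[a]])
        off <- G - diag(diag(G))
        expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
    }
})

test_that("a zero-coefficient bias model is the identity field", {
    m <- headMask(array(TRUE, dim = c(24, 24, 24)))
    bm <- biasModel(buildCosineBasis(m, 3, 60))
    expect_true(all(evalBias(bm) == 1))
    expect_equal(bendingEnergy(bm), 0)
})

test_that("bending energy is a quadratic form vanishing on constants", {
    m <- headMask(array(TRUE, dim = c(24, 24, 24)))
    basis <- buildCosineBasis(m, 3, 40)
    co <- array(0, dim = basis@nBasis)
    co[1, 1, 1] <- 2.5                 # constant log-bias has no curvature
    expect_equal(bendingEnergy(biasModel(basis, co)), 0)
    set.seed(3)
    co <- array(rnorm(prod(basis@nBasis)), dim = basis@nBasis)
    e1 <- bendingEnergy(biasModel(basis, co))
    e2 <- bendingEnergy(biasModel(basis, 2 * co))
    expect_gt(e1, 0)
    expect_equal(e2, 4 * e1, tolerance = 1e-12)
})

test_that("quantile initialization is deterministic and brackets clusters", {
    set.seed(21)
    vals <- c(rnorm(2000, 0.3, 0.02), rnorm(2000, 0.8, 0.03),
              rnorm(2000, 1.2, 0.03))
    mixA <- initMixture(vals)
    mixB <- initMixture(vals)
    expect_identical(mixA@mean, mixB@mean)
    expect_lt(min(mixA@mean), 0.35)     # a component near the CSF cluster
    expect_gt(max(mixA@mean), 1.1)      # one near the WM cluster
    expect_true(any(mixA@mean > 0.6 & mixA@mean < 1.0))
    expect_equal(sum(mixA@weight), 1)
    expect_error(initMixture(rep(1, 2000)), "degenerate")
    expect_error(initMixture(rnorm(500)), "1000")
})

test_that("mixture validity enforces ordering, weights and variances", {
    expect_error(tissueMixture(c(1, 0.5), c(0.1, 0.1), c(0.5, 0.5),
                               c("GM", "GM")), NA)  # constructor sorts
    expect_error(new("TissueMixture", mean = c(1, 0.5), var = c(0.1, 0.1),
                     weight = c(0.5, 0.5), classes = c("GM", "GM")),
                 "ordered")
    expect_error(tissueMixture(1, -0.1, 1, "WM"), "positive")
})

test_that("fit on an unbiased phantom finds an essentially flat field", {
    ds <- generatePhantom(smallSpec(b1PeakDeviation = 0))
    fit <- runUnicort(ds$pdw, ds$t1w, acquisitionParams())
    m <- maskArray(fit@headMask)
    expect_lt(median(abs(volData(fit@eta)[m] - 1)), 0.02)
})

test_that("heavy regularization forces the field to a constant", {
    ds <- smallPhantom()
    hm <- headMaskFromPDw(ds$pdw)
    app <- r1AppMap(ds$pdw, ds$t1w, acquisitionParams())
    fit <- fitBiasField(app$r1app,
                        headMask(maskArray(hm) & maskArray(app$valid)),
                        kappa = 1e3)
    eta <- evalBias(fit@bias)[fit@maskIdx]
    expect_lt(median(abs(eta - 1)), 0.01)
})

test_that("penalized objective is monotone and responsibilities proper", {
    fit <- smallFit()@fit
    tr <- fit@objectiveTrace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-1]))))
    r <- fit@responsibilities
    expect_true(all(r >= 0 & r <= 1))
    expect_lt(max(abs(rowSums(r) - 1)), 1e-8)
    expect_equal(ncol(r), 9L)           # 2+2+2 brain + 3 non-brain
})

test_that("fitted log-bias tracks the true field on the coarse phantom", {
    fit <- smallFit()
    ds <- smallPhantom()
    m <- maskArray(fit@headMask)
    etaTrue <- 1 / volData(ds$truth@psiTrue)^2
    expect_gt(cor(log(volData(fit@eta)[m]), log(etaTrue[m])), 0.95)
})

test_that("intensity rescaling moves the mixture, not the bias field", {
    ds <- smallPhantom()
    hm <- headMaskFromPDw(ds$pdw)
    app <- r1AppMap(ds$pdw, ds$t1w, acquisitionParams())
    fmask <- headMask(maskArray(hm) & maskArray(app$valid))
    fitA <- fitBiasField(app$r1app, fmask, maxIter = 6L)
    scaled <- brainVolume(volData(app$r1app) * 3,
                          affine = volAffine(app$r1app))
    fitB <- fitBiasField(scaled, fmask, maxIter = 6L)
    expect_equal(fitB@mixture@mean, 3 * fitA@mixture@mean, tolerance = 1e-6)
    expect_equal(evalBias(fitB@bias), evalBias(fitA@bias), tolerance = 1e-6)
})

test_that("single-coefficient fit agrees with exhaustive search (1D toy)", {
    # 1D lattice, two well-separated classes, one cosine bias coefficient
    n <- 2000L
    vox <- 1
    cTrue <- 0.15
    t <- (seq_len(n) - 0.5) / n
    phi1 <- sqrt(2) * cos(pi * t)
    set.seed(5)
    mu <- sample(c(0.7, 1.3), n, replace = TRUE)
    y <- mu * exp(cTrue * phi1)           # biased observations
    vol <- brainVolume(array(y, dim = c(n, 1, 1)), voxelSize = vox)
    mask <- headMask(array(TRUE, dim = c(n, 1, 1)))
    fwhm <- 1.5 * n * vox                  # admits constant + one cosine
    kappa <- 1e-3
    nPer <- c(GM = 1L, WM = 1L, CSF = 1L, other = 1L)
    fit <- fitBiasField(vol, mask, fwhm = fwhm, kappa = kappa,
                        nPerClass = nPer, calibrate = FALSE)
    expect_equal(length(fit@bias@coeffs), 2L)
    cHat <- fit@bias@coeffs[2]

    # oracle: profile the penalized objective over a grid of the cosine
    # coefficient, running plain EM (no bias updates) at each grid point
    basis <- buildCosineBasis(mask, vox, fwhm)
    R1 <- bendingDiag(basis)[2]
    lambda <- kappa * n
    grid <- seq(-0.3, 0.3, by = 0.01)
    objAt <- function(cc) {
        u <- cc * phi1
        z <- y * exp(-u)
        mix <- initMixture(z, nPer)
        ll <- -Inf
        for (i in 1:200) {
            es <- unicort:::.eStep(z, mix)
            mix <- unicort:::.mStep(z, es$resp, mix, 1e-6 * var(z))
            if (es$loglik - ll < 1e-8 * max(1, abs(es$loglik))) break
            ll <- es$loglik
        }
        unicort:::.mixLogLik(z, mix) - sum(u) - lambda * R1 * cc^2
    }
    best <- grid[which.max(vapply(grid, objAt, numeric(1)))]
    expect_lt(abs(cHat - best), 0.01 + 1e-9)
})
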