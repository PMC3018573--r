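test_that("head geometry contains all four tissue classes in sane amounts", {
    geo <- makeGeometry(phantomSpec())
    m <- maskArray(geo$headMask)
    cls <- sort(unique(geo$labels[m]))
    expect_equal(cls, 1:4)
    frac <- tabulate(geo$labels[m], 4) / sum(m)
    expect_true(all(frac >= 0.01))
    # frozen reference composition of the default normal head
    expect_equal(frac, c(0.311588, 0.238040, 0.131536, 0.318836),
                 tolerance = 1e-4)
    # background carries no label
    expect_true(all(geo$labels[!m] == 0L))
})

test_that("enlarged-ventricle preset adds CSF; cyst preset adds one pocket", {
    nrm <- makeGeometry(phantomSpec())
    env <- makeGeometry(phantomSpec(geometry = "enlarged_ventricles"))
    cys <- makeGeometry(phantomSpec(geometry = "cyst"))
    csf <- function(g) sum(g$labels == 3L)
    expect_gt(csf(env), csf(nrm))
    expect_gt(csf(cys), csf(nrm))
    # identical spec => identical labels (pure function)
    nrm2 <- makeGeometry(phantomSpec())
    expect_identical(nrm$labels, nrm2$labels)
})

test_that("transmit field has unit head mean, bounded deviation, zero case", {
    for (preset in c("normal", "enlarged_ventricles", "cyst")) {
        spec <- phantomSpec(geometry = preset)
        geo <- makeGeometry(spec)
        psi <- volData(makeB1Field(spec, geo$headMask))
        m <- maskArray(geo$headMask)
        expect_equal(mean(psi[m]), 1, tolerance = 1e-6)
        expect_lte(max(abs(psi[m] - 1)), spec@b1PeakDeviation + 0.02)
    }
    spec <- phantomSpec()
    geo <- makeGeometry(spec)
    psi <- volData(makeB1Field(spec, geo$headMask))
    m <- maskArray(geo$headMask)
    # the default field reaches a substantial but sub-peak deviation
    expect_gte(max(abs(psi[m] - 1)), 0.20)
    expect_lte(max(abs(psi[m] - 1)), 0.27)
    # zero-amplitude case: a perfectly homogeneous transmit field
    flat <- makeB1Field(phantomSpec(b1PeakDeviation = 0), geo$headMask)
    expect_true(all(volData(flat) == 1))
})

test_that("Ernst signal matches the closed form and its limits", {
    expect_equal(ernstSignal(1, 1, 0, 0.0237), 0)
    expect_equal(ernstSignal(1, 1, 6 * pi / 180, 0.0237), 0.08509211,
                 tolerance = 1e-6)
    expect_equal(ernstSignal(1, 1, 20 * pi / 180, 0.0187), 0.08153171,
                 tolerance = 1e-6)
    expect_error(ernstSignal(1, -1, 0.1, 0.02), "positive")
    expect_error(ernstSignal(1, 1, 1.6, 0.02), "flip")
})

test_that("rational approximation is close to Ernst at the protocol", {
    for (a in c(6, 20)) {
        tr <- if (a == 6) 0.0237 else 0.0187
        al <- a * pi / 180
        rel <- abs(rationalSignal(1, 1, al, tr) - ernstSignal(1, 1, al, tr)) /
            ernstSignal(1, 1, al, tr)
        expect_lt(rel, 0.03)
    }
    expect_equal(rationalSignal(1, 1, 0, 0.02), 0)
    # linear in proton density
    expect_equal(rationalSignal(2, 0.8, 0.1, 0.02),
                 2 * rationalSignal(1, 0.8, 0.1, 0.02))
})

test_that("phantom generation is a pure, seeded function of its spec", {
    spec <- phantomSpec(gridDims = c(24, 24, 24), noiseSNR = 50)
    a <- generatePhantom(spec)
    b <- generatePhantom(spec)
    expect_identical(volData(a$pdw), volData(b$pdw))
    expect_identical(volData(a$t1w), volData(b$t1w))
    # a different seed changes the noise
    c2 <- generatePhantom(phantomSpec(gridDims = c(24, 24, 24),
                                      noiseSNR = 50, seed = 7L))
    expect_false(identical(volData(a$pdw), volData(c2$pdw)))
})

test_that("noise level matches the requested SNR in the background", {
    spec <- phantomSpec(noiseSNR = 50)
    ds <- generatePhantom(spec)
    m <- maskArray(ds$truth@headMask)
    # noiseless signal means over the head set sigma per volume
    clean <- generatePhantom(phantomSpec())
    for (nm in c("pdw", "t1w")) {
        sigma <- mean(volData(clean[[nm]])[m]) / 50
        expect_equal(sd(volData(ds[[nm]])[!m]), sigma, tolerance = 0.1)
    }
})

test_that("noiseless signals are positive in the head and zero outside", {
    ds <- refPhantom()
    m <- maskArray(ds$truth@headMask)
    expect_true(all(volData(ds$pdw)[m] > 0))
    expect_true(all(volData(ds$t1w)[m] > 0))
    expect_true(all(volData(ds$pdw)[!m] == 0))
})

test_that("with a homogeneous transmit field the VFA estimate recovers truth", {
    ds <- generatePhantom(smallSpec(b1PeakDeviation = 0))
    app <- r1AppMap(ds$pdw, ds$t1w, acquisitionParams())
    m <- maskArray(ds$truth@headMask)
    rel <- abs(volData(app$r1app)[m] - volData(ds$truth@r1True)[m]) /
        volData(ds$truth@r1True)[m]
    expect_lt(max(rel), 0.03)
})

test_that("ground truth psi has unit head mean for the reference dataset", {
    tr <- refPhantom()$truth
    m <- maskArray(tr@headMask)
    expect_equal(mean(volData(tr@psiTrue)[m]), 1, tolerance = 1e-6)
    expect_true(all(volData(tr@r1True)[m] > 0))
})

test_that("phantom directory export writes all volumes plus a spec sidecar", {
    dir <- withr::local_tempdir()
    spec <- phantomSpec(gridDims = c(24, 24, 24))
    ds <- generatePhantom(spec)
    writePhantom(ds, spec, dir)
    expect_true(all(file.exists(file.path(dir,
        c("pdw.nii.gz", "t1w.nii.gz", "r1_true.nii.gz", "psi_true.nii.gz",
          "mask.nii.gz", "phantom.json")))))
    side <- jsonlite::read_json(file.path(dir, "phantom.json"),
                                simplifyVector = TRUE)
    expect_equal(side$geometry, "normal")
    expect_equal(side$seed, 42L)
})
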