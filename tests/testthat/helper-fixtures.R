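# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code; the expensive pipeline runs are reused across files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (!exists(name, envir = .fx, inherits = FALSE))
        assign(name, build(), envir = .fx)
    get(name, envir = .fx, inherits = FALSE)
}

# The reference validation phantom: 64^3 at 3 mm, normal anatomy, 25% peak
# central transmit deviation plus 5% tilt, noiseless, seed 42.
refPhantom <- function() fixture("refPhantom", function()
    generatePhantom(phantomSpec()))

# Default full pipeline run on the reference phantom.
refFit <- function() fixture("refFit", function() {
    ds <- refPhantom()
    runUnicort(ds$pdw, ds$t1w, acquisitionParams())
})

# A coarser phantom for quick unit tests of the fit machinery: same 192 mm
# field of view at 4.8 mm voxels.
smallSpec <- function(...) phantomSpec(gridDims = c(40L, 40L, 40L),
                                       voxelSize = 4.8, ...)

smallPhantom <- function() fixture("smallPhantom", function()
    generatePhantom(smallSpec()))

smallFit <- function() fixture("smallFit", function() {
    ds <- smallPhantom()
    runUnicort(ds$pdw, ds$t1w, acquisitionParams())
})

# Deviation summaries of a pipeline run against phantom ground truth.
deviationSummary <- function(fit, truth) {
    bm <- brainMask(fit)
    dPsi <- symmetricDeviation(fit@psiUnicort, truth@psiTrue,
                               fit@headMask, "D_B1")@medianPercent
    dR1 <- symmetricDeviation(fit@r1Unicort, truth@r1True,
                              bm, "D_unicort")@medianPercent
    dApp <- symmetricDeviation(fit@r1App, truth@r1True,
                               bm, "D_app")@medianPercent
    list(dPsi = dPsi, dR1 = dR1, dApp = dApp,
         reduction = (dApp - dR1) / dApp)
}
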