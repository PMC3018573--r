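#' @include fit-bias.R vfa.R
NULL

#' Transmit-ratio map from a bias field
#'
#' The multiplicative bias on apparent R1 and the transmit-field ratio are
#' algebraically linked: \eqn{\psi^2 = 1/\eta}, so \eqn{\psi = 1/\sqrt\eta}
#' voxel-wise.
#'
#' @param eta bias-field \linkS4class{BrainVolume} (positive where used).
#' @param mask optional \linkS4class{HeadMask}; outside it psi is set to 1.
#' @return psi as a \linkS4class{BrainVolume}.
#' @export
psiFromEta <- function(eta, mask = NULL) {
    stopifnot(is(eta, "BrainVolume"))
    e <- eta@data
    if (is.null(mask)) {
        if (any(e <= 0)) stop("eta must be positive", call. = FALSE)
        p <- 1 / sqrt(e)
    } else {
        checkSameGrid(eta, mask, "eta and mask")
        m <- mask@mask
        if (any(e[m] <= 0))
            stop("eta must be positive inside the mask", call. = FALSE)
        p <- array(1, dim = dim(e))
        p[m] <- 1 / sqrt(e[m])
    }
    brainVolume(p, affine = eta@affine, unit = "ratio")
}

#' Run the full transmit-bias correction pipeline
#'
#' End-to-end correction of a variable-flip-angle FLASH pair: builds the
#' head mask from the PDw image, computes the apparent R1 map, fits the
#' smooth multiplicative bias field eta with the Gaussian-mixture model
#' ([fitBiasField()]), and emits the corrected map
#' \eqn{R1_{corr} = R1_{app}/\eta} together with the intrinsic estimate of
#' the transmit-field ratio \eqn{\psi = 1/\sqrt\eta}.  The fit is
#' calibrated so that the mean of psi over the head mask is exactly 1
#' (scanner flip-angle calibration assumption).  Outside the mask, eta and
#' psi are 1 and R1 is 0.
#'
#' @param pdw,t1w PDw and T1w \linkS4class{BrainVolume}s, co-registered on
#'   the same lattice.
#' @param acq \linkS4class{AcquisitionParams} of the pair.
#' @param fwhm bias smoothness in mm (default 60).
#' @param kappa bias regularization constant (default 1e-3).  The defaults
#'   are the optimum found for 3 T brain data; both should be re-optimized
#'   for substantially different field strengths or coils.
#' @param mask optional pre-computed \linkS4class{HeadMask}; by default
#'   derived from the PDw image with [headMaskFromPDw()].
#' @param ... further arguments passed to [fitBiasField()].
#' @return a \linkS4class{UnicortFit}.
#' @examples
#' ds <- generatePhantom(phantomSpec(gridDims = c(32, 32, 32)))
#' fit <- runUnicort(ds$pdw, ds$t1w, acquisitionParams(), maxIter = 8)
#' fit
#' @export
runUnicort <- function(pdw, t1w, acq = acquisitionParams(), fwhm = 60,
                       kappa = 1e-3, mask = NULL, ...) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(mask)) mask <- headMaskFromPDw(pdw)
    checkSameGrid(pdw, mask, "PDw volume and mask")
    app <- r1AppMap(pdw, t1w, acq)
    fitMaskArr <- mask@mask & app$valid@mask
    if (!any(fitMaskArr))
        stop("no valid apparent-R1 voxels inside the head mask",
             call. = FALSE)
    fit <- fitBiasField(app$r1app, headMask(fitMaskArr), fwhm = fwhm,
                        kappa = kappa, ...)

    d <- dim(pdw)
    m <- mask@mask
    etaArr <- array(1, dim = d)
    etaFull <- evalBias(fit@bias)
    etaArr[m] <- etaFull[m]
    psiArr <- array(1, dim = d)
    psiArr[m] <- 1 / sqrt(etaArr[m])
    # the fit calibrates over its own (valid) voxels; re-anchor the scale so
    # the mean flip-angle ratio over the full head mask is exactly nominal
    s <- mean(psiArr[m])
    psiArr[m] <- psiArr[m] / s
    etaArr[m] <- etaArr[m] * s^2
    r1u <- array(0, dim = d)
    r1u[m] <- app$r1app@data[m] / etaArr[m]

    # per-class posterior volumes from the component responsibilities
    segs <- lapply(.tissueClasses, function(cl) {
        v <- array(0, dim = d)
        cols <- fit@mixture@classes == cl
        v[fit@maskIdx] <- rowSums(fit@responsibilities[, cols, drop = FALSE])
        brainVolume(v, affine = pdw@affine, unit = "probability")
    })
    names(segs) <- .tissueClasses

    report <- list(fwhm = fwhm, kappa = kappa,
                   nBasis = fit@bias@basis@nBasis,
                   nMaskVoxels = sum(m), nFitVoxels = length(fit@maskIdx),
                   nIter = fit@nIter, converged = fit@converged,
                   objective = utils::tail(fit@objectiveTrace, 1),
                   meanPsiMask = mean(psiArr[m]),
                   elapsedSeconds = proc.time()[["elapsed"]] - t0)
    new("UnicortFit",
        r1App = app$r1app,
        r1Unicort = brainVolume(r1u, affine = pdw@affine, unit = "1/s"),
        psiUnicort = brainVolume(psiArr, affine = pdw@affine, unit = "ratio"),
        eta = brainVolume(etaArr, affine = pdw@affine, unit = "ratio"),
        segmentations = segs, headMask = mask, validMask = app$valid,
        fit = fit, report = report)
}

setMethod("show", "UnicortFit", function(object) {
    r <- object@report
    cat(sprintf("UnicortFit: fwhm %g mm, kappa %.3g, %d head voxels\n",
                r$fwhm, r$kappa, r$nMaskVoxels))
    cat(sprintf("  %d iterations (%s), mean psi over mask %.6f\n",
                r$nIter, if (r$converged) "converged" else "not converged",
                r$meanPsiMask))
    m <- object@headMask@mask
    cat(sprintf("  R1 corrected, median over mask: %.4g 1/s; psi range [%.3f, %.3f]\n",
                stats::median(object@r1Unicort@data[m]),
                min(object@psiUnicort@data[m]),
                max(object@psiUnicort@data[m])))
})

#' Brain mask from a pipeline fit
#'
#' Whole-brain aggregation mask: voxels whose combined GM+WM+CSF posterior
#' exceeds 0.5, intersected with the head mask.  This is the mask over
#' which aggregate R1 deviation statistics are reported.
#'
#' @param fit a \linkS4class{UnicortFit}.
#' @param threshold posterior threshold (default 0.5).
#' @return a \linkS4class{HeadMask}.
#' @export
brainMask <- function(fit, threshold = 0.5) {
    stopifnot(is(fit, "UnicortFit"))
    p <- fit@segmentations$GM@data + fit@segmentations$WM@data +
        fit@segmentations$CSF@data
    headMask(p > threshold & fit@headMask@mask)
}

#' Write all pipeline outputs to a directory
#'
#' @param fit a \linkS4class{UnicortFit}.
#' @param dir output directory.
#' @param units \code{"s-1"} writes R1 maps in 1/s; \code{"ms"} writes
#'   T1 = 1000/R1 maps in milliseconds (0 outside the mask).
#' @param gzip write compressed NIfTI.
#' @return the directory, invisibly.
#' @export
writeUnicortFit <- function(fit, dir, units = c("s-1", "ms"), gzip = TRUE) {
    units <- match.arg(units)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".nii.gz" else ".nii"
    conv <- function(v) {
        if (units == "s-1") return(v)
        x <- v@data
        out <- array(0, dim = dim(x))
        nz <- x > 0
        out[nz] <- 1000 / x[nz]
        brainVolume(out, affine = v@affine, unit = "ms")
    }
    writeVolume(conv(fit@r1App), file.path(dir, paste0("r1_app", ext)))
    writeVolume(conv(fit@r1Unicort), file.path(dir, paste0("r1_unicort", ext)))
    writeVolume(fit@psiUnicort, file.path(dir, paste0("b1_unicort", ext)))
    writeVolume(fit@eta, file.path(dir, paste0("eta", ext)))
    for (cl in names(fit@segmentations))
        writeVolume(fit@segmentations[[cl]],
                    file.path(dir, paste0("seg_", tolower(cl), ext)))
    writeMask(fit@headMask, fit@r1App, file.path(dir, paste0("mask", ext)))
    rep <- fit@report
    rep$objectiveTrace <- fit@fit@objectiveTrace
    rep$mixtureMeans <- fit@fit@mixture@mean
    rep$mixtureVars <- fit@fit@mixture@var
    rep$mixtureWeights <- fit@fit@mixture@weight
    rep$mixtureClasses <- fit@fit@mixture@classes
    jsonlite::write_json(rep, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
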