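#' @include volume-io.R
NULL

#' Construct a PhantomSpec
#'
#' Defaults describe the reference validation phantom: a 64^3 lattice at
#' 3 mm (192 mm field of view), literature-typical 3 T tissue parameters,
#' a smooth transmit field with 25% peak central deviation plus a 5%
#' left-right tilt (unit mean over the head), and no noise.
#'
#' @param gridDims integer(3) lattice size, >= 16 per axis.
#' @param voxelSize isotropic voxel size in mm.
#' @param tissueR1 named per-class R1 in 1/s.
#' @param tissuePD named per-class relative proton density.
#' @param geometry \code{"normal"}, \code{"enlarged_ventricles"} or
#'   \code{"cyst"}.
#' @param b1PeakDeviation peak fractional deviation of psi at the head
#'   centre; transmit inhomogeneities of up to ~30% are typical at 3 T.
#' @param b1Asymmetry amplitude of the linear left-right tilt.
#' @param b1Sign +1 (default): psi > 1 centrally.
#' @param noiseSNR mean-head-signal SNR of the additive noise; 0 disables.
#' @param rician use Rician instead of additive Gaussian noise.
#' @param seed RNG seed for the noise draw.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(gridDims = c(32, 32, 32))
#' @export
phantomSpec <- function(gridDims = c(64L, 64L, 64L), voxelSize = 3,
                        tissueR1 = c(GM = 0.77, WM = 1.18, CSF = 0.25,
                                     other = 0.50),
                        tissuePD = c(GM = 0.80, WM = 0.70, CSF = 1.00,
                                     other = 0.90),
                        geometry = c("normal", "enlarged_ventricles", "cyst"),
                        b1PeakDeviation = 0.25, b1Asymmetry = 0.05,
                        b1Sign = 1, noiseSNR = 0, rician = FALSE,
                        seed = 42L) {
    new("PhantomSpec", gridDims = as.integer(gridDims),
        voxelSize = as.numeric(voxelSize), tissueR1 = tissueR1,
        tissuePD = tissuePD, geometry = match.arg(geometry),
        b1PeakDeviation = b1PeakDeviation, b1Asymmetry = b1Asymmetry,
        b1Sign = b1Sign, noiseSNR = noiseSNR, rician = rician,
        seed = as.integer(seed))
}

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PhantomSpec", function(x) rep(x@voxelSize, 3L))

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(paste0("PhantomSpec: %s, %dx%dx%d @ %g mm, ",
                       "B1 peak %.0f%% / tilt %.0f%%, SNR %g, seed %d\n"),
                object@geometry, object@gridDims[1], object@gridDims[2],
                object@gridDims[3], object@voxelSize,
                100 * object@b1PeakDeviation, 100 * object@b1Asymmetry,
                object@noiseSNR, object@seed))
})

# World-coordinate grids (mm) centred on the lattice, per axis.
.axisCoords <- function(spec) {
    d <- spec@gridDims
    h <- spec@voxelSize
    lapply(1:3, function(a) (seq_len(d[a]) - (d[a] + 1) / 2) * h)
}

# Normalized squared ellipsoidal radius for semi-axes `ax` (mm) and centre
# `ctr` (mm): 1 on the ellipsoid surface.
.ellipseRho2 <- function(coords, ax, ctr = c(0, 0, 0)) {
    x1 <- (coords[[1]] - ctr[1]) / ax[1]
    x2 <- (coords[[2]] - ctr[2]) / ax[2]
    x3 <- (coords[[3]] - ctr[3]) / ax[3]
    d <- c(length(x1), length(x2), length(x3))
    outer(outer(x1^2, x2^2, "+"), x3^2, "+")
}

# Head semi-axes scale with the field of view so the head fills ~80% of it.
.headSemiAxes <- function(spec) {
    fov <- spec@gridDims * spec@voxelSize
    c(0.39, 0.46, 0.42) * fov
}

#' Build the phantom tissue geometry
#'
#' Nested-ellipsoid head: an outer non-brain shell (scalp/skull, class
#' \code{other}), a CSF layer, a cortical GM shell and a WM core.  The
#' \code{enlarged_ventricles} preset adds two central CSF lobes inside the
#' WM core; the \code{cyst} preset adds one off-centre CSF sphere.  Every
#' class occupies at least 1% of the head.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{labels} (integer array: 0 background, 1 GM,
#'   2 WM, 3 CSF, 4 other) and \code{headMask} (\linkS4class{HeadMask}).
#' @export
makeGeometry <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    coords <- .axisCoords(spec)
    ax <- .headSemiAxes(spec)
    if (any(ax < 4 * spec@voxelSize))
        stop("grid too small to fit the nested head shells", call. = FALSE)
    rho2 <- .ellipseRho2(coords, ax)
    labels <- array(0L, dim = spec@gridDims)
    # shells by scaled ellipsoids (fractions of the head semi-axes)
    labels[rho2 <= 1] <- 4L                     # other: scalp/skull shell
    labels[rho2 <= 0.88^2] <- 3L                # CSF layer
    labels[rho2 <= 0.82^2] <- 1L                # GM cortex
    labels[rho2 <= 0.62^2] <- 2L                # WM core
    if (spec@geometry == "enlarged_ventricles") {
        vax <- c(0.14, 0.30, 0.16) * ax
        for (s in c(-1, 1)) {
            ctr <- c(s * 0.22 * ax[1], 0.05 * ax[2], 0.05 * ax[3])
            v2 <- .ellipseRho2(coords, vax, ctr)
            labels[v2 <= 1 & labels == 2L] <- 3L
        }
    } else if (spec@geometry == "cyst") {
        r <- 0.21 * min(ax)
        ctr <- c(0.28, -0.32, -0.22) * ax
        c2 <- .ellipseRho2(coords, rep(r, 3), ctr)
        labels[c2 <= 1 & labels != 0L] <- 3L
    }
    head <- labels > 0L
    frac <- tabulate(labels[head], nbins = 4L) / sum(head)
    if (any(frac < 0.01))
        stop("degenerate geometry: a tissue class occupies < 1% of the head",
             call. = FALSE)
    list(labels = labels, headMask = headMask(head))
}

#' Parametric transmit-field (B1+) inhomogeneity
#'
#' Smooth ratio field psi(x) of local over nominal flip angle: a centred
#' Gaussian-shaped bump (central brightening, the dominant dielectric
#' standing-wave pattern at 3 T) plus a normalized left-right linear tilt
#' reproducing the typical asymmetric component.  Both terms have zero mean
#' over the head; the field is rescaled so its head mean is exactly 1,
#' matching the scanner calibration assumption that the mean flip angle
#' equals the nominal one.  With \code{b1PeakDeviation = 0} the field is
#' identically 1.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param mask the phantom \linkS4class{HeadMask}.
#' @return psi as a \linkS4class{BrainVolume} (1 outside the head).
#' @export
makeB1Field <- function(spec, mask) {
    stopifnot(is(spec, "PhantomSpec"), is(mask, "HeadMask"))
    psi <- array(1, dim = spec@gridDims)
    a <- spec@b1PeakDeviation
    if (a == 0)
        return(brainVolume(psi, voxelSize = spec@voxelSize, unit = "ratio"))
    m <- mask@mask
    coords <- .axisCoords(spec)
    ax <- .headSemiAxes(spec)
    rho2 <- .ellipseRho2(coords, ax)
    # central bump: Gaussian in the normalized ellipsoidal radius
    G <- exp(-rho2 / (2 * 0.45^2))
    Gm <- G - mean(G[m])
    Ghat <- Gm / max(Gm[m])                     # peak +1 at centre, mean 0
    # left-right tilt, mean 0, normalized to max |.| = 1 over the head
    x1 <- coords[[1]]
    Tf <- array(rep(x1, times = prod(spec@gridDims[2:3])),
                dim = spec@gridDims)
    Tm <- Tf - mean(Tf[m])
    That <- Tm / max(abs(Tm[m]))
    dev <- spec@b1Sign * (a * Ghat + spec@b1Asymmetry * That)
    field <- 1 + dev
    if (min(field[m]) <= 0)
        stop("B1 deviation too large: non-positive psi", call. = FALSE)
    field <- field / mean(field[m])             # exact unit head mean
    psi[m] <- field[m]
    brainVolume(psi, voxelSize = spec@voxelSize, unit = "ratio")
}

#' Steady-state spoiled gradient-echo (FLASH) signal
#'
#' The Ernst equation for a perfectly spoiled gradient echo:
#' \deqn{S = PD \sin\alpha \, (1 - E) / (1 - \cos\alpha \, E), \quad
#'       E = e^{-TR \cdot R1}.}
#'
#' @param pd relative proton density (spin density times receive
#'   sensitivity; arbitrary units).
#' @param r1 longitudinal relaxation rate, 1/s (> 0).
#' @param alphaLocal local flip angle in radians, in (0, pi/2); pass
#'   \code{psi * alphaNominal} to include transmit inhomogeneity.
#' @param tr repetition time in seconds (> 0).
#' @return signal amplitude (same units as \code{pd}); vectorized.
#' @examples
#' ernstSignal(1, 1, 6 * pi / 180, 0.0237)
#' @export
ernstSignal <- function(pd, r1, alphaLocal, tr) {
    if (any(r1 <= 0)) stop("r1 must be positive", call. = FALSE)
    if (any(alphaLocal < 0) || any(alphaLocal >= pi / 2))
        stop("local flip angle must lie in [0, pi/2)", call. = FALSE)
    if (any(tr <= 0)) stop("tr must be positive", call. = FALSE)
    E <- exp(-tr * r1)
    pd * sin(alphaLocal) * (1 - E) / (1 - cos(alphaLocal) * E)
}

#' Rational small-angle approximation of the Ernst signal
#'
#' The short-TR, small-angle approximation
#' \deqn{S \approx PD \, \alpha \, TR \, R1 / (\alpha^2/2 + TR \, R1)}
#' that underlies the algebraic two-point R1 estimator
#' (see [r1AppMap()]); at the default protocol it deviates from the full
#' Ernst equation by well under 3%.
#'
#' @inheritParams ernstSignal
#' @return approximate signal amplitude; vectorized.
#' @export
rationalSignal <- function(pd, r1, alphaLocal, tr) {
    if (any(r1 <= 0)) stop("r1 must be positive", call. = FALSE)
    if (any(alphaLocal < 0) || any(alphaLocal >= pi / 2))
        stop("local flip angle must lie in [0, pi/2)", call. = FALSE)
    if (any(tr <= 0)) stop("tr must be positive", call. = FALSE)
    pd * alphaLocal * tr * r1 / (alphaLocal^2 / 2 + tr * r1)
}

#' Generate a synthetic variable-flip-angle dataset
#'
#' Builds the phantom geometry and transmit field, simulates the PDw and
#' T1w FLASH magnitude volumes under the Ernst equation with local flip
#' angles \code{psi * alpha}, and (optionally) adds seeded noise with
#' standard deviation \code{mean(head signal) / noiseSNR} per volume.  The
#' background outside the head carries noise only.  A pure function of the
#' spec: the same spec always yields bitwise-identical volumes.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param acq an \linkS4class{AcquisitionParams}; defaults to the package
#'   protocol (PDw TR 23.7 ms / 6 degrees, T1w 18.7 ms / 20 degrees).
#' @return list with \code{pdw}, \code{t1w} (\linkS4class{BrainVolume})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' ds <- generatePhantom(phantomSpec(gridDims = c(24, 24, 24)))
#' range(volData(ds$pdw))
#' @export
generatePhantom <- function(spec, acq = acquisitionParams()) {
    stopifnot(is(spec, "PhantomSpec"), is(acq, "AcquisitionParams"))
    geo <- makeGeometry(spec)
    m <- geo$headMask@mask
    psi <- makeB1Field(spec, geo$headMask)
    r1 <- array(0, dim = spec@gridDims)
    pd <- array(0, dim = spec@gridDims)
    cls <- geo$labels[m]
    r1[m] <- spec@tissueR1[.tissueClasses][cls]
    pd[m] <- spec@tissuePD[.tissueClasses][cls]
    sig <- function(alpha, tr) {
        s <- array(0, dim = spec@gridDims)
        s[m] <- ernstSignal(pd[m], r1[m], volData(psi)[m] * alpha, tr)
        s
    }
    s1 <- sig(acq@alpha1, acq@tr1)
    s2 <- sig(acq@alpha2, acq@tr2)
    if (spec@noiseSNR > 0) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(spec@seed)
        n <- prod(spec@gridDims)
        for (nm in c("s1", "s2")) {
            s <- get(nm)
            sigma <- mean(s[m]) / spec@noiseSNR
            if (spec@rician) {
                s <- sqrt((s + rnorm(n, sd = sigma))^2 +
                          rnorm(n, sd = sigma)^2)
            } else {
                s <- s + array(rnorm(n, sd = sigma), dim = spec@gridDims)
            }
            assign(nm, s)
        }
    }
    vs <- spec@voxelSize
    truth <- new("GroundTruth",
        r1True = brainVolume(r1, voxelSize = vs, unit = "1/s"),
        psiTrue = psi,
        pdTrue = brainVolume(pd, voxelSize = vs, unit = "a.u."),
        labels = geo$labels, headMask = geo$headMask)
    list(pdw = brainVolume(s1, voxelSize = vs, unit = "a.u."),
         t1w = brainVolume(s2, voxelSize = vs, unit = "a.u."),
         truth = truth)
}

#' Write a phantom dataset to a directory
#'
#' Writes \code{pdw}, \code{t1w}, \code{r1_true}, \code{psi_true} and
#' \code{mask} NIfTI volumes plus a JSON sidecar recording the spec.
#'
#' @param dataset output of [generatePhantom()].
#' @param spec the \linkS4class{PhantomSpec} used.
#' @param dir output directory (created if needed).
#' @param gzip write \code{.nii.gz} instead of \code{.nii}.
#' @return the directory, invisibly.
#' @export
writePhantom <- function(dataset, spec, dir, gzip = TRUE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".nii.gz" else ".nii"
    writeVolume(dataset$pdw, file.path(dir, paste0("pdw", ext)))
    writeVolume(dataset$t1w, file.path(dir, paste0("t1w", ext)))
    writeVolume(dataset$truth@r1True, file.path(dir, paste0("r1_true", ext)))
    writeVolume(dataset$truth@psiTrue, file.path(dir, paste0("psi_true", ext)))
    writeMask(dataset$truth@headMask, dataset$pdw,
              file.path(dir, paste0("mask", ext)))
    side <- list(gridDims = spec@gridDims, voxelSize = spec@voxelSize,
                 tissueR1 = as.list(spec@tissueR1),
                 tissuePD = as.list(spec@tissuePD),
                 geometry = spec@geometry,
                 b1PeakDeviation = spec@b1PeakDeviation,
                 b1Asymmetry = spec@b1Asymmetry, b1Sign = spec@b1Sign,
                 noiseSNR = spec@noiseSNR, seed = spec@seed)
    jsonlite::write_json(side, file.path(dir, "phantom.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
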