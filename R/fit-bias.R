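#' @include basis.R mixture.R
NULL

# Preconditioned conjugate gradients for the Gauss-Newton system.
# Hv: function returning H %*% v for a coefficient-shaped vector v.
.cgSolve <- function(Hv, b, Pdiag, tol = 1e-4, maxit = 120L) {
    x <- numeric(length(b))
    r <- b
    z <- r / Pdiag
    p <- z
    rz <- sum(r * z)
    bnorm <- sqrt(sum(b * b))
    if (bnorm == 0) return(x)
    for (i in seq_len(maxit)) {
        Ap <- Hv(p)
        pAp <- sum(p * Ap)
        if (pAp <= 0) break               # safeguard: leave with current x
        alpha <- rz / pAp
        x <- x + alpha * p
        r <- r - alpha * Ap
        if (sqrt(sum(r * r)) < tol * bnorm) break
        z <- r / Pdiag
        rzn <- sum(r * z)
        p <- z + (rzn / rz) * p
        rz <- rzn
    }
    x
}

#' Fit the multiplicative bias field on a masked apparent-R1 map
#'
#' Penalized maximum-likelihood estimation of a smooth multiplicative bias
#' field eta on the masked apparent R1 map, under a Gaussian-mixture tissue
#' model (GM/WM/CSF/other) with an exponential cosine-basis log-bias.  The
#' objective is
#' \deqn{\sum_i \Big[ \log \sum_k w_k \, N(\beta_i y_i; \mu_k, \sigma_k^2)
#'       + \log \beta_i \Big] - \lambda(\kappa)\, \Omega(c)}
#' with \eqn{y_i} the masked apparent-R1 value, \eqn{\beta_i = 1/\eta(x_i)}
#' the correction factor, \eqn{\Omega} the bending energy of the log-bias
#' and \eqn{\lambda = \kappa N_{vox}}.  Optimization alternates (a)
#' E-step responsibilities, (b) closed-form M-step for the Gaussian
#' parameters on bias-corrected data, and (c) a Gauss-Newton update of the
#' basis coefficients solved by preconditioned conjugate gradients with a
#' step-halving line search, so the objective never decreases.  After
#' convergence the constant coefficient is rescaled so that the implied
#' transmit-ratio map \eqn{\psi = 1/\sqrt{\eta}} has unit mean over the
#' mask (the scanner flip-angle calibration assumption); the mixture means
#' and variances are rescaled accordingly.
#'
#' @param r1App apparent R1 \linkS4class{BrainVolume} (1/s).
#' @param mask \linkS4class{HeadMask} of voxels entering the likelihood
#'   (head mask intersected with the validity mask of [r1AppMap()]).
#' @param fwhm bias smoothness in mm; sets the cosine-basis cutoff
#'   (default 60).
#' @param kappa dimensionless regularization constant scaling the bending
#'   penalty (default 1e-3).
#' @param nPerClass Gaussian components per tissue class.
#' @param maxIter,tol outer-iteration cap and relative objective-change
#'   tolerance.
#' @param nInner maximum mixture EM sweeps per outer iteration (the sweep
#'   loop exits early once the mixture log-likelihood stalls).
#' @param calibrate apply the unit-mean-psi calibration after convergence.
#' @param verbose log per-iteration objectives to stderr.
#' @return a \linkS4class{BiasFit}.
#' @seealso [runUnicort()] for the full pipeline.
#' @export
fitBiasField <- function(r1App, mask, fwhm = 60, kappa = 1e-3,
                         nPerClass = c(GM = 2L, WM = 2L, CSF = 2L,
                                       other = 3L),
                         maxIter = 64L, tol = 1e-5, nInner = 16L,
                         calibrate = TRUE, verbose = FALSE) {
    stopifnot(is(r1App, "BrainVolume"), is(mask, "HeadMask"))
    checkSameGrid(r1App, mask, "R1 volume and mask")
    if (!any(mask@mask)) stop("empty mask", call. = FALSE)
    maskIdx <- which(mask@mask)
    y <- r1App@data[maskIdx]
    if (!all(is.finite(y)))
        stop("non-finite apparent-R1 values inside the mask", call. = FALSE)
    nvox <- length(y)

    basis <- buildCosineBasis(mask, voxelSize(r1App), fwhm)
    Rdiag <- as.vector(bendingDiag(basis))
    lambda <- kappa * nvox
    cvec <- numeric(prod(basis@nBasis))

    maskBox <- fullToBbox(basis, mask@mask)
    inBox <- which(maskBox)
    # column-major order of the mask is preserved when restricting to the
    # bounding box, so rows of everything below align with `maskIdx`
    yb <- fullToBbox(basis, r1App@data)[inBox]

    varFloor <- 1e-6 * stats::var(yb)
    mix <- initMixture(yb, nPerClass)

    uOf <- function(cv) dctSynthesize(basis, cv)[inBox]
    objective <- function(cv, mixm, u = NULL) {
        if (is.null(u)) u <- uOf(cv)
        z <- yb * exp(-u)
        .mixLogLik(z, mixm) - sum(u) - lambda * sum(Rdiag * cv^2)
    }

    ## one Gauss-Newton step at fixed mixture; returns the new coefficients
    ## and objective (never smaller than the current one)
    gnStep <- function(cvec, mix, objCur) {
        u <- uOf(cvec)
        z <- yb * exp(-u)
        es <- .eStep(z, mix)
        wm <- sweep(es$resp, 2, 1 / mix@var, `*`)       # r_ik / sigma_k^2
        gi <- z * (z * rowSums(wm) -
                   as.vector(wm %*% mix@mean)) - 1      # dL/du_i
        hi <- z^2 * rowSums(wm)                         # GN curvature
        dBox <- array(0, dim = basis@bboxDims); dBox[inBox] <- gi
        hBox <- array(0, dim = basis@bboxDims); hBox[inBox] <- hi
        grad <- as.vector(dctAnalyze(basis, dBox)) - 2 * lambda * Rdiag * cvec
        damp <- 1e-8 * max(hi) + 1e-12
        Hv <- function(v) {
            f <- dctSynthesize(basis, v)     # hBox is 0 outside the mask
            as.vector(dctAnalyze(basis, f * hBox)) +
                (2 * lambda * Rdiag + damp) * v
        }
        Pdiag <- as.vector(dctAnalyze(basis, hBox, squared = TRUE)) +
            2 * lambda * Rdiag + damp
        step <- .cgSolve(Hv, grad, Pdiag, tol = 2e-4, maxit = 48L)
        alpha <- 1
        for (h in 1:12) {
            cand <- cvec + alpha * step
            objNew <- objective(cand, mix)
            if (is.finite(objNew) && objNew >= objCur)
                return(list(cvec = cand, obj = objNew, accepted = TRUE))
            alpha <- alpha / 2
        }
        list(cvec = cvec, obj = objCur, accepted = FALSE)
    }

    trace <- numeric(0)
    obj <- objective(cvec, mix)
    converged <- FALSE
    iter <- 0L
    innerTol <- 0.1 * tol
    cPrev <- cvec
    for (iter in seq_len(maxIter)) {
        ## (a)+(b): mixture EM sweeps to (approximate) convergence at
        ## fixed bias; each sweep cannot decrease the objective
        z <- yb * exp(-uOf(cvec))
        llPrev <- -Inf
        for (s in seq_len(nInner)) {
            es <- .eStep(z, mix)
            mix <- .mStep(z, es$resp, mix, varFloor)
            if (es$loglik - llPrev <= innerTol * max(1, abs(es$loglik)))
                break
            llPrev <- es$loglik
        }
        objCur <- objective(cvec, mix)
        ## (c): Gauss-Newton bias updates at fixed mixture, repeated while
        ## they still improve the penalized objective appreciably
        for (s in seq_len(8L)) {
            res <- gnStep(cvec, mix, objCur)
            gain <- res$obj - objCur
            cvec <- res$cvec; objCur <- res$obj
            if (!res$accepted || gain <= innerTol * max(1, abs(objCur)))
                break
        }
        ## over-relaxation along the direction the coefficients moved this
        ## iteration; the coupled bias/variance updates otherwise approach
        ## the optimum in many small co-linear steps.  Only candidates that
        ## improve the penalized objective are accepted, so monotonicity is
        ## preserved.
        if (iter > 1L) {
            dir <- cvec - cPrev
            for (gamma in c(4, 2, 1)) {
                cand <- cvec + gamma * dir
                objNew <- objective(cand, mix)
                if (is.finite(objNew) && objNew > objCur) {
                    cvec <- cand; objCur <- objNew
                    break
                }
            }
        }
        cPrev <- cvec
        trace <- c(trace, objCur)
        uniMessage("iter %2d: objective %.8e", iter, objCur)
        if (iter > 1L && abs(objCur - obj) <= tol * max(1, abs(obj))) {
            converged <- TRUE
            obj <- objCur
            break
        }
        obj <- objCur
    }

    u <- uOf(cvec)
    if (calibrate) {
        # shift the constant coefficient so mean(1/sqrt(eta)) = 1 over the
        # mask, and move the mixture to the matching intensity scale
        delta <- 2 * log(mean(exp(-u / 2)))
        cvec[1] <- cvec[1] + delta
        u <- u + delta
        sc <- exp(-delta)
        mix <- new("TissueMixture", mean = mix@mean * sc,
                   var = mix@var * sc^2, weight = mix@weight,
                   classes = mix@classes)
    }
    z <- yb * exp(-u)
    es <- .eStep(z, mix)

    bm <- biasModel(basis, coeffs = array(cvec, dim = basis@nBasis),
                    kappa = kappa)
    new("BiasFit", bias = bm, mixture = mix, responsibilities = es$resp,
        maskIdx = as.integer(maskIdx), objectiveTrace = trace,
        converged = converged, nIter = iter)
}

setMethod("show", "BiasFit", function(object) {
    cat(sprintf("BiasFit: %d voxels, %dx%dx%d basis, kappa %.3g, %d iterations (%s)\n",
                length(object@maskIdx), object@bias@basis@nBasis[1],
                object@bias@basis@nBasis[2], object@bias@basis@nBasis[3],
                object@bias@kappa, object@nIter,
                if (object@converged) "converged" else "not converged"))
    eta <- evalBias(object@bias)[object@maskIdx]
    cat(sprintf("  eta over mask: median %.4g, range [%.4g, %.4g]\n",
                stats::median(eta), min(eta), max(eta)))
})
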