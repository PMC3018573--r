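#' @include volume-io.R
NULL

#' Construct acquisition parameters for the VFA pair
#'
#' Accepts the scanner-console convention (degrees and milliseconds) and
#' stores coherent units (radians, seconds), in which the two-point R1
#' estimator is dimensionally consistent.  Defaults are the 3 T protocol the
#' package is validated against: PDw TR 23.7 ms at 6 degrees, T1w TR
#' 18.7 ms at 20 degrees.
#'
#' @param flipAngles numeric(2), nominal flip angles (PDw, T1w).
#' @param tr numeric(2), repetition times (PDw, T1w).
#' @param degrees flip angles given in degrees (default) or radians.
#' @param milliseconds repetition times given in ms (default) or seconds.
#' @return an \linkS4class{AcquisitionParams}.
#' @examples
#' acq <- acquisitionParams()            # the default protocol
#' acq2 <- acquisitionParams(c(4, 25), c(20, 20))
#' @export
acquisitionParams <- function(flipAngles = c(6, 20), tr = c(23.7, 18.7),
                              degrees = TRUE, milliseconds = TRUE) {
    stopifnot(length(flipAngles) == 2L, length(tr) == 2L)
    a <- if (degrees) flipAngles * pi / 180 else flipAngles
    t <- if (milliseconds) tr / 1000 else tr
    new("AcquisitionParams", alpha1 = a[1], alpha2 = a[2],
        tr1 = t[1], tr2 = t[2])
}

setMethod("show", "AcquisitionParams", function(object) {
    cat(sprintf("AcquisitionParams: PDw %.3g deg / TR %.4g ms, T1w %.3g deg / TR %.4g ms\n",
                object@alpha1 * 180 / pi, object@tr1 * 1000,
                object@alpha2 * 180 / pi, object@tr2 * 1000))
})

#' Apparent R1 map from a variable-flip-angle FLASH pair
#'
#' Algebraic two-point estimator based on the rational (small-angle,
#' short-TR) approximation of the Ernst equation:
#' \deqn{R1_{app} = \frac{1}{2} \,
#'   \frac{S_2 \alpha_2 / TR_2 - S_1 \alpha_1 / TR_1}
#'        {S_1 / \alpha_1 - S_2 / \alpha_2}.}
#' Receive-coil sensitivity profiles cancel in the ratio, but transmit-field
#' inhomogeneity does not: with a local/nominal flip-angle ratio psi the
#' estimate is biased as \eqn{R1_{app} = R1 / \psi^2}.
#'
#' Voxels where the denominator is (near) zero or the estimate falls outside
#' the physiological range [0, 10] 1/s are set to 0 and flagged invalid;
#' noise can drive the algebraic estimator to arbitrarily large or negative
#' values and such voxels must not enter the bias fit.
#'
#' @param S1,S2 PDw and T1w \linkS4class{BrainVolume}s on the same grid.
#' @param acq \linkS4class{AcquisitionParams}.
#' @param r1Max upper clamp of the valid range, 1/s.
#' @return list with \code{r1app} (a \linkS4class{BrainVolume}, 1/s, zeros
#'   at invalid voxels) and \code{valid} (a \linkS4class{HeadMask} of voxels
#'   with a usable estimate).
#' @references the estimator inverts [rationalSignal()] exactly.
#' @export
r1AppMap <- function(S1, S2, acq, r1Max = 10) {
    stopifnot(is(S1, "BrainVolume"), is(S2, "BrainVolume"),
              is(acq, "AcquisitionParams"))
    validObject(acq)
    checkSameGrid(S1, S2, "PDw and T1w volumes")
    s1 <- S1@data; s2 <- S2@data
    a1 <- acq@alpha1; a2 <- acq@alpha2
    num <- 0.5 * (s2 * a2 / acq@tr2 - s1 * a1 / acq@tr1)
    den <- s1 / a1 - s2 / a2
    eps <- 1e-12 * max(abs(s1) / a1, abs(s2) / a2)
    ok <- is.finite(num) & is.finite(den) & abs(den) > eps
    r1 <- array(0, dim = dim(s1))
    r1[ok] <- num[ok] / den[ok]
    ok <- ok & r1 >= 0 & r1 <= r1Max & is.finite(r1)
    r1[!ok] <- 0
    list(r1app = brainVolume(r1, affine = S1@affine, unit = "1/s"),
         valid = headMask(ok))
}

#' Reference-standard correction with a measured B1+ map
#'
#' With a measured transmit-field ratio map psi, the apparent R1 is
#' corrected voxel-wise as \eqn{R1 = R1_{app} \, \psi^2}.
#'
#' @param r1App apparent R1 \linkS4class{BrainVolume}.
#' @param psi measured (or estimated) transmit-ratio \linkS4class{BrainVolume}.
#' @param mask optional \linkS4class{HeadMask}; psi must be positive inside
#'   it and the product is only applied there (0 outside).  With no mask the
#'   product is applied everywhere and psi must be positive everywhere.
#' @return corrected R1 \linkS4class{BrainVolume}.
#' @export
correctWithB1 <- function(r1App, psi, mask = NULL) {
    stopifnot(is(r1App, "BrainVolume"), is(psi, "BrainVolume"))
    checkSameGrid(r1App, psi, "R1 and psi volumes")
    if (is.null(mask)) {
        if (any(psi@data <= 0))
            stop("psi must be positive everywhere (or supply a mask)",
                 call. = FALSE)
        out <- r1App@data * psi@data^2
    } else {
        checkSameGrid(r1App, mask, "R1 volume and mask")
        m <- mask@mask
        if (any(psi@data[m] <= 0))
            stop("psi must be positive inside the mask", call. = FALSE)
        out <- array(0, dim = dim(r1App@data))
        out[m] <- r1App@data[m] * psi@data[m]^2
    }
    brainVolume(out, affine = r1App@affine, unit = r1App@unit)
}

#' Head mask from the PDw image
#'
#' Histogram-threshold head mask: the PDw intensities are binned into 256
#' equal-width bins spanning [0, max]; the threshold is five times the
#' centre of the modal bin, and the mask keeps voxels strictly above it.
#' For acquired data the modal bin is the background-noise peak, so the
#' threshold lands well below tissue; for noiseless synthetic data the
#' modal bin is the zero-background bin and the (tiny) threshold separates
#' background from head exactly.  Values below zero (possible with additive
#' noise) count towards the lowest bin.
#'
#' @param S1 PDw \linkS4class{BrainVolume}, non-negative up to noise and not
#'   constant.
#' @param cleanup keep only the largest 6-connected component (default
#'   \code{TRUE}); removes salt noise that clears the threshold.
#' @return a \linkS4class{HeadMask}.
#' @export
headMaskFromPDw <- function(S1, cleanup = TRUE) {
    stopifnot(is(S1, "BrainVolume"))
    x <- S1@data
    x <- x[is.finite(x)]
    mx <- max(x)
    if (mx <= 0 || diff(range(x)) == 0)
        stop("degenerate PDw intensity distribution: cannot find a mode",
             call. = FALSE)
    nb <- 256L
    w <- mx / nb
    binIdx <- pmin(pmax(floor(S1@data / w), 0), nb - 1)   # 0-based bins
    counts <- tabulate(binIdx[is.finite(binIdx)] + 1L, nbins = nb)
    modal <- which.max(counts)                             # 1-based
    thr <- 5 * (modal - 0.5) * w                           # 5 x modal centre
    m <- is.finite(S1@data) & S1@data > thr
    if (!any(m))
        stop("head mask is empty: threshold exceeds all intensities ",
             "(no background mode in the histogram?)", call. = FALSE)
    if (cleanup)
        m <- largestComponent(m)
    headMask(m)
}

# Largest 6-connected component of a logical 3D array.
largestComponent <- function(m) {
    idx <- which(m)
    if (length(idx) <= 1L) return(m)
    d <- dim(m)
    pos <- arrayInd(idx, d)
    lab <- integer(prod(d)); lab[idx] <- seq_along(idx)
    strides <- c(1L, d[1], d[1] * d[2])
    from <- integer(0); to <- integer(0)
    for (a in 1:3) {
        keep <- pos[, a] < d[a]
        nb <- idx[keep] + strides[a]
        has <- lab[nb] > 0L
        from <- c(from, lab[idx[keep][has]])
        to <- c(to, lab[nb[has]])
    }
    if (!length(from)) return(m)   # all voxels isolated: nothing to prune
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    if (igraph::vcount(g) < length(idx))
        g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
    comp <- igraph::components(g)
    out <- array(FALSE, dim = d)
    out[idx[comp$membership == which.max(comp$csize)]] <- TRUE
    out
}
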