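#' @include volume-io.R
NULL

#' Build the separable cosine basis for a bias field
#'
#' Constructs the low-frequency DCT-II-type tensor-product basis spanning
#' the bounding box of the head mask.  The per-axis count follows a
#' Nyquist-style rule tying the shortest representable period to the
#' requested bias smoothness: \code{n_k = max(1, floor(2 * L_k / fwhm) + 1)}
#' with \code{L_k} the bounding-box extent in mm along voxel axis \code{k}
#' (number of spanned voxels times the physical voxel spacing).  Larger
#' \code{fwhm} therefore means fewer, smoother basis functions; the first
#' function per axis is the constant 1.
#'
#' @param mask a \linkS4class{HeadMask} (non-empty).
#' @param voxelSize numeric(1) or numeric(3), physical spacing in mm along
#'   the voxel axes (affine column norms for oblique volumes).
#' @param fwhm bias smoothness in mm (> 0); \code{fwhm >= 2 L} yields a
#'   constant-only basis.
#' @return a \linkS4class{CosineBasis}.
#' @examples
#' m <- headMask(array(TRUE, dim = c(64, 64, 64)))
#' b <- buildCosineBasis(m, 3, 60)   # 192 mm box -> 7 functions per axis
#' b@nBasis
#' @export
buildCosineBasis <- function(mask, voxelSize, fwhm) {
    stopifnot(is(mask, "HeadMask"))
    if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
    if (!any(mask@mask)) stop("empty mask", call. = FALSE)
    vs <- rep_len(as.numeric(voxelSize), 3L)
    d <- dim(mask@mask)
    idx <- which(mask@mask)
    pos <- arrayInd(idx, d)
    lo <- apply(pos, 2, min)
    hi <- apply(pos, 2, max)
    nGrid <- hi - lo + 1L
    L <- nGrid * vs
    nB <- pmax(1L, as.integer(floor(2 * L / fwhm)) + 1L)
    B <- lapply(1:3, function(a) {
        t <- (seq_len(nGrid[a]) - 0.5) / nGrid[a]
        mat <- matrix(1, nrow = nGrid[a], ncol = nB[a])
        if (nB[a] > 1L)
            for (m in seq_len(nB[a] - 1L))
                mat[, m + 1L] <- sqrt(2) * cos(pi * m * t)
        mat
    })
    new("CosineBasis", B = B, nBasis = nB, bboxStart = as.integer(lo),
        bboxDims = as.integer(nGrid), gridDims = as.integer(d),
        spacing = vs, fwhm = as.numeric(fwhm))
}

setMethod("show", "CosineBasis", function(object) {
    cat(sprintf("CosineBasis: %dx%dx%d functions over a %sx%sx%s-voxel box, fwhm %g mm\n",
                object@nBasis[1], object@nBasis[2], object@nBasis[3],
                object@bboxDims[1], object@bboxDims[2], object@bboxDims[3],
                object@fwhm))
})

## Separable tensor transforms ---------------------------------------------

# Apply one basis matrix along mode `a` of a 3D array.
.modeProduct <- function(A, X, a) {
    d <- dim(X)
    if (a == 1L) {
        out <- A %*% matrix(X, d[1], d[2] * d[3])
        array(out, dim = c(nrow(A), d[2], d[3]))
    } else if (a == 2L) {
        Xp <- aperm(X, c(2, 1, 3))
        out <- A %*% matrix(Xp, d[2], d[1] * d[3])
        aperm(array(out, dim = c(nrow(A), d[1], d[3])), c(2, 1, 3))
    } else {
        out <- matrix(X, d[1] * d[2], d[3]) %*% t(A)
        array(out, dim = c(d[1], d[2], nrow(A)))
    }
}

# Coefficients (n1 x n2 x n3) -> field on the bounding-box grid.
dctSynthesize <- function(basis, coeffs) {
    X <- array(coeffs, dim = basis@nBasis)
    X <- .modeProduct(basis@B[[1]], X, 1L)
    X <- .modeProduct(basis@B[[2]], X, 2L)
    .modeProduct(basis@B[[3]], X, 3L)
}

# Adjoint: field-sized array on the bounding box -> coefficient array.
dctAnalyze <- function(basis, field, squared = FALSE) {
    Bs <- if (squared) lapply(basis@B, function(b) b^2) else basis@B
    X <- .modeProduct(t(Bs[[1]]), field, 1L)
    X <- .modeProduct(t(Bs[[2]]), X, 2L)
    .modeProduct(t(Bs[[3]]), X, 3L)
}

# Embed a bounding-box array into the full lattice (fill value outside).
bboxToFull <- function(basis, X, fill = 0) {
    out <- array(fill, dim = basis@gridDims)
    i <- lapply(1:3, function(a)
        seq.int(basis@bboxStart[a], length.out = basis@bboxDims[a]))
    out[i[[1]], i[[2]], i[[3]]] <- X
    out
}

# Extract the bounding-box region of a full-lattice array.
fullToBbox <- function(basis, X) {
    i <- lapply(1:3, function(a)
        seq.int(basis@bboxStart[a], length.out = basis@bboxDims[a]))
    X[i[[1]], i[[2]], i[[3]], drop = FALSE]
}

#' Construct a BiasModel
#'
#' @param basis a \linkS4class{CosineBasis}.
#' @param coeffs coefficient array (defaults to all zero, i.e. a flat
#'   field eta = 1).
#' @param kappa regularization constant associated with the model.
#' @return a \linkS4class{BiasModel}.
#' @export
biasModel <- function(basis, coeffs = NULL, kappa = NA_real_) {
    if (is.null(coeffs)) coeffs <- array(0, dim = basis@nBasis)
    new("BiasModel", coeffs = array(coeffs, dim = basis@nBasis),
        basis = basis, kappa = as.numeric(kappa))
}

#' @rdname evalBias
#' @export
setMethod("evalBias", "BiasModel", function(object) {
    u <- dctSynthesize(object@basis, object@coeffs)
    bboxToFull(object@basis, exp(u), fill = 1)
})

# Diagonal of the bending-energy quadratic form: the integral over the
# bounding box of the summed squared second derivatives of the log-bias
# u(x) = sum_k c_k phi_k(x).  With phi separable in cos(pi m t) the basis
# functions diagonalize the form, each contributing
# (w1^2 + w2^2 + w3^2)^2 * V with w_a = pi m_a / L_a and V the box volume.
# Lengths are measured in units of 100 mm (head scale), making the
# regularization constant kappa dimensionless.
bendingDiag <- function(basis) {
    L <- basis@bboxDims * basis@spacing / 100   # in 100-mm units
    w2 <- lapply(1:3, function(a) (pi * (seq_len(basis@nBasis[a]) - 1) / L[a])^2)
    s <- outer(outer(w2[[1]], w2[[2]], "+"), w2[[3]], "+")
    array(s^2 * prod(L), dim = basis@nBasis)
}

#' @rdname bendingEnergy
#' @export
setMethod("bendingEnergy", "BiasModel", function(object) {
    sum(bendingDiag(object@basis) * object@coeffs^2)
})
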