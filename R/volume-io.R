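#' @include AllGenerics.R
NULL

#' Construct a BrainVolume
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-world matrix (NIfTI convention, 0-based voxel
#'   indices).  If missing, a diagonal affine built from \code{voxelSize} is
#'   used, centred so that world coordinate 0 falls at the lattice centre.
#' @param voxelSize numeric(1) or numeric(3) voxel size in mm (used only
#'   when \code{affine} is missing).
#' @param unit free-text unit label.
#' @return a \linkS4class{BrainVolume}.
#' @examples
#' v <- brainVolume(array(1, dim = c(8, 8, 8)), voxelSize = 3)
#' voxelSize(v)
#' @export
brainVolume <- function(data, affine = NULL, voxelSize = c(1, 1, 1),
                        unit = "") {
    data <- as.array(data)
    if (length(dim(data)) != 3L)
        stop("data must be a 3D array", call. = FALSE)
    if (is.null(affine)) {
        vs <- rep_len(as.numeric(voxelSize), 3L)
        d <- dim(data)
        affine <- diag(c(vs, 1))
        # centre of the lattice at world 0
        affine[1:3, 4] <- -vs * (d - 1) / 2
    }
    new("BrainVolume", data = data, affine = unname(as.matrix(affine)),
        unit = as.character(unit))
}

#' @describeIn brainVolume construct a HeadMask from a logical array.
#' @param mask logical 3D array.
#' @export
headMask <- function(mask) {
    storage.mode(mask) <- "logical"
    new("HeadMask", mask = mask)
}

#' @rdname volData
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BrainVolume",
    function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname volAffine
#' @export
setMethod("volAffine", "BrainVolume", function(x) x@affine)

#' @rdname volUnit
#' @export
setMethod("volUnit", "BrainVolume", function(x) x@unit)

#' @rdname maskArray
#' @export
setMethod("maskArray", "HeadMask", function(x) x@mask)

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "HeadMask", function(x) sum(x@mask))

#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "HeadMask", function(x) dim(x@mask))

setMethod("show", "BrainVolume", function(object) {
    d <- dim(object@data)
    vs <- voxelSize(object)
    cat(sprintf("BrainVolume %dx%dx%d voxels, %.3gx%.3gx%.3g mm%s\n",
                d[1], d[2], d[3], vs[1], vs[2], vs[3],
                if (nzchar(object@unit)) paste0(" [", object@unit, "]") else ""))
    r <- range(object@data[is.finite(object@data)])
    cat(sprintf("  data range: [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "HeadMask", function(object) {
    d <- dim(object@mask)
    cat(sprintf("HeadMask %dx%dx%d, %d voxels inside (%.1f%%)\n",
                d[1], d[2], d[3], sum(object@mask),
                100 * mean(object@mask)))
})

## Grid compatibility -------------------------------------------------------

# Pairwise operations require identical lattices and affines (1e-4 absolute
# tolerance on affine entries); anything else needs resampling, which is out
# of scope.
checkSameGrid <- function(a, b, what = "volumes") {
    da <- if (is(a, "HeadMask")) dim(a@mask) else dim(a@data)
    db <- if (is(b, "HeadMask")) dim(b@mask) else dim(b@data)
    if (!identical(da, db))
        stop(sprintf("%s have mismatched lattice dimensions (%s vs %s)",
                     what, paste(da, collapse = "x"),
                     paste(db, collapse = "x")), call. = FALSE)
    if (is(a, "BrainVolume") && is(b, "BrainVolume") &&
        max(abs(a@affine - b@affine)) > 1e-4)
        stop(sprintf("%s have mismatched affines", what), call. = FALSE)
    invisible(TRUE)
}

## NIfTI I/O ----------------------------------------------------------------

#' Read a single-volume NIfTI-1 image
#'
#' Reads a 3D NIfTI-1 file into a \linkS4class{BrainVolume}.  Integer-typed
#' storage is promoted to floating point with the header's slope/intercept
#' scaling applied; the sform (or qform) affine is preserved.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param unit optional unit label to attach.
#' @return a \linkS4class{BrainVolume}.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, unit = "") {
    if (!file.exists(path))
        stop("file does not exist: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) {
        img2 <- array(as.numeric(img), dim = d[1:3])
        aff <- RNifti::xform(img)
        return(brainVolume(img2, affine = aff, unit = unit))
    }
    if (length(d) != 3L)
        stop("expected a single 3D volume, got ", length(d),
             " dimensions", call. = FALSE)
    aff <- RNifti::xform(img)
    if (!all(is.finite(aff)))
        stop("non-finite affine in NIfTI header", call. = FALSE)
    dat <- array(as.numeric(img), dim = d)
    brainVolume(dat, affine = unclass(aff)[1:4, 1:4, drop = FALSE],
                unit = unit)
}

#' Write a BrainVolume as 32-bit float NIfTI-1
#'
#' @param vol a \linkS4class{BrainVolume} with finite data everywhere
#'   (zero-fill non-finite voxels first).
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "BrainVolume"))
    if (!all(is.finite(vol@data)))
        stop("volume contains non-finite voxels; zero-fill before writing",
             call. = FALSE)
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- voxelSize(vol)
    aff <- structure(vol@affine, code = 2L)
    RNifti::`sform<-`(img, aff) -> img
    RNifti::`qform<-`(img, aff) -> img
    RNifti::writeNifti(img, path, datatype = "float")
    invisible(path)
}

#' Write a HeadMask as a 0/1 NIfTI volume
#' @param mask a \linkS4class{HeadMask}.
#' @param template a \linkS4class{BrainVolume} supplying the affine.
#' @param path output path.
#' @export
writeMask <- function(mask, template, path) {
    checkSameGrid(mask, template, "mask and template")
    writeVolume(brainVolume(array(as.numeric(mask@mask), dim = dim(mask@mask)),
                            affine = template@affine), path)
}

## World coordinates --------------------------------------------------------

# World coordinates (mm) of 0-based voxel indices under the affine.
voxelToWorld <- function(affine, ijk) {
    ijk1 <- cbind(ijk, 1)
    t(affine %*% t(ijk1))[, 1:3, drop = FALSE]
}

## Configuration and logging ------------------------------------------------

#' Read a pipeline configuration file
#'
#' Flat-key YAML with any of: \code{fa} (degrees, length 2), \code{tr}
#' (milliseconds, length 2), \code{fwhm} (mm), \code{kappa}, \code{snr},
#' \code{b1_peak}, \code{b1_asymmetry}, \code{preset}, \code{seed}.  Missing
#' keys fall back to the package defaults (the acquisition protocol and the
#' optimum regularization reported for 3 T brain data).
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return named list of parameters.
#' @export
readPipelineConfig <- function(path = NULL) {
    cfg <- list(fa = c(6, 20), tr = c(23.7, 18.7), fwhm = 60, kappa = 1e-3,
                snr = 0, b1_peak = 0.25, b1_asymmetry = 0.05,
                preset = "normal", seed = 42L)
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        user <- yaml::read_yaml(path)
        for (k in names(user)) cfg[[k]] <- user[[k]]
    }
    cfg
}

# stderr logging, gated by options(unicort.verbose = TRUE)
uniMessage <- function(...) {
    if (isTRUE(getOption("unicort.verbose", FALSE)))
        message(sprintf(...))
    invisible(NULL)
}
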