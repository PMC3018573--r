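#' @import methods
NULL

#' BrainVolume: a 3D scalar lattice with world orientation
#'
#' Container for a single 3D quantitative-MRI volume: the voxel lattice, its
#' 4x4 voxel-to-world affine (NIfTI convention, 0-based voxel indices) and a
#' free-text unit label.  Used throughout for signal amplitudes (arbitrary
#' units), relaxation-rate maps (1/s) and dimensionless field maps (psi, eta).
#'
#' @slot data numeric 3D array.
#' @slot affine numeric 4x4 voxel-to-world transform; the Euclidean norms of
#'   its first three columns are the voxel sizes in mm.
#' @slot unit character(1) free-text unit label, e.g. \code{"1/s"}.
#' @aliases BrainVolume-class
#' @exportClass BrainVolume
setClass("BrainVolume",
    representation(data = "array", affine = "matrix", unit = "character"),
    prototype(unit = ""))

setValidity("BrainVolume", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L)
        return("data must be a 3D array")
    if (any(d < 1L))
        return("all lattice dimensions must be >= 1")
    if (!all(dim(object@affine) == c(4L, 4L)))
        return("affine must be a 4x4 matrix")
    if (!all(is.finite(object@affine)))
        return("affine entries must be finite")
    vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(vs <= 0))
        return("voxel sizes (affine column norms) must be strictly positive")
    if (length(object@unit) != 1L)
        return("unit must be character(1)")
    TRUE
})

#' HeadMask: a boolean lattice selecting head voxels
#'
#' @slot mask logical 3D array; \code{TRUE} marks voxels inside the head
#'   (brain, skull, scalp/neck for phantoms).
#' @aliases HeadMask-class
#' @exportClass HeadMask
setClass("HeadMask", representation(mask = "array"))

setValidity("HeadMask", function(object) {
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
        return("mask must be a logical 3D array")
    if (!any(object@mask))
        return("mask must contain at least one TRUE voxel")
    TRUE
})

#' AcquisitionParams: the variable-flip-angle FLASH pair
#'
#' Nominal excitation flip angles and repetition times of the PDw/T1w spoiled
#' gradient-echo pair.  Stored internally in coherent units (radians and
#' seconds); the constructor accepts the scanner-console convention (degrees
#' and milliseconds).
#'
#' @slot alpha1,alpha2 nominal flip angles in radians (PDw, T1w).
#' @slot tr1,tr2 repetition times in seconds (PDw, T1w).
#' @aliases AcquisitionParams-class
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
    representation(alpha1 = "numeric", alpha2 = "numeric",
                   tr1 = "numeric", tr2 = "numeric"))

setValidity("AcquisitionParams", function(object) {
    a <- c(object@alpha1, object@alpha2)
    tr <- c(object@tr1, object@tr2)
    if (any(!is.finite(c(a, tr)))) return("parameters must be finite")
    if (any(a <= 0) || any(a >= pi / 2))
        return("flip angles must lie strictly between 0 and 90 degrees")
    if (any(tr <= 0)) return("repetition times must be positive")
    if (object@alpha1 == object@alpha2 && object@tr1 == object@tr2)
        return("the two acquisitions must differ in flip angle or TR")
    TRUE
})

#' PhantomSpec: parameters of the digital head phantom
#'
#' Fully specifies one synthetic dataset: lattice, tissue parameters,
#' transmit-field (B1+) inhomogeneity, noise level and seed.  The generator
#' is a pure function of this object.
#'
#' @slot gridDims integer(3) lattice dimensions (>= 16 per axis).
#' @slot voxelSize numeric(1) isotropic voxel size in mm.
#' @slot tissueR1 named numeric, longitudinal relaxation rate per class in
#'   1/s (names \code{GM, WM, CSF, other}).
#' @slot tissuePD named numeric, relative proton density per class.
#' @slot geometry one of \code{"normal"}, \code{"enlarged_ventricles"},
#'   \code{"cyst"}.
#' @slot b1PeakDeviation peak fractional deviation of the local/nominal
#'   flip-angle ratio psi at the head centre (0 = homogeneous field).
#' @slot b1Asymmetry amplitude of the left-right linear tilt of psi.
#' @slot b1Sign +1 for central brightening (psi > 1 centrally), -1 for the
#'   opposite polarity.
#' @slot noiseSNR signal-to-noise ratio of the mean head signal (0 =
#'   noiseless); \code{rician} switches additive Gaussian to Rician noise.
#' @slot rician logical(1).
#' @slot seed integer RNG seed for the noise draw.
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(gridDims = "integer", voxelSize = "numeric",
                   tissueR1 = "numeric", tissuePD = "numeric",
                   geometry = "character", b1PeakDeviation = "numeric",
                   b1Asymmetry = "numeric", b1Sign = "numeric",
                   noiseSNR = "numeric", rician = "logical",
                   seed = "integer"))

.tissueClasses <- c("GM", "WM", "CSF", "other")

setValidity("PhantomSpec", function(object) {
    if (length(object@gridDims) != 3L || any(object@gridDims < 16L))
        return("gridDims must be three integers >= 16")
    if (object@voxelSize <= 0) return("voxelSize must be positive")
    for (s in c("tissueR1", "tissuePD")) {
        v <- slot(object, s)
        if (!all(.tissueClasses %in% names(v)))
            return(sprintf("%s must be named with %s", s,
                           paste(.tissueClasses, collapse = ", ")))
        if (any(v[.tissueClasses] <= 0))
            return(sprintf("%s values must be positive", s))
    }
    if (!object@geometry %in% c("normal", "enlarged_ventricles", "cyst"))
        return("unknown geometry preset")
    if (object@b1PeakDeviation < 0 || object@b1PeakDeviation >= 1)
        return("b1PeakDeviation must lie in [0, 1)")
    if (object@b1Asymmetry < 0 || object@b1Asymmetry >= 1)
        return("b1Asymmetry must lie in [0, 1)")
    if (!object@b1Sign %in% c(-1, 1)) return("b1Sign must be +1 or -1")
    if (object@noiseSNR < 0) return("noiseSNR must be >= 0")
    TRUE
})

#' GroundTruth: the phantom's known parameter maps
#'
#' @slot r1True true R1 map (1/s), 0 outside the head.
#' @slot psiTrue true local/nominal flip-angle ratio, unit mean over the
#'   head, 1 outside.
#' @slot pdTrue relative proton density map.
#' @slot labels integer 3D array of tissue class indices (0 = background,
#'   then the order of \code{levels = GM, WM, CSF, other}).
#' @slot headMask \linkS4class{HeadMask} of the phantom head.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(r1True = "BrainVolume", psiTrue = "BrainVolume",
                   pdTrue = "BrainVolume", labels = "array",
                   headMask = "HeadMask"))

#' CosineBasis: separable low-frequency cosine basis over a mask bounding box
#'
#' A 3D DCT-II-type tensor-product basis spanning the bounding box of a head
#' mask.  The per-axis count is tied to the requested bias smoothness:
#' \code{n_k = max(1, floor(2 * L_k / fwhm) + 1)} where \code{L_k} is the
#' bounding-box extent in mm, so the shortest representable period is
#' approximately \code{fwhm}.  The first basis function on each axis is the
#' constant 1; higher ones are \code{sqrt(2) * cos(pi * m * t)} evaluated at
#' cell centres \code{t = (j + 0.5) / N}, which are mutually orthogonal on
#' the full bounding-box grid.
#'
#' @slot B list of three per-axis basis matrices (grid points x n_k).
#' @slot nBasis integer(3) per-axis basis counts.
#' @slot bboxStart integer(3) first voxel index (1-based) of the bounding box.
#' @slot bboxDims integer(3) bounding-box extents in voxels.
#' @slot gridDims integer(3) full lattice dimensions.
#' @slot spacing numeric(3) physical voxel spacing (mm) along voxel axes.
#' @slot fwhm numeric(1) requested smoothness in mm.
#' @aliases CosineBasis-class
#' @exportClass CosineBasis
setClass("CosineBasis",
    representation(B = "list", nBasis = "integer", bboxStart = "integer",
                   bboxDims = "integer", gridDims = "integer",
                   spacing = "numeric", fwhm = "numeric"))

#' BiasModel: exponential cosine-basis bias field
#'
#' The multiplicative bias field eta(x) = exp(sum_k c_k phi_k(x)) relating
#' the apparent to the true R1 map, parameterized by coefficients on a
#' \linkS4class{CosineBasis}.  With all coefficients zero, eta is identically
#' one.  eta relates to the transmit-field ratio by psi^2 = 1/eta.
#'
#' @slot coeffs numeric array of basis coefficients (n1 x n2 x n3).
#' @slot basis \linkS4class{CosineBasis}.
#' @slot kappa regularization constant used during fitting.
#' @aliases BiasModel-class
#' @exportClass BiasModel
setClass("BiasModel",
    representation(coeffs = "array", basis = "CosineBasis",
                   kappa = "numeric"))

setValidity("BiasModel", function(object) {
    if (!all(dim(object@coeffs) == object@basis@nBasis))
        return("coefficient array does not match the basis counts")
    if (!all(is.finite(object@coeffs)))
        return("coefficients must be finite")
    TRUE
})

#' TissueMixture: Gaussian mixture over tissue classes
#'
#' Per-component means, variances and weights of the intensity model, with a
#' class label (GM/WM/CSF/other) attached to each component.  Several
#' components may share a class; weights are global mixing proportions
#' summing to one; components are ordered by mean within class.
#'
#' @slot mean,var,weight numeric vectors, one entry per component
#'   (means in 1/s, variances in 1/s^2).
#' @slot classes character vector of class labels per component.
#' @aliases TissueMixture-class
#' @exportClass TissueMixture
setClass("TissueMixture",
    representation(mean = "numeric", var = "numeric", weight = "numeric",
                   classes = "character"))

setValidity("TissueMixture", function(object) {
    k <- length(object@mean)
    if (length(object@var) != k || length(object@weight) != k ||
        length(object@classes) != k)
        return("mean, var, weight and classes must have equal length")
    if (any(object@var <= 0)) return("variances must be positive")
    if (any(object@weight < 0)) return("weights must be non-negative")
    if (abs(sum(object@weight) - 1) > 1e-8)
        return("weights must sum to 1")
    if (!all(object@classes %in% .tissueClasses))
        return("unknown class label")
    for (cl in unique(object@classes)) {
        m <- object@mean[object@classes == cl]
        if (is.unsorted(m)) return("components must be ordered by mean within class")
    }
    TRUE
})

#' BiasFit: result of the penalized-likelihood bias/segmentation fit
#'
#' @slot bias fitted \linkS4class{BiasModel}.
#' @slot mixture fitted \linkS4class{TissueMixture}.
#' @slot responsibilities matrix (masked voxels x components) of posterior
#'   component memberships; rows sum to 1.
#' @slot maskIdx integer indices (into the full lattice) of the voxels the
#'   fit used, in the row order of \code{responsibilities}.
#' @slot objectiveTrace penalized log-likelihood after each iteration;
#'   non-decreasing.
#' @slot converged logical(1).
#' @slot nIter integer(1).
#' @aliases BiasFit-class
#' @exportClass BiasFit
setClass("BiasFit",
    representation(bias = "BiasModel", mixture = "TissueMixture",
                   responsibilities = "matrix", maskIdx = "integer",
                   objectiveTrace = "numeric", converged = "logical",
                   nIter = "integer"))

setValidity("BiasFit", function(object) {
    r <- object@responsibilities
    if (nrow(r) != length(object@maskIdx))
        return("responsibility rows must match the masked voxels")
    if (any(r < -1e-12) || any(r > 1 + 1e-12))
        return("responsibilities must lie in [0, 1]")
    if (max(abs(rowSums(r) - 1)) > 1e-6)
        return("responsibilities must sum to 1 per voxel")
    tr <- object@objectiveTrace
    if (length(tr) > 1 && any(diff(tr) < -1e-8 * pmax(1, abs(tr[-1]))))
        return("objective trace must be non-decreasing")
    TRUE
})

#' UnicortFit: outputs of the end-to-end correction pipeline
#'
#' @slot r1App apparent (uncorrected) R1 map, 1/s.
#' @slot r1Unicort bias-corrected R1 map, 1/s; equal to
#'   \code{r1App / eta} inside the mask, 0 outside.
#' @slot psiUnicort estimated transmit-field ratio map, \code{1/sqrt(eta)}
#'   inside the mask, 1 outside, unit mean over the mask.
#' @slot eta estimated multiplicative bias field, 1 outside the mask.
#' @slot segmentations named list of per-class posterior probability volumes.
#' @slot headMask head mask used for fitting.
#' @slot validMask voxels with a usable apparent-R1 estimate.
#' @slot fit the underlying \linkS4class{BiasFit}.
#' @slot report list of fit metadata (parameters, convergence, timings).
#' @aliases UnicortFit-class
#' @exportClass UnicortFit
setClass("UnicortFit",
    representation(r1App = "BrainVolume", r1Unicort = "BrainVolume",
                   psiUnicort = "BrainVolume", eta = "BrainVolume",
                   segmentations = "list", headMask = "HeadMask",
                   validMask = "HeadMask", fit = "BiasFit",
                   report = "list"))

#' DeviationReport: voxel-wise symmetric deviation between two maps
#'
#' @slot metricName label, e.g. \code{"D_unicort"}, \code{"D_app"},
#'   \code{"D_B1"}.
#' @slot deviationMap voxel-wise symmetric deviation
#'   \code{2 (a - b) / (a + b)} (dimensionless), 0 outside the mask.
#' @slot medianPercent median of the (absolute, unless signed) deviation
#'   over the mask, in percent.
#' @slot maskUsed evaluation mask.
#' @slot nExcluded voxels inside the mask excluded because \code{a + b <= 0}.
#' @slot signed whether the median was taken over signed values.
#' @aliases DeviationReport-class
#' @exportClass DeviationReport
setClass("DeviationReport",
    representation(metricName = "character", deviationMap = "BrainVolume",
                   medianPercent = "numeric", maskUsed = "HeadMask",
                   nExcluded = "integer", signed = "logical"))
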