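#' @include AllClasses.R
NULL

#' Extract the voxel lattice of a volume
#' @param x a \linkS4class{BrainVolume}.
#' @return numeric 3D array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' Voxel sizes in mm
#' @param x a \linkS4class{BrainVolume} or \linkS4class{PhantomSpec}.
#' @return numeric(3).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel-to-world affine
#' @param x a \linkS4class{BrainVolume}.
#' @return numeric 4x4 matrix.
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' Unit label of a volume
#' @param x a \linkS4class{BrainVolume}.
#' @return character(1).
#' @export
setGeneric("volUnit", function(x) standardGeneric("volUnit"))

#' Logical mask array
#' @param x a \linkS4class{HeadMask}.
#' @return logical 3D array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Number of voxels inside a mask
#' @param x a \linkS4class{HeadMask}.
#' @return integer(1).
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Evaluate the multiplicative bias field on the full lattice
#' @param object a \linkS4class{BiasModel}.
#' @return numeric 3D array of eta values (positive everywhere).
#' @export
setGeneric("evalBias", function(object) standardGeneric("evalBias"))

#' Bending energy of the log-bias field
#'
#' Quadratic roughness functional of the log of the bias field, computed
#' analytically from the cosine-basis frequencies (sum over all squared
#' second derivatives, lengths measured in units of 100 mm).  Zero for a
#' constant field; scales quadratically with the coefficients.
#'
#' @param object a \linkS4class{BiasModel}.
#' @return non-negative scalar.
#' @export
setGeneric("bendingEnergy", function(object) standardGeneric("bendingEnergy"))
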