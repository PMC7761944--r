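#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom stats median IQR sd friedman.test wilcox.test kruskal.test p.adjust rnorm runif
#' @importFrom utils combn read.table write.table
#' @useDynLib occlusalWear, .registration = TRUE
NULL

#' TriangleMesh: an indexed triangle surface in millimetres
#'
#' The universal carrier of geometry in this package: a vertex matrix in mm
#' (right-handed coordinates) and a face matrix of 1-based vertex indices with
#' consistent outward orientation, plus an optional per-vertex scalar field
#' (mm) used for signed distance maps. Faces are stored 1-based internally;
#' on-disk label files use 0-based indices (see \code{\link{writeWearCase}}).
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot field numeric vector of length 0 (absent) or n (per-vertex scalar, mm).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", field = "numeric"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3), field = numeric(0)))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (length(v) && !all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f)) {
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("degenerate faces (repeated vertex index)")
  }
  if (length(object@field) && length(object@field) != nrow(v))
    return("field length must equal number of vertices")
  TRUE
})

#' RegionMask: a named vertex subset of a mesh
#'
#' Marks a superimposition reference area or anatomical label (e.g. "crown",
#' "buccal", "lingual", "composite", "adjacent_intact") as a set of vertex
#' indices into a specific mesh.
#'
#' @slot name character label.
#' @slot indices integer vector of 1-based vertex indices (non-empty, sorted).
#' @export
setClass("RegionMask",
  representation(name = "character", indices = "integer"))

setValidity("RegionMask", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (!length(object@indices)) return("mask must be non-empty")
  if (anyNA(object@indices) || min(object@indices) < 1L)
    return("indices must be positive integers")
  TRUE
})

#' RigidTransform: rotation plus translation
#'
#' Maps points by \code{x -> R x + t}. Used to carry the result of rigid
#' registration (T1 geometry into the T0 frame and vice versa).
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 vector (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (tolerance 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must have determinant +1")
  TRUE
})

#' ICPSettings: the registration dialect
#'
#' Settings of the trimmed iterative-closest-point registration: the
#' estimated-overlap trimming fraction, the matching metric, the source
#' sampling fraction, overhang exclusion, and the iteration budget.
#' Defaults follow the basic setting used throughout the workflow:
#' 100\% overlap, point-to-plane matching, exact nearest neighbours,
#' 100\% point sampling, exclude overhangs, 50 iterations.
#'
#' @slot overlapFraction fraction in (0,1] of closest-point pairs retained
#'   each iteration (estimated overlap of meshes).
#' @slot matching "point_to_plane" or "point_to_point".
#' @slot samplingFraction fraction in (0,1] of source reference vertices used.
#' @slot excludeOverhangs logical; discard correspondences whose closest point
#'   lies on an open boundary of the target.
#' @slot maxIterations positive integer.
#' @slot convergenceTol RMS-change stopping threshold in mm.
#' @export
setClass("ICPSettings",
  representation(overlapFraction = "numeric", matching = "character",
                 samplingFraction = "numeric", excludeOverhangs = "logical",
                 maxIterations = "integer", convergenceTol = "numeric"))

setValidity("ICPSettings", function(object) {
  if (object@overlapFraction <= 0 || object@overlapFraction > 1)
    return("overlapFraction must be in (0, 1]")
  if (object@samplingFraction <= 0 || object@samplingFraction > 1)
    return("samplingFraction must be in (0, 1]")
  if (!object@matching %in% c("point_to_plane", "point_to_point"))
    return("matching must be point_to_plane or point_to_point")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@convergenceTol < 0) return("convergenceTol must be >= 0")
  TRUE
})

#' RegistrationResult: outcome of a (staged) ICP run
#'
#' @slot transform RigidTransform mapping the source into the target frame,
#'   cumulative from the original initial position.
#' @slot rmsResidual RMS distance (mm) over retained correspondences at the
#'   final iteration.
#' @slot retainedCount number of correspondences retained at the final
#'   iteration (floor(overlap x sampled)).
#' @slot iterationsRun iterations executed in the final stage.
#' @slot stages list of per-stage logs (label, rms, iterations, retained).
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", rmsResidual = "numeric",
                 retainedCount = "integer", iterationsRun = "integer",
                 stages = "list"))

#' TechniqueSpec: one of the eight superimposition techniques
#'
#' Reference area x estimated-overlap combinations: GS (adjacent intact teeth
#' and alveolar processes, 100\%), PC_A (buccal surface, 100\%), PC_B
#' (buccolingual surfaces without composite, user defined), PC_C (complete
#' crown without composite, user defined), PC_D (complete crown without
#' composite, 40\%), CC_A (complete crown, 40\%), CC_B (complete crown, user
#' defined), CC_C (complete crown, 20\%).
#'
#' @slot id technique identifier.
#' @slot referenceArea label resolved against the case's region masks.
#' @slot overlap numeric overlap fraction, NA when user defined.
#' @slot userDefined logical; TRUE when the overlap is optimised per case.
#' @export
setClass("TechniqueSpec",
  representation(id = "character", referenceArea = "character",
                 overlap = "numeric", userDefined = "logical"))

#' SlicePlane: a crown slicing plane
#'
#' @slot point a point on the plane (mm).
#' @slot normal unit normal; the kept (occlusal) half-space is the positive
#'   side of the normal.
#' @slot role "gingival", "mesial" or "distal".
#' @export
setClass("SlicePlane",
  representation(point = "numeric", normal = "numeric", role = "character"))

setValidity("SlicePlane", function(object) {
  if (length(object@point) != 3L || length(object@normal) != 3L)
    return("point and normal must be length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be unit length (tolerance 1e-9)")
  if (!object@role %in% c("gingival", "mesial", "distal"))
    return("role must be gingival, mesial or distal")
  TRUE
})

#' WearMeasurement: result of the slicing/volumetry workflow
#'
#' Occlusal wear is the volume difference between the identically sliced and
#' capped occlusal parts of the superimposed T0 and T1 crowns:
#' \code{wearVolume = t0PartVolume - t1PartVolume} (mm^3), positive for
#' material loss.
#'
#' @slot techniqueId technique used for the superimposition.
#' @slot t0PartVolume,t1PartVolume volumes (mm^3) of the capped parts.
#' @slot wearVolume t0PartVolume - t1PartVolume (mm^3).
#' @slot planes list of SlicePlane used (identical for both crowns).
#' @slot watertight named logical: both capped parts passed the check.
#' @slot registration the RegistrationResult that aligned T1 to T0.
#' @slot distances per-vertex signed distance map (mm) on the T0 crown.
#' @export
setClass("WearMeasurement",
  representation(techniqueId = "character", t0PartVolume = "numeric",
                 t1PartVolume = "numeric", wearVolume = "numeric",
                 planes = "list", watertight = "logical",
                 registration = "RegistrationResult", distances = "numeric"))

#' WearCase: one synthetic validation case with ground truth
#'
#' A generated arch segment at baseline (T0) and after occlusal grinding,
#' retainer placement and independent scan noise (T1, in a different pose),
#' with region masks, coarse-alignment landmarks and the constructed removed
#' volume.
#'
#' @slot id case identifier.
#' @slot t0,t1 TriangleMesh models of the arch segment.
#' @slot t0Labels,t1Labels named lists of RegionMask (crown, buccal, lingual,
#'   composite, adjacent_intact, tooth_<k>).
#' @slot t0Landmarks,t1Landmarks 4 x 3 matrices (cusp tip, gingival midpoint,
#'   mesial and distal extremes of the test tooth).
#' @slot trueRemovedVolume constructed removed volume (mm^3).
#' @slot info list of generator parameters (tooth type, loss, pattern, ...).
#' @export
setClass("WearCase",
  representation(id = "character", t0 = "TriangleMesh", t1 = "TriangleMesh",
                 t0Labels = "list", t1Labels = "list",
                 t0Landmarks = "matrix", t1Landmarks = "matrix",
                 trueRemovedVolume = "numeric", info = "list"))

setValidity("WearCase", function(object) {
  if (object@trueRemovedVolume < 0) return("trueRemovedVolume must be >= 0")
  nv0 <- nrow(object@t0@vertices)
  nv1 <- nrow(object@t1@vertices)
  for (m in object@t0Labels)
    if (max(m@indices) > nv0) return("t0 label indices out of range")
  for (m in object@t1Labels)
    if (max(m@indices) > nv1) return("t1 label indices out of range")
  TRUE
})
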