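#' Construct a TriangleMesh
#'
#' Degenerate faces (repeated vertex index or zero area) are dropped with a
#' message stating the count, matching the import behaviour for scanned
#' surface models.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param field optional per-vertex scalar (length n), e.g. a distance map.
#' @param dropDegenerate drop zero-area/repeated-index faces (default TRUE).
#' @return A \linkS4class{TriangleMesh}.
#' @export
TriangleMesh <- function(vertices, faces, field = numeric(0),
                         dropDegenerate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (dropDegenerate && nrow(faces)) {
    bad <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (!all(bad)) {
      # zero-area check on the remainder
      f <- faces[!bad, , drop = FALSE]
      a <- vertices[f[, 1], , drop = FALSE]
      b <- vertices[f[, 2], , drop = FALSE]
      c3 <- vertices[f[, 3], , drop = FALSE]
      cr <- vcross(b - a, c3 - a)
      zero <- rowSums(cr^2) == 0
      bad[!bad][zero] <- TRUE
    }
    if (any(bad)) {
      message("dropping ", sum(bad), " degenerate face(s)")
      faces <- faces[!bad, , drop = FALSE]
    }
  }
  new("TriangleMesh", vertices = vertices, faces = faces,
      field = as.numeric(field))
}

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("vertexField", function(x) standardGeneric("vertexField"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("vertexField<-", function(x, value) standardGeneric("vertexField<-"))

#' Accessors for TriangleMesh
#'
#' @param x a \linkS4class{TriangleMesh}.
#' @param value replacement per-vertex scalar field.
#' @name TriangleMesh-accessors
#' @aliases meshVertices meshFaces nVertices nFaces vertexField vertexField<-
NULL

#' @rdname TriangleMesh-accessors
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname TriangleMesh-accessors
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)
#' @rdname TriangleMesh-accessors
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname TriangleMesh-accessors
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname TriangleMesh-accessors
setMethod("vertexField", "TriangleMesh", function(x) x@field)
#' @rdname TriangleMesh-accessors
setReplaceMethod("vertexField", "TriangleMesh", function(x, value) {
  x@field <- as.numeric(value)
  validObject(x)
  x
})

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces")
  if (length(object@field)) cat(", with per-vertex field")
  cat("\n")
  if (nrow(object@vertices)) {
    rng <- apply(object@vertices, 2, range)
    cat(sprintf("  extent (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

#' Construct a RegionMask
#'
#' @param name label, e.g. "crown".
#' @param indices vertex indices (1-based) into the referenced mesh.
#' @param mesh optional \linkS4class{TriangleMesh} to validate against.
#' @return A \linkS4class{RegionMask}.
#' @export
RegionMask <- function(name, indices, mesh = NULL) {
  m <- new("RegionMask", name = as.character(name),
           indices = sort(unique(as.integer(indices))))
  if (!is.null(mesh) && max(m@indices) > nVertices(mesh))
    stop("mask '", name, "' has indices beyond the mesh vertex count")
  m
}

#' @rdname RegionMask
#' @param x a RegionMask.
#' @export
setGeneric("maskIndices", function(x) standardGeneric("maskIndices"))
#' @rdname RegionMask
setMethod("maskIndices", "RegionMask", function(x) x@indices)

#' @rdname RegionMask
#' @export
setGeneric("maskName", function(x) standardGeneric("maskName"))
#' @rdname RegionMask
setMethod("maskName", "RegionMask", function(x) x@name)

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask '", object@name, "': ", length(object@indices),
      " vertices\n", sep = "")
})

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param translation length-3 vector (mm).
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3]))
})

#' Construct ICPSettings
#'
#' @param overlapFraction estimated overlap of meshes, in (0,1].
#' @param matching "point_to_plane" (default) or "point_to_point".
#' @param samplingFraction fraction of source reference vertices sampled.
#' @param excludeOverhangs discard boundary-contact correspondences.
#' @param maxIterations iteration budget (default 50).
#' @param convergenceTol RMS-change stopping threshold, mm (default 1e-7).
#' @return An \linkS4class{ICPSettings}.
#' @export
ICPSettings <- function(overlapFraction = 1, matching = "point_to_plane",
                        samplingFraction = 1, excludeOverhangs = TRUE,
                        maxIterations = 50L, convergenceTol = 1e-7) {
  new("ICPSettings", overlapFraction = overlapFraction, matching = matching,
      samplingFraction = samplingFraction,
      excludeOverhangs = excludeOverhangs,
      maxIterations = as.integer(maxIterations),
      convergenceTol = convergenceTol)
}

setMethod("show", "ICPSettings", function(object) {
  cat(sprintf("ICPSettings: overlap %d%%, %s, sampling %d%%, %s, max %d iterations\n",
              round(100 * object@overlapFraction), object@matching,
              round(100 * object@samplingFraction),
              if (object@excludeOverhangs) "exclude overhangs" else "keep overhangs",
              object@maxIterations))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: rms %.3g mm over %d pairs, %d iterations, %d stage(s)\n",
              object@rmsResidual, object@retainedCount, object@iterationsRun,
              length(object@stages)))
})

#' @rdname RegistrationResult-accessors
#' @param x a RegistrationResult.
#' @export
setGeneric("regTransform", function(x) standardGeneric("regTransform"))
#' Accessors for RegistrationResult
#' @name RegistrationResult-accessors
#' @param x a RegistrationResult.
NULL
#' @rdname RegistrationResult-accessors
setMethod("regTransform", "RegistrationResult", function(x) x@transform)
#' @rdname RegistrationResult-accessors
#' @export
setGeneric("rmsResidual", function(x) standardGeneric("rmsResidual"))
#' @rdname RegistrationResult-accessors
setMethod("rmsResidual", "RegistrationResult", function(x) x@rmsResidual)

#' Construct a SlicePlane
#'
#' @param point point on the plane (mm).
#' @param normal plane normal; normalised internally. The kept (occlusal)
#'   half-space is the positive side.
#' @param role "gingival", "mesial" or "distal".
#' @return A \linkS4class{SlicePlane}.
#' @export
SlicePlane <- function(point, normal, role = "gingival") {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("degenerate plane normal")
  new("SlicePlane", point = as.numeric(point), normal = n / nn, role = role)
}

setMethod("show", "WearMeasurement", function(object) {
  cat(sprintf("WearMeasurement [%s]: wear %.4f mm^3 (T0 part %.4f, T1 part %.4f), %d plane(s)\n",
              object@techniqueId, object@wearVolume, object@t0PartVolume,
              object@t1PartVolume, length(object@planes)))
})

#' @rdname WearMeasurement-accessors
#' @param x a WearMeasurement.
#' @export
setGeneric("wearVolume", function(x) standardGeneric("wearVolume"))
#' Accessors for WearMeasurement
#' @name WearMeasurement-accessors
#' @param x a WearMeasurement.
NULL
#' @rdname WearMeasurement-accessors
setMethod("wearVolume", "WearMeasurement", function(x) x@wearVolume)

setMethod("show", "WearCase", function(object) {
  cat(sprintf("WearCase '%s': %s, loss %.2f mm (%s), true removed volume %.4f mm^3\n",
              object@id,
              if (is.null(object@info$toothType)) "?" else object@info$toothType,
              if (is.null(object@info$verticalLoss)) NA_real_ else object@info$verticalLoss,
              if (is.null(object@info$pattern)) "?" else object@info$pattern,
              object@trueRemovedVolume))
})

#' @rdname WearCase-accessors
#' @param x a WearCase.
#' @export
setGeneric("trueRemovedVolume", function(x) standardGeneric("trueRemovedVolume"))
#' Accessors for WearCase
#' @name WearCase-accessors
#' @param x a WearCase.
NULL
#' @rdname WearCase-accessors
setMethod("trueRemovedVolume", "WearCase", function(x) x@trueRemovedVolume)
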