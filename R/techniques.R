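# The eight superimposition techniques: a reference area combined with an
# estimated-overlap setting, dispatched onto the staged registration.

.TECHNIQUES <- data.frame(
  id = c("GS", "PC_A", "PC_B", "PC_C", "PC_D", "CC_A", "CC_B", "CC_C"),
  referenceArea = c("adjacent_intact", "buccal", "buccolingual_no_composite",
                    "crown_no_composite", "crown_no_composite",
                    "crown", "crown", "crown"),
  overlap = c(1, 1, NA, NA, 0.4, 0.4, NA, 0.2),
  stringsAsFactors = FALSE)

#' The technique table
#'
#' Reference area and estimated-overlap setting of the eight superimposition
#' techniques: the gold standard (GS: adjacent intact teeth and alveolar
#' processes, 100\%), the partial-crown group PC_A-PC_D, and the
#' complete-crown group CC_A-CC_C. \code{NA} overlap means "user defined"
#' (optimised per case against known-intact structures; available only in the
#' synthetic/benchmark setting).
#'
#' @return a data.frame with columns id, referenceArea, overlap.
#' @export
techniqueTable <- function() .TECHNIQUES

#' Construct a TechniqueSpec
#'
#' @param id one of GS, PC_A, PC_B, PC_C, PC_D, CC_A, CC_B, CC_C.
#' @return a \linkS4class{TechniqueSpec}.
#' @export
techniqueSpec <- function(id) {
  row <- .TECHNIQUES[.TECHNIQUES$id == id, ]
  if (!nrow(row)) stop("unknown technique id: ", id)
  new("TechniqueSpec", id = row$id, referenceArea = row$referenceArea,
      overlap = row$overlap, userDefined = is.na(row$overlap))
}

setMethod("show", "TechniqueSpec", function(object) {
  cat(sprintf("TechniqueSpec %s: reference '%s', overlap %s\n", object@id,
              object@referenceArea,
              if (object@userDefined) "user defined"
              else sprintf("%d%%", round(100 * object@overlap))))
})

#' Resolve a technique's reference area to a vertex mask
#'
#' GS uses the adjacent intact structures; PC_A the buccal surface; PC_B the
#' buccolingual surfaces minus the composite footprint; PC_C/PC_D the
#' complete crown minus the composite footprint; CC_* the complete crown.
#'
#' @param mesh the (T0) mesh the labels refer to.
#' @param labels named list of \linkS4class{RegionMask} (needs, depending on
#'   the technique: crown, buccal, lingual, composite, adjacent_intact).
#' @param spec a \linkS4class{TechniqueSpec}.
#' @return a \linkS4class{RegionMask} for the registration reference.
#' @export
resolveReference <- function(mesh, labels, spec) {
  need <- function(nm) {
    if (is.null(labels[[nm]]))
      stop("configuration error: missing label '", nm, "' required by ",
           spec@id)
    labels[[nm]]
  }
  compIdx <- if (!is.null(labels$composite)) maskIndices(labels$composite) else integer(0)
  idx <- switch(spec@referenceArea,
    adjacent_intact = maskIndices(need("adjacent_intact")),
    buccal = maskIndices(need("buccal")),
    buccolingual_no_composite =
      setdiff(union(maskIndices(need("buccal")), maskIndices(need("lingual"))),
              compIdx),
    crown_no_composite = setdiff(maskIndices(need("crown")), compIdx),
    crown = maskIndices(need("crown")),
    stop("unknown reference area: ", spec@referenceArea))
  if (!length(idx))
    stop("configuration error: empty reference area for ", spec@id)
  RegionMask(spec@referenceArea, idx, mesh)
}

#' Run one superimposition technique
#'
#' Resolves the reference area on the T0 model, builds the ICP settings
#' (a "user defined" overlap triggers the grid search of
#' \code{\link{optimizeOverlapFraction}} against the adjacent intact
#' structures), and runs the staged registration with correspondences from
#' the T0 reference region into the T1 surface. The returned transform maps
#' T0 into the T1 frame; its inverse moves T1 onto T0 for wear measurement.
#'
#' @param t0Model,t1Model \linkS4class{TriangleMesh} models.
#' @param labels named list of \linkS4class{RegionMask} on the T0 model.
#' @param spec a \linkS4class{TechniqueSpec} (or technique id string).
#' @param landmarks list with 4 x 3 matrices \code{t0} and \code{t1}
#'   (corresponding coarse-alignment landmarks).
#' @param seed integer seed for stochastic paths.
#' @param settings base \linkS4class{ICPSettings}; the overlap is overridden
#'   by the technique.
#' @return a \linkS4class{RegistrationResult}; the technique id and (for user
#'   defined settings) the selected overlap fraction are appended to the
#'   stage log.
#' @export
runTechnique <- function(t0Model, t1Model, labels, spec, landmarks,
                         seed = 1L, settings = ICPSettings()) {
  if (is.character(spec)) spec <- techniqueSpec(spec)
  ref <- resolveReference(t0Model, labels, spec)
  lm <- list(source = landmarks$t0, target = landmarks$t1)
  overlap <- spec@overlap
  chosen <- NULL
  if (spec@userDefined) {
    if (is.null(labels$adjacent_intact))
      stop("configuration error: user-defined overlap requires the ",
           "'adjacent_intact' label")
    opt <- optimizeOverlapFraction(t0Model, ref, t1Model,
                                   labels$adjacent_intact,
                                   settings = settings, landmarkPairs = lm,
                                   seed = seed)
    overlap <- opt$fraction
    chosen <- opt
  }
  settings@overlapFraction <- overlap
  res <- stagedRegister(t0Model, ref, t1Model, settings, lm, seed = seed)
  res@stages <- c(list(list(label = "technique", id = spec@id,
                            overlap = overlap,
                            overlapScores = chosen$scores)), res@stages)
  res
}
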