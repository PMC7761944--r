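# In-silico replica of the validation experiment: parametric anterior teeth
# (superellipse cross-sections with incisal-edge or single-cusp tapers) in a
# short arch segment with intact neighbours and an alveolar band, occlusal
# grinding by planar/tilted truncation with closed-form ground truth, a
# lingual retainer relief (wire + composite blobs), and a clamped Gaussian
# scan-noise model.

#' Tooth shape specification
#'
#' @param toothType "incisor" or "canine".
#' @param crownHeight clinical crown height, mm.
#' @param mesiodistal,buccolingual crown widths, mm.
#' @param position arch position index (0 = test tooth, +-1 neighbours).
#' @param resolution target triangle count (>= 500).
#' @return a list of class "toothSpec".
#' @export
toothSpec <- function(toothType = c("incisor", "canine"), crownHeight = NULL,
                      mesiodistal = NULL, buccolingual = NULL, position = 0L,
                      resolution = 8000L) {
  toothType <- match.arg(toothType)
  def <- switch(toothType,
    incisor = c(h = 10.0, md = 8.5, bl = 7.0),
    canine = c(h = 10.5, md = 7.5, bl = 8.0))
  if (is.null(crownHeight)) crownHeight <- def[["h"]]
  if (is.null(mesiodistal)) mesiodistal <- def[["md"]]
  if (is.null(buccolingual)) buccolingual <- def[["bl"]]
  stopifnot(crownHeight > 0, mesiodistal > 0, buccolingual > 0,
            resolution >= 500)
  structure(list(toothType = toothType, crownHeight = crownHeight,
                 mesiodistal = mesiodistal, buccolingual = buccolingual,
                 position = as.integer(position),
                 resolution = as.integer(resolution)),
            class = "toothSpec")
}

#' Wear (grinding) specification
#'
#' @param verticalLoss vertical loss in mm (validation levels 0.5, 1, 2).
#' @param pattern "symmetric" (horizontal facet) or "asymmetric" (tilted).
#' @param tiltDeg facet tilt for the asymmetric pattern, degrees (<= 30).
#' @return a list of class "wearSpec".
#' @export
wearSpec <- function(verticalLoss, pattern = c("symmetric", "asymmetric"),
                     tiltDeg = 15) {
  pattern <- match.arg(pattern)
  stopifnot(verticalLoss >= 0, tiltDeg >= 0, tiltDeg <= 30)
  structure(list(verticalLoss = verticalLoss, pattern = pattern,
                 tiltDeg = tiltDeg), class = "wearSpec")
}

#' Retainer specification
#'
#' A twisted ligature wire (0.3 mm diameter) running across the middle of the
#' lingual surfaces, stabilised by a composite blob on each tooth.
#'
#' @param wireDiameter wire diameter, mm (default 0.3).
#' @param wireHeightFrac wire height as a fraction of crown height (middle of
#'   the lingual surface).
#' @param blobHeight composite blob relief height per tooth, mm.
#' @param blobRadius composite blob lateral radius, mm.
#' @return a list of class "retainerSpec".
#' @export
retainerSpec <- function(wireDiameter = 0.3, wireHeightFrac = 0.45,
                         blobHeight = 0.8, blobRadius = 1.6) {
  stopifnot(wireDiameter > 0)
  structure(list(wireDiameter = wireDiameter, wireHeightFrac = wireHeightFrac,
                 blobHeight = blobHeight, blobRadius = blobRadius),
            class = "retainerSpec")
}

#' Scanner noise specification
#'
#' Zero-mean Gaussian displacement along vertex normals. The parameters
#' describe the scanner's repeated-scan surface deviation -- the quantity
#' scanner validations report ("distance between corresponding surfaces" of
#' two scans of the same object): each realisation is drawn with
#' \code{sd/sqrt(2)} and clamped at \code{maxDev/2}, so any two independent
#' scans differ by a zero-mean field with standard deviation \code{sd},
#' everywhere below \code{maxDev}.
#'
#' @param sd repeated-scan standard deviation, mm (default 0.002).
#' @param maxDev repeated-scan clamp, mm (default 0.005, >= sd).
#' @return a list of class "scanNoiseSpec".
#' @export
scanNoiseSpec <- function(sd = 0.002, maxDev = 0.005) {
  stopifnot(sd >= 0, maxDev >= sd)
  structure(list(sd = sd, maxDev = maxDev), class = "scanNoiseSpec")
}

# crown radius profiles: a bulbous, curved crown so a side band constrains
# every rigid degree of freedom during registration
crownProfile <- function(t) 0.82 + 0.18 * cos((t - 0.35) * pi / 1.3)

generateTooth <- function(spec) {
  h <- spec$crownHeight
  a0 <- spec$mesiodistal / 2
  b0 <- spec$buccolingual / 2
  baseDepth <- 2.5
  tipH <- 0.4
  res <- spec$resolution
  nTheta <- max(16L, round(sqrt(res / 2)))
  nRings <- max(10L, round(res / (2 * nTheta)))
  p <- if (spec$toothType == "incisor") 3.0 else 2.2
  zs <- seq(-baseDepth, h, length.out = nRings)
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  ct <- sign(cos(theta)) * abs(cos(theta))^(2 / p)
  st <- sign(sin(theta)) * abs(sin(theta))^(2 / p)
  verts <- matrix(0, 0, 3)
  for (z in zs) {
    if (z < 0) {
      t <- 0
      shrink <- 0.8 + 0.2 * (1 + z / baseDepth)  # gingival constriction
    } else {
      t <- z / h
      shrink <- 1
    }
    prof <- crownProfile(t) * shrink
    if (spec$toothType == "incisor") {
      at <- a0 * prof * (1 - 0.25 * t^2)
      bt <- b0 * prof * sqrt(1 - 0.98 * t^3)
    } else {
      at <- a0 * prof * sqrt(1 - 0.94 * t^2.5)
      bt <- b0 * prof * sqrt(1 - 0.94 * t^2.5)
    }
    px <- at * ct
    py <- bt * st
    # anatomical relief that pins rigid registration: developmental lobes,
    # cusp ridges (canine), and a lingual cingulum bulge at the gingival
    # third -- real crowns are not axially self-similar
    rad <- sqrt(px^2 + py^2)
    lobes <- 0.05 * cos(3 * theta + 0.8) * sin(pi * max(t, 0))
    ridge <- if (spec$toothType == "canine") 0.05 * cos(2 * theta) * t^2 else 0
    cing <- 0.7 * exp(-((theta - pi / 2)^2) / (2 * 0.5^2)) *
      exp(-((t - 0.22)^2) / (2 * 0.13^2))
    # lingual fossa: the shovel-shaped concavity between cingulum and incisal
    # edge of incisors
    fossa <- if (spec$toothType == "incisor")
      -0.8 * exp(-((theta - pi / 2)^2) / (2 * 0.6^2)) *
        exp(-((t - 0.62)^2) / (2 * 0.18^2)) else 0
    scaleF <- 1 + lobes + ridge + (cing + fossa) / pmax(rad, 0.5)
    verts <- rbind(verts, cbind(px * scaleF, py * scaleF, z))
  }
  nv <- nrow(verts)
  bottomC <- nv + 1L
  apex <- nv + 2L
  verts <- rbind(verts, c(0, 0, -baseDepth - 0.3), c(0, 0, h + tipH))
  faces <- list()
  ringIdx <- function(r) (r - 1L) * nTheta + seq_len(nTheta)
  for (r in seq_len(nRings - 1L)) {
    i0 <- ringIdx(r)
    i1 <- ringIdx(r + 1L)
    j2 <- c(2:nTheta, 1L)
    faces[[r]] <- rbind(cbind(i0, i0[j2], i1[j2]), cbind(i0, i1[j2], i1))
  }
  bot <- ringIdx(1L)
  top <- ringIdx(nRings)
  j2 <- c(2:nTheta, 1L)
  faces[[nRings]] <- cbind(bot[j2], bot, bottomC)
  faces[[nRings + 1L]] <- cbind(top, top[j2], apex)
  TriangleMesh(verts, do.call(rbind, faces))
}

makeAlveolarBand <- function(xRange, blHalf, nx = 40L, ny = 12L, nz = 6L) {
  # subdivided box with a gently scalloped top, sitting under the tooth bases
  xs <- seq(xRange[1], xRange[2], length.out = nx)
  ys <- seq(-blHalf - 1.5, blHalf + 1.5, length.out = ny)
  zTop <- -1.2
  zBot <- -5.0
  zs <- seq(zBot, zTop, length.out = nz)
  grid <- function(u, v) cbind(rep(u, each = length(v)), rep(v, times = length(u)))
  idx <- function(i, j, ni, nj) (i - 1L) * nj + j
  verts <- list(); faces <- list()
  # build as a displaced box surface: 6 grids welded
  addGrid <- function(P, flip = FALSE) {
    off <- if (length(verts)) sum(vapply(verts, nrow, 0L)) else 0L
    ni <- attr(P, "ni"); nj <- attr(P, "nj")
    verts[[length(verts) + 1L]] <<- P
    f <- matrix(0L, 0, 3)
    for (i in seq_len(ni - 1L)) {
      a <- off + idx(i, seq_len(nj - 1L), ni, nj)
      b <- off + idx(i, 2:nj, ni, nj)
      c3 <- off + idx(i + 1L, seq_len(nj - 1L), ni, nj)
      d <- off + idx(i + 1L, 2:nj, ni, nj)
      f <- rbind(f, cbind(a, b, d), cbind(a, d, c3))
    }
    if (flip) f <- f[, c(1, 3, 2)]
    faces[[length(faces) + 1L]] <<- f
  }
  sheet <- function(A, ni, nj) { attr(A, "ni") <- ni; attr(A, "nj") <- nj; A }
  scallop <- function(x) 0.35 * sin(2 * pi * x / 7.5)
  gxy <- grid(xs, ys)
  topP <- cbind(gxy, zTop + scallop(gxy[, 1]))
  botP <- cbind(gxy, zBot)
  addGrid(sheet(topP, nx, ny), flip = TRUE)
  addGrid(sheet(botP, nx, ny))
  gxz <- grid(xs, zs)
  s1 <- cbind(gxz[, 1], ys[1], gxz[, 2])
  s1[gxz[, 2] == zTop, 3] <- zTop + scallop(s1[gxz[, 2] == zTop, 1])
  s2 <- cbind(gxz[, 1], ys[ny], gxz[, 2])
  s2[gxz[, 2] == zTop, 3] <- zTop + scallop(s2[gxz[, 2] == zTop, 1])
  addGrid(sheet(s1, nx, nz), flip = TRUE)
  addGrid(sheet(s2, nx, nz))
  gyz <- grid(ys, zs)
  e1 <- cbind(xs[1], gyz[, 1], gyz[, 2])
  e1[gyz[, 2] == zTop, 3] <- zTop + scallop(xs[1])
  e2 <- cbind(xs[nx], gyz[, 1], gyz[, 2])
  e2[gyz[, 2] == zTop, 3] <- zTop + scallop(xs[nx])
  addGrid(sheet(e1, ny, nz))
  addGrid(sheet(e2, ny, nz), flip = TRUE)
  weldVertices(TriangleMesh(do.call(rbind, verts), do.call(rbind, faces)),
               tol = 1e-9)
}

#' Generate a synthetic arch segment
#'
#' Places the parametric teeth along the mesiodistal (x) axis with the test
#' tooth at the origin, the occlusal direction along +z and the lingual
#' direction along +y, plus a scalloped alveolar band below the tooth bases.
#' With \code{crowding}, the neighbours receive seeded rotations and offsets.
#' All teeth and the band are disjoint closed components, so the segment is
#' watertight and component volumes add.
#'
#' @param specs list of \code{\link{toothSpec}} (>= 3; the spec with
#'   \code{position == 0} is the test tooth).
#' @param crowding logical; jitter neighbour placement.
#' @param seed integer seed (bit-identical output per seed).
#' @return list with \code{mesh} (\linkS4class{TriangleMesh}), \code{labels}
#'   (named \linkS4class{RegionMask} list), \code{landmarks} (4 x 3 matrix),
#'   and \code{info} (placement table used to re-derive labels).
#' @export
generateArchSegment <- function(specs, crowding = FALSE, seed = 1L) {
  if (length(specs) < 3L)
    stop("need at least 3 teeth (test tooth flanked by intact neighbours)")
  pos <- vapply(specs, function(s) s$position, integer(1))
  if (sum(pos == 0L) != 1L) stop("exactly one spec must have position 0")
  ord <- order(pos)
  specs <- specs[ord]
  pos <- pos[ord]
  rng <- localSeed(seed, 7L)
  widths <- vapply(specs, function(s) s$mesiodistal, numeric(1))
  centers <- cumsum(c(0, (widths[-length(widths)] + widths[-1]) / 2 + 0.4))
  centers <- centers - centers[pos == 0L]
  meshes <- list()
  placements <- list()
  for (k in seq_along(specs)) {
    tooth <- generateTooth(specs[[k]])
    rotZ <- 0; dy <- 0; dz <- 0
    if (crowding && pos[k] != 0L) {
      rotZ <- rng$runif(1, -12, 12) * pi / 180
      dy <- rng$runif(1, -0.8, 0.8)
      dz <- rng$runif(1, -0.3, 0.3)
    }
    R <- rotationMatrix(c(0, 0, 1), rotZ)
    tr <- RigidTransform(R, c(centers[k], dy, dz))
    meshes[[k]] <- applyTransform(tooth, tr)
    placements[[k]] <- list(spec = specs[[k]], center = c(centers[k], dy, dz),
                            rotZ = rotZ, position = pos[k])
  }
  band <- makeAlveolarBand(range(centers) + c(-1, 1) * (max(widths) / 2 + 1.5),
                           max(vapply(specs, function(s) s$buccolingual, numeric(1))) / 2)
  mesh <- mergeMeshes(c(meshes, list(band)))
  info <- list(placements = placements, nTeeth = length(specs),
               crowding = crowding, seed = seed)
  labels <- labelArch(mesh, info)
  testSpec <- specs[[which(pos == 0L)]]
  landmarks <- rbind(
    cuspTip = c(0, 0, testSpec$crownHeight + 0.4),
    gingivalMid = c(0, -testSpec$buccolingual / 2 * 0.9, 0),
    mesial = c(-testSpec$mesiodistal / 2, 0, testSpec$crownHeight * 0.4),
    distal = c(testSpec$mesiodistal / 2, 0, testSpec$crownHeight * 0.4))
  list(mesh = mesh, labels = labels, landmarks = landmarks, info = info)
}

rotationMatrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# geometric labelling: assign components to teeth/band by centroid, then
# split the test tooth into crown/buccal/lingual in its local frame.
# Works identically on T0 and on the worn/retainered T1, so label indices
# never need to be remapped across topology changes.
labelArch <- function(mesh, info) {
  comp <- meshComponents(mesh)
  f <- mesh@faces
  nv <- nVertices(mesh)
  vcomp <- integer(nv)
  for (j in 1:3) vcomp[f[, j]] <- comp
  ncomp <- max(comp)
  centroids <- t(vapply(seq_len(ncomp), function(ci) {
    colMeans(mesh@vertices[vcomp == ci, , drop = FALSE])
  }, numeric(3)))
  toothC <- t(vapply(info$placements, function(p) p$center, numeric(3)))
  # the band is the component much below; teeth matched by x distance
  bandComp <- which.min(centroids[, 3])
  toothComp <- integer(nrow(toothC))
  for (k in seq_len(nrow(toothC))) {
    dx <- abs(centroids[, 1] - toothC[k, 1])
    dx[bandComp] <- Inf
    toothComp[k] <- which.min(dx)
  }
  posv <- vapply(info$placements, function(p) p$position, integer(1))
  testK <- which(posv == 0L)
  testComp <- toothComp[testK]
  spec <- info$placements[[testK]]$spec
  center <- info$placements[[testK]]$center
  v <- mesh@vertices
  isTest <- vcomp == testComp
  zLoc <- v[, 3] - center[3]
  yLoc <- v[, 2] - center[2]
  crown <- which(isTest & zLoc > 0)
  buccal <- which(isTest & zLoc > 0 & yLoc < -0.05 * spec$buccolingual)
  lingual <- which(isTest & zLoc > 0 & yLoc > 0.05 * spec$buccolingual)
  adjacent <- which(vcomp != testComp)
  labs <- list(
    crown = RegionMask("crown", crown, mesh),
    buccal = RegionMask("buccal", buccal, mesh),
    lingual = RegionMask("lingual", lingual, mesh),
    adjacent_intact = RegionMask("adjacent_intact", adjacent, mesh))
  for (k in seq_len(nrow(toothC))) {
    nm <- sprintf("tooth_%d", posv[k])
    idx <- which(vcomp == toothComp[k])
    labs[[nm]] <- RegionMask(nm, idx, mesh)
  }
  labs$band <- RegionMask("band", which(vcomp == bandComp), mesh)
  labs
}

#' Apply occlusal grinding to the test tooth
#'
#' Removes the occlusal region above a horizontal (symmetric) or tilted
#' (asymmetric) cut plane and reseals the tooth watertight; the removed solid
#' is capped as well and its volume -- exact for this construction -- is the
#' ground-truth removed volume.
#'
#' @param mesh arch-segment \linkS4class{TriangleMesh}.
#' @param toothMask \linkS4class{RegionMask} of the tooth to grind (vertex
#'   set of its component).
#' @param spec a \code{\link{wearSpec}}.
#' @return list with \code{mesh} (arch with the worn tooth),
#'   \code{removedVolume} (mm^3) and \code{removedMesh}.
#' @export
applyWear <- function(mesh, toothMask, spec) {
  if (spec$verticalLoss == 0)
    return(list(mesh = mesh, removedVolume = 0, removedMesh = NULL))
  comp <- meshComponents(mesh)
  inMask <- logical(nVertices(mesh))
  inMask[maskIndices(toothMask)] <- TRUE
  target <- comp[which(inMask[mesh@faces[, 1]])[1]]
  toothFaces <- which(comp == target)
  tooth <- subMesh(mesh, faces = toothFaces)
  rest <- subMesh(mesh, faces = which(comp != target))
  zTop <- max(tooth@vertices[, 3])
  zBase <- min(tooth@vertices[, 3])
  cx <- mean(range(tooth@vertices[, 1]))
  cy <- mean(range(tooth@vertices[, 2]))
  if (spec$verticalLoss >= zTop - max(0, zBase))
    stop("invalid wear spec: vertical loss >= crown height")
  n <- c(0, 0, 1)
  if (spec$pattern == "asymmetric") {
    n <- as.numeric(rotationMatrix(c(1, 0, 0), spec$tiltDeg * pi / 180) %*% n)
  }
  pl <- SlicePlane(c(cx, cy, zTop - spec$verticalLoss), n, "gingival")
  removed <- capOcclusalPart(tooth, list(pl))
  keptPlane <- SlicePlane(pl@point, -pl@normal, "gingival")
  worn <- capOcclusalPart(tooth, list(keptPlane))
  out <- mergeMeshes(list(rest, worn))
  attr(out, "vertexOffsets") <- NULL
  list(mesh = out, removedVolume = meshVolume(removed), removedMesh = removed)
}

# displacement amplitude of the retainer relief at lingual surface points;
# shared between applyRetainer and the footprint predicate so the composite
# footprint can be derived consistently on T0 and T1
retainerRelief <- function(x, z, spec, toothCenters, crownHeight) {
  zWire <- crownHeight * spec$wireHeightFrac
  wire <- spec$wireDiameter * exp(-((z - zWire)^2) / (2 * 0.25^2))
  blob <- 0
  for (cx in toothCenters) {
    blob <- pmax(blob, spec$blobHeight *
                   exp(-((x - cx)^2 + (z - zWire)^2) / (2 * (spec$blobRadius / 2)^2)))
  }
  pmax(wire, blob)
}

#' Simulate a bonded lingual retainer
#'
#' Adds the retainer relief (wire ridge plus composite blobs) to the lingual
#' surfaces of the listed teeth by displacing lingual vertices along their
#' outward normals. Buccal and occlusal vertices remain bit-identical and
#' mesh topology (hence watertightness) is preserved. The composite footprint
#' mask (displacement above 1 nm) is returned for the partial-crown
#' techniques; the same predicate applied to the unmodified T0 yields the
#' matching T0 footprint.
#'
#' @param mesh arch-segment \linkS4class{TriangleMesh}.
#' @param info arch placement info from \code{\link{generateArchSegment}}.
#' @param spec a \code{\link{retainerSpec}} (NULL leaves the mesh unchanged).
#' @param positions arch positions receiving the relief. The default (test
#'   tooth only) keeps the adjacent teeth intact, as required for a valid
#'   gold-standard reference; pass \code{c(-1L, 0L, 1L)} for a wire spanning
#'   the whole segment.
#' @return list with \code{mesh} and \code{footprint}
#'   (\linkS4class{RegionMask} of displaced vertices).
#' @export
applyRetainer <- function(mesh, info, spec, positions = 0L) {
  if (is.null(spec)) return(list(mesh = mesh, footprint = NULL))
  labs <- labelArch(mesh, info)
  posv <- vapply(info$placements, function(p) p$position, integer(1))
  testK <- which(posv == 0L)
  hCrown <- info$placements[[testK]]$spec$crownHeight
  sel <- which(posv %in% positions)
  toothCenters <- vapply(info$placements[sel], function(p) p$center[1],
                         numeric(1))
  # lingual vertices of the receiving teeth: positive local y, above margin
  v <- mesh@vertices
  lingAll <- integer(0)
  for (k in sel) {
    nm <- sprintf("tooth_%d", posv[k])
    idx <- maskIndices(labs[[nm]])
    ctr <- info$placements[[k]]$center
    bl <- info$placements[[k]]$spec$buccolingual
    lingAll <- c(lingAll, idx[v[idx, 2] - ctr[2] > 0.05 * bl &
                                v[idx, 3] - ctr[3] > 0])
  }
  amp <- retainerRelief(v[lingAll, 1], v[lingAll, 3], spec, toothCenters, hCrown)
  amp[amp <= 1e-6] <- 0  # below 1 nm: leave the vertex bit-identical
  vn <- vertexNormals(mesh)
  v2 <- v
  v2[lingAll, ] <- v[lingAll, ] + amp * vn[lingAll, , drop = FALSE]
  moved <- lingAll[amp > 0]
  if (!length(moved)) stop("retainer placement error: relief touches no lingual vertex")
  out <- mesh
  out@vertices <- v2
  list(mesh = out, footprint = RegionMask("composite", moved, out))
}

#' Apply scanner noise
#'
#' Displaces every vertex along its normal by zero-mean Gaussian noise,
#' clamped at \code{maxDev}; topology is unchanged. Deterministic per seed.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param spec a \code{\link{scanNoiseSpec}}.
#' @param seed integer seed.
#' @return the noisy mesh.
#' @export
applyScanNoise <- function(mesh, spec, seed = 1L) {
  if (spec$sd == 0) return(mesh)
  rng <- localSeed(seed, 23L)
  disp <- rng$rnorm(nVertices(mesh), sd = spec$sd / sqrt(2))
  disp <- pmax(pmin(disp, spec$maxDev / 2), -spec$maxDev / 2)
  out <- mesh
  out@vertices <- mesh@vertices + disp * vertexNormals(mesh)
  out
}

randomRigidDisplacement <- function(rng, maxRotDeg = 15, maxTrans = 10) {
  ax <- rng$rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- rng$runif(1, 0.3, 1) * maxRotDeg * pi / 180
  tr <- rng$runif(3, -maxTrans, maxTrans)
  RigidTransform(rotationMatrix(ax, ang), tr)
}

#' Build one synthetic wear case
#'
#' T0 is the pristine arch segment; T1 derives from it by grinding the test
#' tooth, adding the retainer relief to the lingual surfaces, and applying an
#' independent scan-noise realisation, then moving the whole model to a
#' random initial pose (rotation <= 15 degrees, translation <= 10 mm) so the
#' registration is always exercised. T0 receives its own noise realisation.
#' Labels are derived geometrically on each mesh in the canonical frame.
#'
#' @param id case identifier.
#' @param toothType "incisor" or "canine".
#' @param loss vertical loss, mm.
#' @param pattern "symmetric" or "asymmetric".
#' @param crowding logical.
#' @param seed integer seed.
#' @param resolution triangle target per tooth.
#' @param noise a \code{\link{scanNoiseSpec}}, or NULL for noise-free.
#' @param retainer a \code{\link{retainerSpec}}, or NULL for none.
#' @return a \linkS4class{WearCase}.
#' @export
makeWearCase <- function(id, toothType = "incisor", loss = 1,
                         pattern = "symmetric", crowding = FALSE, seed = 1L,
                         resolution = 8000L, noise = scanNoiseSpec(),
                         retainer = retainerSpec()) {
  specs <- list(
    toothSpec(if (toothType == "incisor") "canine" else "incisor",
              position = -1L, resolution = resolution),
    toothSpec(toothType, position = 0L, resolution = resolution),
    toothSpec("incisor", position = 1L, resolution = resolution))
  arch <- generateArchSegment(specs, crowding = crowding, seed = seed)
  t0 <- arch$mesh
  t0Labels <- arch$labels
  worn <- applyWear(t0, t0Labels$tooth_0, wearSpec(loss, pattern))
  ret <- applyRetainer(worn$mesh, arch$info, retainer)
  t1 <- ret$mesh
  t1Labels <- labelArch(t1, arch$info)
  t1Labels$composite <- ret$footprint
  # matching T0 footprint: same relief predicate on the pristine lingual
  if (!is.null(retainer)) {
    lIdx <- maskIndices(t0Labels$lingual)
    amp0 <- retainerRelief(t0@vertices[lIdx, 1], t0@vertices[lIdx, 3],
                           retainer,
                           vapply(arch$info$placements, function(p) p$center[1],
                                  numeric(1)),
                           specs[[2]]$crownHeight)
    t0Labels$composite <- RegionMask("composite", lIdx[amp0 > 1e-6], t0)
  }
  rng <- localSeed(seed, 41L)
  if (!is.null(noise)) {
    s0 <- (as.numeric(seed) * 2 + 1) %% 2147483629
    t0 <- applyScanNoise(t0, noise, seed = s0)
    t1 <- applyScanNoise(t1, noise, seed = s0 + 1)
  }
  pose <- randomRigidDisplacement(rng)
  t1 <- applyTransform(t1, pose)
  t1Landmarks <- applyTransform(arch$landmarks, pose)
  new("WearCase", id = as.character(id), t0 = t0, t1 = t1,
      t0Labels = t0Labels, t1Labels = t1Labels,
      t0Landmarks = arch$landmarks, t1Landmarks = t1Landmarks,
      trueRemovedVolume = worn$removedVolume,
      info = list(toothType = toothType, verticalLoss = loss,
                  pattern = pattern, crowding = crowding, seed = seed,
                  resolution = resolution,
                  noise = noise, retainer = retainer, pose = pose))
}

#' Build the synthetic validation benchmark
#'
#' A balanced set of cases mirroring the validation design: incisors and
#' canines, vertical losses of 0.5/1/2 mm, symmetric and asymmetric grinding,
#' an even crowding mix, a lingual retainer on every case, and independent
#' scan noise for T0 and T1. Deterministic per seed.
#'
#' @param nIncisors,nCanines cases per tooth type (validation set: 18 + 18).
#' @param lossLevels vertical loss levels, mm.
#' @param patterns grinding patterns.
#' @param crowdingMix fraction of cases with crowded neighbours.
#' @param seed integer seed.
#' @param resolution triangle target per tooth.
#' @param noise scan-noise spec (NULL for noise-free).
#' @param retainer retainer spec (NULL for none).
#' @return list of \linkS4class{WearCase}; the manifest data.frame is
#'   attached as attribute \code{"manifest"}.
#' @export
buildBenchmark <- function(nIncisors = 18L, nCanines = 18L,
                           lossLevels = c(0.5, 1, 2),
                           patterns = c("symmetric", "asymmetric"),
                           crowdingMix = 0.5, seed = 1L, resolution = 8000L,
                           noise = scanNoiseSpec(), retainer = retainerSpec()) {
  stopifnot(nIncisors >= 1L || nCanines >= 1L)
  plan <- list()
  for (tt in c("incisor", "canine")) {
    n <- if (tt == "incisor") nIncisors else nCanines
    for (i in seq_len(n)) {
      plan[[length(plan) + 1L]] <- list(
        toothType = tt,
        loss = lossLevels[(i - 1L) %% length(lossLevels) + 1L],
        pattern = patterns[((i - 1L) %/% length(lossLevels)) %% length(patterns) + 1L],
        crowding = (i %% round(1 / max(crowdingMix, 1e-9))) == 0 & crowdingMix > 0)
    }
  }
  cases <- vector("list", length(plan))
  manifest <- data.frame(caseId = character(0), toothType = character(0),
                         loss = numeric(0), pattern = character(0),
                         crowding = logical(0), trueVolume = numeric(0))
  for (k in seq_along(plan)) {
    p <- plan[[k]]
    id <- sprintf("case_%02d_%s_%g_%s", k, p$toothType, p$loss,
                  substr(p$pattern, 1, 3))
    caseSeed <- (as.numeric(seed) %% 100000) * 1000 + k
    cases[[k]] <- makeWearCase(id, p$toothType, p$loss, p$pattern, p$crowding,
                               seed = caseSeed, resolution = resolution,
                               noise = noise, retainer = retainer)
    manifest <- rbind(manifest, data.frame(
      caseId = id, toothType = p$toothType, loss = p$loss,
      pattern = p$pattern, crowding = p$crowding,
      trueVolume = cases[[k]]@trueRemovedVolume))
  }
  attr(cases, "manifest") <- manifest
  cases
}
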