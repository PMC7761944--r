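# From a superimposed T0/T1 crown pair: signed distance maps, automatic
# slice-plane placement, identical plane slicing of both crowns, splitting of
# non-planar hole boundaries into planar loops, ear-clipping cap fill, and
# the wear volume as the difference of the watertight occlusal parts.

#' Signed per-vertex distance map
#'
#' For each source (baseline) vertex, the distance to the exact closest point
#' on the target (follow-up) surface, signed by the target normal at that
#' point: positive where the follow-up surface lies outside the baseline
#' (added material), negative where it lies inside (wear). The sign is a pure
#' convention; the workflow consumes magnitudes.
#'
#' @param source,target \linkS4class{TriangleMesh} objects.
#' @return numeric vector of signed distances (mm), one per source vertex.
#' @export
distanceMap <- function(source, target) {
  if (!nFaces(target)) stop("empty target mesh")
  corr <- findCorrespondences(source@vertices, target,
                              excludeOverhangs = FALSE)
  s <- sign(rowSums((corr$point - source@vertices) * corr$normal))
  s[s == 0] <- 1
  s * corr$distance
}

planeDistances <- function(vertices, plane) {
  as.numeric((vertices - matrix(plane@point, nrow(vertices), 3,
                                byrow = TRUE)) %*% plane@normal)
}

#' Slice a mesh with planes, keeping the occlusal side
#'
#' Keeps the intersection of the positive half-spaces of the planes.
#' Triangles crossing a plane are split exactly at the plane: new boundary
#' vertices are projected onto the plane so their signed distance is below
#' 1e-9 mm, and split points are shared across neighbouring triangles so the
#' cut stays sewn.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param planes list of \linkS4class{SlicePlane}.
#' @return the open occlusal part, with attribute \code{"origVertex"} (index
#'   into the input mesh, NA for vertices created on a plane).
#' @export
sliceWithPlanes <- function(mesh, planes) {
  orig <- seq_len(nVertices(mesh))
  part <- mesh
  for (pl in planes) {
    part <- clipHalfSpace(part, pl)
    orig <- orig[attr(part, "parentVertex")]
    orig[is.na(attr(part, "parentVertex"))] <- NA
    # parentVertex indexes the previous part; NA marks plane-created vertices
  }
  if (!nFaces(part))
    stop("empty part: the planes leave no occlusal geometry")
  attr(part, "origVertex") <- orig
  part
}

clipHalfSpace <- function(mesh, plane, snapTol = 1e-12) {
  v <- mesh@vertices
  f <- mesh@faces
  d <- planeDistances(v, plane)
  d[abs(d) < snapTol] <- 0
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  allKeep <- s1 >= 0 & s2 >= 0 & s3 >= 0 & (s1 > 0 | s2 > 0 | s3 > 0)
  allDrop <- (s1 <= 0 & s2 <= 0 & s3 <= 0)
  mixed <- which(!allKeep & !allDrop)
  keptFaces <- f[allKeep, , drop = FALSE]
  newV <- list()
  newF <- list()
  edgeCache <- new.env(hash = TRUE)
  nv <- nrow(v)
  nNew <- 0L
  cutPoint <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    hit <- edgeCache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p <- p - sum((p - plane@point) * plane@normal) * plane@normal  # exact on-plane
    nNew <<- nNew + 1L
    newV[[nNew]] <<- p
    idx <- nv + nNew
    edgeCache[[key]] <- idx
    idx
  }
  for (fi in mixed) {
    tri <- f[fi, ]
    dd <- d[tri]
    poly <- integer(0)
    for (k in 1:3) {
      i <- tri[k]; j <- tri[(k %% 3L) + 1L]
      if (dd[k] >= 0) poly <- c(poly, i)
      if (dd[k] * dd[(k %% 3L) + 1L] < 0) poly <- c(poly, cutPoint(i, j))
    }
    if (length(poly) >= 3) {
      for (k in 2:(length(poly) - 1L))
        newF[[length(newF) + 1L]] <- c(poly[1], poly[k], poly[k + 1L])
    }
  }
  V <- rbind(v, do.call(rbind, newV))
  F2 <- rbind(keptFaces,
              if (length(newF)) do.call(rbind, newF) else NULL)
  # drop unreferenced vertices, remembering parents
  used <- sort(unique(as.integer(F2)))
  map <- integer(nrow(V))
  map[used] <- seq_along(used)
  out <- TriangleMesh(V[used, , drop = FALSE],
                      if (length(F2)) matrix(map[F2], ncol = 3) else matrix(0L, 0, 3),
                      dropDegenerate = FALSE)
  parent <- used
  parent[parent > nv] <- NA_integer_
  attr(out, "parentVertex") <- parent
  out
}

#' Split a non-planar hole boundary into planar loops
#'
#' A boundary loop produced by slicing with a single plane is returned
#' unchanged. A loop spanning several planes is split at the junction
#' vertices lying on two planes simultaneously: chords along the intersection
#' lines of adjacent slicing planes close each single-plane arc, so every
#' output loop is planar within tolerance and identical chords (in opposite
#' directions) keep adjacent caps sewn.
#'
#' @param loop integer vector: an ordered boundary vertex cycle of
#'   \code{part}.
#' @param planes list of \linkS4class{SlicePlane} used for the slicing.
#' @param part the sliced \linkS4class{TriangleMesh} the loop indexes into.
#' @param tol planarity tolerance in mm (default 1e-6).
#' @return list of integer vertex cycles, each planar within \code{tol}.
#' @export
splitHole <- function(loop, planes, part, tol = 1e-6) {
  v <- part@vertices[loop, , drop = FALSE]
  onPlane <- vapply(planes, function(pl) abs(planeDistances(v, pl)) < tol,
                    logical(length(loop)))
  onPlane <- matrix(onPlane, nrow = length(loop))
  whole <- which(colSums(onPlane) == length(loop))
  if (length(whole)) return(list(loop))
  nOn <- rowSums(onPlane)
  if (any(nOn == 0))
    stop("topology error: loop vertex lies on no slicing plane")
  junction <- nOn >= 2
  if (sum(junction) < 2)
    stop("topology error: non-planar loop without junction vertices")
  # rotate so the loop starts at a junction
  st <- which(junction)[1]
  ordIdx <- c(st:length(loop), seq_len(st - 1L))
  loop2 <- loop[ordIdx]
  onP2 <- onPlane[ordIdx, , drop = FALSE]
  junc2 <- junction[ordIdx]
  # split into arcs at junctions; each arc must lie on a single plane
  jpos <- which(junc2)
  arcs <- list()
  for (k in seq_along(jpos)) {
    from <- jpos[k]
    if (k < length(jpos)) {
      pos <- from:jpos[k + 1L]
    } else {
      pos <- c(from:length(loop2), 1L)  # wrap to the starting junction
    }
    common <- which(colSums(onP2[pos, , drop = FALSE]) == length(pos))
    if (!length(common))
      stop("topology error: arc does not lie on a single plane")
    arcs[[length(arcs) + 1L]] <- list(vertices = loop2[pos], plane = common[1])
  }
  # close arcs per plane; chain multiple arcs on one plane through chords
  planesUsed <- vapply(arcs, function(a) a$plane, integer(1))
  out <- list()
  for (pl in unique(planesUsed)) {
    mine <- arcs[planesUsed == pl]
    if (length(mine) == 1L) {
      cyc <- mine[[1]]$vertices
      # the closing chord (end junction -> start junction) is implicit
      if (cyc[1] == cyc[length(cyc)]) cyc <- cyc[-length(cyc)]
      out[[length(out) + 1L]] <- cyc
    } else {
      # chain arcs: the chord from one arc's end junction must stay on an
      # intersection line, i.e. connect to an arc start lying on the same
      # pair of planes
      remaining <- mine
      cyc <- remaining[[1]]$vertices
      last <- remaining[[1]]
      remaining <- remaining[-1]
      guard <- 0L
      while (length(remaining)) {
        guard <- guard + 1L
        if (guard > 64L) stop("topology error: cannot chain arcs into planar loops")
        endVertex <- cyc[length(cyc)]
        endPlanes <- which(onPlane[match(endVertex, loop), ])
        nxt <- NULL
        for (ri in seq_along(remaining)) {
          sv <- remaining[[ri]]$vertices[1]
          svPlanes <- which(onPlane[match(sv, loop), ])
          if (length(intersect(setdiff(endPlanes, pl), setdiff(svPlanes, pl)))) {
            nxt <- ri
            break
          }
        }
        if (is.null(nxt)) stop("topology error: cannot chain arcs into planar loops")
        cyc <- c(cyc, remaining[[nxt]]$vertices)
        remaining <- remaining[-nxt]
      }
      cyc <- cyc[!duplicated(cyc)]
      out[[length(out) + 1L]] <- cyc
    }
  }
  # planarity check on every output loop
  for (cyc in out) {
    pv <- part@vertices[cyc, , drop = FALSE]
    ok <- any(vapply(planes, function(pl) all(abs(planeDistances(pv, pl)) < tol),
                     logical(1)))
    if (!ok) stop("topology error: split produced a non-planar loop")
  }
  out
}

# Newell normal of a 3D polygon
polygonNormal <- function(P) {
  Q <- rbind(P[-1, , drop = FALSE], P[1, , drop = FALSE])
  n <- c(sum((P[, 2] - Q[, 2]) * (P[, 3] + Q[, 3])),
         sum((P[, 3] - Q[, 3]) * (P[, 1] + Q[, 1])),
         sum((P[, 1] - Q[, 1]) * (P[, 2] + Q[, 2])))
  len <- sqrt(sum(n^2))
  if (len == 0) stop("geometry error: degenerate polygon")
  n / len
}

# ear-clipping triangulation of a planar polygon given as 2D coordinates
# (CCW); returns index triples into the polygon
earClip2D <- function(x, y) {
  n <- length(x)
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  area2 <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  eps <- 1e-12 * scale2
  guard <- 0L
  while (length(idx) > 3L) {
    guard <- guard + 1L
    if (guard > 4L * n)
      stop("geometry error: cannot triangulate cap polygon (self-intersecting?)")
    m <- length(idx)
    clipped <- FALSE
    for (strict in c(TRUE, FALSE)) {
      for (k in seq_len(m)) {
        a <- idx[(k - 2L) %% m + 1L]
        b <- idx[(k - 1L) %% m + 1L]
        c3 <- idx[k %% m + 1L]
        cr <- area2(x[a], y[a], x[b], y[b], x[c3], y[c3])
        if (strict && cr <= eps) next
        if (!strict && cr < -eps) next
        # no other polygon vertex strictly inside
        others <- setdiff(idx, c(a, b, c3))
        inside <- FALSE
        if (abs(cr) > eps) {
          for (o in others) {
            w1 <- area2(x[a], y[a], x[b], y[b], x[o], y[o])
            w2 <- area2(x[b], y[b], x[c3], y[c3], x[o], y[o])
            w3 <- area2(x[c3], y[c3], x[a], y[a], x[o], y[o])
            if (w1 > -eps && w2 > -eps && w3 > -eps) { inside <- TRUE; break }
          }
        }
        if (inside) next
        tris <- rbind(tris, c(a, b, c3))
        idx <- idx[idx != b]
        clipped <- TRUE
        break
      }
      if (clipped) break
    }
    if (!clipped)
      stop("geometry error: cannot triangulate cap polygon (self-intersecting?)")
  }
  rbind(tris, idx)
}

#' Cap planar hole loops to make a part watertight
#'
#' Each planar loop is triangulated in its plane by ear clipping and the cap
#' is oriented to match the part's outward convention (the cap traverses each
#' boundary edge opposite to its single incident surface face). The enclosed
#' volume is independent of the particular cap triangulation because all cap
#' triangles lie in one plane.
#'
#' @param part an open \linkS4class{TriangleMesh} (sliced crown part).
#' @param planarLoops list of planar vertex cycles, ordered as produced by
#'   \code{\link{boundaryLoops}} / \code{\link{splitHole}}.
#' @return a watertight TriangleMesh.
#' @export
fillHoles <- function(part, planarLoops) {
  caps <- list()
  for (loop in planarLoops) {
    cyc <- rev(loop)  # cap opposes the surface boundary direction
    P <- part@vertices[cyc, , drop = FALSE]
    nrm <- polygonNormal(P)
    e1 <- c(nrm[2], -nrm[1], 0)
    if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    xx <- as.numeric(P %*% e1)
    yy <- as.numeric(P %*% e2)
    tris <- earClip2D(xx, yy)
    caps[[length(caps) + 1L]] <- matrix(cyc[tris], ncol = 3)
  }
  TriangleMesh(part@vertices, rbind(part@faces, do.call(rbind, caps)),
               dropDegenerate = FALSE)
}

#' Propose slicing planes isolating the occlusal change
#'
#' Places the gingival plane (normal along the occlusal axis) at an offset
#' below the lowest point of the occlusal changed region, so the changed
#' region is entirely on the occlusal side, then verifies that along the
#' plane's cut line the two models differ by less than
#' \code{distanceThreshold} (the numeric counterpart of the operator's
#' colour-coded distance-map check). Mesial/distal planes are added only when
#' the cut-line check fails at the crown's proximal ends. Fails when the
#' changed region cannot be isolated above the gingival limit.
#'
#' @param t0Crown,t1Crown superimposed \linkS4class{TriangleMesh} crowns (T1
#'   already aligned to T0).
#' @param distanceThreshold changed-region / edge-check threshold in mm
#'   (default 0.05).
#' @param offset distance (mm) below the changed region at which the gingival
#'   plane is placed (default 0.2).
#' @param axis occlusal axis (+z in the synthetic frame).
#' @param gingivalLimit lowest admissible plane offset along the axis (e.g.
#'   the gingival boundary of the crown mask); NULL disables the check.
#' @return list of 1 to 3 \linkS4class{SlicePlane}.
#' @export
proposeSlicePlanes <- function(t0Crown, t1Crown, distanceThreshold = 0.05,
                               offset = 0.2, axis = c(0, 0, 1),
                               gingivalLimit = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  # changed regions are detected on BOTH models: a ground facet carries few
  # or no off-surface vertices on the worn model itself, so a single-sided
  # vertex distance map would miss it when the roles are swapped
  sides <- list(list(mesh = t0Crown, other = t1Crown),
                list(mesh = t1Crown, other = t0Crown))
  for (k in 1:2) {
    s <- sides[[k]]
    s$d <- distanceMap(s$mesh, s$other)
    s$z <- as.numeric(s$mesh@vertices %*% axis)
    s$changed <- abs(s$d) > distanceThreshold
    sides[[k]] <- s
  }
  centroid <- colMeans(t0Crown@vertices)
  planeAt <- function(zc) {
    SlicePlane(centroid + (zc - sum(centroid * axis)) * axis, axis, "gingival")
  }
  z <- sides[[1]]$z
  if (!any(sides[[1]]$changed) && !any(sides[[2]]$changed)) {
    # unchanged pair: default to an occlusal part comparable to the parts
    # measured on worn cases (a slice ~2.5 mm below the occlusal extreme),
    # not a mid-crown cut through the widest cross-section
    zc <- max(z) - 2.5
    if (!is.null(gingivalLimit)) zc <- max(zc, gingivalLimit + 0.5)
    zc <- min(zc, mean(range(z)) + 0.25 * diff(range(z)))
    return(list(planeAt(zc)))
  }
  # the occlusal wear patch is the connected changed component (on whichever
  # model shows it) containing the topmost changed point; other changed
  # patches (e.g. a retainer relief) sit further gingivally
  tops <- vapply(sides, function(s)
    if (any(s$changed)) max(s$z[s$changed]) else -Inf, numeric(1))
  w <- which.max(tops)
  sw <- sides[[w]]
  comp <- changedComponents(sw$mesh, sw$changed)
  topIdx <- which.max(ifelse(sw$changed, sw$z, -Inf))
  patchOf <- vector("list", 2)
  patchOf[[w]] <- comp == comp[topIdx] & sw$changed
  patchOf[[3 - w]] <- rep(FALSE, length(sides[[3 - w]]$changed))
  zPatchMin <- min(sw$z[patchOf[[w]]])
  otherZ <- c(sides[[1]]$z[sides[[1]]$changed & !patchOf[[1]]],
              sides[[2]]$z[sides[[2]]$changed & !patchOf[[2]]])
  # changed points on the other model that belong to the wear region (above
  # the patch floor) are part of the patch, not obstacles
  otherZ <- otherZ[otherZ < zPatchMin]
  zCut <- zPatchMin - offset
  if (length(otherZ)) {
    zOther <- max(otherZ)
    if (zOther >= zCut) {
      # squeeze the plane between wear patch and the other changed region
      zCut <- (zPatchMin + zOther) / 2
      if (zCut > zPatchMin - 0.01 || zOther >= zCut)
        stop("cannot-isolate error: changed regions cannot be separated by a gingival plane")
    }
  }
  if (!is.null(gingivalLimit) && zCut <= gingivalLimit)
    stop("cannot-isolate error: changed region reaches the gingival mask boundary")
  planes <- list(planeAt(zCut))
  badPts <- do.call(rbind, lapply(sides, function(s) {
    s$mesh@vertices[cutLineViolations(s$z, s$d, zCut, distanceThreshold), ,
                    drop = FALSE]
  }))
  if (!is.null(badPts) && nrow(badPts)) {
    # offending points at the proximal ends can be excluded by vertical
    # mesial/distal planes; otherwise the case cannot be isolated
    xAxis <- proximalAxis(axis)
    xc <- sum(centroid * xAxis)
    allX <- as.numeric(t0Crown@vertices %*% xAxis)
    halfW <- max(abs(allX - xc))
    offX <- abs(as.numeric(badPts %*% xAxis) - xc)
    if (all(offX > 0.6 * halfW)) {
      inner <- 0.95 * min(offX)
      planes <- c(planes,
                  list(SlicePlane(centroid + (xc + inner - sum(centroid * xAxis)) * xAxis,
                                  -xAxis, "distal"),
                       SlicePlane(centroid + (xc - inner - sum(centroid * xAxis)) * xAxis,
                                  xAxis, "mesial")))
    } else {
      stop("cannot-isolate error: models differ along the slicing edge")
    }
  }
  planes
}

cutLineViolations <- function(z, d, zCut, thr, band = 0.15) {
  abs(z - zCut) < band & abs(d) > thr
}

proximalAxis <- function(axis) {
  # mesiodistal direction: the frame's x axis projected off the occlusal axis
  e <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  if (sum(e^2) < 1e-12) e <- c(0, 1, 0) - sum(c(0, 1, 0) * axis) * axis
  e / sqrt(sum(e^2))
}

changedComponents <- function(mesh, changed) {
  n <- nVertices(mesh)
  f <- mesh@faces
  ed <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  keep <- changed[ed[, 1]] & changed[ed[, 2]]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(keep)) g <- igraph::add_edges(g, t(ed[keep, , drop = FALSE]))
  igraph::components(g)$membership
}

# slice + split + fill + check, shared by both crowns
capOcclusalPart <- function(mesh, planes) {
  part <- sliceWithPlanes(mesh, planes)
  loops <- boundaryLoops(part)
  planar <- list()
  for (lp in loops) planar <- c(planar, splitHole(lp, planes, part))
  closed <- fillHoles(part, planar)
  if (!isWatertight(closed))
    stop("watertight check failed after hole filling (",
         length(loops), " loops, ", length(planes), " planes)")
  closed
}

#' Measure occlusal wear volume for one case
#'
#' The complete workflow: run the superimposition technique, move the T1
#' model into the T0 frame, isolate the test tooth, propose slicing planes
#' from the signed distance map, slice both crowns with the identical planes,
#' split and fill the hole boundaries identically, verify watertightness, and
#' report \code{wear = V(T0 part) - V(T1 part)} in mm^3 (material loss
#' positive; added material never enters because the planes are verified to
#' cut through unchanged geometry).
#'
#' @param t0Model,t1Model arch-segment \linkS4class{TriangleMesh} models.
#' @param t0Labels,t1Labels named lists of \linkS4class{RegionMask}; both
#'   need \code{crown} (the test tooth), T0 additionally the technique's
#'   reference labels.
#' @param technique a \linkS4class{TechniqueSpec} or id string.
#' @param landmarks list with 4 x 3 matrices \code{t0}, \code{t1}.
#' @param seed integer seed.
#' @param distanceThreshold plane placement / edge check threshold (mm).
#' @param settings base \linkS4class{ICPSettings}.
#' @param planeOffset gingival plane offset below the changed region (mm).
#' @param axis occlusal axis in the T0 frame.
#' @param keepIntermediates attach the intermediate meshes (isolated crowns,
#'   aligned T1 crown with distance-map field, capped parts) as attribute
#'   \code{"intermediates"} for export/inspection.
#' @return a \linkS4class{WearMeasurement}.
#' @export
measureWear <- function(t0Model, t1Model, t0Labels, t1Labels, technique,
                        landmarks, seed = 1L, distanceThreshold = 0.05,
                        settings = ICPSettings(), planeOffset = 0.2,
                        axis = c(0, 0, 1), keepIntermediates = FALSE) {
  if (is.character(technique)) technique <- techniqueSpec(technique)
  reg <- runTechnique(t0Model, t1Model, t0Labels, technique, landmarks,
                      seed = seed, settings = settings)
  inv <- invertTransform(reg@transform)
  t0Tooth <- toothComponent(t0Model, t0Labels$crown)
  t1Tooth <- applyTransform(toothComponent(t1Model, t1Labels$crown), inv)
  crownZ <- t0Model@vertices[maskIndices(t0Labels$crown), , drop = FALSE] %*% axis
  planes <- proposeSlicePlanes(t0Tooth, t1Tooth,
                               distanceThreshold = distanceThreshold,
                               offset = planeOffset, axis = axis,
                               gingivalLimit = min(crownZ))
  part0 <- capOcclusalPart(t0Tooth, planes)
  part1 <- capOcclusalPart(t1Tooth, planes)
  v0 <- meshVolume(part0)
  v1 <- meshVolume(part1)
  d <- distanceMap(t0Tooth, t1Tooth)
  out <- new("WearMeasurement", techniqueId = technique@id,
             t0PartVolume = v0, t1PartVolume = v1, wearVolume = v0 - v1,
             planes = planes,
             watertight = c(t0 = TRUE, t1 = TRUE),
             registration = reg,
             distances = d)
  if (keepIntermediates) {
    vertexField(t0Tooth) <- d  # distance map rides on the T0 crown (PLY "quality")
    attr(out, "intermediates") <- list(t0Crown = t0Tooth,
                                       t1CrownAligned = t1Tooth,
                                       t0Part = part0, t1Part = part1)
  }
  out
}

# sub-mesh of the connected component holding a vertex mask
toothComponent <- function(mesh, crownMask) {
  comp <- meshComponents(mesh)
  inMask <- logical(nVertices(mesh))
  inMask[maskIndices(crownMask)] <- TRUE
  hits <- comp[inMask[mesh@faces[, 1]]]
  if (!length(hits)) stop("crown mask touches no face")
  target <- as.integer(names(which.max(table(hits))))
  subMesh(mesh, faces = which(comp == target))
}
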