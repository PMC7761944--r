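# Mesh topology, watertightness, volume, components and rigid transforms.

# row-wise cross product of n x 3 matrices
vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rotationAngle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# directed edges of all faces, as a 3m x 2 matrix (u -> v in traversal order)
directedEdges <- function(mesh) {
  f <- mesh@faces
  rbind(cbind(f[, 1], f[, 2]),
        cbind(f[, 2], f[, 3]),
        cbind(f[, 3], f[, 1]))
}

edgeKeys <- function(edges, n) {
  # undirected key; n = vertex count, numeric to avoid integer overflow
  pmin(edges[, 1], edges[, 2]) * (n + 1) + pmax(edges[, 1], edges[, 2])
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight (closed and 2-manifold) when every edge is shared by
#' exactly two faces traversed in opposite directions. Multiple disjoint
#' closed components still count as watertight; their volumes add.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return TRUE or FALSE.
#' @export
isWatertight <- function(mesh) {
  if (!nFaces(mesh)) return(FALSE)
  de <- directedEdges(mesh)
  n <- nVertices(mesh)
  keys <- edgeKeys(de, n)
  cnt <- table(keys)
  if (any(cnt != 2L)) return(FALSE)
  # opposite traversal: each directed edge appears exactly once
  dkeys <- de[, 1] * (n + 1) + de[, 2]
  !anyDuplicated(dkeys)
}

#' Extract ordered boundary loops
#'
#' Boundary edges are edges with exactly one incident face. They are chained
#' into closed cycles following the incident faces' traversal direction;
#' loops partition all boundary edges. A closed mesh returns an empty list.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return list of integer vectors, each an ordered cycle of vertex indices.
#' @export
boundaryLoops <- function(mesh) {
  de <- directedEdges(mesh)
  n <- nVertices(mesh)
  keys <- edgeKeys(de, n)
  cnt <- table(keys)
  if (any(cnt > 2L)) stop("non-manifold edge: more than two incident faces")
  bkeys <- names(cnt)[cnt == 1L]
  if (!length(bkeys)) return(list())
  isB <- as.character(keys) %in% bkeys
  be <- de[isB, , drop = FALSE]
  # successor map along directed boundary edges
  succ <- integer(n)
  if (anyDuplicated(be[, 1]))
    stop("non-manifold boundary vertex (branching boundary)")
  succ[be[, 1]] <- be[, 2]
  visited <- rep(FALSE, nrow(be))
  names(visited) <- be[, 1]
  loops <- list()
  starts <- be[, 1]
  seen <- rep(FALSE, n)
  for (s in starts) {
    if (seen[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      seen[v] <- TRUE
      v <- succ[v]
      if (v == 0L) stop("open boundary chain: boundary is not a set of cycles")
      if (v == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem: the sum of signed tetrahedra from
#' the origin to each face. Positive for outward-oriented closed surfaces and
#' invariant under rigid motion; for multi-component watertight meshes the
#' component volumes add.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  if (!isWatertight(mesh))
    stop("mesh is not watertight: volume undefined")
  signedMeshVolume(mesh)
}

# no watertightness check; used internally where closure is known
signedMeshVolume <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * vcross(b, c3))) / 6
}

#' Weld duplicate vertices
#'
#' Merges vertices whose coordinates coincide within \code{tol} (default
#' 1e-9 mm: exact-duplicate welding only, so fine wire geometry is never
#' accidentally merged). STL stores a triangle soup, so welding is applied on
#' import. Welding is idempotent.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param tol coordinate tolerance in mm.
#' @return a welded TriangleMesh.
#' @export
weldVertices <- function(mesh, tol = 1e-9) {
  v <- mesh@vertices
  if (!nrow(v)) return(mesh)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newV <- v[first, , drop = FALSE]
  newF <- matrix(map[mesh@faces], ncol = 3)
  fld <- if (length(mesh@field)) mesh@field[first] else numeric(0)
  TriangleMesh(newV, newF, field = fld)
}

#' Apply a rigid transform
#'
#' @param x a \linkS4class{TriangleMesh} or an n x 3 point matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @return object of the same kind, transformed.
#' @export
applyTransform <- function(x, transform) {
  R <- transform@rotation
  t <- transform@translation
  if (is(x, "TriangleMesh")) {
    v <- x@vertices %*% t(R)
    v <- sweep(v, 2, t, "+")
    out <- x
    out@vertices <- v
    return(out)
  }
  p <- matrix(as.numeric(x), ncol = 3)
  sweep(p %*% t(R), 2, t, "+")
}

#' Compose rigid transforms
#'
#' \code{composeTransforms(a, b)} returns the transform applying \code{b}
#' first, then \code{a}.
#' @param a,b RigidTransform objects.
#' @return a RigidTransform.
#' @export
composeTransforms <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param transform a RigidTransform.
#' @return its inverse.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Serialize / read a transform as a 4 x 4 row-major matrix
#'
#' @param transform a RigidTransform.
#' @param path plain-text file path.
#' @return \code{readTransform} returns a RigidTransform.
#' @export
writeTransform <- function(transform, path) {
  M <- rbind(cbind(transform@rotation, transform@translation), c(0, 0, 0, 1))
  writeLines(apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  M <- unname(as.matrix(read.table(path)))
  RigidTransform(M[1:3, 1:3], M[1:3, 4])
}

#' Per-face and per-vertex normals
#'
#' Face normals are unit normals of the triangle planes (outward for
#' consistently oriented meshes); vertex normals are area-weighted averages,
#' used by the scan-noise model and distance-map signing.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return an n x 3 (or m x 3) matrix of unit normals.
#' @export
faceNormals <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  n <- vcross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
              v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname faceNormals
#' @export
vertexNormals <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  fn <- vcross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
               v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])  # area-weighted
  vn <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    vn[, 1] <- vn[, 1] + tabulateSum(f[, j], fn[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulateSum(f[, j], fn[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulateSum(f[, j], fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tabulateSum <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Connected components of a mesh
#'
#' Faces are connected when they share a vertex. Used to isolate single teeth
#' from an arch segment.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return integer vector of component ids, one per face.
#' @export
meshComponents <- function(mesh) {
  f <- mesh@faces
  n <- nVertices(mesh)
  g <- igraph::graph_from_edgelist(
    rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comp <- memb[f[, 1]]
  match(comp, unique(comp))
}

#' Extract a sub-mesh by faces or vertices
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param faces face indices to keep; or
#' @param vertices vertex indices (keeps faces with all three vertices in the
#'   set).
#' @return a TriangleMesh with attribute \code{"origVertex"}: for each new
#'   vertex, its index in the input mesh.
#' @export
subMesh <- function(mesh, faces = NULL, vertices = NULL) {
  if (is.null(faces)) {
    keep <- rep(FALSE, nVertices(mesh))
    keep[vertices] <- TRUE
    faces <- which(keep[mesh@faces[, 1]] & keep[mesh@faces[, 2]] &
                     keep[mesh@faces[, 3]])
  }
  f <- mesh@faces[faces, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  map <- integer(nVertices(mesh))
  map[used] <- seq_along(used)
  out <- TriangleMesh(mesh@vertices[used, , drop = FALSE],
                      matrix(map[f], ncol = 3),
                      field = if (length(mesh@field)) mesh@field[used] else numeric(0))
  attr(out, "origVertex") <- used
  out
}

#' Concatenate meshes into one (disjoint components)
#'
#' @param meshes list of TriangleMesh.
#' @return a TriangleMesh with attribute \code{"vertexOffsets"} giving the
#'   index offset of each input mesh's vertices.
#' @export
mergeMeshes <- function(meshes) {
  nv <- vapply(meshes, nVertices, integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  v <- do.call(rbind, lapply(meshes, meshVertices))
  f <- do.call(rbind, mapply(function(m, o) m@faces + o, meshes, off,
                             SIMPLIFY = FALSE))
  out <- TriangleMesh(v, f)
  attr(out, "vertexOffsets") <- off
  out
}

# bounding-box diagonal, used to scale tolerances
meshDiagonal <- function(mesh) {
  rng <- apply(mesh@vertices, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}
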