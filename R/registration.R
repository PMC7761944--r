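# Rigid alignment of serial models by a trimmed iterative closest point
# dialect: exact nearest neighbours on the target surface, distance-rank
# trimming to the estimated overlap fraction, point-to-plane (linearized) or
# point-to-point (Procrustes) updates, and optional rejection of
# correspondences that land on an open boundary of the target (overhangs).

#' Least-squares rigid fit of corresponding point pairs
#'
#' Orthogonal Procrustes (Kabsch) with det +1 enforced; stands in for the
#' operator's on-screen manual approximation of the two models, using
#' corresponding landmark pairs.
#'
#' @param sourcePoints,targetPoints n x 3 matrices of corresponding points,
#'   n >= 3, not collinear.
#' @return a \linkS4class{RigidTransform} mapping source onto target.
#' @export
coarseAlign <- function(sourcePoints, targetPoints) {
  P <- matrix(as.numeric(sourcePoints), ncol = 3)
  Q <- matrix(as.numeric(targetPoints), ncol = 3)
  if (nrow(P) != nrow(Q)) stop("point sets must have equal size")
  if (nrow(P) < 3) stop("degenerate input: need at least 3 point pairs")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  scale <- sqrt(sum(Pc^2) / nrow(P))
  if (scale == 0 || sv$d[2] / max(sv$d[1], .Machine$double.eps) < 1e-9)
    stop("degenerate input: points are collinear or coincident")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  RigidTransform(R, cq - as.numeric(R %*% cp))
}

# boundary edge/vertex lookup tables for overhang rejection
boundaryFeatures <- function(mesh) {
  de <- directedEdges(mesh)
  n <- nVertices(mesh)
  keys <- edgeKeys(de, n)
  cnt <- table(keys)
  bkeys <- as.numeric(names(cnt)[cnt == 1L])
  bvert <- logical(n)
  if (length(bkeys)) {
    isB <- keys %in% bkeys
    bvert[unique(as.integer(de[isB, ]))] <- TRUE
  }
  list(edgeKeys = bkeys, boundaryVertex = bvert, n = n)
}

#' Exact closest-point correspondences on a target mesh
#'
#' For each sampled source point, the exact closest point on the target
#' surface (face interiors, edges and vertices are all candidate features).
#' When \code{excludeOverhangs} is TRUE, pairs whose closest point lies on a
#' boundary edge or boundary vertex of the target are discarded, so regions
#' present in only one model do not bias the registration.
#'
#' @param sourcePoints n x 3 matrix of query points (mm).
#' @param targetMesh a \linkS4class{TriangleMesh} with at least one face.
#' @param excludeOverhangs logical.
#' @param boundary optional precomputed \code{boundaryFeatures(targetMesh)}.
#' @param targetNormals optional precomputed \code{faceNormals(targetMesh)}.
#' @return list with matrices/vectors \code{sourceIndex}, \code{point}
#'   (closest target point), \code{distance} (mm), \code{normal} (target face
#'   normal at the closest point).
#' @export
findCorrespondences <- function(sourcePoints, targetMesh,
                                excludeOverhangs = TRUE, boundary = NULL,
                                targetNormals = NULL) {
  P <- matrix(as.numeric(sourcePoints), ncol = 3)
  if (!nrow(P)) stop("invalid input: empty source sample")
  if (!nFaces(targetMesh)) stop("target mesh has no faces")
  res <- .cppClosestPoints(P, targetMesh@vertices,
                           matrix(as.integer(targetMesh@faces), ncol = 3))
  if (is.null(targetNormals)) targetNormals <- faceNormals(targetMesh)
  faceIdx <- as.integer(res[, 5])
  keep <- rep(TRUE, nrow(P))
  if (excludeOverhangs) {
    if (is.null(boundary)) boundary <- boundaryFeatures(targetMesh)
    if (length(boundary$edgeKeys) || any(boundary$boundaryVertex)) {
      bary <- res[, 6:8, drop = FALSE]
      tol <- 1e-9
      nzero <- rowSums(bary <= tol)
      f <- targetMesh@faces[faceIdx, , drop = FALSE]
      n <- boundary$n
      # on a vertex: two barycentrics ~ 0
      onV <- nzero >= 2L
      if (any(onV)) {
        vIdx <- f[cbind(which(onV), max.col(bary[onV, , drop = FALSE]))]
        keep[onV][boundary$boundaryVertex[vIdx]] <- FALSE
      }
      # on an edge: exactly one barycentric ~ 0; the edge is the one opposite
      # the vanishing corner
      onE <- nzero == 1L
      if (any(onE) && length(boundary$edgeKeys)) {
        zc <- apply(bary[onE, , drop = FALSE], 1, which.min)
        fe <- f[onE, , drop = FALSE]
        o1 <- fe[cbind(seq_len(nrow(fe)), (zc %% 3L) + 1L)]
        o2 <- fe[cbind(seq_len(nrow(fe)), ((zc + 1L) %% 3L) + 1L)]
        ek <- pmin(o1, o2) * (n + 1) + pmax(o1, o2)
        keep[onE][ek %in% boundary$edgeKeys] <- FALSE
      }
    }
  }
  list(sourceIndex = which(keep),
       point = res[keep, 1:3, drop = FALSE],
       distance = res[keep, 4],
       normal = targetNormals[faceIdx[keep], , drop = FALSE])
}

#' Trim correspondences to the estimated overlap
#'
#' Retains the \code{k = floor(overlapFraction * n)} pairs with smallest
#' distance (k >= 1 enforced); ties are broken by source index order, so
#' trimming is stable and deterministic.
#'
#' @param corr correspondence list as returned by
#'   \code{\link{findCorrespondences}}.
#' @param overlapFraction fraction in (0, 1].
#' @return the trimmed correspondence list.
#' @export
trimCorrespondences <- function(corr, overlapFraction) {
  n <- length(corr$distance)
  if (!n) stop("no correspondences to trim")
  k <- max(1L, min(n, floor(overlapFraction * n)))
  ord <- order(corr$distance, corr$sourceIndex)[seq_len(k)]
  ord <- sort(ord)  # keep source order within the retained set
  list(sourceIndex = corr$sourceIndex[ord],
       point = corr$point[ord, , drop = FALSE],
       distance = corr$distance[ord],
       normal = corr$normal[ord, , drop = FALSE])
}

# point-to-plane increment: minimise sum(((R p + t - q) . n)^2) in the
# small-angle linearization; rotation re-orthonormalized afterwards.
solvePointToPlane <- function(P, Q, N) {
  C <- vcross(P, N)
  A <- cbind(C, N)
  b <- -rowSums((P - Q) * N)
  M <- crossprod(A)
  if (rcond(M) < 1e-14) return(NULL)  # degenerate normals; caller falls back
  x <- solve(M, crossprod(A, b))
  w <- x[1:3]
  R <- orthonormalize(smallAngleRotation(w))
  RigidTransform(R, x[4:6])
}

smallAngleRotation <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

orthonormalize <- function(R) {
  sv <- svd(R)
  S <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% S %*% t(sv$v)
}

solvePointToPoint <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  sv <- svd(crossprod(sweep(P, 2, cp), sweep(Q, 2, cq)))
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  RigidTransform(R, cq - as.numeric(R %*% cp))
}

#' Trimmed iterative closest point registration
#'
#' Iterates: sample the source reference region, find exact closest-point
#' correspondences on the target surface, trim to the estimated overlap,
#' solve the point-to-plane (linearized, re-orthonormalized) or
#' point-to-point (Procrustes) update, and compose. Stops at
#' \code{maxIterations} or when the RMS residual changes by less than
#' \code{convergenceTol}. The returned transform is cumulative from the
#' initial position.
#'
#' @param sourceMesh a \linkS4class{TriangleMesh} (moving model).
#' @param sourceRegion a \linkS4class{RegionMask} on the source mesh: the
#'   superimposition reference area.
#' @param targetMesh the fixed model.
#' @param settings an \linkS4class{ICPSettings}.
#' @param initial initial \linkS4class{RigidTransform} (source into target
#'   frame); default identity.
#' @param seed integer seed for the sampling path when
#'   \code{samplingFraction < 1}.
#' @return a \linkS4class{RegistrationResult}.
#' @export
icpRegister <- function(sourceMesh, sourceRegion, targetMesh, settings,
                        initial = RigidTransform(), seed = 1L) {
  idx <- maskIndices(sourceRegion)
  if (max(idx) > nVertices(sourceMesh))
    stop("source region indices exceed source mesh")
  if (settings@samplingFraction < 1) {
    k <- max(3L, floor(settings@samplingFraction * length(idx)))
    rs <- localSeed(seed, 101L)
    idx <- sort(rs$sample(idx, k))
  }
  P0 <- sourceMesh@vertices[idx, , drop = FALSE]
  boundary <- boundaryFeatures(targetMesh)
  tn <- faceNormals(targetMesh)
  Tcur <- initial
  rmsPrev <- Inf
  rms <- NA_real_
  retained <- 0L
  iters <- 0L
  rmsTrace <- numeric(0)
  # the trim is annealed from no trimming down to the requested estimated
  # overlap over the first iterations (standard trimmed-ICP practice): a hard
  # jump to an aggressive trim can lock onto a spurious partial fit
  ramp <- min(10L, settings@maxIterations - 1L)
  for (it in seq_len(settings@maxIterations)) {
    iters <- it
    frac <- if (ramp > 0L && it <= ramp)
      1 - (1 - settings@overlapFraction) * (it - 1L) / ramp
    else settings@overlapFraction
    P <- applyTransform(P0, Tcur)
    corr <- findCorrespondences(P, targetMesh,
                                excludeOverhangs = settings@excludeOverhangs,
                                boundary = boundary, targetNormals = tn)
    if (!length(corr$sourceIndex))
      stop("no correspondences: all pairs excluded as overhangs")
    corr <- trimCorrespondences(corr, frac)
    retained <- length(corr$distance)
    rms <- sqrt(mean(corr$distance^2))
    rmsTrace <- c(rmsTrace, rms)
    if (frac <= settings@overlapFraction &&
        abs(rmsPrev - rms) < settings@convergenceTol) break
    rmsPrev <- rms
    Pr <- P[corr$sourceIndex, , drop = FALSE]
    inc <- NULL
    if (settings@matching == "point_to_plane")
      inc <- solvePointToPlane(Pr, corr$point, corr$normal)
    if (is.null(inc))  # point_to_point mode, or degenerate normals fallback
      inc <- solvePointToPoint(Pr, corr$point)
    Tcur <- composeTransforms(inc, Tcur)
  }
  new("RegistrationResult", transform = Tcur, rmsResidual = rms,
      retainedCount = as.integer(retained), iterationsRun = as.integer(iters),
      stages = list(list(label = sprintf("icp_overlap_%g", settings@overlapFraction),
                         rms = rms, iterations = iters, retained = retained,
                         rmsTrace = rmsTrace)))
}

#' Staged registration: coarse alignment, partial approximation, final ICP
#'
#' The full pipeline always starts from the original initial position of the
#' models: a landmark-based coarse alignment first; then, when the requested
#' estimated overlap is below 50\%, a partial approximation at 100\% overlap;
#' then the final ICP at the requested setting. The returned transform is
#' cumulative from the original pose and the per-stage logs are kept.
#'
#' @inheritParams icpRegister
#' @param landmarkPairs list with matrices \code{source} and \code{target}
#'   (>= 3 corresponding landmarks) for the coarse alignment.
#' @return a \linkS4class{RegistrationResult} with one log entry per stage.
#' @export
stagedRegister <- function(sourceMesh, sourceRegion, targetMesh, settings,
                           landmarkPairs, seed = 1L) {
  coarse <- coarseAlign(landmarkPairs$source, landmarkPairs$target)
  stages <- list(list(label = "coarse_landmarks", rms = NA_real_,
                      iterations = 0L, retained = nrow(landmarkPairs$source)))
  Tcur <- coarse
  if (settings@overlapFraction < 0.5) {
    pre <- settings
    pre@overlapFraction <- 1
    r1 <- icpRegister(sourceMesh, sourceRegion, targetMesh, pre,
                      initial = Tcur, seed = seed)
    stages <- c(stages, r1@stages)
    Tcur <- r1@transform
  }
  rf <- icpRegister(sourceMesh, sourceRegion, targetMesh, settings,
                    initial = Tcur, seed = seed)
  new("RegistrationResult", transform = rf@transform,
      rmsResidual = rf@rmsResidual, retainedCount = rf@retainedCount,
      iterationsRun = rf@iterationsRun, stages = c(stages, rf@stages))
}

#' Grid search for the best estimated-overlap fraction
#'
#' Emulates the operator's iterative "user defined" overlap choice: runs the
#' staged registration for each fraction in the grid and returns the fraction
#' minimising the RMS distance of an intact region (known-unchanged
#' structures, available only in the synthetic/benchmark context) to the
#' target surface.
#'
#' @inheritParams stagedRegister
#' @param intactRegion a \linkS4class{RegionMask} on the source mesh of
#'   structures known to be unchanged.
#' @param grid overlap fractions to test (default 0.05 to 1.00, step 0.05).
#' @return list with \code{fraction} (the winner) and \code{scores}
#'   (data.frame of fraction and intact-region RMS in mm).
#' @export
optimizeOverlapFraction <- function(sourceMesh, sourceRegion, targetMesh,
                                    intactRegion, settings = ICPSettings(),
                                    landmarkPairs, grid = seq(0.05, 1, by = 0.05),
                                    seed = 1L) {
  if (!length(grid)) stop("empty overlap grid")
  Pint <- sourceMesh@vertices[maskIndices(intactRegion), , drop = FALSE]
  boundary <- boundaryFeatures(targetMesh)
  tn <- faceNormals(targetMesh)
  score <- vapply(grid, function(fr) {
    s <- settings
    s@overlapFraction <- fr
    reg <- stagedRegister(sourceMesh, sourceRegion, targetMesh, s,
                          landmarkPairs, seed = seed)
    corr <- findCorrespondences(applyTransform(Pint, reg@transform),
                                targetMesh, excludeOverhangs = FALSE,
                                boundary = boundary, targetNormals = tn)
    sqrt(mean(corr$distance^2))
  }, numeric(1))
  list(fraction = grid[which.min(score)],
       scores = data.frame(fraction = grid, rms = score))
}

# small deterministic RNG scope: never touches the global .Random.seed
localSeed <- function(seed, salt) {
  env <- new.env()
  env$state <- NULL
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer((as.numeric(seed) + as.numeric(salt)) %% 2147483629))
    if (!is.null(env$state)) assign(".Random.seed", env$state, envir = globalenv())
    out <- expr
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(
    sample = function(x, k) run(sample(x, k)),
    rnorm = function(n, sd = 1) run(stats::rnorm(n, sd = sd)),
    runif = function(n, min = 0, max = 1) run(stats::runif(n, min, max))
  )
}
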