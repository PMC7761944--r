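test_that("landmark coarse alignment recovers a known rigid transform", {
  P <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0), c(1, 1, 2))
  R <- occlusalWear:::rotationMatrix(c(0, 0, 1), 10 * pi / 180)
  tr <- RigidTransform(R, c(1, 2, 3))
  Q <- applyTransform(P, tr)
  fit <- coarseAlign(P, Q)
  expect_lt(max(abs(applyTransform(P, fit) - Q)), 1e-9)
  expect_lt(max(abs(fit@rotation - R)), 1e-9)
  idf <- coarseAlign(P, P)
  expect_lt(max(abs(idf@rotation - diag(3))), 1e-12)
  expect_lt(max(abs(idf@translation)), 1e-12)
  expect_error(coarseAlign(P[1:2, ], Q[1:2, ]), "at least 3")
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(coarseAlign(col, col + 1), "collinear")
})

test_that("closest-point correspondences are exact against a brute-force scan", {
  # a flat square patch in z = 0
  sq <- TriangleMesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  corr <- findCorrespondences(rbind(c(0, 0, 1)), sq, excludeOverhangs = FALSE)
  expect_equal(as.numeric(corr$point), c(0, 0, 0))
  expect_equal(corr$distance, 1)
  # a point beyond the rim projects onto the boundary -> discarded as overhang
  out <- findCorrespondences(rbind(c(2, 0, 0.2)), sq, excludeOverhangs = TRUE)
  expect_length(out$sourceIndex, 0L)
  keep <- findCorrespondences(rbind(c(2, 0, 0.2)), sq, excludeOverhangs = FALSE)
  expect_equal(as.numeric(keep$point), c(1, 0, 0))

  mesh <- makeIcosphere(2)  # 320 faces
  set.seed(42)
  pts <- matrix(rnorm(45, sd = 1.5), ncol = 3)
  corr <- findCorrespondences(pts, mesh, excludeOverhangs = FALSE)
  for (i in seq_len(nrow(pts))) {
    oracle <- oracleClosestOnMesh(pts[i, ], mesh)
    expect_equal(corr$distance[i], oracle$distance, tolerance = 1e-9)
    expect_lt(sqrt(sum((corr$point[i, ] - oracle$point)^2)), 1e-7)
  }
  expect_error(findCorrespondences(matrix(0, 0, 3), mesh), "empty")
})

test_that("distance-rank trimming keeps the k smallest with a stable tie rule", {
  corr <- list(sourceIndex = 1:10,
               point = matrix(0, 10, 3),
               distance = c(10, 1, 9, 2, 8, 3, 7, 4, 6, 5),
               normal = matrix(rep(c(0, 0, 1), each = 10), 10, 3))
  tr <- trimCorrespondences(corr, 0.4)
  expect_setequal(tr$distance, 1:4)
  expect_length(trimCorrespondences(corr, 1)$distance, 10L)
  # sort-based brute-force equivalence over random draws
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:60, 1)
    d <- round(runif(n, 0, 5), 2)  # deliberate ties
    corr2 <- list(sourceIndex = seq_len(n), point = matrix(0, n, 3),
                  distance = d, normal = matrix(0, n, 3))
    fr <- runif(1, 0.1, 1)
    k <- max(1, floor(fr * n))
    expected <- sort(order(d, seq_len(n))[seq_len(k)])
    expect_identical(trimCorrespondences(corr2, fr)$sourceIndex, expected)
  }
  # all distances equal: the first floor(n/2) by source index are kept
  eq <- list(sourceIndex = 1:9, point = matrix(0, 9, 3),
             distance = rep(2, 9), normal = matrix(0, 9, 3))
  expect_identical(trimCorrespondences(eq, 0.5)$sourceIndex, 1:4)
  expect_length(trimCorrespondences(eq, 0.01)$distance, 1L)  # k >= 1
})

test_that("ICP recovers a known displacement to sub-micrometre residual", {
  tooth <- occlusalWear:::generateTooth(toothSpec("incisor", resolution = 1200))
  disp <- RigidTransform(occlusalWear:::rotationMatrix(c(1, 0, 0), 5 * pi / 180),
                         c(0.5, -0.2, 0.3))
  target <- applyTransform(tooth, disp)
  region <- RegionMask("all", seq_len(nVertices(tooth)), tooth)
  res <- icpRegister(tooth, region, target, ICPSettings())
  expect_lt(res@rmsResidual, 1e-6)
  expect_lt(max(abs(res@transform@rotation - disp@rotation)), 1e-6)
  # already aligned: identity within tolerance, converges quickly
  res0 <- icpRegister(tooth, region, tooth, ICPSettings())
  expect_lt(occlusalWear:::rotationAngle(res0@transform@rotation), 1e-8)
  expect_lt(res0@iterationsRun, 5L)
  expect_equal(res0@retainedCount, nVertices(tooth))
})

test_that("point-to-point trimmed RMS is non-increasing across iterations", {
  tooth <- occlusalWear:::generateTooth(toothSpec("canine", resolution = 1000))
  disp <- RigidTransform(occlusalWear:::rotationMatrix(c(0, 1, 1), 8 * pi / 180),
                         c(1, 0.5, -0.7))
  target <- applyTransform(tooth, disp)
  region <- RegionMask("all", seq_len(nVertices(tooth)), tooth)
  for (fr in c(1, 0.4)) {
    res <- icpRegister(tooth, region, target,
                       ICPSettings(overlapFraction = fr,
                                   matching = "point_to_point"))
    trace <- res@stages[[1]]$rmsTrace
    expect_true(all(diff(trace) <= 1e-12))
  }
})

test_that("staged registration runs the documented stages and is deterministic", {
  case <- tinyCase()
  ref <- resolveReference(case@t0, case@t0Labels, techniqueSpec("CC_C"))
  lm <- list(source = case@t0Landmarks, target = case@t1Landmarks)
  r02 <- stagedRegister(case@t0, ref, case@t1,
                        ICPSettings(overlapFraction = 0.2), lm, seed = 1)
  expect_length(r02@stages, 3L)  # coarse, partial approximation, final
  expect_equal(vapply(r02@stages, `[[`, "", "label"),
               c("coarse_landmarks", "icp_overlap_1", "icp_overlap_0.2"))
  r10 <- stagedRegister(case@t0, ref, case@t1, ICPSettings(), lm, seed = 1)
  expect_length(r10@stages, 2L)  # coarse + final only
  again <- stagedRegister(case@t0, ref, case@t1,
                          ICPSettings(overlapFraction = 0.2), lm, seed = 1)
  expect_identical(again@transform@rotation, r02@transform@rotation)
  expect_identical(again@transform@translation, r02@transform@translation)
})

test_that("random displacements are recovered at 100% overlap (property)", {
  tooth <- occlusalWear:::generateTooth(toothSpec("incisor", resolution = 900))
  region <- RegionMask("all", seq_len(nVertices(tooth)), tooth)
  h <- max(meshVertices(tooth)[, 3])
  lmSrc <- rbind(c(0, 0, h), c(0, -3, 0), c(-3, 0, 4), c(3, 0, 4))
  for (seed in 1:10) {
    set.seed(seed)
    ax <- rnorm(3)
    disp <- RigidTransform(
      occlusalWear:::rotationMatrix(ax, runif(1, 0, 20) * pi / 180),
      runif(3, -5, 5))
    target <- applyTransform(tooth, disp)
    res <- stagedRegister(tooth, region, target, ICPSettings(),
                          list(source = lmSrc,
                               target = applyTransform(lmSrc, disp)))
    err <- composeTransforms(invertTransform(disp), res@transform)
    moved <- applyTransform(meshVertices(tooth), err)
    rms <- sqrt(mean(rowSums((moved - meshVertices(tooth))^2)))
    expect_lt(rms, 1e-5)
  }
})

test_that("overlap grid search favours full overlap on unchanged surfaces", {
  tooth <- occlusalWear:::generateTooth(toothSpec("canine", resolution = 900))
  region <- RegionMask("all", seq_len(nVertices(tooth)), tooth)
  h <- max(meshVertices(tooth)[, 3])
  lm <- list(source = rbind(c(0, 0, h), c(0, -3, 0), c(-3, 0, 4), c(3, 0, 4)))
  lm$target <- lm$source
  opt <- optimizeOverlapFraction(tooth, region, tooth, region,
                                 landmarkPairs = lm, grid = c(0.2, 0.6, 1.0))
  expect_equal(opt$fraction, 1.0)
  single <- optimizeOverlapFraction(tooth, region, tooth, region,
                                    landmarkPairs = lm, grid = 0.2)
  expect_equal(single$fraction, 0.2)
  expect_error(optimizeOverlapFraction(tooth, region, tooth, region,
                                       landmarkPairs = lm, grid = numeric(0)),
               "empty")
})

test_that("grid search lowers the overlap when part of the surface changed", {
  # ~30% of the crown surface is displaced outward: the best fraction must
  # not exceed the truly unchanged share plus one grid step
  tooth <- occlusalWear:::generateTooth(toothSpec("incisor", resolution = 1200))
  v <- meshVertices(tooth)
  changed <- v[, 3] > quantile(v[, 3], 0.7)
  v2 <- v
  vn <- vertexNormals(tooth)
  v2[changed, ] <- v[changed, ] + 0.8 * vn[changed, , drop = FALSE]
  target <- TriangleMesh(v2, meshFaces(tooth))
  region <- RegionMask("all", seq_len(nVertices(tooth)), tooth)
  intact <- RegionMask("intact", which(!changed & v[, 3] > -1), tooth)
  h <- max(v[, 3])
  lm <- list(source = rbind(c(0, 0, h), c(0, -3, 0), c(-3, 0, 4), c(3, 0, 4)))
  lm$target <- lm$source
  opt <- optimizeOverlapFraction(tooth, region, target, intact,
                                 landmarkPairs = lm,
                                 grid = seq(0.15, 1, by = 0.1))
  expect_lte(opt$fraction, 0.75)
})
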