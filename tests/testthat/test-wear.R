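test_that("signed distance maps follow the documented convention", {
  sq <- function(z) TriangleMesh(rbind(c(-1, -1, z), c(1, -1, z),
                                       c(1, 1, z), c(-1, 1, z)),
                                 rbind(c(1, 2, 3), c(1, 3, 4)))
  m <- sq(0)
  expect_equal(distanceMap(m, m), c(0, 0, 0, 0))
  # follow-up surface 0.5 mm above the baseline (normals +z): positive
  expect_equal(distanceMap(sq(0), sq(0.5)), rep(0.5, 4))
  expect_equal(distanceMap(sq(0.5), sq(0)), rep(-0.5, 4))
  expect_error(distanceMap(m, TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3))),
               "empty")
})

test_that("worn synthetic crown shows the nominal vertical loss in the map", {
  case <- tinyCase(loss = 1, noise = NULL, retainer = NULL)
  m <- measureCaseWear(case, "GS", seed = 1)
  expect_equal(min(m@distances), -1, tolerance = 0.1)  # wear is negative
})

test_that("plane slicing splits triangles exactly on the plane", {
  cube <- makeCubeMesh()
  part <- sliceWithPlanes(cube, list(SlicePlane(c(0, 0, 0.5), c(0, 0, 1))))
  d <- meshVertices(part)[, 3] - 0.5
  newV <- is.na(attr(part, "origVertex"))
  expect_true(any(newV))
  expect_lt(max(abs(d[newV])), 1e-9)
  capped <- fillHoles(part, boundaryLoops(part))
  expect_true(isWatertight(capped))
  expect_equal(meshVolume(capped), 0.5)
  expect_error(sliceWithPlanes(cube, list(SlicePlane(c(0, 0, 1.5), c(0, 0, 1)))),
               "empty part")
})

test_that("sliced sphere caps match the analytic spherical-cap volume", {
  sph <- makeIcosphere(4)
  for (zc in c(-0.4, 0.3, 0.62)) {
    part <- occlusalWear:::capOcclusalPart(sph, list(SlicePlane(c(0, 0, zc),
                                                               c(0, 0, 1))))
    h <- 1 - zc
    expect_equal(meshVolume(part), pi * h^2 * (3 - h) / 3, tolerance = 0.01)
  }
})

test_that("slicing conserves volume between part and complement", {
  for (mesh in list(makeCubeMesh(2), makeIcosphere(2))) {
    pl <- SlicePlane(c(0.3, 0.2, 0.4), c(0.3, -0.2, 1))
    up <- occlusalWear:::capOcclusalPart(mesh, list(pl))
    dn <- occlusalWear:::capOcclusalPart(mesh, list(SlicePlane(pl@point,
                                                               -pl@normal)))
    expect_equal(meshVolume(up) + meshVolume(dn), meshVolume(mesh),
                 tolerance = 1e-9)
  }
})

test_that("hole splitting returns single-plane loops unchanged", {
  cube <- makeCubeMesh()
  pl <- list(SlicePlane(c(0, 0, 0.5), c(0, 0, 1)))
  part <- sliceWithPlanes(cube, pl)
  loops <- boundaryLoops(part)
  expect_length(loops, 1L)
  expect_identical(splitHole(loops[[1]], pl, part), loops)
})

test_that("a two-plane hole splits into planar loops joined on the crease", {
  # L-shaped part of a box, cut by orthogonal planes: the loop spans both
  # planes and must split into two planar cycles sharing the crease chord
  box <- makeBoxMesh(c(2, 1, 1))
  planes <- list(SlicePlane(c(0, 0, 0.5), c(0, 0, 1)),
                 SlicePlane(c(1.5, 0, 0), c(-1, 0, 0)))
  part <- sliceWithPlanes(box, planes)
  loops <- boundaryLoops(part)
  expect_length(loops, 1L)
  pieces <- splitHole(loops[[1]], planes, part)
  expect_length(pieces, 2L)
  v <- meshVertices(part)
  for (cyc in pieces) {
    onSome <- vapply(planes, function(pl)
      all(abs(occlusalWear:::planeDistances(v[cyc, , drop = FALSE], pl)) < 1e-6),
      logical(1))
    expect_true(any(onSome))
  }
  # manual decomposition: loop vertices on each plane
  d1 <- abs(occlusalWear:::planeDistances(v[loops[[1]], ], planes[[1]])) < 1e-6
  d2 <- abs(occlusalWear:::planeDistances(v[loops[[1]], ], planes[[2]])) < 1e-6
  expect_setequal(unlist(pieces)[!unlist(pieces) %in% loops[[1]][d1 & d2]],
                  loops[[1]][xor(d1, d2)])
  capped <- fillHoles(part, pieces)
  expect_true(isWatertight(capped))
  expect_equal(meshVolume(capped), 1.5 * 1 * 0.5)
})

test_that("cap volume is independent of the triangulation of planar caps", {
  cube <- makeCubeMesh()
  pl <- list(SlicePlane(c(0, 0, 0.5), c(0, 0, 1)))
  part <- sliceWithPlanes(cube, pl)
  loops <- boundaryLoops(part)
  v1 <- meshVolume(fillHoles(part, loops))
  # a rotated loop ordering yields a different (but planar) triangulation
  rot <- lapply(loops, function(l) c(l[-1], l[1]))
  v2 <- meshVolume(fillHoles(part, rot))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("self-intersecting cap polygons are rejected", {
  # bow-tie: planar but self-intersecting
  v <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  fakePart <- TriangleMesh(v, rbind(c(1, 2, 3)))
  expect_error(fillHoles(fakePart, list(c(1, 2, 3, 4))), "geometry error")
})

test_that("plane proposal isolates the occlusal change and verifies the edge", {
  case <- tinyCase(loss = 0.5, noise = NULL)
  m <- measureCaseWear(case, "GS", seed = 1)
  expect_length(m@planes, 1L)
  expect_equal(m@planes[[1]]@role, "gingival")
  # the plane sits below the wear facet but above the retainer relief
  zc <- m@planes[[1]]@point[3]
  h <- 10  # incisor crown height
  expect_gt(zc, 0.6 * h)

  # unchanged pair: an occlusal part is measured and wear is ~0
  t0 <- case@t0
  dup <- measureWear(t0, t0, case@t0Labels, case@t0Labels, "CC_C",
                     list(t0 = case@t0Landmarks, t1 = case@t0Landmarks))
  expect_lt(abs(wearVolume(dup)), 0.005)
})

test_that("wear reaching the gingival margin cannot be isolated", {
  tooth <- occlusalWear:::generateTooth(toothSpec("incisor", resolution = 1200))
  # pretend the crown mask stops at z = 8.4: the change below it cannot be
  # isolated by a gingival plane
  worn <- occlusalWear:::capOcclusalPart(
    tooth, list(SlicePlane(c(0, 0, 8.5), c(0, 0, -1))))
  expect_error(
    proposeSlicePlanes(tooth, worn, gingivalLimit = 8.8),
    "cannot-isolate")
})

test_that("measured wear matches constructed truth and is anti-symmetric", {
  case <- tinyCase(loss = 1, noise = NULL)
  m <- measureCaseWear(case, "GS", seed = 1)
  expect_equal(wearVolume(m), case@trueRemovedVolume,
               tolerance = 0.02)
  expect_true(all(m@watertight))
  # swapping T0 and T1 negates the wear volume
  sw <- measureWear(case@t1, case@t0, case@t1Labels, case@t0Labels, "GS",
                    list(t0 = case@t1Landmarks, t1 = case@t0Landmarks),
                    axis = as.numeric(case@info$pose@rotation %*% c(0, 0, 1)))
  expect_equal(wearVolume(sw), -wearVolume(m), tolerance = 0.01)
})

test_that("wear volume is insensitive to the exact gingival plane position", {
  case <- tinyCase(loss = 1, noise = NULL)
  m <- measureCaseWear(case, "GS", seed = 1)
  w1 <- wearVolume(m)
  m2 <- measureCaseWear(case, "GS", seed = 1, planeOffset = 0.4)
  expect_lt(abs(wearVolume(m2) - w1) / w1, 0.005)
})

test_that("intermediate meshes can be exported with the distance map attached", {
  case <- tinyCase(loss = 1, noise = NULL)
  m <- measureCaseWear(case, "GS", seed = 1, keepIntermediates = TRUE)
  im <- attr(m, "intermediates")
  expect_named(im, c("t0Crown", "t1CrownAligned", "t0Part", "t1Part"))
  expect_true(isWatertight(im$t0Part))
  expect_equal(vertexField(im$t0Crown), m@distances)
  tmp <- withr::local_tempfile(fileext = ".ply")
  saveScalarField(im$t0Crown, tmp)
  back <- readMesh(tmp)
  expect_lt(max(abs(vertexField(back) - m@distances)), 1e-6)
})
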