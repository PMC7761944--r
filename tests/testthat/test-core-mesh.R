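test_that("STL round trip welds the triangle soup back to shared vertices", {
  cube <- makeCubeMesh()
  tmp <- withr::local_tempfile(fileext = ".stl")
  writeMesh(cube, tmp, "stl_binary")
  # brute-force oracle: distinct coordinate triples in the 36-corner soup
  soup <- do.call(rbind, lapply(seq_len(nFaces(cube)), function(k)
    meshVertices(cube)[meshFaces(cube)[k, ], ]))
  expect_equal(nrow(unique(soup)), 8L)
  back <- readMesh(tmp)
  expect_equal(nVertices(back), 8L)
  expect_equal(nFaces(back), 12L)
  expect_equal(meshVolume(back), 1, tolerance = 1e-6)

  writeMesh(cube, tmp, "stl_ascii")
  backA <- readMesh(tmp)
  expect_equal(nVertices(backA), 8L)
  expect_equal(meshVolume(backA), 1, tolerance = 1e-6)
})

test_that("empty and corrupt mesh files are rejected", {
  tmp <- withr::local_tempfile(fileext = ".stl")
  con <- file(tmp, "wb")
  writeBin(raw(80), con)
  writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(readMesh(tmp), "no triangles")
  writeLines(c("solid x", "endsolid x"), tmp)
  expect_error(readMesh(tmp, "stl_ascii"), "no triangles")
  expect_error(readMesh(file.path(tempdir(), "no_such.stl")), "not found")
})

test_that("PLY persists a per-vertex scalar field at full precision", {
  sph <- makeIcosphere(2)
  vertexField(sph) <- sin(meshVertices(sph)[, 3]) * 0.01
  for (fmt in c("ply_ascii", "ply_binary")) {
    tmp <- withr::local_tempfile(fileext = ".ply")
    writeMesh(sph, tmp, fmt)
    back <- readMesh(tmp)
    expect_equal(nVertices(back), nVertices(sph))
    expect_lt(max(abs(vertexField(back) - vertexField(sph))), 1e-6)
    expect_lt(max(abs(meshVertices(back) - meshVertices(sph))), 1e-9)
  }
  # saving an open mesh is allowed: no watertightness requirement for I/O
  open <- TriangleMesh(meshVertices(sph), meshFaces(sph)[-1, ])
  tmp2 <- withr::local_tempfile(fileext = ".stl")
  expect_silent(writeMesh(open, tmp2, "stl_binary"))
})

test_that("watertightness follows the shared-edge/opposite-orientation rule", {
  cube <- makeCubeMesh()
  expect_true(isWatertight(cube))
  openCube <- TriangleMesh(meshVertices(cube), meshFaces(cube)[-1, ])
  expect_false(isWatertight(openCube))
  two <- mergeMeshes(list(cube, makeCubeMesh(1, c(5, 0, 0))))
  expect_true(isWatertight(two))
  expect_equal(meshVolume(two), 2)  # component volumes add
})

test_that("boundary loops partition boundary edges into ordered cycles", {
  expect_identical(boundaryLoops(makeCubeMesh()), list())
  cube <- makeCubeMesh()
  noTop <- TriangleMesh(meshVertices(cube), meshFaces(cube)[-(3:4), ])
  loops <- boundaryLoops(noTop)
  expect_length(loops, 1L)
  expect_length(loops[[1]], 4L)
  expect_setequal(loops[[1]], c(5L, 6L, 7L, 8L))

  cyl <- makeOpenCylinder()
  loops <- boundaryLoops(cyl)
  expect_length(loops, 2L)
  expect_equal(sum(lengths(loops)), oracleBoundaryEdgeCount(cyl))

  # watertight <=> no boundary loops, for manifold meshes
  for (m in list(cube, noTop, cyl, makeIcosphere(1)))
    expect_identical(isWatertight(m), length(boundaryLoops(m)) == 0L)

  # a non-manifold edge (three incident faces) is a topology error
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(2, 1, 4), c(1, 2, 5))
  expect_error(boundaryLoops(TriangleMesh(v, f)), "non-manifold")
})

test_that("enclosed volume is exact for cubes and accurate for spheres", {
  for (a in c(1, 2.5)) {
    expect_equal(meshVolume(makeCubeMesh(a)), a^3)
    expect_equal(meshVolume(makeCubeMesh(a, c(100, -50, 7))), a^3)
  }
  sph <- makeIcosphere(3)
  expect_equal(meshVolume(sph), 4 * pi / 3, tolerance = 0.01)
  # cross-check the divergence-theorem sum with a direct per-face computation
  v <- meshVertices(sph)
  f <- meshFaces(sph)
  direct <- sum(vapply(seq_len(nrow(f)), function(k)
    det(rbind(v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])) / 6, numeric(1)))
  expect_equal(meshVolume(sph), direct)
  expect_error(meshVolume(makeOpenCylinder()), "not watertight")
})

test_that("volume is invariant under rigid motion", {
  sph <- makeIcosphere(2, r = 1.3)
  v0 <- meshVolume(sph)
  for (seed in 1:5) {
    set.seed(seed)
    ax <- rnorm(3)
    tr <- RigidTransform(occlusalWear:::rotationMatrix(ax, runif(1, 0, pi)),
                         runif(3, -20, 20))
    expect_equal(meshVolume(applyTransform(sph, tr)), v0, tolerance = 1e-9)
  }
})

test_that("vertex welding is idempotent and preserves fine geometry", {
  cube <- makeCubeMesh()
  soupV <- do.call(rbind, lapply(seq_len(nFaces(cube)), function(k)
    meshVertices(cube)[meshFaces(cube)[k, ], ]))
  soup <- TriangleMesh(soupV, matrix(seq_len(36), ncol = 3, byrow = TRUE))
  w1 <- weldVertices(soup)
  w2 <- weldVertices(w1)
  expect_equal(nVertices(w1), 8L)
  expect_identical(meshVertices(w1), meshVertices(w2))
  expect_identical(meshFaces(w1), meshFaces(w2))
  # vertices 1e-6 apart (fine wire scale) must NOT be merged at the 1e-9 tol
  v <- rbind(c(0, 0, 0), c(1e-6, 0, 0), c(1, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 3, 4), c(2, 4, 3))
  expect_equal(nVertices(weldVertices(TriangleMesh(v, f))), 4L)
})

test_that("degenerate faces are dropped at construction with a message", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 2), c(1, 2, 4))  # repeated index; zero area
  expect_message(m <- TriangleMesh(v, f), "2 degenerate")
  expect_equal(nFaces(m), 1L)
  expect_error(TriangleMesh(rbind(c(0, 0, Inf)), rbind(c(1, 1, 1)),
                            dropDegenerate = FALSE))
})

test_that("rigid transforms compose, invert and serialize", {
  R1 <- occlusalWear:::rotationMatrix(c(0, 0, 1), 0.3)
  a <- RigidTransform(R1, c(1, 2, 3))
  b <- RigidTransform(occlusalWear:::rotationMatrix(c(1, 1, 0), -0.7), c(-2, 0.5, 4))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(applyTransform(applyTransform(p, b), a),
               applyTransform(p, composeTransforms(a, b)))
  expect_equal(applyTransform(applyTransform(p, a), invertTransform(a)), p)
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeTransform(a, tmp)
  back <- readTransform(tmp)
  expect_equal(back@rotation, a@rotation)
  expect_equal(back@translation, a@translation)
  expect_error(RigidTransform(matrix(rnorm(9), 3), c(0, 0, 0)), "orthonormal")
})
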