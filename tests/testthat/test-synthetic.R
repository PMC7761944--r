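test_that("generated arch segments are watertight, labelled and deterministic", {
  specs <- list(toothSpec("canine", position = -1L, resolution = 900),
                toothSpec("incisor", position = 0L, resolution = 900),
                toothSpec("incisor", position = 1L, resolution = 900))
  arch <- generateArchSegment(specs, seed = 1)
  expect_true(isWatertight(arch$mesh))
  expect_equal(nrow(arch$landmarks), 4L)
  # per-tooth masks partition the tooth surfaces (disjoint, cover all teeth)
  toothMasks <- arch$labels[grep("^tooth_", names(arch$labels))]
  all <- unlist(lapply(toothMasks, maskIndices))
  expect_false(anyDuplicated(all) > 0)
  expect_setequal(union(all, maskIndices(arch$labels$band)),
                  seq_len(nVertices(arch$mesh)))
  # crown/buccal/lingual nest properly
  expect_true(all(maskIndices(arch$labels$buccal) %in%
                    maskIndices(arch$labels$crown)))
  expect_true(all(maskIndices(arch$labels$lingual) %in%
                    maskIndices(arch$labels$crown)))
  expect_length(intersect(maskIndices(arch$labels$buccal),
                          maskIndices(arch$labels$lingual)), 0L)

  again <- generateArchSegment(specs, seed = 1)
  expect_identical(meshVertices(again$mesh), meshVertices(arch$mesh))

  crowded <- generateArchSegment(specs, crowding = TRUE, seed = 2)
  expect_true(isWatertight(crowded$mesh))
  rots <- vapply(crowded$info$placements, function(p) p$rotZ, numeric(1))
  expect_true(any(rots != 0))

  expect_error(generateArchSegment(specs[1:2]), "at least 3")
})

test_that("planar grinding of a prism gives the exact analytic removed volume", {
  # rectangular-prism test tooth, cross-section 6 x 7 mm, height 10 mm
  prism <- makeBoxMesh(c(6, 7, 10), origin = c(-3, -3.5, -1))
  mask <- RegionMask("tooth", seq_len(nVertices(prism)), prism)
  res <- applyWear(prism, mask, wearSpec(1, "symmetric"))
  expect_equal(res$removedVolume, 42)
  expect_true(isWatertight(res$mesh))
  expect_equal(meshVolume(res$mesh), 6 * 7 * 10 - 42)

  none <- applyWear(prism, mask, wearSpec(0))
  expect_identical(meshVertices(none$mesh), meshVertices(prism))
  expect_equal(none$removedVolume, 0)

  expect_error(applyWear(prism, mask, wearSpec(11)), "crown height")
})

test_that("removed volume increases strictly with the grinding level", {
  arch <- generateArchSegment(list(toothSpec("canine", position = -1L, resolution = 900),
                                   toothSpec("incisor", position = 0L, resolution = 900),
                                   toothSpec("incisor", position = 1L, resolution = 900)),
                              seed = 4)
  vols <- vapply(c(0.5, 1, 2), function(loss)
    applyWear(arch$mesh, arch$labels$tooth_0, wearSpec(loss))$removedVolume,
    numeric(1))
  expect_true(all(diff(vols) > 0))
  # asymmetric grinding on the same tooth also reseals watertight
  asym <- applyWear(arch$mesh, arch$labels$tooth_0,
                    wearSpec(1, "asymmetric", tiltDeg = 20))
  expect_true(isWatertight(asym$mesh))
  expect_gt(asym$removedVolume, 0)
})

test_that("the retainer relief changes only the lingual surfaces", {
  specs <- list(toothSpec("canine", position = -1L, resolution = 900),
                toothSpec("incisor", position = 0L, resolution = 900),
                toothSpec("incisor", position = 1L, resolution = 900))
  arch <- generateArchSegment(specs, seed = 6)
  # wire spanning the whole segment: lingual volume grows on every tooth
  ret <- applyRetainer(arch$mesh, arch$info, retainerSpec(),
                       positions = c(-1L, 0L, 1L))
  expect_true(isWatertight(ret$mesh))
  expect_gt(meshVolume(ret$mesh), meshVolume(arch$mesh))
  moved <- maskIndices(ret$footprint)
  buccal <- maskIndices(arch$labels$buccal)
  expect_length(intersect(moved, buccal), 0L)
  # buccal and occlusal vertices bit-identical
  untouched <- setdiff(seq_len(nVertices(arch$mesh)), moved)
  expect_identical(meshVertices(ret$mesh)[untouched, ],
                   meshVertices(arch$mesh)[untouched, ])
  # default: test tooth only; footprint within its lingual surface
  ret0 <- applyRetainer(arch$mesh, arch$info, retainerSpec())
  expect_true(all(maskIndices(ret0$footprint) %in%
                    maskIndices(arch$labels$lingual)))
  # absent spec: unchanged
  none <- applyRetainer(arch$mesh, arch$info, NULL)
  expect_identical(meshVertices(none$mesh), meshVertices(arch$mesh))
})

test_that("scan noise is clamped, seeded and topology-preserving", {
  tooth <- occlusalWear:::generateTooth(toothSpec("incisor", resolution = 900))
  expect_identical(applyScanNoise(tooth, scanNoiseSpec(sd = 0)), tooth)
  spec <- scanNoiseSpec(sd = 0.002, maxDev = 0.005)
  noisy <- applyScanNoise(tooth, spec, seed = 1)
  disp <- sqrt(rowSums((meshVertices(noisy) - meshVertices(tooth))^2))
  expect_lte(max(disp), 0.0025 + 1e-12)  # per-scan clamp: half the pair bound
  expect_gt(max(disp), 0)
  # the scanner bound holds between any two repeated scans of the same tooth
  other <- applyScanNoise(tooth, spec, seed = 7)
  pair <- sqrt(rowSums((meshVertices(noisy) - meshVertices(other))^2))
  expect_lt(max(pair), 0.005 + 1e-12)
  expect_identical(meshFaces(noisy), meshFaces(tooth))
  noisy2 <- applyScanNoise(tooth, spec, seed = 2)
  expect_false(identical(meshVertices(noisy), meshVertices(noisy2)))
  expect_identical(meshVertices(applyScanNoise(tooth, spec, seed = 1)),
                   meshVertices(noisy))
})

test_that("wear cases carry consistent labels, landmarks and ground truth", {
  case <- tinyCase()
  expect_true(isWatertight(case@t0))
  expect_true(isWatertight(case@t1))
  expect_gt(case@trueRemovedVolume, 0)
  expect_true(all(maskIndices(case@t1Labels$composite) %in%
                    maskIndices(case@t1Labels$lingual)))
  # T1 landmarks are the T0 landmarks under the stored pose
  expect_equal(case@t1Landmarks,
               applyTransform(case@t0Landmarks, case@info$pose))
})

test_that("the benchmark is balanced and reproducible", {
  cases <- buildBenchmark(nIncisors = 18, nCanines = 18, seed = 1,
                          resolution = 500, noise = NULL, retainer = NULL)
  man <- attr(cases, "manifest")
  expect_equal(nrow(man), 36L)
  counts <- table(man$toothType, man$loss, man$pattern)
  expect_true(all(counts == 3L))  # 2 types x 3 losses x 2 patterns x 3 each
  expect_true(any(man$crowding) && any(!man$crowding))
  man2 <- attr(buildBenchmark(nIncisors = 18, nCanines = 18, seed = 1,
                              resolution = 500, noise = NULL,
                              retainer = NULL), "manifest")
  expect_identical(man, man2)
})

test_that("noise-free gold-standard measurement recovers the generator truth", {
  # the generator and the measurement agree through independent code paths
  for (args in list(list(toothType = "incisor", loss = 1),
                    list(toothType = "canine", loss = 0.5,
                         pattern = "asymmetric"))) {
    case <- do.call(tinyCase, c(args, list(noise = NULL)))
    m <- measureCaseWear(case, "GS", seed = 1)
    expect_equal(wearVolume(m), case@trueRemovedVolume,
                 tolerance = 0.005)
  }
})
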