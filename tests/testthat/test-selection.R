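test_that("orientation fractions are per-axis displacement shares", {
  pure <- classifyOrientation(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_identical(pure$dominantAxis, "SI")
  expect_equal(unname(pure$fractions), c(0, 0, 1))
  ap <- classifyOrientation(rbind(c(0, 0, 0), c(0, 10, 0)))
  expect_identical(ap$dominantAxis, "AP")
  expect_equal(unname(ap$fractions), c(0, 1, 0))
  # hand-summed segment displacements: |dx| = 2, |dy| = 4, |dz| = 6
  mixed <- classifyOrientation(rbind(c(0, 0, 0), c(1, 2, 3), c(2, 4, 6)))
  expect_equal(unname(mixed$fractions), c(2, 4, 6) / 12)
  expect_identical(mixed$dominantAxis, "SI")
  # exact tie broken SI > AP > LR
  tie <- classifyOrientation(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(tie$dominantAxis, "SI")
  expect_error(classifyOrientation(rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero total displacement")
})

test_that("endpoint parcel assignment matches exhaustive brute force", {
  # 2 mm grid with two labelled voxels; world centres at even coordinates
  parc <- tinyParcellation(dims = c(8L, 8L, 8L),
                           voxels = rbind(c(3, 3, 3, 1), c(5, 3, 3, 2)))
  cen1 <- voxelToWorld(c(3, 3, 3), affine(parc))[1, ]
  expect_identical(assignEndpointParcel(cen1, parc), 1L)
  # background point 3 mm from the nearest label with radius 2 -> none
  p <- cen1 + c(0, 3, 0)
  expect_true(is.na(assignEndpointParcel(p, parc, radiusMm = 2)))
  expect_identical(assignEndpointParcel(p, parc, radiusMm = 3.5), 1L)
  # equidistant between labels 1 and 2 -> smaller label id
  mid <- (cen1 + voxelToWorld(c(5, 3, 3), affine(parc))[1, ]) / 2 + c(0, 1.4, 0)
  expect_identical(assignEndpointParcel(mid, parc, radiusMm = 3), 1L)
  # randomized agreement with the exhaustive oracle
  set.seed(33)
  for (r in 1:40) {
    p <- runif(3, -8, 8)
    expect_identical(assignEndpointParcel(p, parc, radiusMm = 2.5),
                     bruteAssign(p, parc, radiusMm = 2.5))
  }
  expect_error(assignEndpointParcel(c(0, NA, 0), parc), "finite")
})

test_that("two-ROI selection accepts exactly dorsal-to-ventral terminations", {
  parc <- tinyParcellation(dims = c(8L, 8L, 8L),
                           voxels = rbind(c(3, 3, 6, 1), c(4, 3, 6, 2),
                                          c(3, 3, 1, 3), c(4, 3, 1, 4)))
  aff <- affine(parc)
  w <- function(v) voxelToWorld(v, aff)[1, ]
  mk <- function(a, b) {
    p0 <- w(a); p1 <- w(b)
    rbind(p0, (p0 + p1) / 2, p1)
  }
  tg <- tractogram(list(
    mk(c(3, 3, 6), c(3, 3, 1)),   # V3A -> V4: candidate
    mk(c(3, 3, 1), c(4, 3, 6)),   # V4 -> V7: candidate (reversed ends)
    mk(c(3, 3, 6), c(4, 3, 6)),   # dorsal-dorsal: rejected
    mk(c(3, 3, 1), c(4, 3, 1)),   # ventral-ventral: rejected
    mk(c(0, 0, 0), c(3, 3, 1))))  # background -> V4: rejected
  crit <- selectionCriteria(groupA = "dorsal", groupB = "ventral",
                            requiredAxis = NA, hemisphere = "L")
  cand <- selectTwoRoi(tg, parc, crit)
  expect_identical(cand$index, c(1L, 2L))
  expect_identical(cand$labelA, c(1L, 2L))  # group-A side normalised
  expect_identical(cand$labelB, c(3L, 3L))
  expect_error(selectTwoRoi(tg, parc, selectionCriteria(groupA = "nosuch",
                                                        groupB = "ventral")),
               "unknown parcel|empty parcel")
})

test_that("ROA filter removes exactly the streamlines whose points enter the mask", {
  ph <- smallPhantom()
  tr <- truth(ph)
  vofIdx <- tr$index[tr$bundle == "vof"][1:60]
  dims <- dim(labelGrid(parcellation(ph)))
  aff <- affine(parcellation(ph))
  # empty mask: identity
  empty <- scalarVolume(array(0, dims), aff)
  expect_identical(filterRoa(phantomTractogram(ph), vofIdx, empty), vofIdx)
  # full mask: everything removed
  full <- scalarVolume(array(1, dims), aff)
  expect_identical(length(filterRoa(phantomTractogram(ph), vofIdx, full)), 0L)
  # one transverse plane: compare against brute-force point-in-mask scan
  arr <- array(0, dims); arr[, , 40] <- 1
  plane <- scalarVolume(arr, aff)
  kept <- filterRoa(phantomTractogram(ph), vofIdx, plane)
  bruteHit <- vapply(vofIdx, function(i) {
    vox <- worldToVoxel(streamlines(ph)[[i]], aff)
    any(apply(vox, 1, function(v) all(v >= 0) && all(v < dims) &&
                arr[v[1] + 1, v[2] + 1, v[3] + 1] != 0))
  }, logical(1))
  expect_identical(kept, vofIdx[!bruteHit])
  expect_gt(sum(bruteHit), 0)
  expect_error(filterRoa(phantomTractogram(ph), vofIdx,
                         scalarVolume(array(0.5, dims), aff)), "binary")
})

test_that("relative-position filters match brute force and separate the bundles", {
  ph <- smallPhantom()
  tg <- phantomTractogram(ph)
  tr <- truth(ph)
  vofIdx <- tr$index[tr$bundle == "vof"]
  ilfIdx <- tr$index[tr$bundle == "ilf"]
  afIdx <- tr$index[tr$bundle == "af"]
  ilf <- phantomBundle(ph, "ilf"); af <- phantomBundle(ph, "af")
  vof <- phantomBundle(ph, "vof")

  # trivial sign rule: single candidates against a single reference
  cand <- tractogram(list(rbind(c(-40, -60, -20), c(-40, -60, 20))))
  ref <- tractogram(list(rbind(c(-25, -60, -20), c(-25, -60, 20))))
  expect_identical(filterRelativePosition(cand, 1L, ref, "lateral", "L")[1], 1L)
  expect_identical(length(filterRelativePosition(cand, 1L, ref, "lateral", "R")), 0L)

  # all true VOF retained against both references
  keptLat <- filterRelativePosition(tg, vofIdx, ilf, "lateral", "L")
  keptPost <- filterRelativePosition(tg, vofIdx, af, "posterior", "L")
  expect_identical(as.integer(keptLat), vofIdx)
  expect_identical(as.integer(keptPost), vofIdx)
  # ILF is not lateral to the VOF, AF is not posterior to the VOF
  expect_identical(length(filterRelativePosition(tg, ilfIdx, vof, "lateral", "L")), 0L)
  expect_identical(length(filterRelativePosition(tg, afIdx, vof, "posterior", "L")), 0L)
  # no shared z-slab: filter inapplicable, candidate retained and flagged
  high <- tractogram(list(rbind(c(-40, -60, 70), c(-40, -60, 78))))
  out <- filterRelativePosition(high, 1L, ilf, "lateral", "L")
  expect_identical(attr(out, "inapplicable"), 1L)

  # exact agreement with the independent per-slab oracle on a mixed set
  mixed <- c(vofIdx[1:40], ilfIdx[1:30], afIdx[1:30])
  for (rel in c("lateral", "posterior")) {
    ref <- if (rel == "lateral") ilf else af
    refPts <- do.call(rbind, streamlines(ref))
    kept <- filterRelativePosition(tg, mixed, ref, rel, "L")
    oracle <- mixed[vapply(mixed, function(i) {
      bruteRelative(streamlines(tg)[[i]], refPts, rel, "L")
    }, logical(1))]
    expect_identical(as.integer(kept), oracle)
  }
})

test_that("full selection recovers the truth VOF exactly on the default phantom", {
  ph <- smallPhantom()
  parc <- parcellation(ph)
  rep <- runSelection(phantomTractogram(ph), parc, phantomCriteria(ph))
  tr <- truth(ph)
  vofIdx <- tr$index[tr$bundle == "vof"]
  expect_setequal(accepted(rep), vofIdx)
  expect_identical(length(accepted(rep)) + sum(rejections(rep)), rep@nInput)
  # endpoint assignments equal generator truth parcel for parcel
  asn <- assignments(rep)
  tru <- tr[match(asn$index, tr$index), ]
  expect_identical(asn$parcelA, tru$parcelA)
  expect_identical(asn$parcelB, tru$parcelB)
  # empty input: empty report
  rep0 <- runSelection(tractogram(), parc, phantomCriteria(ph))
  expect_identical(rep0@nInput, 0L)
  expect_true(all(rejections(rep0) == 0L))
})

test_that("selection is order-invariant, idempotent, and filter-order-independent", {
  ph <- smallPhantom()
  parc <- parcellation(ph)
  tg <- phantomTractogram(ph)
  crit <- phantomCriteria(ph)
  rep <- runSelection(tg, parc, crit)
  # permuting streamline order changes indices but not the accepted set
  set.seed(4)
  perm <- sample(nStreamlines(tg))
  tgP <- tractogram(streamlines(tg)[perm], voxelSize = c(2, 2, 2))
  repP <- runSelection(tgP, parc, crit)
  expect_setequal(perm[accepted(repP)], accepted(rep))
  # idempotence: re-running on the accepted output returns everything
  tgAcc <- tractogram(streamlines(tg)[accepted(rep)], voxelSize = c(2, 2, 2))
  repAcc <- runSelection(tgAcc, parc, crit)
  expect_identical(length(accepted(repAcc)), nStreamlines(tgAcc))
  # two-ROI, orientation and ROA are independent predicates: any order,
  # same accepted set (exercised with a plane ROA that clips some VOF)
  dims <- dim(labelGrid(parc)); arr <- array(0, dims); arr[, , 40] <- 1
  roa <- scalarVolume(arr, affine(parc))
  critRoa <- phantomCriteria(ph, roa = roa)
  repRoa <- runSelection(tg, parc, critRoa)
  # independent recomputation in a different order: ROA first, then two-ROI
  keptRoa <- filterRoa(tg, seq_len(nStreamlines(tg)), roa)
  cand <- selectTwoRoi(tg, parc, crit)
  ori <- cand$index[vapply(cand$index, function(i) {
    o <- classifyOrientation(streamlines(tg)[[i]])
    o$dominantAxis == "SI" && o$fractions[["SI"]] >= 0.5
  }, logical(1))]
  lat <- filterRelativePosition(tg, intersect(keptRoa, ori),
                                critRoa@lateralReference, "lateral", "L")
  post <- filterRelativePosition(tg, as.integer(lat),
                                 critRoa@posteriorReference, "posterior", "L")
  expect_setequal(accepted(repRoa), post)
  expect_gt(rejections(repRoa)[["roa"]], 0)
})
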