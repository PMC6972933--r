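reportFrom <- function(pairs, parc) {
  # build a SelectionReport directly from (parcelA, parcelB) name pairs
  tab <- labelTable(parc)
  id <- function(nm) tab$label_id[match(nm, tab$name)]
  n <- nrow(pairs)
  new("SelectionReport", accepted = seq_len(n),
      rejections = c(two_roi = 0L, orientation = 0L, roa = 0L,
                     posterior = 0L, lateral = 0L),
      assignments = data.frame(index = seq_len(n),
                               labelA = id(pairs[, 1]), labelB = id(pairs[, 2]),
                               parcelA = pairs[, 1], parcelB = pairs[, 2],
                               stringsAsFactors = FALSE),
      nInput = n)
}

test_that("connectivity matrix counts unordered endpoint pairs symmetrically", {
  parc <- tinyParcellation()
  m0 <- buildConnectivityMatrix(reportFrom(matrix(character(0), 0, 2), parc), parc)
  expect_true(all(counts(m0) == 0L))
  expect_identical(matrixTotal(m0), 0L)

  pairs <- rbind(c("V3A", "V4"), c("V3A", "V4"), c("V4", "V3A"), c("V7", "PIT"))
  m <- buildConnectivityMatrix(reportFrom(pairs, parc), parc)
  expect_identical(counts(m)["V3A", "V4"], 3L)
  expect_identical(counts(m)["V4", "V3A"], 3L)
  expect_identical(counts(m)["V7", "PIT"], 1L)
  expect_identical(matrixTotal(m), 4L)
  expect_true(isSymmetric(unname(counts(m))))
})

test_that("phantom connectivity matrix equals the generator truth pair table", {
  ph <- smallPhantom()
  parc <- parcellation(ph)
  rep <- runSelection(phantomTractogram(ph), parc, phantomCriteria(ph))
  m <- buildConnectivityMatrix(rep, parc, "L")
  tr <- truth(ph)
  tr <- tr[tr$bundle == "vof", ]
  nm <- rownames(counts(m))
  oracle <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (s in seq_len(nrow(tr))) {
    a <- tr$parcelA[s]; b <- tr$parcelB[s]
    oracle[a, b] <- oracle[a, b] + 1L
    if (a != b) oracle[b, a] <- oracle[b, a] + 1L
  }
  expect_identical(counts(m), oracle)
  expect_identical(matrixTotal(m), nrow(tr))
})

test_that("endpoint ratios follow the endpoints-per-group convention", {
  parc <- tinyParcellation()
  one <- endpointRatios(buildConnectivityMatrix(
    reportFrom(rbind(c("V3A", "V4")), parc), parc), tinyLabelTable())
  expect_equal(one$dorsal$percent[one$dorsal$parcel == "V3A"], 100)
  expect_equal(one$ventral$percent[one$ventral$parcel == "V4"], 100)

  two <- endpointRatios(buildConnectivityMatrix(
    reportFrom(rbind(c("V3A", "V4"), c("V3A", "PIT")), parc), parc),
    tinyLabelTable())
  expect_equal(two$dorsal$percent[two$dorsal$parcel == "V3A"], 100)
  expect_equal(two$ventral$percent[two$ventral$parcel == "V4"], 50)
  expect_equal(two$ventral$percent[two$ventral$parcel == "PIT"], 50)

  # diagonal connection contributes two endpoints to its parcel's group
  diag2 <- endpointRatios(buildConnectivityMatrix(
    reportFrom(rbind(c("V4", "V4"), c("V3A", "PIT")), parc), parc),
    tinyLabelTable())
  expect_equal(diag2$ventral$percent[diag2$ventral$parcel == "V4"], 200 / 3)
  # conservation within every group
  for (g in names(diag2)) {
    tot <- sum(diag2[[g]]$percent)
    expect_true(abs(tot - 100) < 1e-6 || tot == 0)
  }
})

test_that("connection ratios are percentages of the accepted total", {
  parc <- tinyParcellation()
  single <- connectionRatios(buildConnectivityMatrix(
    reportFrom(rbind(c("V3A", "V4")), parc), parc))
  expect_equal(single$percent, 100)
  m <- buildConnectivityMatrix(
    reportFrom(rbind(c("V3A", "V4"), c("V3A", "V4"), c("V3A", "V4"),
                     c("V7", "PIT")), parc), parc)
  cr <- connectionRatios(m)
  expect_equal(sort(cr$percent), c(25, 75))
  expect_equal(sum(cr$percent), 100)
  expect_error(connectionRatios(buildConnectivityMatrix(
    reportFrom(matrix(character(0), 0, 2), parc), parc)), "empty")
})

test_that("ratio tables are invariant under duplicating every streamline", {
  ph <- smallPhantom()
  parc <- parcellation(ph)
  rep <- runSelection(phantomTractogram(ph), parc, phantomCriteria(ph))
  m <- buildConnectivityMatrix(rep, parc, "L")
  asn <- assignments(rep)
  dup <- reportFrom(as.matrix(rbind(asn, asn)[, c("parcelA", "parcelB")]), parc)
  m2 <- buildConnectivityMatrix(dup, parc, "L")
  expect_identical(counts(m2), counts(m) * 2L)
  expect_equal(endpointRatios(m2, labelTable(parc)),
               endpointRatios(m, labelTable(parc)))
  expect_equal(connectionRatios(m2)$percent, connectionRatios(m)$percent)
})

test_that("tract volume counts unique voxels against a brute-force marker", {
  dims <- c(16L, 16L, 16L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -15
  geom <- scalarVolume(array(0.5, dims), aff)
  # brute-force oracle: mark voxels of the 1 mm-resampled polyline in a grid
  bruteVolume <- function(sl) {
    arr <- array(FALSE, dims)
    for (m in sl) {
      r <- resampleStreamline(m, 1)
      vox <- worldToVoxel(r, aff)
      for (q in seq_len(nrow(vox))) {
        v <- vox[q, ]
        if (all(v >= 0) && all(v < dims)) arr[v[1] + 1, v[2] + 1, v[3] + 1] <- TRUE
      }
    }
    sum(arr) * 8
  }
  straight <- list(rbind(c(0.3, 0.3, -5), c(0.3, 0.3, 5)))
  expect_equal(tractVolume(straight, geom), bruteVolume(straight))
  set.seed(55)
  bent <- replicate(5, {
    p <- matrix(rnorm(12, sd = 6), ncol = 3)
    p[order(p[, 3]), ]
  }, simplify = FALSE)
  expect_equal(tractVolume(bent, geom), bruteVolume(bent))
  # duplication leaves the unique-voxel volume unchanged
  expect_equal(tractVolume(c(straight, straight), geom), tractVolume(straight, geom))
  # disjoint bundles add
  shifted <- list(straight[[1]] + matrix(rep(c(10, 10, 0), each = 2), ncol = 3))
  expect_equal(tractVolume(c(straight, shifted), geom),
               tractVolume(straight, geom) + tractVolume(shifted, geom))
})

test_that("mean FA averages over the tract's unique voxel support", {
  dims <- c(16L, 16L, 16L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -15
  flat <- scalarVolume(array(0.55, dims), aff)
  sl <- list(rbind(c(0, 0, -10), c(0, 0, 10)))
  expect_equal(meanFa(sl, flat), 0.55)
  # bundle confined to a region of FA 0.2
  arr <- array(0.9, dims); arr[8:9, 8:9, ] <- 0.2
  expect_equal(meanFa(sl, scalarVolume(arr, aff)), 0.2)
  # noiseless phantom: configured bundle FA exactly
  cfg <- phantomConfig(nVof = 40L, nIlf = 0L, nAf = 0L, nClutter = 0L,
                       faNoiseSd = 0, seed = 8L)
  ph <- makePhantom(cfg)
  expect_equal(meanFa(phantomBundle(ph, "vof"), faVolume(ph)), 0.55)
})

test_that("per-connection metrics carry count, volume and FA per parcel pair", {
  ph <- smallPhantom()
  parc <- parcellation(ph)
  rep <- runSelection(phantomTractogram(ph), parc, phantomCriteria(ph))
  met <- tractMetrics(rep, phantomTractogram(ph), faVolume(ph), "L")
  tot <- met[met$parcelA == "total", ]
  expect_identical(as.integer(tot$n_tracts), length(accepted(rep)))
  expect_identical(as.integer(sum(met$n_tracts[met$parcelA != "total"])),
                   length(accepted(rep)))
  expect_true(all(met$volume_mm3 > 0))
  expect_true(all(met$mean_fa >= 0 & met$mean_fa <= 1))
})
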