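test_that("parcellation respects group geometry and parcel counts", {
  cfg <- smallPhantomConfig()
  parc <- makeParcellation(cfg)
  tab <- labelTable(parc)
  expect_identical(nrow(tab), 22L)
  expect_setequal(setdiff(unique(as.integer(labelGrid(parc))), 0L), tab$label_id)

  # centre of mass: dorsal parcels superior to lateral-occipital, ventral inferior
  comZ <- vapply(tab$label_id, function(id) {
    idx <- which(labelGrid(parc) == id, arr.ind = TRUE)
    mean(voxelToWorld(idx - 1L, affine(parc))[, 3])
  }, numeric(1))
  expect_true(min(comZ[tab$group == "dorsal"]) > max(comZ[tab$group == "lateral_occipital"]))
  expect_true(max(comZ[tab$group == "ventral"]) < min(comZ[tab$group == "lateral_occipital"]))

  # one-parcel config: every shell voxel of its group band carries that label
  one <- phantomConfig(parcels = data.frame(name = "V4", group = "ventral"),
                       nVof = 0L)
  oneParc <- makeParcellation(one)
  labs <- setdiff(unique(as.integer(labelGrid(oneParc))), 0L)
  expect_identical(labs, 1L)
  # drawing a bundle with an empty dorsal probability vector is an error
  expect_error(makeVofBundle(phantomConfig(parcels = data.frame(name = "V4",
                                                                group = "ventral")),
                             oneParc, "L"),
               "empty endpoint probability vector")
})

test_that("VOF truth endpoints follow the configured multinomials", {
  props <- c(V4 = 0.2, V8 = 0.2, PIT = 0.2, FFC = 0.2, VVC = 0.2)
  cfg <- phantomConfig(nVof = 10000L, nIlf = 0L, nAf = 0L, nClutter = 0L,
                       ventralShare = 1, endpointPropsVentral = props,
                       jitterMm = 0.5, seed = 9L)
  ph <- makePhantom(cfg)
  tr <- truth(ph)
  shares <- table(factor(tr$parcelB, levels = names(props))) / nrow(tr)
  # exact binomial 99.9% CI at n = 10^4, p = 0.2
  ci <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.2) / 10000
  expect_true(all(shares >= ci[1] & shares <= ci[2]))
  # and within 1.5 percentage points of the configured 20%
  expect_true(all(abs(shares - 0.2) < 0.015))

  # degenerate one-hot multinomial
  oneHot <- phantomConfig(nVof = 200L, nIlf = 0L, nAf = 0L, nClutter = 0L,
                          ventralShare = 1, endpointPropsVentral = c(V4 = 1),
                          seed = 3L)
  expect_true(all(truth(makePhantom(oneHot))$parcelB == "V4"))
  expect_identical(nStreamlines(phantomTractogram(
    makePhantom(phantomConfig(nVof = 0L, nIlf = 0L, nAf = 0L, nClutter = 0L)))), 0L)
})

test_that("identical config and seed give bitwise-identical phantoms", {
  cfg <- smallPhantomConfig(seed = 5L)
  a <- makePhantom(cfg); b <- makePhantom(cfg)
  expect_identical(truth(a), truth(b))
  expect_identical(streamlines(a), streamlines(b))
  expect_identical(scalarValues(faVolume(a)), scalarValues(faVolume(b)))
})

test_that("geometric separation invariants hold for every streamline", {
  ph <- smallPhantom()
  tr <- truth(ph)
  sl <- streamlines(ph)
  fracs <- t(vapply(sl, function(m) vofseg:::.axisFractions(m), numeric(3)))
  vof <- tr$bundle == "vof"; ilf <- tr$bundle == "ilf"; af <- tr$bundle == "af"
  # VOF superior-inferior dominant; ILF anterior-posterior dominant
  expect_true(all(apply(fracs[vof, ], 1, which.max) == 3))
  expect_true(all(fracs[vof, 3] >= 0.5))
  expect_true(all(apply(fracs[ilf, ], 1, which.max) == 2))
  # ILF strictly medial to the VOF corridor over the shared z-range
  vofMinAbsX <- min(abs(do.call(rbind, sl[tr$index[vof]])[, 1]))
  ilfPts <- do.call(rbind, sl[tr$index[ilf]])
  vofZ <- range(do.call(rbind, sl[tr$index[vof]])[, 3])
  inZ <- ilfPts[, 3] >= vofZ[1] & ilfPts[, 3] <= vofZ[2]
  expect_true(all(abs(ilfPts[inZ, 1]) < vofMinAbsX))
  # AF strictly anterior to the VOF corridor
  vofMaxY <- max(do.call(rbind, sl[tr$index[vof]])[, 2])
  afPts <- do.call(rbind, sl[tr$index[af]])
  expect_gt(min(afPts[, 2]), vofMaxY)
  # clutter never has both endpoints inside parcels
  arr <- labelGrid(parcellation(ph)); aff <- affine(parcellation(ph))
  for (i in tr$index[tr$bundle == "clutter"]) {
    ends <- worldToVoxel(sl[[i]][c(1, nrow(sl[[i]])), ], aff)
    labs <- arr[ends + 1L]
    expect_true(any(labs == 0L))
  }
})

test_that("left/right twin phantoms are exact mirrors", {
  cfgL <- phantomConfig(nVof = 150L, nIlf = 40L, nAf = 40L, nClutter = 40L,
                        seed = 21L, hemisphere = "L")
  cfgR <- phantomConfig(nVof = 150L, nIlf = 40L, nAf = 40L, nClutter = 40L,
                        seed = 21L, hemisphere = "R")
  L <- makePhantom(cfgL); R <- makePhantom(cfgR)
  mirror <- function(m) { m[, 1] <- -m[, 1]; m }
  expect_equal(streamlines(R), lapply(streamlines(L), mirror))
  dims <- dim(scalarValues(faVolume(L)))
  expect_equal(scalarValues(faVolume(R)),
               scalarValues(faVolume(L))[rev(seq_len(dims[1])), , ])
  expect_equal(labelGrid(parcellation(R)),
               labelGrid(parcellation(L))[rev(seq_len(dims[1])), , ])
})

test_that("FA field reflects bundle occupancy, background and noise settings", {
  cfg <- phantomConfig(nVof = 60L, nIlf = 0L, nAf = 0L, nClutter = 0L,
                       faNoiseSd = 0, seed = 13L)
  ph <- makePhantom(cfg)
  fa <- scalarValues(faVolume(ph))
  expect_true(all(fa %in% c(0.15, 0.55)))
  vox <- vofseg:::.tractVoxelSet(streamlines(ph), affine(faVolume(ph)), dim(fa))
  expect_true(all(fa[vox] == 0.55))
  expect_true(all(fa[-vox] == 0.15))

  # empty phantom: background everywhere, global mean at the configured level
  bg <- makePhantom(phantomConfig(nVof = 0L, nIlf = 0L, nAf = 0L, nClutter = 0L,
                                  faNoiseSd = 0.02, seed = 2L))
  expect_equal(mean(scalarValues(faVolume(bg))), 0.15, tolerance = 0.01)
  expect_true(all(scalarValues(faVolume(bg)) >= 0 & scalarValues(faVolume(bg)) <= 1))
})

test_that("published endpoint proportions are valid multinomials with the printed masses", {
  for (h in c("L", "R")) for (g in c("dorsal", "ventral", "lateral_occipital")) {
    p <- vofEndpointProps(h, g)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_setequal(names(p), defaultParcels()$name[defaultParcels()$group == g])
  }
})
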