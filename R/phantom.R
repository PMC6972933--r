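# Synthetic hemispheric phantom: parcellation, VOF/ILF/AF bundles, clutter
# and an FA field, with generator-controlled endpoint statistics so the whole
# dissection pipeline can be validated against ground truth.
#
# All geometry is constructed in a canonical LEFT-hemisphere frame (world
# x < 0) and mirrored about the mid-sagittal plane (x -> -x) for the right
# hemisphere; the grid is centred so the mirror maps voxel centers onto
# voxel centers exactly.

.phantomBands <- list(
  # world-mm closed intervals of voxel centers, left-hemisphere frame
  dorsal  = list(x = c(-47, -33), y = c(-71, -55), z = c(35, 55)),
  ventral = list(x = c(-47, -33), y = c(-71, -55), z = c(-55, -35)),
  lateral_occipital = list(x = c(-59, -51), y = c(-71, -55), z = c(-31, -15))
)

#' Default phantom parcel set
#'
#' 22 occipital parcels modelled on the HCP MMP1.0 vision-associated areas:
#' 7 dorsal (V3A, V3B, V3CD, V6, V6A, V7, IP0), 7 lateral-occipital (LO1,
#' LO2, LO3, V4t, MT, MST, FST) and 8 ventral (V4, V8, PIT, FFC, VVC,
#' VMV1-3).
#'
#' @return data.frame with columns `name` and `group`.
#' @export
defaultParcels <- function() {
  data.frame(
    name = c("V3A", "V3B", "V3CD", "V6", "V6A", "V7", "IP0",
             "LO1", "LO2", "LO3", "V4t", "MT", "MST", "FST",
             "V4", "V8", "PIT", "FFC", "VVC", "VMV1", "VMV2", "VMV3"),
    group = rep(c("dorsal", "lateral_occipital", "ventral"), c(7, 7, 8)),
    stringsAsFactors = FALSE)
}

.uniformProps <- function(parcels, group) {
  nm <- parcels$name[parcels$group == group]
  stats::setNames(rep(1 / length(nm), length(nm)), nm)
}

#' Phantom generator configuration
#'
#' Defaults define the standard well-separated study phantom: a 64x96x80 grid
#' of 2 mm voxels, 22 parcels, 2000 VOF streamlines (70% dorsal-to-ventral,
#' 30% dorsal-to-lateral-occipital), 300 ILF-like and 300 AF-like reference
#' streamlines, 400 clutter streamlines, 0.5 mm smooth jitter, bundle FA
#' 0.55 over background 0.15.
#'
#' @param hemisphere `"L"`, `"R"` or `"both"`.
#' @param gridShape voxel grid dimensions.
#' @param voxelMm isotropic voxel size in mm.
#' @param parcels data.frame with columns `name`, `group`.
#' @param nVof,nIlf,nAf,nClutter streamline counts per hemisphere.
#' @param endpointPropsDorsal,endpointPropsVentral,endpointPropsLateral named
#'   multinomial probability vectors over the parcels of each group (must sum
#'   to 1); defaults are uniform.
#' @param ventralShare probability that a VOF streamline targets the ventral
#'   (vs lateral-occipital) group.
#' @param jitterMm s.d. of the smooth Gaussian point jitter (truncated at
#'   +/-0.99 mm so a jittered endpoint can never leave its voxel).
#' @param bundleFa,backgroundFa,faNoiseSd FA field parameters.
#' @param ilfMarginMm,afMarginMm minimum medial / anterior clearance between
#'   the VOF corridor and the reference bundles.
#' @param seed RNG seed driving every draw.
#' @return A validated config list of class `phantomConfig`.
#' @export
phantomConfig <- function(hemisphere = "L", gridShape = c(64L, 96L, 80L),
                          voxelMm = 2, parcels = defaultParcels(),
                          nVof = 2000L, nIlf = 300L, nAf = 300L, nClutter = 400L,
                          endpointPropsDorsal = NULL, endpointPropsVentral = NULL,
                          endpointPropsLateral = NULL, ventralShare = 0.7,
                          jitterMm = 0.5, bundleFa = 0.55, backgroundFa = 0.15,
                          faNoiseSd = 0.02, ilfMarginMm = 6, afMarginMm = 6,
                          seed = 1L) {
  stopifnot(hemisphere %in% c("L", "R", "both"), voxelMm > 0,
            length(gridShape) == 3L, all(gridShape > 0),
            all(c("name", "group") %in% names(parcels)))
  if (is.null(endpointPropsDorsal)) endpointPropsDorsal <- .uniformProps(parcels, "dorsal")
  if (is.null(endpointPropsVentral)) endpointPropsVentral <- .uniformProps(parcels, "ventral")
  if (is.null(endpointPropsLateral)) {
    endpointPropsLateral <- .uniformProps(parcels, "lateral_occipital")
  }
  checkProps <- function(p, group) {
    if (!any(parcels$group == group)) {
      if (length(p) && !all(vapply(p, is.na, logical(1)))) {
        stop("endpoint proportions given for group ", group,
             " but the parcel set has no such parcels")
      }
      return(stats::setNames(numeric(0), character(0)))
    }
    if (!length(p)) stop("empty endpoint probability vector for group ", group)
    if (abs(sum(p) - 1) > 1e-9) stop("endpoint proportions for group ", group,
                                     " must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("negative endpoint proportion for group ", group)
    bad <- setdiff(names(p), parcels$name[parcels$group == group])
    if (length(bad)) stop("endpoint proportions name parcels outside group ",
                          group, ": ", paste(bad, collapse = ", "))
    p
  }
  cfg <- list(hemisphere = hemisphere, gridShape = as.integer(gridShape),
              voxelMm = voxelMm, parcels = parcels,
              nVof = as.integer(nVof), nIlf = as.integer(nIlf),
              nAf = as.integer(nAf), nClutter = as.integer(nClutter),
              endpointPropsDorsal = checkProps(endpointPropsDorsal, "dorsal"),
              endpointPropsVentral = checkProps(endpointPropsVentral, "ventral"),
              endpointPropsLateral = checkProps(endpointPropsLateral, "lateral_occipital"),
              ventralShare = ventralShare, jitterMm = jitterMm,
              bundleFa = bundleFa, backgroundFa = backgroundFa,
              faNoiseSd = faNoiseSd, ilfMarginMm = ilfMarginMm,
              afMarginMm = afMarginMm, seed = as.integer(seed))
  if (cfg$ventralShare < 0 || cfg$ventralShare > 1) stop("ventralShare must be in [0,1]")
  if (cfg$bundleFa < 0 || cfg$bundleFa > 1) stop("bundleFa must be in [0,1]")
  if (any(c(cfg$nVof, cfg$nIlf, cfg$nAf, cfg$nClutter) < 0)) stop("counts must be >= 0")
  if (cfg$jitterMm < 0) stop("jitterMm must be >= 0")
  class(cfg) <- "phantomConfig"
  cfg
}

.phantomAffine <- function(config) {
  vs <- config$voxelMm
  a <- diag(c(vs, vs, vs, 1))
  a[1:3, 4] <- -(config$gridShape - 1) * vs / 2  # centred grid: mirror-exact
  a
}

# distinct deterministic parcel colours, one ramp per group
.parcelColors <- function(parcels) {
  base <- c(dorsal = 240, lateral_occipital = 60, ventral = 120)  # hue degrees
  out <- matrix(0L, nrow(parcels), 3)
  for (g in unique(parcels$group)) {
    sel <- which(parcels$group == g)
    hue <- (base[[g]] + seq(0, 40, length.out = length(sel))) %% 360
    rgb <- grDevices::col2rgb(grDevices::hsv(hue / 360, 0.75, 0.9))
    out[sel, ] <- t(rgb)
  }
  out
}

#' Build the phantom parcellation volume
#'
#' Parcels are Voronoi regions (nearest deterministic lattice centroid)
#' restricted to three disjoint cortical bands of the occipital shell: the
#' dorsal group in a superior-posterior band, the ventral group in an
#' inferior band, and the lateral-occipital group in a lateral band between
#' them. Deterministic: uses no RNG.
#'
#' @param config a [phantomConfig()].
#' @return A [ParcellationVolume-class] (both hemispheres if configured).
#' @export
makeParcellation <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  dims <- config$gridShape
  aff <- .phantomAffine(config)
  labels <- array(0L, dims)
  hems <- if (config$hemisphere == "both") c("L", "R") else config$hemisphere
  parcels <- config$parcels
  rows <- do.call(rbind, lapply(hems, function(h) {
    cbind(parcels, hemisphere = h, stringsAsFactors = FALSE)
  }))
  rows$label_id <- seq_len(nrow(rows))
  cols <- .parcelColors(rows)
  rows$r <- cols[, 1]; rows$g <- cols[, 2]; rows$b <- cols[, 3]

  # world coordinates of all voxel centers, one axis at a time
  ax <- lapply(1:3, function(d) aff[d, d] * (seq_len(dims[d]) - 1) + aff[d, 4])
  for (h in hems) {
    for (g in names(.phantomBands)) {
      band <- .phantomBands[[g]]
      bx <- if (h == "L") band$x else sort(-band$x)
      ii <- which(ax[[1]] >= bx[1] & ax[[1]] <= bx[2])
      jj <- which(ax[[2]] >= band$y[1] & ax[[2]] <= band$y[2])
      kk <- which(ax[[3]] >= band$z[1] & ax[[3]] <= band$z[2])
      sel <- which(rows$group == g & rows$hemisphere == h)
      if (!length(sel)) next
      vox <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
      world <- cbind(ax[[1]][vox[, 1]], ax[[2]][vox[, 2]], ax[[3]][vox[, 3]])
      cen <- .bandCentroids(band, length(sel))
      if (h == "R") cen[, 1] <- -cen[, 1]
      if (anyDuplicated(round(cen, 6))) stop("overlapping parcel centroids")
      d2 <- outer(rowSums(world^2), rowSums(cen^2), "+") - 2 * world %*% t(cen)
      nearest <- max.col(-d2, ties.method = "first")
      labels[vox] <- rows$label_id[sel][nearest]
    }
  }
  parcellationVolume(labels, aff,
                     rows[, c("label_id", "name", "hemisphere", "group", "r", "g", "b")])
}

# deterministic centroid lattice spread over the band's (y, z) face
.bandCentroids <- function(band, k) {
  ny <- ceiling(sqrt(k)); nz <- ceiling(k / ny)
  ys <- band$y[1] + (seq_len(ny) - 0.5) / ny * diff(band$y)
  zs <- band$z[1] + (seq_len(nz) - 0.5) / nz * diff(band$z)
  grid <- expand.grid(y = ys, z = zs)[seq_len(k), ]
  cbind(x = mean(band$x), y = grid$y, z = grid$z)
}

# list of 0-based voxel index matrices per label id, expressed in the
# canonical left-hemisphere frame (x mirrored for right-hemisphere labels)
# and sorted in a frame-independent order, so the generator's voxel draws
# for left/right twin phantoms are exact mirrors under one seed
.canonicalVoxelLists <- function(parc, hemisphere) {
  keep <- parc@labelTable$label_id[parc@labelTable$hemisphere == hemisphere]
  idx <- which(parc@labels %in% keep)
  lab <- parc@labels[idx]
  dims <- dim(parc@labels)
  i <- (idx - 1) %% dims[1]
  j <- ((idx - 1) %/% dims[1]) %% dims[2]
  k <- (idx - 1) %/% (dims[1] * dims[2])
  if (hemisphere == "R") i <- dims[1] - 1 - i
  ord <- order(k, j, i)
  split.data.frame(cbind(i, j, k)[ord, , drop = FALSE], lab[ord])
}

.bezier <- function(ctrl, n = 24L) {
  t <- seq(0, 1, length.out = n)
  deg <- nrow(ctrl) - 1L
  w <- sapply(0:deg, function(d) choose(deg, d) * t^d * (1 - t)^(deg - d))
  w %*% ctrl
}

# smooth truncated Gaussian jitter: N(0, sd) drawn at ~20 mm knots, linearly
# interpolated between them, clamped to +/-0.99 mm per axis so a jittered
# endpoint always rounds back to its own 2 mm voxel
.smoothJitter <- function(n, sd) {
  if (sd <= 0 || n < 2) return(matrix(0, n, 3))
  k <- max(2L, ceiling(n / 20))
  at <- seq(1, n, length.out = k)
  vals <- matrix(pmin(0.99, pmax(-0.99, stats::rnorm(3 * k, 0, sd))), k, 3)
  cbind(approx(at, vals[, 1], xout = seq_len(n))$y,
        approx(at, vals[, 2], xout = seq_len(n))$y,
        approx(at, vals[, 3], xout = seq_len(n))$y)
}

.truncNorm <- function(n, sd, lim) pmin(lim, pmax(-lim, stats::rnorm(n, 0, sd)))

.axisFractions <- function(m) {
  d <- colSums(abs(diff(m)))
  tot <- sum(d)
  if (tot == 0) stop("zero total displacement")
  d / tot
}

#' Generate the VOF-like bundle with controlled endpoint statistics
#'
#' Each streamline: the dorsal endpoint parcel is drawn from
#' `endpointPropsDorsal`; the target group (ventral vs lateral-occipital)
#' from `ventralShare`; the target parcel from the matching proportion
#' vector. Endpoints sit at voxel centers drawn uniformly within the parcel,
#' the curve is a cubic Bezier with laterally displaced control points,
#' resampled at 1 mm and smoothly jittered. Superior-inferior dominance
#' (fraction >= 0.55) is asserted for every streamline; within-parcel
#' geometry (never the parcel draws) is redrawn if the assertion fails.
#'
#' @param config a [phantomConfig()].
#' @param parc the phantom [ParcellationVolume-class].
#' @param hemisphere `"L"` or `"R"`; geometry is mirrored for `"R"`.
#' @return list with `streamlines` (in world RAS mm) and `truth` data.frame
#'   (`bundle`, `hemisphere`, `labelA`, `labelB`, `parcelA`, `parcelB`).
#' @export
makeVofBundle <- function(config, parc, hemisphere = "L") {
  n <- config$nVof
  tab <- parc@labelTable
  if (n == 0L) {
    return(list(streamlines = list(), truth = .emptyTruth()))
  }
  voxLists <- .canonicalVoxelLists(parc, hemisphere)
  aff <- parc@affine
  lookupId <- function(name) {
    tab$label_id[tab$name == name & tab$hemisphere == hemisphere]
  }
  pd <- config$endpointPropsDorsal
  pv <- config$endpointPropsVentral
  pl <- config$endpointPropsLateral
  if (!length(pd)) stop("empty endpoint probability vector for group dorsal")
  if (config$ventralShare > 0 && !length(pv)) {
    stop("empty endpoint probability vector for group ventral")
  }
  if (config$ventralShare < 1 && !length(pl)) {
    stop("empty endpoint probability vector for group lateral_occipital")
  }
  # all multinomial draws first, in one documented RNG order
  dorsalName <- sample(names(pd), n, replace = TRUE, prob = pd)
  targetVentral <- stats::runif(n) < config$ventralShare
  targetName <- character(n)
  targetName[targetVentral] <- sample(names(pv), sum(targetVentral),
                                      replace = TRUE, prob = pv)
  targetName[!targetVentral] <- sample(names(pl), sum(!targetVentral),
                                       replace = TRUE, prob = pl)
  sl <- vector("list", n)
  labA <- integer(n); labB <- integer(n)
  for (s in seq_len(n)) {
    labA[s] <- lookupId(dorsalName[s])
    labB[s] <- lookupId(targetName[s])
    vA <- voxLists[[as.character(labA[s])]]
    vB <- voxLists[[as.character(labB[s])]]
    for (try in 1:50) {
      p0 <- voxelToWorld(vA[sample.int(nrow(vA), 1L), ], aff)[1, ]
      p3 <- voxelToWorld(vB[sample.int(nrow(vB), 1L), ], aff)[1, ]
      d <- p3 - p0
      del1 <- c(.truncNorm(2L, 1.5, 3), 0)  # x, y only; z kept monotone
      del2 <- c(.truncNorm(2L, 1.5, 3), 0)
      ctrl <- rbind(p0, p0 + d / 3 + del1, p0 + 2 * d / 3 + del2, p3)
      m <- resampleStreamline(.bezier(ctrl), 1)
      jit <- .smoothJitter(nrow(m), config$jitterMm)
      jit[1, ] <- pmin(0.99, pmax(-0.99, jit[1, ]))
      jit[nrow(m), ] <- pmin(0.99, pmax(-0.99, jit[nrow(m), ]))
      m <- m + jit
      fr <- .axisFractions(m)
      if (fr[3] >= 0.55 && which.max(fr) == 3L) break
      if (try == 50) stop("could not realise a superior-inferior dominant streamline")
    }
    if (hemisphere == "R") m[, 1] <- -m[, 1]
    sl[[s]] <- m
  }
  truth <- data.frame(bundle = "vof", hemisphere = hemisphere,
                      labelA = labA, labelB = labB,
                      parcelA = dorsalName, parcelB = targetName,
                      stringsAsFactors = FALSE)
  list(streamlines = sl, truth = truth)
}

.emptyTruth <- function() {
  data.frame(bundle = character(0), hemisphere = character(0),
             labelA = integer(0), labelB = integer(0),
             parcelA = character(0), parcelB = character(0),
             stringsAsFactors = FALSE)
}

.naTruth <- function(bundle, hemisphere, n) {
  if (n == 0L) return(.emptyTruth())
  data.frame(bundle = bundle, hemisphere = hemisphere,
             labelA = NA_integer_, labelB = NA_integer_,
             parcelA = NA_character_, parcelB = NA_character_,
             stringsAsFactors = FALSE)[rep(1, n), ]
}

#' Generate the ILF-like and AF-like reference bundles
#'
#' ILF-like streamlines run anterior-posterior (dominant axis y) in a
#' corridor strictly medial to the VOF (|x| smaller by at least
#' `ilfMarginMm`) across the VOF's z-overlap. AF-like streamlines arc
#' anterior to the VOF corridor (y larger by at least `afMarginMm`).
#'
#' @inheritParams makeVofBundle
#' @return list with `ilf` and `af` streamline lists (world RAS mm).
#' @export
makeReferenceBundles <- function(config, hemisphere = "L") {
  half <- (config$gridShape - 1) * config$voxelMm / 2
  if (config$ilfMarginMm > 2 * half[1] || config$afMarginMm > 2 * half[2]) {
    stop("reference-bundle margins exceed the grid extent")
  }
  mir <- function(m) { if (hemisphere == "R") m[, 1] <- -m[, 1]; m }
  vofMinAbsX <- 33 - 4  # corridor inner wall incl. control/jitter excursions
  vofMaxY <- -55 + 4
  ilf <- vector("list", config$nIlf)
  for (s in seq_len(config$nIlf)) {
    x0 <- stats::runif(1, -19, -13)
    z0 <- stats::runif(1, -29, 9)
    dx <- .truncNorm(2L, 1, 1)
    dz <- .truncNorm(2L, 1, 1)
    ctrl <- rbind(c(x0, -75, z0), c(x0 + dx[1], -60, z0 + dz[1]),
                  c(x0 + dx[2], -45, z0 + dz[2]), c(x0, -31, z0))
    m <- resampleStreamline(.bezier(ctrl), 1)
    m <- m + .smoothJitter(nrow(m), config$jitterMm)
    fr <- .axisFractions(m)
    stopifnot(which.max(fr) == 2L, max(abs(m[, 1])) < vofMinAbsX - config$ilfMarginMm + 1e-9)
    ilf[[s]] <- mir(m)
  }
  af <- vector("list", config$nAf)
  for (s in seq_len(config$nAf)) {
    x0 <- stats::runif(1, -45, -35)
    y0 <- -43 + stats::runif(1, 0, 4)
    y1 <- 25 - stats::runif(1, 0, 4)
    z0 <- -30 + stats::runif(1, -4, 4)
    z1 <- -30 + stats::runif(1, -4, 4)
    ctrl <- rbind(c(x0, y0, z0), c(x0 + .truncNorm(1L, 2, 4), (y0 + y1) / 2, 70),
                  c(x0, y1, z1))
    m <- resampleStreamline(.bezier(ctrl), 1)
    m <- m + .smoothJitter(nrow(m), config$jitterMm)
    stopifnot(min(m[, 2]) > vofMaxY + config$afMarginMm - 1e-9)
    af[[s]] <- mir(m)
  }
  list(ilf = ilf, af = af)
}

#' Generate clutter streamlines
#'
#' Uniform random short arcs with random dominant axis, placed anterior to
#' the parcel bands so neither endpoint can fall inside a parcel; they
#' exercise the rejection paths of every selection filter.
#'
#' @inheritParams makeVofBundle
#' @param parc phantom parcellation (used only to assert endpoints miss it).
#' @return list of streamlines (world RAS mm).
#' @export
makeClutter <- function(config, parc, hemisphere = "L") {
  out <- vector("list", config$nClutter)
  dims <- dim(parc@labels)
  for (s in seq_len(config$nClutter)) {
    cen <- c(stats::runif(1, -50, -12), stats::runif(1, -25, 25),
             stats::runif(1, -40, 40))
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    len <- stats::runif(1, 20, 40)
    bump <- .truncNorm(3L, 3, 6)
    ctrl <- rbind(cen - u * len / 2, cen + bump, cen + u * len / 2)
    m <- resampleStreamline(.bezier(ctrl), 1)
    m <- m + .smoothJitter(nrow(m), config$jitterMm)
    if (hemisphere == "R") m[, 1] <- -m[, 1]
    ends <- worldToVoxel(m[c(1, nrow(m)), ], parc@affine)
    idx <- .voxelLinearIndex(ends, dims)
    lab <- ifelse(is.na(idx), 0L, parc@labels[pmax(idx, 1L)])
    lab[is.na(idx)] <- 0L
    stopifnot(any(lab == 0L))  # never both endpoints inside parcels
    out[[s]] <- m
  }
  out
}

#' Generate the phantom FA field
#'
#' Voxels traversed by any generated streamline carry `bundleFa`, the rest
#' `backgroundFa`; a smooth Gaussian field (drawn on a coarse lattice and
#' trilinearly upsampled) with s.d. `faNoiseSd` is added and the result is
#' clipped to [0, 1].
#'
#' @param config a [phantomConfig()].
#' @param tract a [Tractogram-class] of all phantom streamlines.
#' @return A [ScalarVolume-class].
#' @export
makeFa <- function(config, tract) {
  dims <- config$gridShape
  aff <- .phantomAffine(config)
  arr <- array(config$backgroundFa, dims)
  if (nStreamlines(tract) > 0) {
    vox <- .tractVoxelSet(tract@streamlines, aff, dims)
    arr[vox] <- config$bundleFa
  }
  if (config$faNoiseSd > 0) {
    step <- 8L
    co <- lapply(dims, function(d) seq(1, d, by = step))
    coarse <- array(stats::rnorm(prod(lengths(co)), 0, config$faNoiseSd),
                    lengths(co))
    noise <- .trilinearUpsample(coarse, co, dims)
    # canonical-frame noise: right-hemisphere twins get the mirrored field so
    # twin phantoms under one seed are mirror-symmetric voxel for voxel, and
    # a bilateral phantom gets a symmetrized field so it is an exact null
    # for laterality analyses
    if (config$hemisphere == "R") {
      noise <- noise[rev(seq_len(dims[1])), , ]
    } else if (config$hemisphere == "both") {
      half <- seq_len(dims[1] %/% 2)
      noise[dims[1] + 1 - half, , ] <- noise[half, , ]
    }
    arr <- arr + noise
  }
  arr[arr < 0] <- 0; arr[arr > 1] <- 1
  scalarVolume(arr, aff)
}

.trilinearUpsample <- function(coarse, knots, dims) {
  interpAxis <- function(a, knotPos, d, axis) {
    full <- seq_len(d)
    ap <- apply(a, setdiff(1:3, axis), function(v) {
      approx(knotPos, v, xout = full, rule = 2)$y
    })
    # apply collapses the chosen axis to dim 1; restore order
    dims3 <- dim(a); dims3[axis] <- d
    perm <- order(c(axis, setdiff(1:3, axis)))
    aperm(array(ap, c(d, dim(a)[setdiff(1:3, axis)])), perm)
  }
  out <- coarse
  for (axis in 1:3) out <- interpAxis(out, knots[[axis]], dims[axis], axis)
  out
}

#' Generate a complete phantom
#'
#' One RNG (seeded from `config$seed`) drives all draws in a fixed order per
#' hemisphere: VOF parcel draws, VOF geometry, ILF, AF, clutter, then the FA
#' noise field. Identical configs therefore give bitwise-identical phantoms.
#'
#' @param config a [phantomConfig()].
#' @return A [Phantom-class].
#' @export
makePhantom <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  set.seed(config$seed)
  parc <- makeParcellation(config)
  hems <- if (config$hemisphere == "both") c("L", "R") else config$hemisphere
  sl <- list(); truth <- .emptyTruth()
  for (h in hems) {
    # both hemispheres consume identical draws, so (at equal counts) the two
    # sides of a bilateral phantom are exact mirror twins
    set.seed(config$seed)
    cfgh <- config
    # optional hemispheric count asymmetry (e.g. rightward-lateralized VOF)
    if (h == "R" && !is.null(config$nVofRight)) cfgh$nVof <- config$nVofRight
    vof <- makeVofBundle(cfgh, parc, h)
    refs <- makeReferenceBundles(config, h)
    clut <- makeClutter(config, parc, h)
    sl <- c(sl, vof$streamlines, refs$ilf, refs$af, clut)
    truth <- rbind(truth, vof$truth,
                   .naTruth("ilf", h, config$nIlf),
                   .naTruth("af", h, config$nAf),
                   .naTruth("clutter", h, config$nClutter))
  }
  truth$index <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  tract <- tractogram(sl, spaceId = "phantom_world_ras_mm",
                      voxelSize = rep(config$voxelMm, 3))
  set.seed(config$seed + 1L)  # FA noise stream decoupled from bundle draws
  fa <- makeFa(config, tract)
  new("Phantom", parcellation = parc, tractogram = tract, fa = fa,
      truth = truth, config = unclass(config))
}

#' Reference bundles of a phantom as Tractograms
#'
#' Convenience split of a phantom's streamlines by ground-truth bundle.
#'
#' @param phantom a [Phantom-class].
#' @param bundle one of `"vof"`, `"ilf"`, `"af"`, `"clutter"`.
#' @param hemisphere optional `"L"`/`"R"` restriction.
#' @return A [Tractogram-class].
#' @export
phantomBundle <- function(phantom, bundle, hemisphere = NULL) {
  sel <- phantom@truth$bundle == bundle
  if (!is.null(hemisphere)) sel <- sel & phantom@truth$hemisphere == hemisphere
  tractogram(phantom@tractogram@streamlines[phantom@truth$index[sel]],
             spaceId = phantom@tractogram@spaceId,
             voxelSize = phantom@tractogram@voxelSize)
}
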