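# Shared fixtures, built in code. The small phantom keeps the full bundle
# structure (VOF + ILF + AF + clutter) at reduced counts.

smallPhantomConfig <- function(seed = 42L, ...) {
  phantomConfig(nVof = 400L, nIlf = 120L, nAf = 120L, nClutter = 150L,
                seed = seed, ...)
}

.phantomCache <- new.env(parent = emptyenv())

smallPhantom <- function() {
  if (is.null(.phantomCache$ph)) .phantomCache$ph <- makePhantom(smallPhantomConfig())
  .phantomCache$ph
}

phantomCriteria <- function(ph, hemisphere = "L", ...) {
  selectionCriteria(lateralReference = phantomBundle(ph, "ilf", hemisphere),
                    posteriorReference = phantomBundle(ph, "af", hemisphere),
                    hemisphere = hemisphere, ...)
}

# tiny hand-built parcellation: dims voxels of 2 mm, affine centred at 0,
# labels assigned from an explicit list of (i, j, k, label) rows
tinyParcellation <- function(dims = c(10L, 10L, 10L), voxelMm = 2,
                             voxels = NULL, table = tinyLabelTable()) {
  arr <- array(0L, dims)
  if (!is.null(voxels)) {
    arr[voxels[, 1:3, drop = FALSE] + 1L] <- as.integer(voxels[, 4])
  }
  aff <- diag(c(rep(voxelMm, 3), 1))
  aff[1:3, 4] <- -(dims - 1) * voxelMm / 2
  parcellationVolume(arr, aff, table)
}

tinyLabelTable <- function() {
  data.frame(label_id = 1:4,
             name = c("V3A", "V7", "V4", "PIT"),
             hemisphere = "L",
             group = c("dorsal", "dorsal", "ventral", "ventral"),
             r = c(0, 10, 20, 30), g = c(0, 10, 20, 30), b = c(255, 245, 0, 10),
             stringsAsFactors = FALSE)
}

# independent brute-force endpoint assigner: exhaustive scan of every voxel
bruteAssign <- function(p, parc, radiusMm = 2) {
  arr <- labelGrid(parc)
  dims <- dim(arr)
  aff <- affine(parc)
  best <- NA_integer_; bestD <- Inf
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1)) {
    lab <- arr[i + 1, j + 1, k + 1]
    if (lab == 0L) next
    cen <- voxelToWorld(c(i, j, k), aff)[1, ]
    d <- sqrt(sum((cen - p)^2))
    vox <- worldToVoxel(rbind(p), aff)[1, ]
    if (all(vox == c(i, j, k))) return(lab)  # containing voxel wins outright
    if (d <= radiusMm + 1e-12 &&
        (d < bestD - 1e-9 || (abs(d - bestD) <= 1e-9 && lab < best))) {
      best <- lab; bestD <- d
    }
  }
  best
}

# independent per-slab relative-position check for one candidate streamline
bruteRelative <- function(cand, refPts, relation, hemisphere, slabMm = 5,
                          majority = 1) {
  slabOf <- function(z) floor(z / slabMm)
  cs <- slabOf(cand[, 3]); rs <- slabOf(refPts[, 3])
  shared <- intersect(unique(cs), unique(rs))
  if (!length(shared)) return(TRUE)
  ok <- vapply(shared, function(s) {
    cm <- median(cand[cs == s, if (relation == "lateral") 1 else 2])
    rm <- median(refPts[rs == s, if (relation == "lateral") 1 else 2])
    if (relation == "posterior") cm < rm
    else if (hemisphere == "L") cm < rm else cm > rm
  }, logical(1))
  mean(ok) >= majority - 1e-12
}

maxPointDiff <- function(a, b) {
  stopifnot(nStreamlines(a) == nStreamlines(b))
  if (nStreamlines(a) == 0L) return(0)
  max(mapply(function(p, q) max(abs(p - q)), streamlines(a), streamlines(b)))
}
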