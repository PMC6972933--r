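# Endpoint analysis: parcel-by-parcel termination counts, endpoint and
# connection ratio tables, tract volume and mean FA over the tract's
# unique-voxel support.

#' Build the parcel-by-parcel connectivity matrix
#'
#' Each accepted streamline increments exactly one unordered parcel pair
#' (both triangles of the symmetric matrix; the diagonal for streamlines
#' terminating twice in one parcel). Rows/columns cover every parcel of the
#' criteria hemisphere present in the label table.
#'
#' @param report a [SelectionReport-class].
#' @param parc the [ParcellationVolume-class] the selection used.
#' @param hemisphere `"L"` or `"R"` (parcels of this hemisphere form the
#'   matrix axes).
#' @return A [ConnectivityMatrix-class].
#' @export
buildConnectivityMatrix <- function(report, parc, hemisphere = "L") {
  asn <- report@assignments
  if (length(report@accepted) && any(is.na(asn$labelA) | is.na(asn$labelB))) {
    bad <- asn$index[is.na(asn$labelA) | is.na(asn$labelB)]
    stop("missing endpoint assignment for streamline(s) ",
         paste(bad, collapse = ", "))
  }
  tab <- parc@labelTable
  tab <- tab[tab$hemisphere == hemisphere, , drop = FALSE]
  nm <- tab$name
  m <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(asn)) {
    a <- match(asn$labelA, tab$label_id)
    b <- match(asn$labelB, tab$label_id)
    if (any(is.na(a)) || any(is.na(b))) {
      stop("assignments refer to parcels outside hemisphere ", hemisphere)
    }
    for (s in seq_along(a)) {
      m[a[s], b[s]] <- m[a[s], b[s]] + 1L
      if (a[s] != b[s]) m[b[s], a[s]] <- m[b[s], a[s]] + 1L
    }
  }
  new("ConnectivityMatrix", counts = m, hemisphere = hemisphere)
}

# endpoint count per parcel: row sums plus the diagonal again, because a
# diagonal streamline puts both of its endpoints in that parcel
.endpointCounts <- function(m) rowSums(m@counts) + diag(m@counts)

#' Endpoint-projection ratio tables per parcel group
#'
#' For group g, a parcel's value is 100 x (endpoints falling in it) /
#' (endpoints falling in any parcel of g). An accepted streamline
#' contributes one endpoint to the group of each of its two parcels (two to
#' the same group if both ends share a group).
#'
#' @param m a [ConnectivityMatrix-class].
#' @param table the label table annotating each parcel's group.
#' @return Named list of data.frames (one per group present) with columns
#'   `parcel` and `percent`; percentages sum to 100 within each group with
#'   any endpoints.
#' @export
endpointRatios <- function(m, table) {
  tab <- table[table$hemisphere == m@hemisphere, , drop = FALSE]
  cnt <- .endpointCounts(m)
  grp <- tab$group[match(names(cnt), tab$name)]
  out <- list()
  for (g in unique(grp)) {
    sel <- which(grp == g)
    tot <- sum(cnt[sel])
    pct <- if (tot > 0) 100 * cnt[sel] / tot else rep(0, length(sel))
    out[[g]] <- data.frame(parcel = names(cnt)[sel], percent = unname(pct),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Connection ratio table
#'
#' Percentage of accepted streamlines carried by each parcel pair:
#' 100 x count / total over the unordered pairs (upper triangle including
#' the diagonal). Entries sum to 100.
#'
#' @param m a non-empty [ConnectivityMatrix-class].
#' @return data.frame with `parcelA`, `parcelB`, `count`, `percent`,
#'   restricted to pairs with nonzero count, sorted by decreasing percent.
#' @export
connectionRatios <- function(m) {
  total <- matrixTotal(m)
  if (total == 0L) stop("empty connectivity matrix: no accepted streamlines")
  cm <- m@counts
  ut <- which(upper.tri(cm, diag = TRUE) & cm > 0, arr.ind = TRUE)
  out <- data.frame(parcelA = rownames(cm)[ut[, 1]],
                    parcelB = colnames(cm)[ut[, 2]],
                    count = cm[ut], percent = 100 * cm[ut] / total,
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$parcelA, out$parcelB), , drop = FALSE]
}

#' Tract volume in mm^3
#'
#' The number of unique voxels intersected by any streamline point after
#' 1 mm arc-length resampling, times the voxel volume. Unique voxels, not
#' per-streamline sums: overlapping streamlines are not double-counted.
#'
#' @param streamlines a [Tractogram-class] or list of streamline matrices.
#' @param geometry a [ScalarVolume-class] or [ParcellationVolume-class]
#'   supplying the voxel grid and affine.
#' @return Volume in mm^3.
#' @export
tractVolume <- function(streamlines, geometry) {
  sl <- if (is(streamlines, "Tractogram")) streamlines@streamlines else streamlines
  if (!length(sl)) stop("at least one streamline required")
  aff <- affine(geometry)
  dims <- dim(if (is(geometry, "ParcellationVolume")) geometry@labels else geometry@values)
  vox <- .tractVoxelSet(sl, aff, dims)
  length(vox) * abs(det(aff[1:3, 1:3]))
}

#' Mean FA over a tract's voxel support
#'
#' Unweighted mean of the FA values over the same unique-voxel set that
#' [tractVolume()] counts, keeping volume and FA on identical support.
#'
#' @param streamlines a [Tractogram-class] or list of streamline matrices.
#' @param fa a [ScalarVolume-class] FA map.
#' @return Mean FA (dimensionless).
#' @export
meanFa <- function(streamlines, fa) {
  sl <- if (is(streamlines, "Tractogram")) streamlines@streamlines else streamlines
  if (!length(sl)) stop("at least one streamline required")
  vox <- .tractVoxelSet(sl, fa@affine, dim(fa@values))
  mean(fa@values[vox])
}

#' Per-connection tract metrics
#'
#' Streamline count, tract volume and mean FA for every parcel pair of a
#' selection, the per-connection quantities that hemispheric laterality is
#' computed from.
#'
#' @param report a [SelectionReport-class].
#' @param t the [Tractogram-class] the selection ran on.
#' @param fa a [ScalarVolume-class] FA map.
#' @param hemisphere `"L"` or `"R"` tag.
#' @return data.frame with `parcelA`, `parcelB`, `hemisphere`, `n_tracts`,
#'   `volume_mm3`, `mean_fa`, plus a `"total"` row over all accepted
#'   streamlines.
#' @export
tractMetrics <- function(report, t, fa, hemisphere = "L") {
  asn <- report@assignments
  if (!nrow(asn)) {
    return(data.frame(parcelA = character(0), parcelB = character(0),
                      hemisphere = character(0), n_tracts = integer(0),
                      volume_mm3 = numeric(0), mean_fa = numeric(0)))
  }
  a <- pmin(asn$parcelA, asn$parcelB); b <- pmax(asn$parcelA, asn$parcelB)
  key <- paste(a, b, sep = "|")
  rows <- lapply(split(asn$index, key), function(idx) {
    sl <- t@streamlines[idx]
    c(n_tracts = length(idx), volume_mm3 = tractVolume(sl, fa),
      mean_fa = meanFa(sl, fa))
  })
  keys <- strsplit(names(rows), "|", fixed = TRUE)
  out <- data.frame(parcelA = vapply(keys, `[`, "", 1),
                    parcelB = vapply(keys, `[`, "", 2),
                    hemisphere = hemisphere,
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  allSl <- t@streamlines[asn$index]
  out <- rbind(out, data.frame(parcelA = "total", parcelB = "total",
                               hemisphere = hemisphere,
                               n_tracts = nrow(asn),
                               volume_mm3 = tractVolume(allSl, fa),
                               mean_fa = meanFa(allSl, fa)))
  rownames(out) <- NULL
  out
}
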