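# The dissection procedure: two-ROI endpoint selection over parcel groups,
# superior-inferior orientation classification (the "blue" fibres of an RGB
# directional map), region-of-avoidance exclusion, and relative-position
# filtering against the reference bundles (posterior to AF, lateral to ILF).

#' Classify the dominant displacement axis of a streamline
#'
#' The fraction for axis k is the summed absolute per-segment displacement
#' along k divided by the total over all three axes — the quantity an RGB
#' directional map encodes (red LR, green AP, blue SI). The dominant axis is
#' the argmax; exact ties are broken SI > AP > LR.
#'
#' @param s an n-by-3 streamline matrix (world RAS mm) or a
#'   [Tractogram-class] (classified per streamline).
#' @return A list with `dominantAxis` (`"LR"`, `"AP"` or `"SI"`) and
#'   `fractions` (named, sums to 1); for a Tractogram, a list of such lists.
#' @export
classifyOrientation <- function(s) {
  if (is(s, "Tractogram")) return(lapply(s@streamlines, classifyOrientation))
  if (nrow(s) < 2L) stop("streamline needs at least 2 points")
  fr <- .axisFractions(s)
  names(fr) <- c("LR", "AP", "SI")
  # ties broken SI > AP > LR: which.max takes the first maximum in this order
  pri <- c("SI", "AP", "LR")
  dom <- pri[which.max(fr[pri])]
  list(dominantAxis = dom, fractions = fr)
}

#' Assign the parcel of an endpoint coordinate
#'
#' Returns the label of the containing voxel if nonzero; otherwise the
#' nonzero label of the nearest voxel center within `radiusMm` (ties:
#' smallest Euclidean distance, then smallest label id); `NA` if no labelled
#' voxel lies within the radius.
#'
#' @param p length-3 world coordinate (or n-by-3 matrix of them).
#' @param parc a [ParcellationVolume-class].
#' @param radiusMm search radius in mm (default 2).
#' @return Integer label id(s), `NA` where unassigned.
#' @export
assignEndpointParcel <- function(p, parc, radiusMm = 2) {
  p <- rbind(p)
  if (!all(is.finite(p))) stop("endpoint coordinates must be finite")
  dims <- dim(parc@labels)
  vox <- worldToVoxel(p, parc@affine)
  idx <- .voxelLinearIndex(vox, dims)
  lab <- rep(NA_integer_, nrow(p))
  ok <- !is.na(idx)
  lab[ok] <- parc@labels[idx[ok]]
  lab[!is.na(lab) & lab == 0L] <- NA_integer_
  todo <- which(is.na(lab))
  if (length(todo) && radiusMm > 0) {
    # candidate offsets within the bounding box of the radius, in voxels
    vs <- sqrt(colSums(parc@affine[1:3, 1:3]^2))
    span <- ceiling(radiusMm / vs)
    off <- as.matrix(expand.grid(-span[1]:span[1], -span[2]:span[2], -span[3]:span[3]))
    voxf <- worldToVoxel(p, parc@affine, round = FALSE)
    for (t in todo) {
      cand <- sweep(off, 2, roundHalfAway(voxf[t, ]), "+")
      ci <- .voxelLinearIndex(cand, dims)
      keep <- !is.na(ci)
      cand <- cand[keep, , drop = FALSE]; ci <- ci[keep]
      cl <- parc@labels[ci]
      nz <- cl != 0L
      if (!any(nz)) next
      centers <- voxelToWorld(cand[nz, , drop = FALSE], parc@affine)
      d <- sqrt(rowSums(sweep(centers, 2, p[t, ])^2))
      inR <- d <= radiusMm + 1e-12
      if (!any(inR)) next
      dl <- cl[nz][inR]; dd <- d[inR]
      # nearest first; distances equal within 1e-9 tie-break to smallest id
      lab[t] <- min(dl[dd <= min(dd) + 1e-9])
    }
  }
  lab
}

# resolve group names / explicit parcel names to label-id sets
.resolveLabels <- function(sel, tab, hemisphere) {
  tab <- tab[tab$hemisphere == hemisphere, , drop = FALSE]
  groups <- intersect(sel, c("dorsal", "lateral_occipital", "ventral", "other"))
  names_ <- setdiff(sel, groups)
  ids <- c(tab$label_id[tab$group %in% groups], tab$label_id[tab$name %in% names_])
  unknown <- setdiff(names_, tab$name)
  if (length(unknown)) stop("unknown parcel name(s): ", paste(unknown, collapse = ", "))
  ids <- sort(unique(ids))
  if (!length(ids)) stop("criteria resolve to an empty parcel set")
  ids
}

#' Two-ROI candidate selection
#'
#' A streamline is a candidate iff one terminal point assigns to a group-A
#' parcel and the other to a group-B parcel, in either end order.
#'
#' @param t a [Tractogram-class].
#' @param parc a [ParcellationVolume-class].
#' @param criteria a [selectionCriteria()].
#' @return data.frame with `index`, `labelA`, `labelB` (A = group-A side)
#'   for candidate streamlines.
#' @export
selectTwoRoi <- function(t, parc, criteria) {
  validObject(criteria)
  tab <- parc@labelTable
  idsA <- .resolveLabels(criteria@groupA, tab, criteria@hemisphere)
  idsB <- .resolveLabels(criteria@groupB, tab, criteria@hemisphere)
  if (length(intersect(idsA, idsB))) stop("groupA and groupB overlap after resolution")
  n <- nStreamlines(t)
  if (n == 0L) {
    return(data.frame(index = integer(0), labelA = integer(0), labelB = integer(0)))
  }
  first <- do.call(rbind, lapply(t@streamlines, function(m) m[1, ]))
  last <- do.call(rbind, lapply(t@streamlines, function(m) m[nrow(m), ]))
  labF <- assignEndpointParcel(first, parc, criteria@endpointRadiusMm)
  labL <- assignEndpointParcel(last, parc, criteria@endpointRadiusMm)
  fA <- labF %in% idsA; fB <- labF %in% idsB
  lA <- labL %in% idsA; lB <- labL %in% idsB
  fwd <- fA & lB
  rev_ <- fB & lA & !fwd
  idx <- which(fwd | rev_)
  data.frame(index = idx,
             labelA = ifelse(fwd[idx], labF[idx], labL[idx]),
             labelB = ifelse(fwd[idx], labL[idx], labF[idx]))
}

#' Region-of-avoidance filter
#'
#' Removes every streamline with at least one point whose (nearest) voxel is
#' inside the binary mask.
#'
#' @param t a [Tractogram-class].
#' @param candidates integer streamline indices to test.
#' @param roa a binary [ScalarVolume-class] mask (nonzero = avoid).
#' @return The retained subset of `candidates`.
#' @export
filterRoa <- function(t, candidates, roa) {
  stopifnot(is(roa, "ScalarVolume"))
  vals <- roa@values
  if (!all(vals %in% c(0, 1))) stop("ROA mask must be binary")
  dims <- dim(vals)
  hit <- vapply(candidates, function(i) {
    vox <- worldToVoxel(t@streamlines[[i]], roa@affine)
    idx <- .voxelLinearIndex(vox, dims)
    idx <- idx[!is.na(idx)]
    length(idx) > 0 && any(vals[idx] != 0)
  }, logical(1))
  candidates[!hit]
}

# per-slab medians over a z-slab grid anchored at multiples of slabMm
.slabMedians <- function(m, valueCol, slabMm) {
  slab <- floor(m[, 3] / slabMm)
  vapply(split(m[, valueCol], slab), stats::median, numeric(1))
}

#' Relative-position filter against a reference bundle
#'
#' Operationalises "lateral to the ILF" / "posterior to the AF": the z-range
#' is divided into slabs of `slabMm` (anchored at multiples of `slabMm` so
#' every streamline sees the same slab grid); in each slab occupied by both
#' the candidate and the reference, the candidate's median x (lateral) or
#' median y (posterior) is compared with the reference points' median. A
#' candidate is retained iff the relation holds in at least
#' `majority` of the shared slabs ("lateral" follows the hemisphere sign
#' rule: smaller x on the left, larger x on the right; "posterior" is
#' smaller y). Candidates sharing no slab with the reference are retained
#' (filter inapplicable) and reported via the `inapplicable` attribute.
#'
#' @param t a [Tractogram-class].
#' @param candidates integer streamline indices to test.
#' @param reference a non-empty reference [Tractogram-class].
#' @param relation `"lateral"` or `"posterior"`.
#' @param hemisphere `"L"` or `"R"` (sign rule for `"lateral"`).
#' @param slabMm slab thickness in mm (default 5).
#' @param majority required fraction of satisfying shared slabs (default 1).
#' @return Retained subset of `candidates`, with attribute `inapplicable`
#'   giving the indices retained because no slab was shared.
#' @export
filterRelativePosition <- function(t, candidates, reference,
                                   relation = c("lateral", "posterior"),
                                   hemisphere = c("L", "R"), slabMm = 5,
                                   majority = 1) {
  relation <- match.arg(relation)
  hemisphere <- match.arg(hemisphere)
  if (!is(reference, "Tractogram") || nStreamlines(reference) == 0L) {
    stop("reference bundle must be a non-empty Tractogram")
  }
  if (!length(candidates)) {
    out <- integer(0); attr(out, "inapplicable") <- integer(0); return(out)
  }
  valueCol <- if (relation == "lateral") 1L else 2L
  refPts <- do.call(rbind, reference@streamlines)
  refMed <- .slabMedians(refPts, valueCol, slabMm)
  satisfies <- function(cand, ref) {
    if (relation == "posterior") cand < ref
    else if (hemisphere == "L") cand < ref
    else cand > ref
  }
  keep <- logical(length(candidates))
  inap <- logical(length(candidates))
  for (ci in seq_along(candidates)) {
    med <- .slabMedians(t@streamlines[[candidates[ci]]], valueCol, slabMm)
    shared <- intersect(names(med), names(refMed))
    if (!length(shared)) { keep[ci] <- TRUE; inap[ci] <- TRUE; next }
    ok <- satisfies(med[shared], refMed[shared])
    keep[ci] <- mean(ok) >= majority - 1e-12
  }
  out <- candidates[keep]
  attr(out, "inapplicable") <- candidates[inap]
  out
}

#' Run the full VOF selection procedure
#'
#' Applies the filters in the fixed documented order: two-ROI endpoint
#' selection, orientation, region of avoidance, posterior-to-reference,
#' lateral-to-reference. Rejections are attributed to the first failing
#' filter, so accepted + rejected counts always sum to the input count.
#'
#' @param t a [Tractogram-class].
#' @param parc a [ParcellationVolume-class].
#' @param criteria a [selectionCriteria()]; optional slots (`roa`,
#'   `posteriorReference`, `lateralReference`) switch their filters on.
#' @return A [SelectionReport-class].
#' @export
runSelection <- function(t, parc, criteria) {
  validObject(criteria)
  n <- nStreamlines(t)
  rej <- c(two_roi = 0L, orientation = 0L, roa = 0L, posterior = 0L, lateral = 0L)
  cand <- selectTwoRoi(t, parc, criteria)
  rej["two_roi"] <- n - nrow(cand)
  idx <- cand$index
  if (!is.na(criteria@requiredAxis) && length(idx)) {
    ok <- vapply(idx, function(i) {
      o <- classifyOrientation(t@streamlines[[i]])
      o$dominantAxis == criteria@requiredAxis &&
        o$fractions[[criteria@requiredAxis]] >= criteria@minAxisFraction
    }, logical(1))
    rej["orientation"] <- sum(!ok)
    cand <- cand[ok, , drop = FALSE]; idx <- cand$index
  }
  if (!is.null(criteria@roa) && length(idx)) {
    keptRoa <- filterRoa(t, idx, criteria@roa)
    rej["roa"] <- length(idx) - length(keptRoa)
    cand <- cand[idx %in% keptRoa, , drop = FALSE]; idx <- cand$index
  }
  if (!is.null(criteria@posteriorReference) && length(idx)) {
    kept <- filterRelativePosition(t, idx, criteria@posteriorReference,
                                   "posterior", criteria@hemisphere,
                                   criteria@slabMm, criteria@lateralMajority)
    rej["posterior"] <- length(idx) - length(kept)
    cand <- cand[idx %in% kept, , drop = FALSE]; idx <- cand$index
  }
  if (!is.null(criteria@lateralReference) && length(idx)) {
    kept <- filterRelativePosition(t, idx, criteria@lateralReference,
                                   "lateral", criteria@hemisphere,
                                   criteria@slabMm, criteria@lateralMajority)
    rej["lateral"] <- length(idx) - length(kept)
    cand <- cand[idx %in% kept, , drop = FALSE]; idx <- cand$index
  }
  tab <- parc@labelTable
  nm <- stats::setNames(tab$name, tab$label_id)
  assignments <- data.frame(index = cand$index,
                            labelA = cand$labelA, labelB = cand$labelB,
                            parcelA = unname(nm[as.character(cand$labelA)]),
                            parcelB = unname(nm[as.character(cand$labelB)]),
                            stringsAsFactors = FALSE)
  new("SelectionReport", accepted = as.integer(cand$index), rejections = rej,
      assignments = assignments, nInput = as.integer(n))
}
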