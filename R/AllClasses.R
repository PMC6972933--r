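#' @import methods
NULL

.validStreamline <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 3L) {
    return("each streamline must be a numeric matrix with 3 columns (x, y, z)")
  }
  if (nrow(m) < 2L) return("each streamline needs at least 2 points")
  if (!all(is.finite(m))) return("streamline coordinates must be finite")
  d <- abs(diff(m))
  if (all(rowSums(d) == 0)) return("streamline has zero total displacement (all points identical)")
  NULL
}

#' Tractogram: a set of streamlines in world RAS millimetres
#'
#' A `Tractogram` holds streamlines as a list of n-by-3 numeric matrices, one
#' row per point, columns x (left-right, + right), y (posterior-anterior,
#' + anterior), z (inferior-superior, + superior), all in world millimetres.
#' Every reader converts on-disk conventions to this one space at the
#' boundary, so downstream code never sees voxel coordinates.
#'
#' @slot streamlines list of numeric matrices (n_i x 3), each with at least 2
#'   finite points and nonzero total displacement.
#' @slot spaceId free-text provenance tag for the world space (opaque).
#' @slot voxelSize numeric length-3, voxel size in mm of the source grid
#'   (metadata only; coordinates are already world mm).
#' @export
setClass("Tractogram",
  representation(streamlines = "list", spaceId = "character", voxelSize = "numeric"),
  prototype(streamlines = list(), spaceId = "unknown", voxelSize = c(1, 1, 1)))

setValidity("Tractogram", function(object) {
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0)) {
    return("voxelSize must be 3 positive finite numbers")
  }
  for (i in seq_along(object@streamlines)) {
    msg <- .validStreamline(object@streamlines[[i]])
    if (!is.null(msg)) return(sprintf("streamline %d: %s", i, msg))
  }
  TRUE
})

#' Construct a Tractogram
#'
#' @param streamlines list of n-by-3 numeric matrices in world RAS mm.
#' @param spaceId free-text space provenance.
#' @param voxelSize source grid voxel size in mm (metadata).
#' @return A [Tractogram-class] object.
#' @examples
#' tg <- tractogram(list(rbind(c(0, 0, 0), c(0, 0, 10))))
#' nStreamlines(tg)
#' @export
tractogram <- function(streamlines = list(), spaceId = "unknown", voxelSize = c(1, 1, 1)) {
  streamlines <- lapply(streamlines, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  new("Tractogram", streamlines = streamlines, spaceId = as.character(spaceId),
      voxelSize = as.numeric(voxelSize))
}

.validAffine <- function(a) {
  if (!is.matrix(a) || !identical(dim(a), c(4L, 4L)) || !all(is.finite(a))) {
    return("affine must be a finite 4x4 matrix")
  }
  if (abs(det(a[1:3, 1:3])) < 1e-12) return("affine is not invertible")
  if (!isTRUE(all.equal(a[4, ], c(0, 0, 0, 1)))) return("affine last row must be (0,0,0,1)")
  NULL
}

.requiredLabelCols <- c("label_id", "name", "hemisphere", "group", "r", "g", "b")

.validLabelTable <- function(tab) {
  if (!is.data.frame(tab)) return("label table must be a data.frame")
  miss <- setdiff(.requiredLabelCols, names(tab))
  if (length(miss)) return(paste("label table missing columns:", paste(miss, collapse = ", ")))
  if (nrow(tab) == 0L) return(NULL)
  if (anyDuplicated(tab$label_id)) return("duplicate label_id in label table")
  if (anyDuplicated(paste(tab$name, tab$hemisphere))) {
    return("duplicate (name, hemisphere) in label table")
  }
  if (any(tab$label_id <= 0)) return("label_id must be positive (0 is background)")
  if (!all(tab$hemisphere %in% c("L", "R"))) return("hemisphere must be 'L' or 'R'")
  if (!all(tab$group %in% c("dorsal", "lateral_occipital", "ventral", "other"))) {
    return("group must be one of dorsal, lateral_occipital, ventral, other")
  }
  rgb <- as.matrix(tab[, c("r", "g", "b")])
  if (any(rgb < 0 | rgb > 255)) return("rgb values must be in [0, 255]")
  NULL
}

#' Parcellation volume: labelled grid, affine and label table
#'
#' A 3-D non-negative integer label grid (0 = background) together with the
#' 4x4 voxel-to-world affine (0-based voxel indices) and a label table
#' annotating each label id with a name, hemisphere (`L`/`R`), parcel group
#' (`dorsal`, `lateral_occipital`, `ventral`, `other`) and an RGB colour.
#'
#' @slot labels 3-D integer array of parcel labels.
#' @slot affine 4x4 voxel-to-world map (0-based indices, world RAS mm).
#' @slot labelTable data.frame with columns `label_id`, `name`, `hemisphere`,
#'   `group`, `r`, `g`, `b`.
#' @export
setClass("ParcellationVolume",
  representation(labels = "array", affine = "matrix", labelTable = "data.frame"))

setValidity("ParcellationVolume", function(object) {
  msg <- .validAffine(object@affine)
  if (!is.null(msg)) return(msg)
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  if (any(object@labels < 0)) return("labels must be non-negative (0 = background)")
  msg <- .validLabelTable(object@labelTable)
  if (!is.null(msg)) return(msg)
  present <- setdiff(unique(as.integer(object@labels)), 0L)
  orphans <- setdiff(present, object@labelTable$label_id)
  if (length(orphans)) {
    return(paste("labels present in grid but absent from table:",
                 paste(sort(orphans), collapse = ", ")))
  }
  TRUE
})

#' @rdname ParcellationVolume-class
#' @param labels 3-D non-negative integer array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param labelTable label table data.frame (see slots).
#' @export
parcellationVolume <- function(labels, affine, labelTable) {
  storage.mode(labels) <- "integer"
  new("ParcellationVolume", labels = labels, affine = affine,
      labelTable = as.data.frame(labelTable))
}

#' Scalar volume (e.g. fractional anisotropy)
#'
#' @slot values 3-D finite numeric array.
#' @slot affine 4x4 voxel-to-world map (0-based indices, world RAS mm).
#' @export
setClass("ScalarVolume", representation(values = "array", affine = "matrix"))

setValidity("ScalarVolume", function(object) {
  msg <- .validAffine(object@affine)
  if (!is.null(msg)) return(msg)
  if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' @rdname ScalarVolume-class
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @export
scalarVolume <- function(values, affine) {
  storage.mode(values) <- "double"
  new("ScalarVolume", values = values, affine = affine)
}

#' Criteria for two-ROI VOF selection
#'
#' Bundles every tunable of the dissection procedure: the two endpoint parcel
#' sets, the orientation requirement, optional region of avoidance, and the
#' optional reference bundles for relative-position filtering.
#'
#' `groupA`/`groupB` are either parcel-group names (`"dorsal"`,
#' `"lateral_occipital"`, `"ventral"`) or explicit parcel names; they are
#' resolved against the parcellation's label table at selection time and must
#' resolve to disjoint label sets.
#'
#' @slot groupA,groupB character vectors of group names or parcel names.
#' @slot endpointRadiusMm search radius (mm) when a terminal point falls in
#'   background; default 2.
#' @slot requiredAxis dominant displacement axis required of candidates,
#'   one of `"SI"`, `"AP"`, `"LR"` or `NA` (no orientation filter).
#' @slot minAxisFraction minimum share of total absolute displacement on the
#'   required axis, in `[0, 1]`; default 0.5.
#' @slot roa optional [ScalarVolume-class] binary mask; streamlines touching
#'   it are discarded.
#' @slot lateralReference,posteriorReference optional [Tractogram-class]
#'   reference bundles (ILF-like and AF-like).
#' @slot slabMm slab thickness (mm) for per-slab median comparison; default 5.
#' @slot lateralMajority fraction of shared slabs that must satisfy the
#'   relation; default 1 (all).
#' @slot hemisphere `"L"` or `"R"`; restricts parcel resolution and fixes the
#'   sign convention for "lateral".
#' @export
setClass("SelectionCriteria",
  representation(groupA = "character", groupB = "character",
                 endpointRadiusMm = "numeric", requiredAxis = "character",
                 minAxisFraction = "numeric", roa = "ANY",
                 lateralReference = "ANY", posteriorReference = "ANY",
                 slabMm = "numeric", lateralMajority = "numeric",
                 hemisphere = "character"))

setValidity("SelectionCriteria", function(object) {
  if (!length(object@groupA) || !length(object@groupB)) {
    return("groupA and groupB must be non-empty")
  }
  if (length(intersect(object@groupA, object@groupB))) {
    return("groupA and groupB must be disjoint")
  }
  if (object@endpointRadiusMm < 0) return("endpointRadiusMm must be >= 0")
  if (!is.na(object@requiredAxis) && !object@requiredAxis %in% c("SI", "AP", "LR")) {
    return("requiredAxis must be SI, AP, LR or NA")
  }
  if (object@minAxisFraction < 0 || object@minAxisFraction > 1) {
    return("minAxisFraction must be in [0, 1]")
  }
  if (!is.null(object@roa) && !is(object@roa, "ScalarVolume")) {
    return("roa must be NULL or a ScalarVolume")
  }
  for (ref in list(object@lateralReference, object@posteriorReference)) {
    if (!is.null(ref) && !is(ref, "Tractogram")) {
      return("reference bundles must be NULL or Tractogram")
    }
  }
  if (object@slabMm <= 0) return("slabMm must be positive")
  if (object@lateralMajority <= 0 || object@lateralMajority > 1) {
    return("lateralMajority must be in (0, 1]")
  }
  if (!object@hemisphere %in% c("L", "R")) return("hemisphere must be 'L' or 'R'")
  TRUE
})

#' @rdname SelectionCriteria-class
#' @param groupA,groupB parcel-group names or explicit parcel names.
#' @param endpointRadiusMm endpoint search radius in mm.
#' @param requiredAxis required dominant axis (`"SI"` default) or `NA`.
#' @param minAxisFraction minimum displacement share on the required axis.
#' @param roa optional binary [ScalarVolume-class] region of avoidance.
#' @param lateralReference,posteriorReference optional reference
#'   [Tractogram-class] bundles.
#' @param slabMm slab thickness for relative-position comparison.
#' @param lateralMajority required fraction of satisfying shared slabs.
#' @param hemisphere `"L"` or `"R"`.
#' @export
selectionCriteria <- function(groupA = "dorsal",
                              groupB = c("ventral", "lateral_occipital"),
                              endpointRadiusMm = 2, requiredAxis = "SI",
                              minAxisFraction = 0.5, roa = NULL,
                              lateralReference = NULL, posteriorReference = NULL,
                              slabMm = 5, lateralMajority = 1, hemisphere = "L") {
  new("SelectionCriteria", groupA = groupA, groupB = groupB,
      endpointRadiusMm = endpointRadiusMm,
      requiredAxis = as.character(requiredAxis),
      minAxisFraction = minAxisFraction, roa = roa,
      lateralReference = lateralReference, posteriorReference = posteriorReference,
      slabMm = slabMm, lateralMajority = lateralMajority, hemisphere = hemisphere)
}

#' Selection report: accepted streamlines and per-filter rejections
#'
#' @slot accepted integer indices (into the input tractogram) of accepted
#'   streamlines.
#' @slot rejections named integer vector of rejection counts attributed to
#'   the first failing filter, names `two_roi`, `orientation`, `roa`,
#'   `posterior`, `lateral`.
#' @slot assignments data.frame for accepted streamlines: `index`, `labelA`,
#'   `labelB`, `parcelA`, `parcelB` (A = groupA side).
#' @slot nInput number of input streamlines.
#' @export
setClass("SelectionReport",
  representation(accepted = "integer", rejections = "integer",
                 assignments = "data.frame", nInput = "integer"))

setValidity("SelectionReport", function(object) {
  need <- c("two_roi", "orientation", "roa", "posterior", "lateral")
  if (!all(need %in% names(object@rejections))) {
    return("rejections must be named two_roi, orientation, roa, posterior, lateral")
  }
  if (length(object@accepted) + sum(object@rejections) != object@nInput) {
    return("accepted + rejected must equal input count")
  }
  if (nrow(object@assignments) != length(object@accepted)) {
    return("one assignment row per accepted streamline required")
  }
  TRUE
})

#' Hemispheric parcel-by-parcel connectivity matrix
#'
#' Symmetric matrix of streamline-termination counts: each accepted
#' streamline increments exactly one unordered parcel pair (stored in both
#' triangles; diagonal for same-parcel loops), so the upper triangle
#' including the diagonal sums to the number of accepted streamlines.
#'
#' @slot counts symmetric non-negative integer matrix with parcel-name
#'   dimnames.
#' @slot hemisphere `"L"` or `"R"`.
#' @export
setClass("ConnectivityMatrix",
  representation(counts = "matrix", hemisphere = "character"))

setValidity("ConnectivityMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m) || nrow(m) != ncol(m)) return("counts must be a square numeric matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    return("counts must carry identical parcel-name row/col names")
  }
  if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
  if (!isSymmetric(unname(m))) return("counts must be symmetric")
  if (!object@hemisphere %in% c("L", "R")) return("hemisphere must be 'L' or 'R'")
  TRUE
})

#' Synthetic phantom bundle: parcellation, tractogram, FA and ground truth
#'
#' @slot parcellation [ParcellationVolume-class] of the phantom atlas.
#' @slot tractogram [Tractogram-class] of all generated streamlines.
#' @slot fa [ScalarVolume-class] fractional-anisotropy field.
#' @slot truth data.frame, one row per streamline: `index`, `bundle`
#'   (`vof`, `ilf`, `af`, `clutter`), `hemisphere`, `labelA`, `labelB`,
#'   `parcelA`, `parcelB` (NA for non-VOF bundles).
#' @slot config the [phantomConfig()] list that generated the phantom.
#' @export
setClass("Phantom",
  representation(parcellation = "ParcellationVolume", tractogram = "Tractogram",
                 fa = "ScalarVolume", truth = "data.frame", config = "list"))

setValidity("Phantom", function(object) {
  if (nrow(object@truth) != length(object@tractogram@streamlines)) {
    return("one truth row per streamline required")
  }
  lab <- object@truth$labelA
  lab <- c(lab, object@truth$labelB)
  lab <- lab[!is.na(lab)]
  if (length(lab) && !all(lab %in% object@parcellation@labelTable$label_id)) {
    return("truth refers to labels absent from the parcellation")
  }
  TRUE
})

#' Group-level laterality summary
#'
#' @slot quantity which metric was summarised (e.g. `n_tracts`).
#' @slot n integer number of subjects.
#' @slot meanL,meanR group means of the left / right values.
#' @slot meanLI,semLI mean and standard error of per-subject laterality
#'   indices (undefined LIs excluded; see `nUndefined`).
#' @slot statistic,df,pValue Student t-test of left vs right (paired by
#'   default); `statistic` is `Inf`/`-Inf` and `degenerate` is `TRUE` when
#'   the paired differences have zero variance but nonzero mean.
#' @slot paired whether the test paired left and right within subject.
#' @slot significant `pValue < 0.05`.
#' @slot degenerate zero-variance flag (see above).
#' @slot nUndefined number of subjects whose LI was undefined (L + R = 0).
#' @export
setClass("GroupSummary",
  representation(quantity = "character", n = "integer", meanL = "numeric",
                 meanR = "numeric", meanLI = "numeric", semLI = "numeric",
                 statistic = "numeric", df = "numeric", pValue = "numeric",
                 paired = "logical", significant = "logical",
                 degenerate = "logical", nUndefined = "integer"))

setMethod("show", "Tractogram", function(object) {
  np <- if (length(object@streamlines)) {
    sum(vapply(object@streamlines, nrow, integer(1)))
  } else 0L
  cat(sprintf("Tractogram: %d streamline(s), %d points, space '%s'\n",
              length(object@streamlines), np, object@spaceId))
})

setMethod("show", "ParcellationVolume", function(object) {
  cat(sprintf("ParcellationVolume: %s grid, %d parcel(s)\n",
              paste(dim(object@labels), collapse = "x"),
              nrow(object@labelTable)))
})

setMethod("show", "ScalarVolume", function(object) {
  rng <- range(object@values)
  cat(sprintf("ScalarVolume: %s grid, range [%.3g, %.3g]\n",
              paste(dim(object@values), collapse = "x"), rng[1], rng[2]))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d / %d accepted\n",
              length(object@accepted), object@nInput))
  rej <- object@rejections
  cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej), collapse = ", "), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s): %d parcels, %d streamlines\n",
              object@hemisphere, nrow(object@counts), matrixTotal(object)))
})

setMethod("show", "Phantom", function(object) {
  tab <- table(object@truth$bundle)
  cat("Phantom:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary [%s]: n=%d, mean LI=%.4f (SEM %.4f), t=%.3f, p=%.4g%s\n",
              object@quantity, object@n, object@meanLI, object@semLI,
              object@statistic, object@pValue,
              if (object@degenerate) " [degenerate]" else ""))
})
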