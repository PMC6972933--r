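#' Accessors for vofseg S4 classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the relevant class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname accessors
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))
#' @rdname accessors
#' @export
setMethod("nStreamlines", "Tractogram", function(x) length(x@streamlines))

#' @rdname accessors
#' @export
setGeneric("spaceId", function(x) standardGeneric("spaceId"))
#' @rdname accessors
#' @export
setMethod("spaceId", "Tractogram", function(x) x@spaceId)

#' @rdname accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))
#' @rdname accessors
#' @export
setMethod("affine", "ParcellationVolume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("affine", "ScalarVolume", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))
#' @rdname accessors
#' @export
setMethod("labelGrid", "ParcellationVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))
#' @rdname accessors
#' @export
setMethod("labelTable", "ParcellationVolume", function(x) x@labelTable)

#' @rdname accessors
#' @export
setGeneric("scalarValues", function(x) standardGeneric("scalarValues"))
#' @rdname accessors
#' @export
setMethod("scalarValues", "ScalarVolume", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("accepted", function(x) standardGeneric("accepted"))
#' @rdname accessors
#' @export
setMethod("accepted", "SelectionReport", function(x) x@accepted)

#' @rdname accessors
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))
#' @rdname accessors
#' @export
setMethod("rejections", "SelectionReport", function(x) x@rejections)

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setMethod("assignments", "SelectionReport", function(x) x@assignments)

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "ConnectivityMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))
#' @rdname accessors
#' @export
setMethod("hemisphere", "ConnectivityMatrix", function(x) x@hemisphere)

#' Total streamline count of a connectivity matrix
#'
#' Sum of the upper triangle including the diagonal: each accepted streamline
#' contributes exactly one unordered parcel pair.
#'
#' @param x a [ConnectivityMatrix-class].
#' @return Integer streamline total.
#' @export
setGeneric("matrixTotal", function(x) standardGeneric("matrixTotal"))
#' @rdname matrixTotal
#' @export
setMethod("matrixTotal", "ConnectivityMatrix", function(x) {
  m <- x@counts
  as.integer(sum(m[upper.tri(m, diag = TRUE)]))
})

#' @rdname accessors
#' @export
setGeneric("parcellation", function(x) standardGeneric("parcellation"))
#' @rdname accessors
#' @export
setMethod("parcellation", "Phantom", function(x) x@parcellation)

#' @rdname accessors
#' @export
setMethod("streamlines", "Phantom", function(x) x@tractogram@streamlines)

#' @rdname accessors
#' @export
setGeneric("phantomTractogram", function(x) standardGeneric("phantomTractogram"))
#' @rdname accessors
#' @export
setMethod("phantomTractogram", "Phantom", function(x) x@tractogram)

#' @rdname accessors
#' @export
setGeneric("faVolume", function(x) standardGeneric("faVolume"))
#' @rdname accessors
#' @export
setMethod("faVolume", "Phantom", function(x) x@fa)

#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setMethod("truth", "Phantom", function(x) x@truth)
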