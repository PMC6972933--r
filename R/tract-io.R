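# Streamline and volume I/O. Everything is converted to the package's one
# internal convention at this boundary: world RAS mm, 0-based voxel indices.

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tck", "trk")) ext else
    stop("cannot guess tractogram format from extension: ", path)
}

#' Read a tractogram (TCK or TRK) into world RAS mm
#'
#' TCK stores world (scanner) mm directly. TRK stores "voxmm" coordinates
#' (voxel index times voxel size, measured from the voxel corner); these are
#' mapped to world RAS through the header's voxel-to-RAS affine. TRK files
#' without a usable affine (all-zero matrix, pre-version-2 headers) are
#' refused rather than guessed at.
#'
#' Streamlines with fewer than 2 points or zero total displacement are
#' dropped with a message reporting the count.
#'
#' @param path file path.
#' @param format `"tck"` or `"trk"`; guessed from the extension by default.
#' @return A [Tractogram-class] in world RAS mm.
#' @export
readTractogram <- function(path, format = c("auto", "tck", "trk")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, tck = .readTck(path), trk = .readTrk(path))
}

#' Write a tractogram as TCK or TRK
#'
#' The inverse of [readTractogram()]: coordinates are written so that reading
#' the file back reproduces the world RAS mm points (within float32
#' precision, < 1e-4 mm at brain-scale coordinates). The TRK writer emits a
#' version-2 header whose voxel-to-RAS affine is diagonal in the tractogram's
#' `voxelSize`.
#'
#' @param t a [Tractogram-class].
#' @param path output file path.
#' @param format `"tck"` or `"trk"`; guessed from the extension by default.
#' @return Invisibly, `path`.
#' @export
writeTractogram <- function(t, path, format = c("auto", "tck", "trk")) {
  stopifnot(is(t, "Tractogram"))
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  switch(format, tck = .writeTck(t, path), trk = .writeTrk(t, path))
  invisible(path)
}

.dropDegenerate <- function(sl) {
  bad <- vapply(sl, function(m) nrow(m) < 2L || all(abs(diff(m)) == 0), logical(1))
  if (any(bad)) {
    message(sum(bad), " degenerate streamline(s) (fewer than 2 points or zero displacement) dropped")
  }
  sl[!bad]
}

## ---- TCK (MRtrix) ----

.readTck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) {
    stop("malformed TCK header: missing 'mrtrix tracks' magic line")
  }
  fields <- list()
  offset <- NA_real_
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed TCK header: no END line")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed TCK header: line '", line, "'")
    fields[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(fields$datatype)) stop("malformed TCK header: missing field 'datatype'")
  if (!fields$datatype %in% c("Float32LE", "Float64LE")) {
    stop("malformed TCK header: unsupported datatype '", fields$datatype, "'")
  }
  if (is.null(fields$file)) stop("malformed TCK header: missing field 'file'")
  fpart <- strsplit(fields$file, "[[:space:]]+")[[1]]
  if (length(fpart) != 2L || fpart[1] != ".") {
    stop("malformed TCK header: field 'file' must be '. <offset>'")
  }
  offset <- as.numeric(fpart[2])
  size <- if (fields$datatype == "Float32LE") 4L else 8L
  seek(con, where = offset, origin = "start")
  nbytes <- file.size(path) - offset
  raw <- readBin(con, "numeric", n = nbytes / size, size = size, endian = "little")
  if (length(raw) %% 3L != 0L) stop("malformed TCK data: point count not a multiple of 3")
  pts <- matrix(raw, ncol = 3, byrow = TRUE)
  isnan <- rowSums(is.na(pts)) > 0
  isinf <- is.infinite(pts[, 1])
  term <- which(isnan | isinf)
  sl <- list()
  start <- 1L
  for (tm in term) {
    if (tm > start) sl[[length(sl) + 1L]] <- pts[start:(tm - 1L), , drop = FALSE]
    start <- tm + 1L
  }
  vs <- c(1, 1, 1)
  sl <- .dropDegenerate(sl)
  tractogram(sl, spaceId = "world_ras_mm", voxelSize = vs)
}

.writeTck <- function(t, path) {
  sl <- t@streamlines
  body <- lapply(sl, function(m) rbind(m, c(NaN, NaN, NaN)))
  body <- do.call(rbind, c(body, list(matrix(c(Inf, Inf, Inf), 1))))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(sl)),
           sprintf("timestamp: %d", 0L))
  # 'file: . <offset>' must state the byte offset of the data, which depends
  # on the header length; pad the offset to a fixed width to break the cycle
  fileLine <- "file: . %010d"
  offset <- sum(nchar(hdr, type = "bytes")) + length(hdr) +
    nchar(sprintf(fileLine, 0), type = "bytes") + 1L + nchar("END") + 1L
  hdr <- c(hdr, sprintf(fileLine, offset), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(t(body)), con, size = 4L, endian = "little")
  invisible(path)
}

## ---- TRK (TrackVis) ----

.trkCharField <- function(x, width) {
  r <- charToRaw(x)
  length(r) <- width  # zero-pads
  r[is.na(r)] <- as.raw(0)
  r
}

.readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (length(hdr) < 1000L) stop("malformed TRK header: file shorter than 1000 bytes")
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size, endian = "little")
  }
  magic <- rawToChar(hdr[1:5])
  if (!identical(magic, "TRACK")) stop("malformed TRK header: missing 'TRACK' id_string")
  voxelSize <- rd(12L, "numeric", 3L, 4L)
  nScalars <- rd(36L, "integer", 1L, 2L)
  nProperties <- rd(238L, "integer", 1L, 2L)
  voxToRas <- matrix(rd(440L, "numeric", 16L, 4L), 4, 4, byrow = TRUE)
  version <- rd(992L, "integer", 1L, 4L)
  hdrSize <- rd(996L, "integer", 1L, 4L)
  if (!identical(hdrSize, 1000L)) stop("malformed TRK header: hdr_size is not 1000")
  if (all(voxToRas == 0)) {
    stop("TRK header field 'vox_to_ras' is all zero (no usable affine); refusing to guess")
  }
  if (any(voxelSize <= 0)) stop("malformed TRK header: non-positive voxel_size")
  nCount <- rd(988L, "integer", 1L, 4L)
  sl <- list()
  repeat {
    npts <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!length(npts)) break
    vals <- readBin(con, "numeric", n = npts * (3L + nScalars), size = 4L,
                    endian = "little")
    if (nProperties > 0L) {
      readBin(con, "numeric", n = nProperties, size = 4L, endian = "little")
    }
    if (npts > 0L) {
      m <- matrix(vals, ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
      # voxmm -> 0-based voxel (points sit half a voxel past the corner) -> RAS
      vox <- sweep(m, 2, voxelSize, "/") - 0.5
      sl[[length(sl) + 1L]] <- voxelToWorld(vox, voxToRas)
    } else {
      sl[[length(sl) + 1L]] <- matrix(numeric(0), 0, 3)
    }
  }
  if (nCount > 0L && length(sl) != nCount) {
    warning("TRK n_count (", nCount, ") does not match streamlines read (",
            length(sl), ")")
  }
  sl <- .dropDegenerate(sl)
  tractogram(sl, spaceId = "world_ras_mm", voxelSize = voxelSize)
}

.writeTrk <- function(t, path, affine = NULL) {
  vs <- t@voxelSize
  if (is.null(affine)) {
    affine <- diag(c(vs, 1))  # voxel -> world, origin at world 0
  }
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x) writeBin(x, con, endian = "little")
  w(.trkCharField("TRACK", 6L))
  writeBin(as.integer(c(0, 0, 0)), con, size = 2L, endian = "little")   # dim
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")           # voxel_size
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")   # origin
  writeBin(0L, con, size = 2L, endian = "little")                       # n_scalars
  w(raw(200L))                                                          # scalar_name
  writeBin(0L, con, size = 2L, endian = "little")                       # n_properties
  w(raw(200L))                                                          # property_name
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")    # vox_to_ras
  w(raw(444L))                                                          # reserved
  w(.trkCharField("RAS", 4L))                                           # voxel_order
  w(raw(4L))                                                            # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  w(raw(2L))                                                            # pad1
  w(raw(6L))                                                            # invert/swap flags
  writeBin(length(t@streamlines), con, size = 4L, endian = "little")    # n_count
  writeBin(2L, con, size = 4L, endian = "little")                       # version
  writeBin(1000L, con, size = 4L, endian = "little")                    # hdr_size
  for (m in t@streamlines) {
    writeBin(nrow(m), con, size = 4L, endian = "little")
    vox <- worldToVoxel(m, affine, round = FALSE)
    voxmm <- sweep(vox + 0.5, 2, vs, "*")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

## ---- Label table and volumes ----

#' Read / write the parcel label table (TSV)
#'
#' Columns: `label_id` (positive integer), `name`, `hemisphere` (`L`/`R`),
#' `group` (`dorsal`, `lateral_occipital`, `ventral`, `other`), `r`, `g`,
#' `b` (0-255).
#'
#' @param path TSV file path.
#' @return `readLabelTable`: a validated data.frame.
#' @export
readLabelTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  msg <- .validLabelTable(tab)
  if (!is.null(msg)) stop("invalid label table '", path, "': ", msg)
  tab
}

#' @rdname readLabelTable
#' @param tab label table data.frame.
#' @export
writeLabelTable <- function(tab, path) {
  msg <- .validLabelTable(tab)
  if (!is.null(msg)) stop("invalid label table: ", msg)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readNiftiArray <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume: ", path)
  list(arr = arr, affine = aff)
}

.writeNiftiArray <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parcellation volume with its label table
#'
#' @param volumePath NIfTI file of integer labels.
#' @param tablePath TSV label table (see [readLabelTable()]).
#' @return A [ParcellationVolume-class]; errors list any labels present in
#'   the grid but absent from the table.
#' @export
readParcellation <- function(volumePath, tablePath) {
  v <- .readNiftiArray(volumePath)
  if (any(v$arr != round(v$arr)) || any(v$arr < 0)) {
    stop("parcellation grid must be non-negative integer-valued: ", volumePath)
  }
  parcellationVolume(v$arr, v$affine, readLabelTable(tablePath))
}

#' Read a scalar (e.g. FA) volume
#'
#' @param path NIfTI file path.
#' @return A [ScalarVolume-class].
#' @export
readScalarVolume <- function(path) {
  v <- .readNiftiArray(path)
  scalarVolume(v$arr, v$affine)
}

#' Write a parcellation or scalar volume as NIfTI
#'
#' @param x a [ParcellationVolume-class] or [ScalarVolume-class].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "ParcellationVolume")) {
    .writeNiftiArray(x@labels, x@affine, path)
  } else if (is(x, "ScalarVolume")) {
    .writeNiftiArray(x@values, x@affine, path)
  } else stop("writeVolume: unsupported class ", class(x))
}
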