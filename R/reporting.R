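# Pipeline driver and connectogram table export.

#' Export a connectivity matrix as a connectogram table
#'
#' Tab-separated square table in the row/column layout circular-plot table
#' viewers consume: a header row of parcel labels, one row per parcel with
#' its RGB colour (from the label table) and its counts. Re-parsing with
#' [readConnectogram()] reproduces the matrix exactly.
#'
#' @param m a non-empty [ConnectivityMatrix-class].
#' @param table label table supplying parcel RGB colours.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
exportConnectogram <- function(m, table, path) {
  cm <- m@counts
  if (nrow(cm) == 0L) stop("empty connectivity matrix")
  tab <- table[table$hemisphere == m@hemisphere, , drop = FALSE]
  rgb <- tab[match(rownames(cm), tab$name), c("r", "g", "b")]
  if (any(is.na(rgb))) stop("label table lacks colours for some parcels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# connectogram\themisphere=%s", m@hemisphere), con)
  writeLines(paste(c("parcel", "r", "g", "b", rownames(cm)), collapse = "\t"), con)
  for (i in seq_len(nrow(cm))) {
    writeLines(paste(c(rownames(cm)[i], rgb[i, 1], rgb[i, 2], rgb[i, 3],
                       cm[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Parse a connectogram table back into a ConnectivityMatrix
#'
#' @param path TSV written by [exportConnectogram()].
#' @return A [ConnectivityMatrix-class]; parcel colours are attached as the
#'   `colors` attribute (data.frame `parcel`, `r`, `g`, `b`).
#' @export
readConnectogram <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# connectogram\t", "", lines[1]), "=")[[1]]
  hemi <- meta[2]
  header <- strsplit(lines[2], "\t")[[1]]
  parcels <- header[-(1:4)]
  body <- do.call(rbind, strsplit(lines[-(1:2)], "\t"))
  if (!identical(body[, 1], parcels)) stop("malformed connectogram: row/column labels differ")
  cnt <- matrix(as.integer(body[, -(1:4), drop = FALSE]), length(parcels),
                dimnames = list(parcels, parcels))
  out <- new("ConnectivityMatrix", counts = cnt, hemisphere = hemi)
  attr(out, "colors") <- data.frame(parcel = parcels,
                                    r = as.integer(body[, 2]),
                                    g = as.integer(body[, 3]),
                                    b = as.integer(body[, 4]))
  out
}

.criteriaFromList <- function(lst, lateralReference = NULL,
                              posteriorReference = NULL, roa = NULL,
                              hemisphere = "L") {
  args <- list(hemisphere = hemisphere, roa = roa,
               lateralReference = lateralReference,
               posteriorReference = posteriorReference)
  for (nm in intersect(names(lst), c("groupA", "groupB", "endpointRadiusMm",
                                     "requiredAxis", "minAxisFraction",
                                     "slabMm", "lateralMajority"))) {
    args[[nm]] <- lst[[nm]]
  }
  do.call(selectionCriteria, args)
}

#' Run the full dissection pipeline over phantom subjects
#'
#' For each subject (one phantom per seed) and each configured hemisphere:
#' selection against the phantom's own ILF/AF reference bundles, accepted
#' tractogram, connectivity matrix, connectogram table, ratio tables and
#' tract metrics; then, when both hemispheres are present, per-subject
#' laterality tables and group summaries (mean +/- SEM, paired t) for tract
#' count, volume and mean FA. A run log records the package version, seed
#' and per-filter rejection counts for every stage.
#'
#' @param config a list (or path to a YAML file encoding it) with elements:
#'   `phantom` (arguments for [phantomConfig()]; `hemisphere` typically
#'   `"both"`), `subjectSeeds` (integer vector, one phantom per seed),
#'   optional `criteria` (argument list for [selectionCriteria()]), optional
#'   `nVofRight` (right-hemisphere VOF count, to build in a count
#'   asymmetry), and `outDir` (output directory; created).
#' @return Invisibly, a list with per-subject results, group `summaries`,
#'   `laterality` tables and the `log`, all also written under `outDir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outDir <- config$outDir
  stopifnot(!is.null(outDir), !is.null(config$subjectSeeds))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  phArgs <- config$phantom
  if (is.null(phArgs)) phArgs <- list()
  log <- list(package = "vofseg",
              version = as.character(utils::packageVersion("vofseg")),
              subjectSeeds = config$subjectSeeds,
              config = config[setdiff(names(config), "outDir")],
              stages = list())
  subjects <- list()
  for (seed in config$subjectSeeds) {
    sid <- sprintf("subj%03d", seed)
    ph <- tryCatch({
      args <- phArgs; args$seed <- seed
      if (!is.null(config$nVofRight)) args$nVofRight <- config$nVofRight
      do.call(.phantomConfigWithRightCount, args)
    }, error = function(e) stop("stage phantom-config, subject ", sid, ": ",
                                conditionMessage(e)))
    phantom <- tryCatch(makePhantom(ph), error = function(e) {
      stop("stage phantom, subject ", sid, ": ", conditionMessage(e))
    })
    hems <- if (ph$hemisphere == "both") c("L", "R") else ph$hemisphere
    res <- list()
    for (h in hems) {
      res[[h]] <- tryCatch(
        .runSubjectHemisphere(phantom, h, config$criteria, outDir, sid),
        error = function(e) stop("stage selection, subject ", sid,
                                 " hemisphere ", h, ": ", conditionMessage(e)))
      log$stages[[paste(sid, h, sep = "_")]] <-
        as.list(rejections(res[[h]]$report))
    }
    subjects[[sid]] <- res
  }
  summaries <- list(); latTables <- list()
  first <- subjects[[1]]
  if (all(c("L", "R") %in% names(first))) {
    for (q in c("n_tracts", "volume_mm3", "mean_fa")) {
      tot <- t(vapply(subjects, function(s) {
        c(L = s$L$metrics[[q]][s$L$metrics$parcelA == "total"],
          R = s$R$metrics[[q]][s$R$metrics$parcelA == "total"])
      }, numeric(2)))
      summaries[[q]] <- summarizeSubjects(tot[, "L"], tot[, "R"], quantity = q)
      latTables[[q]] <- do.call(rbind, lapply(names(subjects), function(sid) {
        lt <- lateralityTable(subjects[[sid]]$L$metrics,
                              subjects[[sid]]$R$metrics, q)
        cbind(subject = sid, quantity = q, lt)
      }))
      utils::write.table(latTables[[q]],
                         file.path(outDir, paste0("laterality_", q, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sumTab <- do.call(rbind, lapply(summaries, function(s) {
      data.frame(quantity = s@quantity, n = s@n, meanL = s@meanL,
                 meanR = s@meanR, meanLI = s@meanLI, semLI = s@semLI,
                 t = s@statistic, df = s@df, p = s@pValue,
                 significant = s@significant)
    }))
    utils::write.table(sumTab, file.path(outDir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(subjects = subjects, summaries = summaries,
                 laterality = latTables, log = log))
}

# phantomConfig wrapper honouring an optional right-hemisphere VOF count
.phantomConfigWithRightCount <- function(..., nVofRight = NULL) {
  cfg <- phantomConfig(...)
  cfg$nVofRight <- if (is.null(nVofRight)) cfg$nVof else as.integer(nVofRight)
  cfg
}

.runSubjectHemisphere <- function(phantom, h, criteriaList, outDir, sid) {
  parc <- phantom@parcellation
  crit <- .criteriaFromList(if (is.null(criteriaList)) list() else criteriaList,
                            lateralReference = phantomBundle(phantom, "ilf", h),
                            posteriorReference = phantomBundle(phantom, "af", h),
                            hemisphere = h)
  tract <- phantom@tractogram
  rep <- runSelection(tract, parc, crit)
  cm <- buildConnectivityMatrix(rep, parc, h)
  ratios <- endpointRatios(cm, parc@labelTable)
  metrics <- tractMetrics(rep, tract, phantom@fa, h)
  base <- file.path(outDir, paste(sid, h, sep = "_"))
  writeTractogram(tractogram(tract@streamlines[rep@accepted],
                             spaceId = tract@spaceId,
                             voxelSize = tract@voxelSize),
                  paste0(base, "_accepted.tck"))
  utils::write.table(cm@counts, paste0(base, "_connectivity.tsv"),
                     sep = "\t", quote = FALSE)
  exportConnectogram(cm, parc@labelTable, paste0(base, "_connectogram.tsv"))
  for (g in names(ratios)) {
    utils::write.table(ratios[[g]], paste0(base, "_endpoint_ratio_", g, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(accepted = rep@accepted, rejections = as.list(rep@rejections),
         nInput = rep@nInput),
    paste0(base, "_selection.json"), auto_unbox = TRUE, digits = NA)
  mj <- metrics
  jsonlite::write_json(stats::setNames(
    lapply(seq_len(nrow(mj)), function(i) as.list(mj[i, c("n_tracts", "volume_mm3", "mean_fa")])),
    paste(mj$parcelA, mj$parcelB, mj$hemisphere, sep = "|")),
    paste0(base, "_metrics.json"), auto_unbox = TRUE, digits = NA)
  list(report = rep, matrix = cm, ratios = ratios, metrics = metrics)
}
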