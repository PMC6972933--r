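#' Endpoint-ratio recovery experiment
#'
#' Generates a single-hemisphere phantom whose VOF endpoint parcels for one
#' group follow a configured multinomial (by default the published
#' HCP-subject proportions, [vofEndpointProps()]), runs the full selection
#' pipeline against the phantom's own reference bundles, and reads the
#' recovered endpoint-ratio table for that group. The target group receives
#' all 20,000 endpoint draws: dorsal endpoints always (every VOF streamline
#' starts dorsally); for a ventral or lateral-occipital target the
#' dorsal-to-ventral split is set to route every streamline there.
#'
#' @param hemisphere `"L"` or `"R"`.
#' @param group measured group: `"dorsal"`, `"ventral"` or
#'   `"lateral_occipital"`.
#' @param nVof number of VOF streamlines (default 20000).
#' @param seed phantom RNG seed.
#' @param props multinomial over the group's parcels; default the published
#'   proportions for that hemisphere and group.
#' @return list: `table` (the recovered ratio data.frame for the group),
#'   `percent` (named vector of recovered percentages), `accepted` (number
#'   of accepted streamlines), `n` (number of VOF streamlines generated).
#' @export
endpointRecovery <- function(hemisphere = "L",
                             group = c("ventral", "dorsal", "lateral_occipital"),
                             nVof = 20000L, seed = 1L, props = NULL) {
  group <- match.arg(group)
  if (is.null(props)) props <- vofEndpointProps(hemisphere, group)
  args <- list(hemisphere = hemisphere, nVof = as.integer(nVof), seed = seed,
               ventralShare = switch(group, ventral = 1, lateral_occipital = 0,
                                     dorsal = 0.7))
  args[[switch(group, ventral = "endpointPropsVentral",
               dorsal = "endpointPropsDorsal",
               lateral_occipital = "endpointPropsLateral")]] <- props
  ph <- makePhantom(do.call(phantomConfig, args))
  parc <- parcellation(ph)
  crit <- selectionCriteria(hemisphere = hemisphere,
                            lateralReference = phantomBundle(ph, "ilf", hemisphere),
                            posteriorReference = phantomBundle(ph, "af", hemisphere))
  rep <- runSelection(phantomTractogram(ph), parc, crit)
  cm <- buildConnectivityMatrix(rep, parc, hemisphere)
  tabl <- endpointRatios(cm, labelTable(parc))[[group]]
  list(table = tabl,
       percent = stats::setNames(tabl$percent, tabl$parcel),
       accepted = length(accepted(rep)), n = as.integer(nVof))
}
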