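#' Published VOF endpoint-projection proportions (HCP subjects)
#'
#' Multinomial endpoint-parcel proportions of VOF terminations reported for
#' ten HCP subjects, per hemisphere and parcel group, usable directly as
#' phantom endpoint multinomials. The published figures print only the
#' prominent parcels of each group (e.g. left-ventral V4 62.0%, PIT 16.2%;
#' left-dorsal V3CD 35.2%, V6A 24.8%, V3A 14.8%, IP0 9.5%, V7 8.5%;
#' right-dorsal V3A 29.4%, V7 26.5%, V3CD 16.7%, IP0 7.8%, V6A 7.4%;
#' lateral-occipital LO1 35.7/23.4, LO2 27.4/25.7, LO3 21.5/23.6 left/right);
#' the unprinted remainder of each group is distributed uniformly over the
#' remaining parcels of the default 22-parcel set ([defaultParcels()]).
#'
#' @param hemisphere `"L"` or `"R"`.
#' @param group `"dorsal"`, `"ventral"` or `"lateral_occipital"`.
#' @return Named numeric probability vector summing to 1 over the parcels of
#'   the group.
#' @examples
#' vofEndpointProps("L", "ventral")["V4"]  # 0.62
#' @export
vofEndpointProps <- function(hemisphere = c("L", "R"),
                             group = c("dorsal", "ventral", "lateral_occipital")) {
  hemisphere <- match.arg(hemisphere)
  group <- match.arg(group)
  printed <- list(
    L = list(
      dorsal = c(V3CD = 35.2, V6A = 24.8, V3A = 14.8, IP0 = 9.5, V7 = 8.5),
      ventral = c(V4 = 62.0, PIT = 16.2),
      lateral_occipital = c(LO1 = 35.7, LO2 = 27.4, LO3 = 21.5)),
    R = list(
      dorsal = c(V3A = 29.4, V7 = 26.5, V3CD = 16.7, IP0 = 7.8, V6A = 7.4),
      ventral = c(V4 = 26.5, VMV1 = 11.4, PIT = 5.1),
      lateral_occipital = c(LO1 = 23.4, LO2 = 25.7, LO3 = 23.6)))
  p <- printed[[hemisphere]][[group]]
  parcels <- defaultParcels()
  all <- parcels$name[parcels$group == group]
  rest <- setdiff(all, names(p))
  out <- stats::setNames(numeric(length(all)), all)
  out[names(p)] <- p
  out[rest] <- (100 - sum(p)) / length(rest)
  out / 100
}
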