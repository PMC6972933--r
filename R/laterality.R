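# Hemispheric laterality: LI = (L - R) / (L + R), per connection and in
# total, aggregated over subjects as mean +/- SEM with a Student t-test.

#' Laterality index
#'
#' `LI = (L - R) / (L + R)`: +1 is completely left-lateralized, -1
#' completely right-lateralized. Vectorised; `L + R = 0` yields `NA`
#' (undefined, flagged downstream) rather than a number.
#'
#' @param L,R non-negative left / right values (counts, volumes, FA).
#' @return LI in `[-1, 1]`, `NA` where undefined.
#' @examples
#' lateralityIndex(3, 1)  # 0.5
#' lateralityIndex(7, 0)  # +1
#' @export
lateralityIndex <- function(L, R) {
  if (any(L < 0, na.rm = TRUE) || any(R < 0, na.rm = TRUE)) {
    stop("laterality inputs must be non-negative")
  }
  out <- (L - R) / (L + R)
  out[(L + R) == 0] <- NA_real_
  out
}

#' Summarise left/right values over subjects
#'
#' Mean, SEM (`sd / sqrt(n)`) of the per-subject laterality indices, and a
#' two-sided Student t-test of left vs right. Left and right values come
#' from the same subjects, so the test is paired by default; `paired =
#' FALSE` gives the two-sample (Welch) variant. When the paired differences
#' have zero variance the t statistic is degenerate: it is reported as 0
#' (p = 1) if the differences are all zero and as signed infinity (p = 0)
#' otherwise, with the `degenerate` flag set instead of failing silently.
#' Undefined LIs (L + R = 0) are excluded from the LI mean/SEM and counted
#' in `nUndefined`.
#'
#' @param left,right numeric vectors of per-subject values, equal length,
#'   aligned by subject.
#' @param quantity label for the summarised metric.
#' @param paired pair left and right within subject (default `TRUE`).
#' @return A [GroupSummary-class].
#' @export
summarizeSubjects <- function(left, right, quantity = "n_tracts", paired = TRUE) {
  if (length(left) != length(right)) {
    stop("left and right must cover the same subjects (equal length)")
  }
  n <- length(left)
  if (n < 2L) stop("at least 2 subjects required for SEM and t-test")
  li <- lateralityIndex(left, right)
  nUndef <- sum(is.na(li))
  if (nUndef > 0) message(nUndef, " subject(s) with undefined LI (L + R = 0) excluded")
  liOk <- li[!is.na(li)]
  degenerate <- FALSE
  if (paired) {
    d <- left - right
    df <- n - 1
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(left, right, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    }
  } else {
    if (stats::sd(left) == 0 && stats::sd(right) == 0) {
      degenerate <- TRUE
      df <- 2 * (n - 1)
      stat <- if (mean(left) == mean(right)) 0 else sign(mean(left) - mean(right)) * Inf
      p <- if (mean(left) == mean(right)) 1 else 0
    } else {
      tt <- stats::t.test(left, right, paired = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    }
  }
  new("GroupSummary", quantity = quantity, n = as.integer(n),
      meanL = mean(left), meanR = mean(right),
      meanLI = if (length(liOk)) mean(liOk) else NA_real_,
      semLI = if (length(liOk) > 1) stats::sd(liOk) / sqrt(length(liOk)) else NA_real_,
      statistic = stat, df = df, pValue = p, paired = paired,
      significant = is.finite(p) && p < 0.05, degenerate = degenerate,
      nUndefined = as.integer(nUndef))
}

#' Per-subject laterality table
#'
#' Joins per-connection metric tables of the two hemispheres for one subject
#' and computes the LI of each shared or one-sided connection.
#'
#' @param metricsL,metricsR data.frames from [tractMetrics()] for the left
#'   and right hemisphere of one subject.
#' @param quantity column to compare: `"n_tracts"`, `"volume_mm3"` or
#'   `"mean_fa"`.
#' @return data.frame with `parcelA`, `parcelB`, `L`, `R`, `LI` (connections
#'   absent from one hemisphere enter with 0 on that side).
#' @export
lateralityTable <- function(metricsL, metricsR, quantity = "n_tracts") {
  stopifnot(quantity %in% c("n_tracts", "volume_mm3", "mean_fa"))
  keyL <- paste(metricsL$parcelA, metricsL$parcelB)
  keyR <- paste(metricsR$parcelA, metricsR$parcelB)
  keys <- union(keyL, keyR)
  L <- metricsL[[quantity]][match(keys, keyL)]
  R <- metricsR[[quantity]][match(keys, keyR)]
  L[is.na(L)] <- 0; R[is.na(R)] <- 0
  parts <- strsplit(keys, " ", fixed = TRUE)
  data.frame(parcelA = vapply(parts, `[`, "", 1),
             parcelB = vapply(parts, `[`, "", 2),
             L = L, R = R, LI = lateralityIndex(L, R),
             stringsAsFactors = FALSE)
}
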