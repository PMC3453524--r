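## Prior-to-posterior odds (PPOR) marker evidence.

#' Prior-to-posterior odds ratio for a substantial marker effect
#'
#' The Bayes factor for a marker belonging to the substantial mixture
#' component, computed as the change from prior to posterior odds:
#' \code{(p1 / (1 - p1)) / (pi1 / (1 - pi1))}.
#'
#' @param p1 posterior inclusion probability (or vector), strictly inside
#'   (0, 1); use the clamped \code{\link{markerInclusionProb}}.
#' @param pi1 prior substantial fraction, strictly inside (0, 1).
#' @return PPOR value(s).
#' @examples
#' ppor(0.5, 0.025)   # 39
#' ppor(0.9, 0.1)     # 81
#' @export
ppor <- function(p1, pi1) {
  if (any(p1 <= 0 | p1 >= 1))
    stop("p1 must lie strictly inside (0, 1); clamp inclusion probabilities first")
  if (length(pi1) != 1L || pi1 <= 0 || pi1 >= 1)
    stop("pi1 must be a single value strictly inside (0, 1)")
  (p1 / (1 - p1)) / (pi1 / (1 - pi1))
}

#' Classify PPOR values into evidence classes
#'
#' Substantial evidence for 3.2 < PPOR <= 10, strong for 10 < PPOR <= 100,
#' decisive for PPOR > 100; boundary values fall in the lower class (the
#' thresholds are strict).
#'
#' @param x numeric vector of finite, non-negative PPOR values.
#' @return Ordered factor with levels \code{none < substantial < strong <
#'   decisive}.
#' @export
classifyEvidence <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("PPOR values must be finite and non-negative")
  cut(x, breaks = c(-Inf, 3.2, 10, 100, Inf),
      labels = c("none", "substantial", "strong", "decisive"),
      right = TRUE, ordered_result = TRUE)
}

#' Per-marker evidence table
#'
#' Combines the clamped posterior inclusion probabilities of a mixture fit
#' with the marker map into a table of PPOR values and evidence classes,
#' sorted by chromosome and position. The unclamped probability and the
#' clamp half-width are reported alongside.
#'
#' @param draws a \code{PosteriorDraws} from a mixture fit.
#' @param map a \code{GenotypePanel} or a marker-map \code{data.frame} with
#'   columns \code{marker}, \code{chr}, \code{pos}.
#' @return \code{data.frame} with columns \code{marker}, \code{chr},
#'   \code{pos}, \code{p1}, \code{p1Raw}, \code{ppor}, \code{class}; the
#'   clamp half-width is attached as attribute \code{"clamp"}.
#' @export
markerEvidence <- function(draws, map) {
  if (is(map, "GenotypePanel")) map <- markerMap(map)
  stopifnot(all(c("marker", "chr", "pos") %in% names(map)))
  p1 <- markerInclusionProb(draws)
  rows <- match(draws@markers, map$marker)
  if (anyNA(rows))
    stop(sprintf("marker '%s' missing from the map",
                 draws@markers[is.na(rows)][1L]))
  pp <- ppor(as.numeric(p1), draws@pi1)
  ev <- data.frame(marker = draws@markers, chr = map$chr[rows],
                   pos = map$pos[rows], p1 = as.numeric(p1),
                   p1Raw = as.numeric(attr(p1, "raw")), ppor = pp,
                   class = classifyEvidence(pp), stringsAsFactors = FALSE)
  ev <- ev[order(ev$chr, ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "clamp") <- attr(p1, "clamp")
  ev
}

#' Evidence-class counts
#'
#' @param ev an evidence table from \code{\link{markerEvidence}} (or any
#'   data.frame with a \code{class} column).
#' @return Named integer vector of marker counts per evidence class.
#' @export
evidenceCounts <- function(ev) {
  cl <- factor(ev$class, levels = c("none", "substantial", "strong",
                                    "decisive"))
  table(cl)
}

#' Manhattan-style plot table
#'
#' Adds a cumulative genome coordinate to an evidence table: each
#' chromosome is offset by the summed lengths (maximum mapped position) of
#' the chromosomes before it, giving one x-axis for any plotting front-end.
#'
#' @param ev an evidence table from \code{\link{markerEvidence}}.
#' @return The table with an extra \code{cumPos} column; one row per input
#'   marker.
#' @export
manhattanTable <- function(ev) {
  stopifnot(all(c("chr", "pos") %in% names(ev)))
  chrs <- unique(ev$chr)
  lens <- vapply(chrs, function(ch) max(ev$pos[ev$chr == ch]), numeric(1))
  offsets <- setNames(cumsum(c(0, lens[-length(lens)])), chrs)
  ev$cumPos <- ev$pos + offsets[ev$chr]
  ev
}
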