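# Transposable-element composition, flank classification and ARMD analysis.

is_alu <- function(family) startsWith(family, "Alu")

#' Major transposable element of one inserted sequence
#'
#' The interspersed-repeat class masking the largest number of insert bases;
#' ties resolve to the class of the feature with the smallest start so the
#' answer is stable under annotation row order.
#'
#' @param repeat_features Features on insert coordinates (`start`, `end`,
#'   `class`).
#' @return Class name, or `"NONE"` when no interspersed repeat is annotated.
#' @export
major_te <- function(repeat_features) {
  if (is.null(repeat_features) || !nrow(repeat_features)) return("NONE")
  feats <- repeat_features[repeat_features$class %in% INTERSPERSED_CLASSES, ,
                           drop = FALSE]
  if (!nrow(feats)) return("NONE")
  by_class <- split(feats, feats$class)
  masked <- vapply(by_class, function(f)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(f$start, f$end)))),
    numeric(1))
  first_start <- vapply(by_class, function(f) min(f$start), numeric(1))
  ord <- order(-masked, first_start)
  names(by_class)[ord[1L]]
}

#' Classify the transposable elements flanking an NUI's breakpoints
#'
#' A flank family is assigned only when a TE interval on the reference
#' annotation contains the breakpoint position itself. Categories follow the
#' Alu/Alu, Alu/LINE, LINE/LINE, OtherTE, NonTE taxonomy: `OtherTE` covers
#' every combination with at least one TE flank that is not one of the first
#' three, and flanks inside simple or low-complexity repeats count as non-TE.
#'
#' @param call Single-row call (`chrom`, `ref_left`, `ref_right`).
#' @param ref_repeats Reference repeat annotation (RepeatMasker-style table).
#' @param window Search window around each breakpoint (bp); containment of
#'   the breakpoint is still required.
#' @return List with `left_family`, `right_family` (NA when not in a TE) and
#'   `category`.
#' @export
classify_flanks <- function(call, ref_repeats, window = 300L) {
  flank_feature <- function(bp) {
    f <- ref_repeats[ref_repeats$query == call$chrom &
                       ref_repeats$class %in% INTERSPERSED_CLASSES &
                       ref_repeats$start <= bp & ref_repeats$end >= bp &
                       ref_repeats$start >= bp - window - 1e7 &
                       ref_repeats$end <= bp + window + 1e7, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    f[order(f$start, -f$score), ][1, , drop = FALSE]
  }
  fl <- flank_feature(call$ref_left)
  fr <- flank_feature(call$ref_right)
  fam <- function(f) if (is.null(f)) NA_character_ else f$family
  cls <- function(f) if (is.null(f)) NA_character_ else f$class
  lf <- fam(fl); rf <- fam(fr)
  lc <- cls(fl); rc <- cls(fr)
  alu_l <- !is.na(lf) && is_alu(lf)
  alu_r <- !is.na(rf) && is_alu(rf)
  line_l <- !is.na(lc) && lc == "LINE"
  line_r <- !is.na(rc) && rc == "LINE"
  category <- if (alu_l && alu_r) "Alu/Alu"
  else if ((alu_l && line_r) || (line_l && alu_r)) "Alu/LINE"
  else if (line_l && line_r) "LINE/LINE"
  else if (!is.na(lf) || !is.na(rf)) "OtherTE"
  else "NonTE"
  list(left_family = lf, right_family = rf, category = category,
       left_feature = fl, right_feature = fr)
}

#' Homologous-end overlap, thresholded
#'
#' Reference overlaps below `min_olap` are treated as absent (0), matching
#' the 10 bp floor used for the homology analysis.
#'
#' @param ref_overlap Overlap length(s) from the breakpoint caller.
#' @param min_olap Minimum counted overlap.
#' @return Numeric vector.
#' @export
homologous_overlap <- function(ref_overlap, min_olap = 10L) {
  ifelse(ref_overlap >= min_olap, ref_overlap, 0L)
}

#' Identify ARMD candidates among Alu-flanked NUIs
#'
#' An NUI is an Alu-recombination-mediated deletion candidate when both
#' breakpoints fall inside Alu elements, its homologous-end overlap passes
#' the threshold, and the two flanking Alu features coincide or intersect on
#' the reference, i.e. the reference carries a single chimeric Alu straddling
#' the collapsed NUI interval. The chimera breakpoint is mapped onto the Alu
#' consensus through the feature's consensus coordinates.
#'
#' @param catalog Catalog table with `id`, `chrom`, `ref_left`, `ref_right`,
#'   `ref_overlap`.
#' @param ref_repeats Reference repeat annotation.
#' @param min_olap Overlap threshold (bp).
#' @param window See [classify_flanks()].
#' @return `data.frame` of candidates: `id`, `consensus_bp`, `overlap`,
#'   `left_family`, `right_family`.
#' @export
armd_candidates <- function(catalog, ref_repeats, min_olap = 10L,
                            window = 300L) {
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    call <- catalog[i, ]
    w <- homologous_overlap(call$ref_overlap, min_olap)
    if (w == 0L) next
    fc <- classify_flanks(call, ref_repeats, window)
    if (fc$category != "Alu/Alu") next
    fl <- fc$left_feature; fr <- fc$right_feature
    chimeric <- fl$start == fr$start && fl$end == fr$end ||
      (fl$start <= fr$end && fr$start <= fl$end)
    if (!chimeric) next
    # consensus position of the left breakpoint within the chimera
    p <- if (fl$strand == "+")
      fl$cons_start + (call$ref_left - fl$start)
    else fl$cons_end - (call$ref_left - fl$start)
    out[[length(out) + 1L]] <- data.frame(
      id = call$id, consensus_bp = p, overlap = w,
      left_family = fc$left_family, right_family = fc$right_family,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(), consensus_bp = integer(),
                      overlap = integer(), left_family = character(),
                      right_family = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Breakpoint frequency along the Alu consensus
#'
#' Each candidate contributes total mass 1 spread uniformly over its
#' breakpoint range: the overlap length is subtracted from the breakpoint
#' position, giving the range `[p - w + 1, p]` with weight `1/w` per
#' position. Ranges extending outside the consensus are clipped with a
#' warning and the weight renormalised over the clipped width, so the vector
#' always sums to the number of candidates.
#'
#' @param candidates Candidate table from [armd_candidates()] (columns
#'   `consensus_bp`, `overlap`).
#' @param consensus_len Alu consensus length.
#' @return Numeric frequency vector of length `consensus_len`.
#' @export
breakpoint_frequency <- function(candidates, consensus_len = 312L) {
  freq <- numeric(consensus_len)
  for (i in seq_len(nrow(candidates))) {
    p <- candidates$consensus_bp[i]
    w <- max(1L, candidates$overlap[i])
    lo <- p - w + 1L; hi <- p
    clo <- max(1L, lo); chi <- min(consensus_len, hi)
    if (clo > chi) {
      warning("breakpoint range entirely outside consensus for candidate ", i)
      next
    }
    if (clo != lo || chi != hi)
      warning("breakpoint range clipped to consensus for candidate ", i)
    freq[clo:chi] <- freq[clo:chi] + 1 / (chi - clo + 1L)
  }
  freq
}

#' Hotspot intervals of the consensus breakpoint-frequency profile
#'
#' Maximal runs of consecutive positions whose frequency exceeds the baseline
#' (the mean per-position frequency when not supplied); runs shorter than
#' `min_run` are discarded.
#'
#' @param freq Frequency vector from [breakpoint_frequency()].
#' @param baseline Exceedance threshold (default: mean of `freq`).
#' @param min_run Minimum hotspot width.
#' @return `data.frame` of consensus intervals (`start`, `end`).
#' @export
hotspot_intervals <- function(freq, baseline = NULL, min_run = 10L) {
  if (is.null(baseline)) baseline <- mean(freq)
  above <- freq > baseline
  if (!any(above)) return(data.frame(start = integer(), end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- data.frame(start = starts[r$values], end = ends[r$values])
  out[out$end - out$start + 1L >= min_run, , drop = FALSE]
}
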