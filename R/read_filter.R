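# Read-pair filter banks: stage 1 pulls unaligned/poorly aligned pairs out of
# the reference alignment; stage 2 re-accepts pairs realigned to the diploid
# pseudo-haplotypes under stringent criteria.

#' Linked-read aligner alignment score
#'
#' The per-read score used by the extraction filter:
#' `-2*mismatches - 3*indels - 5*clipped_segments - 0.5*clipped_bases -
#' 4*improper_pair`. A perfect, properly paired read scores 0; forty
#' mismatches alone reach the -80 extraction threshold.
#'
#' @param mismatches,indels,clipped_segments,clipped_bases Non-negative counts.
#' @param improper_pair 0 or 1.
#' @return Numeric score (vectorised).
#' @export
lariat_score <- function(mismatches, indels = 0, clipped_segments = 0,
                         clipped_bases = 0, improper_pair = 0) {
  args <- cbind(mismatches, indels, clipped_segments, clipped_bases,
                improper_pair)
  if (any(args < 0)) stop("all counts must be non-negative")
  if (any(!improper_pair %in% c(0, 1))) stop("improper_pair must be 0 or 1")
  as.numeric(-2 * mismatches - 3 * indels - 5 * clipped_segments -
               0.5 * clipped_bases - 4 * improper_pair)
}

#' Estimate insert-size bounds from proper pairs
#'
#' Bounds are `mean +/- 3 SD` of the absolute insert sizes of properly
#' oriented pairs, estimated from at most the first `n_max` such records.
#'
#' @param rec Alignment record table.
#' @param n_max Number of proper-pair records to use.
#' @param fallback Bounds to return when no proper pairs exist.
#' @return Numeric `c(lo, hi)`.
#' @export
estimate_insert_bounds <- function(rec, n_max = 100000L,
                                   fallback = c(50, 1000)) {
  sizes <- abs(rec$insert_size[which(rec$proper_flag & !is.na(rec$insert_size))])
  if (!length(sizes)) return(fallback)
  sizes <- head(sizes, n_max)
  m <- mean(sizes)
  s <- if (length(sizes) > 1L) sd(sizes) else 0
  c(m - 3 * s, m + 3 * s)
}

# A pair is in FR inward orientation when both mates are mapped, exactly one
# is on the reverse strand, and the forward mate starts at or before the
# reverse mate (mates face each other).
is_fr_inward <- function(m1, m2) {
  if (m1$unmapped || m2$unmapped) return(FALSE)
  if (is.na(m1$chrom) || is.na(m2$chrom) || m1$chrom != m2$chrom) return(FALSE)
  if (m1$reverse == m2$reverse) return(FALSE)
  fwd <- if (m1$reverse) m2 else m1
  rev <- if (m1$reverse) m1 else m2
  fwd$pos <= rev$pos + rev$ref_span - 1
}

#' Stage-1 selection of unaligned/poorly aligned read pairs
#'
#' A pair is selected for the discovery stream when at least one criterion
#' fires: either mate unmapped; absolute insert size outside `insert_bounds`;
#' wrong orientation (anything but forward-reverse inward); either mate with
#' alignment score at or below `as_drop`; either mate with more than
#' `max_clip` clipped bases. Selection always carries both mates.
#'
#' @param m1,m2 Single-row alignment records for mate 1 and mate 2.
#' @param insert_bounds `c(lo, hi)` from [estimate_insert_bounds()].
#' @param as_drop Alignment-score selection threshold (score `<= as_drop`
#'   selects).
#' @param max_clip Clipped-base selection threshold (strictly more selects).
#' @return List with `selected` (logical) and `reasons` (character vector,
#'   subset of `unmapped`, `insert_size`, `orientation`, `low_AS`, `clipped`).
#' @export
select_poorly_aligned <- function(m1, m2, insert_bounds, as_drop = -80,
                                  max_clip = 40) {
  if (m1$read_name != m2$read_name)
    stop("mates with mismatched read names: ", m1$read_name, " vs ",
         m2$read_name)
  reasons <- character()
  if (m1$unmapped || m2$unmapped) reasons <- c(reasons, "unmapped")
  isz <- c(m1$insert_size, m2$insert_size)
  isz <- isz[!is.na(isz)]
  if (!(m1$unmapped || m2$unmapped)) {
    if (!length(isz) ||
        any(abs(isz) < insert_bounds[1] | abs(isz) > insert_bounds[2]))
      reasons <- c(reasons, "insert_size")
    if (!is_fr_inward(m1, m2)) reasons <- c(reasons, "orientation")
  }
  as_vals <- c(m1$align_score, m2$align_score)
  if (any(!is.na(as_vals) & as_vals <= as_drop))
    reasons <- c(reasons, "low_AS")
  if (any(c(m1$clipped_bases, m2$clipped_bases) > max_clip))
    reasons <- c(reasons, "clipped")
  list(selected = length(reasons) > 0L, reasons = reasons)
}

# Reshape an alignment table into one row per complete pair (mate-1 columns
# prefixed m1_, mate-2 columns m2_); solo reads are reported separately.
pair_table <- function(rec) {
  ord <- order(rec$read_name, rec$mate)
  r <- rec[ord, , drop = FALSE]
  runs <- rle(r$read_name)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  complete <- runs$lengths == 2L & r$mate[starts] == 1L & r$mate[ends] == 2L
  i1 <- starts[complete]; i2 <- ends[complete]
  list(m1 = r[i1, , drop = FALSE], m2 = r[i2, , drop = FALSE],
       solo = runs$values[!complete])
}

fr_inward_vec <- function(m1, m2) {
  both <- !m1$unmapped & !m2$unmapped & !is.na(m1$chrom) & !is.na(m2$chrom) &
    m1$chrom == m2$chrom & (m1$reverse != m2$reverse)
  fwd_pos <- ifelse(m1$reverse, m2$pos, m1$pos)
  rev_end <- ifelse(m1$reverse, m1$pos + m1$ref_span - 1L,
                    m2$pos + m2$ref_span - 1L)
  both & !is.na(fwd_pos) & !is.na(rev_end) & fwd_pos <= rev_end
}

#' Vectorised stage-1 selection over a full alignment table
#'
#' Applies the [select_poorly_aligned()] criteria to every pair; reads
#' without a resolvable mate are selected under the `unmapped` reason.
#'
#' @param rec Alignment table (as from [read_alignments()]).
#' @param insert_bounds,as_drop,max_clip See [select_poorly_aligned()].
#' @return `data.frame` with `read_name`, `selected`, and `reasons`
#'   (comma-collapsed).
#' @export
select_pairs <- function(rec, insert_bounds = NULL, as_drop = -80,
                         max_clip = 40) {
  if (is.null(insert_bounds)) insert_bounds <- estimate_insert_bounds(rec)
  pt <- pair_table(rec)
  m1 <- pt$m1; m2 <- pt$m2
  unm <- m1$unmapped | m2$unmapped
  both <- !unm
  isz <- ifelse(is.na(m1$insert_size), m2$insert_size, m1$insert_size)
  isz_bad <- both & (is.na(isz) | abs(isz) < insert_bounds[1] |
                       abs(isz) > insert_bounds[2])
  orient_bad <- both & !fr_inward_vec(m1, m2)
  low_as <- (!is.na(m1$align_score) & m1$align_score <= as_drop) |
    (!is.na(m2$align_score) & m2$align_score <= as_drop)
  clipped <- m1$clipped_bases > max_clip | m2$clipped_bases > max_clip
  reasons <- apply(cbind(unmapped = unm, insert_size = isz_bad,
                         orientation = orient_bad, low_AS = low_as,
                         clipped = clipped), 1L, function(row)
                           paste(names(row)[row], collapse = ","))
  out <- data.frame(read_name = m1$read_name,
                    selected = unm | isz_bad | orient_bad | low_as | clipped,
                    reasons = reasons, stringsAsFactors = FALSE)
  if (length(pt$solo))
    out <- rbind(out, data.frame(read_name = pt$solo, selected = TRUE,
                                 reasons = "unmapped",
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Trim linked-read barcode artifacts off the first mate
#'
#' Removes the leading 23 bases of mate 1 (16 bp droplet barcode plus the 7 bp
#' low-accuracy oligo stretch) from both sequence and base qualities; mate 2
#' is untouched. Pairs whose mate 1 is not longer than the trim length are
#' dropped with a warning.
#'
#' @param m1,m2 Single-row alignment records.
#' @param trim_len Bases removed from the start of mate 1.
#' @return List `(m1, m2)` or `NULL` when the pair is dropped.
#' @export
trim_linked_read_artifacts <- function(m1, m2, trim_len = 23L) {
  if (nchar(m1$seq) <= trim_len) {
    warning("mate 1 of ", m1$read_name, " shorter than trim length; pair dropped")
    return(NULL)
  }
  m1$seq <- substring(m1$seq, trim_len + 1L)
  if (!is.na(m1$qual) && m1$qual != "*")
    m1$qual <- substring(m1$qual, trim_len + 1L)
  m1$read_len <- nchar(m1$seq)
  list(m1 = m1, m2 = m2)
}

qual_to_int <- function(qual) utf8ToInt(qual) - 33L

#' Pair-level base-quality filter
#'
#' The whole pair is removed when either mate has fewer than `frac` of its
#' bases at quality `q_threshold` or above.
#'
#' @param m1,m2 Single-row alignment records with `qual` strings.
#' @param q_threshold Phred threshold.
#' @param frac Minimum passing fraction.
#' @return `TRUE` to keep the pair.
#' @export
quality_filter <- function(m1, m2, q_threshold = 30L, frac = 0.70) {
  ok <- function(m) {
    if (is.na(m$qual) || m$qual == "" || m$qual == "*") return(FALSE)
    q <- qual_to_int(m$qual)
    mean(q >= q_threshold) >= frac
  }
  ok(m1) && ok(m2)
}

#' Stringent acceptance of a pair realigned to a pseudo-haplotype
#'
#' All criteria must hold: mate 1 alignment score at least `min_as1` (mate 1
#' is shorter after barcode trimming), mate 2 at least `min_as2`, proper
#' forward-reverse inward orientation, absolute insert size within
#' `insert_bounds`, and both mapping qualities at least `min_mapq`. A missing
#' alignment score fails.
#'
#' @param m1,m2 Single-row alignment records against a pseudo-haplotype.
#' @param insert_bounds `c(lo, hi)`.
#' @param min_as1,min_as2,min_mapq Acceptance thresholds.
#' @return `TRUE` when the pair is accepted.
#' @export
accept_stringent_realignment <- function(m1, m2, insert_bounds,
                                         min_as1 = 90, min_as2 = 113,
                                         min_mapq = 30L) {
  if (m1$unmapped || m2$unmapped) return(FALSE)
  if (is.na(m1$align_score) || is.na(m2$align_score)) return(FALSE)
  if (m1$align_score < min_as1 || m2$align_score < min_as2) return(FALSE)
  if (!is_fr_inward(m1, m2)) return(FALSE)
  isz <- c(m1$insert_size, m2$insert_size)
  isz <- isz[!is.na(isz)]
  if (!length(isz) ||
      any(abs(isz) < insert_bounds[1] | abs(isz) > insert_bounds[2]))
    return(FALSE)
  m1$mapq >= min_mapq && m2$mapq >= min_mapq
}

# Apply accept_stringent_realignment over a table; returns read names of
# accepted pairs.
accepted_pair_names <- function(rec, insert_bounds = NULL, min_as1 = 90,
                                min_as2 = 113, min_mapq = 30L) {
  if (!nrow(rec)) return(character())
  if (is.null(insert_bounds)) insert_bounds <- estimate_insert_bounds(rec)
  pt <- pair_table(rec)
  m1 <- pt$m1; m2 <- pt$m2
  if (!nrow(m1)) return(character())
  isz <- ifelse(is.na(m1$insert_size), m2$insert_size, m1$insert_size)
  ok <- !m1$unmapped & !m2$unmapped &
    !is.na(m1$align_score) & !is.na(m2$align_score) &
    m1$align_score >= min_as1 & m2$align_score >= min_as2 &
    fr_inward_vec(m1, m2) &
    !is.na(isz) & abs(isz) >= insert_bounds[1] &
    abs(isz) <= insert_bounds[2] &
    m1$mapq >= min_mapq & m2$mapq >= min_mapq
  m1$read_name[ok]
}

#' Remove pairs that realign concordantly to the core reference
#'
#' Pairs passing the stringent acceptance criteria against the reference
#' realignment are discarded from the haplotype streams: a pair that still
#' fits the reference cleanly carries no insertion signal.
#'
#' @param hap_rec Alignment table against one pseudo-haplotype.
#' @param ref_rec Realignment table of the same pairs against the core
#'   reference.
#' @param insert_bounds Bounds for the reference-side concordance check
#'   (estimated from `ref_rec` when `NULL`).
#' @return `hap_rec` without the reference-concordant pairs.
#' @export
discard_reference_concordant <- function(hap_rec, ref_rec,
                                         insert_bounds = NULL) {
  if (!nrow(hap_rec) || !nrow(ref_rec)) return(hap_rec)
  concordant <- accepted_pair_names(ref_rec, insert_bounds)
  hap_rec[!(hap_rec$read_name %in% concordant), , drop = FALSE]
}
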