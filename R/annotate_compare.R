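# Orthogonal annotation: primate ancestry, transcription evidence,
# external call-set overlap, cohort-frequency filtering.

#' Presence of an NUI in a non-human primate genome
#'
#' The flanked NUI must align at `min_id` identity over at least `min_cov`
#' of its length; both thresholds are required.
#'
#' @param extended_seq NUI plus reference flanks.
#' @param primate_genome Primate sequence collection.
#' @param min_id,min_cov Hit thresholds.
#' @return `TRUE` when present.
#' @export
primate_presence <- function(extended_seq, primate_genome, min_id = 0.95,
                             min_cov = 0.95) {
  nrow(find_hits(extended_seq, primate_genome, min_identity = min_id,
                 min_coverage = min_cov)) > 0L
}

#' Union of per-primate presence flags
#'
#' @param flags Data frame or named list of logical vectors, one per primate,
#'   all over the same NUI set.
#' @return List with `union` (logical vector), `per_primate` counts,
#'   `union_count`, and `total`.
#' @export
ancestral_union <- function(flags) {
  flags <- as.data.frame(flags)
  if (!ncol(flags)) stop("at least one primate flag vector required")
  u <- Reduce(`|`, flags)
  list(union = u,
       per_primate = vapply(flags, sum, numeric(1)),
       union_count = sum(u),
       total = length(u))
}

#' Transcription evidence from an EST collection
#'
#' Two-step rule: extract NUI subregions aligning to an EST at `min_id`
#' identity regardless of query coverage (subject to a minimum region length,
#' since database entries are short), then discard any region that also
#' aligns to the core reference. The NUI is transcribed when at least one
#' region survives.
#'
#' @param insert_seq Inserted sequence.
#' @param est_db EST sequence collection.
#' @param reference Core reference collection.
#' @param min_id Identity threshold.
#' @param min_region Minimum aligned-region length (bp).
#' @return `TRUE` when transcription evidence remains after the reference
#'   screen.
#' @export
est_transcription <- function(insert_seq, est_db, reference, min_id = 0.95,
                              min_region = 30L) {
  if (is.null(est_db) || !length(est_db)) return(FALSE)
  regions <- find_local_regions(insert_seq, est_db, min_identity = min_id,
                                min_len = min_region)
  if (!nrow(regions)) return(FALSE)
  for (i in seq_len(nrow(regions))) {
    sub <- substring(insert_seq, regions$q_start[i], regions$q_end[i])
    ref_hit <- find_hits(sub, reference, min_identity = min_id,
                         min_coverage = 0.95)
    if (!nrow(ref_hit)) return(TRUE)
  }
  FALSE
}

#' Transcription evidence from RNA-seq read pairs on the extended NUI
#'
#' Pairs are judged against the NUI extended by `flank` bases on both ends.
#' A pair supports transcription when all criteria hold: both mates mapped;
#' the two mates do not both reside entirely in the flanks; proper
#' orientation with insert size inside `insert_bounds`; combined alignment
#' score at least `min_as`; and the unique-mapping flag set on both mates.
#'
#' @param pairs `data.frame` with columns `m1_start`, `m1_end`, `m2_start`,
#'   `m2_end` (1-based coordinates on the extended NUI, `NA` when unmapped),
#'   `proper` (logical), `as_total` (combined alignment score), `unique`
#'   (logical).
#' @param insert_len Length of the NUI itself.
#' @param flank Flank extension used when aligning (bp).
#' @param min_as Combined alignment-score threshold.
#' @param insert_bounds Optional `c(lo, hi)` on the pair's outer span; when
#'   `NULL` the `proper` flag alone vouches for insert size.
#' @return `TRUE` when at least one pair passes every criterion.
#' @export
rnaseq_transcription <- function(pairs, insert_len, flank = 300L,
                                 min_as = 140, insert_bounds = NULL) {
  if (is.null(pairs) || !nrow(pairs)) return(FALSE)
  core_lo <- flank + 1L
  core_hi <- flank + insert_len
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (any(is.na(c(p$m1_start, p$m1_end, p$m2_start, p$m2_end)))) next
    in_flanks <- function(s, e) e < core_lo || s > core_hi
    if (in_flanks(p$m1_start, p$m1_end) && in_flanks(p$m2_start, p$m2_end))
      next
    if (!isTRUE(p$proper)) next
    if (!is.null(insert_bounds)) {
      span <- max(p$m1_end, p$m2_end) - min(p$m1_start, p$m2_start) + 1L
      if (span < insert_bounds[1] || span > insert_bounds[2]) next
    }
    if (is.na(p$as_total) || p$as_total < min_as) next
    if (!isTRUE(p$unique)) next
    return(TRUE)
  }
  FALSE
}

#' Combine EST and RNA-seq transcription flags
#'
#' @param est_flags,rnaseq_flags Named logical vectors over the same catalog
#'   ids.
#' @return List with `union` flags and the counts `n_est`, `n_rnaseq`,
#'   `n_both`, `n_union` (inclusion-exclusion consistent by construction).
#' @export
transcription_union <- function(est_flags, rnaseq_flags) {
  if (!identical(sort(names(est_flags)), sort(names(rnaseq_flags))))
    stop("EST and RNA-seq flags cover different catalog ids")
  rnaseq_flags <- rnaseq_flags[names(est_flags)]
  u <- est_flags | rnaseq_flags
  list(union = u,
       n_est = sum(est_flags), n_rnaseq = sum(rnaseq_flags),
       n_both = sum(est_flags & rnaseq_flags), n_union = sum(u))
}

#' Reciprocal overlap with an external contig set
#'
#' Direction A aligns each NUI against the external contigs, direction B
#' aligns each contig against the NUI set; each direction filters at
#' `min_id`/`min_cov` on its own query, and the shared set is the union of
#' NUIs hit in either direction.
#'
#' @param catalog_seqs Named character vector (or `DNAStringSet`) of NUI
#'   sequences keyed by catalog id.
#' @param external_contigs External contig collection.
#' @param min_id,min_cov Per-direction thresholds.
#' @return Character vector of shared NUI ids.
#' @export
reciprocal_overlap <- function(catalog_seqs, external_contigs, min_id = 0.95,
                               min_cov = 0.95) {
  catalog_seqs <- seq_chars(catalog_seqs)
  if (is.null(external_contigs) || !length(external_contigs))
    return(character())
  dir_a <- names(catalog_seqs)[vapply(catalog_seqs, function(s)
    nrow(find_hits(s, external_contigs, min_identity = min_id,
                   min_coverage = min_cov)) > 0L, logical(1))]
  ext <- seq_chars(external_contigs)
  dir_b <- unique(unlist(lapply(ext, function(cseq) {
    hits <- find_hits(cseq, catalog_seqs, min_identity = min_id,
                      min_coverage = min_cov)
    hits$target
  })))
  sort(union(dir_a, dir_b))
}

#' Drop cohort singletons from an occurrence matrix
#'
#' @param matrix Binary occurrence matrix (samples x NUIs).
#' @return The matrix restricted to NUIs carried by at least two samples.
#' @export
singleton_filter <- function(matrix) {
  matrix[, colSums(matrix) >= 2L, drop = FALSE]
}
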