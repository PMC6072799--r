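# Breakpoint computation from anchored contigs aligned to the reference.

#' Pick the best anchor alignment among candidates
#'
#' Candidates are ranked by alignment length, then identity. When an anchor
#' end hits more than `max_loci` genomic loci, the winning alignment must be
#' at least `min_len_if_multi` bases long, otherwise the anchor is rejected
#' as unplaceable.
#'
#' @param candidates Candidate table from [anchor_candidates()].
#' @param min_len_if_multi Minimum length required when multi-mapping.
#' @param max_loci Locus-count threshold triggering the length requirement.
#' @return Single-row `data.frame`, or `NULL` when the anchor is rejected or
#'   unaligned.
#' @export
select_best_anchor <- function(candidates, min_len_if_multi = 3500L,
                               max_loci = 5L) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  candidates <- candidates[order(-candidates$length, -candidates$identity), ,
                           drop = FALSE]
  best <- candidates[1, , drop = FALSE]
  if (nrow(candidates) > max_loci && best$length < min_len_if_multi)
    return(NULL)
  best
}

#' Compute an insertion breakpoint call from two selected anchors
#'
#' The left breakpoint is the last reference base of the left anchor and the
#' right breakpoint the first reference base of the right anchor; when the
#' anchors overlap on the reference the overlap length is recorded and the
#' reported inserted sequence carries one copy of the shared (homologous)
#' bases at each end. Calls are rejected when the anchors disagree on
#' chromosome, the reference overlap exceeds `max_overlap`, the inserted
#' sequence is shorter than `min_insert`, or the contig bases immediately
#' beyond either anchor are `N`.
#'
#' @param left,right Single-row anchor alignments.
#' @param contig_seq The anchored contig sequence.
#' @param max_overlap Maximum tolerated reference overlap (bp).
#' @param min_insert Minimum inserted-sequence length (bp).
#' @return Single-row `data.frame` call, or `NULL` when rejected.
#' @export
call_breakpoints <- function(left, right, contig_seq, max_overlap = 800L,
                             min_insert = 50L) {
  reject <- function(why) NULL
  if (is.null(left) || is.null(right)) return(reject("anchor_unaligned"))
  if (left$chrom != right$chrom) return(reject("translocation_like"))
  ref_left <- left$ref_end
  ref_right <- right$ref_start
  ref_overlap <- max(0L, ref_left - ref_right + 1L)
  if (ref_overlap > max_overlap) return(reject("overlap"))
  ins_start <- left$ctg_end - ref_overlap + 1L
  ins_end <- right$ctg_start + ref_overlap - 1L
  insert_len <- ins_end - ins_start + 1L
  if (insert_len < min_insert) return(reject("short_insert"))
  flank_l <- substring(contig_seq, left$ctg_end + 1L, left$ctg_end + 1L)
  flank_r <- substring(contig_seq, right$ctg_start - 1L, right$ctg_start - 1L)
  if (identical(flank_l, "N") || identical(flank_r, "N"))
    return(reject("n_gap"))
  data.frame(chrom = left$chrom, ref_left = ref_left, ref_right = ref_right,
             ref_overlap = ref_overlap, insert_len = insert_len,
             seq = substring(contig_seq, ins_start, ins_end),
             stringsAsFactors = FALSE)
}

#' Call breakpoints for every anchored contig of one haplotype
#'
#' Runs anchor candidate generation, best-anchor selection and breakpoint
#' computation over an anchored-contig table.
#'
#' @param contigs Anchored contig table from [extract_anchored_contigs()].
#' @param reference Reference collection (named character or `DNAStringSet`).
#' @param seed_len Seed length for anchor alignment.
#' @param max_overlap,min_insert See [call_breakpoints()].
#' @param min_len_if_multi,max_loci See [select_best_anchor()].
#' @return `data.frame` of calls with a `contig_name` column; rejected
#'   contigs are dropped.
#' @export
contig_breakpoints <- function(contigs, reference, seed_len = 32L,
                               max_overlap = 800L, min_insert = 50L,
                               min_len_if_multi = 3500L, max_loci = 5L) {
  calls <- lapply(seq_len(nrow(contigs)), function(i) {
    cseq <- contigs$seq[i]
    left <- select_best_anchor(
      anchor_candidates(cseq, reference, "left", seed_len),
      min_len_if_multi, max_loci)
    right <- select_best_anchor(
      anchor_candidates(cseq, reference, "right", seed_len),
      min_len_if_multi, max_loci)
    call <- call_breakpoints(left, right, cseq, max_overlap, min_insert)
    if (is.null(call)) return(NULL)
    call$contig_name <- contigs$contig_name[i]
    call
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty_calls())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(chrom = character(), ref_left = integer(), ref_right = integer(),
             ref_overlap = integer(), insert_len = integer(), seq = character(),
             contig_name = character(), stringsAsFactors = FALSE)
}

#' Unify calls from the two pseudo-haplotypes of one sample
#'
#' Calls whose breakpoints agree to within `tol` bases on both sides
#' (strictly less than `tol` apart) collapse into a single homozygous call
#' whose sequence is taken from haplotype 1; all other calls keep their
#' haplotype label.
#'
#' @param calls_h1,calls_h2 Call tables from [contig_breakpoints()].
#' @param tol Breakpoint agreement tolerance (exclusive, bp).
#' @return Unified call table with a `zygosity` column
#'   (`hap1`/`hap2`/`homozygous`).
#' @export
merge_haplotype_calls <- function(calls_h1, calls_h2, tol = 10L) {
  h1 <- calls_h1; h2 <- calls_h2
  if (nrow(h1)) h1$zygosity <- "hap1"
  if (nrow(h2)) h2$zygosity <- "hap2"
  if (!nrow(h1) || !nrow(h2)) {
    out <- rbind(h1, h2)
    if (!nrow(out)) out$zygosity <- character()
    return(out)
  }
  used2 <- rep(FALSE, nrow(h2))
  for (i in seq_len(nrow(h1))) {
    j <- which(!used2 & h2$chrom == h1$chrom[i] &
                 abs(h2$ref_left - h1$ref_left[i]) < tol &
                 abs(h2$ref_right - h1$ref_right[i]) < tol)
    if (length(j)) {
      h1$zygosity[i] <- "homozygous"
      used2[j[1L]] <- TRUE
    }
  }
  out <- rbind(h1, h2[!used2, , drop = FALSE])
  out <- out[order(out$chrom, out$ref_left), , drop = FALSE]
  rownames(out) <- NULL
  out
}
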