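# Read clusters on the pseudo-haplotypes and anchored contig extraction.

#' Per-base read coverage along one contig
#'
#' @param rec Alignment table restricted to reads placed on `contig`.
#' @param contig Contig name.
#' @param contig_len Contig length in bases.
#' @return Integer depth vector of length `contig_len`; `depth[i]` counts the
#'   reads whose aligned reference span covers position `i` (1-based).
#' @export
per_base_coverage <- function(rec, contig, contig_len) {
  rec <- rec[!is.na(rec$chrom) & rec$chrom == contig & !rec$unmapped, ,
             drop = FALSE]
  if (!nrow(rec)) return(integer(contig_len))
  ir <- IRanges::IRanges(start = rec$pos,
                         end = pmin(rec$pos + rec$ref_span - 1L, contig_len))
  as.integer(IRanges::coverage(ir, width = contig_len))
}

#' Locate read clusters as coverage runs inside a depth corridor
#'
#' Maximal runs of positions with `lo <= depth <= hi`. Positions above `hi`
#' (collapsed-repeat signal) are excluded, so a high spike inside a plateau
#' splits it into two clusters.
#'
#' @param depth Integer depth vector.
#' @param lo,hi Inclusive coverage bounds.
#' @return `data.frame` with 1-based `start`, `end` (inclusive) and
#'   `peak_depth` per cluster.
#' @export
find_clusters <- function(depth, lo = 8L, hi = 100L) {
  in_cluster <- depth >= lo & depth <= hi
  if (!any(in_cluster))
    return(data.frame(start = integer(), end = integer(),
                      peak_depth = integer()))
  r <- rle(in_cluster)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$peak_depth <- vapply(seq_len(nrow(out)), function(i)
    max(depth[out$start[i]:out$end[i]]), numeric(1))
  out
}

#' Extract anchored contig sequences around read clusters
#'
#' Each cluster span is extended by `extension` bases on both sides (clipped
#' at the contig ends) to provide alignment anchors. Extended intervals that
#' overlap or are separated by less than `merge_gap` bases are merged into a
#' single anchored contig. Sequences containing more than `max_n` ambiguous
#' bases are dropped.
#'
#' @param clusters Cluster table from [find_clusters()].
#' @param hap_seq Haplotype contig sequence (single character string).
#' @param contig_name Contig name used in output identifiers.
#' @param merge_gap Merge threshold on the gap between extended intervals.
#' @param extension Anchor extension in bases.
#' @param max_n Maximum tolerated `N` count in the extracted sequence.
#' @return `data.frame` with `contig_name`, `core_start`, `core_end`,
#'   `ext_start`, `ext_end`, `seq`, `n_count` (one row per anchored contig).
#' @export
extract_anchored_contigs <- function(clusters, hap_seq, contig_name,
                                     merge_gap = 200L, extension = 7000L,
                                     max_n = 10L) {
  empty <- data.frame(contig_name = character(), core_start = integer(),
                      core_end = integer(), ext_start = integer(),
                      ext_end = integer(), seq = character(),
                      n_count = integer(), stringsAsFactors = FALSE)
  if (!nrow(clusters)) return(empty)
  len <- nchar(hap_seq)
  if (any(clusters$start < 1L | clusters$end > len))
    stop("cluster outside contig bounds")
  clusters <- clusters[order(clusters$start), , drop = FALSE]
  ext_start <- pmax(1L, clusters$start - extension)
  ext_end <- pmin(len, clusters$end + extension)
  # merge extended intervals that overlap or leave a gap < merge_gap
  grp <- integer(nrow(clusters))
  grp[1] <- 1L
  if (nrow(clusters) > 1L) {
    cur_end <- ext_end[1]
    for (i in 2L:nrow(clusters)) {
      gap <- ext_start[i] - cur_end - 1L
      grp[i] <- if (gap < merge_gap) grp[i - 1L] else grp[i - 1L] + 1L
      cur_end <- max(cur_end, ext_end[i])
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(clusters)), grp), function(idx) {
    es <- min(ext_start[idx]); ee <- max(ext_end[idx])
    s <- substring(hap_seq, es, ee)
    data.frame(contig_name = contig_name,
               core_start = min(clusters$start[idx]),
               core_end = max(clusters$end[idx]),
               ext_start = es, ext_end = ee, seq = s,
               n_count = lengths(regmatches(s, gregexpr("N", s))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[out$n_count <= max_n, , drop = FALSE]
}
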