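# Gapless seed-and-extend alignment primitives.
#
# The pipeline treats alignment as a pluggable contract: anything that can
# report anchor alignments (contig span, reference span, identity, length)
# and identity/coverage hits can stand behind these functions. The default
# implementation is an exact-seed, gapless extension aligner suited to the
# high-identity, indel-free fixtures the simulator produces; production use
# can substitute an external aligner emitting the same record shapes.

# Longest common extension between a[a_start..] and b[b_start..], compared on
# raw bytes in chunks.
common_extension <- function(a, a_start, b, b_start, direction = 1L) {
  max_len <- if (direction > 0L)
    min(nchar(a) - a_start + 1L, nchar(b) - b_start + 1L)
  else
    min(a_start, b_start)
  if (max_len <= 0L) return(0L)
  got <- 0L
  chunk <- 4096L
  while (got < max_len) {
    take <- min(chunk, max_len - got)
    if (direction > 0L) {
      ra <- charToRaw(substring(a, a_start + got, a_start + got + take - 1L))
      rb <- charToRaw(substring(b, b_start + got, b_start + got + take - 1L))
    } else {
      ra <- charToRaw(substring(a, a_start - got - take + 1L, a_start - got))
      rb <- charToRaw(substring(b, b_start - got - take + 1L, b_start - got))
      ra <- rev(ra); rb <- rev(rb)
    }
    neq <- which(ra != rb)
    if (length(neq)) return(got + neq[1L] - 1L)
    got <- got + take
  }
  got
}

#' Candidate anchor alignments for one end of an anchored contig
#'
#' Seeds the terminal `seed_len` bases of the chosen contig end against the
#' reference and extends each exact seed hit maximally without gaps. Each
#' candidate records its contig span, reference span, identity (1 for exact
#' extensions) and length.
#'
#' @param contig_seq Anchored contig sequence (character string).
#' @param reference Named character vector (or `DNAStringSet`) of reference
#'   chromosomes.
#' @param side `"left"` (contig start) or `"right"` (contig end).
#' @param seed_len Exact seed length.
#' @return `data.frame` of candidates: `chrom`, `ref_start`, `ref_end`,
#'   `ctg_start`, `ctg_end`, `length`, `identity` (empty when the end is
#'   unalignable).
#' @export
anchor_candidates <- function(contig_seq, reference, side = c("left", "right"),
                              seed_len = 32L) {
  side <- match.arg(side)
  reference <- seq_chars(reference)
  qlen <- nchar(contig_seq)
  if (qlen < seed_len) return(empty_anchor_candidates())
  seed <- if (side == "left") substring(contig_seq, 1L, seed_len)
          else substring(contig_seq, qlen - seed_len + 1L, qlen)
  hits <- lapply(names(reference), function(chrom) {
    m <- Biostrings::matchPattern(seed, Biostrings::DNAString(reference[[chrom]]))
    if (!length(m)) return(NULL)
    data.frame(chrom = chrom, pos = BiocGenerics::start(m),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(empty_anchor_candidates())
  out <- lapply(seq_len(nrow(hits)), function(i) {
    chrom <- hits$chrom[i]
    refseq <- reference[[chrom]]
    if (side == "left") {
      ext <- common_extension(contig_seq, seed_len + 1L, refseq,
                              hits$pos[i] + seed_len, 1L)
      len <- seed_len + ext
      data.frame(chrom = chrom, ref_start = hits$pos[i],
                 ref_end = hits$pos[i] + len - 1L,
                 ctg_start = 1L, ctg_end = len,
                 length = len, identity = 1, stringsAsFactors = FALSE)
    } else {
      seed_end <- hits$pos[i] + seed_len - 1L
      ext <- common_extension(contig_seq, qlen - seed_len, refseq,
                              hits$pos[i] - 1L, -1L)
      len <- seed_len + ext
      data.frame(chrom = chrom, ref_start = seed_end - len + 1L,
                 ref_end = seed_end,
                 ctg_start = qlen - len + 1L, ctg_end = qlen,
                 length = len, identity = 1, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  # distinct loci only (duplicate seeds inside one extension collapse)
  out[!duplicated(out[, c("chrom", "ref_start", "ref_end")]), , drop = FALSE]
}

empty_anchor_candidates <- function() {
  data.frame(chrom = character(), ref_start = integer(), ref_end = integer(),
             ctg_start = integer(), ctg_end = integer(), length = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}

# Exact seeds of a query at fixed stride, packaged once as a PDict so a
# single Aho-Corasick pass per target finds every gapless diagonal
# (target_pos - query_pos offset) carrying at least one seed hit.
query_seed_dict <- function(query, seed_len, stride) {
  qlen <- nchar(query)
  if (qlen < seed_len) return(NULL)
  starts <- unique(c(seq(1L, qlen - seed_len + 1L, by = stride),
                     qlen - seed_len + 1L))
  seeds <- substring(query, starts, starts + seed_len - 1L)
  keep <- !grepl("N", seeds, fixed = TRUE)
  starts <- starts[keep]; seeds <- seeds[keep]
  if (!length(seeds)) return(NULL)
  list(pdict = Biostrings::PDict(seeds), starts = starts)
}

seed_diagonals <- function(sdict, target_dna) {
  if (is.null(sdict)) return(integer())
  m <- Biostrings::matchPDict(sdict$pdict, target_dna)
  hit_starts <- BiocGenerics::start(m)
  offs <- unlist(lapply(seq_along(sdict$starts), function(i)
    hit_starts[[i]] - sdict$starts[i]), use.names = FALSE)
  unique(offs)
}

# Boolean per-base match vector of query against target at a fixed gapless
# offset; positions outside the target are NA.
gapless_match_vector <- function(query, target, offset) {
  qlen <- nchar(query)
  qs <- max(1L, 1L - offset)
  qe <- min(qlen, nchar(target) - offset)
  m <- rep(NA, qlen)
  if (qs > qe) return(m)
  rq <- charToRaw(substring(query, qs, qe))
  rt <- charToRaw(substring(target, qs + offset, qe + offset))
  m[qs:qe] <- rq == rt
  m
}

# Maximal-scoring contiguous segment of a match vector (match +1,
# mismatch -penalty); poorly matching ends are trimmed the way a local
# aligner would. Returns c(start, end) query positions or NULL.
best_gapless_segment <- function(mv, penalty = 3) {
  ok <- which(!is.na(mv))
  if (!length(ok)) return(NULL)
  sc <- ifelse(mv[ok], 1, -penalty)
  best <- -Inf; best_i <- 1L; best_j <- 0L
  cur <- 0; cur_i <- 1L
  for (k in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[k]; cur_i <- k } else cur <- cur + sc[k]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- k }
  }
  if (best <= 0) return(NULL)
  c(ok[best_i], ok[best_j])
}

#' Gapless identity/coverage hits of a query against a target collection
#'
#' Seeds `seed_len`-mers at fixed stride, groups exact seed matches by
#' diagonal, and on each diagonal scores the maximal well-matching local
#' segment (poorly matching termini are trimmed). Identity is matches over
#' the segment's columns and coverage is the segment length over the query
#' length, matching the conventions of the BLAST-style filters built on
#' top.
#'
#' @param query Query sequence (character string).
#' @param targets Named character vector or `DNAStringSet`.
#' @param min_identity,min_coverage Hit-reporting thresholds.
#' @param seed_len,stride Seeding parameters.
#' @return `data.frame` of hits: `target`, `offset`, `identity`, `coverage`,
#'   `t_start`, `t_end`.
#' @export
find_hits <- function(query, targets, min_identity = 0, min_coverage = 0,
                      seed_len = 16L, stride = 8L) {
  targets <- seq_chars(targets)
  qlen <- nchar(query)
  empty <- data.frame(target = character(), offset = integer(),
                      identity = numeric(), coverage = numeric(),
                      t_start = integer(), t_end = integer(),
                      stringsAsFactors = FALSE)
  if (qlen < seed_len) return(empty)
  sdict <- query_seed_dict(query, seed_len, stride)
  out <- list()
  for (tname in names(targets)) {
    tseq <- targets[[tname]]
    tdna <- Biostrings::DNAString(tseq)
    offs <- seed_diagonals(sdict, tdna)
    for (off in offs) {
      mv <- gapless_match_vector(query, tseq, off)
      seg <- best_gapless_segment(mv)
      if (is.null(seg)) next
      cov <- (seg[2L] - seg[1L] + 1L) / qlen
      ident <- mean(mv[seg[1L]:seg[2L]])
      if (ident >= min_identity && cov >= min_coverage)
        out[[length(out) + 1L]] <- data.frame(
          target = tname, offset = off, identity = ident, coverage = cov,
          t_start = seg[1L] + off, t_end = seg[2L] + off,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(-res$identity * res$coverage), , drop = FALSE]
}

#' Well-matching local query regions against a target collection
#'
#' Used by the EST screen, where short database entries make query coverage
#' meaningless: reports maximal query intervals that align gaplessly at
#' `min_identity` or better and span at least `min_len` bases.
#'
#' @param query,targets,seed_len,stride As in [find_hits()].
#' @param min_identity Minimum region identity.
#' @param min_len Minimum region length in query bases.
#' @return `data.frame` of regions: `target`, `q_start`, `q_end`, `identity`.
#' @export
find_local_regions <- function(query, targets, min_identity = 0.95,
                               min_len = 30L, seed_len = 16L, stride = 8L) {
  targets <- seq_chars(targets)
  empty <- data.frame(target = character(), q_start = integer(),
                      q_end = integer(), identity = numeric(),
                      offset = integer(), stringsAsFactors = FALSE)
  if (nchar(query) < seed_len) return(empty)
  sdict <- query_seed_dict(query, seed_len, stride)
  out <- list()
  for (tname in names(targets)) {
    tdna <- Biostrings::DNAString(targets[[tname]])
    offs <- seed_diagonals(sdict, tdna)
    for (off in offs) {
      mv <- gapless_match_vector(query, targets[[tname]], off)
      mv[is.na(mv)] <- FALSE
      r <- rle(mv)
      ends <- cumsum(r$lengths); sts <- ends - r$lengths + 1L
      runs <- data.frame(start = sts[r$values], end = ends[r$values])
      if (!nrow(runs)) next
      # greedily merge match runs across short mismatch gaps while the
      # combined identity stays above threshold
      merged <- runs[1, ]
      if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
        cand_start <- merged$start[nrow(merged)]
        cand_end <- runs$end[i]
        ident <- sum(mv[cand_start:cand_end]) / (cand_end - cand_start + 1L)
        if (ident >= min_identity)
          merged$end[nrow(merged)] <- cand_end
        else merged <- rbind(merged, runs[i, ])
      }
      merged$identity <- vapply(seq_len(nrow(merged)), function(i)
        mean(mv[merged$start[i]:merged$end[i]]), numeric(1))
      keep <- merged$end - merged$start + 1L >= min_len &
        merged$identity >= min_identity
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          target = tname, q_start = merged$start[keep],
          q_end = merged$end[keep], identity = merged$identity[keep],
          offset = off, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("q_start", "q_end")]), , drop = FALSE]
}
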