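# Symmetric DUST low-complexity masking.
#
# A window of w bases contains w-2 overlapping triplets. The score of an
# interval holding k triplets with per-triplet counts c_t is
#   S = sum_t c_t (c_t - 1) / 2 / (k - 1),
# the (scaled) number of repeated triplet pairs. An interval is "perfect"
# when S exceeds threshold/10 and is at least the score of every one of its
# subintervals; the mask is the union of all perfect intervals no longer
# than the window. Runs of N are never scored and never masked.

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

triplet_codes <- function(seg) {
  b <- BASE_CODE[strsplit(seg, "")[[1]]]
  n <- length(b)
  if (n < 3L) return(integer(0))
  16L * b[1:(n - 2L)] + 4L * b[2:(n - 1L)] + b[3:n] + 1L
}

dust_segment <- function(seg, window, threshold) {
  L <- nchar(seg)
  trip <- triplet_codes(seg)
  nt <- length(trip)
  if (!nt) return(NULL)
  wk <- window - 2L            # max triplets per interval
  score_thr <- threshold / 10
  S <- matrix(0, nrow = nt, ncol = wk)
  for (i in seq_len(nt)) {
    cnt <- integer(64L)
    acc <- 0L
    kmax <- min(wk, nt - i + 1L)
    for (k in seq_len(kmax)) {
      t <- trip[i + k - 1L]
      acc <- acc + cnt[t]
      cnt[t] <- cnt[t] + 1L
      S[i, k] <- if (k >= 2L) acc / (k - 1L) else 0
    }
  }
  # M[i,k]: maximum score over all subintervals of the interval starting at
  # triplet i with k triplets
  M <- matrix(0, nrow = nt, ncol = wk)
  perfect <- matrix(FALSE, nrow = nt, ncol = wk)
  for (i in nt:1L) {
    kmax <- min(wk, nt - i + 1L)
    for (k in seq_len(kmax)) {
      sub_max <- 0
      if (k > 1L) {
        sub_max <- M[i, k - 1L]
        if (i < nt) sub_max <- max(sub_max, M[i + 1L, k - 1L])
      }
      s <- S[i, k]
      M[i, k] <- max(s, sub_max)
      perfect[i, k] <- s > score_thr && s >= sub_max
    }
  }
  idx <- which(perfect, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  # triplet interval (i, k) covers bases i .. i+k+1
  IRanges::IRanges(start = idx[, 1L], end = idx[, 1L] + idx[, 2L] + 1L)
}

#' Mask low-complexity sequence with the symmetric DUST algorithm
#'
#' @param seq Nucleotide string (`A,C,G,T,N`).
#' @param window Window size in bases.
#' @param threshold Score threshold (scaled by 10, as conventionally quoted;
#'   an interval must score strictly above `threshold/10`).
#' @return `data.frame` of merged masked intervals with 1-based inclusive
#'   `start` and `end` columns (zero rows when nothing is masked).
#' @export
dust_mask <- function(seq, window = 64L, threshold = 20L) {
  empty <- data.frame(start = integer(), end = integer())
  if (is.na(seq) || nchar(seq) == 0L) return(empty)
  seq <- toupper(seq)
  # split on N runs; each segment is dusted independently
  segs <- gregexpr("[ACGT]+", seq)[[1]]
  if (segs[1L] == -1L) return(empty)
  out <- list()
  for (i in seq_along(segs)) {
    off <- segs[i]
    seg <- substring(seq, off, off + attr(segs, "match.length")[i] - 1L)
    ir <- dust_segment(seg, window, threshold)
    if (!is.null(ir)) out[[length(out) + 1L]] <- IRanges::shift(ir, off - 1L)
  }
  if (!length(out)) return(empty)
  merged <- IRanges::reduce(do.call(c, out))
  data.frame(start = BiocGenerics::start(merged),
             end = BiocGenerics::end(merged))
}
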