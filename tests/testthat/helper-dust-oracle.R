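# Independent brute-force DUST oracle: interval scores computed from scratch
# with table(), perfectness checked by exhaustive subinterval enumeration.
# Only usable on short strings.
dust_oracle <- function(seq, window = 64L, threshold = 20L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  score_of <- function(i, j) {
    k <- j - i + 1L - 2L
    if (k < 2L) return(0)
    trips <- vapply(i:(j - 2L), function(s)
      paste(ch[s:(s + 2L)], collapse = ""), character(1))
    cts <- table(trips)
    sum(cts * (cts - 1) / 2) / (k - 1L)
  }
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:min(n, i + window - 1L))
    S[i, j] <- score_of(i, j)
  masked <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in i:min(n, i + window - 1L)) {
    s <- S[i, j]
    if (s <= threshold / 10) next
    sub_max <- 0
    for (i2 in i:j) for (j2 in i2:j)
      if (!(i2 == i && j2 == j)) sub_max <- max(sub_max, S[i2, j2])
    if (s >= sub_max) masked[i:j] <- TRUE
  }
  if (!any(masked)) return(data.frame(start = integer(), end = integer()))
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  data.frame(start = (ends - r$lengths + 1L)[r$values], end = ends[r$values])
}

mask_to_logical <- function(mask, n) {
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(mask))) out[mask$start[i]:mask$end[i]] <- TRUE
  out
}
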