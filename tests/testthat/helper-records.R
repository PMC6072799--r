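# Single-row alignment record builder for filter-level tests.
make_rec <- function(read_name = "r1", mate = 1L, unmapped = FALSE,
                     mate_unmapped = FALSE, proper = TRUE,
                     reverse = mate == 2L, mate_reverse = mate == 1L,
                     chrom = "chr1", pos = 1000L, mapq = 60L,
                     cigar = "151M", insert_size = 350L,
                     seq = strrep("A", 151L), qual = strrep("I", 151L),
                     clipped_segments = 0, clipped_bases = 0, indels = 0,
                     ref_span = 151, align_score = 0, mismatches = 0) {
  data.frame(read_name = read_name, mate = mate, flag = 0L,
             unmapped = unmapped, mate_unmapped = mate_unmapped,
             proper_flag = proper, reverse = reverse,
             mate_reverse = mate_reverse,
             chrom = if (unmapped) NA_character_ else chrom,
             pos = if (unmapped) NA_integer_ else pos,
             mapq = mapq, cigar = cigar, insert_size = insert_size,
             seq = seq, qual = qual, clipped_segments = clipped_segments,
             clipped_bases = clipped_bases, indels = indels,
             ref_span = ref_span, align_score = align_score,
             mismatches = mismatches, read_len = nchar(seq),
             stringsAsFactors = FALSE)
}

# FR-inward pair at the given positions/insert size.
make_pair <- function(read_name = "p1", pos1 = 1000L, isize = 350L, ...) {
  m1 <- make_rec(read_name, 1L, pos = pos1, insert_size = isize, ...)
  m2 <- make_rec(read_name, 2L, pos = pos1 + isize - 151L,
                 insert_size = -isize, ...)
  list(m1 = m1, m2 = m2)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
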