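test_that("unique bases use the union of repeat and low-complexity masks", {
  s <- rand_dna(100L)
  mk <- unique_bases(s, NULL,
                     data.frame(start = integer(), end = integer()))
  expect_equal(mk$unique_bases, 100L)

  feats <- data.frame(start = 1L, end = 30L, class = "SINE")
  dust <- data.frame(start = 21L, end = 60L)
  mk <- unique_bases(s, feats, dust)
  expect_equal(mk$unique_bases, 40L)       # union, not sum
  expect_equal(mk$interspersed_masked, 30L)
  expect_equal(mk$low_complexity_masked, 40L)

  expect_error(unique_bases(s, data.frame(start = 1L, end = 150L,
                                          class = "SINE"), dust),
               "outside sequence bounds")
})

test_that("known-reference screen needs full coverage at 95% identity", {
  set.seed(71)
  patch <- rand_dna(2000L)
  ext <- substring(patch, 501L, 900L)        # verbatim alt substring
  expect_false(filter_known_reference(ext, c(alt1 = patch)))

  # same length, ~6% diverged: kept
  ch <- strsplit(ext, "")[[1]]
  idx <- seq(1L, 400L, by = 17L)
  ch[idx] <- vapply(ch[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1L], character(1))
  expect_true(filter_known_reference(paste(ch, collapse = ""),
                                     c(alt1 = patch)))

  # full identity but only 99% coverage: kept
  ext99 <- paste0(substring(patch, 501L, 900L), rand_dna(5L))
  expect_true(filter_known_reference(ext99, c(alt1 = patch)))
  expect_true(filter_known_reference(ext, NULL))
})

test_that("translocation screen drops verbatim moved copies", {
  set.seed(72)
  ref <- c(chr1 = rand_dna(5000L), chr2 = rand_dna(5000L))
  moved <- substring(ref[["chr2"]], 2001L, 2400L)
  expect_false(filter_translocation(moved, ref))
  # a 10% novel centre defeats full-length coverage
  novel <- paste0(substring(moved, 1L, 180L), rand_dna(40L),
                  substring(moved, 221L))
  expect_true(filter_translocation(novel, ref))
  expect_true(filter_translocation(rand_dna(400L), ref))
})

test_that("blacklist filter drops calls whose breakpoints are indexed", {
  idx <- structure(list(ranges = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1000L, 2000L))), class = "blacklist_index")
  call <- data.frame(chrom = "chr1", ref_left = 1500L, ref_right = 1501L)
  expect_false(filter_blacklist(call, idx))
  call2 <- data.frame(chrom = "chr1", ref_left = 2500L, ref_right = 2501L)
  expect_true(filter_blacklist(call2, idx))
  # boundary: interval end is inclusive in 1-based closed coordinates
  call3 <- data.frame(chrom = "chr1", ref_left = 2000L, ref_right = 2001L)
  expect_false(filter_blacklist(call3, idx))
  call4 <- data.frame(chrom = "chr1", ref_left = 2001L, ref_right = 2002L)
  expect_true(filter_blacklist(call4, idx))
})

mk_call <- function(left, right, seq = strrep("A", 60L), uniq = 60,
                    zyg = "hap1", chrom = "chr1") {
  data.frame(chrom = chrom, ref_left = left, ref_right = right,
             ref_overlap = 0L, insert_len = nchar(seq), seq = seq,
             contig_name = "c", zygosity = zyg, unique_bases = uniq,
             stringsAsFactors = FALSE)
}

test_that("cross-sample merging honours the shared-breakpoint clauses", {
  # identical left breakpoint, right 300 apart: merged
  res <- merge_across_samples(list(s1 = mk_call(1000L, 1001L),
                                   s2 = mk_call(1000L, 1301L)))
  expect_equal(nrow(res$catalog), 1L)

  # identical right breakpoint, left 51 apart: merged regardless of left
  res <- merge_across_samples(list(s1 = mk_call(1000L, 1500L),
                                   s2 = mk_call(1051L, 1500L)))
  expect_equal(nrow(res$catalog), 1L)

  # both 51 apart and neither identical: two entries
  res <- merge_across_samples(list(s1 = mk_call(1000L, 1001L),
                                   s2 = mk_call(1051L, 1052L)))
  expect_equal(nrow(res$catalog), 2L)

  # both within 50 (inclusive): merged
  res <- merge_across_samples(list(s1 = mk_call(1000L, 1001L),
                                   s2 = mk_call(1050L, 1051L)))
  expect_equal(nrow(res$catalog), 1L)

  # same coordinates on different chromosomes stay apart
  res <- merge_across_samples(list(s1 = mk_call(1000L, 1001L),
                                   s2 = mk_call(1000L, 1001L,
                                                chrom = "chr2")))
  expect_equal(nrow(res$catalog), 2L)
})

test_that("merging is sample-order invariant with a deterministic representative", {
  set.seed(31)
  calls <- list(
    s1 = rbind(mk_call(1000L, 1001L, uniq = 55),
               mk_call(5000L, 5001L, uniq = 80)),
    s2 = rbind(mk_call(1010L, 1011L, uniq = 90, zyg = "homozygous"),
               mk_call(9000L, 9001L, uniq = 70)),
    s3 = mk_call(1040L, 1041L, uniq = 90))
  a <- merge_across_samples(calls)
  b <- merge_across_samples(calls[c(3L, 1L, 2L)])
  expect_equal(a$catalog, b$catalog)
  expect_equal(a$matrix, b$matrix)
  # representative: most unique bases, ties by smaller coordinate
  expect_equal(a$catalog$unique_bases[1L], 90)
  expect_equal(a$catalog$ref_left[1L], 1010L)
})

test_that("occurrence matrix recodes genotype 2 to 1 and sums match sharing", {
  calls <- list(
    s1 = mk_call(1000L, 1001L, zyg = "homozygous"),
    s2 = mk_call(1000L, 1001L, zyg = "hap2"),
    s3 = mk_call(7000L, 7001L, zyg = "hap1"))
  res <- merge_across_samples(calls)
  expect_equal(sort(unique(as.vector(res$raw_matrix))), c(0L, 1L, 2L))
  expect_true(all(res$matrix %in% c(0L, 1L)))
  expect_equal(unname(colSums(res$matrix)), c(2, 1))

  smry <- catalog_summary(res$catalog, res$matrix,
                          c(s1 = "AFR", s2 = "AFR", s3 = "EUR"))
  expect_equal(unname(smry$by_individuals[c("1", "2")]),
               c(1L, 1L), ignore_attr = TRUE)
  expect_error(catalog_summary(res$catalog, res$matrix, c(s1 = "AFR")),
               "population label")
})

test_that("empty inputs give empty catalog and all-zero summaries", {
  none <- mk_call(1L, 2L)[0L, ]
  res <- merge_across_samples(list(s1 = none, s2 = none))
  expect_equal(nrow(res$catalog), 0L)
  expect_equal(dim(res$matrix), c(2L, 0L))
})
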