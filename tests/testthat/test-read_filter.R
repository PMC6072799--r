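test_that("linked-read alignment score evaluates the penalty formula", {
  expect_equal(lariat_score(0, 0, 0, 0, 0), 0)
  expect_equal(lariat_score(40, 0, 0, 0, 0), -80)   # 40 mismatches alone
  expect_equal(lariat_score(1, 1, 1, 10, 1), -19)
  expect_error(lariat_score(-1), "non-negative")
  expect_error(lariat_score(1, improper_pair = 2), "improper_pair")
})

test_that("alignment score is monotone non-increasing in every argument", {
  base <- c(3, 1, 1, 12, 0)
  s0 <- do.call(lariat_score, as.list(base))
  for (k in 1:5) {
    up <- base
    up[k] <- up[k] + 1
    expect_lte(do.call(lariat_score, as.list(up)), s0)
  }
})

bounds <- c(200, 500)

test_that("stage-1 selection fires on each criterion at its boundary", {
  pr <- make_pair()
  v <- select_poorly_aligned(pr$m1, pr$m2, bounds)
  expect_false(v$selected)          # fully concordant pair
  expect_length(v$reasons, 0L)

  # clipping: strictly more than 40 bases
  pr$m1$clipped_bases <- 40
  expect_false(select_poorly_aligned(pr$m1, pr$m2, bounds)$selected)
  pr$m1$clipped_bases <- 41
  v <- select_poorly_aligned(pr$m1, pr$m2, bounds)
  expect_true(v$selected)
  expect_equal(v$reasons, "clipped")

  # alignment score: at or below -80
  pr <- make_pair()
  pr$m1$align_score <- -79.5
  expect_false(select_poorly_aligned(pr$m1, pr$m2, bounds)$selected)
  pr$m1$align_score <- -80
  expect_equal(select_poorly_aligned(pr$m1, pr$m2, bounds)$reasons, "low_AS")

  # unmapped mate carries the pair
  pr <- make_pair()
  pr$m2$unmapped <- TRUE
  pr$m2$chrom <- NA_character_
  expect_true("unmapped" %in%
                select_poorly_aligned(pr$m1, pr$m2, bounds)$reasons)

  # insert size outside the bounds
  pr <- make_pair(isize = 501L)
  expect_true("insert_size" %in%
                select_poorly_aligned(pr$m1, pr$m2, bounds)$reasons)
  pr <- make_pair(isize = 500L)
  expect_false(select_poorly_aligned(pr$m1, pr$m2, bounds)$selected)

  # orientation: FF is wrong
  pr <- make_pair()
  pr$m2$reverse <- FALSE
  pr$m1$mate_reverse <- FALSE
  expect_true("orientation" %in%
                select_poorly_aligned(pr$m1, pr$m2, bounds)$reasons)

  expect_error(select_poorly_aligned(make_rec("a"), make_rec("b", mate = 2L),
                                     bounds), "mismatched")
})

test_that("selection partitions pairs and reasons match the verdict", {
  set.seed(5)
  rec <- do.call(rbind, lapply(1:40, function(i) {
    pr <- make_pair(sprintf("p%02d", i),
                    isize = sample(c(150L, 350L, 700L), 1L))
    pr$m1$align_score <- sample(c(0, -50, -90), 1L)
    pr$m2$clipped_bases <- sample(c(0, 39, 60), 1L)
    rbind(pr$m1, pr$m2)
  }))
  sel <- select_pairs(rec, bounds)
  expect_equal(nrow(sel), 40L)
  expect_setequal(sel$selected, c(TRUE, FALSE))
  expect_true(all(sel$selected == (sel$reasons != "")))
  # agreement with the scalar rule
  for (i in seq_len(nrow(sel))) {
    pr <- rec[rec$read_name == sel$read_name[i], ]
    v <- select_poorly_aligned(pr[pr$mate == 1L, ], pr[pr$mate == 2L, ],
                               bounds)
    expect_equal(sel$selected[i], v$selected)
  }
})

test_that("barcode trimming shortens mate 1 by exactly 23 bases", {
  pr <- make_pair()
  tr <- trim_linked_read_artifacts(pr$m1, pr$m2)
  expect_equal(nchar(tr$m1$seq), 128L)
  expect_equal(nchar(tr$m1$qual), 128L)
  expect_equal(nchar(tr$m2$seq), 151L)
  expect_equal(tr$m1$seq, substring(pr$m1$seq, 24L))

  short <- make_rec("s", seq = strrep("A", 23L), qual = strrep("I", 23L))
  expect_warning(out <- trim_linked_read_artifacts(short, pr$m2), "dropped")
  expect_null(out)
})

test_that("quality filter removes the whole pair at the 70% boundary", {
  qual_of <- function(n_good, n) paste0(strrep("I", n_good),
                                        strrep("#", n - n_good))
  m1 <- make_rec("q", 1L, seq = strrep("A", 100L), qual = qual_of(69L, 100L))
  m2 <- make_rec("q", 2L, seq = strrep("A", 100L), qual = qual_of(100L, 100L))
  expect_false(quality_filter(m1, m2))     # 69% < 70%
  m1$qual <- qual_of(70L, 100L)
  m2$qual <- qual_of(70L, 100L)
  expect_true(quality_filter(m1, m2))      # exactly 70% passes
  m2$qual <- qual_of(50L, 100L)
  expect_false(quality_filter(m1, m2))     # one failing mate removes the pair
  m2$qual <- ""
  expect_false(quality_filter(m1, m2))
})

test_that("stringent re-acceptance requires every criterion at its boundary", {
  ok <- function(pr) accept_stringent_realignment(pr$m1, pr$m2, bounds)
  pr <- make_pair()
  pr$m1$align_score <- 90; pr$m2$align_score <- 113
  pr$m1$mapq <- 30L; pr$m2$mapq <- 30L
  expect_true(ok(pr))
  pr$m1$align_score <- 89
  expect_false(ok(pr))
  pr$m1$align_score <- 90; pr$m2$align_score <- 112
  expect_false(ok(pr))
  pr$m2$align_score <- 113; pr$m1$mapq <- 29L
  expect_false(ok(pr))
  pr$m1$mapq <- 30L; pr$m1$align_score <- NA_real_
  expect_false(ok(pr))                     # missing score fails
  pr <- make_pair(isize = 501L)
  pr$m1$align_score <- 90; pr$m2$align_score <- 113
  expect_false(ok(pr))                     # insert size out of bounds
})

test_that("reference-concordant pairs are discarded from haplotype streams", {
  hap <- do.call(rbind, lapply(c("c1", "c2", "c3"), function(nm) {
    pr <- make_pair(nm)
    rbind(pr$m1, pr$m2)
  }))
  ref <- hap
  ref$align_score <- ifelse(ref$read_name == "c2", 10, 120)
  ref$mapq <- 60L
  out <- discard_reference_concordant(hap, ref, bounds)
  expect_setequal(unique(out$read_name), "c2")   # only the poor ref pair stays
  expect_equal(discard_reference_concordant(hap[0, ], ref, bounds),
               hap[0, ])
})
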