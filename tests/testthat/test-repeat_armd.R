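feat <- function(start, end, family = "AluY", class = "SINE",
                 chrom = "chr1", cons_start = 1L, cons_end = 312L,
                 strand = "+", score = 1000) {
  data.frame(score = score, divergence = 3, query = chrom, start = start,
             end = end, strand = strand, family = family, class = class,
             cons_start = cons_start, cons_end = cons_end,
             stringsAsFactors = FALSE)
}

test_that("major TE is the class masking the most bases", {
  feats <- rbind(feat(1L, 60L, class = "SINE"),
                 feat(70L, 99L, family = "L1", class = "LINE"))
  expect_equal(major_te(feats), "SINE")
  expect_equal(major_te(NULL), "NONE")
  expect_equal(major_te(feat(1L, 20L, family = "AT_rich",
                             class = "Low_complexity")), "NONE")

  # exact tie resolves to the class whose feature starts first, stably
  tie <- rbind(feat(10L, 39L, class = "SINE"),
               feat(50L, 79L, family = "L1", class = "LINE"))
  expect_equal(major_te(tie), "SINE")
  expect_equal(major_te(tie[2:1, ]), "SINE")
})

test_that("flank classification needs the TE to contain the breakpoint", {
  call <- data.frame(chrom = "chr1", ref_left = 1000L, ref_right = 1001L)
  ann <- rbind(feat(900L, 1100L),                       # contains both
               feat(5000L, 5300L, family = "L1", class = "LINE"))
  fc <- classify_flanks(call, ann)
  expect_equal(fc$category, "Alu/Alu")

  # left in an Alu, right outside any TE: OtherTE
  ann2 <- feat(900L, 1000L)
  fc <- classify_flanks(call, ann2)
  expect_equal(fc$left_family, "AluY")
  expect_true(is.na(fc$right_family))
  expect_equal(fc$category, "OtherTE")

  # neither breakpoint inside a TE
  fc <- classify_flanks(call, feat(5000L, 5300L))
  expect_equal(fc$category, "NonTE")

  # Alu/LINE is symmetric
  ann3 <- rbind(feat(900L, 1000L),
                feat(1001L, 1400L, family = "L1", class = "LINE"))
  expect_equal(classify_flanks(call, ann3)$category, "Alu/LINE")
  call_sw <- data.frame(chrom = "chr1", ref_left = 1400L, ref_right = 950L)
  ann4 <- rbind(feat(900L, 1000L),
                feat(1001L, 1500L, family = "L1", class = "LINE"))
  expect_equal(classify_flanks(call_sw, ann4)$category, "Alu/LINE")

  # LINE/LINE; low-complexity flanks count as non-TE
  ann5 <- feat(900L, 1100L, family = "L1", class = "LINE")
  expect_equal(classify_flanks(call, ann5)$category, "LINE/LINE")
  ann6 <- feat(900L, 1100L, family = "AT_rich", class = "Low_complexity")
  expect_equal(classify_flanks(call, ann6)$category, "NonTE")

  # invariant to annotation row order
  annr <- rbind(feat(5000L, 5300L), feat(900L, 1100L))
  expect_equal(classify_flanks(call, annr)$category, "Alu/Alu")
})

test_that("homologous overlap applies the 10 bp floor", {
  expect_equal(homologous_overlap(c(10L, 9L, 0L, 25L)), c(10L, 0L, 0L, 25L))
})

test_that("ARMD candidates require Alu/Alu flanks, overlap and a chimera", {
  cat_row <- function(id, left, right, overlap)
    data.frame(id = id, chrom = "chr1", ref_left = left, ref_right = right,
               ref_overlap = overlap, stringsAsFactors = FALSE)
  chimera <- feat(1000L, 1311L)          # one Alu containing both breakpoints

  cands <- armd_candidates(cat_row("n1", 1150L, 1126L, 25L), chimera)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$overlap, 25L)
  # consensus position of the left breakpoint within the chimera
  expect_equal(cands$consensus_bp, 1L + (1150L - 1000L))

  expect_equal(nrow(armd_candidates(cat_row("n2", 1150L, 1151L, 0L),
                                    chimera)), 0L)
  line <- feat(1000L, 1311L, family = "L1", class = "LINE")
  expect_equal(nrow(armd_candidates(cat_row("n3", 1150L, 1126L, 25L),
                                    line)), 0L)
  # overlap below the floor
  expect_equal(nrow(armd_candidates(cat_row("n4", 1150L, 1142L, 9L),
                                    chimera)), 0L)
})

test_that("breakpoint frequency spreads unit mass over the range", {
  cands <- data.frame(consensus_bp = 100L, overlap = 1L)
  f <- breakpoint_frequency(cands)
  expect_equal(f[100L], 1)
  expect_equal(sum(f), 1)

  cands <- data.frame(consensus_bp = 100L, overlap = 10L)
  f <- breakpoint_frequency(cands)
  expect_equal(f[91:100], rep(0.1, 10L))
  expect_equal(sum(f[-(91:100)]), 0)

  # conservation against a brute-force sum over many candidates
  set.seed(41)
  cands <- data.frame(consensus_bp = sample(50:300, 25L, TRUE),
                      overlap = sample(1:40, 25L, TRUE))
  f <- breakpoint_frequency(cands)
  expect_equal(sum(f), 25, tolerance = 1e-9)
  brute <- numeric(312L)
  for (i in 1:25) {
    rng <- (cands$consensus_bp[i] - cands$overlap[i] + 1L):cands$consensus_bp[i]
    brute[rng] <- brute[rng] + 1 / length(rng)
  }
  expect_equal(f, brute)

  # ranges clipped at the consensus edge renormalise and warn
  expect_warning(f <- breakpoint_frequency(
    data.frame(consensus_bp = 5L, overlap = 10L)), "clipped")
  expect_equal(sum(f), 1)
  expect_equal(f[1:5], rep(0.2, 5L))
})

test_that("hotspots are mean-exceedance runs of minimum width", {
  expect_equal(nrow(hotspot_intervals(rep(1, 312L))), 0L)

  f <- rep(0.1, 312L)
  f[12:52] <- 2
  h <- hotspot_intervals(f)
  expect_equal(h$start, 12L)
  expect_equal(h$end, 52L)

  f[156:205] <- 3
  h <- hotspot_intervals(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$start, c(12L, 156L))
  expect_equal(h$end, c(52L, 205L))

  # runs shorter than the minimum width are discarded
  g <- rep(0.1, 312L)
  g[100:105] <- 5
  expect_equal(nrow(hotspot_intervals(g)), 0L)
  expect_equal(nrow(hotspot_intervals(g, min_run = 5L)), 1L)
})
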