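small_cfg <- function(...) {
  cfg <- sim_config(seed = 19, n_samples = 2L,
                    pop_sizes = c(AFR = 1L, EUR = 1L),
                    n_chroms = 2L, chrom_len = 60000L, n_insertions = 2L,
                    coverage_depth = 30)
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg
}

test_that("simulation is a pure function of the configuration", {
  a <- sim_cohort(small_cfg())
  b <- sim_cohort(small_cfg())
  expect_identical(a$reference, b$reference)
  expect_identical(a$events, b$events)
  expect_identical(a$donors, b$donors)
  expect_identical(emit_sample_alignments(a, a$samples[1]),
                   emit_sample_alignments(b, b$samples[1]))
  cfg2 <- small_cfg()
  cfg2$seed <- 20L
  c <- sim_cohort(cfg2)
  expect_false(identical(a$reference, c$reference))
})

test_that("planted repeat copies match their consensus at 95%+ identity", {
  sim <- sim_cohort(small_cfg())
  cons <- setNames(sim$library$seq, sim$library$class)
  for (i in seq_len(nrow(sim$repeats))) {
    f <- sim$repeats[i, ]
    planted <- substring(sim$reference[[f$query]], f$start, f$end)
    model <- substring(cons[[f$class]], f$cons_start, f$cons_end)
    expect_equal(nchar(planted), nchar(model))
    ident <- mean(strsplit(planted, "")[[1]] == strsplit(model, "")[[1]])
    expect_gte(ident, 0.95)
  }
})

test_that("donor haplotypes carry the planted insertions verbatim", {
  sim <- sim_cohort(small_cfg())
  ev <- sim$events
  for (s in sim$samples) for (h in 1:2) {
    present <- which(sim$hap_code[s, ] == h | sim$hap_code[s, ] == 3L)
    for (j in present) {
      donor <- sim$donors[[s]][[h]][[ev$chrom[j]]]
      q <- sim$donor_q[s, j]
      expect_true(grepl(ev$seq[j], donor, fixed = TRUE))
      # the insertion sits immediately after the reference prefix ending at q
      prefix_tail <- substring(sim$reference[[ev$chrom[j]]], q - 20L, q)
      expect_true(grepl(paste0(prefix_tail, substring(ev$seq[j], 1L, 20L)),
                        donor, fixed = TRUE))
    }
    absent <- which(sim$hap_code[s, ] %in% c(0L, 3L - h) &
                      nchar(ev$seq) > 60L)
    for (j in absent)
      expect_false(grepl(ev$seq[j], sim$donors[[s]][[h]][[ev$chrom[j]]],
                         fixed = TRUE))
  }
})

test_that("ARMD events reduce to one chimeric Alu annotation on the reference", {
  cfg <- small_cfg(n_insertions = 4L, armd_fraction = 0.5,
                   chrom_len = 80000L)
  sim <- sim_cohort(cfg)
  armd <- sim$events[sim$events$is_armd, ]
  expect_gt(nrow(armd), 0L)
  for (i in seq_len(nrow(armd))) {
    hit <- sim$repeats[sim$repeats$query == armd$chrom[i] &
                         sim$repeats$start <= armd$truth_left[i] &
                         sim$repeats$end >= armd$truth_left[i], ]
    expect_equal(nrow(hit), 1L)
    expect_true(startsWith(hit$family, "Alu"))
    # both breakpoints sit inside the same chimera feature
    expect_true(hit$start <= armd$truth_right[i] &&
                  hit$end >= armd$truth_right[i])
    # the inserted sequence ends with the homologous reference bases
    hom <- substring(sim$reference[[armd$chrom[i]]],
                     armd$truth_left[i] - armd$homology[i] + 1L,
                     armd$truth_left[i])
    expect_equal(substring(armd$seq[i], nchar(armd$seq[i]) -
                             armd$homology[i] + 1L), hom)
  }
})

test_that("emitted reference alignments show the insertion signatures", {
  sim <- sim_cohort(small_cfg())
  s <- sim$samples[1]
  aln <- emit_sample_alignments(sim, s)
  lr <- aln$lr_ref

  carried <- which(sim$carriers[s, ] > 0L & nchar(sim$events$seq) > 300L)
  expect_gt(length(carried), 0L)
  # reads fully inside a long insertion are unmapped on the reference
  expect_gt(sum(lr$unmapped), 0L)
  # mapped mates of unmapped reads pile up near event loci
  solo_mapped <- lr[!lr$unmapped & lr$mate_unmapped, ]
  ev <- sim$events
  near_event <- vapply(seq_len(nrow(solo_mapped)), function(i)
    any(ev$chrom == solo_mapped$chrom[i] &
          abs(ev$q - solo_mapped$pos[i]) < 1000L), logical(1))
  expect_true(all(near_event))
  # clipped reads never clip more than the read length
  expect_true(all(lr$clipped_bases <= lr$read_len))
  # a perfect proper pair scores 0 under the linked-read model
  perfect <- lr[!lr$unmapped & lr$proper_flag & lr$clipped_bases == 0 &
                  lr$mismatches == 0, ]
  expect_true(all(perfect$align_score == 0))

  # coverage near the configured depth away from any event
  chr <- sim$chroms[1]
  ev_chr <- ev$q[ev$chrom == chr]
  win_start <- Filter(function(x) all(abs(ev_chr - x) > 2500L) &&
                        all(abs(ev_chr - (x + 6000L)) > 2500L),
                      seq(3000L, nchar(sim$reference[[chr]]) - 9500L,
                          by = 500L))[[1L]]
  win <- win_start:(win_start + 6000L)
  depth <- per_base_coverage(lr[!lr$unmapped & lr$chrom == chr, ], chr,
                             nchar(sim$reference[[chr]]))
  expect_lt(abs(mean(depth[win]) - sim$config$coverage_depth) /
              sim$config$coverage_depth, 0.2)
})

test_that("simulation files round-trip through the standard formats", {
  cfg <- small_cfg()
  sim <- sim_cohort(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, samples = sim$samples[1])
  ref <- read_fasta(file.path(dir, "ref.fa"))
  expect_equal(setNames(as.character(ref), names(ref))[names(sim$reference)],
               sim$reference)
  feats <- read_repeat_table(file.path(dir, "repeats.out"))
  expect_equal(nrow(feats), nrow(sim$repeats))
  expect_equal(feats$start, sim$repeats$start)
  s <- sim$samples[1]
  back <- read_alignments(file.path(dir, sprintf("%s_lr_ref.sam", s)))
  aln <- emit_sample_alignments(sim, s)
  expect_equal(nrow(back), nrow(aln$lr_ref))
  ord <- order(back$read_name, back$mate)
  ord2 <- order(aln$lr_ref$read_name, aln$lr_ref$mate)
  expect_equal(back$pos[ord], aln$lr_ref$pos[ord2])
  expect_equal(back$clipped_bases[ord], aln$lr_ref$clipped_bases[ord2])
  expect_equal(back$align_score[ord], aln$lr_ref$align_score[ord2])
})
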