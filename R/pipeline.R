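# Per-sample discovery orchestration and cohort-level merging/annotation.

#' Pipeline configuration with every threshold surfaced
#'
#' Defaults are the discovery pipeline's operating points: extraction at
#' alignment score <= -80 or > 40 clipped bases, 70% of bases at Q30,
#' stringent re-acceptance at scores 90/113 and mapping quality 30, cluster
#' coverage 8..100 with 7 kb anchors merged under 200 bp gaps and at most
#' 10 N bases, anchor selection at 3500 bp beyond 5 loci, breakpoint calls
#' within 800 bp reference overlap and at least 50 bp inserted, haplotype
#' merging under 10 bp, 50 unique bases after masking, 95% identity screens,
#' cross-sample merging within 50 bp, and optical validation of >2 kb calls
#' with 10 kb exclusion radii.
#'
#' @param ... Overrides.
#' @return Named list of thresholds.
#' @export
nui_config <- function(...) {
  cfg <- list(
    as_drop = -80, max_clip = 40L, trim_len = 23L,
    q_threshold = 30L, q_frac = 0.70,
    min_as1 = 90, min_as2 = 113, min_mapq = 30L,
    cov_lo = 8L, cov_hi = 100L,
    extension = 7000L, merge_gap = 200L, max_n = 10L,
    seed_len = 32L, min_len_if_multi = 3500L, max_loci = 5L,
    max_overlap = 800L, min_insert = 50L,
    hap_tol = 10L, min_unique = 50L,
    known_ref_flank = 50L, known_ref_id = 0.95,
    transloc_id = 0.95, contam_id = 0.90, contam_cov = 0.90,
    merge_tol = 50L,
    dust_window = 64L, dust_threshold = 20L
  )
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg
}

# trim + quality filtering of selected pairs; returns surviving read names
trim_and_quality_filter <- function(rec, names, cfg) {
  keep <- character(0)
  idx <- split(seq_len(nrow(rec)), rec$read_name)
  for (nm in names) {
    rows <- idx[[nm]]
    if (is.null(rows) || length(rows) != 2L) next
    pr <- rec[rows, ]
    m1 <- pr[pr$mate == 1L, ][1, ]
    m2 <- pr[pr$mate == 2L, ][1, ]
    tr <- withCallingHandlers(
      trim_linked_read_artifacts(m1, m2, cfg$trim_len),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(tr)) next
    if (quality_filter(tr$m1, tr$m2, cfg$q_threshold, cfg$q_frac))
      keep <- c(keep, nm)
  }
  keep
}

#' Run per-sample NUI discovery
#'
#' Executes the discovery stages for one sample: stage-1 extraction from the
#' reference alignment, barcode trimming and base-quality filtering,
#' discarding of reference-concordant pairs, stringent haplotype
#' re-acceptance, cluster detection and anchored-contig extraction on each
#' pseudo-haplotype, breakpoint calling against the reference, haplotype
#' unification, and the NUI definition filters. The repeat annotation of
#' inserted sequences is supplied as a function (annotation is input to the
#' pipeline, not computed by it).
#'
#' @param lr_ref Reference alignment table (linked-read scores, untrimmed).
#' @param bwa_ref Reference realignment table (trimmed mate 1, aligner
#'   scores comparable to the stringent thresholds).
#' @param hap_recs List of two alignment tables against the
#'   pseudo-haplotypes.
#' @param hap_seqs List of two named character vectors of haplotype contigs.
#' @param reference Core reference collection.
#' @param alt_patches Alt/patch collection (may be empty).
#' @param blacklist A `blacklist_index`.
#' @param repeat_annotator `function(seq) -> repeat feature table` on insert
#'   coordinates.
#' @param contaminants Contaminant collection (default empty).
#' @param cfg Thresholds from [nui_config()].
#' @return List with `calls` (filtered per-sample NUI table) and `manifest`
#'   (per-stage record counts).
#' @export
run_sample <- function(lr_ref, bwa_ref, hap_recs, hap_seqs, reference,
                       alt_patches = NULL, blacklist = NULL,
                       repeat_annotator = function(seq) empty_repeat_features(),
                       contaminants = NULL, cfg = nui_config()) {
  reference <- seq_chars(reference)
  manifest <- list(n_pairs = length(unique(lr_ref$read_name)))

  bounds <- estimate_insert_bounds(lr_ref)
  sel <- select_pairs(lr_ref, bounds, cfg$as_drop, cfg$max_clip)
  selected <- sel$read_name[sel$selected]
  manifest$n_selected <- length(selected)

  kept <- trim_and_quality_filter(lr_ref, selected, cfg)
  manifest$n_after_quality <- length(kept)

  bwa_bounds <- estimate_insert_bounds(bwa_ref)
  calls_by_hap <- lapply(1:2, function(h) {
    recs <- hap_recs[[h]]
    recs <- recs[recs$read_name %in% kept, , drop = FALSE]
    bwa_sub <- bwa_ref[bwa_ref$read_name %in% kept, , drop = FALSE]
    recs <- discard_reference_concordant(recs, bwa_sub, bwa_bounds)
    hb <- estimate_insert_bounds(hap_recs[[h]], fallback = bwa_bounds)
    acc <- accepted_pair_names(recs, hb, cfg$min_as1, cfg$min_as2,
                               cfg$min_mapq)
    acc_recs <- recs[recs$read_name %in% acc, , drop = FALSE]
    contigs <- do.call(rbind, lapply(names(hap_seqs[[h]]), function(ctg) {
      depth <- per_base_coverage(acc_recs, ctg, nchar(hap_seqs[[h]][[ctg]]))
      cl <- find_clusters(depth, cfg$cov_lo, cfg$cov_hi)
      extract_anchored_contigs(cl, hap_seqs[[h]][[ctg]], ctg,
                               cfg$merge_gap, cfg$extension, cfg$max_n)
    }))
    if (is.null(contigs) || !nrow(contigs)) return(empty_calls())
    contig_breakpoints(contigs, reference, cfg$seed_len, cfg$max_overlap,
                       cfg$min_insert, cfg$min_len_if_multi, cfg$max_loci)
  })
  manifest$n_calls_hap1 <- nrow(calls_by_hap[[1]])
  manifest$n_calls_hap2 <- nrow(calls_by_hap[[2]])

  merged <- merge_haplotype_calls(calls_by_hap[[1]], calls_by_hap[[2]],
                                  cfg$hap_tol)
  manifest$n_unified <- nrow(merged)

  # ----- NUI definition filters -----------------------------------------
  keep <- logical(nrow(merged))
  merged$unique_bases <- rep(NA_real_, nrow(merged))
  merged$major_te <- rep(NA_character_, nrow(merged))
  for (i in seq_len(nrow(merged))) {
    s <- merged$seq[i]
    feats <- repeat_annotator(s)
    dust <- dust_mask(s, cfg$dust_window, cfg$dust_threshold)
    mk <- unique_bases(s, feats, dust)
    merged$unique_bases[i] <- mk$unique_bases
    merged$major_te[i] <- major_te(feats)
    if (mk$unique_bases < cfg$min_unique) next
    ch <- merged$chrom[i]
    fl <- substring(reference[[ch]],
                    max(1L, merged$ref_right[i] - cfg$known_ref_flank),
                    merged$ref_right[i] - 1L)
    fr <- substring(reference[[ch]], merged$ref_left[i] + 1L,
                    min(nchar(reference[[ch]]),
                        merged$ref_left[i] + cfg$known_ref_flank))
    ext <- paste0(fl, s, fr)
    if (!filter_known_reference(ext, alt_patches, cfg$known_ref_id)) next
    if (!filter_translocation(s, reference, cfg$transloc_id)) next
    if (!is.null(blacklist) && !filter_blacklist(merged[i, ], blacklist)) next
    if (!filter_contaminants(s, contaminants, cfg$contam_id,
                             cfg$contam_cov)) next
    keep[i] <- TRUE
  }
  calls <- merged[keep, , drop = FALSE]
  rownames(calls) <- NULL
  manifest$n_defined <- nrow(calls)
  list(calls = calls, manifest = manifest)
}

#' Run per-sample discovery directly on a simulated cohort
#'
#' Convenience wrapper wiring [emit_sample_alignments()] output and the
#' simulator's fixtures into [run_sample()].
#'
#' @param sim A `nui_simulation`.
#' @param sample Sample name.
#' @param cfg Thresholds from [nui_config()].
#' @return As [run_sample()].
#' @export
run_sample_sim <- function(sim, sample, cfg = nui_config()) {
  aln <- emit_sample_alignments(sim, sample)
  run_sample(aln$lr_ref, aln$bwa_ref,
             hap_recs = list(aln$hap1, aln$hap2),
             hap_seqs = sim$donors[[sample]],
             reference = sim$reference,
             alt_patches = sim$alt_patches,
             blacklist = sim$blacklist,
             repeat_annotator = function(s) annotate_repeats(s, sim$library),
             cfg = cfg)
}

#' Merge per-sample call sets into the cohort catalog
#'
#' @param per_sample_calls Named list of per-sample call tables (duplicate
#'   sample names are an error).
#' @param populations Named character vector mapping sample to population
#'   (optional; enables the summary).
#' @param tol Cross-sample breakpoint merge tolerance.
#' @return List with `catalog`, `matrix`, `raw_matrix` and (when populations
#'   are given) `summary`.
#' @export
run_cohort <- function(per_sample_calls, populations = NULL, tol = 50L) {
  if (anyDuplicated(names(per_sample_calls)))
    stop("duplicate sample ids")
  res <- merge_across_samples(per_sample_calls, tol)
  if (!is.null(populations) && nrow(res$catalog))
    res$summary <- catalog_summary(res$catalog, res$matrix, populations)
  res
}

#' Annotate a cohort catalog against the orthogonal fixtures
#'
#' Runs the primate-presence, EST, RNA-seq and external-overlap screens over
#' every catalog entry.
#'
#' @param catalog Catalog table.
#' @param reference Core reference collection.
#' @param primates Named list of primate genome collections.
#' @param est_db EST collection (or `NULL`).
#' @param rna_pairs Named list of RNA pair tables keyed by
#'   `"chrom:ref_left"` (or `NULL`).
#' @param external_contigs External contig collection (or `NULL`).
#' @param flank Reference flank added for the primate screen (bp).
#' @return `data.frame` keyed by catalog id with one logical column per
#'   screen plus `primate_union` and `transcribed`.
#' @export
annotate_cohort <- function(catalog, reference, primates = NULL,
                            est_db = NULL, rna_pairs = NULL,
                            external_contigs = NULL, flank = 50L) {
  reference <- seq_chars(reference)
  n <- nrow(catalog)
  ann <- data.frame(id = catalog$id, stringsAsFactors = FALSE)
  ext_seq <- vapply(seq_len(n), function(i) {
    ch <- catalog$chrom[i]
    paste0(substring(reference[[ch]],
                     max(1L, catalog$ref_right[i] - flank),
                     catalog$ref_right[i] - 1L),
           catalog$seq[i],
           substring(reference[[ch]], catalog$ref_left[i] + 1L,
                     catalog$ref_left[i] + flank))
  }, character(1))
  if (!is.null(primates)) {
    for (pr in names(primates))
      ann[[pr]] <- vapply(ext_seq, primate_presence, logical(1),
                          primate_genome = primates[[pr]], USE.NAMES = FALSE)
    ann$primate_union <- ancestral_union(ann[names(primates)])$union
  }
  if (!is.null(est_db))
    ann$est <- vapply(catalog$seq, est_transcription, logical(1),
                      est_db = est_db, reference = reference,
                      USE.NAMES = FALSE)
  if (!is.null(rna_pairs))
    ann$rnaseq <- vapply(seq_len(n), function(i) {
      key <- sprintf("%s:%d", catalog$chrom[i], catalog$ref_left[i])
      rnaseq_transcription(rna_pairs[[key]], nchar(catalog$seq[i]))
    }, logical(1))
  if (!is.null(ann$est) && !is.null(ann$rnaseq))
    ann$transcribed <- ann$est | ann$rnaseq
  if (!is.null(external_contigs)) {
    shared <- reciprocal_overlap(setNames(catalog$seq, catalog$id),
                                 external_contigs)
    ann$shared_external <- ann$id %in% shared
  }
  ann
}
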