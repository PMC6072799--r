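# Synthetic cohort generator with full ground truth.
#
# Every planted event is represented as a point insertion: a reference
# position q and an inserted string S placed between q and q+1 on carrier
# haplotypes. An ARMD (Alu-recombination-mediated deletion) pre-deletion
# allele fits this representation exactly: the reference carries a single
# chimeric Alu and S = alu_tail + interstitial + alu_head + homology, whose
# suffix repeats the w reference bases immediately left of the junction, so
# the homologous reference overlap of the two anchors emerges from sequence
# content alone. Events are spaced far enough apart that extended anchors of
# different events never merge and a read or fragment overlaps at most one
# event.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n_mut <- rbinom(1L, length(ch), rate)
  if (n_mut > 0L) {
    idx <- sample.int(length(ch), n_mut)
    ch[idx] <- vapply(ch[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# force position i of string s to differ from base `avoid`
force_diff <- function(s, i, avoid) {
  if (substring(s, i, i) != avoid) return(s)
  repl <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  paste0(substring(s, 1L, i - 1L), repl, substring(s, i + 1L))
}

#' Default simulation configuration
#'
#' The cohort layout mirrors the study conditions: 17 individuals from five
#' super-populations (5 AFR, 3 AMR, 4 EAS, 3 EUR, 2 SAS), 60x total read
#' coverage of 151 bp pairs with ~350 +/- 50 bp insert sizes, and a 14%
#' ARMD fraction among planted insertions. Genome size and insertion count
#' are desk-scale choices; events are spaced so that 7 kb anchor extensions
#' of neighbouring events cannot merge.
#'
#' @param ... Overrides for any configuration entry.
#' @return Named list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chroms = 2L,
    chrom_len = 150000L,
    n_samples = 17L,
    pop_sizes = c(AFR = 5L, AMR = 3L, EAS = 4L, EUR = 3L, SAS = 2L),
    n_insertions = 12L,
    insertion_len_range = c(100L, 3000L),
    armd_fraction = 0.14,
    homology_len_range = c(10L, 40L),
    interstitial_len_range = c(300L, 1500L),
    te_insert_fraction = 0.3,
    repeat_density = 0.05,
    repeat_divergence = 0.015,
    read_len = 151L,
    coverage_depth = 60,
    insert_size_mean = 350,
    insert_size_sd = 50,
    breakpoint_jitter = 0L,
    error_rate = 0.001,
    bad_pair_fraction = 0.01,
    transcribed_fraction = 0.35,
    ancestral_fraction = 0.64,
    primate_presence = c(chimp = 0.90, gorilla = 0.87, bonobo = 0.78,
                         orangutan = 0.42),
    primate_divergence = 0.005,
    external_fraction = 0.5,
    n_translocation_decoys = 1L,
    n_lowcomplex_decoys = 1L,
    n_blacklist_decoys = 1L,
    n_alt_patch_decoys = 1L,
    event_spacing = 16500L,
    event_margin = 9000L,
    alu_len = 312L,
    line_len = 1200L
  )
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg
}

sample_names <- function(cfg) {
  unlist(lapply(names(cfg$pop_sizes), function(p)
    sprintf("%s_%d", p, seq_len(cfg$pop_sizes[[p]]))))
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds the reference (with planted Alu-like and LINE-like repeat copies
#' and chimeric Alus at ARMD loci), the event set (clean insertions, ARMD
#' pre-deletion alleles, and decoys designed to be removed by the definition
#' filters), population-structured carrier assignments, per-sample diploid
#' donor haplotypes, and every orthogonal fixture (alt patches, blacklist,
#' primate genomes, EST and RNA evidence, optical calls, external contigs).
#' All output is a pure function of the configuration (including its seed).
#'
#' @param cfg Configuration from [sim_config()].
#' @return A list of class `nui_simulation`.
#' @export
sim_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  samples <- sample_names(cfg)
  stopifnot(length(samples) == cfg$n_samples)
  populations <- setNames(rep(names(cfg$pop_sizes), cfg$pop_sizes), samples)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))

  alu_cons <- rand_seq(cfg$alu_len)
  line_cons <- rand_seq(cfg$line_len)
  library_df <- data.frame(
    name = c("AluCons", "L1Cons"),
    seq = c(alu_cons, line_cons),
    family = c("AluY", "L1"),
    class = c("SINE", "LINE"),
    stringsAsFactors = FALSE)

  n_armd <- max(0L, round(cfg$armd_fraction * cfg$n_insertions))
  n_clean <- cfg$n_insertions - n_armd
  decoy_types <- c(rep("translocation", cfg$n_translocation_decoys),
                   rep("lowcomplex", cfg$n_lowcomplex_decoys),
                   rep("blacklist", cfg$n_blacklist_decoys),
                   rep("alt_patch", cfg$n_alt_patch_decoys))
  n_events <- cfg$n_insertions + length(decoy_types)

  # --- event slots on a coarse grid -------------------------------------
  slots <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(cfg$event_margin, cfg$chrom_len - cfg$event_margin,
               by = cfg$event_spacing)
    data.frame(chrom = ch, base_pos = pos, stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n_events)
    stop("genome too small for ", n_events, " events at the configured spacing")
  slots <- slots[sample.int(nrow(slots), n_events), , drop = FALSE]
  slots$base_pos <- slots$base_pos +
    sample(-1500L:1500L, n_events, replace = TRUE)

  event_kind <- c(rep("armd", n_armd), rep("clean", n_clean), decoy_types)
  event_kind <- sample(event_kind)   # shuffle kinds over slots

  # --- reference assembly ------------------------------------------------
  base <- setNames(vapply(chroms, function(ch) rand_seq(cfg$chrom_len),
                          character(1)), chroms)

  # background repeat copies (positions in base coordinates)
  n_bg_per_chrom <- round(cfg$repeat_density * cfg$chrom_len / 330)
  elements <- list()   # splice list: chrom, base_pos, seq, annot fields
  for (ch in chroms) {
    taken <- slots$base_pos[slots$chrom == ch]
    placed <- 0L; tries <- 0L
    while (placed < n_bg_per_chrom && tries < 200L * n_bg_per_chrom) {
      tries <- tries + 1L
      pos <- sample.int(cfg$chrom_len - 2000L, 1L) + 1000L
      if (any(abs(pos - taken) < 2500L)) next
      taken <- c(taken, pos)
      placed <- placed + 1L
      if (runif(1) < 0.75) {
        cs <- sample.int(cfg$alu_len - 80L, 1L)
        ce <- if (runif(1) < 0.7) cfg$alu_len else
          min(cfg$alu_len, cs + 80L + sample.int(cfg$alu_len, 1L))
        if (runif(1) < 0.7) cs <- 1L
        fam <- sample(c("AluSx", "AluY"), 1L)
        cons <- alu_cons; cls <- "SINE"
      } else {
        cs <- sample.int(cfg$line_len - 300L, 1L)
        ce <- min(cfg$line_len, cs + 300L + sample.int(cfg$line_len, 1L))
        fam <- "L1"; cons <- line_cons; cls <- "LINE"
      }
      copy <- mutate_seq(substring(cons, cs, ce), cfg$repeat_divergence)
      elements[[length(elements) + 1L]] <- list(
        chrom = ch, base_pos = pos, seq = copy, family = fam, class = cls,
        cons_start = cs, cons_end = ce, event = NA_integer_)
    }
  }

  # ARMD chimeras are reference elements; remember p (consensus breakpoint)
  # and w (homology) per event
  ev_p <- integer(n_events); ev_w <- integer(n_events)
  ev_chimera <- character(n_events)
  for (i in which(event_kind == "armd")) {
    w <- sample(cfg$homology_len_range[1]:cfg$homology_len_range[2], 1L)
    p <- sample((w + 15L):(cfg$alu_len - 15L), 1L)
    chimera <- mutate_seq(alu_cons, cfg$repeat_divergence)
    ev_p[i] <- p; ev_w[i] <- w; ev_chimera[i] <- chimera
    elements[[length(elements) + 1L]] <- list(
      chrom = slots$chrom[i], base_pos = slots$base_pos[i], seq = chimera,
      family = "AluY", class = "SINE", cons_start = 1L,
      cons_end = cfg$alu_len, event = i)
  }

  reference <- character(0)
  repeats <- list()
  ev_q <- integer(n_events)        # final ref coordinate of insertion point
  for (ch in chroms) {
    els <- Filter(function(e) e$chrom == ch, elements)
    ord <- order(vapply(els, `[[`, numeric(1), "base_pos"))
    els <- els[ord]
    pieces <- character(0)
    cursor <- 0L; grown <- 0L
    for (e in els) {
      pieces <- c(pieces, substring(base[[ch]], cursor + 1L, e$base_pos), e$seq)
      start_final <- e$base_pos + grown + 1L
      end_final <- start_final + nchar(e$seq) - 1L
      repeats[[length(repeats) + 1L]] <- data.frame(
        score = 1000, divergence = cfg$repeat_divergence * 100,
        query = ch, start = start_final, end = end_final, strand = "+",
        family = e$family, class = e$class, cons_start = e$cons_start,
        cons_end = e$cons_end, stringsAsFactors = FALSE)
      if (!is.na(e$event))
        ev_q[e$event] <- start_final + ev_p[e$event] - 1L
      cursor <- e$base_pos
      grown <- grown + nchar(e$seq)
    }
    pieces <- c(pieces, substring(base[[ch]], cursor + 1L, cfg$chrom_len))
    reference[[ch]] <- paste(pieces, collapse = "")
    # clean/decoy event points: map base positions through the splices
    for (i in which(slots$chrom == ch & event_kind != "armd")) {
      grown_before <- sum(vapply(els, function(e)
        if (e$base_pos < slots$base_pos[i]) nchar(e$seq) else 0L, numeric(1)))
      ev_q[i] <- slots$base_pos[i] + grown_before
    }
  }
  repeats <- do.call(rbind, repeats)

  # --- inserted strings and truth ---------------------------------------
  events <- data.frame(
    id = sprintf("EV%02d", seq_len(n_events)),
    chrom = slots$chrom, q = ev_q, kind = event_kind,
    stringsAsFactors = FALSE)
  events$is_armd <- event_kind == "armd"
  events$decoy <- ifelse(event_kind %in% c("clean", "armd"), NA_character_,
                         event_kind)
  events$homology <- 0L
  events$consensus_bp <- NA_integer_
  events$seq <- NA_character_
  events$novel_start <- NA_integer_   # novel span inside truth_seq
  events$novel_end <- NA_integer_

  ref_base_at <- function(ch, pos) substring(reference[[ch]], pos, pos)

  for (i in seq_len(n_events)) {
    ch <- events$chrom[i]; q <- events$q[i]
    if (event_kind[i] == "armd") {
      p <- ev_p[i]; w <- ev_w[i]
      chimera <- ev_chimera[i]
      a2 <- mutate_seq(substring(alu_cons, p + 1L, cfg$alu_len),
                       cfg$repeat_divergence)
      a2 <- force_diff(a2, 1L, substring(chimera, p + 1L, p + 1L))
      ilen <- sample(cfg$interstitial_len_range[1]:cfg$interstitial_len_range[2], 1L)
      inter <- rand_seq(ilen)
      b1 <- mutate_seq(substring(alu_cons, 1L, p - w), cfg$repeat_divergence)
      b1 <- force_diff(b1, nchar(b1), substring(chimera, p - w, p - w))
      hom <- substring(reference[[ch]], q - w + 1L, q)
      s <- paste0(a2, inter, b1, hom)
      events$seq[i] <- s
      events$homology[i] <- w
      events$consensus_bp[i] <- p
      events$novel_start[i] <- w + nchar(a2) + 1L
      events$novel_end[i] <- w + nchar(a2) + ilen
    } else if (event_kind[i] == "translocation") {
      # verbatim copy from another chromosome; the chunk is redrawn until
      # its natural ends differ from the junction bases, so the copied
      # content stays untouched and the translocation screen sees a
      # perfect full-coverage hit
      other <- setdiff(chroms, ch)[1L]
      repeat {
        src <- sample.int(nchar(reference[[other]]) - 5000L, 1L) + 2000L
        s <- substring(reference[[other]], src, src + 399L)
        if (substring(s, 1L, 1L) != ref_base_at(ch, q + 1L) &&
            substring(s, 400L, 400L) != ref_base_at(ch, q)) break
      }
      events$seq[i] <- s
    } else if (event_kind[i] == "lowcomplex") {
      s <- strrep("AT", 100L)
      s <- force_diff(s, 1L, ref_base_at(ch, q + 1L))
      s <- force_diff(s, nchar(s), ref_base_at(ch, q))
      events$seq[i] <- s
    } else {
      len <- sample(cfg$insertion_len_range[1]:cfg$insertion_len_range[2], 1L)
      # the first clean event is always optical-scale (> 2 kb) so the
      # validation stratum is never empty
      if (i == which(event_kind == "clean")[1L] &&
          cfg$insertion_len_range[2] > 2200L)
        len <- 2200L + sample.int(min(800L, cfg$insertion_len_range[2] -
                                        2200L), 1L)
      if (event_kind[i] == "clean" && len >= 800L &&
          runif(1) < cfg$te_insert_fraction) {
        u1 <- max(320L, round(len * 0.35))
        te <- mutate_seq(alu_cons, cfg$repeat_divergence)
        u2 <- max(60L, len - u1 - nchar(te))
        s <- paste0(rand_seq(u1), te, rand_seq(u2))
        events$novel_start[i] <- 1L; events$novel_end[i] <- u1
      } else {
        s <- rand_seq(len)
        events$novel_start[i] <- 1L; events$novel_end[i] <- nchar(s)
      }
      s <- force_diff(s, 1L, ref_base_at(ch, q + 1L))
      s <- force_diff(s, nchar(s), ref_base_at(ch, q))
      events$seq[i] <- s
    }
  }
  events$len <- nchar(events$seq)
  events$truth_left <- events$q
  events$truth_right <- ifelse(events$homology > 0L,
                               events$q - events$homology + 1L,
                               events$q + 1L)
  events$truth_seq <- ifelse(
    events$homology > 0L,
    paste0(substring(reference[events$chrom],
                     events$q - events$homology + 1L, events$q), events$seq),
    events$seq)
  # --- carriers ----------------------------------------------------------
  pops <- names(cfg$pop_sizes)
  hap_code <- matrix(0L, nrow = length(samples), ncol = n_events,
                     dimnames = list(samples, events$id))
  for (j in seq_len(n_events)) {
    f <- runif(1, 0.15, 0.85)
    pf <- setNames(rep(f, length(pops)), pops)
    if (runif(1) < 0.5) {
      home <- sample(pops, 1L)
      pf[] <- f * 0.5
      pf[home] <- min(0.95, f + 0.4)
    }
    repeat {
      for (s in samples) {
        p <- pf[[populations[[s]]]]
        if (runif(1) < p)
          hap_code[s, j] <- if (runif(1) < p) 3L else sample(1:2, 1L)
        else hap_code[s, j] <- 0L
      }
      if (any(hap_code[, j] > 0L)) break
    }
  }
  carriers <- hap_code
  carriers[carriers == 3L] <- 2L
  carriers[carriers %in% c(1L, 2L) & hap_code != 3L] <- 1L

  # --- orthogonal truth flags -------------------------------------------
  real <- is.na(events$decoy)
  novel_len <- events$novel_end - events$novel_start + 1L
  events$transcribed <- real & novel_len >= 300L &
    runif(n_events) < cfg$transcribed_fraction
  ancestral <- real & runif(n_events) < cfg$ancestral_fraction
  for (pr in names(cfg$primate_presence))
    events[[pr]] <- ancestral & runif(n_events) < cfg$primate_presence[[pr]]
  events$in_external <- real & runif(n_events) < cfg$external_fraction
  if (!any(events$in_external) && any(real))
    events$in_external[which(real)[1L]] <- TRUE

  # --- donors ------------------------------------------------------------
  jit <- cfg$breakpoint_jitter
  donor_q <- array(rep(events$q, each = length(samples)),
                   dim = c(length(samples), n_events),
                   dimnames = list(samples, events$id))
  if (jit > 0L)
    donor_q[] <- donor_q + matrix(sample((-jit):jit,
                                         length(samples) * n_events,
                                         replace = TRUE),
                                  nrow = length(samples)) *
      (hap_code > 0L)
  donors <- lapply(samples, function(s) {
    lapply(1:2, function(h) {
      sel <- which(hap_code[s, ] == h | hap_code[s, ] == 3L)
      setNames(vapply(chroms, function(ch) {
        idx <- sel[events$chrom[sel] == ch]
        idx <- idx[order(donor_q[s, idx])]
        if (!length(idx)) return(reference[[ch]])
        pieces <- character(0); cursor <- 0L
        for (j in idx) {
          pieces <- c(pieces, substring(reference[[ch]], cursor + 1L,
                                        donor_q[s, j]), events$seq[j])
          cursor <- donor_q[s, j]
        }
        paste(c(pieces, substring(reference[[ch]], cursor + 1L)),
              collapse = "")
      }, character(1)), chroms)
    })
  })
  names(donors) <- samples

  # --- blacklist / alt patches ------------------------------------------
  bl_rows <- list()
  for (i in which(event_kind == "blacklist"))
    bl_rows[[length(bl_rows) + 1L]] <-
      data.frame(chrom = events$chrom[i], start = events$q[i] - 100L,
                 end = events$q[i] + 100L)
  bl_rows[[length(bl_rows) + 1L]] <-
    data.frame(chrom = chroms[1L], start = 10L, end = 500L)
  blacklist_bed <- do.call(rbind, bl_rows)
  blacklist <- structure(list(ranges = GenomicRanges::GRanges(
    blacklist_bed$chrom,
    IRanges::IRanges(blacklist_bed$start + 1L, blacklist_bed$end))),
    class = "blacklist_index")

  alt_patches <- character(0)
  for (i in which(event_kind == "alt_patch")) {
    ch <- events$chrom[i]; q <- events$q[i]
    alt_patches[[sprintf("alt_patch_%s", events$id[i])]] <-
      paste0(substring(reference[[ch]], q - 60L, q), events$seq[i],
             substring(reference[[ch]], q + 1L, q + 60L))
  }

  structure(list(
    config = cfg, samples = samples, populations = populations,
    chroms = chroms, reference = reference, repeats = repeats,
    library = library_df, events = events, hap_code = hap_code,
    carriers = carriers, donor_q = donor_q, donors = donors,
    blacklist = blacklist, blacklist_bed = blacklist_bed,
    alt_patches = alt_patches,
    insert_bounds = c(cfg$insert_size_mean - 3 * cfg$insert_size_sd,
                      cfg$insert_size_mean + 3 * cfg$insert_size_sd)
  ), class = "nui_simulation")
}

# ---------------------------------------------------------------------------
# Read emission with derived alignments
# ---------------------------------------------------------------------------

# cumulative inserted length before reference position x
cum_before <- function(x, q, len) {
  if (!length(q)) return(numeric(length(x)))
  cums <- cumsum(len)
  idx <- findInterval(x - 1L, q)
  c(0, cums)[idx + 1L]
}

# Place reads from a source haplotype onto a target event set.
# a, b: donor coordinates; src: df(q, len, id) of source events on this
# chromosome (sorted by q); tgt: same for target. Returns pos/run/clip.
place_reads <- function(a, b, src, tgt) {
  n <- length(a)
  rl <- b - a + 1L
  pos <- integer(n); run <- integer(n)
  clip_l <- integer(n); clip_r <- integer(n)
  mapped <- rep(TRUE, n)

  if (nrow(src)) {
    s_cum <- c(0, cumsum(src$len))
    ds <- src$q + s_cum[seq_len(nrow(src))] + 1L   # donor start of event
    de <- ds + src$len - 1L
    i_cand <- findInterval(b, ds)
    has_src <- i_cand >= 1L & ifelse(i_cand >= 1L,
                                     a <= de[pmax(i_cand, 1L)] &
                                       b >= ds[pmax(i_cand, 1L)], FALSE)
  } else {
    has_src <- rep(FALSE, n)
    i_cand <- integer(n)
  }

  ra <- integer(n); rb <- integer(n)
  plain <- !has_src
  if (any(plain)) {
    if (nrow(src)) {
      # number of source events entirely before position x (donor coords)
      off_a <- c(0, cumsum(src$len))[findInterval(a[plain], de) + 1L]
      ra[plain] <- a[plain] - off_a
      rb[plain] <- b[plain] - off_a
    } else {
      ra[plain] <- a[plain]; rb[plain] <- b[plain]
    }
  }

  # source-event reads
  for (i in which(has_src)) {
    e <- i_cand[i]
    shared <- nrow(tgt) && src$id[e] %in% tgt$id
    if (shared) {
      if (a[i] < ds[e]) {
        pr <- a[i] - s_cum[e]
        pos[i] <- pr + cum_before(pr, tgt$q, tgt$len)
      } else {
        rel <- a[i] - ds[e]
        tq <- src$q[e]
        pos[i] <- tq + cum_before(tq, tgt$q, tgt$len) +
          tgt$len[match(src$id[e], tgt$id)] * 0L + rel + 1L +
          cum_extra_for_event(src$id[e], tgt)
      }
      run[i] <- rl[i]
    } else {
      la <- max(0L, ds[e] - a[i])
      lb <- max(0L, b[i] - de[e])
      if (max(la, lb) < 20L) { mapped[i] <- FALSE; next }
      if (la >= lb) {
        pr <- a[i] - s_cum[e]
        pos[i] <- pr + cum_before(pr, tgt$q, tgt$len)
        run[i] <- la; clip_r[i] <- rl[i] - la
      } else {
        pr <- src$q[e] + 1L
        pos[i] <- pr + cum_before(pr, tgt$q, tgt$len)
        run[i] <- lb; clip_l[i] <- rl[i] - lb
      }
    }
  }

  # plain reads: check target-event intrusion
  if (any(plain)) {
    idx <- which(plain)
    if (nrow(tgt)) {
      hi <- findInterval(rb[idx] - 1L, tgt$q)
      lo <- findInterval(ra[idx] - 1L, tgt$q)
      intr <- hi > lo
    } else intr <- rep(FALSE, length(idx))
    clean <- idx[!intr]
    pos[clean] <- ra[clean] + cum_before(ra[clean], tgt$q, tgt$len)
    run[clean] <- rl[clean]
    for (i in idx[intr]) {
      qq <- tgt$q[findInterval(rb[i] - 1L, tgt$q)]
      la <- qq - ra[i] + 1L
      lb <- rb[i] - qq
      if (la >= lb) {
        pos[i] <- ra[i] + cum_before(ra[i], tgt$q, tgt$len)
        run[i] <- la; clip_r[i] <- lb
      } else {
        pr <- qq + 1L
        pos[i] <- pr + cum_before(pr, tgt$q, tgt$len)
        run[i] <- lb; clip_l[i] <- la
      }
    }
  }
  list(pos = ifelse(mapped, pos, NA_integer_),
       run = ifelse(mapped, run, 0L),
       clip_l = ifelse(mapped, clip_l, 0L),
       clip_r = ifelse(mapped, clip_r, 0L),
       mapped = mapped)
}

# extra offset when a read starts inside a shared event: inserted length of
# target events strictly before this event at the same q is impossible
# (unique loci), so nothing extra is needed; kept explicit for clarity.
cum_extra_for_event <- function(event_id, tgt) 0L

cigar_string <- function(run, clip_l, clip_r, mapped) {
  out <- rep("*", length(run))
  m <- which(mapped)
  out[m] <- paste0(ifelse(clip_l[m] > 0L, paste0(clip_l[m], "S"), ""),
                   run[m], "M",
                   ifelse(clip_r[m] > 0L, paste0(clip_r[m], "S"), ""))
  out
}

#' Emit a sample's reads with derived alignments against all targets
#'
#' Paired reads are drawn from both donor haplotypes at the configured
#' coverage and placed (by coordinate arithmetic on the known event
#' structure, not by running an aligner) against three targets: the
#' reference (linked-read-style scores for the extraction filter, and
#' separately BWA-style scores for the concordance screen, with mate 1
#' barcode-trimmed) and the two pseudo-haplotypes (BWA-style, trimmed).
#' Sequencing errors enter the score/mismatch model; reads fully inside an
#' insertion absent from the target are unmapped, partial overlaps are
#' soft-clipped.
#'
#' @param sim A `nui_simulation`.
#' @param sample Sample name.
#' @return List of alignment tables: `lr_ref`, `bwa_ref`, `hap1`, `hap2`.
#' @export
emit_sample_alignments <- function(sim, sample) {
  cfg <- sim$config
  set.seed(cfg$seed + 7919L * match(sample, sim$samples))
  rl <- cfg$read_len
  trim <- 23L
  ev <- sim$events
  hap_events <- lapply(1:2, function(h) {
    sel <- which(sim$hap_code[sample, ] == h | sim$hap_code[sample, ] == 3L)
    data.frame(q = sim$donor_q[sample, sel], len = ev$len[sel],
               id = ev$id[sel], chrom = ev$chrom[sel],
               stringsAsFactors = FALSE)
  })
  out <- list(lr_ref = list(), bwa_ref = list(), hap1 = list(), hap2 = list())
  for (h in 1:2) {
    for (ch in sim$chroms) {
      donor <- sim$donors[[sample]][[h]][[ch]]
      dlen <- nchar(donor)
      nfrag <- round(cfg$coverage_depth / 2 * dlen / (2 * rl))
      flen <- pmin(pmax(round(rnorm(nfrag, cfg$insert_size_mean,
                                    cfg$insert_size_sd)), 2L * rl + 8L), 700L)
      st <- floor(runif(nfrag, 1, dlen - flen + 1))
      names <- sprintf("%s_h%d_%s_%06d", sample, h, ch, seq_len(nfrag))
      a1 <- st; b1 <- st + rl - 1L
      a2 <- st + flen - rl; b2 <- st + flen - 1L
      src <- hap_events[[h]][hap_events[[h]]$chrom == ch, , drop = FALSE]
      src <- src[order(src$q), , drop = FALSE]
      tgts <- list(
        ref = src[0, , drop = FALSE],
        hap1 = {
          t1 <- hap_events[[1]][hap_events[[1]]$chrom == ch, , drop = FALSE]
          t1[order(t1$q), , drop = FALSE]
        },
        hap2 = {
          t2 <- hap_events[[2]][hap_events[[2]]$chrom == ch, , drop = FALSE]
          t2[order(t2$q), , drop = FALSE]
        })
      p1u <- lapply(tgts, function(tg) place_reads(a1, b1, src, tg))
      p1t <- lapply(tgts, function(tg) place_reads(a1 + trim, b1, src, tg))
      p2 <- lapply(tgts, function(tg) place_reads(a2, b2, src, tg))
      seq1 <- substring(donor, a1, b1)
      seq2 <- revcomp(substring(donor, a2, b2))
      qual1 <- strrep("I", rl)
      qual2 <- strrep("I", rl)
      quals1 <- rep(qual1, nfrag)
      bad <- runif(nfrag) < cfg$bad_pair_fraction
      quals1[bad] <- paste0(strrep("I", floor(rl * 0.55)),
                            strrep("#", rl - floor(rl * 0.55)))
      quals2 <- rep(qual2, nfrag)
      build <- function(p_m1, p_m2, m1_seq, m1_qual, score_model) {
        n <- nfrag
        mk <- function(p, mate, other, seqs, quals) {
          len <- nchar(seqs[1])
          mm <- rbinom(n, pmax(p$run, 0L), cfg$error_rate)
          nseg <- (p$clip_l > 0L) + (p$clip_r > 0L)
          clip <- p$clip_l + p$clip_r
          both <- p$mapped & other$mapped
          left <- pmin(p$pos, other$pos)
          right <- pmax(p$pos + p$run - 1L, other$pos + other$run - 1L)
          tlen <- ifelse(both, right - left + 1L, NA_integer_)
          proper <- both & !is.na(tlen) &
            tlen >= sim$insert_bounds[1] & tlen <= sim$insert_bounds[2]
          improper <- !proper
          as_val <- if (score_model == "lariat")
            lariat_score(mm, 0, nseg, clip, as.numeric(improper))
          else p$run - 5 * mm
          as_val[!p$mapped] <- NA_real_
          flag <- 1L + 2L * proper + 4L * (!p$mapped) +
            8L * (!other$mapped) +
            16L * (mate == 2L) + 32L * (mate == 1L) +
            (if (mate == 1L) 64L else 128L)
          data.frame(
            read_name = names, mate = mate, flag = flag,
            unmapped = !p$mapped, mate_unmapped = !other$mapped,
            proper_flag = proper, reverse = mate == 2L,
            mate_reverse = mate == 1L,
            chrom = ifelse(p$mapped, ch, NA_character_),
            pos = p$pos, mapq = ifelse(!p$mapped, 0L,
                                       ifelse(clip > 0L, 30L, 60L)),
            cigar = cigar_string(p$run, p$clip_l, p$clip_r, p$mapped),
            insert_size = ifelse(both, ifelse(p$pos <= other$pos, tlen,
                                              -tlen), NA_integer_),
            seq = seqs, qual = quals,
            clipped_segments = as.numeric(nseg),
            clipped_bases = as.numeric(clip), indels = 0,
            ref_span = as.numeric(p$run),
            align_score = as_val, mismatches = as.numeric(mm),
            read_len = len, stringsAsFactors = FALSE)
        }
        rbind(mk(p_m1, 1L, p_m2, m1_seq, m1_qual),
              mk(p_m2, 2L, p_m1, seq2, quals2))
      }
      qual1t <- substring(quals1, trim + 1L)
      seq1t <- substring(seq1, trim + 1L)
      out$lr_ref[[paste(h, ch)]] <- build(p1u$ref, p2$ref, seq1, quals1,
                                          "lariat")
      out$bwa_ref[[paste(h, ch)]] <- build(p1t$ref, p2$ref, seq1t, qual1t,
                                           "bwa")
      out$hap1[[paste(h, ch)]] <- build(p1t$hap1, p2$hap1, seq1t, qual1t,
                                        "bwa")
      out$hap2[[paste(h, ch)]] <- build(p1t$hap2, p2$hap2, seq1t, qual1t,
                                        "bwa")
    }
  }
  lapply(out, function(lst) {
    df <- do.call(rbind, lst)
    rownames(df) <- NULL
    df
  })
}

# ---------------------------------------------------------------------------
# Orthogonal fixtures
# ---------------------------------------------------------------------------

#' Primate genome fixtures
#'
#' Each primate genome is the reference with the ancestral (primate-present)
#' insertions included, lightly diverged.
#'
#' @param sim A `nui_simulation`.
#' @return Named list of sequence collections, one per primate.
#' @export
sim_primate_genomes <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 101L)
  ev <- sim$events
  out <- list()
  for (pr in names(cfg$primate_presence)) {
    genome <- character(0)
    for (ch in sim$chroms) {
      idx <- which(ev$chrom == ch & ev[[pr]])
      idx <- idx[order(ev$q[idx])]
      pieces <- character(0); cursor <- 0L
      for (j in idx) {
        pieces <- c(pieces, substring(sim$reference[[ch]], cursor + 1L,
                                      ev$q[j]), ev$seq[j])
        cursor <- ev$q[j]
      }
      s <- paste(c(pieces, substring(sim$reference[[ch]], cursor + 1L)),
                 collapse = "")
      genome[[ch]] <- mutate_seq(s, cfg$primate_divergence)
    }
    out[[pr]] <- genome
  }
  out
}

#' EST fixture: fragments of transcribed insertions plus reference decoys
#'
#' @param sim A `nui_simulation`.
#' @return Named character vector of EST sequences.
#' @export
sim_est_db <- function(sim) {
  set.seed(sim$config$seed + 211L)
  ev <- sim$events
  out <- character(0)
  for (i in which(ev$transcribed)) {
    ns <- ev$novel_start[i]; ne <- ev$novel_end[i]
    width <- min(250L, ne - ns + 1L)
    st <- ns + sample.int(max(1L, ne - ns + 2L - width), 1L) - 1L
    out[[sprintf("est_%s", ev$id[i])]] <-
      substring(ev$truth_seq[i], st, st + width - 1L)
  }
  # reference-derived decoy ESTs: regions that hit an EST must be screened
  # against the reference and discarded
  for (k in 1:2) {
    ch <- sim$chroms[1L]
    st <- 2000L + 3000L * k
    out[[sprintf("est_ref_decoy%d", k)]] <-
      substring(sim$reference[[ch]], st, st + 249L)
  }
  out
}

#' RNA-seq pair fixtures keyed by NUI locus
#'
#' For every transcribed event, emits read-pair placements on the extended
#' NUI (300 bp flanks) that pass the transcription filter bank, together
#' with negative-control pairs (flank-only, low score). Keys are
#' `"chrom:truth_left"`.
#'
#' @param sim A `nui_simulation`.
#' @param n_pairs Passing pairs per transcribed event.
#' @return Named list of pair tables for [rnaseq_transcription()].
#' @export
sim_rna_pairs <- function(sim, n_pairs = 4L) {
  set.seed(sim$config$seed + 307L)
  ev <- sim$events
  flank <- 300L
  out <- list()
  for (i in seq_len(nrow(ev))) {
    key <- sprintf("%s:%d", ev$chrom[i], ev$truth_left[i])
    if (!ev$transcribed[i]) {
      out[[key]] <- data.frame(
        m1_start = 1L, m1_end = 150L, m2_start = 120L, m2_end = 270L,
        proper = TRUE, as_total = 290, unique = TRUE)   # flank-only pair
      next
    }
    len <- nchar(ev$truth_seq[i])
    pass <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
      off <- sample.int(100L, 1L)
      m1s <- flank - 60L - off
      data.frame(m1_start = m1s, m1_end = m1s + 149L,
                 m2_start = flank + 40L + off,
                 m2_end = flank + 189L + off,
                 proper = TRUE, as_total = 280 + sample.int(20L, 1L),
                 unique = TRUE)
    }))
    fail <- data.frame(
      m1_start = c(1L, flank - 160L),
      m1_end = c(150L, flank - 11L),
      m2_start = c(60L, flank + 10L),
      m2_end = c(209L, flank + 159L),
      proper = c(TRUE, TRUE),
      as_total = c(300, 120),        # flank-only pair; low-score pair
      unique = c(TRUE, TRUE))
    out[[key]] <- rbind(pass, fail)
  }
  out
}

#' Optical-map call fixtures per sample
#'
#' Insertion calls (with 10% sizing noise) at every carried event longer
#' than 2 kb, plus one zero-coverage region and one deletion call. The
#' extra rows are anchored at short-event loci (never evaluable against
#' optical maps anyway), so they exercise the exclusion rules without
#' removing support for any validatable call.
#'
#' @param sim A `nui_simulation`.
#' @return Named list of optical call tables, one per sample.
#' @export
sim_optical_calls <- function(sim) {
  set.seed(sim$config$seed + 401L)
  ev <- sim$events
  short <- which(ev$len <= 1500L)
  out <- list()
  for (s in sim$samples) {
    rows <- list()
    for (j in which(sim$carriers[s, ] > 0L & ev$len > 2000L &
                      is.na(ev$decoy))) {
      size <- round(ev$len[j] * runif(1, 0.9, 1.1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ev$chrom[j], start = ev$q[j] - 500L, end = ev$q[j] + 500L,
        type = "insertion", size = size, coverage = 35L)
    }
    if (length(short) >= 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ev$chrom[short[1L]], start = ev$q[short[1L]] - 200L,
        end = ev$q[short[1L]] + 200L,
        type = "zero_coverage", size = 0L, coverage = 0L)
    if (length(short) >= 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ev$chrom[short[2L]], start = ev$q[short[2L]] - 300L,
        end = ev$q[short[2L]] + 300L,
        type = "deletion", size = 600L, coverage = 30L)
    out[[s]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 type = character(), size = integer(), coverage = integer(),
                 stringsAsFactors = FALSE)
  }
  out
}

#' External comparison-contig fixtures
#'
#' @param sim A `nui_simulation`.
#' @return Named character vector of contigs covering the events flagged
#'   `in_external` with 200 bp of reference context.
#' @export
sim_external_contigs <- function(sim) {
  ev <- sim$events
  out <- character(0)
  for (i in which(ev$in_external)) {
    ch <- ev$chrom[i]; q <- ev$q[i]
    out[[sprintf("ext_%s", ev$id[i])]] <-
      paste0(substring(sim$reference[[ch]], q - 200L, q), ev$seq[i],
             substring(sim$reference[[ch]], q + 1L, q + 200L))
  }
  out
}

#' Annotate a sequence against the simulator's repeat library
#'
#' Minimal k-mer-seeded library matcher used to annotate inserted sequences
#' in fixtures (full repeat-library search is annotation input, not a
#' pipeline computation). Gapless diagonal regions at 80% identity or better
#' and 30+ bp are reported with consensus coordinates.
#'
#' @param seq Sequence to annotate.
#' @param library_df Library table (`name`, `seq`, `family`, `class`).
#' @return Repeat feature table on `seq` coordinates.
#' @export
annotate_repeats <- function(seq, library_df) {
  out <- list()
  for (i in seq_len(nrow(library_df))) {
    regions <- find_local_regions(seq, setNames(library_df$seq[i],
                                                library_df$name[i]),
                                  min_identity = 0.80, min_len = 30L,
                                  seed_len = 12L, stride = 6L)
    if (!nrow(regions)) next
    out[[length(out) + 1L]] <- data.frame(
      score = round(regions$identity * 1000), divergence =
        (1 - regions$identity) * 100,
      query = "insert", start = regions$q_start, end = regions$q_end,
      strand = "+", family = library_df$family[i],
      class = library_df$class[i],
      cons_start = regions$q_start + regions$offset,
      cons_end = regions$q_end + regions$offset,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_repeat_features())
  feats <- do.call(rbind, out)
  # drop regions mostly contained in a longer one
  feats <- feats[order(-(feats$end - feats$start)), , drop = FALSE]
  keep <- rep(TRUE, nrow(feats))
  for (i in seq_len(nrow(feats))) {
    if (!keep[i]) next
    if (i < nrow(feats)) for (j in (i + 1L):nrow(feats)) {
      ov <- min(feats$end[i], feats$end[j]) - max(feats$start[i],
                                                  feats$start[j]) + 1L
      if (ov > 0.5 * (feats$end[j] - feats$start[j] + 1L)) keep[j] <- FALSE
    }
  }
  feats <- feats[keep, , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Write a simulated cohort to disk in the pipeline's file formats
#'
#' @param sim A `nui_simulation`.
#' @param dir Output directory (created if needed).
#' @param samples Samples to emit alignments for (default: all).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, samples = sim$samples) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "ref.fa"))
  write_repeat_table(sim$repeats, file.path(dir, "repeats.out"))
  if (length(sim$alt_patches))
    write_fasta(sim$alt_patches, file.path(dir, "alt_patches.fa"))
  write.table(sim$blacklist_bed, file.path(dir, "blacklist.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$events[, c("id", "chrom", "truth_left", "truth_right",
                             "homology", "len", "kind", "decoy",
                             "transcribed")],
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  seqinfo <- setNames(nchar(sim$reference), names(sim$reference))
  for (s in samples) {
    aln <- emit_sample_alignments(sim, s)
    write_alignments(aln$lr_ref, file.path(dir, sprintf("%s_lr_ref.sam", s)),
                     seqinfo)
    write_alignments(aln$bwa_ref, file.path(dir, sprintf("%s_bwa_ref.sam", s)),
                     seqinfo)
    for (h in 1:2) {
      hap <- sim$donors[[s]][[h]]
      write_fasta(hap, file.path(dir, sprintf("%s_hap%d.fa", s, h)))
      write_alignments(aln[[sprintf("hap%d", h)]],
                       file.path(dir, sprintf("%s_hap%d.sam", s, h)),
                       setNames(nchar(hap), names(hap)))
    }
  }
  invisible(dir)
}
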