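#' @import methods
#' @importFrom stats median sd setNames aov TukeyHSD fisher.test chisq.test
#'   cor.test prcomp pf rnorm runif rbinom rpois sample.int
#' @importFrom utils read.table write.table head tail
NULL

# ---------------------------------------------------------------------------
# Sequence collections
# ---------------------------------------------------------------------------

#' Read a FASTA file into a genome sequence collection
#'
#' Sequences are uppercased on load and validated against the nucleotide
#' alphabet `A,C,G,T,N`. Record order is preserved and duplicate names are an
#' error, so a collection can be addressed by name throughout the pipeline.
#'
#' @param path Path to a FASTA file.
#' @param role Collection role, one of `"reference"`, `"alt_patch"`,
#'   `"pseudo_haplotype"`, `"comparison_contig"`.
#' @return A named [Biostrings::DNAStringSet] with a `role` metadata entry.
#' @export
read_fasta <- function(path, role = c("reference", "alt_patch",
                                      "pseudo_haplotype", "comparison_contig")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome_sequences(setNames(toupper(as.character(seqs)), names(seqs)), role)
}

#' Build a validated genome sequence collection from a named character vector
#'
#' @param x Named character vector of nucleotide strings.
#' @param role See [read_fasta()].
#' @return A named `DNAStringSet` carrying `role` metadata.
#' @export
as_genome_sequences <- function(x, role = "reference") {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("every sequence needs a name")
  dup <- names(x)[duplicated(names(x))]
  if (length(dup))
    stop("duplicate sequence name(s): ", paste(unique(dup), collapse = ", "))
  x <- toupper(x)
  if (any(nchar(x) == 0L))
    stop("empty sequence for record: ",
         paste(names(x)[nchar(x) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-ACGTN characters in record: ",
         paste(names(x)[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(x)
  S4Vectors::metadata(out)$role <- role
  out
}

#' Write a sequence collection to FASTA
#'
#' @param seqs Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# Character access helper: collections are stored as DNAStringSet but most of
# the pipeline manipulates plain strings.
seq_chars <- function(seqs) setNames(as.character(seqs), names(seqs))

# ---------------------------------------------------------------------------
# SAM dialect
# ---------------------------------------------------------------------------

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(len = integer(), op = character()))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

# Summaries used by the filters: clip segment/base counts, indel events,
# reference span consumed.
cigar_summary <- function(cigars) {
  out <- t(vapply(cigars, function(cg) {
    ops <- cigar_ops(cg)
    clip <- ops$op %in% c("S", "H")
    c(clipped_segments = sum(clip),
      clipped_bases = sum(ops$len[clip]),
      indels = sum(ops$op %in% c("I", "D")),
      ref_span = sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")]))
  }, numeric(4)))
  rownames(out) <- NULL
  as.data.frame(out)
}

sam_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (!length(hit)) return(NA_real_)
  as.numeric(sub("^..:.:", "", hit[1]))
}

#' Read a SAM-dialect alignment file into a table of alignment records
#'
#' Parses the headered tab-separated SAM text dialect used throughout the
#' pipeline. Both integer (`AS:i`) and float (`AS:f`) alignment-score tags are
#' accepted and stored as numeric; mismatch counts come from `NM:i`. Clipping
#' statistics (soft plus hard) and indel event counts are derived from the
#' CIGAR. Positions stay 1-based as in SAM; unmapped reads carry `NA`
#' coordinates. Mates are paired by read name; a read whose mate is missing is
#' kept and reported with a warning.
#'
#' @param path SAM file path.
#' @return A `data.frame` with one row per read, ordered so that mates of a
#'   pair are adjacent (mate 1 first).
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  core <- matrix("", nrow = n, ncol = 11)
  for (i in seq_len(n)) {
    if (length(fields[[i]]) < 11L)
      stop("malformed SAM line ", i, ": fewer than 11 fields")
    core[i, ] <- fields[[i]][1:11]
  }
  flag <- as.integer(core[, 2])
  unmapped <- bitwAnd(flag, 4L) > 0L
  rec <- data.frame(
    read_name = core[, 1],
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    flag = flag,
    unmapped = unmapped,
    mate_unmapped = bitwAnd(flag, 8L) > 0L,
    proper_flag = bitwAnd(flag, 2L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    mate_reverse = bitwAnd(flag, 32L) > 0L,
    chrom = ifelse(unmapped | core[, 3] == "*", NA_character_, core[, 3]),
    pos = ifelse(unmapped, NA_integer_, as.integer(core[, 4])),
    mapq = as.integer(core[, 5]),
    cigar = core[, 6],
    insert_size = ifelse(core[, 9] == "0", NA_integer_, as.integer(core[, 9])),
    seq = core[, 10],
    qual = core[, 11],
    stringsAsFactors = FALSE
  )
  rec <- cbind(rec, cigar_summary(rec$cigar))
  rec$align_score <- vapply(fields, sam_tag, numeric(1), tag = "AS")
  rec$mismatches <- vapply(fields, sam_tag, numeric(1), tag = "NM")
  rec$read_len <- nchar(rec$seq)
  # order mates of a pair adjacently, mate 1 first
  rec <- rec[order(match(rec$read_name, unique(rec$read_name)), rec$mate), ]
  tab <- table(rec$read_name)
  solo <- names(tab)[tab == 1L]
  if (length(solo))
    warning(length(solo), " read(s) without a resolvable mate, emitted solo")
  rownames(rec) <- NULL
  rec
}

empty_alignments <- function() {
  data.frame(read_name = character(), mate = integer(), flag = integer(),
             unmapped = logical(), mate_unmapped = logical(),
             proper_flag = logical(), reverse = logical(),
             mate_reverse = logical(), chrom = character(), pos = integer(),
             mapq = integer(), cigar = character(), insert_size = integer(),
             seq = character(), qual = character(), clipped_segments = numeric(),
             clipped_bases = numeric(), indels = numeric(), ref_span = numeric(),
             align_score = numeric(), mismatches = numeric(),
             read_len = integer(), stringsAsFactors = FALSE)
}

#' Write alignment records back out as SAM text
#'
#' @param rec Alignment record table as produced by [read_alignments()].
#' @param path Output path.
#' @param seqinfo Named integer vector of target sequence lengths for `@SQ`
#'   header lines.
#' @export
write_alignments <- function(rec, path, seqinfo = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(seqinfo))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo),
                          as.integer(seqinfo)))
  tags <- paste0(
    ifelse(is.na(rec$align_score), "",
           sprintf("\tAS:f:%g", rec$align_score)),
    ifelse(is.na(rec$mismatches), "",
           sprintf("\tNM:i:%d", as.integer(round(rec$mismatches)))))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                  rec$read_name, rec$flag,
                  ifelse(is.na(rec$chrom), "*", rec$chrom),
                  ifelse(is.na(rec$pos), 0L, rec$pos),
                  rec$mapq, rec$cigar, "=",
                  0L, ifelse(is.na(rec$insert_size), 0L, rec$insert_size),
                  rec$seq, rec$qual, tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Blacklist intervals (BED / BEDPE)
# ---------------------------------------------------------------------------

#' Read a BED file (0-based half-open) into 1-based closed genomic ranges
#'
#' Rows with `start >= end` are rejected with a warning.
#'
#' @param path BED path (3+ columns).
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  bad <- df[[2]] >= df[[3]]
  if (any(bad)) {
    warning(sum(bad), " BED row(s) with start >= end rejected")
    df <- df[!bad, , drop = FALSE]
  }
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
}

#' Build a queryable blacklist index from BED and BEDPE files
#'
#' The BED intervals and both breakend intervals of every BEDPE row are pooled
#' into one overlap index used by the breakpoint blacklist filter.
#'
#' @param bed_path BED file of problematic regions (or `NULL`).
#' @param bedpe_path BEDPE file (6+ columns) whose two end intervals are both
#'   indexed (or `NULL`).
#' @return An object of class `blacklist_index`.
#' @export
read_blacklist <- function(bed_path = NULL, bedpe_path = NULL) {
  grl <- list()
  if (!is.null(bed_path)) grl <- c(grl, list(read_bed(bed_path)))
  if (!is.null(bedpe_path)) {
    df <- read.table(bedpe_path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    keep1 <- df[[2]] < df[[3]]
    keep2 <- df[[5]] < df[[6]]
    if (any(!keep1) || any(!keep2))
      warning(sum(!keep1) + sum(!keep2), " BEDPE end interval(s) rejected")
    grl <- c(grl, list(
      GenomicRanges::GRanges(df[[1]][keep1],
                             IRanges::IRanges(df[[2]][keep1] + 1L, df[[3]][keep1])),
      GenomicRanges::GRanges(df[[4]][keep2],
                             IRanges::IRanges(df[[5]][keep2] + 1L, df[[6]][keep2]))))
  }
  gr <- if (length(grl)) suppressWarnings(do.call(c, grl)) else
    GenomicRanges::GRanges()
  structure(list(ranges = gr), class = "blacklist_index")
}

#' Query a blacklist index at single positions
#'
#' @param index A `blacklist_index`.
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @return Logical vector: `TRUE` where the position falls inside an indexed
#'   interval.
#' @export
blacklist_contains <- function(index, chrom, pos) {
  stopifnot(inherits(index, "blacklist_index"))
  if (!length(index$ranges)) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  suppressWarnings(IRanges::overlapsAny(q, index$ranges))
}

# ---------------------------------------------------------------------------
# Repeat annotation and optical-map call tables
# ---------------------------------------------------------------------------

#' Read a RepeatMasker-style whitespace table of repeat features
#'
#' Expected columns: score, divergence, deletion, insertion percentages,
#' query name, query begin/end (1-based inclusive), strand, repeat family,
#' repeat class, consensus begin/end. Header lines are skipped automatically.
#'
#' @param path Annotation table path.
#' @return A `data.frame` of repeat features.
#' @export
read_repeat_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !grepl("^(SW|score|bit)", lines)]
  if (!length(lines)) return(empty_repeat_features())
  f <- strsplit(lines, "\\s+")
  out <- data.frame(
    score = vapply(f, function(x) as.numeric(x[1]), numeric(1)),
    divergence = vapply(f, function(x) as.numeric(x[2]), numeric(1)),
    query = vapply(f, function(x) x[5], character(1)),
    start = vapply(f, function(x) as.integer(x[6]), integer(1)),
    end = vapply(f, function(x) as.integer(x[7]), integer(1)),
    strand = vapply(f, function(x) x[8], character(1)),
    family = vapply(f, function(x) x[9], character(1)),
    class = vapply(f, function(x) x[10], character(1)),
    cons_start = vapply(f, function(x) as.integer(x[11]), integer(1)),
    cons_end = vapply(f, function(x) as.integer(x[12]), integer(1)),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(out$cons_start) & !is.na(out$cons_end) &
    out$cons_start > out$cons_end
  if (any(bad)) stop("repeat feature with consensus_start > consensus_end")
  out
}

empty_repeat_features <- function() {
  data.frame(score = numeric(), divergence = numeric(), query = character(),
             start = integer(), end = integer(), strand = character(),
             family = character(), class = character(), cons_start = integer(),
             cons_end = integer(), stringsAsFactors = FALSE)
}

#' Write repeat features in the RepeatMasker-style whitespace layout
#' @param feats Repeat feature table.
#' @param path Output path.
#' @export
write_repeat_table <- function(feats, path) {
  lines <- sprintf("%g %g 0.0 0.0 %s %d %d %s %s %s %d %d",
                   feats$score, feats$divergence, feats$query, feats$start,
                   feats$end, feats$strand, feats$family, feats$class,
                   feats$cons_start, feats$cons_end)
  writeLines(lines, path)
  invisible(path)
}

#' Read optical-map structural-variant calls from a TSV
#'
#' Generic layout: `chrom, start, end, type, size, coverage` with a header
#' row. `type` is one of insertion/deletion/inversion/complex/zero_coverage;
#' zero-coverage rows describe map regions with no molecule support and drive
#' the validation exclusion rules.
#'
#' @param path TSV path.
#' @return A `data.frame` of optical calls.
#' @export
read_optical_calls <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type", "size", "coverage")
  if (!all(need %in% names(df)))
    stop("optical call table must have columns: ", paste(need, collapse = ", "))
  ins <- df$type == "insertion"
  if (any(ins & df$size <= 0)) stop("insertion call with non-positive size")
  df
}
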