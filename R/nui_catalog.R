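# The NUI definition filters, cross-sample merging and the occurrence matrix.

INTERSPERSED_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "Other")

#' Masking summary of one inserted sequence
#'
#' Combines interspersed-repeat features (annotation input, on insert
#' coordinates) with low-complexity DUST intervals and counts the bases
#' masked by neither — the "unique" bases of the NUI definition.
#'
#' @param seq Inserted sequence.
#' @param repeat_features Repeat feature table on insert coordinates
#'   (columns `start`, `end`, `class`; may be empty).
#' @param dust_intervals Intervals from [dust_mask()] (computed when `NULL`).
#' @return List with `total_len`, `interspersed_masked`,
#'   `low_complexity_masked`, `unique_bases`.
#' @export
unique_bases <- function(seq, repeat_features = NULL, dust_intervals = NULL) {
  len <- nchar(seq)
  if (is.null(dust_intervals)) dust_intervals <- dust_mask(seq)
  rep_ir <- IRanges::IRanges()
  lc_ir <- IRanges::IRanges()
  if (!is.null(repeat_features) && nrow(repeat_features)) {
    if (any(repeat_features$start < 1L | repeat_features$end > len))
      stop("repeat feature outside sequence bounds")
    inter <- repeat_features$class %in% INTERSPERSED_CLASSES
    rep_ir <- IRanges::IRanges(repeat_features$start[inter],
                               repeat_features$end[inter])
    lc_ir <- IRanges::IRanges(repeat_features$start[!inter],
                              repeat_features$end[!inter])
  }
  dust_ir <- IRanges::IRanges(dust_intervals$start, dust_intervals$end)
  lc_ir <- c(lc_ir, dust_ir)
  all_masked <- IRanges::reduce(c(rep_ir, lc_ir))
  list(total_len = len,
       interspersed_masked = sum(IRanges::width(IRanges::reduce(rep_ir))),
       low_complexity_masked = sum(IRanges::width(IRanges::reduce(lc_ir))),
       unique_bases = len - sum(IRanges::width(all_masked)))
}

#' Known-reference screen against alternative loci and patches
#'
#' The NUI, extended by `flank` reference bases on both ends, is aligned to
#' the alt/patch collection; a full-coverage hit at `min_id` identity or
#' better means the sequence is already represented and the NUI is dropped.
#'
#' @param extended_seq Insert plus reference flanks.
#' @param alt_patches Alt/patch sequence collection (may be empty).
#' @param min_id Identity threshold.
#' @return `TRUE` to keep the NUI.
#' @export
filter_known_reference <- function(extended_seq, alt_patches, min_id = 0.95) {
  if (is.null(alt_patches) || !length(alt_patches)) return(TRUE)
  hits <- find_hits(extended_seq, alt_patches, min_identity = min_id,
                    min_coverage = 1)
  nrow(hits) == 0L
}

#' Translocation screen against the core reference
#'
#' The bare breakpoint-to-breakpoint insert aligned anywhere in the core
#' reference at `min_id` identity over its full length is a moved copy, not
#' novel sequence, and is dropped.
#'
#' @param insert_seq Inserted sequence (no flanks).
#' @param reference Core reference collection.
#' @param min_id Identity threshold.
#' @return `TRUE` to keep the NUI.
#' @export
filter_translocation <- function(insert_seq, reference, min_id = 0.95) {
  hits <- find_hits(insert_seq, reference, min_identity = min_id,
                    min_coverage = 1)
  nrow(hits) == 0L
}

#' Contaminant screen against a supplied library
#'
#' @param insert_seq Inserted sequence.
#' @param library Contaminant sequence collection (default empty).
#' @param min_id,min_cov Hit thresholds.
#' @return `TRUE` to keep the NUI.
#' @export
filter_contaminants <- function(insert_seq, library = NULL, min_id = 0.90,
                                min_cov = 0.90) {
  if (is.null(library) || !length(library)) return(TRUE)
  hits <- find_hits(insert_seq, library, min_identity = min_id,
                    min_coverage = min_cov)
  nrow(hits) == 0L
}

#' Breakpoint blacklist filter
#'
#' @param call Single-row call with `chrom`, `ref_left`, `ref_right`.
#' @param blacklist A `blacklist_index`.
#' @return `TRUE` to keep (neither breakpoint inside an indexed interval).
#' @export
filter_blacklist <- function(call, blacklist) {
  !any(blacklist_contains(blacklist, rep(call$chrom, 2L),
                          c(call$ref_left, call$ref_right)))
}

# single-linkage connected components via union-find
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge per-sample calls into the non-redundant catalog
#'
#' Two calls on the same chromosome belong to the same NUI when they share an
#' identical left or right breakpoint, or when both breakpoints lie within
#' `tol` bases (inclusive) of each other; clusters are the single-linkage
#' closure of this predicate, which makes the result independent of sample
#' order. Each cluster is represented by the member with the most unique
#' bases (ties: smaller left breakpoint, then lexicographically smallest
#' sample). Occurrence-matrix genotypes are 2 for homozygous and 1 for
#' single-haplotype presence, then recoded 2 to 1 to give the binary matrix
#' used by all population statistics.
#'
#' @param per_sample_calls Named list (by sample) of call tables carrying at
#'   least `chrom`, `ref_left`, `ref_right`, `ref_overlap`, `insert_len`,
#'   `seq`, `zygosity`, `unique_bases`.
#' @param tol Breakpoint merge tolerance (inclusive, bp).
#' @return List with `catalog` (one row per NUI, ids `NUI_...`), `matrix`
#'   (binary samples x NUIs), and `raw_matrix` (0/1/2 before recoding).
#' @export
merge_across_samples <- function(per_sample_calls, tol = 50L) {
  samples <- sort(names(per_sample_calls))
  all <- do.call(rbind, lapply(samples, function(s) {
    df <- per_sample_calls[[s]]
    if (!nrow(df)) return(NULL)
    df$sample <- s
    df
  }))
  if (is.null(all) || !nrow(all)) {
    mat <- matrix(0L, nrow = length(samples), ncol = 0L,
                  dimnames = list(samples, character()))
    return(list(catalog = empty_calls(), matrix = mat, raw_matrix = mat))
  }
  all <- all[order(all$chrom, all$ref_left, all$ref_right, all$sample), ,
             drop = FALSE]
  edges <- do.call(rbind, lapply(split(seq_len(nrow(all)), all$chrom),
                                 function(idx) {
    if (length(idx) < 2L) return(NULL)
    pairs <- t(utils::combn(idx, 2L))
    a <- all[pairs[, 1L], ]; b <- all[pairs[, 2L], ]
    hit <- a$ref_left == b$ref_left | a$ref_right == b$ref_right |
      (abs(a$ref_left - b$ref_left) <= tol &
         abs(a$ref_right - b$ref_right) <= tol)
    pairs[hit, , drop = FALSE]
  }))
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2L)
  comp <- uf_components(nrow(all), edges)
  clusters <- split(seq_len(nrow(all)), comp)
  reps <- vapply(clusters, function(idx) {
    sub <- all[idx, ]
    ord <- order(-sub$unique_bases, sub$ref_left, sub$sample)
    idx[ord[1L]]
  }, integer(1))
  catalog <- all[reps, , drop = FALSE]
  ord <- order(catalog$chrom, catalog$ref_left, catalog$ref_right)
  catalog <- catalog[ord, , drop = FALSE]
  clusters <- clusters[ord]
  catalog$id <- sprintf("NUI_%05d", seq_len(nrow(catalog)))
  raw <- matrix(0L, nrow = length(samples), ncol = nrow(catalog),
                dimnames = list(samples, catalog$id))
  for (ci in seq_along(clusters)) {
    for (i in clusters[[ci]]) {
      g <- if (all$zygosity[i] == "homozygous") 2L else 1L
      raw[all$sample[i], ci] <- max(raw[all$sample[i], ci], g)
    }
  }
  bin <- raw
  bin[bin == 2L] <- 1L
  catalog$sample <- NULL
  rownames(catalog) <- NULL
  catalog <- catalog[, c("id", setdiff(names(catalog), "id"))]
  list(catalog = catalog, matrix = bin, raw_matrix = raw)
}

#' Cohort summary of a catalog and occurrence matrix
#'
#' @param catalog Catalog table from [merge_across_samples()].
#' @param matrix Binary occurrence matrix (samples x NUIs).
#' @param populations Named character vector mapping sample to population.
#' @return List with `per_sample` (count and summed insert bp),
#'   `population_median` (median count per population), `by_individuals`
#'   (how many NUIs are shared by k individuals) and `by_populations`
#'   (shared by k populations).
#' @export
catalog_summary <- function(catalog, matrix, populations) {
  samples <- rownames(matrix)
  if (any(!samples %in% names(populations)))
    stop("sample(s) without population label: ",
         paste(setdiff(samples, names(populations)), collapse = ", "))
  pop <- populations[samples]
  counts <- rowSums(matrix)
  bp <- as.numeric(matrix %*% catalog$insert_len[match(colnames(matrix),
                                                       catalog$id)])
  per_sample <- data.frame(sample = samples, population = unname(pop),
                           count = as.integer(counts), bp = bp,
                           stringsAsFactors = FALSE)
  pop_median <- vapply(split(per_sample$count, per_sample$population),
                       median, numeric(1))
  n_ind <- colSums(matrix)
  n_pop <- apply(matrix, 2L, function(col) length(unique(pop[col > 0L])))
  list(per_sample = per_sample,
       population_median = pop_median,
       mean_count = mean(per_sample$count),
       mean_bp = mean(per_sample$bp),
       by_individuals = table(factor(n_ind, levels = 0:length(samples))),
       by_populations = table(factor(n_pop,
                                     levels = 0:length(unique(pop)))))
}
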