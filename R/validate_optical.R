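# Validation of large NUIs against optical-map insertion calls.

interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(b_start - a_end, a_start - b_end))
}

#' Restrict NUIs to those evaluable against optical maps
#'
#' Keeps NUIs strictly longer than `min_len` (optical maps cannot size
#' smaller events reliably), then removes NUIs within `exclusion` bases of a
#' zero-coverage map region or of any non-insertion structural-variant call
#' (deletion, inversion, complex), since a size change between two labels
#' cannot be attributed when variants stack.
#'
#' @param nuis Call table (`chrom`, `ref_left`, `ref_right`, `insert_len`).
#' @param optical_calls Optical call table from [read_optical_calls()].
#' @param min_len Minimum insert length (exclusive, bp).
#' @param exclusion Exclusion radius (bp).
#' @return List with `validatable` (kept rows) and the exclusion counts
#'   `n_excluded_small`, `n_excluded_zero_cov`, `n_excluded_nearby_sv`.
#' @export
filter_validatable <- function(nuis, optical_calls, min_len = 2000L,
                               exclusion = 10000L) {
  big <- nuis$insert_len > min_len
  n_small <- sum(!big)
  nuis <- nuis[big, , drop = FALSE]
  zero <- optical_calls[optical_calls$type == "zero_coverage" |
                          optical_calls$coverage == 0, , drop = FALSE]
  sv <- optical_calls[optical_calls$type %in%
                        c("deletion", "inversion", "complex"), , drop = FALSE]
  near_any <- function(call, tab) {
    tab <- tab[tab$chrom == call$chrom, , drop = FALSE]
    if (!nrow(tab)) return(FALSE)
    lo <- min(call$ref_left, call$ref_right)
    hi <- max(call$ref_left, call$ref_right)
    any(interval_gap(lo, hi, tab$start, tab$end) <= exclusion)
  }
  in_zero <- vapply(seq_len(nrow(nuis)), function(i)
    near_any(nuis[i, ], zero), logical(1))
  n_zero <- sum(in_zero)
  nuis <- nuis[!in_zero, , drop = FALSE]
  in_sv <- vapply(seq_len(nrow(nuis)), function(i)
    near_any(nuis[i, ], sv), logical(1))
  list(validatable = nuis[!in_sv, , drop = FALSE],
       n_excluded_small = n_small,
       n_excluded_zero_cov = n_zero,
       n_excluded_nearby_sv = sum(in_sv))
}

#' Does an insertion-type optical call support this NUI?
#'
#' @param nui Single-row call.
#' @param optical_calls Optical call table.
#' @param window Symmetric matching distance (bp).
#' @return `TRUE` when an insertion call lies within `window` of the NUI
#'   locus.
#' @export
support_match <- function(nui, optical_calls, window = 10000L) {
  ins <- optical_calls[optical_calls$type == "insertion" &
                         optical_calls$chrom == nui$chrom, , drop = FALSE]
  if (!nrow(ins)) return(FALSE)
  lo <- min(nui$ref_left, nui$ref_right)
  hi <- max(nui$ref_left, nui$ref_right)
  any(interval_gap(lo, hi, ins$start, ins$end) <= window)
}

#' Validation precision
#'
#' @param n_supported,n_unsupported Non-negative counts.
#' @return `n_supported / (n_supported + n_unsupported)`; `NA` with a
#'   warning when nothing was evaluable.
#' @export
precision <- function(n_supported, n_unsupported) {
  stopifnot(n_supported >= 0, n_unsupported >= 0)
  total <- n_supported + n_unsupported
  if (total == 0) {
    warning("no evaluable calls; precision undefined")
    return(NA_real_)
  }
  n_supported / total
}

#' Validate a sample's NUIs against its optical-map calls
#'
#' @param nuis Call table for one sample.
#' @param optical_calls Optical call table for the same sample.
#' @param min_len,exclusion See [filter_validatable()].
#' @param window See [support_match()].
#' @return List with the exclusion counts, `n_supported`, `n_unsupported`
#'   and `precision`.
#' @export
validate_against_optical <- function(nuis, optical_calls, min_len = 2000L,
                                     exclusion = 10000L, window = 10000L) {
  flt <- filter_validatable(nuis, optical_calls, min_len, exclusion)
  v <- flt$validatable
  supported <- vapply(seq_len(nrow(v)), function(i)
    support_match(v[i, ], optical_calls, window), logical(1))
  n_sup <- sum(supported)
  n_unsup <- nrow(v) - n_sup
  list(n_supported = n_sup, n_unsupported = n_unsup,
       n_excluded_small = flt$n_excluded_small,
       n_excluded_zero_cov = flt$n_excluded_zero_cov,
       n_excluded_nearby_sv = flt$n_excluded_nearby_sv,
       precision = if (n_sup + n_unsup > 0) precision(n_sup, n_unsup)
                   else NA_real_)
}
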