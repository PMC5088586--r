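#' Find maximal exact repeats (direct and inverted)
#'
#' Reports every maximal repeated pair of length at least `min_len`:
#' forward (direct) copies and reverse-complement (inverted, including
#' palindromic) copies. A pair is maximal when no one-position extension on
#' either side preserves the match. Each unordered pair is reported once,
#' self-overlapping tandem copies are allowed, and `N` never matches
#' anything, including another `N`. Circular sequences are handled so that
#' copies may span the origin.
#'
#' @param x DNA string or a [plastome()].
#' @param min_len Minimum repeat length in bp (default 30).
#' @param include_direct,include_inverted Which orientations to report.
#' @param circular Treat the sequence as circular; defaults to the
#'   plastome's own flag, or `FALSE` for a bare string.
#' @return `data.frame` with columns `pos1`, `pos2` (1-based starts of the
#'   two copies, `pos1 <= pos2`), `length`, `orientation`.
#' @export
find_maximal_repeats <- function(x, min_len = 30, include_direct = TRUE,
                                 include_inverted = TRUE, circular = NULL) {
  if (inherits(x, "plastome")) {
    circular <- circular %||% x$circular
    x <- x$sequence
  }
  circular <- circular %||% FALSE
  stopifnot(is.character(x), length(x) == 1)
  x <- normalize_dna(x)
  if (nchar(x) < min_len)
    stop("sequence shorter than min_len")
  df <- find_repeats_cpp(x, as.integer(min_len), include_direct,
                         include_inverted, circular)
  df[order(df$pos1, df$pos2, df$length, df$orientation), , drop = FALSE]
}

#' Mask coverage of a repeat hit set
#'
#' Merges every interval participating in at least one repeat hit (both
#' copies) into a non-overlapping mask and reports the fraction of the
#' genome covered — the "non-overlapping repeat elements" accounting used in
#' plastome comparisons (plain interval union; no scoring or
#' defragmentation).
#'
#' @param hits Hit table from [find_maximal_repeats()].
#' @param genome_len Genome length in bp.
#' @param circular Intervals extending past `genome_len` wrap to the origin.
#' @return A `repeat_mask`: merged `intervals` (`data.frame` of
#'   `start`/`end`), `masked_bp`, `coverage`.
#' @export
mask_coverage <- function(hits, genome_len, circular = TRUE) {
  stopifnot(is.data.frame(hits), genome_len >= 1)
  if (nrow(hits) == 0) {
    return(structure(list(intervals = data.frame(start = integer(),
                                                 end = integer()),
                          masked_bp = 0L, coverage = 0),
                     class = "repeat_mask"))
  }
  starts <- c(hits$pos1, hits$pos2)
  lens <- rep(hits$length, 2)
  if (any(starts < 1) || (!circular && any(starts + lens - 1 > genome_len)))
    stop("validation error: repeat interval beyond genome length")
  if (circular && any(starts > genome_len))
    stop("validation error: repeat start beyond genome length")
  ends <- starts + lens - 1
  wrap <- ends > genome_len
  ir <- IRanges::IRanges(start = c(starts, rep(1, sum(wrap))),
                         end = c(pmin(ends, genome_len),
                                 ends[wrap] - genome_len))
  red <- IRanges::reduce(ir)
  masked <- sum(IRanges::width(red))
  structure(list(intervals = data.frame(start = IRanges::start(red),
                                        end = IRanges::end(red)),
                 masked_bp = masked, coverage = masked / genome_len),
            class = "repeat_mask")
}

#' @export
print.repeat_mask <- function(x, ...) {
  cat(sprintf("<repeat_mask> %d merged interval(s), %s bp, coverage %.2f%%\n",
              nrow(x$intervals), format(x$masked_bp, big.mark = ","),
              100 * x$coverage))
  invisible(x)
}
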