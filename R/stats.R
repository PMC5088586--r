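#' Basic composition statistics of a plastome
#'
#' A+T fraction is computed over unambiguous residues only: `N` is excluded
#' from both numerator and denominator, and the value is invariant under
#' reverse complementation.
#'
#' @param x A [plastome()].
#' @return A `genome_stats` object with `length` and `at_fraction` filled in.
#' @export
basic_stats <- function(x) {
  stopifnot(inherits(x, "plastome"))
  f <- Biostrings::letterFrequency(Biostrings::DNAString(x$sequence),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0)
    stop("undefined A+T fraction: sequence contains no unambiguous residues")
  structure(list(length = x$length,
                 at_fraction = unname((f[["A"]] + f[["T"]]) / tot),
                 n_conserved_genes = NA_integer_,
                 intron_fraction = NA_real_,
                 intergenic_fraction = NA_real_,
                 coding_fraction = NA_real_,
                 mean_intergenic_size = NA_real_,
                 n_intergenic_gaps = NA_integer_),
            class = "genome_stats")
}

#' Genome accounting over annotated features
#'
#' Partitions the genome into coding (conserved-gene exons and structural
#' RNAs), intron, and intergenic fractions, in the accounting style used for
#' plastome comparisons:
#' \itemize{
#'   \item conserved genes are features of kind `gene`, `tRNA` or `rRNA`
#'     (optionally restricted to a reference gene list); names matching
#'     `orf...` and all `orf`-kind features are excluded and their span counts
#'     as intergenic, since unidentified ORFs are treated as spacer sequence;
#'   \item genes duplicated in the inverted repeat are counted once;
#'   \item fractions use interval unions, so overlapping annotations are
#'     never double-counted (a warning reports exon/intron overlap);
#'   \item the mean intergenic size divides total intergenic bp by the number
#'     of maximal intergenic gaps on the circle (the two terminal gaps of a
#'     circular genome merge across the origin).
#' }
#'
#' @param x An annotated [plastome()].
#' @param gene_list Optional character vector restricting which names count
#'   as conserved genes.
#' @return A `genome_stats` object with the full partition filled in.
#' @export
annotation_accounting <- function(x, gene_list = NULL) {
  stopifnot(inherits(x, "plastome"))
  st <- basic_stats(x)
  gr <- x$features
  mc <- S4Vectors::mcols(gr)
  L <- x$length

  is_orf_like <- mc$kind == "orf" | grepl("^orf", mc$name, ignore.case = TRUE)
  coding_kinds <- mc$kind %in% c("gene", "CDS", "tRNA", "rRNA") & !is_orf_like
  if (!is.null(gene_list)) {
    keep <- mc$name %in% gene_list | mc$kind %in% c("CDS")
    coding_kinds <- coding_kinds & keep
  }
  gene_sel <- mc$kind %in% c("gene", "tRNA", "rRNA") & !is_orf_like
  if (!is.null(gene_list)) gene_sel <- gene_sel & mc$name %in% gene_list
  st$n_conserved_genes <- length(unique(mc$name[gene_sel]))

  rng <- function(sel) IRanges::reduce(IRanges::ranges(gr[sel]))
  exons <- rng(coding_kinds)
  introns <- rng(mc$kind == "intron")

  ov <- IRanges::intersect(exons, introns)
  if (sum(IRanges::width(ov)) > 0)
    warning("overlapping exon/intron annotations resolved by union (",
            sum(IRanges::width(ov)), " bp)")
  exon_only <- IRanges::setdiff(exons, introns)

  intron_bp <- sum(IRanges::width(introns))
  coding_bp <- sum(IRanges::width(exon_only))
  intergenic_bp <- L - intron_bp - coding_bp

  covered <- IRanges::reduce(IRanges::union(exons, introns))
  gaps <- IRanges::gaps(covered, start = 1, end = L)
  n_gaps <- length(gaps)
  if (x$circular && n_gaps >= 2 &&
      IRanges::start(gaps)[1] == 1 &&
      IRanges::end(gaps)[n_gaps] == L &&
      !(length(covered) == 0))
    n_gaps <- n_gaps - 1  # first and last gap are one gap across the origin
  if (length(covered) == 0) n_gaps <- 1  # whole circle is one gap

  st$intron_fraction <- intron_bp / L
  st$intergenic_fraction <- intergenic_bp / L
  st$coding_fraction <- coding_bp / L
  st$n_intergenic_gaps <- n_gaps
  st$mean_intergenic_size <- if (intergenic_bp == 0) 0 else intergenic_bp / n_gaps
  st
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("<genome_stats> %s bp, A+T %.1f%%\n",
              format(x$length, big.mark = ","), 100 * x$at_fraction))
  if (!is.na(x$n_conserved_genes))
    cat(sprintf("  conserved genes: %d\n  coding %.1f%% | introns %.1f%% | intergenic %.1f%% (mean gap %.0f bp over %d gaps)\n",
                x$n_conserved_genes, 100 * x$coding_fraction,
                100 * x$intron_fraction, 100 * x$intergenic_fraction,
                x$mean_intergenic_size, x$n_intergenic_gaps))
  invisible(x)
}
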