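#' Plastome: a circular chloroplast genome with typed features
#'
#' The central container of the package: a (usually circular) DNA sequence
#' plus an ordered set of typed, stranded features held in a
#' [GenomicRanges::GRanges]. Multi-interval features (trans-spliced genes,
#' features wrapping the circular origin) are stored as several ranges
#' sharing one `feature_id`, with a `part` index preserving interval order.
#'
#' All coordinates are 1-based inclusive, the GenBank/GFF3 convention, both
#' internally (IRanges) and in every file read or written, so there is no
#' conversion boundary to cross.
#'
#' @param id Accession-like identifier.
#' @param sequence DNA string; normalized to uppercase `{A,C,G,T,N}`
#'   (`U` becomes `T`, other letters become `N`).
#' @param features Optional feature table: a `data.frame` with columns
#'   `name`, `kind`, `strand`, `start`, `end` and optionally `part` and
#'   `attrs` (sorted `key=value;...` pairs), or a ready-made `GRanges`.
#'   Recognized kinds: `gene`, `CDS`, `tRNA`, `rRNA`, `intron`, `orf`,
#'   `repeat_region`, `IR`, `misc`.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @return An object of class `plastome`.
#' @export
plastome <- function(id, sequence, features = NULL, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            is.character(sequence), length(sequence) == 1)
  sequence <- normalize_dna(sequence)
  len <- nchar(sequence)
  if (len == 0) stop("empty sequence for plastome '", id, "'")
  gr <- as_features_granges(features, id, len, circular)
  structure(list(id = id, sequence = sequence, length = len,
                 circular = circular, features = gr),
            class = "plastome")
}

FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "intron", "orf",
                   "repeat_region", "IR", "misc")

as_features_granges <- function(features, id, len, circular) {
  si <- GenomeInfoDb::Seqinfo(seqnames = id, seqlengths = len,
                              isCircular = circular)
  if (is.null(features)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      feature_id = character(), name = character(), kind = character(),
      part = integer(), attrs = character())
    return(gr)
  }
  if (methods::is(features, "GRanges")) {
    GenomeInfoDb::seqinfo(features) <- si
    return(features)
  }
  df <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("name", "kind", "strand", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(df$name, df$kind, sep = "\r")
  key_change <- c(TRUE, key[-1] != key[-length(key)])
  if (!"part" %in% names(df)) {
    # consecutive rows sharing (name, kind) form one multi-interval feature
    fid <- cumsum(key_change)
    df$part <- stats::ave(seq_len(nrow(df)), fid, FUN = seq_along)
    df$.fid <- fid
  } else {
    df$.fid <- cumsum(key_change | df$part == 1)
  }
  if (!"attrs" %in% names(df)) df$attrs <- ""
  df$attrs[is.na(df$attrs)] <- ""
  bad <- !(df$kind %in% FEATURE_KINDS)
  if (any(bad)) {
    warning("unknown feature kind(s): ",
            paste(unique(df$kind[bad]), collapse = ", "),
            "; kept as 'misc' with orig_kind attribute")
    for (i in which(bad)) {
      a <- attrs_parse(df$attrs[i])
      a$orig_kind <- df$kind[i]
      df$attrs[i] <- attrs_build(a)
    }
    df$kind[bad] <- "misc"
  }
  if (any(df$start < 1) || any(df$end > len) || any(df$start > df$end))
    stop("coordinate error: feature interval outside [1, ", len, "]")
  if (any(!nzchar(df$name)) || any(is.na(df$name)))
    stop("feature with empty name")
  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(df$strand %in% c("-", "-1"), "-", "+"),
    seqinfo = si)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = paste0("f", df$.fid),
    name = df$name, kind = df$kind,
    part = as.integer(df$part), attrs = df$attrs)
  gr
}

#' Feature table of a plastome
#'
#' Flat 1-based inclusive view of the features of a [plastome()], one row per
#' interval, in stored order.
#'
#' @param x A `plastome`.
#' @return `data.frame` with columns `name`, `kind`, `strand`, `start`,
#'   `end`, `part`, `attrs`.
#' @export
feature_table <- function(x) {
  stopifnot(inherits(x, "plastome"))
  gr <- x$features
  data.frame(name = S4Vectors::mcols(gr)$name,
             kind = S4Vectors::mcols(gr)$kind,
             strand = as.character(BiocGenerics::strand(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             part = S4Vectors::mcols(gr)$part,
             attrs = S4Vectors::mcols(gr)$attrs,
             stringsAsFactors = FALSE)
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %s, %d feature interval(s)\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(x$features)))
  kinds <- table(S4Vectors::mcols(x$features)$kind)
  if (length(kinds))
    cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

# subsequence of the (possibly circular) genome, 1-based inclusive;
# end < start means wrap through the origin
plastome_subseq <- function(x, start, end) {
  L <- x$length
  start <- mod1(start, L); end <- mod1(end, L)
  if (start <= end) return(substr(x$sequence, start, end))
  if (!x$circular) stop("interval wraps origin of a linear sequence")
  paste0(substr(x$sequence, start, L), substr(x$sequence, 1, end))
}
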