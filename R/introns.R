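#' An intron registry
#'
#' Introns are tracked in a plain `data.frame`, one row per intron copy,
#' with columns `taxon`, `host_gene`, `intron_class` (`I`, `IIA`, `IIB`),
#' `splicing` (`cis`/`trans`), `site` (reference coordinate of the
#' nucleotide immediately preceding the intron), `orf_domains`
#' (`+`-separated subset of RT, maturase, HNH, LAGLIDADG, GIY-YIG; empty for
#' ORF-less introns) and `sequence` (may be empty for trans-spliced
#' introns).
#'
#' @param df `data.frame` to validate.
#' @return The validated registry (invisibly the same `data.frame`).
#' @export
intron_registry <- function(df) {
  req <- c("taxon", "host_gene", "intron_class", "splicing", "site",
           "orf_domains", "sequence")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("intron registry lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$intron_class %in% c("I", "IIA", "IIB")))
    stop("intron_class must be one of I, IIA, IIB")
  if (!all(df$splicing %in% c("cis", "trans")))
    stop("splicing must be cis or trans")
  if (any(df$site < 1)) stop("sites are 1-based reference coordinates")
  cis_empty <- df$splicing == "cis" & !nzchar(df$sequence)
  if (any(cis_empty)) stop("cis-spliced introns must carry a sequence")
  df[req]
}

#' Read an intron registry from TSV
#'
#' @param path Tab-separated file with the columns of [intron_registry()].
#' @return Validated registry `data.frame`.
#' @export
read_intron_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$site <- as.integer(df$site)
  df$orf_domains[is.na(df$orf_domains)] <- ""
  df$sequence[is.na(df$sequence)] <- ""
  intron_registry(df)
}

#' Write an intron registry to TSV
#' @param df Registry `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intron_registry <- function(df, path) {
  utils::write.table(intron_registry(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Map an intron insertion site onto reference-gene coordinates
#'
#' Intron positions are only comparable across taxa after mapping onto a
#' common reference gene (a deeply diverging taxon's homolog, or E. coli
#' rRNA for ribosomal sites). The concatenated host exons are aligned to the
#' reference with an ends-free (overlap) global alignment and the reference
#' position aligned to the host nucleotide immediately preceding the intron
#' is returned. When that host position aligns to a gap, the nearest
#' upstream reference position is returned with `is_approximate = TRUE`.
#'
#' @param host_exons Concatenated exon sequence of the host gene.
#' @param reference_gene Homologous reference gene sequence.
#' @param intron_offset 1-based position within `host_exons` of the last
#'   exon nucleotide before the intron.
#' @param min_identity Minimum alignment identity (default 0.4); below it a
#'   homology error is raised.
#' @return List with `site` (reference coordinate) and `is_approximate`.
#' @export
map_insertion_site <- function(host_exons, reference_gene, intron_offset,
                               min_identity = 0.4) {
  stopifnot(is.character(host_exons), is.character(reference_gene),
            intron_offset >= 1, intron_offset <= nchar(host_exons))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(normalize_dna(host_exons)),
    Biostrings::DNAString(normalize_dna(reference_gene)),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 3, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- mean(pa == sa & pa != "-")
  if (ident < min_identity)
    stop(sprintf("homology error: alignment identity %.0f%% below %.0f%%",
                 100 * ident, 100 * min_identity))
  ppos <- cumsum(pa != "-") + Biostrings::start(Biostrings::pattern(aln)) - 1
  spos <- cumsum(sa != "-") + Biostrings::start(Biostrings::subject(aln)) - 1
  col <- match(TRUE, pa != "-" & ppos == intron_offset)
  if (is.na(col)) {
    # intron offset outside the aligned region; extrapolate from its edge
    if (intron_offset < ppos[1]) {
      return(list(site = max(1, spos[1] - (ppos[1] - intron_offset)),
                  is_approximate = TRUE))
    }
    last <- length(pa)
    return(list(site = spos[last] + (intron_offset - ppos[last]),
                is_approximate = TRUE))
  }
  if (sa[col] != "-") return(list(site = spos[col], is_approximate = FALSE))
  up <- which(sa[seq_len(col)] != "-")
  site <- if (length(up)) spos[max(up)] else max(1, spos[1] - 1)
  list(site = site, is_approximate = TRUE)
}

#' Group introns by positional homology
#'
#' Introns of different taxa are positional homologs when they sit at the
#' identical (host gene, reference site) pair. Grouping is by exact
#' equality; groups are ordered by gene then site.
#'
#' @param records Intron registry `data.frame` (sites already mapped to
#'   shared reference coordinates).
#' @return The registry with an added integer `homolog_group` column.
#' @export
positional_homologs <- function(records) {
  records <- intron_registry(records)
  key <- paste(records$host_gene, records$site, sep = "@")
  levels <- unique(key[order(records$host_gene, records$site)])
  records$homolog_group <- match(key, levels)
  records[order(records$homolog_group), ]
}

#' Intron distribution matrix
#'
#' Taxa in rows, insertion sites (`gene@site`) in columns; cells are
#' `"absent"`, `"ORF-less"` for an intron without ORF, or `"ORF:"` followed
#' by the encoded domain set.
#'
#' @param records Intron registry `data.frame`.
#' @param taxa Row order; defaults to the taxa present in `records`.
#' @return Character matrix with dimnames.
#' @export
distribution_matrix <- function(records, taxa = NULL) {
  if (nrow(records)) records <- intron_registry(records)
  taxa <- taxa %||% unique(records$taxon)
  if (nrow(records) == 0) {
    return(matrix(character(), nrow = length(taxa), ncol = 0,
                  dimnames = list(taxa, NULL)))
  }
  key <- paste(records$host_gene, records$site, sep = "@")
  cols <- unique(key[order(records$host_gene, records$site)])
  m <- matrix("absent", nrow = length(taxa), ncol = length(cols),
              dimnames = list(taxa, cols))
  for (i in seq_len(nrow(records))) {
    val <- if (nzchar(records$orf_domains[i]))
      paste0("ORF:", records$orf_domains[i]) else "ORF-less"
    m[records$taxon[i], key[i]] <- val
  }
  m
}

#' Per-taxon intron counts by class
#'
#' @param records Intron registry `data.frame`.
#' @return Integer table, taxa x intron class.
#' @export
intron_counts <- function(records) {
  records <- intron_registry(records)
  table(factor(records$taxon),
        factor(records$intron_class, levels = c("I", "IIA", "IIB")))
}

#' Pairwise intron identity over a global alignment
#'
#' Needleman-Wunsch global alignment (defaults: match +1, mismatch -1, gap
#' of length k costs 5 + 2(k-1)); identity is the fraction of matching
#' columns over all alignment columns, gap columns included, so the value
#' reflects the full spans of both sequences.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (`gap_open` is the cost of a gap's first position).
#' @return List with `identity` (fraction) and `columns` (alignment length).
#' @export
pairwise_intron_identity <- function(a, b, match = 1, mismatch = -1,
                                     gap_open = 5, gap_extend = 2) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(normalize_dna(a)),
    Biostrings::DNAString(normalize_dna(b)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(identity = mean(pa == sa & pa != "-"), columns = length(pa))
}
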