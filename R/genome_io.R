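#' Read plastome sequences from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any residue outside
#' `{A,C,G,T,N}` is collapsed to `N`. The record id is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file (one or more records).
#' @param circular Treat molecules as circular (default `TRUE`).
#' @return A list of [plastome()] objects (without features).
#' @export
read_fasta <- function(path, circular = TRUE) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("format error reading FASTA '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0) stop("format error: no FASTA records in '", path, "'")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  seqs <- toupper(as.character(ss))
  lapply(seq_along(ss), function(i) {
    s <- seqs[[i]]
    n_bad <- nchar(gsub("[ACGTUN]", "", s))
    if (nchar(s) == 0 || n_bad > 0.1 * nchar(s))
      stop("format error: record '", ids[i],
           "' is not nucleotide-dominant (>10% non-ACGTN residues)")
    plastome(ids[i], s, circular = circular)
  })
}

#' Write plastomes to a FASTA file
#'
#' @param x A `plastome` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "plastome")) x <- list(x)
  ss <- Biostrings::DNAStringSet(vapply(x, function(p) p$sequence, ""))
  names(ss) <- vapply(x, function(p) p$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an annotation feature table
#'
#' Supports three dialects, all with 1-based inclusive coordinates:
#' \describe{
#'   \item{`tsv`}{Columns `name`, `kind`, `strand`, `start`, `end` and
#'     optionally `attrs`. Consecutive rows sharing (`name`, `kind`) are
#'     joined into one multi-interval feature.}
#'   \item{`genbank_ft`}{The FEATURES block of a GenBank flat file (or a file
#'     containing one): `join(...)`/`order(...)` produce multi-interval
#'     features and `complement(...)` sets the minus strand. Qualifiers become
#'     attributes; the name comes from `/gene`, `/standard_name`, `/label`,
#'     `/name`, `/locus_tag` or `/product`, in that order.}
#'   \item{`gff3`}{GFF3 as written by [write_gff3()]; lines sharing an `ID`
#'     are reassembled into one feature using their `part` attribute.}
#' }
#'
#' @param path Input file.
#' @param dialect One of `"tsv"`, `"genbank_ft"`, `"gff3"`.
#' @param seq_length Optional declared sequence length; intervals beyond it
#'   raise a coordinate error.
#' @return Feature `data.frame` suitable for [plastome()] (columns `name`,
#'   `kind`, `strand`, `start`, `end`, `part`, `attrs`).
#' @export
read_feature_table <- function(path, dialect = c("tsv", "genbank_ft", "gff3"),
                               seq_length = NULL) {
  dialect <- match.arg(dialect)
  df <- switch(dialect,
               tsv = read_features_tsv(path),
               genbank_ft = read_features_genbank(path),
               gff3 = read_features_gff3(path))
  if (!is.null(seq_length) &&
      (any(df$start < 1) || any(df$end > seq_length)))
    stop("coordinate error: feature interval outside [1, ", seq_length, "]")
  if (any(df$start > df$end))
    stop("coordinate error: interval start > end")
  check_kinds(df)
}

check_kinds <- function(df) {
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
  df
}

read_features_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("name", "kind", "strand", "start", "end")
  if (!all(req %in% names(df)))
    stop("TSV feature table needs columns: ", paste(req, collapse = ", "))
  out <- data.frame(name = df$name, kind = df$kind, strand = df$strand,
                    start = as.integer(df$start), end = as.integer(df$end),
                    stringsAsFactors = FALSE)
  out$attrs <- if ("attrs" %in% names(df)) df$attrs else ""
  key <- paste(out$name, out$kind, sep = "\r")
  fid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  out$part <- stats::ave(seq_len(nrow(out)), fid, FUN = seq_along)
  out[c("name", "kind", "strand", "start", "end", "part", "attrs")]
}

# --- GenBank feature table ---------------------------------------------------

parse_gb_location <- function(loc) {
  loc <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  rec <- function(s) {
    if (grepl("^complement\\(", s)) {
      strand <<- if (strand == "+") "-" else "+"
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(rev_intervals(rec(inner)))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      parts <- split_toplevel(inner)
      return(do.call(rbind, lapply(parts, rec)))
    }
    if (grepl("^\\d+\\.\\.\\d+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      return(matrix(ab, nrow = 1))
    }
    if (grepl("^\\d+$", s)) {
      a <- as.integer(s)
      return(matrix(c(a, a), nrow = 1))
    }
    stop("cannot parse GenBank location: ", loc)
  }
  rev_intervals <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  m <- rec(loc)
  list(intervals = m, strand = strand)
}

split_toplevel <- function(s) {
  depth <- 0
  cut <- integer()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    else if (chars[i] == ")") depth <- depth - 1
    else if (chars[i] == "," && depth == 0) cut <- c(cut, i)
  }
  starts <- c(1, cut + 1)
  ends <- c(cut - 1, length(chars))
  vapply(seq_along(starts),
         function(k) paste(chars[starts[k]:ends[k]], collapse = ""), "")
}

read_features_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) lines <- lines[-seq_len(fstart[1])]
  fend <- grep("^(ORIGIN|//)", lines)
  if (length(fend)) lines <- lines[seq_len(fend[1] - 1)]
  feats <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) feats[[length(feats) + 1]] <<- cur
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^ {0,10}[A-Za-z][A-Za-z0-9_'-]* {2,}\\S", ln) &&
        !grepl("^ {11,}", ln)) {
      flush()
      kind <- sub("^\\s*(\\S+)\\s+.*$", "\\1", ln)
      loc <- sub("^\\s*\\S+\\s+", "", ln)
      cur <- list(kind = kind, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      t <- trimws(ln)
      if (startsWith(t, "/")) cur$quals <- c(cur$quals, t)
      else if (length(cur$quals) == 0) cur$loc <- paste0(cur$loc, t)
      else cur$quals[length(cur$quals)] <-
          paste(cur$quals[length(cur$quals)], t)
    }
  }
  flush()
  if (!length(feats)) stop("no features found in GenBank feature table")
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    loc <- parse_gb_location(f$loc)
    q <- list()
    for (s in f$quals) {
      s <- sub("^/", "", s)
      kv <- strsplit(s, "=", fixed = TRUE)[[1]]
      key <- kv[1]
      val <- if (length(kv) > 1) gsub('^"|"$', "", paste(kv[-1], collapse = "="))
             else "true"
      q[[key]] <- val
    }
    name <- q$gene %||% q$standard_name %||% q$label %||% q$name %||%
      q$locus_tag %||% q$product %||% paste0(f$kind, "_", i)
    q <- q[setdiff(names(q), c("gene", "standard_name", "label", "name",
                               "locus_tag"))]
    ni <- nrow(loc$intervals)
    data.frame(name = name, kind = f$kind, strand = loc$strand,
               start = loc$intervals[, 1], end = loc$intervals[, 2],
               part = seq_len(ni), attrs = attrs_build(q),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- GFF3 --------------------------------------------------------------------

GFF3_TYPE <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
               intron = "intron", orf = "ORF", repeat_region = "repeat_region",
               IR = "inverted_repeat", misc = "misc_feature")

#' Write a plastome's features as GFF3
#'
#' Coordinates are written 1-based inclusive. Multi-interval features are
#' emitted as one line per interval sharing an `ID`, with a `part` attribute
#' preserving interval order, so [read_feature_table()] with
#' `dialect = "gff3"` round-trips losslessly for the supported kinds.
#'
#' @param x A [plastome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  stopifnot(inherits(x, "plastome"))
  ft <- feature_table(x)
  fid <- S4Vectors::mcols(x$features)$feature_id
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", x$id, x$length))
  for (i in seq_len(nrow(ft))) {
    a <- attrs_parse(ft$attrs[i])
    astr <- paste0(
      "ID=", fid[i], ";Name=", ft$name[i], ";part=", ft$part[i],
      if (length(a)) paste0(";", attrs_build(a)) else "")
    lines <- c(lines, paste(
      x$id, "plastarch", GFF3_TYPE[[ft$kind[i]]],
      ft$start[i], ft$end[i], ".", ft$strand[i], ".", astr, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0)
    return(data.frame(name = character(), kind = character(),
                      strand = character(), start = integer(), end = integer(),
                      part = integer(), attrs = character()))
  mc <- S4Vectors::mcols(gr)
  rev_type <- stats::setNames(names(GFF3_TYPE), GFF3_TYPE)
  type <- as.character(mc$type)
  kind <- ifelse(type %in% names(rev_type), rev_type[type], type)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    paste0("f", seq_along(gr))
  name <- if ("Name" %in% names(mc)) as.character(mc$Name) else id
  part <- if ("part" %in% names(mc)) as.integer(as.character(mc$part)) else
    rep(1L, length(gr))
  skip <- c("type", "source", "score", "phase", "ID", "Name", "part")
  extra <- setdiff(names(mc), skip)
  attrs <- vapply(seq_along(gr), function(i) {
    a <- list()
    for (k in extra) {
      v <- mc[[k]][i]
      if (is.list(v) || methods::is(v, "List")) v <- unlist(v)
      if (length(v) == 1 && !is.na(v)) a[[k]] <- as.character(v)
    }
    attrs_build(a)
  }, "")
  df <- data.frame(name = name, kind = unname(kind),
                   strand = as.character(BiocGenerics::strand(gr)),
                   start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                   part = part, attrs = attrs, .id = id,
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  # restore original feature order: features in order of first appearance,
  # intervals by part
  first <- match(unique(df$.id), df$.id)
  ord <- order(match(df$.id, df$.id[first]), df$part)
  df <- df[ord, setdiff(names(df), ".id"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a plain gene list (one gene name per line)
#'
#' Used to restrict shared gene-order extraction and conserved-gene counting
#' to a reference repertoire.
#'
#' @param path Text file; blank lines and `#` comments ignored.
#' @return Character vector of gene names.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
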