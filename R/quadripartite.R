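#' Detect the large inverted repeat and derive the quadripartite map
#'
#' Finds the longest pair of disjoint segments such that one is the exact
#' reverse complement of the other (the two IR copies), handling the circular
#' origin, then partitions the remainder of the circle into the two
#' single-copy arcs. `SC1` is the larger single-copy region and `SC2` the
#' smaller, labelled by size, not gene content. The copy labelled `IR-A` is
#' the one followed (in ascending coordinates) by `SC1`, so the circle reads
#' IRa, SC1, IRb, SC2.
#'
#' With `tolerance > 0`, collinear exact inverted matches separated by up to
#' `tolerance` total mismatched positions are chained into one IR; the number
#' of mismatches actually absorbed is reported, never silently dropped.
#'
#' @param x A [plastome()].
#' @param min_len Minimum IR copy length in bp (default 5000).
#' @param tolerance Maximum number of mismatches allowed between the two
#'   copies (default 0, exact identity).
#' @return A `quadripartite_map`, or `NULL` when no inverted repeat of at
#'   least `min_len` exists.
#' @export
detect_inverted_repeat <- function(x, min_len = 5000, tolerance = 0) {
  stopifnot(inherits(x, "plastome"))
  L <- x$length
  if (L < 2 * min_len) return(NULL)
  seed_len <- if (tolerance > 0) max(30L, min(min_len %/% 4L, 2000L)) else min_len
  hits <- find_maximal_repeats(x$sequence, min_len = seed_len,
                               include_direct = FALSE, include_inverted = TRUE,
                               circular = x$circular)
  if (nrow(hits) == 0) return(NULL)
  if (tolerance > 0) hits <- chain_inverted_hits(hits, L, tolerance)
  # copies must be disjoint on the circle
  disj <- !circ_inside(hits$pos2, hits$pos1, hits$length, L) &
    !circ_inside(hits$pos1, hits$pos2, hits$length, L) &
    (2 * hits$length <= L)
  hits <- hits[disj & hits$length >= min_len, , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  hits <- hits[order(-hits$length, hits$pos1), , drop = FALSE]
  best <- hits[1, ]
  build_quadripartite_map(best$pos1, best$pos2, best$length, L,
                          best$mismatches %||% 0)
}

# chain collinear inverted hits (same anti-diagonal) absorbing <= tol mismatches
chain_inverted_hits <- function(hits, L, tol) {
  hits$anti <- (hits$pos1 + hits$pos2 + hits$length - 2) %% L
  hits$mismatches <- 0
  out <- hits
  for (a in unique(hits$anti)) {
    h <- hits[hits$anti == a, , drop = FALSE]
    if (nrow(h) < 2) next
    h <- h[order(h$pos1), ]
    i <- 1
    while (i < nrow(h)) {
      gap <- h$pos1[i + 1] - (h$pos1[i] + h$length[i])
      if (gap >= 1 && h$mismatches[i] + gap <= tol) {
        h$length[i] <- h$pos1[i + 1] + h$length[i + 1] - h$pos1[i]
        h$pos2[i] <- h$pos2[i + 1]
        h$mismatches[i] <- h$mismatches[i] + gap
        h <- h[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    out <- rbind(out[out$anti != a, , drop = FALSE], h)
  }
  out
}

build_quadripartite_map <- function(p1, p2, len, L, mismatches = 0) {
  a_end <- mod1(p1 + len - 1, L)
  b_end <- mod1(p2 + len - 1, L)
  arc_ab <- circ_gap(p1 + len - 1, p2, L)       # arc after copy at p1
  arc_ba <- circ_gap(p2 + len - 1, p1 + L, L)   # arc after copy at p2
  if (arc_ab >= arc_ba) {
    ira <- c(start = p1, end = a_end); irb <- c(start = p2, end = b_end)
    sc1_len <- arc_ab; sc2_len <- arc_ba
  } else {
    ira <- c(start = p2, end = b_end); irb <- c(start = p1, end = a_end)
    sc1_len <- arc_ba; sc2_len <- arc_ab
  }
  sc1 <- c(start = mod1(ira[["end"]] + 1, L),
           end = mod1(ira[["end"]] + sc1_len, L))
  sc2 <- c(start = mod1(irb[["end"]] + 1, L),
           end = mod1(irb[["end"]] + sc2_len, L))
  junctions <- c("IRa|SC1" = ira[["end"]], "SC1|IRb" = sc1[["end"]],
                 "IRb|SC2" = irb[["end"]], "SC2|IRa" = sc2[["end"]])
  structure(list(ir_a = ira, ir_b = irb, ir_length = len,
                 sc1 = sc1, sc2 = sc2, sc1_length = sc1_len,
                 sc2_length = sc2_len, junctions = junctions,
                 mismatches = mismatches, genome_length = L),
            class = "quadripartite_map")
}

#' @export
print.quadripartite_map <- function(x, ...) {
  cat(sprintf("<quadripartite_map> IR %s bp (x2), SC1 %s bp, SC2 %s bp of %s bp\n",
              format(x$ir_length, big.mark = ","),
              format(x$sc1_length, big.mark = ","),
              format(x$sc2_length, big.mark = ","),
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  IRa %d..%d  IRb %d..%d%s\n", x$ir_a[["start"]], x$ir_a[["end"]],
              x$ir_b[["start"]], x$ir_b[["end"]],
              if (x$mismatches > 0) sprintf("  (%d mismatches absorbed)", x$mismatches) else ""))
  invisible(x)
}

# bp of a feature's intervals inside a circular region (start,len)
feature_bp_in_region <- function(starts, ends, rstart, rlen, L) {
  tot <- 0
  for (k in seq_along(starts)) {
    iv_len <- ends[k] - starts[k] + 1
    off <- (starts[k] - rstart) %% L
    # overlap of [off, off+iv_len) with [0, rlen) on the circle
    if (off < rlen) tot <- tot + min(iv_len, rlen - off)
    # wrapped tail of the interval past the origin of the region
    if (off + iv_len > L) tot <- tot + min(off + iv_len - L, rlen)
  }
  tot
}

#' Compare IR/single-copy junctions between two genomes
#'
#' For each of the four junctions of each quadripartite map, reports the gene
#' spanning the junction (and how many bp of it lie inside the IR — the "ebb
#' and flow" signal), or, when the junction falls in an intergenic spacer,
#' the nearest gene and its distance.
#'
#' @param map_a,map_b `quadripartite_map`s from [detect_inverted_repeat()].
#' @param a,b The corresponding annotated [plastome()]s.
#' @return A list of two `data.frame`s (one per genome) with columns
#'   `junction`, `position`, `gene`, `spans_junction`, `bp_in_ir`, `distance`.
#' @export
compare_junctions <- function(map_a, a, map_b, b) {
  if (is.null(map_a) || is.null(map_b))
    stop("unsupported comparison: both genomes must have a detected IR")
  list(a = junction_report(map_a, a), b = junction_report(map_b, b))
}

junction_report <- function(map, p) {
  stopifnot(inherits(map, "quadripartite_map"), inherits(p, "plastome"))
  gr <- p$features
  mc <- S4Vectors::mcols(gr)
  sel <- mc$kind %in% c("gene", "tRNA", "rRNA")
  gr <- gr[sel]
  nm <- mc$name[sel]
  L <- p$length
  ir_for_junction <- list(
    "IRa|SC1" = map$ir_a, "SC1|IRb" = map$ir_b,
    "IRb|SC2" = map$ir_b, "SC2|IRa" = map$ir_a)
  rows <- lapply(names(map$junctions), function(jn) {
    jpos <- map$junctions[[jn]]
    nxt <- mod1(jpos + 1, L)
    ir <- ir_for_junction[[jn]]
    ir_start <- ir[["start"]]
    ir_len <- map$ir_length
    st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
    spans <- st <= jpos & en >= nxt & st <= en  # non-wrapping intervals only
    if (nxt < jpos) spans <- st <= jpos & en >= nxt # wrap at origin: degenerate
    if (any(spans)) {
      genes <- unique(nm[spans])
      g <- genes[1]
      gsel <- nm == g
      bp <- feature_bp_in_region(st[gsel], en[gsel], ir_start, ir_len, L)
      data.frame(junction = jn, position = jpos, gene = g,
                 spans_junction = TRUE, bp_in_ir = bp, distance = 0L,
                 stringsAsFactors = FALSE)
    } else if (length(gr) == 0) {
      data.frame(junction = jn, position = jpos, gene = NA_character_,
                 spans_junction = FALSE, bp_in_ir = 0L, distance = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      dist_circ <- pmin((st - jpos) %% L, (jpos - en) %% L)
      i <- which.min(dist_circ)
      data.frame(junction = jn, position = jpos, gene = nm[i],
                 spans_junction = FALSE, bp_in_ir = 0L,
                 distance = as.integer(dist_circ[i]), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
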