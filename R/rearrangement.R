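#' Extract the shared signed gene order of two plastomes
#'
#' Builds the signed permutation relating the circular gene orders of two
#' annotated genomes over their shared gene set:
#' \itemize{
#'   \item the shared set is the intersection of gene names (kinds `gene`,
#'     `tRNA`, `rRNA`), optionally intersected with `gene_list`;
#'   \item genes duplicated in the inverted repeat are collapsed to the copy
#'     inside IR-A (a quadripartite map must be supplied when duplicates
#'     exist); a gene duplicated outside the IR is an error;
#'   \item trans-spliced (multi-interval) genes are represented once, at
#'     their 5'-most exon (the first stored interval);
#'   \item each circle is linearized by cutting just before the anchor gene
#'     and flipping, if needed, so the anchor reads forward; genome `a` then
#'     maps to the identity and genome `b` to a signed permutation of
#'     `1..n`.
#' }
#'
#' @param a,b Annotated [plastome()]s.
#' @param gene_list Optional character vector restricting the shared set.
#' @param map_a,map_b Optional [detect_inverted_repeat()] maps used to
#'   collapse IR-duplicated genes.
#' @param anchor Anchor gene name; default the first shared gene of `a`.
#' @return A `signed_gene_order` object: `n`, `anchor`, `genes` (names in
#'   identity order), `perm` (genome `b` as a signed permutation).
#' @export
extract_shared_order <- function(a, b, gene_list = NULL,
                                 map_a = NULL, map_b = NULL, anchor = NULL) {
  ga <- gene_positions(a, map_a)
  gb <- gene_positions(b, map_b)
  shared <- intersect(ga$name, gb$name)
  if (!is.null(gene_list)) shared <- intersect(shared, gene_list)
  if (length(shared) < 3)
    stop("insufficient data: fewer than 3 shared genes")
  ga <- ga[ga$name %in% shared, ]
  gb <- gb[gb$name %in% shared, ]
  if (is.null(anchor)) anchor <- ga$name[1]
  if (!anchor %in% shared) stop("anchor gene '", anchor, "' is not shared")
  oa <- linearize_at(ga, anchor)
  ob <- linearize_at(gb, anchor)
  ids <- stats::setNames(seq_along(oa$name), oa$name)
  sign_a <- stats::setNames(oa$sign, oa$name)
  perm <- as.integer(ids[ob$name] * ob$sign * sign_a[ob$name])
  structure(list(n = length(shared), anchor = anchor,
                 genes = oa$name, perm = perm),
            class = "signed_gene_order")
}

# per-genome table of gene name, representative position (start of the
# 5'-most exon) and sign, ordered around the circle
gene_positions <- function(p, map = NULL) {
  stopifnot(inherits(p, "plastome"))
  gr <- p$features
  mc <- S4Vectors::mcols(gr)
  sel <- mc$kind %in% c("gene", "tRNA", "rRNA") & mc$part == 1
  df <- data.frame(name = mc$name[sel],
                   pos = BiocGenerics::start(gr[sel]),
                   sign = ifelse(as.character(BiocGenerics::strand(gr[sel])) == "-",
                                 -1L, 1L),
                   stringsAsFactors = FALSE)
  dup <- names(which(table(df$name) > 1))
  if (length(dup)) {
    if (is.null(map))
      stop("duplicated gene(s) ", paste(dup, collapse = ", "),
           ": supply a quadripartite map to collapse IR copies")
    L <- p$length
    keep <- rep(TRUE, nrow(df))
    for (g in dup) {
      idx <- which(df$name == g)
      in_a <- circ_inside(df$pos[idx], map$ir_a[["start"]], map$ir_length, L)
      in_b <- circ_inside(df$pos[idx], map$ir_b[["start"]], map$ir_length, L)
      if (!all(in_a | in_b) || sum(in_a) != 1)
        stop("duplication error: gene '", g, "' duplicated outside the IR")
      keep[idx[!in_a]] <- FALSE
    }
    df <- df[keep, ]
  }
  df[order(df$pos), ]
}

# rotate a circular order to start at the anchor; flip so the anchor is +
linearize_at <- function(df, anchor) {
  i <- match(anchor, df$name)
  n <- nrow(df)
  rot <- df[c(i:n, seq_len(i - 1))[seq_len(n)], , drop = FALSE]
  if (rot$sign[1] < 0) {
    rot <- rot[c(1, n:2)[seq_len(n)], , drop = FALSE]
    rot$sign <- -rot$sign
  }
  rot
}

#' @export
print.signed_gene_order <- function(x, ...) {
  cat(sprintf("<signed_gene_order> n=%d, anchor=%s\n", x$n, x$anchor))
  cat("  perm:", paste(x$perm, collapse = " "), "\n")
  invisible(x)
}

#' Exact signed reversal distance (breakpoint graph)
#'
#' Computes the minimum number of reversals transforming a signed permutation
#' into the identity, via the breakpoint graph of the framed permutation:
#' `d = (n + 1) - c + h + f`, with `c` alternating cycles, `h` hurdles
#' (minimal unoriented components plus a greatest hurdle when one contains
#' all others) and `f` the fortress indicator. Hurdle and fortress handling
#' is implemented in full even though close plastome pairs rarely exercise
#' it.
#'
#' @param order A `signed_gene_order` from [extract_shared_order()], or an
#'   integer vector that is a signed permutation of `1..n`.
#' @return A `breakpoint_graph_summary`: `n`, `cycles`, `hurdles`,
#'   `fortress`, `d`.
#' @export
reversal_distance <- function(order) {
  perm <- as_signed_perm(order)
  s <- hp_summary_cpp(perm)
  structure(s, class = "breakpoint_graph_summary")
}

as_signed_perm <- function(order) {
  if (inherits(order, "signed_gene_order")) return(order$perm)
  if (!is.numeric(order) || any(order != as.integer(order)))
    stop("validation error: not a signed permutation")
  as.integer(order)
}

#' @export
print.breakpoint_graph_summary <- function(x, ...) {
  cat(sprintf("<breakpoint_graph_summary> n=%d cycles=%d hurdles=%d fortress=%s -> d=%d\n",
              x$n, x$cycles, x$hurdles, x$fortress, x$d))
  invisible(x)
}

#' A minimum-length sorting scenario of reversals
#'
#' Returns a sequence of exactly `d` reversals (1-based position ranges)
#' transforming the permutation into the identity; each step is found
#' greedily among distance-reducing reversals.
#'
#' @inheritParams reversal_distance
#' @return `data.frame` with columns `start`, `end` (positions of each
#'   reversed block, applied in order). Zero rows for the identity.
#' @export
sorting_scenario <- function(order) {
  perm <- as_signed_perm(order)
  m <- sorting_scenario_cpp(perm)
  as.data.frame(m)
}

#' Apply one reversal to a signed permutation
#'
#' Reverses the block `start..end` and flips its signs.
#'
#' @param perm Integer signed permutation.
#' @param start,end 1-based block bounds.
#' @return The rearranged permutation.
#' @export
apply_reversal <- function(perm, start, end) {
  stopifnot(start >= 1, end <= length(perm), start <= end)
  perm[start:end] <- -rev(perm[start:end])
  perm
}

#' Exhaustive reversal distances by breadth-first search
#'
#' Brute-force oracle: BFS over the full reversal graph from the identity.
#' Feasible for `n <= 7`; used to validate [reversal_distance()].
#'
#' @param perms Integer matrix, one signed permutation per row.
#' @return Integer vector of exact distances.
#' @export
reversal_distance_bfs <- function(perms) {
  if (is.vector(perms)) perms <- matrix(as.integer(perms), nrow = 1)
  bfs_distances_cpp(perms)
}

#' Count substitutions between two aligned sequences
#'
#' Plug-in pairwise estimator: columns containing a gap or `N` in either
#' sequence are dropped, then the per-site distance is estimated under the
#' chosen model (raw Hamming proportion, or the JC69/K80 closed-form
#' maximum-likelihood corrections via [ape::dist.dna()]) and scaled by the
#' number of retained sites. This replaces tree-based codon-model branch
#' lengths with a simple pairwise distance; an externally computed count can
#' be fed directly to [rearrangement_rate()] instead.
#'
#' @param a,b Aligned sequences (equal-length character strings; `-` for
#'   gaps).
#' @param model `"K80"` (default), `"JC69"` or `"raw"`.
#' @return A `substitution_estimate`: `s` (substitution count), `sites`,
#'   `distance` (per site), `se` (standard error of `s`; `NA` for raw),
#'   `model`.
#' @export
pairwise_substitutions <- function(a, b, model = c("K80", "JC69", "raw")) {
  model <- match.arg(model)
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) stop("sequences are not aligned (unequal lengths)")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  sites <- length(av)
  if (sites == 0) stop("no comparable sites after dropping gap/N columns")
  if (model == "raw") {
    s <- sum(av != bv)
    return(structure(list(s = s, sites = sites, distance = s / sites,
                          se = NA_real_, model = model),
                     class = "substitution_estimate"))
  }
  bin <- ape::as.DNAbin(rbind(a = av, b = bv))
  d <- ape::dist.dna(bin, model = model, variance = TRUE)
  v <- attr(d, "variance")
  d <- as.numeric(d)
  if (!is.finite(d) || d < 0)
    stop("saturation error: ", model, " distance undefined for these sequences")
  structure(list(s = d * sites, sites = sites, distance = d,
                 se = sqrt(v) * sites, model = model),
            class = "substitution_estimate")
}

#' @export
print.substitution_estimate <- function(x, ...) {
  cat(sprintf("<substitution_estimate> %s: %.1f substitutions over %d sites (d=%.4f/site)\n",
              x$model, x$s, x$sites, x$distance))
  invisible(x)
}

#' Rearrangement rate: reversals per 1,000 substitutions
#'
#' @param r Number of reversals.
#' @param s Number of substitutions over the compared alignment (a bare
#'   count or a `substitution_estimate`).
#' @return A `rate_estimate`: `reversals`, `substitutions`, `rate`
#'   (reversals per 1,000 substitutions).
#' @export
rearrangement_rate <- function(r, s) {
  if (inherits(s, "substitution_estimate")) s <- s$s
  stopifnot(is.numeric(r), r >= 0, is.numeric(s))
  if (s <= 0) stop("undefined rate: substitution count must be positive")
  structure(list(reversals = r, substitutions = s, rate = 1000 * r / s),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %g reversal(s) / %g substitutions = %.2f per 1,000\n",
              x$reversals, x$substitutions, x$rate))
  invisible(x)
}
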