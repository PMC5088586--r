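# Dispersed-repeat accounting must not be dominated by the quadripartite IR
# itself: hits whose two copies simply restate the IRa/IRb duplication (one
# copy inside each IR copy, inverted) are dropped. Repeats dispersed within
# the IR copies still count.
drop_ir_pair_hits <- function(hits, map, L) {
  if (is.null(map) || nrow(hits) == 0) return(hits)
  in_reg <- function(pos, len, reg)
    circ_inside(pos, reg[["start"]], map$ir_length, L) &
      circ_inside(mod1(pos + len - 1, L), reg[["start"]], map$ir_length, L)
  ir_pair <- hits$orientation == "inverted" &
    ((in_reg(hits$pos1, hits$length, map$ir_a) &
        in_reg(hits$pos2, hits$length, map$ir_b)) |
       (in_reg(hits$pos1, hits$length, map$ir_b) &
          in_reg(hits$pos2, hits$length, map$ir_a)))
  hits[!ir_pair, , drop = FALSE]
}

#' Full two-genome comparison
#'
#' Orchestrates the whole pipeline — genome accounting, inverted-repeat and
#' junction mapping, shared gene order and reversal distance with a sorting
#' scenario and (when a substitution count or alignment is available) the
#' rearrangement rate, dispersed-repeat coverage, intron distribution, and
#' EBS/IBS pairing with the mobility classification. Repeat coverage counts
#' dispersed repeats only: the hit restating the IRa/IRb duplication itself
#' is excluded. Stages whose inputs are
#' missing (e.g. no intron registry) are marked `"absent"` in the report,
#' never silently zeroed; a failing stage raises an error naming the stage.
#'
#' @param a,b Annotated [plastome()]s.
#' @param gene_list Optional reference gene list for shared-order
#'   extraction and conserved-gene counting.
#' @param registry Optional intron registry `data.frame`.
#' @param pairing_table Optional pairing table `data.frame` (see
#'   [read_pairing_table()]).
#' @param substitutions Optional externally computed substitution count for
#'   the rate estimate (a number or `substitution_estimate`).
#' @param min_ir_len,min_repeat_len Detection thresholds.
#' @return A `comparison_report`.
#' @export
compare_genomes <- function(a, b, gene_list = NULL, registry = NULL,
                            pairing_table = NULL, substitutions = NULL,
                            min_ir_len = 5000, min_repeat_len = 30) {
  stopifnot(inherits(a, "plastome"), inherits(b, "plastome"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  has_genes <- function(p)
    any(S4Vectors::mcols(p$features)$kind %in% c("gene", "tRNA", "rRNA"))

  stats <- stage("stats", list(
    a = if (has_genes(a)) annotation_accounting(a, gene_list) else basic_stats(a),
    b = if (has_genes(b)) annotation_accounting(b, gene_list) else basic_stats(b)))

  map_a <- stage("ir", detect_inverted_repeat(a, min_len = min_ir_len))
  map_b <- stage("ir", detect_inverted_repeat(b, min_len = min_ir_len))
  junctions <- if (!is.null(map_a) && !is.null(map_b) &&
                   has_genes(a) && has_genes(b))
    stage("junctions", compare_junctions(map_a, a, map_b, b)) else "absent"

  rearr <- if (has_genes(a) && has_genes(b)) stage("rearrangement", {
    ord <- extract_shared_order(a, b, gene_list = gene_list,
                                map_a = map_a, map_b = map_b)
    dsum <- reversal_distance(ord)
    scen <- sorting_scenario(ord)
    rate <- if (!is.null(substitutions))
      rearrangement_rate(dsum$d, substitutions) else "absent"
    list(order = ord, distance = dsum, scenario = scen, rate = rate)
  }) else "absent"

  repeats <- stage("repeats", {
    ha <- drop_ir_pair_hits(find_maximal_repeats(a, min_len = min_repeat_len),
                            map_a, a$length)
    hb <- drop_ir_pair_hits(find_maximal_repeats(b, min_len = min_repeat_len),
                            map_b, b$length)
    list(a = list(hits = ha, mask = mask_coverage(ha, a$length, a$circular)),
         b = list(hits = hb, mask = mask_coverage(hb, b$length, b$circular)))
  })

  introns <- if (!is.null(registry)) stage("introns", {
    reg <- positional_homologs(registry)
    list(registry = reg, matrix = distribution_matrix(reg),
         counts = intron_counts(reg))
  }) else "absent"

  pairing <- if (!is.null(pairing_table)) stage("pairing", {
    fam <- pairing_family(pairing_table)
    profiles <- lapply(fam, function(m) list(
      id = m$id,
      ebs1 = pairing_profile(m$ebs1, m$site$ibs1),
      ebs2 = pairing_profile(m$ebs2, m$site$ibs2),
      delta = pairing_profile(m$delta, m$site$delta_prime)))
    sig <- if (length(fam) >= 3) mobility_signature(fam) else "absent"
    list(profiles = profiles, signature = sig)
  }) else "absent"

  structure(list(ids = c(a = a$id, b = b$id), stats = stats,
                 quadripartite = list(a = map_a, b = map_b,
                                      junctions = junctions),
                 rearrangement = rearr, repeats = repeats,
                 introns = introns, pairing = pairing,
                 params = list(gene_list = !is.null(gene_list),
                               min_ir_len = min_ir_len,
                               min_repeat_len = min_repeat_len)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n", x$ids[["a"]], x$ids[["b"]]))
  for (g in c("a", "b")) {
    st <- x$stats[[g]]
    cat(sprintf("  [%s] %s bp, A+T %.1f%%", x$ids[[g]],
                format(st$length, big.mark = ","), 100 * st$at_fraction))
    if (!is.na(st$n_conserved_genes))
      cat(sprintf(", %d conserved genes, introns %.1f%%, intergenic %.1f%%",
                  st$n_conserved_genes, 100 * st$intron_fraction,
                  100 * st$intergenic_fraction))
    map <- x$quadripartite[[g]]
    if (!is.null(map)) cat(sprintf(", IR %s bp",
                                   format(map$ir_length, big.mark = ",")))
    mask <- x$repeats[[g]]$mask
    cat(sprintf(", repeats %.1f%%\n", 100 * mask$coverage))
  }
  if (!identical(x$rearrangement, "absent")) {
    d <- x$rearrangement$distance
    cat(sprintf("  shared genes n=%d, reversal distance d=%d\n", d$n, d$d))
    if (!identical(x$rearrangement$rate, "absent"))
      cat(sprintf("  rate: %.2f reversals per 1,000 substitutions\n",
                  x$rearrangement$rate$rate))
  }
  if (!identical(x$introns, "absent")) {
    cat("  intron counts:\n")
    print(x$introns$counts)
  }
  if (!identical(x$pairing, "absent") &&
      !identical(x$pairing$signature, "absent"))
    cat(sprintf("  mobility signature: %s (D=%.2f, C=%.2f)\n",
                x$pairing$signature$classification,
                x$pairing$signature$D, x$pairing$signature$C))
  invisible(x)
}

#' Write a comparison report to a directory
#'
#' Emits a human-readable `report.txt` (the printed report plus parameter
#' echo) and machine-readable TSVs containing the same numbers: per-genome
#' stats, IR/SC coordinates, the sorting scenario, repeat hits, the intron
#' matrix and the pairing evidence.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  header <- c("# plastarch comparison report",
              paste("# params:", paste(names(report$params),
                                       unlist(report$params), sep = "=",
                                       collapse = " ")))
  writeLines(c(header, utils::capture.output(print(report))),
             file.path(dir, "report.txt"))

  st <- do.call(rbind, lapply(c("a", "b"), function(g) {
    s <- report$stats[[g]]
    data.frame(genome = report$ids[[g]], length = s$length,
               at_fraction = s$at_fraction,
               n_conserved_genes = s$n_conserved_genes,
               coding_fraction = s$coding_fraction,
               intron_fraction = s$intron_fraction,
               intergenic_fraction = s$intergenic_fraction,
               mean_intergenic_size = s$mean_intergenic_size,
               repeat_coverage = report$repeats[[g]]$mask$coverage)
  }))
  w(st, "stats.tsv")
  qp <- do.call(rbind, lapply(c("a", "b"), function(g) {
    m <- report$quadripartite[[g]]
    if (is.null(m)) return(NULL)
    data.frame(genome = report$ids[[g]], region = c("IRa", "IRb", "SC1", "SC2"),
               start = c(m$ir_a[["start"]], m$ir_b[["start"]],
                         m$sc1[["start"]], m$sc2[["start"]]),
               end = c(m$ir_a[["end"]], m$ir_b[["end"]],
                       m$sc1[["end"]], m$sc2[["end"]]),
               length = c(m$ir_length, m$ir_length, m$sc1_length,
                          m$sc2_length))
  }))
  if (!is.null(qp)) w(qp, "quadripartite.tsv")
  if (!identical(report$rearrangement, "absent")) {
    w(report$rearrangement$scenario, "scenario.tsv")
    d <- report$rearrangement$distance
    w(data.frame(n = d$n, cycles = d$cycles, hurdles = d$hurdles,
                 fortress = d$fortress, d = d$d), "reversal_distance.tsv")
  }
  for (g in c("a", "b"))
    w(report$repeats[[g]]$hits, paste0("repeats_", report$ids[[g]], ".tsv"))
  if (!identical(report$introns, "absent")) {
    m <- report$introns$matrix
    w(data.frame(taxon = rownames(m), m, check.names = FALSE),
      "intron_matrix.tsv")
  }
  if (!identical(report$pairing, "absent") &&
      !identical(report$pairing$signature, "absent"))
    w(report$pairing$signature$evidence, "pairing_evidence.tsv")
  invisible(dir)
}
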