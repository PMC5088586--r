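#' Target site of a group IIA intron
#'
#' The DNA target recognized by an intron ribonucleoprotein: the last 24 nt
#' of the 5' exon (positions -24..-1, holding the intron-binding sites IBS1
#' and IBS2) and the first nucleotides of the 3' exon (holding delta-prime).
#' Default window geometry is the canonical IIA layout: IBS1 at -6..-1
#' (abutting the intron), IBS2 at -13..-7, delta-prime at +1.
#'
#' @param exon5 At least the last 13 nt of the 5' exon (24 recommended).
#' @param exon3 First nucleotides of the 3' exon (>= `delta_len`).
#' @param ibs1_len,ibs2_len,delta_len Window lengths (defaults 6, 7, 1;
#'   delta may be 1-3).
#' @return A `target_site` with the window sequences and coordinates.
#' @export
target_site <- function(exon5, exon3, ibs1_len = 6, ibs2_len = 7,
                        delta_len = 1) {
  exon5 <- normalize_dna(exon5); exon3 <- normalize_dna(exon3)
  n5 <- nchar(exon5)
  stopifnot(delta_len >= 1, delta_len <= 3)
  if (n5 < ibs1_len + ibs2_len)
    stop("exon5 too short for the IBS windows")
  if (nchar(exon3) < delta_len) stop("exon3 shorter than delta_len")
  ibs1 <- substr(exon5, n5 - ibs1_len + 1, n5)
  ibs2 <- substr(exon5, n5 - ibs1_len - ibs2_len + 1, n5 - ibs1_len)
  structure(list(exon5 = exon5, exon3 = exon3,
                 ibs1 = ibs1, ibs2 = ibs2,
                 delta_prime = substr(exon3, 1, delta_len),
                 windows = list(ibs1 = c(-ibs1_len, -1),
                                ibs2 = c(-ibs1_len - ibs2_len, -ibs1_len - 1),
                                delta_prime = c(1, delta_len))),
            class = "target_site")
}

PAIR_WC <- c(A = "T", T = "A", G = "C", C = "G")

#' Base-pairing profile of an intron motif against its exon window
#'
#' Pairs the intron motif (5'->3') antiparallel against the exon window
#' (read 3'->5'), anchored at the intron-proximal ends, and classifies each
#' position as Watson-Crick (`WC`), `wobble` (G.T/T.G, counted as pairing
#' when `allow_wobble`), or `mismatch`. The verdict operationalizes
#' "perfect or nearly perfect complementarity": `perfect` with 0
#' mismatches, `near_perfect` with exactly 1, otherwise `incompatible`.
#'
#' @param motif Intron-side motif (EBS1, EBS2 or delta), 5'->3'.
#' @param window Exon-side window (IBS1, IBS2 or delta-prime), 5'->3'.
#' @param allow_wobble Count G.T pairs as pairing (default `TRUE`); when
#'   `FALSE` they are tallied as mismatches.
#' @return A `pairing_profile`: `pairing` (per-position classes), `n_wc`,
#'   `n_wobble`, `n_mismatch`, `verdict`.
#' @export
pairing_profile <- function(motif, window, allow_wobble = TRUE) {
  motif <- normalize_dna(motif); window <- normalize_dna(window)
  stopifnot(nzchar(motif), nzchar(window))
  if (abs(nchar(motif) - nchar(window)) > 2)
    stop("annotation error: motif/window length mismatch > 2")
  m <- strsplit(motif, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])  # antiparallel
  len <- min(length(m), length(w))
  m <- m[seq_len(len)]; w <- w[seq_len(len)]
  wc <- PAIR_WC[m] == w & !is.na(PAIR_WC[m])
  wob <- (m == "G" & w == "T") | (m == "T" & w == "G")
  cls <- ifelse(wc, "WC", ifelse(wob, "wobble", "mismatch"))
  n_wc <- sum(wc)
  n_wob <- sum(wob)
  n_mm <- if (allow_wobble) len - n_wc - n_wob else len - n_wc
  if (!allow_wobble) n_wob <- 0L
  verdict <- if (n_mm == 0) "perfect" else if (n_mm == 1) "near_perfect"
             else "incompatible"
  structure(list(pairing = cls, n_wc = as.integer(n_wc),
                 n_wobble = as.integer(n_wob), n_mismatch = as.integer(n_mm),
                 verdict = verdict, allow_wobble = allow_wobble),
            class = "pairing_profile")
}

#' @export
print.pairing_profile <- function(x, ...) {
  cat(sprintf("<pairing_profile> %s (WC=%d wobble=%d mismatch=%d): %s\n",
              paste(substr(x$pairing, 1, 1), collapse = ""),
              x$n_wc, x$n_wobble, x$n_mismatch, x$verdict))
  invisible(x)
}

#' Locate an exon-binding site within an intron
#'
#' Slides a window of the requested length over the search region of the
#' intron and returns the subsequence maximizing pairing (WC + wobble)
#' against the exon window; ties are broken by the smallest start
#' coordinate. When no candidate pairs at half its length or better, a
#' not-found result is returned.
#'
#' @param intron_seq Intron sequence.
#' @param search_region `c(start, end)` 1-based bounds to scan.
#' @param window Exon window the motif must pair with.
#' @param length Motif length to search for.
#' @param allow_wobble Passed to [pairing_profile()].
#' @return List with `found`, and when found `motif`, `start`, `end`,
#'   `score`.
#' @export
locate_ebs <- function(intron_seq, search_region, window, length,
                       allow_wobble = TRUE) {
  intron_seq <- normalize_dna(intron_seq)
  stopifnot(length(search_region) == 2,
            search_region[1] >= 1, search_region[2] <= nchar(intron_seq),
            length <= search_region[2] - search_region[1] + 1)
  best <- list(score = -1L, start = NA_integer_)
  for (s in search_region[1]:(search_region[2] - length + 1)) {
    cand <- substr(intron_seq, s, s + length - 1)
    pp <- pairing_profile(cand, window, allow_wobble = allow_wobble)
    score <- pp$n_wc + pp$n_wobble
    if (score > best$score) best <- list(score = score, start = s, motif = cand)
  }
  if (best$score < length / 2) return(list(found = FALSE))
  list(found = TRUE, motif = best$motif, start = best$start,
       end = best$start + length - 1, score = best$score)
}

#' Column-wise conservation of an intron alignment
#'
#' For each column of a gapped alignment, counts the maximum residue
#' multiplicity (gaps never count as residues), and reports
#' `f(k)` = fraction of columns in which at least `k` sequences carry the
#' identical residue.
#'
#' @param aligned Character vector of equal-length gapped sequences (`-` or
#'   `.` for gaps).
#' @param k Conservation threshold(s) of interest (default 6, the "in six
#'   or more introns" convention).
#' @return A `consensus_profile`: `n_introns`, `length`, `max_multiplicity`
#'   per column, and `f` (named vector over `k`).
#' @export
consensus_conservation <- function(aligned, k = 6) {
  stopifnot(is.character(aligned), length(aligned) >= 2)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1)
    stop("validation error: ragged alignment")
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  mm <- apply(m, 2, function(col) {
    col <- col[!col %in% c("-", ".")]
    if (!length(col)) 0L else max(table(col))
  })
  f <- vapply(k, function(kk) mean(mm >= kk), 0)
  names(f) <- paste0("f", k)
  structure(list(n_introns = length(aligned), length = lens[1],
                 max_multiplicity = as.integer(mm), f = f),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile> %d sequences, %d columns; %s\n",
              x$n_introns, x$length,
              paste(sprintf("%s=%.1f%%", names(x$f), 100 * x$f),
                    collapse = ", ")))
  invisible(x)
}

#' Classify how an intron family spread: retrohoming vs retrotransposition
#'
#' Two dispersal pathways leave opposite signatures in the exon-binding
#' sites of an intron family. Under ectopic retrohoming, each copy's
#' EBS1/EBS2/delta motifs diverge to match its own new target site, so
#' motifs differ between copies (high inter-copy divergence `D`) yet each
#' copy pairs perfectly or nearly perfectly with its own site (high
#' self-compatibility `C`). Under retrotransposition, motifs stay
#' near-ancestral and tolerate mismatches at the colonized sites (low `C`).
#'
#' `D` is the mean pairwise mismatch fraction across members' concatenated
#' EBS1+EBS2+delta motifs; `C` is the fraction of members whose EBS1 and
#' EBS2 verdicts are both `perfect` or `near_perfect` against their own
#' site. Defaults: retrohoming-like when `D >= 0.2` and `C >= 0.8`;
#' retrotransposition-like when `C < 0.5`; otherwise indeterminate (e.g. a
#' family of identical, perfectly pairing motifs carries no divergence
#' signal). The thresholds are package defaults validated by
#' synthetic-recovery tests, not literature constants.
#'
#' @param family List of members, each a list with `ebs1`, `ebs2`, `delta`
#'   motif strings and `site` (a [target_site()]).
#' @param d_min Minimum divergence for the retrohoming call (default 0.2).
#' @param c_min Minimum self-compatibility for retrohoming (default 0.8).
#' @param c_max Self-compatibility below which the family is
#'   retrotransposition-like (default 0.5).
#' @param allow_wobble Passed to [pairing_profile()].
#' @return A `mobility_signature`: `classification`, `D`, `C`, and a
#'   per-member `evidence` table.
#' @export
mobility_signature <- function(family, d_min = 0.2, c_min = 0.8, c_max = 0.5,
                               allow_wobble = TRUE) {
  if (length(family) < 3)
    stop("insufficient family: at least 3 members are required")
  concat <- vapply(family, function(m)
    paste0(m$ebs1, m$ebs2, m$delta), "")
  if (length(unique(nchar(concat))) != 1)
    stop("members have unequal concatenated motif lengths")
  cm <- do.call(rbind, strsplit(concat, ""))
  n <- nrow(cm)
  pairs <- utils::combn(n, 2)
  D <- mean(apply(pairs, 2, function(ij) mean(cm[ij[1], ] != cm[ij[2], ])))
  ev <- lapply(seq_along(family), function(i) {
    m <- family[[i]]
    p1 <- pairing_profile(m$ebs1, m$site$ibs1, allow_wobble)
    p2 <- pairing_profile(m$ebs2, m$site$ibs2, allow_wobble)
    pd <- pairing_profile(m$delta, m$site$delta_prime, allow_wobble)
    data.frame(member = i,
               ebs1_verdict = p1$verdict, ebs2_verdict = p2$verdict,
               delta_verdict = pd$verdict,
               compatible = p1$verdict %in% c("perfect", "near_perfect") &&
                 p2$verdict %in% c("perfect", "near_perfect"),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  C <- mean(ev$compatible)
  classification <- if (C < c_max) "retrotransposition_like"
    else if (D >= d_min && C >= c_min) "retrohoming_like"
    else "indeterminate"
  structure(list(classification = classification, D = D, C = C,
                 evidence = ev,
                 thresholds = c(d_min = d_min, c_min = c_min, c_max = c_max)),
            class = "mobility_signature")
}

#' @export
print.mobility_signature <- function(x, ...) {
  cat(sprintf("<mobility_signature> %s (D=%.2f, C=%.2f, n=%d)\n",
              x$classification, x$D, x$C, nrow(x$evidence)))
  invisible(x)
}

#' Read a pairing table: one intron copy per row
#'
#' Columns: `intron_id`, `host_gene`, `ebs1`, `ebs2`, `delta`, `exon5`
#' (last 24 nt of the 5' exon), `exon3` (first nt of the 3' exon).
#'
#' @param path TSV file.
#' @param delta_len delta-prime window length (default 1).
#' @return A list of family members suitable for [mobility_signature()],
#'   with the table attached as attribute `"table"`.
#' @export
read_pairing_table <- function(path, delta_len = 1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  pairing_family(df, delta_len = delta_len)
}

#' Build a mobility family from a pairing table
#' @param df `data.frame` with the columns of [read_pairing_table()].
#' @param delta_len delta-prime window length.
#' @return List of members (`ebs1`, `ebs2`, `delta`, `site`).
#' @export
pairing_family <- function(df, delta_len = 1) {
  req <- c("intron_id", "ebs1", "ebs2", "delta", "exon5", "exon3")
  if (!all(req %in% names(df)))
    stop("pairing table lacks column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  fam <- lapply(seq_len(nrow(df)), function(i) {
    list(id = df$intron_id[i], ebs1 = df$ebs1[i], ebs2 = df$ebs2[i],
         delta = df$delta[i],
         site = target_site(df$exon5[i], df$exon3[i], delta_len = delta_len))
  })
  attr(fam, "table") <- df
  fam
}
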