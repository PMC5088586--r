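# Synthetic plastomes with recorded ground truth. Defaults emulate the
# architecture of an oedogonialean chloroplast genome: ~204 kb circle at
# A+T 0.70, ~100 conserved genes, a 23.7-kb IR housing the rRNA operon, and
# a larger/smaller single-copy split.

PLASTID_GENES <- c(
  "atpA", "atpB", "atpE", "atpF", "atpH", "atpI", "ccsA", "cemA", "chlB",
  "chlL", "chlN", "clpP", "cysA", "cysT", "ftsH", "infA", "petA", "petB",
  "petD", "petG", "petL", "psaA", "psaB", "psaC", "psaJ", "psbA", "psbB",
  "psbC", "psbD", "psbE", "psbF", "psbH", "psbI", "psbJ", "psbK", "psbL",
  "psbM", "psbN", "psbT", "psbZ", "rbcL", "rpl2", "rpl5", "rpl12", "rpl14",
  "rpl16", "rpl19", "rpl20", "rpl23", "rpl32", "rpl36", "rpoA", "rpoB",
  "rpoC1", "rpoC2", "rps2", "rps3", "rps4", "rps7", "rps8", "rps9", "rps11",
  "rps12", "rps14", "rps18", "rps19", "tufA", "ycf1", "ycf3", "ycf4",
  "ycf12", "ycf20", "ycf47", "ycf62",
  paste0("trn", c("A-UGC2", "C-GCA", "D-GUC", "E-UUC", "F-GAA", "G-GCC",
                  "H-GUG", "I-CAU", "K-UUU", "L-UAA", "L-UAG", "Me-CAU",
                  "Mf-CAU", "N-GUU", "P-UGG", "Q-UUG", "R-ACG", "R-UCU",
                  "S-GCU", "S-UGA", "T-UGU", "V-UAC", "W-CCA", "Y-GUA",
                  "G-UCC", "R-CCG", "S-GGA", "T-GGU", "V-GAC", "L-CAA")))

RRNA_OPERON <- data.frame(
  name = c("rrs", "trnI-GAU", "trnA-UGC", "rrl", "rrf"),
  kind = c("rRNA", "tRNA", "tRNA", "rRNA", "rRNA"),
  len = c(1480L, 75L, 75L, 2900L, 120L),
  stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' One top-level seed drives independent per-component substreams, so that
#' (for example) changing repeat planting does not perturb reversal
#' sampling; identical configurations give byte-identical outputs.
#'
#' @param seed Integer master seed.
#' @param genome_length Circle size in bp (default 204,438).
#' @param at_fraction Background A+T proportion (default 0.702).
#' @param n_genes Number of distinct conserved genes (the rRNA-operon block
#'   is part of this count when an IR is planted).
#' @param ir_length Planted inverted-repeat copy length in bp (default
#'   23,748; 0 for an IR-less genome).
#' @param sc1_fraction Fraction of the non-IR circle given to the larger
#'   single-copy region (default 0.63).
#' @param gene_length_range Sampled gene lengths in bp.
#' @param k_reversals Reversals applied by [apply_reversals()] when driven
#'   from a config.
#' @param subst_distance Per-site substitution distance for
#'   [evolve_sequence()] (default 0.07, the order implied by one reversal at
#'   0.38 reversals per 1,000 substitutions over a 37-kb data set).
#' @param kappa Transition/transversion ratio for the K80 model.
#' @param repeat_coverage_target Target masked repeat coverage (default
#'   0.113).
#' @param repeat_length_range Planted repeat lengths in bp.
#' @param family_size Group IIA intron family size (default 6).
#' @param mobility_mode `"retrohoming"` or `"retrotransposition"`.
#' @param ebs_divergence Minimum inter-copy motif divergence planted in
#'   retrohoming mode.
#' @param site_mismatches Minimum per-element EBS/IBS mismatches planted in
#'   retrotransposition mode.
#' @param delta_len delta/delta-prime pairing length (1-3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_length = 204438, at_fraction = 0.702,
                       n_genes = 100, ir_length = 23748, sc1_fraction = 0.63,
                       gene_length_range = c(300, 1500), k_reversals = 1,
                       subst_distance = 0.07, kappa = 2,
                       repeat_coverage_target = 0.113,
                       repeat_length_range = c(30, 500), family_size = 6,
                       mobility_mode = c("retrohoming", "retrotransposition"),
                       ebs_divergence = 0.2, site_mismatches = 2,
                       delta_len = 1) {
  mobility_mode <- match.arg(mobility_mode)
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              at_fraction = at_fraction, n_genes = n_genes,
              ir_length = ir_length, sc1_fraction = sc1_fraction,
              gene_length_range = gene_length_range,
              k_reversals = k_reversals, subst_distance = subst_distance,
              kappa = kappa,
              repeat_coverage_target = repeat_coverage_target,
              repeat_length_range = repeat_length_range,
              family_size = family_size, mobility_mode = mobility_mode,
              ebs_divergence = ebs_divergence,
              site_mismatches = site_mismatches, delta_len = delta_len)
  stopifnot(cfg$genome_length > 0, cfg$n_genes >= 0, cfg$ir_length >= 0,
            cfg$at_fraction >= 0, cfg$at_fraction <= 1,
            cfg$sc1_fraction > 0.5, cfg$sc1_fraction < 1,
            cfg$repeat_coverage_target >= 0, cfg$repeat_coverage_target < 0.5,
            cfg$family_size >= 0, cfg$delta_len %in% 1:3)
  structure(cfg, class = "sim_config")
}

# distribute `extra` bp over n spacers of at least `min_gap` bp each
random_spacers <- function(n, total, min_gap = 20) {
  if (total < n * min_gap) stop("config error: infeasible packing")
  extra <- total - n * min_gap
  if (n == 1) return(total)
  w <- stats::runif(n)
  add <- floor(extra * w / sum(w))
  add[1] <- add[1] + (extra - sum(add))
  min_gap + add
}

#' Simulate a plastome with a planted quadripartite architecture
#'
#' Generates a circular genome of `genome_length` bp at the configured A+T
#' fraction, with `n_genes` named, stranded genes. When `ir_length > 0`, an
#' exact inverted repeat containing the rRNA-operon block (rrs, trnI, trnA,
#' rrl, rrf) is planted, the remaining genes are packed into the two
#' single-copy arcs (sized by `sc1_fraction`), and the IR flanks are set so
#' that the planted repeat is maximal — it cannot be extended by one
#' position in either direction.
#'
#' @param config A [sim_config()].
#' @return List with `plastome` and `truth` (planted IR/SC coordinates,
#'   gene order and strands).
#' @export
simulate_plastome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  ir <- config$ir_length
  withr::with_seed(seed_stream(config$seed, 1), {
    feats <- NULL
    if (ir > 0) {
      if (L < 2 * ir + 200) stop("config error: genome too small for the IR")
      if (config$n_genes < nrow(RRNA_OPERON) + 3)
        stop("config error: need at least ", nrow(RRNA_OPERON) + 3,
             " genes with an IR")
      op_total <- sum(RRNA_OPERON$len)
      n_sp <- nrow(RRNA_OPERON) + 1
      if (ir < op_total + n_sp * 20)
        stop("config error: ir_length too small for the rRNA operon")
      sp <- random_spacers(n_sp, ir - op_total)
      # sequential layout inside IR-A (IR-A occupies [1, ir])
      cur <- 0
      ir_rows <- NULL
      for (i in seq_len(nrow(RRNA_OPERON))) {
        cur <- cur + sp[i]
        ir_rows <- rbind(ir_rows, data.frame(
          name = RRNA_OPERON$name[i], kind = RRNA_OPERON$kind[i],
          strand = "+", start = cur + 1, end = cur + RRNA_OPERON$len[i],
          stringsAsFactors = FALSE))
        cur <- cur + RRNA_OPERON$len[i]
      }
      sc_pool <- setdiff(PLASTID_GENES, RRNA_OPERON$name)
      n_sc <- config$n_genes - nrow(RRNA_OPERON)
      sc_start1 <- ir + 1
      rest <- L - 2 * ir
      sc1_len <- round(rest * config$sc1_fraction)
      sc2_len <- rest - sc1_len
      irb_start <- ir + sc1_len + 1
      sc2_start <- irb_start + ir
    } else {
      ir_rows <- NULL
      sc_pool <- PLASTID_GENES
      n_sc <- config$n_genes
      sc_start1 <- 1
      sc1_len <- L
      sc2_len <- 0
      irb_start <- NA
      sc2_start <- NA
    }
    if (n_sc > length(sc_pool))
      sc_pool <- c(sc_pool, sprintf("ycf%03d", seq_len(n_sc)))
    sc_names <- if (n_sc > 0) sample(sc_pool, n_sc) else character()
    n1 <- if (sc2_len > 0) round(n_sc * sc1_len / (sc1_len + sc2_len)) else n_sc
    region_genes <- list(
      list(names = utils::head(sc_names, n1), start = sc_start1, len = sc1_len),
      list(names = utils::tail(sc_names, n_sc - n1),
           start = sc2_start, len = sc2_len))
    sc_rows <- NULL
    for (rg in region_genes) {
      ng <- length(rg$names)
      if (ng == 0) next
      glens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                      ng, replace = TRUE)
      if (sum(glens) + (ng + 1) * 20 > rg$len)
        stop("config error: infeasible packing of genes into a single-copy region")
      sp <- random_spacers(ng + 1, rg$len - sum(glens))
      cur <- rg$start - 1
      for (i in seq_len(ng)) {
        cur <- cur + sp[i]
        sc_rows <- rbind(sc_rows, data.frame(
          name = rg$names[i], kind = gene_kind(rg$names[i]),
          strand = sample(c("+", "-"), 1), start = cur + 1,
          end = cur + glens[i], stringsAsFactors = FALSE))
        cur <- cur + glens[i]
      }
    }
    seqc <- random_dna(L, config$at_fraction)
    if (ir > 0) {
      ira_seq <- substr(seqc, 1, ir)
      irb_end <- irb_start + ir - 1
      substr(seqc, irb_start, irb_end) <- revcomp(ira_seq)
      # break one-position extensions so the planted IR is maximal
      seqc <- break_ir_extension(seqc, L, ir, irb_start, irb_end)
      # mirror the operon genes into IR-B (position x of IR-A maps to
      # irb_start + ir - x)
      irb_rows <- ir_rows
      irb_rows$start <- irb_start + (ir - ir_rows$end)
      irb_rows$end <- irb_start + (ir - ir_rows$start)
      irb_rows$strand <- "-"
      ir_feats <- data.frame(
        name = c("IRa", "IRb"), kind = "IR", strand = c("+", "-"),
        start = c(1, irb_start), end = c(ir, irb_end),
        stringsAsFactors = FALSE)
      feats <- rbind(ir_rows, irb_rows, sc_rows, ir_feats)
    } else {
      feats <- sc_rows
    }
    if (!is.null(feats)) {
      feats <- feats[order(feats$start, feats$end), ]
      rownames(feats) <- NULL
    }
    p <- plastome(sprintf("sim%08d", config$seed), seqc, features = feats,
                  circular = TRUE)
    truth <- list(
      ir = if (ir > 0) c(a_start = 1, a_end = ir, b_start = irb_start,
                         b_end = irb_end) else NULL,
      ir_length = ir,
      sc1 = if (ir > 0) c(start = ir + 1, end = ir + sc1_len) else NULL,
      sc2 = if (ir > 0) c(start = sc2_start, end = L) else NULL,
      gene_order = if (!is.null(feats))
        feats[feats$kind %in% c("gene", "tRNA", "rRNA"),
              c("name", "strand", "start", "end")] else NULL,
      config = config)
    list(plastome = p, truth = truth)
  })
}

gene_kind <- function(name) {
  if (grepl("^trn", name)) "tRNA"
  else if (grepl("^rr(s|l|f)", name)) "rRNA"
  else "gene"
}

# adjust the four IR flank positions so neither copy can be extended
break_ir_extension <- function(seqc, L, ir, irb_start, irb_end) {
  fix <- function(s, i, forbidden) {
    cur <- substr(s, i, i)
    if (cur == forbidden) {
      repl <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
      substr(s, i, i) <- repl
    }
    s
  }
  comp1 <- function(b) chartr("ACGTN", "TGCAN", b)
  # left of IR-A (position L) vs right of IR-B (irb_end + 1)
  seqc <- fix(seqc, mod1(irb_end + 1, L), comp1(substr(seqc, L, L)))
  # right of IR-A (ir + 1) vs left of IR-B (irb_start - 1)
  seqc <- fix(seqc, irb_start - 1, comp1(substr(seqc, ir + 1, ir + 1)))
  seqc
}

#' Apply random segmental reversals to a plastome
#'
#' Each reversal picks two cut points in intergenic gaps (never splitting a
#' gene, and never splitting an IR copy) and reverse-complements the
#' enclosed segment, flipping the strands and coordinates of the features
#' inside. The ground truth records each reversal's cut coordinates.
#'
#' @param x An annotated [plastome()] (typically from
#'   [simulate_plastome()]).
#' @param k Number of reversals.
#' @param seed Integer seed.
#' @return List with `plastome` and `truth` (a `data.frame` of the applied
#'   cuts).
#' @export
apply_reversals <- function(x, k, seed = 1) {
  stopifnot(inherits(x, "plastome"), k >= 0)
  L <- x$length
  cuts <- data.frame(start = integer(), end = integer())
  withr::with_seed(seed_stream(seed, 2), {
    for (rep_i in seq_len(k)) {
      ft <- feature_table(x)
      genes <- ft[ft$kind %in% c("gene", "tRNA", "rRNA"), ]
      genes <- genes[order(genes$start), ]
      irf <- ft[ft$kind == "IR", ]
      if (nrow(genes) < 2) stop("need at least 2 genes to reverse between")
      # candidate cut points: midpoints of inter-gene gaps (linear view)
      ends <- genes$end[-nrow(genes)]
      starts <- genes$start[-1]
      mids <- floor((ends + starts) / 2)
      mids <- mids[starts - ends >= 3]
      if (nrow(irf)) {
        inside_ir <- rep(FALSE, length(mids))
        for (j in seq_len(nrow(irf)))
          inside_ir <- inside_ir | (mids >= irf$start[j] & mids <= irf$end[j])
        mids <- mids[!inside_ir]
      }
      ok <- FALSE
      for (try_i in 1:200) {
        cc <- sort(sample(mids, 2))
        seg <- c(cc[1] + 1, cc[2])
        # the segment may not touch an IR copy at all: reversing one copy
        # would turn the inverted repeat into a direct one
        if (nrow(irf) && any(irf$start <= seg[2] & irf$end >= seg[1])) next
        # no interval may straddle a cut, and every multi-part feature must
        # be entirely in or out
        fid <- paste(ft$name, ft$kind)
        inside <- ft$start >= seg[1] & ft$end <= seg[2]
        touching <- ft$end >= seg[1] & ft$start <= seg[2]
        if (any(touching & !inside)) next
        mixed <- tapply(inside, fid, function(z) any(z) && !all(z))
        if (any(mixed)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place a reversal without splitting a feature")
      x <- reverse_segment(x, seg[1], seg[2])
      cuts <- rbind(cuts, data.frame(start = seg[1], end = seg[2]))
    }
  })
  list(plastome = x, truth = list(reversals = cuts, k = k))
}

# reverse-complement [l, r] of the genome and remap the features inside
reverse_segment <- function(x, l, r) {
  s <- x$sequence
  substr(s, l, r) <- revcomp(substr(s, l, r))
  ft <- feature_table(x)
  inside <- ft$start >= l & ft$end <= r
  if (any(inside)) {
    ns <- l + r - ft$end[inside]
    ne <- l + r - ft$start[inside]
    ft$start[inside] <- ns
    ft$end[inside] <- ne
    ft$strand[inside] <- ifelse(ft$strand[inside] == "+", "-", "+")
  }
  ft <- ft[order(ft$start, ft$end), ]
  rownames(ft) <- NULL
  plastome(x$id, s, features = ft, circular = x$circular)
}

#' Evolve a sequence under a nucleotide substitution model
#'
#' Independent per-site substitution at the given expected distance under
#' JC69 or K80 (with transition/transversion ratio `kappa`). `N` sites are
#' left untouched.
#'
#' @param seq DNA string.
#' @param distance Expected substitutions per site.
#' @param model `"JC69"` or `"K80"`.
#' @param kappa K80 transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
evolve_sequence <- function(seq, distance, model = c("JC69", "K80"),
                            kappa = 2, seed = 1) {
  model <- match.arg(model)
  stopifnot(distance >= 0)
  seq <- normalize_dna(seq)
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
  TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  withr::with_seed(seed_stream(seed, 3), {
    if (model == "JC69") {
      p_change <- 3 / 4 * (1 - exp(-4 * distance / 3))
      hit <- stats::runif(n) < p_change & v != "N"
      if (any(hit)) {
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      }
    } else {
      beta <- distance / (kappa + 2)
      alpha <- kappa * beta
      p_ts <- 1 / 4 + 1 / 4 * exp(-4 * beta) - 1 / 2 * exp(-2 * (alpha + beta))
      p_tv <- 1 / 4 - 1 / 4 * exp(-4 * beta)  # each of the two transversions
      u <- stats::runif(n)
      is_ts <- u < p_ts & v != "N"
      is_tv1 <- u >= p_ts & u < p_ts + p_tv & v != "N"
      is_tv2 <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv & v != "N"
      v[is_ts] <- TRANSITION[v[is_ts]]
      v[is_tv1] <- vapply(v[is_tv1], function(b) TRANSVERSIONS[[b]][1], "")
      v[is_tv2] <- vapply(v[is_tv2], function(b) TRANSVERSIONS[[b]][2], "")
    }
  })
  paste(v, collapse = "")
}

#' Plant dispersed repeats to a target masked coverage
#'
#' Copies unique source segments into intergenic positions until the true
#' masked coverage (union of all source and destination intervals) reaches
#' the target. Planted copies become `repeat_region` features; sources never
#' overlap IR copies, so recovered coverage is attributable to the plant.
#'
#' @param x An annotated [plastome()].
#' @param coverage_target Fraction of the genome to cover (< 0.5).
#' @param length_range Sampled repeat lengths (min >= 30).
#' @param seed Integer seed.
#' @param orientation `"direct"` or `"inverted"` copies.
#' @return List with `plastome` and `truth` (planted intervals and exact
#'   coverage).
#' @export
plant_repeats <- function(x, coverage_target = 0.113,
                          length_range = c(30, 500), seed = 1,
                          orientation = c("direct", "inverted")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "plastome"), coverage_target >= 0,
            coverage_target < 0.5)
  L <- x$length
  truth_iv <- IRanges::IRanges()
  planted <- data.frame(start = integer(), end = integer(),
                        source_start = integer(), source_end = integer())
  if (coverage_target > 0) withr::with_seed(seed_stream(seed, 4), {
    s <- x$sequence
    ft <- feature_table(x)
    n_rep <- 0
    for (iter in 1:10000) {
      cov_now <- sum(IRanges::width(IRanges::reduce(truth_iv))) / L
      if (cov_now >= coverage_target) break
      occupied <- IRanges::reduce(IRanges::IRanges(ft$start, ft$end))
      gaps <- IRanges::gaps(occupied, start = 1, end = L)
      len <- sample(length_range[1]:length_range[2], 1)
      cand <- gaps[IRanges::width(gaps) >= len + 4]
      if (length(cand) == 0) {
        if (len > length_range[1]) next
        stop("config error: insufficient intergenic space for repeat planting")
      }
      g <- cand[sample(length(cand), 1)]
      off <- sample(0:(IRanges::width(g) - len - 4), 1)
      d1 <- IRanges::start(g) + 2 + off
      d2 <- d1 + len - 1
      # source segment: anywhere outside the IR and the destination
      irf <- ft[ft$kind == "IR", ]
      src <- NA
      for (t in 1:100) {
        s1 <- sample(L - len, 1)
        s2 <- s1 + len - 1
        if (s2 >= d1 - 2 && s1 <= d2 + 2) next
        if (nrow(irf) && any(irf$start <= s2 & irf$end >= s1)) next
        if (grepl("N", substr(s, s1, s2), fixed = TRUE)) next
        src <- s1
        break
      }
      if (is.na(src)) next
      piece <- substr(s, src, src + len - 1)
      if (orientation == "inverted") piece <- revcomp(piece)
      substr(s, d1, d2) <- piece
      n_rep <- n_rep + 1
      ft <- rbind(ft, data.frame(name = sprintf("rep%03d", n_rep),
                                 kind = "repeat_region", strand = "+",
                                 start = d1, end = d2, part = 1L, attrs = "",
                                 stringsAsFactors = FALSE))
      truth_iv <- c(truth_iv, IRanges::IRanges(c(d1, src), c(d2, src + len - 1)))
      planted <- rbind(planted, data.frame(start = d1, end = d2,
                                           source_start = src,
                                           source_end = src + len - 1))
    }
    cov_now <- sum(IRanges::width(IRanges::reduce(truth_iv))) / L
    if (cov_now < coverage_target)
      stop("config error: insufficient intergenic space for repeat planting")
    ft <- ft[order(ft$start, ft$end), ]
    x <- plastome(x$id, s, features = ft, circular = x$circular)
  })
  list(plastome = x,
       truth = list(planted = planted,
                    coverage = sum(IRanges::width(IRanges::reduce(truth_iv))) / L))
}

# mutate m random positions of a DNA string to different bases
mutate_positions <- function(s, m) {
  if (m == 0) return(s)
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), min(m, length(v)))
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Plant a group IIA intron family with a known dispersal mode
#'
#' Builds one ancestral IIA intron core and inserts diverged copies at
#' distinct sites in distinct host genes of a compact synthetic genome. In
#' retrohoming mode each copy's EBS1/EBS2/delta motifs are rewritten to the
#' reverse complement of its own IBS windows (with 0-1 residual mismatches
#' per exon-binding site), so motifs diverge between copies while each pairs
#' with its own site; host sites are resampled until inter-copy motif
#' divergence reaches `ebs_divergence`. In retrotransposition mode the
#' motifs stay near-ancestral and host sites are resampled until each
#' element shows at least `site_mismatches` mismatches.
#'
#' @param config A [sim_config()] (uses `family_size`, `mobility_mode`,
#'   `ebs_divergence`, `site_mismatches`, `delta_len`, `seed`).
#' @return List with `plastome` (hosts with introns inserted), `registry`
#'   (intron registry rows), `pairing_table`, and `truth` (mode and
#'   per-copy motifs/sites).
#' @export
plant_intron_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  fam_n <- config$family_size
  if (fam_n < 3) stop("config error: family_size must be at least 3")
  mode <- config$mobility_mode
  dlen <- config$delta_len
  withr::with_seed(seed_stream(config$seed, 5), {
    hosts <- sample(setdiff(PLASTID_GENES, RRNA_OPERON$name), fam_n)
    core <- random_dna(500, 0.65)
    e2c <- c(150, 156); e1c <- c(200, 205); dc <- c(210, 210 + dlen - 1)
    anc <- list(ebs1 = substr(core, e1c[1], e1c[2]),
                ebs2 = substr(core, e2c[1], e2c[2]),
                delta = substr(core, dc[1], dc[2]))
    members <- NULL
    for (attempt in 1:60) {
      members <- lapply(seq_len(fam_n), function(i) {
        hlen <- sample(700:1200, 1)
        hseq <- random_dna(hlen, 0.60)
        for (t in 1:300) {
          site <- sample(200:(hlen - 150), 1)
          ibs1 <- substr(hseq, site - 5, site)
          ibs2 <- substr(hseq, site - 12, site - 6)
          dp <- substr(hseq, site + 1, site + dlen)
          if (mode == "retrohoming") {
            ebs1 <- mutate_positions(revcomp(ibs1), sample(0:1, 1))
            ebs2 <- mutate_positions(revcomp(ibs2), sample(0:1, 1))
            delta <- revcomp(dp)
            break
          } else {
            ebs1 <- mutate_positions(anc$ebs1, sample(0:1, 1))
            ebs2 <- mutate_positions(anc$ebs2, sample(0:1, 1))
            delta <- anc$delta
            mm1 <- pairing_profile(ebs1, ibs1)$n_mismatch
            mm2 <- pairing_profile(ebs2, ibs2)$n_mismatch
            if (mm1 >= config$site_mismatches &&
                mm2 >= config$site_mismatches) break
          }
        }
        list(host = hosts[i], host_seq = hseq, site = site,
             ebs1 = ebs1, ebs2 = ebs2, delta = delta)
      })
      if (mode != "retrohoming") break
      concat <- vapply(members, function(m) paste0(m$ebs1, m$ebs2, m$delta), "")
      cm <- do.call(rbind, strsplit(concat, ""))
      prs <- utils::combn(fam_n, 2)
      D <- mean(apply(prs, 2, function(ij) mean(cm[ij[1], ] != cm[ij[2], ])))
      if (D >= config$ebs_divergence) break
    }
    # build intron copies and the host genome
    spacer <- 150
    seq_parts <- character()
    feats <- NULL
    registry <- NULL
    ptable <- NULL
    cur <- 0
    for (i in seq_len(fam_n)) {
      m <- members[[i]]
      icopy <- core
      substr(icopy, e1c[1], e1c[2]) <- m$ebs1
      substr(icopy, e2c[1], e2c[2]) <- m$ebs2
      substr(icopy, dc[1], dc[2]) <- m$delta
      ilen <- nchar(icopy)
      with_intron <- paste0(substr(m$host_seq, 1, m$site), icopy,
                            substr(m$host_seq, m$site + 1, nchar(m$host_seq)))
      gs <- cur + spacer + 1
      ge <- gs + nchar(with_intron) - 1
      feats <- rbind(feats,
        data.frame(name = m$host, kind = "gene", strand = "+",
                   start = c(gs, gs + m$site + ilen),
                   end = c(gs + m$site - 1, ge),
                   part = 1:2, attrs = "", stringsAsFactors = FALSE),
        data.frame(name = paste0(m$host, ".i1"), kind = "intron",
                   strand = "+", start = gs + m$site,
                   end = gs + m$site + ilen - 1, part = 1L,
                   attrs = "intron_class=IIA;splicing=cis",
                   stringsAsFactors = FALSE))
      registry <- rbind(registry, data.frame(
        taxon = "synthetic", host_gene = m$host, intron_class = "IIA",
        splicing = "cis", site = m$site, orf_domains = "",
        sequence = icopy, stringsAsFactors = FALSE))
      ptable <- rbind(ptable, data.frame(
        intron_id = paste0(m$host, ".i1"), host_gene = m$host,
        ebs1 = m$ebs1, ebs2 = m$ebs2, delta = m$delta,
        exon5 = substr(m$host_seq, m$site - 23, m$site),
        exon3 = substr(m$host_seq, m$site + 1, m$site + 3),
        stringsAsFactors = FALSE))
      seq_parts <- c(seq_parts, random_dna(spacer, config$at_fraction),
                     with_intron)
      cur <- ge
    }
    seq_all <- paste0(paste(seq_parts, collapse = ""),
                      random_dna(spacer, config$at_fraction))
    p <- plastome(sprintf("fam%08d", config$seed), seq_all, features = feats,
                  circular = TRUE)
    truth <- list(mode = mode,
                  motifs = lapply(members, function(m)
                    m[c("host", "site", "ebs1", "ebs2", "delta")]))
    list(plastome = p, registry = intron_registry(registry),
         pairing_table = ptable, truth = truth)
  })
}
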