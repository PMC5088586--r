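test_that("a motif pairs perfectly with the reverse complement of its window", {
  set.seed(131)
  for (i in 1:5) {
    x <- random_dna(6, 0.5)
    pp <- pairing_profile(x, revcomp(x))
    expect_equal(pp$n_wc, 6L)
    expect_equal(pp$n_mismatch, 0L)
    expect_equal(pp$verdict, "perfect")
  }
})

test_that("one true mismatch gives near_perfect, two incompatible", {
  ebs1 <- "GTTCAA"
  ibs1 <- revcomp(ebs1)            # TTGAAC
  expect_equal(pairing_profile(ebs1, ibs1)$verdict, "perfect")
  # A<->C substitutions cannot create G.T wobbles
  sub1 <- ibs1; substr(sub1, 3, 3) <- "C"   # G opposite G
  p1 <- pairing_profile(ebs1, sub1)
  expect_equal(p1$n_mismatch, 1L)
  expect_equal(p1$verdict, "near_perfect")
  sub2 <- sub1; substr(sub2, 4, 4) <- "C"
  expect_equal(pairing_profile(ebs1, sub2)$verdict, "incompatible")
})

test_that("wobble pairs count as pairing only when allowed", {
  # EBS G opposite window T (antiparallel) is a wobble
  pp <- pairing_profile("G", "T")
  expect_equal(pp$n_wobble, 1L)
  expect_equal(pp$verdict, "perfect")
  pp2 <- pairing_profile("G", "T", allow_wobble = FALSE)
  expect_equal(pp2$n_mismatch, 1L)
  expect_equal(pp2$verdict, "near_perfect")
  # disabling wobble never increases the pairing count
  set.seed(133)
  for (i in 1:20) {
    m <- random_dna(6, 0.5); w <- random_dna(6, 0.5)
    with_w <- pairing_profile(m, w, TRUE)
    without <- pairing_profile(m, w, FALSE)
    expect_lte(without$n_wc + without$n_wobble,
               with_w$n_wc + with_w$n_wobble)
  }
})

test_that("a single-nucleotide delta unable to pair is incompatible", {
  expect_equal(pairing_profile("A", "A")$verdict, "near_perfect")
  expect_equal(pairing_profile("A", "T")$verdict, "perfect")
})

test_that("motif/window length mismatch beyond 2 is an annotation error", {
  expect_error(pairing_profile("ACGTAA", "ACG"), "annotation error")
})

test_that("locate_ebs recovers a planted motif and breaks ties leftward", {
  set.seed(137)
  ibs1 <- "TTGAAC"
  motif <- revcomp(ibs1)
  intron <- paste0(random_dna(80, 0.3), motif, random_dna(60, 0.3))
  hit <- locate_ebs(intron, c(1, nchar(intron)), ibs1, 6)
  expect_true(hit$found)
  expect_equal(hit$motif, motif)
  expect_equal(hit$start, 81)
  expect_equal(hit$score, 6)

  # two equal-scoring candidates: leftmost wins
  intron2 <- paste0(random_dna(30, 0.3), motif, random_dna(30, 0.3), motif)
  hit2 <- locate_ebs(intron2, c(1, nchar(intron2)), ibs1, 6)
  expect_equal(hit2$start, 31)
})

test_that("locate_ebs finds a planted motif with one mutation among decoys", {
  set.seed(139)
  for (i in 1:10) {
    ibs1 <- random_dna(6, 0.5)
    motif <- revcomp(ibs1)
    mutated <- motif
    pos <- sample(6, 1)
    substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                         substr(motif, pos, pos))[2]
    intron <- paste0(random_dna(70, 0.75), mutated, random_dna(50, 0.75))
    hit <- locate_ebs(intron, c(1, nchar(intron)), ibs1, 6)
    expect_true(hit$found)
    expect_gte(hit$score, 5)
  }
})

test_that("locate_ebs reports not-found when nothing pairs", {
  # an all-A intron cannot pair with an all-A window (A.A never pairs)
  res <- locate_ebs(strrep("A", 50), c(1, 50), strrep("A", 6), 6)
  expect_false(res$found)
})

test_that("consensus conservation counts identical residues per column", {
  aln <- rep(strrep("ACGT", 10), 8)
  cp <- consensus_conservation(aln, k = 6)
  expect_equal(unname(cp$f["f6"]), 1)
  # max multiplicity 2 everywhere: no column reaches 6
  aln2 <- rep(c("AAAA", "CCCC", "GGGG", "TTTT"), 2)
  expect_equal(unname(consensus_conservation(aln2, 6)$f["f6"]), 0)
  # gaps never count as residues
  aln3 <- c(rep("A-", 6), rep("CA", 2))
  cp3 <- consensus_conservation(aln3, k = 6)
  expect_equal(cp3$max_multiplicity, c(6L, 2L))
  expect_error(consensus_conservation(c("AC", "ACG")), "ragged")
})

test_that("a planted conservation fraction is recovered exactly", {
  set.seed(141)
  ncol <- 400
  conserved <- sample(ncol, 312)  # 78%
  m <- matrix("", 8, ncol)
  for (j in seq_len(ncol)) {
    if (j %in% conserved) {
      base <- sample(c("A", "C", "G", "T"), 1)
      others <- sample(setdiff(c("A", "C", "G", "T"), base), 2)
      m[, j] <- c(rep(base, 6), others)
    } else {
      m[, j] <- sample(rep(c("A", "C", "G", "T"), 2))  # multiplicity 2
    }
  }
  aln <- apply(m, 1, paste, collapse = "")
  cp <- consensus_conservation(aln, k = 6)
  expect_equal(unname(cp$f["f6"]), 0.78)
  # f is non-increasing in k and invariant under column permutation
  fk <- consensus_conservation(aln, k = 1:8)$f
  expect_true(all(diff(fk) <= 0))
  perm <- sample(ncol)
  aln_perm <- apply(m[, perm], 1, paste, collapse = "")
  expect_equal(consensus_conservation(aln_perm, 6)$f, cp$f)
})

test_that("identical perfectly pairing motifs are indeterminate", {
  site <- target_site(paste0(random_dna(11, 0.5), "GCAGTAC", "TTGAAC"), "TAA")
  member <- list(ebs1 = revcomp(site$ibs1), ebs2 = revcomp(site$ibs2),
                 delta = revcomp(site$delta_prime), site = site)
  fam <- list(member, member, member)
  sig <- mobility_signature(fam)
  expect_equal(sig$classification, "indeterminate")
  expect_equal(sig$D, 0)
  expect_equal(sig$C, 1)
})

test_that("families below three members are rejected", {
  expect_error(mobility_signature(list(list(), list())),
               "insufficient family")
})

test_that("the mobility call is invariant under member reordering", {
  fam <- plant_intron_family(sim_config(seed = 143, family_size = 6,
                                        mobility_mode = "retrohoming"))
  members <- pairing_family(fam$pairing_table)
  s1 <- mobility_signature(members)
  s2 <- mobility_signature(rev(members))
  expect_equal(s1$classification, s2$classification)
  expect_equal(s1$D, s2$D)
  expect_equal(s1$C, s2$C)
})

test_that("generator modes are classified as planted", {
  fam_rh <- plant_intron_family(sim_config(seed = 147, family_size = 6,
                                           mobility_mode = "retrohoming"))
  sig_rh <- mobility_signature(pairing_family(fam_rh$pairing_table))
  expect_equal(sig_rh$classification, "retrohoming_like")
  expect_gte(sig_rh$D, 0.2)
  expect_gte(sig_rh$C, 0.8)

  fam_rt <- plant_intron_family(sim_config(seed = 147, family_size = 6,
                                           mobility_mode = "retrotransposition"))
  sig_rt <- mobility_signature(pairing_family(fam_rt$pairing_table))
  expect_equal(sig_rt$classification, "retrotransposition_like")
  expect_lt(sig_rt$C, 0.5)
})

test_that("target sites carry the canonical IIA window geometry", {
  exon5 <- random_dna(24, 0.5)
  ts <- target_site(exon5, "GAT")
  expect_equal(ts$ibs1, substr(exon5, 19, 24))
  expect_equal(ts$ibs2, substr(exon5, 12, 18))
  expect_equal(ts$delta_prime, "G")
  expect_equal(ts$windows$ibs1, c(-6, -1))
  expect_equal(ts$windows$ibs2, c(-13, -7))
  expect_error(target_site("ACGT", "G"), "too short")
})
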