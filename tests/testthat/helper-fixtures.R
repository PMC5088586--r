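# Small fixtures built in code.

# a hand-sized annotated circular genome: L = 1000, one 600-bp gene with a
# 100-bp intron inside it, leaving 300 bp intergenic
tiny_annotated_plastome <- function() {
  set.seed(404)
  feats <- data.frame(
    name = c("psbA", "psbA", "psbA.i1"),
    kind = c("gene", "gene", "intron"),
    strand = "+",
    start = c(101, 451, 351),
    end = c(350, 800, 450),
    part = c(1L, 2L, 1L),
    attrs = c("", "", "intron_class=I;splicing=cis"),
    stringsAsFactors = FALSE)
  plastome("tiny", random_dna(1000, 0.6), features = feats)
}

# genome of `L` bp with an exact inverted repeat of `ir` bp planted at
# [a_start, .] and [b_start, .], flanks fixed so the repeat is maximal
ir_fixture <- function(L = 2000, ir = 200, a_start = 101, b_start = 1101,
                       seed = 7) {
  set.seed(seed)
  s <- random_dna(L, 0.6)
  copy <- substr(s, a_start, a_start + ir - 1)
  substr(s, b_start, b_start + ir - 1) <- rc_chr(copy)
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  fix <- function(s, i, forbidden) {
    if (substr(s, i, i) == forbidden)
      substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
    s
  }
  s <- fix(s, b_start + ir, comp1(substr(s, a_start - 1, a_start - 1)))
  s <- fix(s, b_start - 1, comp1(substr(s, a_start + ir, a_start + ir)))
  s
}

expect_same_features <- function(got, want) {
  cols <- c("name", "kind", "strand", "start", "end", "part", "attrs")
  g <- got[cols]; w <- want[cols]
  rownames(g) <- rownames(w) <- NULL
  expect_equal(g, w)
}
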