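test_that("FASTA reading normalizes residues and ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "acgt"), f)
  p <- read_fasta(f)
  expect_length(p, 1)
  expect_equal(p[[1]]$id, "x")
  expect_equal(p[[1]]$length, 4)
  expect_equal(p[[1]]$sequence, "ACGT")

  writeLines(c(">x", "ACGU"), f)
  expect_equal(read_fasta(f)[[1]]$sequence, "ACGT")

  writeLines(c(">x", "ACGTACGTACGTACGTACGR"), f)  # rare ambiguity code -> N
  expect_equal(read_fasta(f)[[1]]$sequence, "ACGTACGTACGTACGTACGN")
})

test_that("FASTA format errors are raised", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_error(read_fasta(f), "format error|FASTA")
  writeLines(c(">p", "MKVLLTPEEQ"), f)  # protein: not nucleotide-dominant
  expect_error(read_fasta(f), "nucleotide-dominant")
})

test_that("FASTA round-trips through write_fasta", {
  p <- tiny_annotated_plastome()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p, f)
  p2 <- read_fasta(f)[[1]]
  expect_equal(p2$sequence, p$sequence)
  expect_equal(p2$id, p$id)
})

test_that("TSV feature dialect converts coordinates and joins parts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tkind\tstrand\tstart\tend",
               "psbA\tgene\t+\t1\t1062",
               "rps12\tgene\t-\t2000\t2100",
               "rps12\tgene\t-\t2200\t2300"), f)
  df <- read_feature_table(f, "tsv")
  expect_equal(df$start[1], 1)
  expect_equal(df$end[1], 1062)
  # consecutive rows sharing (name, kind) form one 2-part feature
  expect_equal(df$part, c(1L, 1L, 2L))
  expect_error(read_feature_table(f, "tsv", seq_length = 1500),
               "coordinate error")
})

test_that("GenBank feature-table locations parse to strand and intervals", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "FEATURES             Location/Qualifiers",
    "     gene            complement(10..20)",
    '                     /gene="psbA"',
    "     gene            join(100..150,200..260)",
    '                     /gene="rps12"',
    "     intron          151..199",
    '                     /gene="rps12.i1"',
    '                     /intron_class="IIA"'), f)
  df <- read_feature_table(f, "genbank_ft")
  expect_equal(df$strand[df$name == "psbA"], "-")
  expect_equal(df$start[df$name == "psbA"], 10)
  expect_equal(df$end[df$name == "psbA"], 20)
  r12 <- df[df$name == "rps12", ]
  expect_equal(nrow(r12), 2)
  expect_equal(r12$part, 1:2)
  expect_equal(r12$start, c(100, 200))
  ii <- df[df$name == "rps12.i1", ]
  expect_match(ii$attrs, "intron_class=IIA")
})

test_that("unknown feature kinds warn and are kept as misc", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tkind\tstrand\tstart\tend",
               "mys\tweird_kind\t+\t5\t50"), f)
  expect_warning(df <- read_feature_table(f, "tsv"), "unknown feature kind")
  expect_equal(df$kind, "misc")
  expect_match(df$attrs, "orig_kind=weird_kind")
})

test_that("GFF3 write/read round-trips feature tables losslessly", {
  p <- tiny_annotated_plastome()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(p, f)
  got <- read_feature_table(f, "gff3")
  expect_same_features(got, feature_table(p))

  # a trans-spliced 2-interval gene becomes two GFF3 lines sharing one ID
  lines <- readLines(f)
  ids <- sub(".*ID=([^;]+);.*", "\\1", grep("\tgene\t", lines, value = TRUE))
  expect_length(ids, 2)
  expect_length(unique(ids), 1)
  # GFF3 columns are 1-based inclusive
  expect_match(lines[grep("intron", lines)[1]], "\t351\t450\t")
})

test_that("TSV round-trip is the identity on feature tables", {
  p <- tiny_annotated_plastome()
  ft <- feature_table(p)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ft, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_feature_table(f, "tsv")
  expect_same_features(got, ft)
})

test_that("basic_stats computes A+T excluding N", {
  expect_equal(basic_stats(plastome("a", "ATAT"))$at_fraction, 1.0)
  expect_equal(basic_stats(plastome("b", "ACGT"))$at_fraction, 0.5)
  expect_equal(basic_stats(plastome("c", "ACGTNNNN"))$at_fraction, 0.5)
  expect_error(basic_stats(plastome("d", "NNNN")), "undefined")
})

test_that("at_fraction is invariant under reverse complement", {
  set.seed(11)
  for (i in 1:5) {
    s <- random_dna(500, runif(1, 0.3, 0.8))
    expect_equal(basic_stats(plastome("x", s))$at_fraction,
                 basic_stats(plastome("x", revcomp(s)))$at_fraction)
  }
})

test_that("annotation accounting partitions the genome", {
  p <- tiny_annotated_plastome()   # 600 bp exons, 100 bp intron, 300 bp spacer
  st <- annotation_accounting(p)
  expect_equal(st$n_conserved_genes, 1)
  expect_equal(st$coding_fraction, 0.6)
  expect_equal(st$intron_fraction, 0.1)
  expect_equal(st$intergenic_fraction, 0.3)
  expect_equal(st$coding_fraction + st$intron_fraction +
                 st$intergenic_fraction, 1)
  # two gaps ([1,100] + [801,1000] merge across the origin of the circle)
  expect_equal(st$n_intergenic_gaps, 1)
  expect_equal(st$mean_intergenic_size, 300)
})

test_that("a genome fully covered by one gene has zero intergenic fraction", {
  feats <- data.frame(name = "g", kind = "gene", strand = "+",
                      start = 1, end = 400)
  p <- plastome("full", random_dna(400), features = feats)
  expect_equal(annotation_accounting(p)$intergenic_fraction, 0)
})

test_that("orf features count as intergenic and IR duplicates once", {
  feats <- data.frame(
    name = c("psbA", "orf123", "rrs", "rrs"),
    kind = c("gene", "orf", "rRNA", "rRNA"),
    strand = c("+", "+", "+", "-"),
    start = c(1, 201, 301, 501),
    end = c(200, 300, 400, 600),
    part = 1L, attrs = "", stringsAsFactors = FALSE)
  p <- plastome("x", random_dna(1000), features = feats)
  st <- annotation_accounting(p)
  expect_equal(st$n_conserved_genes, 2)       # psbA + rrs (duplicate once)
  expect_equal(st$coding_fraction, 0.4)       # orf is not coding
  expect_equal(st$intergenic_fraction, 0.6)
})

test_that("partition property holds on simulated genomes", {
  sim <- simulate_plastome(sim_config(seed = 3, genome_length = 30000,
                                      n_genes = 20, ir_length = 6000,
                                      gene_length_range = c(200, 500)))
  st <- annotation_accounting(sim$plastome)
  expect_equal(st$coding_fraction + st$intron_fraction +
                 st$intergenic_fraction, 1)
})
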