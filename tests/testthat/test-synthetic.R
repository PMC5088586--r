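test_that("identical configurations give byte-identical outputs", {
  cfg <- sim_config(seed = 151, genome_length = 30000, n_genes = 15,
                    ir_length = 6000, gene_length_range = c(200, 400))
  s1 <- simulate_plastome(cfg)
  s2 <- simulate_plastome(cfg)
  expect_identical(s1$plastome$sequence, s2$plastome$sequence)
  expect_identical(feature_table(s1$plastome), feature_table(s2$plastome))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s1$plastome, f1); write_fasta(s2$plastome, f2)
  expect_identical(readLines(f1), readLines(f2))

  s3 <- simulate_plastome(sim_config(seed = 152, genome_length = 30000,
                                     n_genes = 15, ir_length = 6000,
                                     gene_length_range = c(200, 400)))
  expect_false(identical(s1$plastome$sequence, s3$plastome$sequence))
})

test_that("n_genes = 0 gives a featureless random circle", {
  sim <- simulate_plastome(sim_config(seed = 153, genome_length = 5000,
                                      n_genes = 0, ir_length = 0))
  expect_equal(length(sim$plastome$features), 0)
  expect_equal(sim$plastome$length, 5000)
})

test_that("the simulated composition tracks the configured A+T fraction", {
  sim <- simulate_plastome(sim_config(seed = 154, genome_length = 50000,
                                      n_genes = 0, ir_length = 0,
                                      at_fraction = 0.702))
  expect_equal(basic_stats(sim$plastome)$at_fraction, 0.702, tolerance = 0.02)
})

test_that("infeasible packing is a config error", {
  expect_error(simulate_plastome(sim_config(seed = 155, genome_length = 9000,
                                            ir_length = 4000, n_genes = 40)),
               "config error")
  expect_error(simulate_plastome(sim_config(seed = 156, genome_length = 50000,
                                            ir_length = 2000, n_genes = 20)),
               "config error")  # IR too small for the rRNA operon
})

test_that("generator output is readable by the I/O layer unchanged", {
  sim <- simulate_plastome(sim_config(seed = 157, genome_length = 30000,
                                      n_genes = 20, ir_length = 6000,
                                      gene_length_range = c(200, 500)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_fasta(sim$plastome, fa)
  write_gff3(sim$plastome, gf)
  p2 <- read_fasta(fa)[[1]]
  ft2 <- read_feature_table(gf, "gff3", seq_length = p2$length)
  expect_identical(p2$sequence, sim$plastome$sequence)
  expect_same_features(ft2, feature_table(sim$plastome))
})

test_that("apply_reversals with k = 0 changes nothing", {
  sim <- simulate_plastome(sim_config(seed = 158, genome_length = 20000,
                                      n_genes = 15, ir_length = 0,
                                      gene_length_range = c(200, 400)))
  out <- apply_reversals(sim$plastome, 0, seed = 1)
  expect_identical(out$plastome$sequence, sim$plastome$sequence)
  expect_identical(feature_table(out$plastome), feature_table(sim$plastome))
  expect_equal(nrow(out$truth$reversals), 0)
})

test_that("one applied reversal means distance one", {
  sim <- simulate_plastome(sim_config(seed = 159, genome_length = 25000,
                                      n_genes = 25, ir_length = 0,
                                      gene_length_range = c(200, 400)))
  out <- apply_reversals(sim$plastome, 1, seed = 2)
  ord <- extract_shared_order(sim$plastome, out$plastome)
  expect_equal(reversal_distance(ord)$d, 1)
  # the reversal never splits a gene: all genes keep their lengths
  w0 <- sort(with(feature_table(sim$plastome), end - start))
  w1 <- sort(with(feature_table(out$plastome), end - start))
  expect_identical(w0, w1)
})

test_that("reversed segments are reverse-complemented in place", {
  sim <- simulate_plastome(sim_config(seed = 160, genome_length = 20000,
                                      n_genes = 15, ir_length = 0,
                                      gene_length_range = c(200, 400)))
  out <- apply_reversals(sim$plastome, 1, seed = 3)
  cut <- out$truth$reversals
  s0 <- sim$plastome$sequence; s1 <- out$plastome$sequence
  expect_identical(substr(s1, cut$start, cut$end),
                   revcomp(substr(s0, cut$start, cut$end)))
  expect_identical(substr(s1, 1, cut$start - 1), substr(s0, 1, cut$start - 1))
})

test_that("evolve_sequence honours distance zero and determinism", {
  s <- random_dna(2000, 0.6)
  expect_identical(evolve_sequence(s, 0, "JC69", seed = 5), s)
  e1 <- evolve_sequence(s, 0.1, "K80", kappa = 3, seed = 5)
  e2 <- evolve_sequence(s, 0.1, "K80", kappa = 3, seed = 5)
  expect_identical(e1, e2)
  expect_false(identical(e1, evolve_sequence(s, 0.1, "K80", 3, seed = 6)))
})

test_that("plant_repeats reaches its target and records exact truth", {
  sim <- simulate_plastome(sim_config(seed = 161, genome_length = 30000,
                                      n_genes = 15, ir_length = 0,
                                      gene_length_range = c(200, 400)))
  none <- plant_repeats(sim$plastome, coverage_target = 0, seed = 1)
  expect_identical(none$plastome$sequence, sim$plastome$sequence)
  expect_equal(none$truth$coverage, 0)

  pr <- plant_repeats(sim$plastome, coverage_target = 0.10,
                      length_range = c(30, 300), seed = 7)
  expect_gte(pr$truth$coverage, 0.10)
  expect_lt(pr$truth$coverage, 0.13)
  # each planted copy equals its source on the final sequence
  s <- pr$plastome$sequence
  for (i in seq_len(nrow(pr$truth$planted))) {
    row <- pr$truth$planted[i, ]
    expect_identical(substr(s, row$start, row$end),
                     substr(s, row$source_start, row$source_end))
  }
})

test_that("direct-only planting yields no inverted hits at min_len", {
  sim <- simulate_plastome(sim_config(seed = 162, genome_length = 30000,
                                      n_genes = 15, ir_length = 0,
                                      gene_length_range = c(200, 400)))
  pr <- plant_repeats(sim$plastome, coverage_target = 0.08,
                      length_range = c(40, 200), seed = 9,
                      orientation = "direct")
  hits <- find_maximal_repeats(pr$plastome, min_len = 40)
  expect_equal(sum(hits$orientation == "inverted"), 0)
  expect_gt(sum(hits$orientation == "direct"), 0)
})

test_that("repeat planting without space is a config error", {
  feats <- data.frame(name = "g", kind = "gene", strand = "+",
                      start = 1, end = 2000)
  p <- plastome("dense", random_dna(2000), features = feats)
  expect_error(plant_repeats(p, coverage_target = 0.2, seed = 1),
               "config error")
})

test_that("intron families need at least three members", {
  expect_error(plant_intron_family(sim_config(seed = 163, family_size = 2)),
               "config error")
})

test_that("planted intron families are deterministic and self-consistent", {
  cfg <- sim_config(seed = 164, family_size = 5)
  f1 <- plant_intron_family(cfg)
  f2 <- plant_intron_family(cfg)
  expect_identical(f1$pairing_table, f2$pairing_table)
  expect_identical(f1$plastome$sequence, f2$plastome$sequence)
  # the registry sequences are really inserted at the annotated sites
  ft <- feature_table(f1$plastome)
  introns <- ft[ft$kind == "intron", ]
  for (i in seq_len(nrow(introns)))
    expect_identical(substr(f1$plastome$sequence, introns$start[i],
                            introns$end[i]),
                     f1$registry$sequence[i])
})
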