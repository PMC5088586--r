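test_that("reversal distance handles the canonical small cases", {
  expect_equal(reversal_distance(1:5)$d, 0)
  d <- reversal_distance(c(1L, -3L, -2L, 4L))
  expect_equal(d$d, 1)
  expect_equal(sorting_scenario(c(1L, -3L, -2L, 4L)),
               data.frame(start = 2L, end = 3L))
  expect_equal(nrow(sorting_scenario(1:6)), 0)
  expect_error(reversal_distance(c(1L, 1L, 2L)), "not a signed permutation")
})

test_that("distance matches the BFS oracle on all n <= 4 permutations", {
  for (n in 2:4) {
    M <- all_signed_perms(n)
    bfs <- reversal_distance_bfs(M)
    hp <- vapply(seq_len(nrow(M)), function(i) reversal_distance(M[i, ])$d,
                 integer(1))
    expect_identical(hp, bfs)
  }
})

test_that("a sorting scenario has length d and sorts to the identity", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    perm <- random_signed_perm(n)
    d <- reversal_distance(perm)$d
    sc <- sorting_scenario(perm)
    expect_equal(nrow(sc), d)
    p <- perm
    for (j in seq_len(nrow(sc))) p <- apply_reversal(p, sc$start[j], sc$end[j])
    expect_identical(p, seq_len(n) * 1L)
  }
})

test_that("distance is invariant under dihedral symmetry of linearization", {
  set.seed(37)
  for (i in 1:10) {
    n <- 12
    perm <- random_signed_perm(n)
    d <- reversal_distance(perm)$d
    # view the circle from the other side: reverse the order, flip the
    # signs, and relabel both source and target consistently
    y <- rev(perm)
    q <- as.integer(sign(y) * ((n + 1L) - abs(y)))
    expect_equal(reversal_distance(q)$d, d)
  }
})

test_that("shared order of identical annotations is the identity", {
  sim <- simulate_plastome(sim_config(seed = 41, genome_length = 30000,
                                      n_genes = 30, ir_length = 0,
                                      gene_length_range = c(200, 500)))
  ord <- extract_shared_order(sim$plastome, sim$plastome)
  expect_equal(ord$perm, seq_len(ord$n))
  expect_equal(ord$n, 30)
})

test_that("planted reversals are recovered as the exact distance", {
  sim <- simulate_plastome(sim_config(seed = 43, genome_length = 40000,
                                      n_genes = 40, ir_length = 0,
                                      gene_length_range = c(200, 450)))
  for (k in c(1, 2)) {
    mut <- apply_reversals(sim$plastome, k, seed = 100 + k)
    ord <- extract_shared_order(sim$plastome, mut$plastome)
    expect_equal(reversal_distance(ord)$d, k)
  }
})

test_that("anchor choice never changes the distance on circular inputs", {
  sim <- simulate_plastome(sim_config(seed = 47, genome_length = 30000,
                                      n_genes = 15, ir_length = 0,
                                      gene_length_range = c(200, 500)))
  mut <- apply_reversals(sim$plastome, 2, seed = 7)
  base <- extract_shared_order(sim$plastome, mut$plastome)
  d0 <- reversal_distance(base)$d
  for (g in base$genes) {
    ord <- extract_shared_order(sim$plastome, mut$plastome, anchor = g)
    expect_equal(reversal_distance(ord)$d, d0)
  }
})

test_that("IR-duplicated genes collapse to one copy, others error", {
  sim <- simulate_plastome(sim_config(seed = 51, genome_length = 40000,
                                      n_genes = 20, ir_length = 6000,
                                      gene_length_range = c(200, 500)))
  p <- sim$plastome
  map <- detect_inverted_repeat(p, min_len = 5000)
  # without a map the rRNA duplicates cannot be resolved
  expect_error(extract_shared_order(p, p), "duplicated gene")
  ord <- extract_shared_order(p, p, map_a = map, map_b = map)
  expect_equal(ord$perm, seq_len(ord$n))
  expect_equal(ord$n, 20)  # duplicates counted once

  # a duplication outside the IR is a hard error naming the gene
  ft <- feature_table(p)
  extra <- ft[ft$name == "rrs" & ft$strand == "+", ][1, ]
  extra$start <- map$sc1[["start"]] + 10
  extra$end <- extra$start + 99
  p2 <- plastome(p$id, p$sequence, features = rbind(ft, extra))
  expect_error(extract_shared_order(p2, p, map_a = map, map_b = map),
               "duplication error.*rrs")
})

test_that("fewer than three shared genes is an error", {
  f1 <- data.frame(name = c("a", "b"), kind = "gene", strand = "+",
                   start = c(1, 101), end = c(50, 150))
  p1 <- plastome("p1", random_dna(300), features = f1)
  expect_error(extract_shared_order(p1, p1), "insufficient")
})

test_that("raw substitution counts are Hamming counts on clean columns", {
  expect_equal(pairwise_substitutions("ACGT", "ACGT", "raw")$s, 0)
  set.seed(61)
  a <- random_dna(1000, 0.5)
  av <- strsplit(a, "")[[1]]
  idx <- sample(1000, 100)
  bv <- av
  for (i in idx) bv[i] <- setdiff(c("A", "C", "G", "T"), av[i])[1]
  est <- pairwise_substitutions(a, paste(bv, collapse = ""), "raw")
  expect_equal(est$s, 100)
  # gap and N columns are dropped from the site count
  bv[1:10] <- "-"
  est2 <- pairwise_substitutions(a, paste(bv, collapse = ""), "raw")
  expect_equal(est2$sites, 990)
})

test_that("JC69 and K80 corrections match their closed forms", {
  set.seed(67)
  a <- random_dna(2000, 0.5)
  b <- evolve_sequence(a, 0.15, "JC69", seed = 2)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  p <- mean(av != bv)
  d_hand <- -3 / 4 * log(1 - 4 * p / 3)
  est <- pairwise_substitutions(a, b, "JC69")
  expect_equal(est$distance, d_hand, tolerance = 1e-8)
  expect_equal(est$s, d_hand * 2000, tolerance = 1e-6)

  b2 <- evolve_sequence(a, 0.15, "K80", kappa = 4, seed = 3)
  bv2 <- strsplit(b2, "")[[1]]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  P <- mean(paste0(av, bv2) %in% ts_pairs)
  Q <- mean(av != bv2) - P
  d_k80 <- 0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
  est2 <- pairwise_substitutions(a, b2, "K80")
  expect_equal(est2$distance, d_k80, tolerance = 1e-8)
})

test_that("saturated alignments raise a saturation error", {
  a <- strrep("A", 200)
  b <- strrep("C", 200)
  expect_error(pairwise_substitutions(a, b, "JC69"), "saturation")
})

test_that("rearrangement rate is reversals per 1,000 substitutions", {
  expect_equal(rearrangement_rate(0, 5000)$rate, 0)
  expect_equal(rearrangement_rate(2, 2000)$rate, 1.0)
  expect_equal(rearrangement_rate(20, 13173)$rate, 1000 * 20 / 13173)
  expect_error(rearrangement_rate(1, 0), "undefined rate")
})
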