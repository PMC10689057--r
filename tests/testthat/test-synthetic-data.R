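test_that("all generators are deterministic given the seed", {
  expect_identical(make_orthogroup_matrix(5, 200, seed = 4),
                   make_orthogroup_matrix(5, 200, seed = 4))
  imp <- data.frame(chrom = "c1", start = 100000L, end = 200000L, kind = "dup")
  expect_identical(make_depth_track(c(c1 = 500000L), implants = imp, seed = 4),
                   make_depth_track(c(c1 = 500000L), implants = imp, seed = 4))
  expect_identical(make_pav_matrix(100, c("a1", "a2"), c("b1", "b2"), seed = 4),
                   make_pav_matrix(100, c("a1", "a2"), c("b1", "b2"), seed = 4))
  expect_identical(make_homeolog_counts(50, seed = 4),
                   make_homeolog_counts(50, seed = 4))
  expect_identical(make_sequence_pairs(20, 2, 3, seed = 4),
                   make_sequence_pairs(20, 2, 3, seed = 4))
})

test_that("orthogroup generator honours degenerate proportions", {
  all_core <- make_orthogroup_matrix(6, 100, c(1, 0, 0), seed = 1)
  expect_true(all(all_core$matrix >= 1))
  all_priv <- make_orthogroup_matrix(6, 100, c(0, 0, 1), seed = 1)
  expect_true(all(rowSums(all_priv$matrix >= 1) == 1))
  expect_error(make_orthogroup_matrix(6, 100, c(0.5, 0.5, 0.5), seed = 1),
               "simplex")
  expect_error(make_orthogroup_matrix(1, 10, seed = 1), "n_accessions")
})

test_that("depth generator implants duplications and deletions at the stated levels", {
  flat <- make_depth_track(c(c1 = 100000L), noise_sd = 0, seed = 1)
  expect_true(all(flat$track$depth == 30))
  imp <- data.frame(chrom = "c1", start = 300000L, end = 400000L, kind = "dup")
  d <- make_depth_track(c(c1 = 1000000L), noise_sd = 0, implants = imp, seed = 1)
  inside <- d$track$start >= 300000 & d$track$end <= 400000
  expect_equal(sum(inside), 10)
  expect_true(all(d$track$depth[inside] == 60))
  expect_true(all(d$track$depth[!inside] == 30))
  del <- data.frame(chrom = "c1", start = 0L, end = 100000L, kind = "del")
  d2 <- make_depth_track(c(c1 = 200000L), noise_sd = 0, implants = del, seed = 1)
  expect_true(all(d2$track$depth[1:10] == 1.5))  # 0.05 x base depth
  bad <- data.frame(chrom = "c1", start = 0L, end = 300000L, kind = "dup")
  expect_error(make_depth_track(c(c1 = 200000L), implants = bad, seed = 1),
               "exceeds")
})

test_that("PAV generator produces two-lineage structure with exact truth", {
  sA <- paste0("A", 1:3); sB <- paste0("B", 1:3)
  fixed <- make_pav_matrix(50, sA, sB, frac_differentiated = 1, seed = 2)
  expect_length(fixed$truth, 50)
  fa <- rowMeans(fixed$pav$genotypes[, sA] == "present")
  fb <- rowMeans(fixed$pav$genotypes[, sB] == "present")
  expect_true(all(abs(fa - fb) == 1))
  expect_error(make_pav_matrix(10, c("x", "y"), c("y", "z"), seed = 1),
               "disjoint")
})

test_that("null PAV generator lineage frequencies converge (law of large numbers)", {
  sA <- paste0("A", 1:5); sB <- paste0("B", 1:5)
  sim <- make_pav_matrix(10000, sA, sB, frac_differentiated = 0,
                         missing_rate = 0, seed = 3)
  fa <- rowMeans(sim$pav$genotypes[, sA] == "present")
  fb <- rowMeans(sim$pav$genotypes[, sB] == "present")
  expect_lt(abs(mean(fa - fb)), 0.05)
  expect_length(sim$truth, 0)
})

test_that("homeolog count generator realizes the requested bias", {
  ## near-zero dispersion, no bias: per-pair log2 ratios collapse to zero
  h0 <- make_homeolog_counts(100, n_tissues = 1, n_reps = 3, frac_biased = 0,
                             nb_dispersion = 1e-6,
                             mean_log_range = log(c(5000, 10000)), seed = 5)
  a <- rowMeans(h0$counts[h0$pairs$gene_A, ])
  b <- rowMeans(h0$counts[h0$pairs$gene_B, ])
  expect_true(all(abs(log2(b / a)) < 0.05))
  ## bias_log2fc = 1: Monte-Carlo mean B/A ratio of biased pairs near 2
  h1 <- make_homeolog_counts(200, n_tissues = 1, n_reps = 50, frac_biased = 0.5,
                             bias_log2fc = 1, nb_dispersion = 0.05,
                             mean_log_range = log(c(200, 2000)), seed = 6)
  biased <- h1$pairs$pair_id %in% h1$truth$biased_pairs
  ratio <- rowMeans(h1$counts[h1$pairs$gene_B, ]) /
    rowMeans(h1$counts[h1$pairs$gene_A, ])
  expect_equal(mean(ratio[biased]), 2, tolerance = 0.05)
  expect_equal(mean(ratio[!biased]), 1, tolerance = 0.05)
  expect_error(make_homeolog_counts(10, nb_dispersion = 0, seed = 1),
               "dispersion")
})

test_that("sequence-pair generator implants the exact substitution counts", {
  same <- make_sequence_pairs(10, 0, 0, seed = 7)
  expect_identical(same$seq1, same$seq2)
  one <- make_sequence_pairs(10, 1, 0, seed = 7)
  diffs <- which(strsplit(one$seq1, "")[[1]] != strsplit(one$seq2, "")[[1]])
  expect_length(diffs, 1)
  gc <- Biostrings::GENETIC_CODE
  cod <- one$truth$syn_codons
  c1 <- substring(one$seq1, 3 * cod - 2, 3 * cod)
  c2 <- substring(one$seq2, 3 * cod - 2, 3 * cod)
  expect_identical(unname(gc[c1]), unname(gc[c2]))  # synonymous change
  expect_error(make_sequence_pairs(3, 2, 2, seed = 1), "one change per codon")
  ## no stop codons anywhere
  sp <- make_sequence_pairs(50, 10, 10, seed = 8)
  for (s in c(sp$seq1, sp$seq2)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(gc[cods] == "*"))
  }
})
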