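gt2 <- function(...) {
  m <- rbind(...)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("PAV merging is tolerance- and size-aware", {
  a <- fixture_pav(gt2(c("present", "absent")), start = 1000L)
  b <- fixture_pav(gt2(c("absent", "present")), start = 1000L)
  m <- merge_pavs(list(a, b))
  expect_equal(n_pavs(m), 1)  # identical DELs collapse
  expect_equal(unname(m$genotypes[1, ]), c("present", "present"))

  far <- fixture_pav(gt2(c("present", "absent")), start = 3000L)
  expect_equal(n_pavs(merge_pavs(list(a, far), pos_tol_bp = 1000)), 2)

  small <- fixture_pav(gt2(c("present", "absent")), start = 1000L, svlen = 60L)
  expect_equal(n_pavs(merge_pavs(list(a, small), size_ratio = 0.8)), 2)

  mixed <- fixture_pav(gt2(c("present", "absent")), start = 1000L,
                       backbone = "other")
  expect_error(merge_pavs(list(a, mixed)), "backbones")
})

test_that("PAV merging is idempotent", {
  sets <- lapply(1:3, function(s)
    make_pav_matrix(60, paste0("A", 1:2), paste0("B", 1:2), seed = s)$pav)
  for (s in seq_along(sets)) sets[[s]]$backbone <- "bb"
  m1 <- merge_pavs(sets)
  m2 <- merge_pavs(list(m1))
  expect_equal(m1$records[, -1], m2$records[, -1])  # ids may be re-uniqued
  expect_equal(unname(m1$genotypes), unname(m2$genotypes))
})

test_that("PAV filtering applies missingness and minor-frequency rules", {
  gt <- gt2(c("missing", "missing", "missing", "present", "absent"),
            c("present", "present", "present", "present", "present"),
            c("present", "absent", "present", "absent", "present"))
  pav <- fixture_pav(gt)
  expect_equal(n_pavs(filter_pavs(pav, max_missing = 0.5)), 2)  # 60% missing dropped
  kept <- filter_pavs(pav, max_missing = 1, min_minor_freq = 0.05)
  expect_equal(kept$records$id, c("p001", "p003"))  # monomorphic dropped
  expect_equal(n_pavs(filter_pavs(pav, max_missing = 1, min_minor_freq = 0)), 3)
})

test_that("lineage differentiation uses non-missing frequencies with inclusive threshold", {
  sA <- paste0("A", 1:5); sB <- paste0("B", 1:5)
  gt <- rbind(fixed = c(rep("present", 5), rep("absent", 5)),
              balanced = rep(c("present", "absent"), 5),
              partial = c(rep("present", 5), "present", rep("absent", 4)))
  colnames(gt) <- c(sA, sB)
  pav <- fixture_pav(gt)
  design <- list(samples_A = sA, samples_B = sB)
  expect_equal(lineage_differentiated(pav, design)$records$id, "fixed")
  ## freq_A = 1, freq_B = 0.2 reported at min_freq_diff = 0.8 (inclusive)
  expect_true("partial" %in%
    lineage_differentiated(pav, design, min_freq_diff = 0.8)$records$id)
  ## a record with one lineage all-missing is skipped with a warning
  gt["balanced", sB] <- "missing"
  expect_warning(res <- lineage_differentiated(fixture_pav(gt), design),
                 "skipped")
  expect_false("balanced" %in% res$records$id)
})

test_that("lineage differentiation recovers simulated truth exactly", {
  sA <- paste0("A", 1:3); sB <- paste0("B", 1:3)
  for (seed in 1:5) {
    sim <- make_pav_matrix(400, sA, sB, missing_rate = 0, seed = seed)
    res <- lineage_differentiated(sim$pav,
                                  list(samples_A = sA, samples_B = sB))
    expect_setequal(res$records$id, sim$truth)
  }
  ## null generator: nothing reported at fixed-difference threshold
  null <- make_pav_matrix(10000, paste0("A", 1:5), paste0("B", 1:5),
                          frac_differentiated = 0, seed = 99)
  res0 <- lineage_differentiated(null$pav,
                                 list(samples_A = paste0("A", 1:5),
                                      samples_B = paste0("B", 1:5)))
  expect_lte(n_pavs(res0) / 10000, 0.01)
})

test_that("PAV-gene association follows the 2-kb flank overlap rule", {
  genes <- data.frame(id = "g1", chrom = "bb_chr1", start = 5000L,
                      end = 8000L, strand = "+")
  mk <- function(start, end) {
    rec <- data.frame(id = "pv", chrom = "bb_chr1", start = start, end = end,
                      svtype = "DEL", svlen = end - start)
    pav_table(rec, matrix("present", 1, 1, dimnames = list("pv", "s1")))
  }
  expect_equal(nrow(annotate_pavs_to_genes(mk(3500L, 3580L), genes)), 1)
  expect_equal(nrow(annotate_pavs_to_genes(mk(2500L, 2580L), genes)), 0)
  hit <- annotate_pavs_to_genes(mk(7990L, 8100L), genes)
  expect_equal(hit$distance, 0L)  # overlaps the gene body itself
  ## boundary: a PAV ending exactly at start - flank does not overlap
  expect_equal(nrow(annotate_pavs_to_genes(mk(2900L, 3000L), genes)), 0)
  expect_equal(nrow(annotate_pavs_to_genes(mk(2900L, 3001L), genes)), 1)
  expect_error(annotate_pavs_to_genes(mk(1L, 100L), genes, flank_bp = -1),
               "flank")
})

test_that("overlap permutation p-values behave at the extremes", {
  universe <- sprintf("g%03d", 1:100)
  ## every gene is a DEG: every draw ties the observed overlap
  res <- deg_overlap_permutation(universe[1:10], universe, universe,
                                 n_perm = 99, seed = 1)
  expect_equal(res$observed, 10)
  expect_equal(res$p, 1)
  ## target = DEG = one half: no null draw can reach the observed overlap
  half <- universe[1:50]
  res2 <- deg_overlap_permutation(half, half, universe, n_perm = 99, seed = 1)
  expect_equal(res2$observed, 50)
  expect_equal(res2$p, 1 / 100)
  ## p always within [1/(n_perm+1), 1]
  for (seed in 1:10) {
    set.seed(seed + 1000)
    r <- deg_overlap_permutation(sample(universe, 20), sample(universe, 20),
                                 universe, n_perm = 49, seed = seed)
    expect_gte(r$p, 1 / 50)
    expect_lte(r$p, 1)
  }
  expect_error(deg_overlap_permutation("a", "a", character(0)), "universe")
  expect_error(deg_overlap_permutation("zz", half, universe), "subsets")
})
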