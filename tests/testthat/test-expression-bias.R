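test_that("RLE size factors match the closed form and are scale-equivariant", {
  m <- cbind(s1 = c(5L, 8L, 12L), s2 = c(5L, 8L, 12L))
  expect_equal(unname(rle_size_factors(m)), c(1, 1))

  two <- cbind(s1 = c(10, 20), s2 = c(20, 40))
  expect_equal(unname(rle_size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  set.seed(1)
  r <- matrix(rpois(300, 50) + 1L, 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sf <- rle_size_factors(r)
  r2 <- r; r2[, 2] <- r2[, 2] * 5
  sf2 <- rle_size_factors(r2)
  ## scaling one sample scales its factor relative to the others by the same
  ## constant (the geometric-mean reference absorbs a c^(1/m) share)
  expect_equal((sf2[["b"]] / sf2[["a"]]) / (sf[["b"]] / sf[["a"]]), 5,
               tolerance = 1e-12)
  ## normalized counts have median ratio ~1 to the reference per sample
  norm <- normalize_counts(r, sf)
  ref <- exp(rowMeans(log(r)))
  expect_equal(unname(apply(norm / ref, 2, median)), rep(1, 3),
               tolerance = 1e-4)

  allzero <- cbind(s1 = c(0L, 5L), s2 = c(3L, 0L))
  expect_error(rle_size_factors(allzero), "pseudo-reference")
})

test_that("RLE size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 10) + 1L, 200, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  expect_equal(unname(rle_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("identical homeolog counts give zero log2fc and no bias calls", {
  pairs <- data.frame(pair_id = paste0("p", 1:5),
                      gene_A = paste0("p", 1:5, "_A"),
                      gene_B = paste0("p", 1:5, "_B"))
  counts <- matrix(rep(c(10L, 20L, 40L), each = 10), 10, 3,
                   dimnames = list(c(pairs$gene_A, pairs$gene_B),
                                   paste0("FB_r", 1:3)))
  meta <- data.frame(sample = paste0("FB_r", 1:3), tissue = "FB",
                     replicate = 1:3)
  res <- heb_test(counts, meta, pairs, "FB")
  expect_true(all(res$log2fc == 0))
  expect_false(any(res$biased))
  ## single replicate: effect size reported, no inference
  res1 <- heb_test(counts[, 1, drop = FALSE],
                   meta[1, , drop = FALSE], pairs, "FB")
  expect_true(all(is.na(res1$p)))
  expect_false(any(res1$biased))
})

test_that("estimated log2fc recovers the simulated bias magnitude", {
  est <- vapply(1:50, function(seed) {
    h <- make_homeolog_counts(40, n_tissues = 1, n_reps = 3,
                              frac_biased = 0.5, bias_log2fc = 2,
                              nb_dispersion = 0.05, seed = seed)
    r <- heb_test(h$counts, h$meta, h$pairs, "FB")
    mean(r$log2fc[r$pair_id %in% h$truth$biased_pairs])
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.3)
})

test_that("all-null simulations keep the biased fraction within alpha", {
  frac <- vapply(1:20, function(seed) {
    h <- make_homeolog_counts(150, n_tissues = 1, n_reps = 3, frac_biased = 0,
                              seed = seed)
    mean(heb_test(h$counts, h$meta, h$pairs, "FB", method = "t")$biased)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("tissue-breadth classification counts any/all correctly", {
  res <- data.frame(
    pair_id = rep(c("p1", "p2", "p3"), 2),
    tissue = rep(c("FB", "L"), each = 3),
    log2fc = 0, p = 0.5, q = 0.5,
    biased = c(TRUE, TRUE, FALSE,  FALSE, TRUE, FALSE))
  br <- classify_breadth(res)
  expect_equal(br$n_biased_any, 2)
  expect_equal(br$n_biased_all, 1)
  expect_equal(br$per_pair$n_tissues_biased[br$per_pair$pair_id == "p2"], 2L)
  ## NA p excludes a pair from "all tissues" only
  res$p[res$pair_id == "p2" & res$tissue == "L"] <- NA
  expect_equal(classify_breadth(res)$n_biased_all, 0)
  expect_equal(classify_breadth(res)$n_biased_any, 2)
  ## inconsistent pair sets across tissues
  expect_error(classify_breadth(res[-1, ]), "pair sets")
})

test_that("signed-rank test matches brute-force sign enumeration", {
  expect_equal(signed_rank_test(c(1, 2, 3, -1))$p,
               oracle_signed_rank_p(c(1, 2, 3, -1)))
  set.seed(7)
  for (i in 1:10) {
    x <- round(rnorm(sample(4:10, 1)), 1)
    x <- x[x != 0]
    expect_equal(signed_rank_test(x)$p, oracle_signed_rank_p(x),
                 info = paste("case", i))
  }
  ## tie-free case agrees with stats::wilcox.test exact p
  y <- c(0.3, -1.2, 2.4, 1.1, -0.6, 0.9, 1.7)
  expect_equal(signed_rank_test(y)$p,
               wilcox.test(y, mu = 0, exact = TRUE)$p.value)
})

test_that("chromosome-level bias reports direction and exact p", {
  pairs <- data.frame(pair_id = paste0("p", 1:6),
                      chrom_pair = rep(c("chr1A-chr1B", "chr2A-chr2B"), 3))
  res <- data.frame(pair_id = pairs$pair_id, tissue = "FB",
                    mean_norm_A = 10, mean_norm_B = 20,
                    log2fc = 1, p = 0.1, q = 0.2, biased = FALSE)
  cb <- chromosome_bias(res, pairs)
  glob <- cb[cb$chrom_pair == "global", ]
  expect_equal(glob$direction, "B")
  expect_equal(glob$p, 2 / 2^6)  # all-positive sign pattern and its mirror
  ## symmetric values: no direction
  res$log2fc <- rep(c(1, -1), 3)
  cb2 <- chromosome_bias(res, pairs)
  expect_equal(cb2$direction[cb2$chrom_pair == "global"], "none")
  ## all-zero degenerate case
  res$log2fc <- 0
  cb3 <- chromosome_bias(res, pairs)
  expect_equal(cb3$p[cb3$chrom_pair == "global"], 1)
  expect_equal(cb3$direction[cb3$chrom_pair == "global"], "none")
})

test_that("PAV-affected genes show reduced expression when simulated so", {
  set.seed(5)
  n <- 500
  mu_row <- rep(c(100, 50), each = n)
  counts <- matrix(rnbinom(2 * n * 4, mu = rep(mu_row, times = 4),
                           size = 20), 2 * n, 4,
                   dimnames = list(sprintf("g%04d", 1:(2 * n)),
                                   paste0("L_r", 1:4)))
  meta <- data.frame(sample = paste0("L_r", 1:4), tissue = "L",
                     replicate = 1:4)
  affected <- sprintf("g%04d", (n + 1):(2 * n))  # the 0.5x group
  res <- pav_expression_contrast(counts, meta, affected, "L")
  expect_lt(res$p, 0.05)
  expect_lt(res$median_affected, res$median_other)
  expect_error(pav_expression_contrast(counts, meta, character(0), "L"),
               "non-empty")
})

test_that("DEG analysis is symmetric and controls identical groups", {
  set.seed(9)
  counts <- matrix(rnbinom(100 * 8, mu = 80, size = 20), 100, 8,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:8)))
  g1 <- paste0("s", 1:4); g2 <- paste0("s", 5:8)
  res <- deg_between_groups(counts, g1, g2)
  swapped <- deg_between_groups(counts, g2, g1)
  expect_equal(res$log2fc, -swapped$log2fc, tolerance = 1e-12)
  ## identical groups (same samples duplicated): no DEGs
  dup <- counts[, c(1:4, 1:4)]
  colnames(dup) <- paste0("t", 1:8)
  res0 <- deg_between_groups(dup, paste0("t", 1:4), paste0("t", 5:8))
  expect_equal(sum(res0$deg), 0)
  expect_true(all(res0$q >= res0$p, na.rm = TRUE))
})

test_that("DEG recall is high for strong simulated fold changes", {
  recall <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 400
    mu <- exp(runif(n, log(50), log(500)))
    fc <- rep(1, n); fc[1:40] <- 4
    cnt <- cbind(
      matrix(rnbinom(n * 4, mu = mu, size = 20), n, 4),
      matrix(rnbinom(n * 4, mu = mu * fc, size = 20), n, 4))
    dimnames(cnt) <- list(sprintf("g%04d", 1:n), paste0("s", 1:8))
    res <- deg_between_groups(cnt, paste0("s", 1:4), paste0("s", 5:8))
    mean(res$deg[1:40])
  }, numeric(1))
  expect_gte(mean(recall), 0.8)
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  score <- rnorm(200)
  labels <- runif(200) < 0.3
  score[labels] <- score[labels] + 1.5
  expect_equal(rank_auc(score, labels),
               as.numeric(pROC::auc(pROC::roc(labels, score, quiet = TRUE))),
               tolerance = 1e-12)
})
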