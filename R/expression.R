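#' Median-of-ratios (RLE) size factors
#'
#' Relative Log Expression normalization: the reference is the per-gene
#' geometric mean across samples, computed over genes with all-positive
#' counts; each sample's size factor is the median over those genes of
#' count / reference.
#'
#' @param counts Genes x samples numeric matrix of raw counts.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 20), s2 = c(20, 40))
#' rle_size_factors(m)  # (1/sqrt(2), sqrt(2))
rle_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use))
    ap_stop("no gene has positive counts in every sample; ",
            "normalization needs a pseudo-reference fallback")
  sf <- apply(logc[use, , drop = FALSE], 2,
              function(x) exp(median(x - loggeo[use])))
  setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#' @param counts Genes x samples matrix.
#' @param size_factors Per-sample factors; computed by [rle_size_factors()]
#'   if NULL.
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  sweep(counts, 2, size_factors, "/")
}

#' Test homeolog expression bias per pair within one tissue
#'
#' Counts are normalized by RLE size factors computed over all samples. Per
#' pair, log2fc = log2((mean normalized B + pseudocount) /
#' (mean normalized A + pseudocount)) and a two-sided paired test is run on
#' the per-replicate log2 normalized ratios: an exact sign-flip permutation
#' when the tissue has at most 6 replicates, a one-sample t-test otherwise
#' (overridable via `method`). p-values are BH-corrected across pairs within
#' the tissue; a pair is biased iff q < alpha. With a single replicate the
#' log2fc is reported with p = NA and biased = FALSE.
#'
#' @param counts Genes x samples matrix of raw counts.
#' @param meta Sample sheet (`sample`, `tissue`, `replicate`).
#' @param pairs Homeolog pair table (`pair_id`, `gene_A`, `gene_B`, optional
#'   `chrom_pair`).
#' @param tissue Tissue to test.
#' @param alpha FDR level (default 0.05).
#' @param pseudocount Added inside the log ratio (default 0.5).
#' @param size_factors Optional precomputed size factors over all samples.
#' @param method `"auto"` (spec rule), `"signflip"`, or `"t"`.
#' @return data.frame (class `heb_result`) with `pair_id`, `tissue`,
#'   `log2fc`, `p`, `q`, `biased`.
#' @export
heb_test <- function(counts, meta, pairs, tissue, alpha = 0.05,
                     pseudocount = 0.5, size_factors = NULL,
                     method = c("auto", "signflip", "t")) {
  method <- match.arg(method)
  stopifnot(tissue %in% meta$tissue)
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  norm <- normalize_counts(counts, size_factors)
  smp <- meta$sample[meta$tissue == tissue]
  a <- norm[pairs$gene_A, smp, drop = FALSE]
  b <- norm[pairs$gene_B, smp, drop = FALSE]
  n <- length(smp)
  log2fc <- log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))
  ratios <- log2((b + pseudocount) / (a + pseudocount))
  p <- rep(NA_real_, nrow(pairs))
  if (n >= 2) {
    use_exact <- switch(method, auto = n <= 6, signflip = TRUE, t = FALSE)
    if (use_exact) {
      ## vectorized sign-flip over pairs: all 2^n sign patterns at once
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      obs <- abs(rowMeans(ratios))
      null <- abs(ratios %*% t(signs)) / n
      p <- rowMeans(null >= obs - 1e-12)
    } else {
      m <- rowMeans(ratios)
      s <- apply(ratios, 1, sd)
      tt <- m / (s / sqrt(n))
      p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
      p[s == 0 & m == 0] <- 1
      p[s == 0 & m != 0] <- 0
    }
  }
  q <- bh_adjust(p)
  out <- data.frame(pair_id = pairs$pair_id, tissue = tissue,
                    mean_norm_A = rowMeans(a), mean_norm_B = rowMeans(b),
                    log2fc = log2fc, p = p, q = q,
                    biased = !is.na(q) & q < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("heb_result", "data.frame")
  out
}

#' Run [heb_test()] over every tissue
#'
#' @inheritParams heb_test
#' @return Row-bound `heb_result` over all tissues in `meta`.
#' @export
heb_test_all <- function(counts, meta, pairs, alpha = 0.05,
                         pseudocount = 0.5, method = c("auto", "signflip", "t")) {
  method <- match.arg(method)
  sf <- rle_size_factors(counts)
  out <- do.call(rbind, lapply(unique(meta$tissue), function(tt)
    heb_test(counts, meta, pairs, tt, alpha = alpha,
             pseudocount = pseudocount, size_factors = sf, method = method)))
  class(out) <- c("heb_result", "data.frame")
  out
}

#' Classify homeolog pairs by the tissue breadth of their bias
#'
#' Counts pairs biased in at least one tissue and in all tissues. Pairs with
#' an NA p-value in any tissue are excluded from the "all tissues" count
#' only.
#'
#' @param results `heb_result` rows covering every tissue for the same pair
#'   set.
#' @return List with `per_pair` (pair_id, n_tissues_biased, biased_in_all,
#'   tissues), `n_biased_any`, `n_biased_all`, `n_tissues`.
#' @export
classify_breadth <- function(results) {
  tissues <- unique(results$tissue)
  by_tissue <- split(results$pair_id, results$tissue)
  if (length(unique(lapply(by_tissue, sort))) != 1)
    ap_stop("tissues cover different pair sets")
  n_t <- length(tissues)
  agg_b <- tapply(results$biased, results$pair_id, sum)
  agg_na <- tapply(is.na(results$p), results$pair_id, any)
  tl <- tapply(seq_len(nrow(results)), results$pair_id, function(i)
    paste(sort(results$tissue[i][results$biased[i]]), collapse = ","))
  per_pair <- data.frame(pair_id = names(agg_b),
                         n_tissues_biased = as.integer(agg_b),
                         biased_in_all = !agg_na & agg_b == n_t,
                         tissues = as.character(tl),
                         stringsAsFactors = FALSE)
  rownames(per_pair) <- NULL
  list(per_pair = per_pair,
       n_biased_any = sum(per_pair$n_tissues_biased >= 1),
       n_biased_all = sum(per_pair$biased_in_all),
       n_tissues = n_t)
}

#' Chromosome-level expression bias direction
#'
#' Per chromosome pair (and per tissue), tests the per-pair log2 fold changes
#' against zero. The default is the paired reading — a one-sample Wilcoxon
#' signed-rank test on the pair log2fc values (exact by sign enumeration for
#' small n, tie-corrected normal approximation otherwise); `paired = FALSE`
#' instead runs a two-sample rank-sum of B-homeolog versus A-homeolog
#' values. Direction is B if the median log2fc is positive, A if negative,
#' none if zero. A global row per tissue pools all chromosome pairs.
#'
#' @param results `heb_result` rows.
#' @param pairs Pair table with `pair_id` and `chrom_pair`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param paired Use the paired signed-rank form (default TRUE).
#' @return data.frame with `chrom_pair` (or `"global"`), `tissue`, `n`,
#'   `median_log2fc`, `direction`, `p`, `significant`.
#' @export
chromosome_bias <- function(results, pairs, alpha = 0.05, paired = TRUE) {
  stopifnot("chrom_pair" %in% names(pairs))
  cp <- setNames(pairs$chrom_pair, pairs$pair_id)
  results$chrom_pair <- cp[results$pair_id]
  one <- function(rt, label, tissue) {
    rt <- rt[!is.na(rt$log2fc), , drop = FALSE]
    lfc <- rt$log2fc
    med <- if (length(lfc)) median(lfc) else NA_real_
    if (length(lfc) < 2) {
      p <- NA_real_
    } else if (paired) {
      p <- signed_rank_test(lfc)$p
    } else {
      p <- suppressWarnings(
        wilcox.test(rt$mean_norm_B, rt$mean_norm_A, exact = FALSE)$p.value)
    }
    dirn <- if (is.na(med) || med == 0) "none" else if (med > 0) "B" else "A"
    if (!is.na(med) && length(lfc) && all(lfc == 0)) { p <- 1; dirn <- "none" }
    data.frame(chrom_pair = label, tissue = tissue, n = length(lfc),
               median_log2fc = med, direction = dirn, p = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (tt in unique(results$tissue)) {
    rt <- results[results$tissue == tt, ]
    for (ch in unique(rt$chrom_pair))
      out[[length(out) + 1L]] <- one(rt[rt$chrom_pair == ch, ], ch, tt)
    out[[length(out) + 1L]] <- one(rt, "global", tt)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare expression of PAV-affected genes with the remaining genes
#'
#' Two-sided Wilcoxon rank-sum test on per-gene mean normalized expression
#' within a tissue, PAV-affected set versus all other genes.
#'
#' @param counts Genes x samples matrix of raw counts.
#' @param meta Sample sheet.
#' @param pav_affected Character vector of PAV-affected gene ids.
#' @param tissue Tissue to compare in.
#' @param size_factors Optional precomputed size factors.
#' @return List with `median_affected`, `median_other`, `n_affected`,
#'   `n_other`, `p`.
#' @export
pav_expression_contrast <- function(counts, meta, pav_affected, tissue,
                                    size_factors = NULL) {
  norm <- normalize_counts(counts, size_factors)
  smp <- meta$sample[meta$tissue == tissue]
  expr <- rowMeans(norm[, smp, drop = FALSE])
  affected <- intersect(rownames(counts), pav_affected)
  other <- setdiff(rownames(counts), pav_affected)
  if (!length(affected) || !length(other))
    ap_stop("both gene sets must be non-empty within the matrix")
  p <- suppressWarnings(
    wilcox.test(expr[affected], expr[other], alternative = "two.sided",
                exact = FALSE)$p.value)
  list(median_affected = median(expr[affected]),
       median_other = median(expr[other]),
       n_affected = length(affected), n_other = length(other), p = p)
}

#' Differential expression between two sample groups
#'
#' Counts are RLE-normalized over the union of the two groups; per gene a
#' two-sided test on log2 normalized counts compares the groups: an exact
#' label permutation of the mean difference when the total replicate number
#' is at most 6, Welch's t-test otherwise (overridable via `method`). BH
#' correction across genes; DEG iff q < alpha. log2fc is group2 over group1
#' with a pseudocount, so swapping the groups flips its sign exactly.
#'
#' @param counts Genes x samples matrix of raw counts.
#' @param group1,group2 Character vectors of sample names.
#' @param alpha FDR level (default 0.05).
#' @param pseudocount Added to mean normalized counts in log2fc (default 0.5).
#' @param method `"auto"`, `"permutation"`, or `"t"`.
#' @return data.frame with `gene`, `log2fc`, `p`, `q`, `deg`.
#' @export
deg_between_groups <- function(counts, group1, group2, alpha = 0.05,
                               pseudocount = 0.5,
                               method = c("auto", "permutation", "t")) {
  method <- match.arg(method)
  stopifnot(all(c(group1, group2) %in% colnames(counts)),
            length(group1) >= 2, length(group2) >= 2)
  sub <- counts[, c(group1, group2), drop = FALSE]
  norm <- normalize_counts(sub)
  y <- log2(norm + pseudocount)
  n_tot <- length(group1) + length(group2)
  use_perm <- switch(method, auto = n_tot <= 6, permutation = TRUE, t = FALSE)
  y1 <- y[, group1, drop = FALSE]; y2 <- y[, group2, drop = FALSE]
  log2fc <- log2((rowMeans(norm[, group2, drop = FALSE]) + pseudocount) /
                   (rowMeans(norm[, group1, drop = FALSE]) + pseudocount))
  p <- vapply(seq_len(nrow(y)), function(i) {
    a <- y1[i, ]; b <- y2[i, ]
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) return(1)
      return(perm_meandiff_test(a, b))
    }
    if (use_perm) perm_meandiff_test(a, b)
    else t.test(a, b)$p.value
  }, numeric(1))
  q <- bh_adjust(p)
  data.frame(gene = rownames(counts), log2fc = log2fc, p = p, q = q,
             deg = !is.na(q) & q < alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}
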