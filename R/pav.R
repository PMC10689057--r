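gt_precedence <- c(missing = 0L, absent = 1L, present = 2L)

#' Merge per-sample PAV call sets into a non-redundant table
#'
#' Two records merge iff they share svtype and chromosome, their start
#' positions differ by at most `pos_tol_bp`, and their size ratio
#' min(svlen)/max(svlen) is at least `size_ratio`. The merged record keeps
#' the coordinates of the first-seen member; genotypes are combined over the
#' union of samples with precedence present > absent > missing.
#'
#' @param call_sets List of [pav_table()]s on the same backbone.
#' @param pos_tol_bp Start-position tolerance in bp (default 1000).
#' @param size_ratio Minimum size ratio (default 0.8).
#' @return A non-redundant [pav_table()].
#' @export
merge_pavs <- function(call_sets, pos_tol_bp = 1000L, size_ratio = 0.8) {
  stopifnot(is.list(call_sets), length(call_sets) >= 1)
  backbones <- unique(unlist(lapply(call_sets, function(x) x$backbone)))
  if (length(backbones) > 1)
    ap_stop("call sets are on different backbones: ",
            paste(backbones, collapse = ", "))
  samples <- unique(unlist(lapply(call_sets, function(x) colnames(x$genotypes))))
  recs <- list(); gts <- list()
  for (set in call_sets) {
    for (i in seq_len(nrow(set$records))) {
      r <- set$records[i, ]
      g <- setNames(rep("missing", length(samples)), samples)
      g[colnames(set$genotypes)] <- set$genotypes[i, ]
      hit <- NA_integer_
      for (j in seq_along(recs)) {
        m <- recs[[j]]
        if (m$svtype == r$svtype && m$chrom == r$chrom &&
            abs(m$start - r$start) <= pos_tol_bp &&
            min(m$svlen, r$svlen) / max(m$svlen, r$svlen) >= size_ratio) {
          hit <- j; break
        }
      }
      if (is.na(hit)) {
        recs[[length(recs) + 1L]] <- r
        gts[[length(gts) + 1L]] <- g
      } else {
        old <- gts[[hit]]
        keep_old <- gt_precedence[old] >= gt_precedence[g]
        gts[[hit]] <- ifelse(keep_old, old, g)
      }
    }
  }
  rec <- do.call(rbind, recs)
  rec$id <- make.unique(rec$id, sep = "_m")
  gt <- do.call(rbind, gts)
  rownames(gt) <- rec$id
  pav_table(rec, gt, backbone = backbones %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

pav_freqs <- function(pav) {
  g <- pav$genotypes
  n_miss <- rowSums(g == "missing")
  n_pres <- rowSums(g == "present")
  n_called <- ncol(g) - n_miss
  list(missing_frac = n_miss / ncol(g),
       pres_freq = ifelse(n_called > 0, n_pres / n_called, NA_real_),
       n_called = n_called)
}

#' Filter a PAV genotype table
#'
#' Drops records whose missing fraction exceeds `max_missing` or whose minor
#' presence frequency (computed over non-missing genotypes) is below
#' `min_minor_freq`.
#'
#' @param table A [pav_table()].
#' @param max_missing Maximum missing genotype fraction (default 0.2).
#' @param min_minor_freq Minimum minor presence frequency (default 0).
#' @return The filtered [pav_table()].
#' @export
filter_pavs <- function(table, max_missing = 0.2, min_minor_freq = 0) {
  f <- pav_freqs(table)
  minor <- pmin(f$pres_freq, 1 - f$pres_freq)
  keep <- f$missing_frac <= max_missing
  if (min_minor_freq > 0) keep <- keep & !is.na(minor) & minor >= min_minor_freq
  pav_table(table$records[keep, , drop = FALSE],
            table$genotypes[keep, , drop = FALSE],
            backbone = table$backbone)
}

#' Identify lineage-differentiated PAVs
#'
#' A PAV is reported when the absolute difference of presence frequencies
#' between the two lineages (over non-missing genotypes) reaches
#' `min_freq_diff`. The default of 1 requires a fixed difference — present in
#' every called sample of one lineage and absent in every called sample of
#' the other.
#'
#' @param table A [pav_table()].
#' @param design List or data.frame with `samples_A` and `samples_B`
#'   (disjoint, both genotyped in `table`).
#' @param min_freq_diff Minimum |freq_A - freq_B| (default 1, inclusive).
#' @return The subset [pav_table()] of differentiated records, with a
#'   `freq_diff` column added to `records`.
#' @export
lineage_differentiated <- function(table, design, min_freq_diff = 1) {
  sa <- design$samples_A; sb <- design$samples_B
  if (!length(sa) || !length(sb)) ap_stop("both lineages need samples")
  if (length(intersect(sa, sb))) ap_stop("lineages must be disjoint")
  if (!all(c(sa, sb) %in% colnames(table$genotypes)))
    ap_stop("design samples missing from the PAV table")
  ga <- table$genotypes[, sa, drop = FALSE]
  gb <- table$genotypes[, sb, drop = FALSE]
  ca <- rowSums(ga != "missing"); cb <- rowSums(gb != "missing")
  skip <- ca == 0 | cb == 0
  if (any(skip))
    ap_warn(sum(skip), " PAV(s) skipped: one lineage entirely missing")
  fa <- ifelse(ca > 0, rowSums(ga == "present") / ca, NA_real_)
  fb <- ifelse(cb > 0, rowSums(gb == "present") / cb, NA_real_)
  keep <- !skip & abs(fa - fb) >= min_freq_diff - 1e-12
  rec <- table$records[keep, , drop = FALSE]
  rec$freq_diff <- (fa - fb)[keep]
  pav_table(rec, table$genotypes[keep, , drop = FALSE],
            backbone = table$backbone)
}

#' Associate PAVs with genes by the cis-regulatory flank rule
#'
#' A PAV is associated with a gene when its interval overlaps the gene body
#' extended by `flank_bp` on both sides (2 kb by default — PAVs within 2 kb
#' upstream or downstream are treated as potentially cis-regulatory). The
#' flank is strand-agnostic; each association is listed once.
#'
#' @param pavs A [pav_table()].
#' @param genes data.frame of gene models (`id`, `chrom`, `start`, `end`,
#'   0-based half-open) on the same backbone.
#' @param flank_bp Flank size in bp (default 2000; must be >= 0).
#' @return data.frame with columns `gene_id`, `pav_id`, `svtype`, `distance`
#'   (0 when overlapping the gene body).
#' @export
annotate_pavs_to_genes <- function(pavs, genes, flank_bp = 2000L) {
  if (flank_bp < 0) ap_stop("flank_bp must be >= 0")
  if (!nrow(genes) || !n_pavs(pavs))
    return(data.frame(gene_id = character(), pav_id = character(),
                      svtype = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  ## half-open [start-flank, end+flank) vs PAV [start, end): use IRanges on
  ## the 1-based closed equivalent
  g <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(0L, genes$start - flank_bp) + 1L,
                     end = genes$end + flank_bp))
  p <- GenomicRanges::GRanges(
    pavs$records$chrom,
    IRanges::IRanges(start = pavs$records$start + 1L,
                     end = pavs$records$end))
  hits <- GenomicRanges::findOverlaps(g, p)
  gi <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L,
               pmax(genes$start[gi] - pavs$records$end[pi],
                    pavs$records$start[pi] - genes$end[gi]))
  out <- data.frame(gene_id = genes$id[gi],
                    pav_id = pavs$records$id[pi],
                    svtype = pavs$records$svtype[pi],
                    distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  out[!duplicated(out[, c("gene_id", "pav_id")]), , drop = FALSE]
}

#' Permutation test for overlap between a gene set and DEGs
#'
#' Draws `n_perm` uniform samples of `|target_genes|` genes from the universe
#' without replacement and compares their overlap with `deg_genes` to the
#' observed overlap. The empirical p-value uses the add-one estimator
#' (1 + #null >= observed) / (n_perm + 1), so it is never zero.
#'
#' @param target_genes Character vector (subset of `universe`), e.g. genes
#'   with lineage-differentiated PAVs.
#' @param deg_genes Character vector (subset of `universe`).
#' @param universe Character vector of all eligible genes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return List with `observed`, `null_mean`, `p`, `n_perm`.
#' @export
deg_overlap_permutation <- function(target_genes, deg_genes, universe,
                                    n_perm = 1000L, seed = 1L) {
  if (!length(universe)) ap_stop("empty universe")
  if (n_perm < 1) ap_stop("n_perm must be >= 1")
  target_genes <- unique(target_genes); deg_genes <- unique(deg_genes)
  if (!all(target_genes %in% universe) || !all(deg_genes %in% universe))
    ap_stop("target and DEG sets must be subsets of the universe")
  set.seed(seed)
  observed <- length(intersect(target_genes, deg_genes))
  is_deg <- universe %in% deg_genes
  k <- length(target_genes)
  null <- replicate(n_perm, sum(is_deg[sample.int(length(universe), k)]))
  list(observed = observed, null_mean = mean(null),
       p = (1 + sum(null >= observed)) / (n_perm + 1), n_perm = n_perm)
}
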