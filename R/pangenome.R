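#' Classify orthogroup clusters into core / dispensable / private
#'
#' A cluster present (count >= 1) in all N accessions is core, in exactly one
#' accession private, and in 2..(N-1) accessions dispensable, so the three
#' categories partition the cluster set.
#'
#' @param matrix Clusters x accessions non-negative integer matrix.
#' @return List of class `cluster_classification` with `labels` (named
#'   character vector), `n_core`, `n_dispensable`, `n_private`,
#'   `n_accessions`.
#' @export
#' @examples
#' m <- rbind(all = c(1, 2, 1), two = c(1, 1, 0), one = c(0, 0, 3))
#' classify_clusters(m)$labels
classify_clusters <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1, ncol(matrix) >= 2)
  pres <- rowSums(matrix >= 1)
  if (any(pres == 0))
    ap_stop("cluster with zero presence in every accession: ",
            rownames(matrix)[which(pres == 0)[1]])
  n <- ncol(matrix)
  labels <- ifelse(pres == n, "core", ifelse(pres == 1, "private", "dispensable"))
  names(labels) <- rownames(matrix)
  structure(list(labels = labels,
                 n_core = sum(labels == "core"),
                 n_dispensable = sum(labels == "dispensable"),
                 n_private = sum(labels == "private"),
                 n_accessions = n),
            class = "cluster_classification")
}

#' @method print cluster_classification
#' @export
print.cluster_classification <- function(x, ...) {
  s <- classification_summary(x$n_core, x$n_dispensable, x$n_private)
  cat(sprintf("cluster classification over %d accessions: %d clusters\n",
              x$n_accessions, s$total))
  cat(sprintf("  core        %6d (%.2f%%)\n", x$n_core, s$core_pct))
  cat(sprintf("  dispensable %6d (%.2f%%)\n", x$n_dispensable, s$dispensable_pct))
  cat(sprintf("  private     %6d (%.2f%%)\n", x$n_private, s$private_pct))
  cat(sprintf("  variable (dispensable + private): %.2f%%\n", s$variable_pct))
  invisible(x)
}

#' Summarize a core/dispensable/private partition
#'
#' @param n_core,n_dispensable,n_private Cluster counts per category.
#' @return List with `total` and the percentage of each category plus the
#'   variable (dispensable + private) share.
#' @export
#' @examples
#' classification_summary(18859, 11352, 9041)
classification_summary <- function(n_core, n_dispensable, n_private) {
  total <- n_core + n_dispensable + n_private
  if (total <= 0) ap_stop("empty classification")
  list(total = total,
       core_pct = 100 * n_core / total,
       dispensable_pct = 100 * n_dispensable / total,
       private_pct = 100 * n_private / total,
       variable_pct = 100 * (n_dispensable + n_private) / total)
}

#' Pan- and core-cluster saturation curves
#'
#' For each subset size k of accessions, counts the pan size (clusters present
#' in at least one subset member) and core size (present in every member),
#' averaged over genome subsets: all C(N, k) subsets when that number does not
#' exceed `max_exhaustive`, otherwise `n_samples` uniform random subsets.
#' Averaging is over subsets (not genome orderings); the `exhaustive` column
#' records which mode produced each row.
#'
#' @param matrix Clusters x accessions integer matrix.
#' @param max_exhaustive Largest subset count enumerated exhaustively
#'   (default 1000).
#' @param n_samples Random subsets per k in sampling mode (default 100).
#' @param seed RNG seed for sampling mode.
#' @return data.frame with columns `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`, `exhaustive`, `n_subsets`.
#' @export
saturation_curves <- function(matrix, max_exhaustive = 1000L,
                              n_samples = 100L, seed = 1L) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2)
  pres <- matrix >= 1
  n <- ncol(pres)
  set.seed(seed)
  rows <- lapply(seq_len(n), function(k) {
    n_comb <- choose(n, k)
    if (n_comb <= max_exhaustive) {
      subsets <- combn(n, k, simplify = FALSE)
      exhaustive <- TRUE
    } else {
      if (n_samples < 1) ap_stop("n_samples must be >= 1 in sampling mode")
      subsets <- replicate(n_samples, sample.int(n, k), simplify = FALSE)
      exhaustive <- FALSE
    }
    pan <- core <- numeric(length(subsets))
    for (i in seq_along(subsets)) {
      sub <- pres[, subsets[[i]], drop = FALSE]
      rs <- rowSums(sub)
      pan[i] <- sum(rs > 0)
      core[i] <- sum(rs == k)
    }
    data.frame(k = k, pan_mean = mean(pan),
               pan_sd = if (length(pan) > 1) sd(pan) else 0,
               core_mean = mean(core),
               core_sd = if (length(core) > 1) sd(core) else 0,
               exhaustive = exhaustive, n_subsets = length(subsets))
  })
  do.call(rbind, rows)
}

#' Gene-level category composition per accession
#'
#' Each gene inherits the category of its cluster; per accession the percent
#' of genes in core, dispensable and private clusters is reported (summing
#' to 100).
#'
#' @param matrix Clusters x accessions integer matrix.
#' @param classification Result of [classify_clusters()] on the same matrix.
#' @return data.frame with columns `accession`, `n_genes`, `core_pct`,
#'   `dispensable_pct`, `private_pct`.
#' @export
per_genome_composition <- function(matrix, classification) {
  stopifnot(inherits(classification, "cluster_classification"))
  labels <- classification$labels
  if (!identical(names(labels), rownames(matrix)))
    ap_stop("classification does not match the matrix clusters")
  rows <- lapply(colnames(matrix), function(acc) {
    cnt <- matrix[, acc]
    total <- sum(cnt)
    if (total == 0) ap_stop("accession ", acc, " carries no genes")
    by_cat <- vapply(c("core", "dispensable", "private"),
                     function(l) sum(cnt[labels == l]), numeric(1))
    data.frame(accession = acc, n_genes = total,
               core_pct = 100 * by_cat[["core"]] / total,
               dispensable_pct = 100 * by_cat[["dispensable"]] / total,
               private_pct = 100 * by_cat[["private"]] / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a per-gene metric across pangenome categories
#'
#' Pairwise two-sided Wilcoxon rank-sum tests of a per-gene property (CDS
#' length, log2(TPM+1) expression, or Ka/Ks) between the core, dispensable
#' and private categories, with medians per category. Exact p-values are
#' used when the combined sample size is at most 20 (and no ties), the
#' tie-corrected normal approximation otherwise. Categories with fewer than
#' two observations are excluded with a warning.
#'
#' @param stats data.frame with a `category` column and the metric column.
#' @param metric One of `"cds_length"`, `"expression"`, `"kaks"` (or any
#'   numeric column name present in `stats`).
#' @return List with `medians` (named numeric) and `tests` (data.frame
#'   `category1`, `category2`, `n1`, `n2`, `p`).
#' @export
compare_categories <- function(stats,
                               metric = c("cds_length", "expression", "kaks")) {
  metric <- if (length(metric) > 1) metric[1] else metric
  stopifnot(is.data.frame(stats), "category" %in% names(stats),
            metric %in% names(stats))
  stats <- stats[!is.na(stats[[metric]]), , drop = FALSE]
  vals <- split(stats[[metric]], stats$category)
  small <- names(vals)[vapply(vals, length, integer(1)) < 2]
  if (length(small)) {
    ap_warn("categories excluded (fewer than 2 observations): ",
            paste(small, collapse = ", "))
    vals <- vals[!(names(vals) %in% small)]
  }
  if (length(vals) < 2) ap_stop("need at least two comparable categories")
  medians <- vapply(vals, median, numeric(1))
  combs <- combn(names(vals), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(combs, function(cc) {
    x <- vals[[cc[1]]]; y <- vals[[cc[2]]]
    exact <- (length(x) + length(y)) <= 20
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE)$p.value)
    data.frame(category1 = cc[1], category2 = cc[2],
               n1 = length(x), n2 = length(y), p = p,
               stringsAsFactors = FALSE)
  }))
  list(medians = medians, tests = tests, metric = metric)
}
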