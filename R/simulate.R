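## Synthetic-data module: generates every input the pipeline consumes with
## known ground truth. All generators are deterministic given `seed`.

#' Simulate an orthogroup gene-count matrix with known category labels
#'
#' Core clusters are present in every accession, private clusters in exactly
#' one (uniformly chosen), dispensable clusters in k accessions with k uniform
#' on 2..(n_accessions - 1). Where present, per-cluster gene counts are
#' 1 + Poisson(0.3). Default proportions follow the observed pangenome
#' composition of the six water-caltrop (sub)genomes (48.05% core, 28.92%
#' dispensable, 23.03% private).
#'
#' @param n_accessions Number of accessions (>= 2; >= 3 if any dispensable
#'   clusters are requested).
#' @param n_clusters Number of clusters.
#' @param proportions Length-3 numeric (core, dispensable, private) summing
#'   to 1.
#' @param seed Integer RNG seed.
#' @return List with `matrix` (clusters x accessions integer matrix) and
#'   `truth` (named character vector of cluster labels).
#' @export
#' @examples
#' sim <- make_orthogroup_matrix(6, 100, c(0.5, 0.3, 0.2), seed = 1)
#' table(sim$truth)
make_orthogroup_matrix <- function(n_accessions, n_clusters,
                                   proportions = c(0.4805, 0.2892, 0.2303),
                                   seed) {
  if (n_accessions < 2) ap_stop("need n_accessions >= 2")
  if (length(proportions) != 3 || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    ap_stop("proportions must be a length-3 simplex (core, dispensable, private)")
  set.seed(seed)
  n_core <- round(proportions[1] * n_clusters)
  n_priv <- round(proportions[3] * n_clusters)
  n_disp <- n_clusters - n_core - n_priv
  if (n_disp < 0) { n_priv <- n_priv + n_disp; n_disp <- 0 }
  if (n_disp > 0 && n_accessions < 3)
    ap_stop("dispensable clusters need n_accessions >= 3")
  labels <- rep(c("core", "dispensable", "private"),
                times = c(n_core, n_disp, n_priv))
  ids <- sprintf("OG%06d", seq_len(n_clusters))
  accs <- sprintf("acc%02d", seq_len(n_accessions))
  present <- matrix(FALSE, n_clusters, n_accessions,
                    dimnames = list(ids, accs))
  present[labels == "core", ] <- TRUE
  for (i in which(labels == "private"))
    present[i, sample.int(n_accessions, 1)] <- TRUE
  for (i in which(labels == "dispensable")) {
    k <- sample(2:(n_accessions - 1), 1)
    present[i, sample.int(n_accessions, k)] <- TRUE
  }
  counts <- matrix(0L, n_clusters, n_accessions, dimnames = list(ids, accs))
  counts[present] <- 1L + rpois(sum(present), 0.3)
  list(matrix = counts, truth = setNames(labels, ids))
}

#' Simulate a windowed depth track with implanted duplications/deletions
#'
#' Background windows draw depth from Normal(base_depth, noise_sd) truncated
#' at 0; windows inside a `dup` implant from Normal(2 x base_depth, noise_sd)
#' and inside a `del` implant from Normal(0.05 x base_depth, noise_sd)
#' truncated at 0. The 0.05x deletion level (rather than exactly zero) keeps
#' the "low or no coverage" deletion threshold genuinely exercised.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param window Window size in bp (default 10000).
#' @param base_depth Background mean depth (default 30).
#' @param noise_sd Depth standard deviation (default 3).
#' @param implants data.frame with columns `chrom`, `start`, `end`, `kind`
#'   (dup/del); window-aligned, non-overlapping, within the chromosome.
#' @param seed Integer RNG seed.
#' @return List with `track` (a [depth_track()]) and `truth` (the implant
#'   table plus the generating parameters).
#' @export
make_depth_track <- function(chrom_lengths, window = 10000L, base_depth = 30,
                             noise_sd = 3,
                             implants = data.frame(chrom = character(),
                                                   start = integer(),
                                                   end = integer(),
                                                   kind = character()),
                             seed) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (nrow(implants)) {
    stopifnot(all(implants$kind %in% c("dup", "del")))
    validate_intervals(implants, "implant")
    if (!all(implants$chrom %in% names(chrom_lengths)))
      ap_stop("implant on unknown chromosome")
    if (any(implants$end > chrom_lengths[implants$chrom]))
      ap_stop("implant exceeds chromosome length")
    if (any(implants$start %% window != 0 | implants$end %% window != 0))
      ap_stop("implants must be window-aligned")
    o <- order(implants$chrom, implants$start)
    im <- implants[o, ]
    for (ch in unique(im$chrom)) {
      w <- im[im$chrom == ch, ]
      if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
        ap_stop("implants overlap on ", ch)
    }
  }
  set.seed(seed)
  parts <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = window)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window, len)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  mid <- (df$start + df$end) / 2
  mu <- rep(base_depth, nrow(df))
  if (nrow(implants)) {
    for (i in seq_len(nrow(implants))) {
      hit <- df$chrom == implants$chrom[i] & mid > implants$start[i] &
        mid < implants$end[i]
      mu[hit] <- if (implants$kind[i] == "dup") 2 * base_depth
                 else 0.05 * base_depth
    }
  }
  df$depth <- pmax(0, rnorm(nrow(df), mean = mu, sd = noise_sd))
  list(track = depth_track(df, window),
       truth = list(implants = implants, base_depth = base_depth,
                    noise_sd = noise_sd, window = window))
}

#' Simulate a PAV genotype matrix with two-lineage structure
#'
#' A fraction `frac_differentiated` of PAVs is lineage-fixed: present in all
#' A-lineage samples and absent in all B-lineage samples, or vice versa (fair
#' coin per PAV). The remainder share a presence probability drawn uniform on
#' (0.05, 0.95) across both lineages; draws that land lineage-fixed by
#' chance are rejected and redrawn, so the differentiated set is exactly
#' re-derivable from the genotypes. Genotypes are then masked to missing
#' independently with `missing_rate`. The default differentiated fraction
#' matches the 25.9% observed between the A- and B-lineages.
#'
#' @param n_pavs Number of PAV records.
#' @param samples_A,samples_B Disjoint character vectors of sample names.
#' @param frac_differentiated Probability a PAV is lineage-fixed
#'   (default 0.259).
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param seed Integer RNG seed.
#' @return List with `pav` (a [pav_table()]) and `truth` (ids of
#'   differentiated PAVs).
#' @export
make_pav_matrix <- function(n_pavs, samples_A, samples_B,
                            frac_differentiated = 0.259, missing_rate = 0,
                            seed) {
  if (length(intersect(samples_A, samples_B)))
    ap_stop("sample lists must be disjoint")
  stopifnot(length(samples_A) >= 1, length(samples_B) >= 1,
            frac_differentiated >= 0, frac_differentiated <= 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  samples <- c(samples_A, samples_B)
  ids <- sprintf("pav_%06d", seq_len(n_pavs))
  n_diff <- round(frac_differentiated * n_pavs)
  is_diff <- seq_len(n_pavs) <= n_diff
  gt <- matrix("absent", n_pavs, length(samples),
               dimnames = list(ids, samples))
  a_cols <- samples %in% samples_A
  for (i in which(is_diff)) {
    in_a <- runif(1) < 0.5
    gt[i, a_cols] <- if (in_a) "present" else "absent"
    gt[i, !a_cols] <- if (in_a) "absent" else "present"
  }
  for (i in which(!is_diff)) {
    p <- runif(1, 0.05, 0.95)
    ## reject draws that are lineage-fixed by chance so the differentiated
    ## set in the truth object is exactly re-derivable from the genotypes
    repeat {
      g <- ifelse(runif(length(samples)) < p, "present", "absent")
      fa <- mean(g[a_cols] == "present"); fb <- mean(g[!a_cols] == "present")
      if (abs(fa - fb) < 1) break
    }
    gt[i, ] <- g
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(length(gt)) < missing_rate, nrow = n_pavs)
    gt[mask] <- "missing"
  }
  svlen <- as.integer(round(exp(runif(n_pavs, log(50), log(5000)))))
  start <- sort(sample.int(n_pavs * 2000L, n_pavs)) - 1L
  svtype <- sample(c("INS", "DEL"), n_pavs, replace = TRUE)
  rec <- data.frame(id = ids, chrom = "bb_chr1", start = start,
                    end = as.integer(ifelse(svtype == "DEL", start + svlen,
                                            start + 1L)),
                    svtype = svtype, svlen = svlen, stringsAsFactors = FALSE)
  list(pav = pav_table(rec, gt, backbone = "synthetic_backbone"),
       truth = ids[is_diff])
}

#' Simulate homeolog expression counts with a biased fraction
#'
#' Each homeolog pair has a base mean drawn log-uniform over
#' `exp(mean_log_range)`, modulated by a per-tissue log-normal factor shared
#' by both homeologs. For biased pairs the B-homeolog mean is multiplied by
#' `2^bias_log2fc` in every tissue. Counts are negative binomial with
#' dispersion `nb_dispersion` (variance mu + dispersion x mu^2). The default design
#' is four tissues (flower bud FB, fertilized flower FF, juvenile fruit JF,
#' leaf L) with three biological replicates each.
#'
#' @param n_pairs Number of homeolog pairs.
#' @param n_tissues Number of tissues (1..4, default 4).
#' @param n_reps Replicates per tissue (default 3).
#' @param frac_biased Fraction of pairs with true bias.
#' @param bias_log2fc True log2 fold change (B over A) of biased pairs.
#' @param nb_dispersion NB dispersion (> 0).
#' @param mean_log_range Range of log base means (default log(20)..log(2000)).
#' @param n_chrom_pairs Chromosome-pair labels to spread pairs over
#'   (default 12).
#' @param seed Integer RNG seed.
#' @return List with `counts` (genes x samples), `meta` (sample sheet),
#'   `pairs` (pair table with `chrom_pair`), and `truth` (biased pair ids and
#'   the true log2 fold change).
#' @export
make_homeolog_counts <- function(n_pairs, n_tissues = 4L, n_reps = 3L,
                                 frac_biased = 0.1, bias_log2fc = 2,
                                 nb_dispersion = 0.05,
                                 mean_log_range = log(c(20, 2000)),
                                 n_chrom_pairs = 12L, seed) {
  if (nb_dispersion <= 0) ap_stop("nb_dispersion must be > 0")
  stopifnot(n_tissues >= 1, n_tissues <= 4, n_reps >= 1,
            frac_biased >= 0, frac_biased <= 1)
  set.seed(seed)
  tissues <- c("FB", "FF", "JF", "L")[seq_len(n_tissues)]
  meta <- data.frame(
    sample = paste0(rep(tissues, each = n_reps), "_r", seq_len(n_reps)),
    tissue = rep(tissues, each = n_reps),
    replicate = rep(seq_len(n_reps), times = n_tissues),
    stringsAsFactors = FALSE)
  pid <- sprintf("pair_%05d", seq_len(n_pairs))
  pairs <- data.frame(
    pair_id = pid,
    gene_A = paste0(pid, "_A"), gene_B = paste0(pid, "_B"),
    chrom_pair = sprintf("chr%02dA-chr%02dB",
                         ((seq_len(n_pairs) - 1L) %% n_chrom_pairs) + 1L,
                         ((seq_len(n_pairs) - 1L) %% n_chrom_pairs) + 1L),
    stringsAsFactors = FALSE)
  n_biased <- round(frac_biased * n_pairs)
  biased <- seq_len(n_pairs) <= n_biased
  base_mu <- exp(runif(n_pairs, mean_log_range[1], mean_log_range[2]))
  tissue_fac <- matrix(exp(rnorm(n_pairs * n_tissues, 0, 0.2)),
                       n_pairs, n_tissues)
  size <- 1 / nb_dispersion
  counts <- matrix(0L, 2L * n_pairs, nrow(meta),
                   dimnames = list(c(pairs$gene_A, pairs$gene_B), meta$sample))
  for (t in seq_len(n_tissues)) {
    muA <- base_mu * tissue_fac[, t]
    muB <- muA * ifelse(biased, 2^bias_log2fc, 1)
    for (r in seq_len(n_reps)) {
      s <- (t - 1L) * n_reps + r
      counts[seq_len(n_pairs), s] <- rnbinom(n_pairs, mu = muA, size = size)
      counts[n_pairs + seq_len(n_pairs), s] <-
        rnbinom(n_pairs, mu = muB, size = size)
    }
  }
  list(counts = counts, meta = meta, pairs = pairs,
       truth = list(biased_pairs = pid[biased], bias_log2fc = bias_log2fc,
                    nb_dispersion = nb_dispersion))
}

#' Simulate a codon-aligned sequence pair with known substitution counts
#'
#' Starts from a random stop-free codon sequence and applies exactly `n_syn`
#' synonymous and `n_nonsyn` nonsynonymous single-nucleotide changes, each in
#' a distinct codon and never creating a stop codon. One change per codon
#' keeps NG86 pathway counting exactly enumerable.
#'
#' @param n_codons Alignment length in codons.
#' @param n_syn,n_nonsyn Numbers of synonymous / nonsynonymous changes;
#'   their sum must not exceed `n_codons`.
#' @param seed Integer RNG seed.
#' @return List with `seq1`, `seq2` (character) and `truth`
#'   (n_syn, n_nonsyn, mutated codon indices).
#' @export
make_sequence_pairs <- function(n_codons, n_syn, n_nonsyn, seed) {
  if (n_syn + n_nonsyn > n_codons)
    ap_stop("n_syn + n_nonsyn must not exceed n_codons (one change per codon)")
  stopifnot(n_codons >= 1, n_syn >= 0, n_nonsyn >= 0)
  set.seed(seed)
  tab <- codon_tables()
  cods <- sample(tab$sense, n_codons, replace = TRUE)
  idx <- sample.int(n_codons, n_syn + n_nonsyn)
  syn_idx <- idx[seq_len(n_syn)]
  non_idx <- setdiff(idx, syn_idx)
  ## codons targeted for a synonymous change must have a synonymous neighbour
  for (i in syn_idx)
    if (!length(tab$neigh[[cods[i]]]$syn))
      cods[i] <- sample(tab$syn_capable, 1)
  cods2 <- cods
  for (i in syn_idx) {
    opts <- tab$neigh[[cods[i]]]$syn
    cods2[i] <- opts[sample.int(length(opts), 1)]
  }
  for (i in non_idx) {
    opts <- tab$neigh[[cods[i]]]$nonsyn  # excludes stop codons by construction
    cods2[i] <- opts[sample.int(length(opts), 1)]
  }
  list(seq1 = paste(cods, collapse = ""),
       seq2 = paste(cods2, collapse = ""),
       truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                    syn_codons = sort(syn_idx), nonsyn_codons = sort(non_idx)))
}
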