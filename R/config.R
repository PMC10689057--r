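#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline with their defaults: 10-kb
#' depth windows, the 1.5x duplication and 0.25x deletion depth factors, the
#' 50-kb window-linking gap, the (strict) 80-kb minimum HE segment length, the
#' 2-kb cis-regulatory flank around genes, the 50-bp minimum PAV length, the
#' 10-kb TE family-size contrast threshold, and the 0.05 FDR level.
#'
#' @param window_size_bp Depth window size in bp.
#' @param dup_factor Duplication depth threshold as a multiple of the genome
#'   mean (inclusive).
#' @param del_factor Deletion depth threshold as a multiple of the genome mean
#'   (inclusive).
#' @param link_gap_bp Maximum gap (bp) between same-kind flagged windows that
#'   is still linked into one segment.
#' @param min_he_len_bp Minimum HE segment length in bp; segments must be
#'   strictly longer than this.
#' @param cis_flank_bp Flank in bp added on both sides of a gene when
#'   associating PAVs.
#' @param min_pav_len_bp Minimum absolute PAV length in bp (inclusive).
#' @param te_diff_threshold_bp Minimum absolute lineage size difference (bp)
#'   for flagging a TE family (inclusive).
#' @param fdr_alpha FDR level for biased/DEG calls.
#' @param mutation_rate Substitutions per site per year for LTR dating; no
#'   default is supplied silently, it must be chosen by the user.
#' @param rng_seed Integer seed recorded alongside results.
#'
#' @return A list of class `allopan_config`.
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$window_size_bp
run_config <- function(window_size_bp = 10000L,
                       dup_factor = 1.5,
                       del_factor = 0.25,
                       link_gap_bp = 50000L,
                       min_he_len_bp = 80000L,
                       cis_flank_bp = 2000L,
                       min_pav_len_bp = 50L,
                       te_diff_threshold_bp = 10000L,
                       fdr_alpha = 0.05,
                       mutation_rate = NA_real_,
                       rng_seed = NA_integer_) {
  lens <- c(window_size_bp = window_size_bp, min_he_len_bp = min_he_len_bp,
            cis_flank_bp = cis_flank_bp, min_pav_len_bp = min_pav_len_bp,
            te_diff_threshold_bp = te_diff_threshold_bp)
  if (any(lens <= 0)) ap_stop("all length parameters must be > 0")
  if (link_gap_bp < 0) ap_stop("link_gap_bp must be >= 0")
  if (!(del_factor > 0 && del_factor < 1 && dup_factor > 1))
    ap_stop("need 0 < del_factor < 1 < dup_factor")
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) ap_stop("fdr_alpha must be in (0, 1)")
  structure(list(window_size_bp = as.integer(window_size_bp),
                 dup_factor = dup_factor, del_factor = del_factor,
                 link_gap_bp = as.integer(link_gap_bp),
                 min_he_len_bp = as.integer(min_he_len_bp),
                 cis_flank_bp = as.integer(cis_flank_bp),
                 min_pav_len_bp = as.integer(min_pav_len_bp),
                 te_diff_threshold_bp = as.integer(te_diff_threshold_bp),
                 fdr_alpha = fdr_alpha, mutation_rate = mutation_rate,
                 rng_seed = rng_seed),
            class = "allopan_config")
}

#' @method print allopan_config
#' @export
print.allopan_config <- function(x, ...) {
  cat("allopan configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

## shared validator for interval data.frames (chrom/start/end)
validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    ap_stop(what, ": chrom must be non-empty")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    ap_stop(what, " ", bad[1], ": requires 0 <= start < end (end <= start found)")
  invisible(df)
}
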