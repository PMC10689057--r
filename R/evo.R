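#' Nei-Gojobori (1986) Ka/Ks on a codon alignment
#'
#' Counting method with Jukes-Cantor correction. Per codon, synonymous sites
#' are 3 x (the fraction of the nine single-nucleotide changes that are
#' synonymous), averaged over the two sequences, so S + N = 3 x codons
#' exactly. Differences between codons differing at d positions are averaged
#' with equal weight over all d! orderings of single-nucleotide steps;
#' pathways passing through a stop codon are excluded and the weights
#' renormalized (if every pathway is blocked, all are used). Proportions
#' pS = Sd/S and pN = Nd/N receive the JC69 correction
#' d = -(3/4) ln(1 - 4p/3); a proportion >= 0.75 yields an infinite
#' distance. The Ka/Ks ratio is NA when Ks is zero or non-finite. Universal
#' genetic code only.
#'
#' @param seq1,seq2 Equal-length, gap-free, in-frame coding sequences
#'   (A/C/G/T, length a positive multiple of 3, no stop codons).
#' @return List of class `kaks_result`: `S`, `N` (site totals), `Sd`, `Nd`
#'   (difference counts), `pS`, `pN`, `Ka`, `Ks`, `ratio`, `n_codons`.
#' @export
#' @examples
#' ng86_kaks("GGTGCT", "GGCGCT")$Sd  # one synonymous difference
ng86_kaks <- function(seq1, seq2) {
  seq1 <- check_coding(seq1, "seq1")
  seq2 <- check_coding(seq2, "seq2")
  if (nchar(seq1) != nchar(seq2)) ap_stop("sequences must be equal length")
  tab <- codon_tables()
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  n_codons <- length(c1)
  S <- (sum(tab$syn_sites[c1]) + sum(tab$syn_sites[c2])) / 2
  N <- 3 * n_codons - S
  Sd <- Nd <- 0
  for (i in seq_len(n_codons)) {
    d <- codon_path_diffs(c1[i], c2[i], tab)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc69_distance(pS)
  Ka <- jc69_distance(pN)
  ratio <- if (is.na(Ks) || !is.finite(Ks) || Ks == 0 || !is.finite(Ka))
    NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ka = Ka, Ks = Ks, ratio = ratio, n_codons = n_codons),
            class = "kaks_result")
}

#' @method print kaks_result
#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: %d codons | S=%.2f N=%.2f | Sd=%.2f Nd=%.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("Ka=%.5f Ks=%.5f Ka/Ks=%s\n", x$Ka, x$Ks,
              ifelse(is.na(x$ratio), "undefined", sprintf("%.4f", x$ratio))))
  invisible(x)
}

## average (Sd, Nd) over all orderings of single-nucleotide steps between two
## codons, excluding pathways through stop codons
codon_path_diffs <- function(a, b, tab = codon_tables()) {
  if (a == b) return(c(0, 0))
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  pos <- which(sa != sb)
  orders <- switch(length(pos),
                   list(pos),
                   list(pos, rev(pos)),
                   lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                          function(o) pos[o]))
  paths <- matrix(NA_real_, length(orders), 2)
  for (k in seq_along(orders)) {
    cur <- sa
    sd <- nd <- 0
    ok <- TRUE
    for (p in orders[[k]]) {
      nxt <- cur; nxt[p] <- sb[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (tab$code[[to]] == "*") { ok <- FALSE; break }
      if (tab$code[[from]] == tab$code[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) paths[k, ] <- c(sd, nd)
  }
  valid <- !is.na(paths[, 1])
  if (!any(valid)) {
    ## all pathways blocked by stops: fall back to unrestricted averaging
    for (k in seq_along(orders)) {
      cur <- sa; sd <- nd <- 0
      for (p in orders[[k]]) {
        nxt <- cur; nxt[p] <- sb[p]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        if (tab$code[[from]] == tab$code[[to]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      paths[k, ] <- c(sd, nd)
    }
    valid <- rep(TRUE, nrow(paths))
  }
  colMeans(paths[valid, , drop = FALSE])
}

#' Jukes-Cantor (JC69) corrected distance
#'
#' K = -(3/4) ln(1 - 4p/3), the expected substitutions per site given an
#' observed mismatch fraction p under the one-parameter model. Always at
#' least p; infinite for p >= 0.75.
#'
#' @param p Observed mismatch proportion(s) in \[0, 0.75).
#' @return Corrected distance(s); `Inf` where p >= 0.75.
#' @export
#' @examples
#' jc69_distance(0.1)  # 0.10732
jc69_distance <- function(p) {
  if (any(p < 0, na.rm = TRUE)) ap_stop("mismatch proportion must be >= 0")
  out <- ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
  out[p == 0] <- 0
  out
}

#' Mismatch fraction between two aligned LTR sequences
#'
#' Columns where either sequence has a gap (`-`) or `N` are ignored.
#'
#' @param seq5,seq3 Aligned 5' and 3' LTR sequences (equal length).
#' @return Proportion of mismatched comparable columns.
#' @export
ltr_mismatch <- function(seq5, seq3) {
  seq5 <- toupper(seq5); seq3 <- toupper(seq3)
  if (nchar(seq5) != nchar(seq3)) ap_stop("aligned LTRs must be equal length")
  a <- strsplit(seq5, "")[[1]]; b <- strsplit(seq3, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) ap_stop("no comparable columns")
  mean(a[ok] != b[ok])
}

#' LTR retrotransposon insertion time
#'
#' The two LTRs of an element are identical at insertion and diverge
#' neutrally afterwards, so T = K / (2 mu) with K the JC69-corrected 5'-3'
#' LTR divergence and mu the substitution rate per site per year. No default
#' rate is supplied: ages are only meaningful conditional on a user-chosen
#' rate.
#'
#' @param p Raw mismatch fraction between the two LTRs (used unless `K`
#'   is given).
#' @param K JC69-corrected divergence, overriding `p`.
#' @param mutation_rate Substitutions per site per year (> 0).
#' @return List with `K`, `years`, `mya`.
#' @export
#' @examples
#' ltr_insertion_time(K = 0.026, mutation_rate = 1.3e-8)$mya  # 1
ltr_insertion_time <- function(p = NULL, K = NULL, mutation_rate) {
  if (missing(mutation_rate) || is.na(mutation_rate) || mutation_rate <= 0)
    ap_stop("mutation_rate must be a positive substitutions/site/year value")
  if (is.null(K)) {
    if (is.null(p)) ap_stop("supply either p or K")
    K <- jc69_distance(p)
  }
  years <- K / (2 * mutation_rate)
  list(K = K, years = years, mya = years / 1e6)
}

#' Contrast TE family sizes between two lineages
#'
#' Per family, the mean total size (bp) over the genomes of each lineage is
#' compared; a family is flagged when the absolute difference reaches
#' `threshold_bp` (10 kb by default, inclusive). Genomes lacking a family
#' contribute 0 bp.
#'
#' @param table Long data.frame with columns `family`, `genome`, `size_bp`.
#' @param lineages Named character vector mapping genome -> "A"/"B"; both
#'   lineages need at least one genome.
#' @param threshold_bp Flagging threshold in bp (default 10000).
#' @return List with `per_family` (family, mean_A, mean_B, difference,
#'   flagged) and `summary` (n_flagged, n_larger_A, n_larger_B).
#' @export
te_family_contrast <- function(table, lineages, threshold_bp = 10000L) {
  stopifnot(all(c("family", "genome", "size_bp") %in% names(table)),
            all(table$genome %in% names(lineages)))
  if (!all(c("A", "B") %in% lineages))
    ap_stop("both lineages need at least one genome")
  genomes_A <- names(lineages)[lineages == "A"]
  genomes_B <- names(lineages)[lineages == "B"]
  fams <- sort(unique(table$family))
  sz <- matrix(0, length(fams), length(lineages),
               dimnames = list(fams, names(lineages)))
  sz[cbind(match(table$family, fams), match(table$genome, names(lineages)))] <-
    table$size_bp
  mean_A <- rowMeans(sz[, genomes_A, drop = FALSE])
  mean_B <- rowMeans(sz[, genomes_B, drop = FALSE])
  diffs <- mean_A - mean_B
  flagged <- abs(diffs) >= threshold_bp
  per_family <- data.frame(family = fams, mean_A = mean_A, mean_B = mean_B,
                           difference = diffs, flagged = flagged,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(per_family = per_family,
       summary = list(n_flagged = sum(flagged),
                      n_larger_A = sum(flagged & diffs > 0),
                      n_larger_B = sum(flagged & diffs < 0)))
}
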