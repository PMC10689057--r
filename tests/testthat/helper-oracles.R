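## Independent oracles, deliberately written with different machinery than
## the package implementations they check.

## Brute-force NG86 oracle: recursive pathway enumeration for differences,
## naive per-codon loop for site counting, straight from the genetic code.
oracle_ng86_counts <- function(seq1, seq2) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  cods1 <- substring(seq1, seq(1, nchar(seq1), 3), seq(3, nchar(seq1), 3))
  cods2 <- substring(seq2, seq(1, nchar(seq2), 3), seq(3, nchar(seq2), 3))
  syn_sites <- function(cod) {
    s <- strsplit(cod, "")[[1]]
    n_syn <- 0
    for (pos in 1:3) for (nt in nts) {
      if (nt == s[pos]) next
      alt <- s; alt[pos] <- nt
      if (code[[paste(alt, collapse = "")]] == code[[cod]]) n_syn <- n_syn + 1
    }
    3 * n_syn / 9
  }
  ## recursive enumeration of all orderings of the differing positions
  walk <- function(cur, target) {
    pos <- which(cur != target)
    if (!length(pos)) return(list(c(s = 0, n = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur; nxt[p] <- target[p]
      to <- paste(nxt, collapse = "")
      if (code[[to]] == "*") next  # pathway blocked
      step <- if (code[[paste(cur, collapse = "")]] == code[[to]])
        c(s = 1, n = 0) else c(s = 0, n = 1)
      for (tail in walk(nxt, target))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  S <- mean(c(sum(vapply(cods1, syn_sites, 0)), sum(vapply(cods2, syn_sites, 0))))
  Sd <- Nd <- 0
  for (i in seq_along(cods1)) {
    if (cods1[i] == cods2[i]) next
    paths <- walk(strsplit(cods1[i], "")[[1]], strsplit(cods2[i], "")[[1]])
    if (!length(paths)) {
      ## all pathways blocked: enumerate without the stop restriction
      walk_all <- function(cur, target) {
        pos <- which(cur != target)
        if (!length(pos)) return(list(c(s = 0, n = 0)))
        out <- list()
        for (p in pos) {
          nxt <- cur; nxt[p] <- target[p]
          step <- if (code[[paste(cur, collapse = "")]] ==
                        code[[paste(nxt, collapse = "")]])
            c(s = 1, n = 0) else c(s = 0, n = 1)
          for (tail in walk_all(nxt, target))
            out[[length(out) + 1]] <- step + tail
        }
        out
      }
      paths <- walk_all(strsplit(cods1[i], "")[[1]], strsplit(cods2[i], "")[[1]])
    }
    m <- Reduce(`+`, paths) / length(paths)
    Sd <- Sd + m[["s"]]; Nd <- Nd + m[["n"]]
  }
  list(S = S, N = 3 * length(cods1) - S, Sd = Sd, Nd = Nd)
}

## Brute-force two-sided signed-rank p by full sign enumeration (expand.grid)
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  mu <- sum(r) / 2
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(x)))
  null <- apply(grid, 1, function(g) sum(r[as.logical(g)]))
  mean(abs(null - mu) >= abs(W - mu) - 1e-12)
}

## small deterministic orthogroup fixture: c1 in all, c2 in acc1+acc2, c3 in acc3
fixture_og3 <- function() {
  m <- rbind(c1 = c(1L, 1L, 1L), c2 = c(1L, 2L, 0L), c3 = c(0L, 0L, 1L))
  colnames(m) <- c("acc1", "acc2", "acc3")
  m
}

## depth track built directly from window depths on one chromosome
fixture_track <- function(depths, window = 10000L, chrom = "chr1") {
  n <- length(depths)
  chrom <- rep(chrom, n)
  depth_track(data.frame(chrom = chrom,
                         start = (seq_len(n) - 1L) * window,
                         end = seq_len(n) * window,
                         depth = depths), window)
}

## minimal pav_table from a genotype matrix (rows auto-coordinates)
fixture_pav <- function(gt, svtype = "DEL", svlen = 100L, start = NULL,
                        backbone = "bb") {
  n <- nrow(gt)
  if (is.null(start)) start <- (seq_len(n) - 1L) * 10000L
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("p%03d", seq_len(n))
  rec <- data.frame(id = rownames(gt), chrom = "bb_chr1", start = start,
                    end = ifelse(rep(svtype, n) == "DEL", start + svlen,
                                 start + 1L),
                    svtype = svtype, svlen = svlen, stringsAsFactors = FALSE)
  pav_table(rec, gt, backbone = backbone)
}
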