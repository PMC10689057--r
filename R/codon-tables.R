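## Universal genetic code tables shared by the Ka/Ks machinery and the
## sequence-pair simulator. Built once at load from Biostrings::GENETIC_CODE.

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  nts <- c("A", "C", "G", "T")
  sense <- codons[gc != "*"]
  ## single-nucleotide neighbours of every codon, split by effect
  neigh <- lapply(codons, function(cd) {
    s <- strsplit(cd, "")[[1]]
    out <- list(syn = character(), nonsyn = character(), stop = character())
    for (pos in 1:3) for (nt in setdiff(nts, s[pos])) {
      s2 <- s; s2[pos] <- nt
      cd2 <- paste(s2, collapse = "")
      if (gc[[cd2]] == "*") out$stop <- c(out$stop, cd2)
      else if (gc[[cd2]] == gc[[cd]]) out$syn <- c(out$syn, cd2)
      else out$nonsyn <- c(out$nonsyn, cd2)
    }
    out
  })
  names(neigh) <- codons
  ## NG86 synonymous site count: 3 x (synonymous fraction of the 9 changes);
  ## changes to stop codons count as nonsynonymous
  syn_sites <- vapply(codons, function(cd) 3 * length(neigh[[cd]]$syn) / 9,
                      numeric(1))
  .codon_env$tab <- list(code = gc, codons = codons, sense = sense,
                         neigh = neigh, syn_sites = syn_sites,
                         syn_capable = sense[vapply(sense, function(cd)
                           length(neigh[[cd]]$syn) > 0, logical(1))])
  .codon_env$tab
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

translate_codon <- function(cd) codon_tables()$code[cd]

check_coding <- function(seq, label = "sequence") {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) ap_stop(label, ": alphabet must be A/C/G/T")
  if (nchar(seq) %% 3 != 0 || nchar(seq) < 3)
    ap_stop(label, ": length must be a positive multiple of 3")
  cds <- split_codons(seq)
  if (any(codon_tables()$code[cds] == "*"))
    ap_stop(label, ": contains a stop codon")
  seq
}
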