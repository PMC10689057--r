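#' Read an orthogroup gene-count matrix
#'
#' Reads an OrthoFinder "Orthogroups.GeneCount"-style TSV: first column the
#' cluster id, remaining columns per-accession gene counts (a trailing
#' `Total` column, if present, is dropped).
#'
#' @param path TSV path.
#' @return Integer matrix, clusters x accessions.
#' @export
read_orthogroup_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  if ("Total" %in% colnames(df)) df$Total <- NULL
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0)) ap_stop(path, ": counts must be non-negative integers")
  m
}

#' Write an orthogroup gene-count matrix
#' @param m Integer matrix, clusters x accessions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroup_counts <- function(m, path) {
  df <- data.frame(Orthogroup = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw expression count matrix with its sample sheet
#'
#' @param counts_path Genes x samples TSV (first column gene id).
#' @param samples_path Sample sheet TSV with columns `sample`, `tissue`,
#'   `replicate`.
#' @return List with `counts` (integer matrix) and `meta` (data.frame).
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  m <- as.matrix(read.table(counts_path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  meta <- read.table(samples_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "tissue", "replicate") %in% names(meta)))
  if (!setequal(colnames(m), meta$sample))
    ap_stop("count matrix columns and sample sheet disagree")
  list(counts = m[, meta$sample, drop = FALSE], meta = meta)
}

#' Read a homeolog pair table
#'
#' TSV with columns `pair_id`, `gene_A`, `gene_B` and optionally
#' `chrom_pair` (the homeologous chromosome-pair label). The mapping must be
#' 1:1 — no gene may appear in two pairs.
#'
#' @param path TSV path.
#' @return data.frame of pairs.
#' @export
read_homeolog_pairs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "gene_A", "gene_B") %in% names(df)))
  if (anyDuplicated(c(df$gene_A, df$gene_B)))
    ap_stop(path, ": homeolog pairs must be 1:1 (gene reused)")
  df
}

#' Read a TE family size table
#'
#' Long-format TSV with columns `family`, `genome`, `size_bp`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_te_family_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "genome", "size_bp") %in% names(df)))
  if (any(df$size_bp < 0)) ap_stop(path, ": size_bp must be >= 0")
  df
}

#' Read a codon-aligned CDS (or LTR) pair from FASTA
#'
#' @param path FASTA with exactly two aligned sequences.
#' @return Character vector of length 2 (upper case).
#' @export
read_sequence_pair <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 2) ap_stop(path, ": expected exactly 2 sequences")
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a sequence pair to FASTA
#' @param seqs Named character vector of length 2.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_pair <- function(seqs, path) {
  stopifnot(length(seqs) == 2)
  if (is.null(names(seqs))) names(seqs) <- c("seq1", "seq2")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
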