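#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 annotation, keeps only records of type `gene`, and converts
#' the 1-based closed GFF3 coordinates to the package's 0-based half-open
#' convention. Strand is preserved (`*` becomes `.`).
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(genes) == 0) {
    ap_warn("no 'gene' records in ", path)
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    ap_stop("GFF3 ", path, ": gene record without ID attribute")
  strand <- as.character(GenomicRanges::strand(genes))
  strand[strand == "*"] <- "."
  data.frame(id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(genes)),
             start = GenomicRanges::start(genes) - 1L,
             end = GenomicRanges::end(genes),
             strand = strand,
             stringsAsFactors = FALSE)
}
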