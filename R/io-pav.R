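#' PAV table constructor
#'
#' A set of non-redundant presence-absence variants (insertions/deletions of
#' at least `min_pav_len_bp`, 50 bp by default) on a backbone genome, with a
#' per-sample presence genotype matrix.
#'
#' @param records data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (INS or DEL), `svlen` (positive bp).
#' @param genotypes character matrix (records x samples) with values
#'   `"present"`, `"absent"` or `"missing"`; rownames must match `records$id`.
#' @param backbone Optional backbone genome label; checked on merge.
#' @return A list of class `pav_table` with elements `records`, `genotypes`,
#'   `backbone`.
#' @export
pav_table <- function(records, genotypes, backbone = NULL) {
  stopifnot(is.data.frame(records),
            all(c("id", "chrom", "start", "end", "svtype", "svlen") %in%
                  names(records)))
  if (nrow(records)) {
    validate_intervals(records, "PAV")
    if (!all(records$svtype %in% c("INS", "DEL")))
      ap_stop("pav_table: svtype must be INS or DEL")
    if (any(records$svlen <= 0)) ap_stop("pav_table: svlen must be positive")
    if (anyDuplicated(records$id)) ap_stop("pav_table: duplicated PAV ids")
  }
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(records) ||
      (nrow(records) > 0 &&
         !identical(rownames(genotypes), as.character(records$id))))
    ap_stop("pav_table: genotype rows must match record ids")
  if (nrow(genotypes) && !all(genotypes %in% c("present", "absent", "missing")))
    ap_stop("pav_table: genotypes must be present/absent/missing")
  rownames(records) <- NULL
  structure(list(records = records, genotypes = genotypes,
                 backbone = backbone),
            class = "pav_table")
}

#' @method print pav_table
#' @export
print.pav_table <- function(x, ...) {
  cat(sprintf("pav_table: %d PAVs (%d INS, %d DEL) x %d samples\n",
              nrow(x$records), sum(x$records$svtype == "INS"),
              sum(x$records$svtype == "DEL"), ncol(x$genotypes)))
  invisible(x)
}

#' Number of PAV records
#' @param x A [pav_table()].
#' @return Integer count.
#' @export
n_pavs <- function(x) nrow(x$records)

gt_to_code <- function(g) {
  ## VCF GT string -> presence code; any ALT allele counts as present
  out <- rep("missing", length(g))
  out[!is.na(g) & grepl("1", g)] <- "present"
  out[!is.na(g) & !grepl("1", g) & grepl("0", g)] <- "absent"
  out
}

code_to_gt <- c(present = "1/1", absent = "0/0", missing = "./.")

#' Read a VCF-like PAV file
#'
#' Parses symbolic-ALT structural variant records (SVTYPE INS/DEL with SVLEN)
#' and per-sample GT genotypes into a [pav_table()]. Records shorter than
#' `min_len` (|SVLEN|, inclusive threshold: 50 bp retained at the default)
#' are dropped. A genotype carrying any ALT allele is coded `present`, a
#' called REF genotype `absent`, uncalled `missing`.
#'
#' @param path VCF file path (plain text).
#' @param min_len Minimum |SVLEN| in bp (default 50).
#' @return A [pav_table()].
#' @export
read_pav_vcf <- function(path, min_len = 50L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  if (anyNA(svtype) || anyNA(svlen))
    ap_stop("PAV VCF ", path, ": record ", which(is.na(svtype) | is.na(svlen))[1],
            " lacks SVTYPE or SVLEN")
  if (!all(svtype %in% c("INS", "DEL")))
    ap_stop("PAV VCF ", path, ": SVTYPE must be INS or DEL")
  gt <- vcfR::extract.gt(v, element = "GT")
  start <- as.integer(fix[, "POS"]) - 1L
  svlen <- abs(svlen)
  end <- ifelse(svtype == "DEL", start + as.integer(svlen), start + 1L)
  id <- fix[, "ID"]
  if (anyNA(id)) id[is.na(id)] <- sprintf("pav_%06d", which(is.na(id)))
  keep <- svlen >= min_len
  rec <- data.frame(id = id, chrom = fix[, "CHROM"], start = start,
                    end = as.integer(end), svtype = svtype,
                    svlen = as.integer(svlen),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  codes <- apply(gt[keep, , drop = FALSE], 2, gt_to_code)
  if (!is.matrix(codes))
    codes <- matrix(codes, nrow = sum(keep), dimnames = list(NULL, colnames(gt)))
  rownames(codes) <- rec$id
  pav_table(rec, codes)
}

#' Write a PAV table as a VCF-like file
#'
#' @param pav A [pav_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pav_vcf <- function(pav, path) {
  rec <- pav$records
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(pav$genotypes)), collapse = "\t"))
  svlen_signed <- ifelse(rec$svtype == "DEL", -rec$svlen, rec$svlen)
  body <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", rec$svtype[i],
                    svlen_signed[i], rec$end[i])
    body[i] <- paste(c(rec$chrom[i], rec$start[i] + 1L, rec$id[i], "N",
                       sprintf("<%s>", rec$svtype[i]), ".", "PASS", info, "GT",
                       unname(code_to_gt[pav$genotypes[i, ]])),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
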