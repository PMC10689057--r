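#' Depth track constructor
#'
#' An ordered table of fixed-width, non-overlapping genomic windows with mean
#' mapped read depth, the substrate of the HE caller. Coordinates are 0-based
#' half-open.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @param window_size Window width in bp; all windows must have this width
#'   except possibly the last window of each chromosome.
#' @return `df`, sorted by (chrom, start), with class `depth_track` and a
#'   `window_size` attribute.
#' @export
depth_track <- function(df, window_size) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "depth") %in% names(df)))
  if (!is.numeric(df$depth) || anyNA(df$depth))
    ap_stop("depth track: non-numeric or missing depth")
  if (any(df$depth < 0)) ap_stop("depth track: negative depth")
  validate_intervals(df, "depth window")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    w <- df[df$chrom == ch, ]
    n <- nrow(w)
    if (n > 1 && any(w$start[-1] < w$end[-n]))
      ap_stop("depth track: overlapping windows on ", ch)
    widths <- w$end - w$start
    if (n > 1 && any(widths[-n] != window_size))
      ap_stop("depth track: window width != ", window_size, " on ", ch,
              " before the last window")
    if (widths[n] > window_size)
      ap_stop("depth track: last window on ", ch, " wider than ", window_size)
  }
  structure(df, class = c("depth_track", "data.frame"),
            window_size = as.integer(window_size))
}

#' Read a windowed depth track from a BED-like file
#'
#' Expects tab-separated `chrom start end depth` with non-overlapping windows
#' sorted within chromosome, as produced by windowed coverage tools on a
#' fixed, non-overlapping grid (10-kb windows by default in this pipeline).
#'
#' @param path File path.
#' @param window_size Expected window width in bp (default 10000).
#' @return A [depth_track()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t10000\t30", "chr1\t10000\t20000\t31"), f)
#' read_depth_bed(f)
read_depth_bed <- function(path, window_size = 10000L) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "depth"),
                    colClasses = c("character", "integer", "integer", "character"),
                    quote = "", comment.char = "#")
  depth <- suppressWarnings(as.numeric(raw$depth))
  if (anyNA(depth))
    ap_stop("depth BED ", path, ": non-numeric depth at line ",
            which(is.na(depth))[1])
  raw$depth <- depth
  bad <- which(!(raw$start >= 0 & raw$start < raw$end))
  if (length(bad))
    ap_stop("depth BED ", path, " line ", bad[1], ": end <= start")
  ## flag the first unsorted/overlapping line per file, pre-sort
  for (ch in unique(raw$chrom)) {
    idx <- which(raw$chrom == ch)
    w <- raw[idx, ]
    n <- nrow(w)
    if (n > 1) {
      off <- which(w$start[-1] < w$end[-n])
      if (length(off))
        ap_stop("depth BED ", path, " line ", idx[off[1] + 1],
                ": window overlaps or precedes the previous window on ", ch)
    }
  }
  depth_track(raw, window_size = window_size)
}

#' Write a depth track to a BED-like file
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(track, path) {
  df <- as.data.frame(track)
  df$depth <- format(df$depth, digits = 15, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
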