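## Homeologous-exchange caller: windowed depth of the tetraploid read set
## mapped to the two concatenated parental references. A segment replaced by
## its homeolog shows ~2x depth on the donor reference (both subgenome copies
## map there) and ~0x on the recipient.

#' Length-weighted genome mean depth
#'
#' @param track A [depth_track()].
#' @return The mean depth weighted by window width.
#' @export
genome_mean_depth <- function(track) {
  if (nrow(track) == 0) ap_stop("empty depth track")
  sum(track$depth * (track$end - track$start)) / sum(track$end - track$start)
}

#' Flag depth windows as candidate duplications or deletions
#'
#' Windows with depth at least `dup_factor` times the genome mean are flagged
#' `dup` (candidate HE duplications); windows at or below `del_factor` times
#' the mean are flagged `del` (low or no coverage). Both thresholds are
#' inclusive.
#'
#' @param track A [depth_track()].
#' @param mean_depth Genome mean depth; computed from `track` if NULL.
#' @param dup_factor Duplication multiple (default 1.5).
#' @param del_factor Deletion multiple (default 0.25).
#' @return The track with an added `flag` column (`dup`, `del`, `none`).
#' @export
flag_windows <- function(track, mean_depth = NULL, dup_factor = 1.5,
                         del_factor = 0.25) {
  if (!(dup_factor > 1 && del_factor < 1 && del_factor > 0))
    ap_stop("need dup_factor > 1 > del_factor > 0")
  if (is.null(mean_depth)) mean_depth <- genome_mean_depth(track)
  flag <- rep("none", nrow(track))
  flag[track$depth >= dup_factor * mean_depth] <- "dup"
  flag[track$depth <= del_factor * mean_depth] <- "del"
  out <- as.data.frame(track)
  out$flag <- flag
  attr(out, "window_size") <- attr(track, "window_size")
  out
}

#' Merge flagged windows into candidate HE segments
#'
#' Same-kind flagged windows on one chromosome are linked when the gap from
#' the end of one to the start of the next is at most `link_gap_bp` (50 kb,
#' i.e. up to five 10-kb windows, by default); gap windows are absorbed into
#' the merged interval. Only segments strictly longer than `min_len_bp`
#' (80 kb by default — "extended beyond" read literally) are retained.
#'
#' @param flags Output of [flag_windows()].
#' @param link_gap_bp Maximum linking gap in bp (default 50000).
#' @param min_len_bp Strict minimum segment length in bp (default 80000).
#' @return data.frame with columns `chrom`, `start`, `end`, `kind`,
#'   `mean_depth` (over the flagged member windows), `n_windows` (flagged
#'   windows merged), sorted by position.
#' @export
merge_segments <- function(flags, link_gap_bp = 50000L, min_len_bp = 80000L) {
  stopifnot("flag" %in% names(flags), link_gap_bp >= 0)
  out <- list()
  for (kind in c("dup", "del")) {
    w <- flags[flags$flag == kind, , drop = FALSE]
    for (ch in unique(w$chrom)) {
      v <- w[w$chrom == ch, , drop = FALSE]
      v <- v[order(v$start), , drop = FALSE]
      run_start <- 1L
      for (i in seq_len(nrow(v))) {
        last <- i == nrow(v)
        if (!last && v$start[i + 1L] - v$end[i] <= link_gap_bp) next
        idx <- run_start:i
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = v$start[run_start], end = v$end[i],
          kind = kind, mean_depth = mean(v$depth[idx]),
          n_windows = length(idx), stringsAsFactors = FALSE)
        run_start <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      mean_depth = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  seg <- do.call(rbind, out)
  seg <- seg[seg$end - seg$start > min_len_bp, , drop = FALSE]
  seg <- seg[order(seg$chrom, seg$start, seg$kind), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

## piecewise-linear projection of an interval through a syntenic block map
project_interval <- function(chrom, start, end, map, from = c("A", "B")) {
  from <- match.arg(from)
  if (from == "A") {
    src <- map[, c("chrom_A", "start_A", "end_A")]
    dst <- map[, c("chrom_B", "start_B", "end_B")]
  } else {
    src <- map[, c("chrom_B", "start_B", "end_B")]
    dst <- map[, c("chrom_A", "start_A", "end_A")]
  }
  names(src) <- names(dst) <- c("chrom", "start", "end")
  hit <- which(src$chrom == chrom & src$start < end & start < src$end)
  if (!length(hit)) return(NULL)
  do.call(rbind, lapply(hit, function(i) {
    a <- max(start, src$start[i]); b <- min(end, src$end[i])
    scale <- (dst$end[i] - dst$start[i]) / (src$end[i] - src$start[i])
    data.frame(chrom = dst$chrom[i],
               start = dst$start[i] + (a - src$start[i]) * scale,
               end = dst$start[i] + (b - src$start[i]) * scale,
               stringsAsFactors = FALSE)
  }))
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Pair duplication and deletion segments into directional HE calls
#'
#' A duplication segment on parental genome X whose homeologous projection
#' (through the syntenic interval map) reciprocally overlaps a deletion
#' segment on parental genome Y by at least `min_reciprocal_overlap` of both
#' lengths yields one HE call with direction X -> Y (donor X, recipient Y);
#' the call length is the recipient deletion length. Segments without a
#' partner are reported as unresolved.
#'
#' @param dup_segments_A,del_segments_A,dup_segments_B,del_segments_B
#'   Segment tables from [merge_segments()] on the two parental depth tracks.
#' @param map Homeolog interval map: data.frame with columns `chrom_A`,
#'   `start_A`, `end_A`, `chrom_B`, `start_B`, `end_B` (non-overlapping
#'   within each genome).
#' @param min_reciprocal_overlap Reciprocal overlap fraction (default 0.5).
#' @return List with `calls` (data.frame of donor/recipient intervals,
#'   `direction` A->B or B->A, `length_bp`), `unresolved` (segment table with
#'   `genome` and `kind`), and `summary` (per-direction count and Mb).
#' @export
call_hes <- function(dup_segments_A, del_segments_A,
                     dup_segments_B, del_segments_B,
                     map, min_reciprocal_overlap = 0.5) {
  empty_calls <- data.frame(
    donor_chrom = character(), donor_start = integer(), donor_end = integer(),
    recipient_chrom = character(), recipient_start = integer(),
    recipient_end = integer(), direction = character(),
    length_bp = integer(), stringsAsFactors = FALSE)
  add_genome <- function(df, g, keep = NULL) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    out <- cbind(df, genome = g, stringsAsFactors = FALSE)
    if (!is.null(keep)) out <- out[keep, , drop = FALSE]
    if (nrow(out)) out else NULL
  }
  if (is.null(map) || nrow(map) == 0) {
    ap_warn("empty homeolog interval map: all segments unresolved")
    unresolved <- do.call(rbind, c(list(
      add_genome(dup_segments_A, "A"), add_genome(del_segments_A, "A"),
      add_genome(dup_segments_B, "B"), add_genome(del_segments_B, "B"))))
    return(list(calls = empty_calls, unresolved = unresolved,
                summary = he_summary(empty_calls)))
  }
  pair_one_direction <- function(dups, dels, from) {
    ## returns calls + logical vectors of used dup/del rows
    used_dup <- rep(FALSE, nrow(dups)); used_del <- rep(FALSE, nrow(dels))
    calls <- empty_calls
    if (nrow(dups) == 0 || nrow(dels) == 0)
      return(list(calls = calls, used_dup = used_dup, used_del = used_del))
    for (i in seq_len(nrow(dups))) {
      proj <- project_interval(dups$chrom[i], dups$start[i], dups$end[i],
                               map, from = from)
      if (is.null(proj)) next
      proj_len <- sum(proj$end - proj$start)
      best <- 0; best_j <- NA_integer_
      for (j in seq_len(nrow(dels))) {
        if (used_del[j]) next
        ov <- sum(overlap_len(proj$start, proj$end,
                              dels$start[j], dels$end[j])[
                                proj$chrom == dels$chrom[j]])
        if (ov >= min_reciprocal_overlap * proj_len &&
            ov >= min_reciprocal_overlap * (dels$end[j] - dels$start[j]) &&
            ov > best) { best <- ov; best_j <- j }
      }
      if (!is.na(best_j)) {
        used_dup[i] <- TRUE; used_del[best_j] <- TRUE
        calls <- rbind(calls, data.frame(
          donor_chrom = dups$chrom[i], donor_start = dups$start[i],
          donor_end = dups$end[i],
          recipient_chrom = dels$chrom[best_j],
          recipient_start = dels$start[best_j],
          recipient_end = dels$end[best_j],
          direction = if (from == "A") "A->B" else "B->A",
          length_bp = dels$end[best_j] - dels$start[best_j],
          stringsAsFactors = FALSE))
      }
    }
    list(calls = calls, used_dup = used_dup, used_del = used_del)
  }
  ab <- pair_one_direction(dup_segments_A, del_segments_B, from = "A")
  ba <- pair_one_direction(dup_segments_B, del_segments_A, from = "B")
  calls <- rbind(ab$calls, ba$calls)
  unresolved <- do.call(rbind, c(list(
    add_genome(dup_segments_A, "A", !ab$used_dup),
    add_genome(del_segments_A, "A", !ba$used_del),
    add_genome(dup_segments_B, "B", !ba$used_dup),
    add_genome(del_segments_B, "B", !ab$used_del))))
  if (!is.null(unresolved)) rownames(unresolved) <- NULL
  list(calls = calls, unresolved = unresolved, summary = he_summary(calls))
}

he_summary <- function(calls) {
  dirs <- c("A->B", "B->A")
  data.frame(direction = dirs,
             n = vapply(dirs, function(d) sum(calls$direction == d), integer(1)),
             mb = vapply(dirs, function(d)
               sum(calls$length_bp[calls$direction == d]) / 1e6, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
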