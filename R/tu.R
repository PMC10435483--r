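#' Call nascent transcription units from a stranded occupancy track
#'
#' Transparent gap-merge caller: per (chromosome, strand), covered
#' positions (count >= `min_signal`) are merged into maximal runs in which
#' consecutive covered positions are at most `max_gap` apart; runs
#' spanning fewer than `min_body` bases or holding fewer than `min_count`
#' reads are dropped. Long runs are kept whole — no splitting at internal
#' dips — so transcription units on one strand never overlap. The origin
#' is the 5'-most covered position in unit orientation (leftmost for plus,
#' rightmost for minus strand).
#'
#' @param track an [occupancy_track()] (already filtered and masked).
#' @param max_gap maximum gap between consecutive covered positions within
#'   one unit (bp, default 250; a gap of exactly `max_gap` still merges,
#'   larger splits).
#' @param min_count minimum total read count per unit (default 10).
#' @param min_body minimum unit span (bp, default 150).
#' @param max_init_body retained for interface compatibility with
#'   two-value body-size parameterizations; units longer than this are
#'   kept whole (the caller never splits), so the value has no effect.
#' @param min_signal per-base count needed for a position to count as
#'   covered (default 1).
#' @return data.frame with tu_id, chrom, strand, start, end (0-based
#'   half-open span of covered positions), origin, total_count.
#' @export
call_transcription_units <- function(track, max_gap = 250L, min_count = 10L,
                                     min_body = 150L, max_init_body = 500L,
                                     min_signal = 1L) {
  stopifnot(is_occupancy_track(track))
  if (max_gap <= 0 || min_count <= 0 || min_body <= 0 || min_signal <= 0)
    stop("transcription-unit caller parameters must be positive")
  t <- track[track$count >= min_signal, , drop = FALSE]
  if (!nrow(t)) return(empty_tus())
  t <- t[order(t$chrom, t$strand, t$pos), , drop = FALSE]
  grp <- paste(t$chrom, t$strand)
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap_break <- c(TRUE, diff(t$pos) > max_gap)
  run <- cumsum(new_grp | gap_break)
  first <- !duplicated(run)
  last <- !duplicated(run, fromLast = TRUE)
  tu <- data.frame(chrom = t$chrom[first], strand = t$strand[first],
                   start = t$pos[first], end = t$pos[last] + 1L,
                   total_count = as.integer(rowsum(t$count, run)[, 1]),
                   stringsAsFactors = FALSE)
  keep <- (tu$end - tu$start) >= min_body & tu$total_count >= min_count
  tu <- tu[keep, , drop = FALSE]
  if (!nrow(tu)) return(empty_tus())
  tu <- tu[order(tu$chrom, tu$start, tu$strand), , drop = FALSE]
  tu$origin <- ifelse(tu$strand == "+", tu$start, tu$end - 1L)
  tu$tu_id <- sprintf("tu%05d", seq_len(nrow(tu)))
  rownames(tu) <- NULL
  tu[, c("tu_id", "chrom", "strand", "start", "end", "origin",
         "total_count")]
}

empty_tus <- function() {
  data.frame(tu_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), origin = integer(),
             total_count = integer(), stringsAsFactors = FALSE)
}
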