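#' Construct a stranded single-nucleotide occupancy track
#'
#' An occupancy track is the central currency of the pipeline: a sparse map
#' from (chromosome, strand, 0-based position) to a nonnegative integer
#' count of nascent-RNA 3' ends (engaged Pol II molecules). Positions that
#' have been masked are absent from the track, not stored as zero.
#'
#' @param chrom character vector of reference names.
#' @param pos integer vector of 0-based positions.
#' @param strand character vector, "+" or "-".
#' @param count integer vector of nonnegative counts.
#' @return A data.frame of class `occupancy_track` with columns
#'   `chrom`, `pos`, `strand`, `count`, one row per covered position,
#'   sorted by (chrom, strand, pos). Rows with identical keys are summed;
#'   zero-count rows are dropped.
#' @examples
#' occupancy_track(c("chr1", "chr1"), c(100L, 100L), c("+", "+"), c(1L, 2L))
#' @export
occupancy_track <- function(chrom = character(), pos = integer(),
                            strand = character(), count = integer()) {
  stopifnot(length(chrom) == length(pos),
            length(pos) == length(strand),
            length(strand) == length(count))
  if (any(count < 0)) stop("occupancy counts must be nonnegative")
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand),
                   count = as.numeric(count),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$chrom, df$strand, df$pos)
    if (anyDuplicated(key)) {
      agg <- rowsum(df$count, key, reorder = FALSE)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$count <- agg[match(paste(df$chrom, df$strand, df$pos),
                            rownames(agg)), 1]
    }
    df <- df[df$count > 0, , drop = FALSE]
    df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$count <- as.integer(round(df$count))
  class(df) <- c("occupancy_track", "data.frame")
  df
}

#' Test whether an object is an occupancy track
#' @param x object.
#' @return logical.
#' @export
is_occupancy_track <- function(x) inherits(x, "occupancy_track")

#' Total read count in a track
#' @param track an `occupancy_track`.
#' @return integer total count.
#' @export
track_total <- function(track) {
  stopifnot(is_occupancy_track(track))
  sum(track$count)
}

#' Compare two occupancy tracks position by position
#'
#' Tracks are equal when they cover exactly the same (chrom, strand,
#' position) keys with identical counts.
#'
#' @param a,b `occupancy_track` objects.
#' @return logical scalar.
#' @export
tracks_identical <- function(a, b) {
  stopifnot(is_occupancy_track(a), is_occupancy_track(b))
  a2 <- as.data.frame(a)[, c("chrom", "strand", "pos", "count")]
  b2 <- as.data.frame(b)[, c("chrom", "strand", "pos", "count")]
  a2 <- a2[order(a2$chrom, a2$strand, a2$pos), ]
  b2 <- b2[order(b2$chrom, b2$strand, b2$pos), ]
  rownames(a2) <- rownames(b2) <- NULL
  isTRUE(all.equal(a2, b2, check.attributes = FALSE))
}

#' Convert a track to a GRanges (width-1 ranges, score = count)
#' @param track an `occupancy_track`.
#' @return a `GenomicRanges::GRanges` with 1-based width-1 ranges.
#' @export
track_to_granges <- function(track) {
  stopifnot(is_occupancy_track(track))
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$pos + 1L, width = 1L),
    strand = track$strand,
    score = track$count)
}

#' @export
print.occupancy_track <- function(x, n = 6, ...) {
  cat(sprintf("occupancy_track: %d covered positions, %d reads, %d chrom(s)\n",
              nrow(x), sum(x$count), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more positions\n")
  invisible(x)
}

# 0-based half-open interval data.frame validator used across modules
validate_intervals <- function(df, need = c("chrom", "start", "end")) {
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (nrow(df) && any(df$end <= df$start))
    stop("intervals must satisfy start < end (0-based half-open)")
  invisible(df)
}

# intervals (0-based half-open df) -> GRanges (1-based closed)
intervals_to_granges <- function(df, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  if (!nrow(df)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
}
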