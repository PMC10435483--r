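#' Collapse PCR duplicates by (position, UMI) key
#'
#' Keeps at most one read per (chrom, start, end, strand, UMI) key,
#' mirroring exact-match UMI collapse (no edit-distance clustering). The
#' result is independent of input order: the representative of each key is
#' the one that sorts first.
#'
#' @param reads data.frame with chrom, start, end, strand, umi.
#' @return the de-duplicated reads data.frame.
#' @export
collapse_duplicates <- function(reads) {
  stopifnot(all(c("chrom", "start", "end", "strand", "umi") %in% names(reads)))
  if (!nrow(reads)) return(reads)
  o <- order(reads$chrom, reads$start, reads$end, reads$strand, reads$umi)
  reads <- reads[o, , drop = FALSE]
  key <- paste(reads$chrom, reads$start, reads$end, reads$strand, reads$umi)
  out <- reads[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove reverse-transcription mispriming artifacts
#'
#' A read is a mispriming artifact iff its UMI equals (case-insensitive)
#' the genomic k-mer immediately adjacent to the read's 3' end in read
#' orientation: for a plus-strand read, the k bases following `end`; for a
#' minus-strand read, the reverse complement of the k bases preceding
#' `start` (k = UMI length). When the RT primer anneals to genomic
#' sequence instead of the ligated adapter, the "UMI" it carries is that
#' adjacent sequence, which is what this rule detects. Reads whose
#' adjacent window runs past the chromosome end are kept with a warning.
#'
#' @param reads data.frame with chrom, start, end, strand, umi.
#' @param genome a named `Biostrings::DNAStringSet` (or named character
#'   vector of sequences).
#' @return list with `reads` (kept) and `removed` (count of reads removed).
#' @export
filter_mispriming <- function(reads, genome) {
  stopifnot(all(c("chrom", "start", "end", "strand", "umi") %in% names(reads)))
  if (!nrow(reads)) return(list(reads = reads, removed = 0L))
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  missing_chrom <- setdiff(unique(reads$chrom), names(genome))
  if (length(missing_chrom))
    stop("genome lacks sequence for: ", paste(missing_chrom, collapse = ", "))
  k <- unique(nchar(reads$umi))
  if (length(k) != 1)
    stop("reads carry UMIs of mixed length")
  clen <- Biostrings::width(genome)[match(reads$chrom, names(genome))]
  inb <- ifelse(reads$strand == "+", reads$end + k <= clen,
                reads$start - k >= 0L)
  if (any(!inb))
    warning(sum(!inb), " reads with adjacent window past the chromosome ",
            "end were kept")
  is_art <- rep(FALSE, nrow(reads))
  if (any(inb)) {
    km <- adjacent_kmers(reads[inb, , drop = FALSE], genome, k)
    is_art[inb] <- toupper(reads$umi[inb]) == km
  }
  out <- reads[!is_art, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, removed = sum(is_art))
}

#' Extract single-nucleotide occupancy from aligned reads
#'
#' Each read contributes one count at its 5'-most aligned base in read
#' orientation (`start` for plus-strand, `end - 1` for minus-strand
#' alignments) — the position of the nascent-RNA 3' end, i.e. the engaged
#' polymerase. With `flip = TRUE` (the default, matching the library
#' chemistry) the count is assigned to the strand opposite the read's
#' alignment strand; with `flip = FALSE` to the same strand.
#'
#' @param reads data.frame with chrom, start, end, strand.
#' @param flip assign counts to the opposite strand (default TRUE).
#' @return an [occupancy_track()]; total count equals the number of reads.
#' @export
extract_occupancy <- function(reads, flip = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (!nrow(reads))
    return(occupancy_track())
  pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  strand <- if (flip) ifelse(reads$strand == "+", "-", "+") else reads$strand
  occupancy_track(reads$chrom, pos, strand, rep(1L, nrow(reads)))
}

#' 3'-end positions of annotated exons, introns and polyA sites
#'
#' The positions where RNA-processing intermediates (splicing and 3'-end
#' cleavage products) accumulate: the 3'-most nucleotide, in transcript
#' orientation, of every annotated exon and intron, plus every annotated
#' polyA site, each on the annotation's strand.
#'
#' @param gm a [gene_models()] object.
#' @return data.frame with chrom, pos, strand (unique rows).
#' @export
intermediate_positions <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  ex <- gm$exons
  rows <- list()
  if (nrow(ex)) {
    ## exon 3' ends
    rows[[1]] <- data.frame(
      chrom = ex$chrom,
      pos = ifelse(ex$strand == "+", ex$end - 1L, ex$start),
      strand = ex$strand, stringsAsFactors = FALSE)
    ## intron 3' ends: gaps between consecutive exons of one isoform
    sp <- split(ex, ex$isoform_id)
    intr <- lapply(sp, function(e) {
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) < 2) return(NULL)
      is_ <- e$end[-nrow(e)]
      ie_ <- e$start[-1]
      ok <- ie_ > is_
      if (!any(ok)) return(NULL)
      data.frame(chrom = e$chrom[1],
                 pos = if (e$strand[1] == "+") ie_[ok] - 1L else is_[ok],
                 strand = e$strand[1], stringsAsFactors = FALSE)
    })
    rows <- c(rows, intr[!vapply(intr, is.null, logical(1))])
  }
  if (nrow(gm$isoforms)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = gm$isoforms$chrom, pos = gm$isoforms$polya,
      strand = gm$isoforms$strand, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  out <- do.call(rbind, rows)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Mask RNA-processing-intermediate positions in a track
#'
#' Deletes (not zeroes) track counts at the 3'-most nucleotide of every
#' annotated exon and intron and at every polyA site, on the annotation's
#' strand, and returns the removed positions as a MaskSet so downstream
#' metaprofiles can skip rather than zero them.
#'
#' @param track an [occupancy_track()].
#' @param gm a [gene_models()] object.
#' @return list with `track` (masked) and `mask` (data.frame chrom, start,
#'   end, strand, class = "intermediate").
#' @export
mask_intermediates <- function(track, gm) {
  stopifnot(is_occupancy_track(track))
  ipos <- intermediate_positions(gm)
  if (!nrow(ipos) || !nrow(track))
    return(list(track = track,
                mask = data.frame(chrom = ipos$chrom, start = ipos$pos,
                                  end = ipos$pos + 1L, strand = ipos$strand,
                                  class = rep("intermediate", nrow(ipos)))))
  hit <- paste(track$chrom, track$pos, track$strand) %in%
    paste(ipos$chrom, ipos$pos, ipos$strand)
  out <- track[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  mask <- data.frame(chrom = ipos$chrom, start = ipos$pos,
                     end = ipos$pos + 1L, strand = ipos$strand,
                     class = "intermediate", stringsAsFactors = FALSE)
  list(track = out, mask = mask)
}

#' Mask arbitrary regions (ncRNA, blacklist) out of a track
#'
#' Deletes all track positions falling inside the mask intervals.
#' Intervals with strand "*" (or no strand column) mask both strands.
#' Counts are conserved: total out = total in - total inside masks.
#'
#' @param track an [occupancy_track()].
#' @param masks data.frame with chrom, start, end and optionally strand
#'   and class columns (0-based half-open).
#' @return the masked [occupancy_track()].
#' @export
mask_regions <- function(track, masks) {
  stopifnot(is_occupancy_track(track))
  validate_intervals(masks)
  if (!nrow(track) || !nrow(masks)) return(track)
  t_gr <- track_to_granges(track)
  stranded <- "strand" %in% names(masks)
  m_gr <- GenomicRanges::GRanges(
    seqnames = masks$chrom,
    ranges = IRanges::IRanges(start = masks$start + 1L, end = masks$end),
    strand = if (stranded) masks$strand else "*")
  hit <- IRanges::overlapsAny(t_gr, m_gr, ignore.strand = FALSE)
  out <- track[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  out
}

#' Split reads (or a track) into primary and spike-in fractions
#'
#' Partitions records by reference name: references starting with the
#' reserved spike prefix are the spike-in (exogenous species) fraction,
#' everything else is primary. The partition is exhaustive and disjoint.
#'
#' @param x data.frame with a `chrom` column (reads or track rows).
#' @param spike_prefix reserved reference-name prefix, default "spike_".
#' @param known_chroms optional character vector; if given, any reference
#'   name outside it (and not spike-prefixed) is a configuration error.
#' @return list with `primary` and `spike` data.frames.
#' @export
split_species <- function(x, spike_prefix = "spike_", known_chroms = NULL) {
  stopifnot("chrom" %in% names(x))
  is_spike <- startsWith(x$chrom, spike_prefix)
  if (!is.null(known_chroms)) {
    bad <- !is_spike & !x$chrom %in% known_chroms
    if (any(bad))
      stop("unknown reference name(s): ",
           paste(unique(x$chrom[bad]), collapse = ", "))
  }
  prim <- x[!is_spike, , drop = FALSE]
  spk <- x[is_spike, , drop = FALSE]
  rownames(prim) <- rownames(spk) <- NULL
  list(primary = prim, spike = spk)
}

#' Run the full read-to-track processing chain
#'
#' collapse duplicates -> remove mispriming artifacts -> extract
#' single-nucleotide occupancy (with strand flip) -> mask
#' processing-intermediate positions -> mask ncRNA/blacklist regions.
#' Every step conserves or reduces the total count.
#'
#' @param reads aligned-read data.frame.
#' @param genome named `DNAStringSet` for the mispriming filter (NULL
#'   skips the filter).
#' @param gm [gene_models()] for intermediate masking (NULL skips).
#' @param masks region MaskSet data.frame (NULL skips).
#' @param flip strand-flip flag for [extract_occupancy()].
#' @return list with `track`, `mask` (intermediate MaskSet or NULL) and
#'   `stats` (reads in/out per step).
#' @export
process_reads <- function(reads, genome = NULL, gm = NULL, masks = NULL,
                          flip = TRUE) {
  stats <- c(input = nrow(reads))
  reads <- collapse_duplicates(reads)
  stats["after_collapse"] <- nrow(reads)
  if (!is.null(genome)) {
    fm <- filter_mispriming(reads, genome)
    reads <- fm$reads
  }
  stats["after_mispriming"] <- nrow(reads)
  track <- extract_occupancy(reads, flip = flip)
  imask <- NULL
  if (!is.null(gm)) {
    mi <- mask_intermediates(track, gm)
    track <- mi$track
    imask <- mi$mask
  }
  stats["after_intermediate_mask"] <- track_total(track)
  if (!is.null(masks)) track <- mask_regions(track, masks)
  stats["after_region_mask"] <- track_total(track)
  list(track = track, mask = imask, stats = stats)
}
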