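#' Write a stranded occupancy track as a bedGraph pair
#'
#' One file per strand (`<prefix>.plus.bedgraph`,
#' `<prefix>.minus.bedgraph`), 0-based half-open single-base intervals
#' with the count as score.
#'
#' @param track an [occupancy_track()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_track_bedgraph <- function(track, prefix) {
  stopifnot(is_occupancy_track(track))
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    sub <- track[track$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = if (nrow(sub)) sub$chrom else character(),
      ranges = IRanges::IRanges(start = sub$pos + 1L, width = 1L),
      score = sub$count)
    rtracklayer::export(gr, paths[[if (s == "+") "plus" else "minus"]],
                        format = "bedGraph")
  }
  invisible(paths)
}

#' Read a stranded bedGraph pair into an occupancy track
#'
#' @param plus_file,minus_file bedGraph paths for the two strands.
#' @return an [occupancy_track()].
#' @export
read_track_bedgraph <- function(plus_file, minus_file) {
  parts <- Map(function(f, s) {
    gr <- rtracklayer::import(f, format = "bedGraph")
    if (!length(gr))
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), count = integer()))
    ## expand multi-base runs back to single bases
    w <- GenomicRanges::width(gr)
    data.frame(chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
               pos = sequence(w, from = GenomicRanges::start(gr) - 1L),
               strand = s,
               count = rep(gr$score, w), stringsAsFactors = FALSE)
  }, c(plus_file, minus_file), c("+", "-"))
  df <- do.call(rbind, parts)
  occupancy_track(df$chrom, df$pos, df$strand, df$count)
}

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start, end (0-based half-open) and
#'   optionally name/score/strand columns (defaults ".", 0, "*").
#' @param file output path.
#' @param name_col,score_col columns to use for the BED name and score.
#' @return invisibly, the path.
#' @export
write_bed <- function(df, file, name_col = NULL, score_col = NULL) {
  validate_intervals(df)
  bed <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if (!is.null(name_col)) df[[name_col]] else ".",
    score = if (!is.null(score_col)) df[[score_col]] else 0L,
    strand = if ("strand" %in% names(df)) df$strand else "*")
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file into a 0-based half-open interval data.frame
#'
#' @param file BED path.
#' @return data.frame with chrom, start, end, name, score, strand (as far
#'   as columns are present).
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' Write gene models as GTF
#'
#' Emits gene, transcript and exon records (1-based closed coordinates at
#' the file boundary, converted from the internal 0-based half-open
#' convention).
#'
#' @param gm a [gene_models()] object.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_gtf <- function(gm, file) {
  g <- gm$genes; iso <- gm$isoforms; ex <- gm$exons
  iso_start <- ifelse(iso$strand == "+", iso$tss, iso$polya)
  iso_end <- ifelse(iso$strand == "+", iso$polya + 1L, iso$tss + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = c(g$chrom, iso$chrom, ex$chrom),
    ranges = IRanges::IRanges(
      start = c(g$start, iso_start, ex$start) + 1L,
      end = c(g$end, iso_end, ex$end)),
    strand = c(g$strand, iso$strand, ex$strand),
    type = rep(c("gene", "transcript", "exon"),
               c(nrow(g), nrow(iso), nrow(ex))),
    gene_id = c(g$gene_id, iso$gene_id, ex$gene_id),
    transcript_id = c(rep(NA_character_, nrow(g)), iso$isoform_id,
                      ex$isoform_id))
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read a GTF into gene models
#'
#' Expects gene, transcript and exon records carrying `gene_id` /
#' `transcript_id` attributes. TSS and polyA positions are derived from
#' the transcript ends in transcript orientation. Expression (`tpm`) is
#' not part of GTF and is left NA, to be filled from an expression table
#' by [call_active_genes()].
#'
#' @param file GTF path.
#' @return a [gene_models()] object.
#' @export
read_gtf <- function(file) {
  gr <- rtracklayer::import(file, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = gr$type,
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  g <- df[df$type == "gene", , drop = FALSE]
  tr <- df[df$type == "transcript", , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  genes <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = g$start, end = g$end, strand = g$strand,
                      tss = ifelse(g$strand == "+", g$start, g$end - 1L),
                      polya = ifelse(g$strand == "+", g$end - 1L, g$start),
                      stringsAsFactors = FALSE)
  isoforms <- data.frame(gene_id = tr$gene_id,
                         isoform_id = tr$transcript_id,
                         chrom = tr$chrom, strand = tr$strand,
                         tss = ifelse(tr$strand == "+", tr$start,
                                      tr$end - 1L),
                         polya = ifelse(tr$strand == "+", tr$end - 1L,
                                        tr$start),
                         tpm = NA_real_, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = ex$gene_id, isoform_id = ex$transcript_id,
                      chrom = ex$chrom, strand = ex$strand,
                      start = ex$start, end = ex$end,
                      stringsAsFactors = FALSE)
  gene_models(genes, isoforms, exons)
}

#' Read aligned reads from a headered TSV
#'
#' Expected columns: chrom, start, end, strand, umi (0-based half-open).
#'
#' @param file path.
#' @return reads data.frame.
#' @export
read_reads_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "umi")
  if (!all(need %in% names(df)))
    stop("reads TSV needs columns: ", paste(need, collapse = ", "))
  validate_intervals(df)
  df
}

#' Write aligned reads as a headered TSV
#' @param reads reads data.frame.
#' @param file path.
#' @return invisibly, the path.
#' @export
write_reads_tsv <- function(reads, file) {
  utils::write.table(reads, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write aligned reads as SAM with the UMI in a tag field
#'
#' Minimal single-end SAM: fixed-length ungapped alignments, sequence and
#' quality omitted ("*"), UMI in the `RX` tag (configurable).
#'
#' @param reads reads data.frame (chrom, start, end, strand, umi).
#' @param chrom_lengths named vector of reference lengths for the header.
#' @param file output path.
#' @param umi_tag SAM tag carrying the UMI (default "RX").
#' @return invisibly, the path.
#' @export
write_sam <- function(reads, chrom_lengths, file, umi_tag = "RX") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(reads)) {
    writeLines(sprintf("read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\t%s:Z:%s",
                       seq_len(nrow(reads)),
                       ifelse(reads$strand == "+", 0L, 16L),
                       reads$chrom, reads$start + 1L,
                       reads$end - reads$start, umi_tag, reads$umi), con)
  }
  invisible(file)
}

#' Write a genome as FASTA
#' @param genome named `DNAStringSet` (or named character vector).
#' @param file path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(genome, file) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, file)
  invisible(file)
}
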