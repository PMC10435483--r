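#' Simulate aligned read records from an occupancy track
#'
#' Inverts the occupancy-extraction convention: every occupancy count at a
#' (chrom, position, strand) becomes one aligned read whose 5'-most aligned
#' base in read orientation sits at that position and whose alignment
#' strand is the *opposite* of the occupancy strand (the sequencing
#' chemistry reads the nascent-RNA 3' end from the opposite strand; the
#' extraction step undoes this with its flip flag). Each read carries a
#' random UMI, distinct within its occupancy position. Artifacts are
#' planted per the config: with probability `intermediate_rate` a primary
#' read is relocated to the 3'-most nucleotide of an annotated exon or
#' intron or to a polyA site (an RNA-processing intermediate); with
#' probability `mispriming_rate` a read's UMI is overwritten with the
#' genomic k-mer adjacent to its 3' end in read orientation (a detectable
#' RT-mispriming event); `dup_factor` emits each (position, UMI) read that
#' many times. Truth labels (genuine / spike / intermediate / mispriming /
#' duplicate) are recorded per read.
#'
#' @param track an [occupancy_track()] (spike chromosomes included).
#' @param sim the `sim_genome` providing genome sequence and annotation.
#' @param config a [sim_config()].
#' @return A data.frame of reads: chrom, start, end (0-based half-open),
#'   strand (alignment strand), umi, label, occ_pos, occ_strand.
#' @export
simulate_reads <- function(track, sim, config = sim$config) {
  stopifnot(is_occupancy_track(track), inherits(sim, "sim_genome"))
  set.seed(config$seed + 3L)
  k <- as.integer(config$umi_length)
  L <- as.integer(config$read_length)

  idx <- rep(seq_len(nrow(track)), track$count)
  reads <- data.frame(chrom = track$chrom[idx],
                      occ_pos = track$pos[idx],
                      occ_strand = track$strand[idx],
                      stringsAsFactors = FALSE)
  n <- nrow(reads)
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      umi = character(), label = character(),
                      occ_pos = integer(), occ_strand = character()))
  spike <- startsWith(reads$chrom, config$spike_prefix)
  reads$label <- ifelse(spike, "spike", "genuine")

  ## RNA-processing intermediates: relocate primary reads onto the 3'-most
  ## nucleotide of annotated exons/introns or polyA sites
  ipos <- intermediate_positions(sim$annotation)
  if (config$intermediate_rate > 0 && nrow(ipos)) {
    hit <- !spike & stats::runif(n) < config$intermediate_rate
    if (any(hit)) {
      pick <- sample(nrow(ipos), sum(hit), replace = TRUE)
      reads$chrom[hit] <- ipos$chrom[pick]
      reads$occ_pos[hit] <- ipos$pos[pick]
      reads$occ_strand[hit] <- ipos$strand[pick]
      reads$label[hit] <- "intermediate"
    }
  }

  ## read geometry: alignment strand is opposite the occupancy strand; the
  ## occupancy position is the read's 5'-most aligned base in read
  ## orientation; intervals are clipped at chromosome ends, anchor fixed
  clen <- sim$chrom_lengths[reads$chrom]
  reads$strand <- ifelse(reads$occ_strand == "+", "-", "+")
  plus <- reads$strand == "+"
  reads$start <- ifelse(plus, reads$occ_pos,
                        pmax(0L, reads$occ_pos + 1L - L))
  reads$end <- ifelse(plus, pmin(clen, reads$occ_pos + L),
                      reads$occ_pos + 1L)

  ## UMIs, distinct within each occupancy position
  reads$umi <- random_umis(n, k)
  grp <- paste(reads$chrom, reads$occ_pos, reads$occ_strand)
  repeat {
    dup <- duplicated(paste(grp, reads$umi))
    if (!any(dup)) break
    reads$umi[dup] <- random_umis(sum(dup), k)
  }

  ## RT mispriming: overwrite the UMI with the genomic k-mer adjacent to
  ## the read's 3' end in read orientation, making the artifact detectable
  if (config$mispriming_rate > 0) {
    eligible <- !spike & reads$label == "genuine"
    hit <- eligible & stats::runif(n) < config$mispriming_rate
    inb <- ifelse(reads$strand == "+", reads$end + k <= clen,
                  reads$start - k >= 0L)
    hit <- hit & inb
    if (any(hit)) {
      reads$umi[hit] <- adjacent_kmers(reads[hit, , drop = FALSE],
                                       sim$genome, k)
      reads$label[hit] <- "mispriming"
    }
  }

  ## PCR duplication: each unique read emitted dup_factor times
  if (config$dup_factor > 1) {
    extra <- reads[rep(seq_len(n), config$dup_factor - 1L), , drop = FALSE]
    extra$label <- "duplicate"
    reads <- rbind(reads, extra)
  }
  rownames(reads) <- NULL
  reads[, c("chrom", "start", "end", "strand", "umi", "label",
            "occ_pos", "occ_strand")]
}

random_umis <- function(n, k) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), n, k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## genomic k-mer adjacent to each read's 3' end, in read orientation:
## plus-strand reads: the k bases following `end`; minus-strand reads: the
## reverse complement of the k bases preceding `start`
adjacent_kmers <- function(reads, genome, k) {
  out <- character(nrow(reads))
  seqs <- as.character(genome)
  plus <- reads$strand == "+"
  if (any(plus)) {
    out[plus] <- substring(seqs[reads$chrom[plus]],
                           reads$end[plus] + 1L, reads$end[plus] + k)
  }
  if (any(!plus)) {
    fwd <- substring(seqs[reads$chrom[!plus]],
                     reads$start[!plus] - k + 1L, reads$start[!plus])
    out[!plus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
  }
  toupper(out)
}
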