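#' Sum track counts over regions
#'
#' Counts occupancy over 0-based half-open regions, on the region's own
#' strand (`"sense"`), the opposite strand (`"antisense"`) or both.
#' Masked positions are absent from the track and therefore contribute
#' nothing. Regions sharing a `region_id` (split pieces) are summed.
#'
#' @param track an [occupancy_track()].
#' @param regions data.frame with region_id, chrom, start, end, strand.
#' @param strand_rule "sense", "antisense" or "both".
#' @param chrom_lengths optional named vector; regions outside their
#'   chromosome are an error when given.
#' @return named numeric vector of counts, one per unique region_id (in
#'   first-appearance order).
#' @export
quantify_regions <- function(track, regions,
                             strand_rule = c("sense", "antisense", "both"),
                             chrom_lengths = NULL) {
  strand_rule <- match.arg(strand_rule)
  stopifnot(is_occupancy_track(track))
  validate_intervals(regions)
  stopifnot("region_id" %in% names(regions))
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[regions$chrom]
    if (any(is.na(lim)) || any(regions$end > lim) || any(regions$start < 0))
      stop("region outside chromosome bounds")
  }
  ids <- unique(regions$region_id)
  out <- stats::setNames(numeric(length(ids)), ids)
  if (!nrow(track) || !nrow(regions)) return(out)
  strand <- switch(strand_rule,
                   sense = regions$strand,
                   antisense = ifelse(regions$strand == "+", "-", "+"),
                   both = "*")
  r_gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = strand)
  t_gr <- track_to_granges(track)
  hits <- GenomicRanges::findOverlaps(t_gr, r_gr,
                                      ignore.strand = strand_rule == "both")
  if (length(hits)) {
    cnt <- rowsum(track$count[S4Vectors::queryHits(hits)],
                  regions$region_id[S4Vectors::subjectHits(hits)])
    out[rownames(cnt)] <- out[rownames(cnt)] + cnt[, 1]
  }
  out
}

#' Normalize a count matrix (RPM, TPM or RLE with supplied factors)
#'
#' RPM: count * 1e6 / column sum. TPM: (count / region length in kb) *
#' 1e6 / column sum of length-normalized counts. RLE: divide each column
#' by its supplied size factor (see [spikein_size_factors()]).
#'
#' @param counts numeric matrix, regions x samples.
#' @param method "RPM", "TPM" or "RLE".
#' @param lengths region lengths in bp (required for TPM).
#' @param size_factors per-sample factors (required for RLE).
#' @return normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, method = c("RPM", "TPM", "RLE"),
                             lengths = NULL, size_factors = NULL) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (method == "RPM") {
    cs <- colSums(counts)
    if (any(cs == 0)) stop("zero column sum; cannot RPM-normalize")
    sweep(counts, 2, cs / 1e6, "/")
  } else if (method == "TPM") {
    if (is.null(lengths)) stop("TPM needs region lengths")
    rate <- counts / (lengths / 1000)
    cs <- colSums(rate)
    if (any(cs == 0)) stop("zero column sum; cannot TPM-normalize")
    sweep(rate, 2, cs / 1e6, "/")
  } else {
    if (is.null(size_factors)) stop("RLE needs size factors")
    if (length(size_factors) != ncol(counts))
      stop("one size factor per sample required")
    sweep(counts, 2, size_factors, "/")
  }
}

#' Spike-in median-of-ratios size factors
#'
#' Relative-log-expression (median-of-ratios) factors computed on the
#' spike-in regions only and applied to every region of the sample: the
#' reference for each spike region is its geometric mean across samples
#' (regions with any zero are excluded); a sample's factor is the median
#' over spike regions of count / reference. Because the spike-in was added
#' at a fixed cell ratio, these factors carry global occupancy changes
#' that per-sample library-size normalization would cancel.
#'
#' @param counts numeric matrix, regions x samples.
#' @param spike logical vector flagging the spike rows of `counts`.
#' @return named per-sample size-factor vector.
#' @export
spikein_size_factors <- function(counts, spike) {
  counts <- as.matrix(counts)
  stopifnot(length(spike) == nrow(counts))
  sp <- counts[spike, , drop = FALSE]
  sp <- sp[rowSums(sp == 0) == 0, , drop = FALSE]
  if (!nrow(sp))
    stop("no spike region with nonzero counts in every sample")
  ref <- exp(rowMeans(log(sp)))
  factors <- apply(sp / ref, 2, stats::median)
  stats::setNames(factors, colnames(counts))
}

#' Test differential occupancy with a negative binomial Wald test
#'
#' Regions with fewer than `min_total` raw reads summed over all samples
#' are excluded before testing. For each remaining region the log2 fold
#' change is computed from mean normalized counts with a 0.5 pseudocount;
#' the Wald statistic divides the natural-log difference by a standard
#' error from the NB variance function v(mu) = mu + alpha mu^2, with the
#' dispersion alpha estimated by pooled within-group method of moments (no
#' shrinkage). P-values use a Student-t reference with the pooled
#' within-group degrees of freedom (small-sample correction); with a
#' single replicate per condition a Poisson fallback (alpha = 0, normal
#' reference) is used with a warning. Benjamini-Hochberg adjustment is
#' applied over the tested regions; significance means padj < 0.05.
#'
#' @param counts raw integer matrix, regions x samples (used for the
#'   minimum-count filter).
#' @param design named vector assigning each sample (column) to
#'   "control" or "treated".
#' @param size_factors per-sample normalization factors (default all 1).
#' @param min_total minimum summed raw count per region (default 6;
#'   regions with fewer are excluded, matching the "< 6 reads" rule).
#' @param pseudocount added to mean normalized counts for the fold change
#'   (default 0.5).
#' @param alpha significance level on padj (default 0.05).
#' @return data.frame: region_id, baseMean, log2fc, pvalue, padj,
#'   significant.
#' @export
test_differential <- function(counts, design, size_factors = NULL,
                              min_total = 6, pseudocount = 0.5,
                              alpha = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- names(design)
  design <- design[colnames(counts)]
  if (any(is.na(design)) || !all(design %in% c("control", "treated")))
    stop("design must assign every sample to control or treated")
  ic <- which(design == "control"); it <- which(design == "treated")
  if (!length(ic) || !length(it))
    stop("both conditions need at least one sample")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))

  keep <- rowSums(counts) >= min_total
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("region%05d", seq_len(nrow(counts)))
  norm <- sweep(counts, 2, size_factors, "/")
  nc <- length(ic); nt <- length(it)
  if (nc < 2 || nt < 2)
    warning("fewer than 2 replicates per condition: Poisson fallback, ",
            "no dispersion estimation")

  sub <- which(keep)
  mc <- rowMeans(norm[sub, ic, drop = FALSE])
  mt <- rowMeans(norm[sub, it, drop = FALSE])
  log2fc <- log2((mt + pseudocount) / (mc + pseudocount))

  ## pooled within-group method-of-moments dispersion
  df_pool <- max(0L, (nc - 1L) + (nt - 1L))
  if (df_pool > 0) {
    ssc <- if (nc > 1)
      rowSums((norm[sub, ic, drop = FALSE] - mc)^2) else 0
    sst <- if (nt > 1)
      rowSums((norm[sub, it, drop = FALSE] - mt)^2) else 0
    s2 <- (ssc + sst) / df_pool
    mu_bar <- (mc + mt) / 2
    disp <- pmax(0, (s2 - mu_bar) / mu_bar^2)
  } else {
    disp <- rep(0, length(sub))
  }

  vc <- (mc + pseudocount) + disp * (mc + pseudocount)^2
  vt <- (mt + pseudocount) + disp * (mt + pseudocount)^2
  se <- sqrt(vc / (nc * (mc + pseudocount)^2) +
               vt / (nt * (mt + pseudocount)^2))
  z <- (log(mt + pseudocount) - log(mc + pseudocount)) / se
  pvalue <- if (df_pool > 0) 2 * stats::pt(-abs(z), df = df_pool)
            else 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(pvalue, method = "BH")

  data.frame(region_id = ids[sub],
             baseMean = rowMeans(norm[sub, , drop = FALSE]),
             log2fc = log2fc, pvalue = pvalue, padj = padj,
             significant = padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a promoter-proximal vs distal pausing matrix
#'
#' Pairs each region's proximal and distal log2 fold changes and assigns
#' the sign quadrant (up/up, up/down, down/up, down/down; proximal axis
#' first). A zero fold change maps to "unchanged" on that axis and the
#' cell gets no quadrant (the `note` column says why).
#'
#' @param proximal,distal [test_differential()] results over matching
#'   region ids.
#' @return data.frame: region_id, proximal_log2fc, distal_log2fc,
#'   quadrant (NA when either axis is unchanged), note.
#' @export
pausing_matrix <- function(proximal, distal) {
  if (!setequal(proximal$region_id, distal$region_id))
    stop("proximal and distal results must cover the same region ids")
  m <- merge(proximal[, c("region_id", "log2fc")],
             distal[, c("region_id", "log2fc")],
             by = "region_id", suffixes = c("_prox", "_dist"))
  names(m) <- c("region_id", "proximal_log2fc", "distal_log2fc")
  lab <- function(x) ifelse(x > 0, "up", ifelse(x < 0, "down", "unchanged"))
  lp <- lab(m$proximal_log2fc); ld <- lab(m$distal_log2fc)
  ok <- lp != "unchanged" & ld != "unchanged"
  m$quadrant <- ifelse(ok, paste(lp, ld, sep = "/"), NA_character_)
  m$note <- ifelse(ok, "", "unchanged on at least one axis")
  m
}

#' Stratify regions into signal quantile groups
#'
#' Ranks regions by an external signal (e.g. promoter BRD4 binding) and
#' splits them into `k` groups Q1 (lowest) to Qk (highest) whose sizes
#' differ by at most one (extra members go to the lower quantiles). Ties
#' are broken by stable region-id order, so the split is deterministic.
#'
#' @param region_ids character vector.
#' @param values one numeric value per region.
#' @param k number of groups (default 4).
#' @return factor of labels Q1..Qk, named by region id, in input order.
#' @export
stratify_by_signal <- function(region_ids, values, k = 4L) {
  stopifnot(length(region_ids) == length(values))
  n <- length(values)
  if (k > n) stop("more groups than regions")
  o <- order(values, region_ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab <- rep(paste0("Q", seq_len(k)), sizes)
  out <- character(n)
  out[o] <- lab
  factor(stats::setNames(out, region_ids)[seq_len(n)],
         levels = paste0("Q", seq_len(k)))
}

#' Export counts and spike-in factors for an external DESeq2 run
#'
#' Adapter writing the raw counts, the design and the spike-in size
#' factors as TSV so the same contrast can be re-fit with DESeq2's full
#' dispersion machinery outside this package.
#'
#' @param counts raw count matrix.
#' @param design named condition vector.
#' @param size_factors per-sample factors.
#' @param prefix output file prefix.
#' @return invisibly, the three file paths written.
#' @export
export_deseq2_inputs <- function(counts, design, size_factors, prefix) {
  f1 <- paste0(prefix, "_counts.tsv")
  f2 <- paste0(prefix, "_design.tsv")
  f3 <- paste0(prefix, "_size_factors.tsv")
  utils::write.table(data.frame(region_id = rownames(counts), counts,
                                check.names = FALSE),
                     f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(design), condition = design),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(size_factors),
                                size_factor = size_factors),
                     f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
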