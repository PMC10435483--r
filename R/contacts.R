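#' Assign putative enhancers to target genes via 3D contacts
#'
#' An enhancer is assigned to a gene iff at least one contact with
#' adjusted significance below `sig_threshold` has one anchor overlapping
#' the enhancer's interval and the *other* anchor overlapping the gene's
#' effective span extended by a promoter window (contact bins cannot
#' separate the promoter from the promoter-proximal region, so the window
#' is included). Assignment is symmetric in anchor order.
#'
#' @param enhancers enhancer-call data.frame (enh_id, chrom, start, end).
#' @param gm refined [gene_models()]; only active genes are targets.
#' @param contacts data.frame with chrom1, start1, end1, chrom2, start2,
#'   end2, padj (0-based half-open anchors).
#' @param sig_threshold padj cutoff (default 0.01, strict "<").
#' @param promoter_halfwidth promoter extension of the gene span (bp,
#'   default 500).
#' @return data.frame: enhancer_id, gene_id, n_contacts, min_padj; one
#'   row per assigned pair.
#' @export
assign_targets <- function(enhancers, gm, contacts, sig_threshold = 0.01,
                           promoter_halfwidth = 500L) {
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "padj") %in% names(contacts)))
  sig <- contacts[contacts$padj < sig_threshold, , drop = FALSE]
  empty <- data.frame(enhancer_id = character(), gene_id = character(),
                      n_contacts = integer(), min_padj = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig) || !nrow(enhancers)) return(empty)
  act <- gm$genes[which(gm$genes$active), , drop = FALSE]
  if (!nrow(act)) return(empty)

  e_gr <- intervals_to_granges(
    enhancers[, c("chrom", "start", "end")], use_strand = FALSE)
  g_gr <- intervals_to_granges(
    data.frame(chrom = act$chrom,
               start = pmax(0L, act$eff_start - promoter_halfwidth),
               end = act$eff_end + promoter_halfwidth),
    use_strand = FALSE)
  a1 <- intervals_to_granges(
    data.frame(chrom = sig$chrom1, start = sig$start1, end = sig$end1),
    use_strand = FALSE)
  a2 <- intervals_to_granges(
    data.frame(chrom = sig$chrom2, start = sig$start2, end = sig$end2),
    use_strand = FALSE)

  pair_hits <- function(anch_e, anch_g) {
    he <- GenomicRanges::findOverlaps(anch_e, e_gr, ignore.strand = TRUE)
    hg <- GenomicRanges::findOverlaps(anch_g, g_gr, ignore.strand = TRUE)
    eh <- split(S4Vectors::subjectHits(he), S4Vectors::queryHits(he))
    gh <- split(S4Vectors::subjectHits(hg), S4Vectors::queryHits(hg))
    common <- intersect(names(eh), names(gh))
    out <- list()
    for (ci in common) {
      grid <- expand.grid(e = eh[[ci]], g = gh[[ci]])
      grid$contact <- as.integer(ci)
      out[[length(out) + 1L]] <- grid
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  pairs <- rbind(pair_hits(a1, a2), pair_hits(a2, a1))
  if (is.null(pairs) || !nrow(pairs)) return(empty)
  pairs$enhancer_id <- enhancers$enh_id[pairs$e]
  pairs$gene_id <- act$gene_id[pairs$g]
  pairs$padj <- sig$padj[pairs$contact]
  pairs <- pairs[!duplicated(pairs[, c("enhancer_id", "gene_id",
                                       "contact")]), , drop = FALSE]
  key <- paste(pairs$enhancer_id, pairs$gene_id)
  agg_n <- rowsum(rep(1L, nrow(pairs)), key)
  agg_p <- tapply(pairs$padj, key, min)
  first <- !duplicated(key)
  out <- data.frame(enhancer_id = pairs$enhancer_id[first],
                    gene_id = pairs$gene_id[first],
                    stringsAsFactors = FALSE)
  k2 <- paste(out$enhancer_id, out$gene_id)
  out$n_contacts <- as.integer(agg_n[match(k2, rownames(agg_n)), 1])
  out$min_padj <- as.numeric(agg_p[match(k2, names(agg_p))])
  out <- out[order(out$enhancer_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count responsive enhancers per target gene
#'
#' A responsive enhancer shows a significant *reduction* in occupancy
#' (padj < 0.05 and log2fc < 0) in the supplied differential results.
#' Counts are per gene over its assigned enhancers, and genes are
#' stratified into the groups 0, 1 and >= 2 responsive enhancers for
#' reporting. Assigned enhancers missing from the results are counted as
#' non-responsive with a warning.
#'
#' @param assignment output of [assign_targets()].
#' @param diff_results [test_differential()] results whose region ids are
#'   enhancer ids (or `<enh_id>:<suffix>` region ids).
#' @return data.frame: gene_id, n_responsive, stratum ("0", "1", ">=2").
#' @export
count_responsive_enhancers <- function(assignment, diff_results) {
  if (!nrow(assignment))
    return(data.frame(gene_id = character(), n_responsive = integer(),
                      stratum = character(), stringsAsFactors = FALSE))
  ids <- sub(":.*$", "", diff_results$region_id)
  resp_tab <- diff_results$significant & diff_results$log2fc < 0
  responsive_of <- function(e) {
    hit <- which(ids == e)
    if (!length(hit)) return(NA)
    any(resp_tab[hit])
  }
  resp <- vapply(assignment$enhancer_id, responsive_of, logical(1))
  if (any(is.na(resp))) {
    warning(sum(is.na(resp)), " assigned enhancers missing from the ",
            "differential results; counted as non-responsive")
    resp[is.na(resp)] <- FALSE
  }
  cnt <- rowsum(as.integer(resp), assignment$gene_id)
  out <- data.frame(gene_id = rownames(cnt),
                    n_responsive = as.integer(cnt[, 1]),
                    stringsAsFactors = FALSE)
  out$stratum <- ifelse(out$n_responsive >= 2, ">=2",
                        as.character(out$n_responsive))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
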