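#' Find antisense transcription-unit candidates
#'
#' A transcription unit is an antisense candidate iff it overlaps at least
#' one *active* gene on the opposite strand, where the gene's interval is
#' its effective span (first active TSS to last active polyA) extended
#' upstream by the divergent-antisense window (`dat_window`): a divergent
#' unit originates up to 1 kb upstream of the TSS and would never overlap
#' the gene body itself, so candidacy must reach into that window for the
#' DAT class to exist at all. The host is the candidate gene with the
#' greatest overlap (ties: nearest first active TSS to the unit origin,
#' then gene id).
#'
#' @param tus transcription units from [call_transcription_units()].
#' @param gm [gene_models()] after [refine_active_isoforms()].
#' @param dat_window upstream extension (bp, default 1000, matching the
#'   DAT origin window of [classify_atu()]).
#' @return data.frame of candidates: the TU columns plus `host_gene`,
#'   `cls` (NA until classified) and `discard_reason` ("none").
#' @export
find_antisense_units <- function(tus, gm, dat_window = 1000L) {
  stopifnot(inherits(gm, "gene_models"),
            "eff_start" %in% names(gm$genes))
  act <- gm$genes[which(gm$genes$active), , drop = FALSE]
  if (!nrow(tus) || !nrow(act)) return(empty_atus())
  ext_start <- ifelse(act$strand == "+", act$eff_start - dat_window,
                      act$eff_start)
  ext_end <- ifelse(act$strand == "+", act$eff_end,
                    act$eff_end + dat_window)
  g_gr <- GenomicRanges::GRanges(
    seqnames = act$chrom,
    ranges = IRanges::IRanges(start = pmax(0L, ext_start) + 1L,
                              end = ext_end),
    strand = ifelse(act$strand == "+", "-", "+"))  # flip: antisense match
  t_gr <- intervals_to_granges(tus)
  hits <- GenomicRanges::findOverlaps(t_gr, g_gr, ignore.strand = FALSE)
  if (!length(hits)) return(empty_atus())
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(t_gr)[qh], IRanges::ranges(g_gr)[sh]))
  ftss <- vapply(seq_len(nrow(act)),
                 function(i) first_active_tss(act[i, ]), integer(1))
  d_tss <- abs(tus$origin[qh] - ftss[sh])
  o <- order(qh, -ov, d_tss, act$gene_id[sh])
  keep <- o[!duplicated(qh[o])]
  out <- tus[qh[keep], , drop = FALSE]
  out$host_gene <- act$gene_id[sh[keep]]
  out$cls <- NA_character_
  out$discard_reason <- "none"
  rownames(out) <- NULL
  out
}

empty_atus <- function() {
  cbind(empty_tus(),
        data.frame(host_gene = character(), cls = character(),
                   discard_reason = character(), stringsAsFactors = FALSE))
}

#' Discard antisense units originating from overlapping genes
#'
#' Spill-over protection: an antisense candidate is discarded with reason
#' `overlapping_gene` if it overlaps a same-strand gene (any annotated
#' gene, active or not) such that the overlap covers >= 50% of the unit or
#' >= 90% of the gene, and with reason `covers_antisense_gene` if the unit
#' covers 100% of its host gene's effective span (common over very short
#' genes).
#'
#' @param atus candidates from [find_antisense_units()].
#' @param gm [gene_models()] (all genes, including inactive).
#' @param frac_tu,frac_gene discard thresholds (default 0.50 / 0.90).
#' @return `atus` with `discard_reason` filled.
#' @export
filter_overlapping_gene_atus <- function(atus, gm, frac_tu = 0.50,
                                         frac_gene = 0.90) {
  if (!nrow(atus)) return(atus)
  genes <- gm$genes
  t_gr <- intervals_to_granges(atus)
  g_gr <- intervals_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(t_gr, g_gr, ignore.strand = FALSE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(t_gr)[qh], IRanges::ranges(g_gr)[sh]))
    tu_len <- atus$end[qh] - atus$start[qh]
    g_len <- genes$end[sh] - genes$start[sh]
    bad <- ov / tu_len >= frac_tu | ov / g_len >= frac_gene
    if (any(bad))
      atus$discard_reason[unique(qh[bad])] <- "overlapping_gene"
  }
  ## covers the entire antisense (host) gene region
  hi <- match(atus$host_gene, genes$gene_id)
  span_s <- if ("eff_start" %in% names(genes) && !all(is.na(genes$eff_start[hi])))
    ifelse(is.na(genes$eff_start[hi]), genes$start[hi], genes$eff_start[hi])
  else genes$start[hi]
  span_e <- if ("eff_end" %in% names(genes) && !all(is.na(genes$eff_end[hi])))
    ifelse(is.na(genes$eff_end[hi]), genes$end[hi], genes$eff_end[hi])
  else genes$end[hi]
  covers <- atus$discard_reason == "none" &
    atus$start <= span_s & atus$end >= span_e
  atus$discard_reason[covers] <- "covers_antisense_gene"
  atus$cls[atus$discard_reason != "none"] <- "discarded"
  atus
}

#' Classify antisense units as convergent (CAT) or divergent (DAT)
#'
#' A unit is a DAT iff its origin lies strictly within 1000 bp upstream of
#' *any* active TSS of the host in host orientation — including downstream
#' alternative TSSs, which is what reassigns apparent CATs arising from
#' bidirectional transcription at alternative promoters. Otherwise it is a
#' CAT iff its origin lies strictly downstream of the host's first active
#' TSS and inside the host's effective span. Units fitting neither window
#' are discarded with reason `alt_promoter`.
#'
#' @param atus candidates (not discarded ones) from
#'   [filter_overlapping_gene_atus()].
#' @param gm [gene_models()] after [refine_active_isoforms()].
#' @param dat_window upstream window size (bp, default 1000, strict "<").
#' @return `atus` with `cls` in CAT / DAT / discarded.
#' @export
classify_atu <- function(atus, gm, dat_window = 1000L) {
  if (!nrow(atus)) return(atus)
  genes <- gm$genes
  for (i in seq_len(nrow(atus))) {
    if (!is.na(atus$cls[i]) && atus$cls[i] == "discarded") next
    g <- genes[match(atus$host_gene[i], genes$gene_id), , drop = FALSE]
    tss_set <- g$active_tss[[1]]
    if (is.null(tss_set) || !length(tss_set))
      stop("host gene ", g$gene_id, " carries no active TSS; run ",
           "refine_active_isoforms() first")
    dirp <- if (g$strand == "+") 1L else -1L
    o <- atus$origin[i]
    up <- (tss_set - o) * dirp  # upstream distance to each active TSS
    if (any(up > 0 & up < dat_window)) {
      atus$cls[i] <- "DAT"
    } else {
      ftss <- if (dirp > 0) min(tss_set) else max(tss_set)
      downstream <- (o - ftss) * dirp > 0
      inside <- o >= g$eff_start && o < g$eff_end
      if (downstream && inside) {
        atus$cls[i] <- "CAT"
      } else {
        atus$cls[i] <- "discarded"
        atus$discard_reason[i] <- "alt_promoter"
      }
    }
  }
  atus
}

#' Call putative intragenic enhancers from CAT units
#'
#' One call per convergent antisense unit whose span overlaps (>= 1 bp)
#' both an H3K27ac and an H3K4me1 peak. The call center is the CAT origin.
#'
#' @param cats classified units with `cls == "CAT"`.
#' @param peaks list with `H3K27ac` and `H3K4me1` interval data.frames.
#' @return enhancer-call data.frame (enh_id, kind, directionality, chrom,
#'   start, end, center, host_gene, tu_ids).
#' @export
call_intragenic_enhancers <- function(cats, peaks) {
  check_peaks(peaks)
  cats <- cats[!is.na(cats$cls) & cats$cls == "CAT", , drop = FALSE]
  if (!nrow(cats)) return(empty_enhancers())
  ok <- overlaps_marks(cats[, c("chrom", "start", "end")], peaks)
  cats <- cats[ok, , drop = FALSE]
  if (!nrow(cats)) return(empty_enhancers())
  data.frame(enh_id = sprintf("intra%04d", seq_len(nrow(cats))),
             kind = "intragenic", directionality = "unidirectional",
             chrom = cats$chrom, start = cats$start, end = cats$end,
             center = cats$origin, host_gene = cats$host_gene,
             tu_ids = cats$tu_id, stringsAsFactors = FALSE)
}

#' Call putative extragenic enhancers
#'
#' Eligible units are transcription units distal to active genes (zero
#' overlap with any active gene's effective span on either strand), whose
#' origin lies neither inside any annotated promoter region (any isoform
#' TSS +/- `promoter_halfwidth`, active or not) nor inside the termination
#' zone (polyA to polyA + `term_len` in gene orientation) of an active
#' gene. Opposite-strand eligible units whose origins lie strictly closer
#' than `pair_maxdist` are merged into one bidirectional call (greedy
#' nearest-origin pairing, each unit used once; center = origin midpoint);
#' remaining eligible units become unidirectional calls (center = origin).
#' Every call must overlap both H3K27ac and H3K4me1 (>= 1 bp against the
#' call span).
#'
#' @param tus all transcription units.
#' @param gm [gene_models()] after [refine_active_isoforms()] (all genes,
#'   including inactive ones, are used for the promoter exclusion).
#' @param peaks list with `H3K27ac` and `H3K4me1` interval data.frames.
#' @param promoter_halfwidth promoter exclusion half-window (bp, default
#'   500; a unit origin within `abs(origin - tss) <= promoter_halfwidth`
#'   is excluded).
#' @param term_len termination-zone length downstream of active polyA
#'   sites (bp, default 2000; zone is `[polyA, polyA + term_len)` in gene
#'   orientation).
#' @param pair_maxdist maximum origin distance for bidirectional merging
#'   (bp, default 500, strict "<").
#' @return enhancer-call data.frame as in [call_intragenic_enhancers()],
#'   `kind = "extragenic"`.
#' @export
call_extragenic_enhancers <- function(tus, gm, peaks,
                                      promoter_halfwidth = 500L,
                                      term_len = 2000L,
                                      pair_maxdist = 500L) {
  check_peaks(peaks)
  stopifnot(inherits(gm, "gene_models"))
  if (!nrow(tus)) return(empty_enhancers())
  genes <- gm$genes
  act <- genes[which(genes$active), , drop = FALSE]

  ## distal to active genes: no overlap with any active effective span,
  ## either strand
  eligible <- rep(TRUE, nrow(tus))
  if (nrow(act)) {
    a_gr <- GenomicRanges::GRanges(
      seqnames = act$chrom,
      ranges = IRanges::IRanges(start = act$eff_start + 1L, end = act$eff_end))
    t_gr <- intervals_to_granges(tus, use_strand = FALSE)
    eligible <- !IRanges::overlapsAny(t_gr, a_gr, ignore.strand = TRUE)
  }
  ## promoter exclusion: every annotated isoform TSS, active or not
  if (nrow(gm$isoforms)) {
    for (j in seq_len(nrow(gm$isoforms))) {
      t0 <- gm$isoforms$tss[j]
      ch <- gm$isoforms$chrom[j]
      eligible <- eligible & !(tus$chrom == ch &
                                 abs(tus$origin - t0) <= promoter_halfwidth)
    }
  }
  ## termination zones of active genes
  if (nrow(act)) {
    for (j in seq_len(nrow(act))) {
      pa_set <- act$active_polya[[j]]
      if (is.null(pa_set)) pa_set <- act$polya[j]
      dirp <- if (act$strand[j] == "+") 1L else -1L
      for (pa in pa_set) {
        d <- (tus$origin - pa) * dirp
        eligible <- eligible & !(tus$chrom == act$chrom[j] & d >= 0 &
                                   d < term_len)
      }
    }
  }
  el <- tus[eligible, , drop = FALSE]
  if (!nrow(el)) return(empty_enhancers())

  paired <- pair_bidirectional(el, pair_maxdist)
  calls <- list()
  for (p in paired$pairs) {
    a <- el[p[1], ]; b <- el[p[2], ]
    calls[[length(calls) + 1L]] <- data.frame(
      kind = "extragenic", directionality = "bidirectional",
      chrom = a$chrom, start = min(a$start, b$start),
      end = max(a$end, b$end),
      center = as.integer(floor((a$origin + b$origin) / 2)),
      host_gene = NA_character_,
      tu_ids = paste(sort(c(a$tu_id, b$tu_id)), collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (i in paired$unpaired) {
    u <- el[i, ]
    calls[[length(calls) + 1L]] <- data.frame(
      kind = "extragenic", directionality = "unidirectional",
      chrom = u$chrom, start = u$start, end = u$end,
      center = u$origin, host_gene = NA_character_, tu_ids = u$tu_id,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  ok <- overlaps_marks(out[, c("chrom", "start", "end")], peaks)
  out <- out[ok, , drop = FALSE]
  if (!nrow(out)) return(empty_enhancers())
  out <- out[order(out$chrom, out$center), , drop = FALSE]
  out <- cbind(enh_id = sprintf("extra%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## greedy nearest-origin pairing of opposite-strand units on one
## chromosome; deterministic: pairs sorted by (distance, left origin)
pair_bidirectional <- function(el, pair_maxdist) {
  n <- nrow(el)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (el$chrom[i] != el$chrom[j]) next
      if (el$strand[i] == el$strand[j]) next
      d <- abs(el$origin[i] - el$origin[j])
      if (d < pair_maxdist)
        cand[[length(cand) + 1L]] <- c(i, j, d,
                                       min(el$origin[i], el$origin[j]))
    }
  }
  pairs <- list(); used <- rep(FALSE, n)
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3], cm[, 4], cm[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  list(pairs = pairs, unpaired = which(!used))
}

check_peaks <- function(peaks) {
  if (!is.list(peaks) || !all(c("H3K27ac", "H3K4me1") %in% names(peaks)))
    stop("both H3K27ac and H3K4me1 peak sets are required")
  invisible(peaks)
}

## >= 1 bp overlap with both mark peak sets
overlaps_marks <- function(iv, peaks) {
  if (!nrow(iv)) return(logical(0))
  i_gr <- intervals_to_granges(iv, use_strand = FALSE)
  ok <- rep(TRUE, nrow(iv))
  for (mark in c("H3K27ac", "H3K4me1")) {
    p <- peaks[[mark]]
    if (!nrow(p)) { ok[] <- FALSE; next }
    p_gr <- intervals_to_granges(p, use_strand = FALSE)
    ok <- ok & IRanges::overlapsAny(i_gr, p_gr, ignore.strand = TRUE)
  }
  ok
}

empty_enhancers <- function() {
  data.frame(enh_id = character(), kind = character(),
             directionality = character(), chrom = character(),
             start = integer(), end = integer(), center = integer(),
             host_gene = character(), tu_ids = character(),
             stringsAsFactors = FALSE)
}

#' Run the full antisense classification chain
#'
#' [find_antisense_units()] -> [filter_overlapping_gene_atus()] ->
#' [classify_atu()], returning every candidate with its final class
#' (every candidate ends in exactly one of CAT, DAT or discarded with a
#' reason).
#'
#' @param tus transcription units.
#' @param gm refined [gene_models()].
#' @param dat_window,frac_tu,frac_gene rule thresholds, see the step
#'   functions.
#' @return classified ATU data.frame.
#' @export
classify_antisense <- function(tus, gm, dat_window = 1000L,
                               frac_tu = 0.50, frac_gene = 0.90) {
  atus <- find_antisense_units(tus, gm, dat_window)
  atus <- filter_overlapping_gene_atus(atus, gm, frac_tu, frac_gene)
  classify_atu(atus, gm, dat_window)
}
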