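#' Define quantification regions for differential analysis
#'
#' Builds the standard region classes from an annotation and an enhancer
#' call set: per active gene the whole gene (effective span), the
#' promoter-proximal window `[TSS, TSS + proximal_width)` and the gene
#' body `[TSS + proximal_width, polyA)`, all in gene orientation; per
#' enhancer the whole call span, the proximal window `center +/-
#' enh_proximal_halfwidth` and the distal remainder of the span. Spike-in
#' units (when given) are added as their own class so spike-in size
#' factors can be computed from the same matrix. Gene regions are counted
#' sense-strand; enhancer and spike regions on both strands.
#'
#' @param gm refined [gene_models()].
#' @param enhancers enhancer-call data.frame (may be empty).
#' @param spike_genes optional data.frame (gene_id, chrom, start, end,
#'   strand) of spike-in units.
#' @param proximal_width promoter-proximal window (bp, default 500).
#' @param enh_proximal_halfwidth enhancer proximal half-window (bp,
#'   default 250).
#' @return data.frame: region_id, chrom, start, end, strand, class,
#'   species, strand_rule; distal enhancer remainders may span several
#'   rows sharing one region_id.
#' @export
define_regions <- function(gm, enhancers = empty_enhancers(),
                           spike_genes = NULL, proximal_width = 500L,
                           enh_proximal_halfwidth = 250L) {
  rows <- list()
  add <- function(id, chrom, start, end, strand, class, species, rule) {
    if (end <= start) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      region_id = id, chrom = chrom, start = as.integer(start),
      end = as.integer(end), strand = strand, class = class,
      species = species, strand_rule = rule, stringsAsFactors = FALSE)
  }
  act <- gm$genes[which(gm$genes$active), , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    g <- act[i, ]
    s <- g$eff_start; e <- g$eff_end
    add(paste0(g$gene_id, ":gene"), g$chrom, s, e, g$strand, "gene",
        "primary", "sense")
    if (g$strand == "+") {
      add(paste0(g$gene_id, ":proximal"), g$chrom, s,
          min(e, s + proximal_width), "+", "promoter_proximal",
          "primary", "sense")
      add(paste0(g$gene_id, ":body"), g$chrom, min(e, s + proximal_width),
          e, "+", "gene_body", "primary", "sense")
    } else {
      add(paste0(g$gene_id, ":proximal"), g$chrom,
          max(s, e - proximal_width), e, "-", "promoter_proximal",
          "primary", "sense")
      add(paste0(g$gene_id, ":body"), g$chrom, s,
          max(s, e - proximal_width), "-", "gene_body", "primary", "sense")
    }
  }
  for (i in seq_len(nrow(enhancers))) {
    en <- enhancers[i, ]
    ps <- max(en$start, en$center - enh_proximal_halfwidth)
    pe <- min(en$end, en$center + enh_proximal_halfwidth + 1L)
    add(paste0(en$enh_id, ":enh"), en$chrom, en$start, en$end, "+",
        "enhancer", "primary", "both")
    add(paste0(en$enh_id, ":proximal"), en$chrom, ps, pe, "+",
        "enhancer_proximal", "primary", "both")
    add(paste0(en$enh_id, ":distal"), en$chrom, en$start, ps, "+",
        "enhancer_distal", "primary", "both")
    add(paste0(en$enh_id, ":distal"), en$chrom, pe, en$end, "+",
        "enhancer_distal", "primary", "both")
  }
  if (!is.null(spike_genes)) {
    for (i in seq_len(nrow(spike_genes))) {
      sg <- spike_genes[i, ]
      add(paste0(sg$gene_id, ":spike"), sg$chrom, sg$start, sg$end,
          sg$strand, "spike_gene", "spike", "both")
    }
  }
  if (!length(rows))
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), class = character(),
                      species = character(), strand_rule = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count a set of sample tracks over a region table
#'
#' Applies [quantify_regions()] per sample, honouring each region's
#' `strand_rule` column ("sense" / "antisense" / "both"), and returns a
#' complete count matrix plus the per-region metadata aligned to its rows.
#'
#' @param tracks named list of [occupancy_track()] objects (one per
#'   sample).
#' @param regions region table from [define_regions()].
#' @return list with `counts` (matrix, regions x samples) and `regions`
#'   (one metadata row per matrix row).
#' @export
build_count_matrix <- function(tracks, regions) {
  stopifnot(length(tracks) > 0)
  if (is.null(names(tracks)))
    names(tracks) <- paste0("sample_", seq_along(tracks))
  rule <- if ("strand_rule" %in% names(regions)) regions$strand_rule
          else rep("sense", nrow(regions))
  ids <- unique(regions$region_id)
  counts <- matrix(0, nrow = length(ids), ncol = length(tracks),
                   dimnames = list(ids, names(tracks)))
  for (r in unique(rule)) {
    sub <- regions[rule == r, , drop = FALSE]
    for (s in names(tracks)) {
      q <- quantify_regions(tracks[[s]], sub, strand_rule = r)
      counts[names(q), s] <- counts[names(q), s] + q
    }
  }
  meta <- regions[!duplicated(regions$region_id), , drop = FALSE]
  meta <- meta[match(ids, meta$region_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, regions = meta)
}
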