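#' Gene models: genes, isoforms and exon structure
#'
#' Container tying together a gene table, an isoform table (TSS, polyA and
#' expression per isoform) and an exon table. All coordinates are 0-based
#' half-open; `tss` and `polya` are single 0-based positions (for a minus
#' strand gene the TSS is `end - 1` and the polyA site is `start`).
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand, tss,
#'   polya.
#' @param isoforms data.frame with gene_id, isoform_id, chrom, strand,
#'   tss, polya and optionally tpm.
#' @param exons data.frame with gene_id, isoform_id, chrom, strand, start,
#'   end.
#' @return list of class `gene_models`.
#' @export
gene_models <- function(genes, isoforms, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "tss",
                  "polya") %in% names(genes)),
            all(c("gene_id", "isoform_id", "tss", "polya") %in%
                  names(isoforms)),
            all(c("gene_id", "isoform_id", "chrom", "strand", "start",
                  "end") %in% names(exons)))
  validate_intervals(genes)
  if (nrow(exons)) validate_intervals(exons)
  if (!all(isoforms$gene_id %in% genes$gene_id))
    stop("isoforms reference unknown gene ids")
  ## TSS upstream of polyA in gene orientation
  d <- (isoforms$polya - isoforms$tss) *
    ifelse(isoforms$strand == "+", 1L, -1L)
  if (any(d < 0)) stop("isoform TSS must lie upstream of its polyA site")
  structure(list(genes = genes, isoforms = isoforms, exons = exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d isoforms, %d exons",
              nrow(x$genes), nrow(x$isoforms), nrow(x$exons)))
  if ("active" %in% names(x$genes))
    cat(sprintf("; %d active", sum(x$genes$active)))
  cat("\n")
  invisible(x)
}

#' Call active genes from expression plus nascent transcription evidence
#'
#' A gene is active iff its expression (sum of isoform TPMs) reaches the
#' threshold AND at least one called nascent transcription unit on the
#' gene strand overlaps the gene interval — expression alone is not
#' enough; genes without nascent transcription are removed.
#'
#' @param gm a [gene_models()] object.
#' @param expression data.frame with gene_id, isoform_id, tpm. Isoforms
#'   absent from the table get TPM 0; rows for unknown genes are dropped
#'   with a warning.
#' @param tus transcription-unit data.frame from
#'   [call_transcription_units()] (needs chrom, start, end, strand).
#' @param tpm_threshold minimum gene TPM (inclusive), default 1.
#' @return `gm` with `tpm` and `active` columns on `$genes` and `tpm`
#'   filled on `$isoforms`.
#' @export
call_active_genes <- function(gm, expression, tus, tpm_threshold = 1) {
  stopifnot(inherits(gm, "gene_models"),
            all(c("gene_id", "isoform_id", "tpm") %in% names(expression)))
  unknown <- !expression$gene_id %in% gm$genes$gene_id
  if (any(unknown)) {
    warning(sum(unknown), " expression rows reference unknown genes; ignored")
    expression <- expression[!unknown, , drop = FALSE]
  }
  key <- paste(expression$gene_id, expression$isoform_id)
  gm$isoforms$tpm <- expression$tpm[match(
    paste(gm$isoforms$gene_id, gm$isoforms$isoform_id), key)]
  gm$isoforms$tpm[is.na(gm$isoforms$tpm)] <- 0
  gene_tpm <- rowsum(gm$isoforms$tpm, gm$isoforms$gene_id)
  gm$genes$tpm <- gene_tpm[match(gm$genes$gene_id, rownames(gene_tpm)), 1]
  gm$genes$tpm[is.na(gm$genes$tpm)] <- 0

  has_tu <- rep(FALSE, nrow(gm$genes))
  if (nrow(tus)) {
    g_gr <- intervals_to_granges(gm$genes)
    t_gr <- intervals_to_granges(tus)
    has_tu <- IRanges::overlapsAny(g_gr, t_gr, ignore.strand = FALSE)
  }
  gm$genes$active <- gm$genes$tpm >= tpm_threshold & has_tu
  gm
}

#' Refine active isoforms and the effective gene span
#'
#' An isoform is active iff it contributes at least `min_share` (default
#' 10%) of the gene's summed isoform expression. The active TSS and polyA
#' position sets are those of the active isoforms, and the gene's
#' effective span for all downstream rules runs from the first active TSS
#' to the last active polyA in gene orientation.
#'
#' @param gm a [gene_models()] after [call_active_genes()].
#' @param min_share minimum isoform share of gene expression.
#' @return `gm` with `active` on `$isoforms` and list-columns
#'   `active_tss`, `active_polya` plus `eff_start`/`eff_end` (0-based
#'   half-open effective span) on `$genes` for active genes.
#' @export
refine_active_isoforms <- function(gm, min_share = 0.10) {
  stopifnot(inherits(gm, "gene_models"), "active" %in% names(gm$genes))
  genes <- gm$genes
  iso <- gm$isoforms
  iso$active <- FALSE
  genes$active_tss <- vector("list", nrow(genes))
  genes$active_polya <- vector("list", nrow(genes))
  genes$eff_start <- NA_integer_
  genes$eff_end <- NA_integer_
  for (i in which(genes$active)) {
    gid <- genes$gene_id[i]
    ii <- which(iso$gene_id == gid)
    tot <- sum(iso$tpm[ii])
    if (tot <= 0)
      stop("active gene ", gid, " has zero summed isoform expression")
    act <- ii[iso$tpm[ii] / tot >= min_share]
    iso$active[act] <- TRUE
    tss <- sort(unique(iso$tss[act]))
    pa <- sort(unique(iso$polya[act]))
    genes$active_tss[[i]] <- tss
    genes$active_polya[[i]] <- pa
    if (genes$strand[i] == "+") {
      genes$eff_start[i] <- min(tss)
      genes$eff_end[i] <- max(pa) + 1L
    } else {
      genes$eff_start[i] <- min(pa)
      genes$eff_end[i] <- max(tss) + 1L
    }
  }
  gm$genes <- genes
  gm$isoforms <- iso
  gm
}

## first active TSS in gene orientation (NA when none)
first_active_tss <- function(gene_row) {
  tss <- gene_row$active_tss[[1]]
  if (is.null(tss) || !length(tss)) return(NA_integer_)
  if (gene_row$strand == "+") min(tss) else max(tss)
}
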