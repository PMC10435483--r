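# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small but complete synthetic study system used by several test files
small_cfg <- function(...) {
  sim_config(seed = 42, n_chroms = 2, chrom_length = 3e5, n_genes = 40,
             n_intragenic_enh = 8, n_extragenic_enh = 8, n_decoys = 4,
             n_mask_loci = 3, n_blacklist = 2, read_depth = 2e5,
             n_spike_genes = 10, ...)
}

small_sim <- function() fixture("small_sim", simulate_genome(small_cfg()))

# build a gene_models object from compact per-gene rows; every gene gets
# one isoform spanning it unless isoform rows are supplied
toy_gm <- function(genes, isoforms = NULL, active = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$polya <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  if (is.null(isoforms)) {
    isoforms <- data.frame(gene_id = genes$gene_id,
                           isoform_id = paste0(genes$gene_id, ".1"),
                           chrom = genes$chrom, strand = genes$strand,
                           tss = genes$tss, polya = genes$polya,
                           tpm = 10, stringsAsFactors = FALSE)
  }
  exons <- data.frame(gene_id = isoforms$gene_id,
                      isoform_id = isoforms$isoform_id,
                      chrom = isoforms$chrom, strand = isoforms$strand,
                      start = pmin(isoforms$tss, isoforms$polya),
                      end = pmax(isoforms$tss, isoforms$polya) + 1L,
                      stringsAsFactors = FALSE)
  gm <- gene_models(genes, isoforms, exons)
  gm$genes$active <- if (is.null(active)) rep(TRUE, nrow(genes)) else active
  refine_active_isoforms(gm)
}

# transcription-unit row constructor (0-based half-open)
tu_row <- function(chrom, start, end, strand, id = NULL, count = 50L) {
  data.frame(tu_id = if (is.null(id)) sprintf("tu_%s_%d_%s", chrom, start,
                                              strand) else id,
             chrom = chrom, strand = strand, start = as.integer(start),
             end = as.integer(end),
             origin = if (strand == "+") as.integer(start)
                      else as.integer(end - 1L),
             total_count = as.integer(count), stringsAsFactors = FALSE)
}

both_marks <- function(chrom, center, hw27 = 600L, hw4 = 800L) {
  list(H3K27ac = data.frame(chrom = chrom, start = center - hw27,
                            end = center + hw27),
       H3K4me1 = data.frame(chrom = chrom, start = center - hw4,
                            end = center + hw4))
}

merge_peaks <- function(a, b) {
  list(H3K27ac = rbind(a$H3K27ac, b$H3K27ac),
       H3K4me1 = rbind(a$H3K4me1, b$H3K4me1))
}

no_marks <- function() {
  list(H3K27ac = data.frame(chrom = character(), start = integer(),
                            end = integer()),
       H3K4me1 = data.frame(chrom = character(), start = integer(),
                            end = integer()))
}
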