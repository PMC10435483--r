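#' Simulation configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic-data generator: genome geometry,
#' element counts, signal shape (promoter-proximal pausing, divergent
#' promoter antisense, bidirectional enhancer transcription), artifact
#' rates (RT mispriming, RNA-processing intermediates, PCR duplication),
#' the mouse-style spike-in ratio, and the global perturbation fold
#' changes. A single integer seed fixes every downstream draw; the
#' generator consumes randomness in a documented fixed order so re-running
#' any stage with the same config is byte-identical.
#'
#' @param seed integer; master seed (< 2^31 - 10^6), fixes all draws.
#' @param n_chroms number of primary chromosomes.
#' @param chrom_length length of each primary chromosome (bp).
#' @param n_genes number of genes (distributed round-robin over chromosomes).
#' @param n_intragenic_enh number of intragenic enhancers (planted inside
#'   single-isoform active gene bodies, with a convergent antisense unit).
#' @param n_extragenic_enh number of extragenic enhancers (planted in
#'   intergenic space clear of promoter and termination zones).
#' @param pausing_index ratio of mean promoter-proximal density to mean
#'   gene-body density.
#' @param divergent_promoter_fraction probability that an active gene gets a
#'   divergent antisense unit upstream of its TSS.
#' @param enh_bidirectional_fraction probability that an enhancer is
#'   bidirectional (two opposite-strand origins < 500 bp apart).
#' @param mispriming_rate per-read probability that the UMI is overwritten
#'   by the genomic sequence adjacent to the read (detectable mispriming).
#' @param intermediate_rate per-read probability of relocation to the
#'   3'-most nucleotide of an annotated exon/intron or a polyA site
#'   (RNA-processing intermediate).
#' @param spike_ratio spike-in reads as a fraction of primary reads
#'   (default 1/8, the mouse:human cell ratio the assay uses).
#' @param perturbation_body_fc fold change applied to gene-body and
#'   enhancer-distal signal under the perturbation.
#' @param perturbation_proximal_fc fold change applied to promoter-proximal
#'   and enhancer-proximal signal under the perturbation.
#' @param read_depth total expected primary reads per replicate.
#' @param n_replicates replicates drawn per condition.
#' @param read_length simulated aligned read length (bp).
#' @param umi_length UMI length (nt).
#' @param dup_factor PCR duplication factor; each unique (position, UMI)
#'   read is emitted this many times.
#' @param n_decoys transcribed extragenic decoy loci without histone marks.
#' @param n_mask_loci short sn/snoRNA-like high-signal loci covered by the
#'   ncRNA mask.
#' @param n_blacklist blacklist mask intervals (signal-free).
#' @param n_spike_genes transcribed units on the spike chromosome.
#' @param inactive_gene_fraction fraction of genes with TPM < 1 and no
#'   signal.
#' @param silent_gene_fraction fraction of genes with TPM >= 1 but no
#'   nascent signal (exercises the nascent-transcription requirement).
#' @param alt_tss_fraction fraction of transcribed genes carrying a second
#'   isoform with a downstream alternative TSS.
#' @param noise_weight fraction of primary read depth emitted as uniform
#'   background noise.
#' @param overdispersion gamma-mixing overdispersion of per-position counts
#'   (0 = Poisson).
#' @param decoy_contact_fraction fraction of simulated contacts that are
#'   decoys touching no enhancer.
#' @param perturbation_enhancer_coupling per-gene multiplicative coupling
#'   of the body fold change to the number of contact-connected enhancers:
#'   a gene with k connected enhancers gets body fold change
#'   `perturbation_body_fc * coupling^k`. 1 (default) disables coupling;
#'   values below 1 make genes with more enhancers lose more signal.
#' @param spike_prefix reserved chromosome-name prefix for spike-in
#'   references.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length = 8e5,
                       n_genes = 200L,
                       n_intragenic_enh = 50L,
                       n_extragenic_enh = 50L,
                       pausing_index = 4,
                       divergent_promoter_fraction = 0.6,
                       enh_bidirectional_fraction = 0.7,
                       mispriming_rate = 0.01,
                       intermediate_rate = 0.01,
                       spike_ratio = 1 / 8,
                       perturbation_body_fc = 1,
                       perturbation_proximal_fc = 1,
                       read_depth = 2e6,
                       n_replicates = 2L,
                       read_length = 30L,
                       umi_length = 10L,
                       dup_factor = 1L,
                       n_decoys = 20L,
                       n_mask_loci = 8L,
                       n_blacklist = 4L,
                       n_spike_genes = 40L,
                       inactive_gene_fraction = 0.10,
                       silent_gene_fraction = 0.05,
                       alt_tss_fraction = 0.15,
                       noise_weight = 0.005,
                       overdispersion = 0,
                       decoy_contact_fraction = 0.5,
                       perturbation_enhancer_coupling = 1,
                       spike_prefix = "spike_") {
  cfg <- as.list(environment())
  probs <- c("divergent_promoter_fraction", "enh_bidirectional_fraction",
             "mispriming_rate", "intermediate_rate",
             "inactive_gene_fraction", "silent_gene_fraction",
             "alt_tss_fraction", "noise_weight", "decoy_contact_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", p))
  }
  for (p in c("perturbation_body_fc", "perturbation_proximal_fc",
              "pausing_index", "spike_ratio")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop(sprintf("'%s' must be > 0", p))
  }
  for (p in c("n_chroms", "chrom_length", "n_genes", "n_intragenic_enh",
              "n_extragenic_enh", "read_depth", "n_replicates",
              "read_length", "umi_length", "dup_factor", "n_decoys",
              "n_mask_loci", "n_blacklist", "n_spike_genes")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("'%s' must be a nonnegative count", p))
  }
  if (cfg$n_chroms < 1 || cfg$chrom_length < 2e4)
    stop("need at least one primary chromosome of >= 20 kb")
  if (!is.numeric(cfg$seed) || cfg$seed >= 2^31 - 1e6 || cfg$seed < 0)
    stop("seed must be a nonnegative integer below 2^31 - 1e6")
  cfg$seed <- as.integer(cfg$seed)
  cfg$overdispersion <- max(0, cfg$overdispersion)
  class(cfg) <- "sim_config"
  cfg
}
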