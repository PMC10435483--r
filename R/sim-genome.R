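#' Simulate a genome, gene annotation, marks, masks and truth table
#'
#' Lays out a small multi-chromosome genome with non-overlapping genes,
#' divergent promoter antisense units, intragenic enhancers (a convergent
#' antisense unit inside a host gene body), extragenic enhancers in clear
#' intergenic space, transcribed decoy loci without histone marks,
#' sn/snoRNA-like masked loci, blacklist intervals and a dedicated spike-in
#' chromosome. Every planted enhancer receives an H3K27ac and an H3K4me1
#' peak; decoys receive neither. A machine-readable truth table records
#' each element's class, interval, strand(s) and origin position(s).
#'
#' Randomness is consumed in one fixed order (gene geometry, expression,
#' promoter antisense, intragenic enhancers, intergenic elements, rates,
#' marks, genome sequence), so identical configs give byte-identical output.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_genome` with elements `config`,
#'   `chrom_lengths`, `genome` (a `Biostrings::DNAStringSet`), `annotation`
#'   (a [gene_models()] object), `expression` (gene/isoform TPM table),
#'   `peaks` (list of H3K27ac / H3K4me1 interval data.frames), `masks`
#'   (interval data.frame with a `class` column), `spike_genes`, `segments`
#'   (per-element signal segments used by [simulate_occupancy()]) and
#'   `truth` (the truth table).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- as.integer(config$n_genes)
  n_chroms <- as.integer(config$n_chroms)
  chroms <- paste0("chr", seq_len(n_chroms))
  clen <- as.integer(config$chrom_length)

  ## --- gene geometry -------------------------------------------------
  gene_len <- if (n_genes) round(stats::runif(n_genes, 2000, 5000)) else numeric()
  gene_gap <- if (n_genes) round(stats::runif(n_genes, 6000, 12000)) else numeric()
  gene_strand <- if (n_genes) sample(c("+", "-"), n_genes, replace = TRUE) else character()
  gene_chrom_idx <- if (n_genes) ((seq_len(n_genes) - 1L) %% n_chroms) + 1L else integer()

  gene_start <- integer(n_genes)
  for (ci in seq_len(n_chroms)) {
    idx <- which(gene_chrom_idx == ci)
    cursor <- 3000L
    for (i in idx) {
      gene_start[i] <- cursor
      cursor <- cursor + gene_len[i] + gene_gap[i]
    }
    if (length(idx) && cursor - gene_gap[idx[length(idx)]] + 3000L > clen)
      stop("chromosome too short for the requested number of genes; ",
           "increase chrom_length or n_chroms")
  }
  gene_end <- gene_start + gene_len
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  tss <- ifelse(gene_strand == "+", gene_start, gene_end - 1L)
  polya <- ifelse(gene_strand == "+", gene_end - 1L, gene_start)

  genes <- data.frame(gene_id = gene_id, chrom = chroms[gene_chrom_idx],
                      start = as.integer(gene_start), end = as.integer(gene_end),
                      strand = gene_strand, tss = as.integer(tss),
                      polya = as.integer(polya), stringsAsFactors = FALSE)

  ## --- expression and transcription status ---------------------------
  u_status <- if (n_genes) stats::runif(n_genes) else numeric()
  inactive <- u_status < config$inactive_gene_fraction
  silent <- !inactive &
    u_status < config$inactive_gene_fraction + config$silent_gene_fraction
  transcribed <- !inactive & !silent
  tpm_gene <- numeric(n_genes)
  tpm_gene[!inactive] <- pmax(1.5, stats::rlnorm(sum(!inactive), log(20), 1))
  tpm_gene[inactive] <- stats::runif(sum(inactive), 0, 0.9)

  alt_iso <- transcribed & gene_len >= 3800 &
    stats::runif(n_genes) < config$alt_tss_fraction
  iso1_share <- ifelse(alt_iso, stats::runif(n_genes, 0.55, 0.85), 1)

  ## isoforms: isoform 1 spans the gene; isoform 2 (if any) starts at a
  ## downstream alternative TSS and shares the polyA site
  alt_off <- round(stats::runif(n_genes, 1200, 2000))
  iso_rows <- list()
  for (i in seq_len(n_genes)) {
    dirp <- if (gene_strand[i] == "+") 1L else -1L
    iso_rows[[length(iso_rows) + 1L]] <- data.frame(
      gene_id = gene_id[i], isoform_id = paste0(gene_id[i], ".1"),
      chrom = chroms[gene_chrom_idx[i]], strand = gene_strand[i],
      tss = as.integer(tss[i]), polya = as.integer(polya[i]),
      tpm = tpm_gene[i] * iso1_share[i], stringsAsFactors = FALSE)
    if (alt_iso[i]) {
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], isoform_id = paste0(gene_id[i], ".2"),
        chrom = chroms[gene_chrom_idx[i]], strand = gene_strand[i],
        tss = as.integer(tss[i] + dirp * alt_off[i]),
        polya = as.integer(polya[i]),
        tpm = tpm_gene[i] * (1 - iso1_share[i]), stringsAsFactors = FALSE)
    }
  }
  isoforms <- if (length(iso_rows)) do.call(rbind, iso_rows) else
    data.frame(gene_id = character(), isoform_id = character(),
               chrom = character(), strand = character(), tss = integer(),
               polya = integer(), tpm = numeric())

  ## exon structure of isoform 1: 1-3 exons separated by 200 bp introns
  n_ex <- if (n_genes) sample(1:3, n_genes, replace = TRUE) else integer()
  exon_rows <- list()
  for (i in seq_len(n_genes)) {
    s <- gene_start[i]; e <- gene_end[i]
    k <- n_ex[i]
    cuts <- integer()
    if (k > 1) {
      cand <- sort(round(stats::runif(k - 1, s + 700, e - 900)))
      if (all(diff(c(s, cand, e)) >= 600)) cuts <- cand else k <- 1L
    }
    ex_s <- c(s, cuts + 200L)
    ex_e <- c(cuts, e)
    exon_rows[[i]] <- data.frame(
      gene_id = gene_id[i], isoform_id = paste0(gene_id[i], ".1"),
      chrom = chroms[gene_chrom_idx[i]], strand = gene_strand[i],
      start = as.integer(ex_s), end = as.integer(ex_e),
      stringsAsFactors = FALSE)
  }
  exons <- if (length(exon_rows)) do.call(rbind, exon_rows) else
    data.frame(gene_id = character(), isoform_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer())
  rownames(exons) <- NULL

  ## second isoforms inherit the exon structure clipped to their span
  if (any(alt_iso)) {
    iso2 <- isoforms[grepl("\\.2$", isoforms$isoform_id), , drop = FALSE]
    for (j in seq_len(nrow(iso2))) {
      ex <- exons[exons$gene_id == iso2$gene_id[j] &
                    grepl("\\.1$", exons$isoform_id), , drop = FALSE]
      if (iso2$strand[j] == "+") {
        ex <- ex[ex$end > iso2$tss[j], , drop = FALSE]
        ex$start <- pmax(ex$start, iso2$tss[j])
      } else {
        ex <- ex[ex$start <= iso2$tss[j], , drop = FALSE]
        ex$end <- pmin(ex$end, iso2$tss[j] + 1L)
      }
      ex$isoform_id <- iso2$isoform_id[j]
      exons <- rbind(exons, ex)
    }
    rownames(exons) <- NULL
  }

  ## --- per-gene signal rate and promoter antisense -------------------
  gene_rate <- numeric(n_genes)
  gene_rate[transcribed] <- stats::rlnorm(sum(transcribed), log(1), 0.5)
  has_dat <- transcribed & stats::runif(n_genes) < config$divergent_promoter_fraction
  dat_off <- round(stats::runif(n_genes, 30, 200))
  dat_len <- round(stats::runif(n_genes, 300, 600))

  ## --- intragenic enhancers ------------------------------------------
  host_ok <- which(transcribed & !alt_iso & gene_len >= 3200)
  n_intra <- as.integer(config$n_intragenic_enh)
  if (n_intra > length(host_ok))
    stop("not enough eligible host genes for the requested intragenic enhancers")
  hosts <- if (n_intra) sample(host_ok, n_intra) else integer()
  intra_coff <- if (n_intra)
    round(stats::runif(n_intra, 1500, pmax(1501, gene_len[hosts] - 1200))) else numeric()
  intra_bidir <- if (n_intra) stats::runif(n_intra) < config$enh_bidirectional_fraction else logical()

  ## --- intergenic free gaps ------------------------------------------
  free <- free_gaps(genes, chroms, clen)
  n_extra <- as.integer(config$n_extragenic_enh)
  n_decoy <- as.integer(config$n_decoys)
  n_mask <- as.integer(config$n_mask_loci)
  n_black <- as.integer(config$n_blacklist)
  need <- n_extra + n_decoy + n_mask + n_black
  ## subdivide wide gaps into 2600-bp slots (>= 1300 bp clearance each)
  wide <- free[free$width >= 2600, , drop = FALSE]
  slot_list <- lapply(seq_len(nrow(wide)), function(i) {
    k <- max(1L, (wide$width[i]) %/% 2600L)
    centers <- wide$lo[i] + 1300L + (seq_len(k) - 1L) * 2600L
    data.frame(chrom = wide$chrom[i], center = as.integer(centers),
               stringsAsFactors = FALSE)
  })
  slots_all <- if (length(slot_list)) do.call(rbind, slot_list) else
    data.frame(chrom = character(), center = integer())
  if (nrow(slots_all) < need)
    stop("chromosomes too short: not enough intergenic space for the ",
         "requested extragenic elements")
  pick <- sample(nrow(slots_all), need)
  slots <- slots_all[pick, , drop = FALSE]
  slot_class <- rep(c("extragenic", "decoy", "mask", "blacklist"),
                    c(n_extra, n_decoy, n_mask, n_black))

  extra_bidir <- if (n_extra) stats::runif(n_extra) < config$enh_bidirectional_fraction else logical()
  decoy_bidir <- if (n_decoy) stats::runif(n_decoy) < config$enh_bidirectional_fraction else logical()

  ## --- spike chromosome ----------------------------------------------
  n_spike <- as.integer(config$n_spike_genes)
  spike_chrom <- paste0(config$spike_prefix, "chr1")
  spike_len <- as.integer(3000L * max(1L, n_spike) + 6000L)
  spike_genes <- data.frame(
    gene_id = sprintf("s%03d", seq_len(n_spike)),
    chrom = rep(spike_chrom, n_spike),
    start = as.integer(3000L + (seq_len(n_spike) - 1L) * 3000L),
    end = as.integer(3000L + (seq_len(n_spike) - 1L) * 3000L + 2000L),
    strand = rep(c("+", "-"), length.out = n_spike),
    rate = if (n_spike) stats::rlnorm(n_spike, log(1), 0.4) else numeric(),
    stringsAsFactors = FALSE)

  ## --- build signal segments and the truth table ---------------------
  built <- build_elements(genes, transcribed, gene_rate, has_dat, dat_off,
                          dat_len, hosts, intra_coff, intra_bidir,
                          slots, slot_class, extra_bidir, decoy_bidir,
                          spike_genes, tpm_gene, config)

  ## --- histone mark peaks --------------------------------------------
  peaks <- build_peaks(built$truth, genes, transcribed)

  ## --- masks ----------------------------------------------------------
  masks <- built$masks

  ## --- genome sequence (drawn last) ----------------------------------
  all_chroms <- c(stats::setNames(rep(clen, n_chroms), chroms),
                  stats::setNames(spike_len, spike_chrom))
  seqs <- vapply(all_chroms, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(all_chroms)

  expression <- isoforms[, c("gene_id", "isoform_id", "tpm")]
  gene_info <- cbind(genes, data.frame(
    tpm = tpm_gene, transcribed = transcribed, rate = gene_rate,
    n_isoforms = 1L + as.integer(alt_iso), stringsAsFactors = FALSE))

  out <- list(config = config,
              chrom_lengths = all_chroms,
              genome = genome,
              annotation = gene_models(genes, isoforms, exons),
              gene_info = gene_info,
              expression = expression,
              peaks = peaks,
              masks = masks,
              spike_genes = spike_genes,
              segments = built$segments,
              truth = built$truth)
  class(out) <- "sim_genome"
  out
}

## intergenic intervals clear of promoter windows (TSS side, 1800 bp) and
## termination zones (polyA side, 2600 bp) of flanking genes
free_gaps <- function(genes, chroms, clen) {
  out <- list()
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    left_buf <- ifelse(g$strand == "+", 1800L, 2600L)   # buffer before gene start
    right_buf <- ifelse(g$strand == "+", 2600L, 1800L)  # buffer after gene end
    lo <- c(2000L, g$end + right_buf)
    hi <- c(g$start - left_buf, clen - 2000L)
    w <- hi - lo
    keep <- w > 0
    out[[ch]] <- data.frame(chrom = ch, lo = lo[keep], hi = hi[keep],
                            width = w[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## one truth row plus signal segments per planted element
build_elements <- function(genes, transcribed, gene_rate, has_dat, dat_off,
                           dat_len, hosts, intra_coff, intra_bidir,
                           slots, slot_class, extra_bidir, decoy_bidir,
                           spike_genes, tpm_gene, config) {
  seg <- list(); tru <- list(); msk <- list()
  add_seg <- function(id, cls, chrom, start, end, strand, weight, profile,
                      center = NA_integer_) {
    seg[[length(seg) + 1L]] <<- data.frame(
      element_id = id, class = cls, chrom = chrom,
      start = as.integer(start), end = as.integer(end), strand = strand,
      weight = weight, profile = profile, center = as.integer(center),
      stringsAsFactors = FALSE)
  }
  add_truth <- function(id, cls, chrom, start, end, strand, origin,
                        strand2 = NA_character_, origin2 = NA_integer_,
                        center = NA_integer_, host = NA_character_) {
    tru[[length(tru) + 1L]] <<- data.frame(
      element_id = id, class = cls, chrom = chrom,
      start = as.integer(start), end = as.integer(end), strand = strand,
      origin = as.integer(origin), strand2 = strand2,
      origin2 = as.integer(origin2), center = as.integer(center),
      host_gene = host, stringsAsFactors = FALSE)
  }
  opp <- function(s) ifelse(s == "+", "-", "+")

  ## genes: proximal geometric peak + uniform body; optional divergent
  ## antisense upstream of the TSS on the opposite strand
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    add_truth(gi$gene_id, "gene", gi$chrom, gi$start, gi$end, gi$strand,
              gi$tss)
    if (!transcribed[i]) next
    r <- gene_rate[i]
    if (gi$strand == "+") {
      add_seg(gi$gene_id, "gene_proximal", gi$chrom, gi$tss, gi$tss + 500L,
              "+", r * config$pausing_index, "geom")
      add_seg(gi$gene_id, "gene_body", gi$chrom, gi$tss + 500L, gi$end,
              "+", r, "uniform")
    } else {
      add_seg(gi$gene_id, "gene_proximal", gi$chrom, gi$tss - 499L,
              gi$tss + 1L, "-", r * config$pausing_index, "geom")
      add_seg(gi$gene_id, "gene_body", gi$chrom, gi$start, gi$tss - 499L,
              "-", r, "uniform")
    }
    if (has_dat[i]) {
      id <- paste0("dat_", gi$gene_id)
      if (gi$strand == "+") {
        s <- gi$tss - dat_off[i] - dat_len[i]; e <- gi$tss - dat_off[i]
        org <- e - 1L; st <- "-"
      } else {
        s <- gi$tss + dat_off[i] + 1L; e <- s + dat_len[i]
        org <- s; st <- "+"
      }
      add_seg(id, "DAT", gi$chrom, s, e, st, 0.3 * r, "uniform")
      add_truth(id, "DAT", gi$chrom, s, e, st, org, host = gi$gene_id)
    }
  }

  ## intragenic enhancers: convergent antisense unit inside the host body
  for (j in seq_along(hosts)) {
    i <- hosts[j]; gi <- genes[i, ]
    id <- sprintf("enh_i%03d", j)
    r_e <- stats::rlnorm(1, log(0.6), 0.3)
    len1 <- round(stats::runif(1, 200, 400))
    g2 <- round(stats::runif(1, 40, 300))
    len2 <- round(stats::runif(1, 150, 350))
    if (gi$strand == "+") {
      c0 <- gi$tss + intra_coff[j]
      s1 <- c0 - len1; e1 <- c0; st1 <- "-"; org1 <- c0 - 1L
      s2 <- c0 + g2; e2 <- s2 + len2; st2 <- "+"; org2 <- s2
    } else {
      c0 <- gi$tss - intra_coff[j]
      s1 <- c0 + 1L; e1 <- s1 + len1; st1 <- "+"; org1 <- s1
      e2 <- c0 + 1L - g2; s2 <- e2 - len2; st2 <- "-"; org2 <- e2 - 1L
    }
    if (intra_bidir[j]) {
      center <- as.integer(floor((org1 + org2) / 2))
      add_seg(id, "enhancer", gi$chrom, s1, e1, st1, r_e, "uniform", center)
      add_seg(id, "enhancer", gi$chrom, s2, e2, st2, 0.8 * r_e, "uniform", center)
      add_truth(id, "intragenic_enhancer", gi$chrom, min(s1, s2),
                max(e1, e2), st1, org1, st2, org2, center, gi$gene_id)
    } else {
      center <- as.integer(org1)
      add_seg(id, "enhancer", gi$chrom, s1, e1, st1, r_e, "uniform", center)
      add_truth(id, "intragenic_enhancer", gi$chrom, s1, e1, st1, org1,
                center = center, host = gi$gene_id)
    }
  }

  ## extragenic enhancers and decoys: divergent pair or single unit
  ext_n <- 0L; dec_n <- 0L; mask_n <- 0L; black_n <- 0L
  for (k in seq_len(nrow(slots))) {
    ch <- slots$chrom[k]; c0 <- slots$center[k]
    cls <- slot_class[k]
    if (cls %in% c("extragenic", "decoy")) {
      bidir <- if (cls == "extragenic") {
        ext_n <- ext_n + 1L; extra_bidir[ext_n]
      } else {
        dec_n <- dec_n + 1L; decoy_bidir[dec_n]
      }
      id <- if (cls == "extragenic") sprintf("enh_x%03d", ext_n)
            else sprintf("decoy%03d", dec_n)
      tcls <- if (cls == "extragenic") "extragenic_enhancer" else "decoy"
      r_e <- stats::rlnorm(1, log(0.6), 0.3)
      if (bidir) {
        d1 <- round(stats::runif(1, 25, 200)); d2 <- round(stats::runif(1, 25, 200))
        len1 <- round(stats::runif(1, 200, 400)); len2 <- round(stats::runif(1, 200, 400))
        s1 <- c0 - d1 - len1; e1 <- c0 - d1; org1 <- e1 - 1L        # minus unit
        s2 <- c0 + d2; e2 <- s2 + len2; org2 <- s2                   # plus unit
        center <- as.integer(floor((org1 + org2) / 2))
        add_seg(id, "enhancer", ch, s1, e1, "-", r_e, "uniform", center)
        add_seg(id, "enhancer", ch, s2, e2, "+", 0.8 * r_e, "uniform", center)
        add_truth(id, tcls, ch, s1, e2, "-", org1, "+", org2, center)
      } else {
        len1 <- round(stats::runif(1, 200, 400))
        st <- sample(c("+", "-"), 1)
        if (st == "+") { s1 <- c0; e1 <- c0 + len1; org1 <- c0 }
        else { s1 <- c0 - len1; e1 <- c0; org1 <- c0 - 1L }
        add_seg(id, "enhancer", ch, s1, e1, st, r_e, "uniform",
                as.integer(org1))
        add_truth(id, tcls, ch, s1, e1, st, org1, center = org1)
      }
    } else if (cls == "mask") {
      mask_n <- mask_n + 1L
      id <- sprintf("ncrna%03d", mask_n)
      add_seg(id, "mask_locus", ch, c0, c0 + 150L, "+", 3, "uniform")
      add_truth(id, "mask_locus", ch, c0, c0 + 150L, "+", c0)
      msk[[length(msk) + 1L]] <- data.frame(
        chrom = ch, start = c0, end = c0 + 150L, strand = "*",
        class = "ncRNA", stringsAsFactors = FALSE)
    } else {
      black_n <- black_n + 1L
      msk[[length(msk) + 1L]] <- data.frame(
        chrom = ch, start = c0 - 250L, end = c0 + 250L, strand = "*",
        class = "blacklist", stringsAsFactors = FALSE)
    }
  }

  ## spike-in units
  for (j in seq_len(nrow(spike_genes))) {
    sg <- spike_genes[j, ]
    add_seg(sg$gene_id, "spike", sg$chrom, sg$start, sg$end, sg$strand,
            sg$rate, "uniform")
    add_truth(sg$gene_id, "spike_gene", sg$chrom, sg$start, sg$end,
              sg$strand, if (sg$strand == "+") sg$start else sg$end - 1L)
  }

  segments <- do.call(rbind, seg)
  rownames(segments) <- NULL
  truth <- do.call(rbind, tru)
  rownames(truth) <- NULL
  truth$expected_body_dir <- NA_character_
  truth$expected_proximal_dir <- NA_character_
  masks <- if (length(msk)) do.call(rbind, msk) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), class = character())
  rownames(masks) <- NULL
  list(segments = segments, truth = truth, masks = masks)
}

## every planted enhancer gets both marks; active promoters get H3K27ac;
## decoys get neither mark
build_peaks <- function(truth, genes, transcribed) {
  enh <- truth[truth$class %in% c("intragenic_enhancer",
                                  "extragenic_enhancer"), , drop = FALSE]
  k27 <- k4 <- list()
  if (nrow(enh)) {
    w27 <- round(stats::runif(nrow(enh), 600, 800))
    w4 <- round(stats::runif(nrow(enh), 800, 1000))
    k27[[1]] <- data.frame(chrom = enh$chrom,
                           start = as.integer(enh$center - w27),
                           end = as.integer(enh$center + w27),
                           stringsAsFactors = FALSE)
    k4[[1]] <- data.frame(chrom = enh$chrom,
                          start = as.integer(enh$center - w4),
                          end = as.integer(enh$center + w4),
                          stringsAsFactors = FALSE)
  }
  prom <- genes[transcribed, , drop = FALSE]
  if (nrow(prom)) {
    k27[[length(k27) + 1L]] <- data.frame(
      chrom = prom$chrom, start = as.integer(prom$tss - 500L),
      end = as.integer(prom$tss + 500L), stringsAsFactors = FALSE)
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer())
  list(H3K27ac = if (length(k27)) do.call(rbind, k27) else empty,
       H3K4me1 = if (length(k4)) do.call(rbind, k4) else empty)
}

#' @export
print.sim_genome <- function(x, ...) {
  tb <- table(x$truth$class)
  cat("sim_genome:", length(x$chrom_lengths), "chromosomes;",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
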