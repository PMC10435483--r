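#' Simulate replicate Pol II occupancy tracks from a synthetic genome
#'
#' Expands the per-element signal segments of a [simulate_genome()] object
#' into a per-position expected intensity (promoter-proximal geometric
#' decay from the TSS, uniform gene bodies and enhancer units, uniform
#' background noise, spike-in units on the reserved spike chromosome),
#' scales primary intensity to the configured read depth and spike
#' intensity to `spike_ratio * read_depth`, and draws integer counts
#' (Poisson, or gamma-mixed Poisson when `overdispersion > 0`) for each
#' replicate.
#'
#' @param sim a `sim_genome` object.
#' @param config a [sim_config()]; defaults to the one inside `sim`.
#' @param n_replicates number of replicate tracks to draw.
#' @return A list of class `sim_tracks`: `intensity` (data.frame with
#'   chrom, pos, strand, rate, compartment, element_id), `tracks` (list of
#'   [occupancy_track()] objects, one per replicate, spike chromosome
#'   included), and `condition` ("control").
#' @export
simulate_occupancy <- function(sim, config = sim$config,
                               n_replicates = config$n_replicates) {
  stopifnot(inherits(sim, "sim_genome"))
  set.seed(config$seed + 1L)
  intensity <- expand_segments(sim$segments, config)

  ## background noise over the primary chromosomes (drawn after expansion)
  if (config$noise_weight > 0 && nrow(intensity)) {
    prim <- !startsWith(intensity$chrom, config$spike_prefix)
    sum_sig <- sum(intensity$rate[prim])
    n_noise <- round(config$noise_weight * sum_sig / 0.2)
    if (n_noise > 0) {
      pchroms <- paste0("chr", seq_len(config$n_chroms))
      noise <- data.frame(
        chrom = sample(pchroms, n_noise, replace = TRUE),
        pos = as.integer(floor(stats::runif(n_noise, 100,
                                            config$chrom_length - 100))),
        strand = sample(c("+", "-"), n_noise, replace = TRUE),
        rate = 0.2, compartment = "noise", element_id = "noise",
        stringsAsFactors = FALSE)
      intensity <- rbind(intensity, noise)
    }
  }

  intensity <- scale_intensity(intensity, config)
  tracks <- draw_replicates(intensity, n_replicates, config)
  structure(list(intensity = intensity, tracks = tracks,
                 condition = "control"),
            class = "sim_tracks")
}

## segments -> one row per covered position with its expected rate
expand_segments <- function(segments, config) {
  if (!nrow(segments))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), rate = numeric(),
                      compartment = character(), element_id = character()))
  lens <- segments$end - segments$start
  pos <- sequence(lens, from = segments$start)
  row <- rep(seq_len(nrow(segments)), lens)
  rate <- rep(segments$weight, lens)

  ## promoter-proximal geometric decay away from the TSS, normalized so
  ## the mean over the window equals the segment weight
  geom <- segments$profile == "geom"
  if (any(geom)) {
    gidx <- which(geom[row])
    q <- 0.985
    seg_i <- row[gidx]
    L <- lens[seg_i]
    d <- ifelse(segments$strand[seg_i] == "+",
                pos[gidx] - segments$start[seg_i],
                segments$end[seg_i] - 1L - pos[gidx])
    rate[gidx] <- segments$weight[seg_i] * L * (1 - q) * q^d / (1 - q^L)
  }

  compartment <- c(gene_proximal = "proximal", gene_body = "distal",
                   DAT = "proximal", enhancer = "distal",
                   mask_locus = "distal", spike = "spike")[segments$class][row]
  enh <- segments$class[row] == "enhancer"
  if (any(enh)) {
    ctr <- segments$center[row[enh]]
    compartment[enh] <- ifelse(abs(pos[enh] - ctr) <= 250, "proximal",
                               "distal")
  }
  data.frame(chrom = segments$chrom[row], pos = as.integer(pos),
             strand = segments$strand[row], rate = rate,
             compartment = unname(compartment),
             element_id = segments$element_id[row],
             stringsAsFactors = FALSE)
}

scale_intensity <- function(intensity, config) {
  spike <- startsWith(intensity$chrom, config$spike_prefix)
  s_prim <- sum(intensity$rate[!spike])
  s_spk <- sum(intensity$rate[spike])
  if (s_prim > 0)
    intensity$rate[!spike] <- intensity$rate[!spike] * config$read_depth / s_prim
  if (s_spk > 0)
    intensity$rate[spike] <- intensity$rate[spike] *
      config$spike_ratio * config$read_depth / s_spk
  intensity
}

draw_replicates <- function(intensity, n_replicates, config) {
  lapply(seq_len(n_replicates), function(r) {
    rate <- intensity$rate
    if (config$overdispersion > 0) {
      sh <- 1 / config$overdispersion
      rate <- rate * stats::rgamma(length(rate), shape = sh, rate = sh)
    }
    cnt <- stats::rpois(length(rate), rate)
    keep <- cnt > 0
    occupancy_track(intensity$chrom[keep], intensity$pos[keep],
                    intensity$strand[keep], cnt[keep])
  })
}

#' Apply a global perturbation and simulate treated tracks plus contacts
#'
#' Scales promoter-proximal and enhancer-proximal intensity by
#' `perturbation_proximal_fc` and gene-body / enhancer-distal / background
#' intensity by `perturbation_body_fc` (spike-in intensity is left
#' untouched, which is what makes spike-in normalization informative),
#' draws treated replicate tracks, generates a contact set linking each
#' true enhancer to its host or nearest transcribed gene (plus decoy
#' contacts touching no enhancer and weak sub-threshold contacts), and
#' records the expected differential direction per truth element.
#'
#' @param occ a `sim_tracks` object from [simulate_occupancy()].
#' @param sim the `sim_genome` the tracks came from.
#' @param config a [sim_config()] carrying the perturbation fold changes.
#' @param n_replicates treated replicates to draw.
#' @return A list of class `sim_perturbation`: `treated` (a `sim_tracks`),
#'   `contacts` (anchor-pair data.frame with `padj` and provenance
#'   columns), and `truth` (truth table with expected directions filled).
#' @export
simulate_perturbation <- function(occ, sim, config = sim$config,
                                  n_replicates = config$n_replicates) {
  stopifnot(inherits(occ, "sim_tracks"), inherits(sim, "sim_genome"))
  set.seed(config$seed + 2L)
  contacts <- simulate_contacts(sim, config)

  fc <- c(proximal = config$perturbation_proximal_fc,
          distal = config$perturbation_body_fc,
          noise = config$perturbation_body_fc,
          spike = 1)
  intensity <- occ$intensity
  intensity$rate <- intensity$rate * fc[intensity$compartment]

  ## enhancer coupling: genes with more connected enhancers lose (or gain)
  ## proportionally more body signal; their enhancers scale along
  coup <- config$perturbation_enhancer_coupling
  if (coup != 1) {
    tc <- contacts[contacts$label == "true", , drop = FALSE]
    n_enh <- table(tc$target_gene)
    gene_extra <- stats::setNames(as.numeric(coup)^as.integer(n_enh),
                                  names(n_enh))
    is_body <- intensity$compartment == "distal" &
      intensity$element_id %in% names(gene_extra)
    intensity$rate[is_body] <- intensity$rate[is_body] *
      gene_extra[intensity$element_id[is_body]]
    enh_gene <- stats::setNames(tc$target_gene, tc$enhancer_id)
    is_enh <- intensity$element_id %in% names(enh_gene)
    intensity$rate[is_enh] <- intensity$rate[is_enh] *
      gene_extra[enh_gene[intensity$element_id[is_enh]]]
  }
  tracks <- draw_replicates(intensity, n_replicates, config)
  treated <- structure(list(intensity = intensity, tracks = tracks,
                            condition = "treated"), class = "sim_tracks")

  dir_of <- function(x) if (x < 1) "down" else if (x > 1) "up" else "unchanged"
  truth <- sim$truth
  is_gene <- truth$class == "gene"
  is_enh <- truth$class %in% c("intragenic_enhancer", "extragenic_enhancer",
                               "decoy", "DAT")
  truth$expected_body_dir[is_gene | is_enh] <- dir_of(config$perturbation_body_fc)
  truth$expected_proximal_dir[is_gene | is_enh] <-
    dir_of(config$perturbation_proximal_fc)

  structure(list(treated = treated, contacts = contacts, truth = truth),
            class = "sim_perturbation")
}

## one true contact per enhancer (anchor on the enhancer center, anchor on
## the target gene TSS), decoy contacts clear of all enhancers, and weak
## contacts above the significance threshold
simulate_contacts <- function(sim, config, anchor_halfwidth = 1000L) {
  truth <- sim$truth
  enh <- truth[truth$class %in% c("intragenic_enhancer",
                                  "extragenic_enhancer"), , drop = FALSE]
  gi <- sim$gene_info
  active <- gi[gi$transcribed & gi$tpm >= 1, , drop = FALSE]
  rows <- list()
  for (j in seq_len(nrow(enh))) {
    e <- enh[j, ]
    target <- e$host_gene
    if (is.na(target)) {
      cand <- active[active$chrom == e$chrom, , drop = FALSE]
      if (!nrow(cand)) next
      target <- cand$gene_id[which.min(abs(cand$tss - e$center))]
    }
    t_tss <- gi$tss[gi$gene_id == target]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom1 = e$chrom, start1 = e$center - anchor_halfwidth,
      end1 = e$center + anchor_halfwidth,
      chrom2 = e$chrom, start2 = t_tss - anchor_halfwidth,
      end2 = t_tss + anchor_halfwidth,
      padj = stats::runif(1, 1e-5, 5e-3), label = "true",
      enhancer_id = e$element_id, target_gene = target,
      stringsAsFactors = FALSE)
  }
  true_df <- if (length(rows)) do.call(rbind, rows) else NULL
  n_true <- length(rows)

  ## decoy anchors: random bins at least 1.5 anchor widths from any enhancer
  n_decoy <- if (config$decoy_contact_fraction < 1)
    round(n_true * config$decoy_contact_fraction /
            (1 - config$decoy_contact_fraction)) else 0L
  decoys <- list()
  if (n_decoy > 0 && n_true > 0) {
    pchroms <- paste0("chr", seq_len(config$n_chroms))
    enh_gr <- intervals_to_granges(
      data.frame(chrom = enh$chrom, start = enh$start - 3L * anchor_halfwidth,
                 end = enh$end + 3L * anchor_halfwidth), use_strand = FALSE)
    tries <- 0L
    while (length(decoys) < n_decoy && tries < 50L * n_decoy) {
      tries <- tries + 1L
      ch <- sample(pchroms, 1)
      p <- sort(floor(stats::runif(2, 3000, config$chrom_length - 3000)))
      cand <- intervals_to_granges(
        data.frame(chrom = ch, start = p - anchor_halfwidth,
                   end = p + anchor_halfwidth), use_strand = FALSE)
      if (length(enh_gr) &&
          any(IRanges::overlapsAny(cand, enh_gr, ignore.strand = TRUE)))
        next
      decoys[[length(decoys) + 1L]] <- data.frame(
        chrom1 = ch, start1 = p[1] - anchor_halfwidth,
        end1 = p[1] + anchor_halfwidth,
        chrom2 = ch, start2 = p[2] - anchor_halfwidth,
        end2 = p[2] + anchor_halfwidth,
        padj = stats::runif(1, 1e-4, 5e-3), label = "decoy",
        enhancer_id = NA_character_, target_gene = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  ## weak (non-significant) contacts that do touch enhancers
  weak <- NULL
  if (n_true > 0) {
    n_weak <- max(1L, round(0.3 * n_true))
    idx <- sample(nrow(enh), n_weak, replace = n_weak > nrow(enh))
    gpick <- active[sample(nrow(active), n_weak, replace = TRUE), , drop = FALSE]
    weak <- data.frame(
      chrom1 = enh$chrom[idx],
      start1 = enh$center[idx] - anchor_halfwidth,
      end1 = enh$center[idx] + anchor_halfwidth,
      chrom2 = gpick$chrom, start2 = gpick$tss - anchor_halfwidth,
      end2 = gpick$tss + anchor_halfwidth,
      padj = stats::runif(n_weak, 0.02, 0.5), label = "weak",
      enhancer_id = enh$element_id[idx], target_gene = NA_character_,
      stringsAsFactors = FALSE)
  }

  out <- rbind(true_df, if (length(decoys)) do.call(rbind, decoys), weak)
  if (is.null(out))
    out <- data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(), padj = numeric(),
                      label = character(), enhancer_id = character(),
                      target_gene = character())
  rownames(out) <- NULL
  attr(out, "resolution") <- 2L * anchor_halfwidth
  out
}
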