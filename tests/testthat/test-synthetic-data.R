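test_that("identical configs give byte-identical genomes, tracks and reads", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 1.5e5,
                    n_genes = 12, n_intragenic_enh = 3, n_extragenic_enh = 3,
                    n_decoys = 2, n_mask_loci = 2, n_blacklist = 1,
                    read_depth = 3e4, n_spike_genes = 5)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$genome), as.character(b$genome))
  oa <- simulate_occupancy(a); ob <- simulate_occupancy(b)
  expect_identical(oa$tracks, ob$tracks)
  ra <- simulate_reads(oa$tracks[[1]], a)
  rb <- simulate_reads(ob$tracks[[1]], b)
  expect_identical(ra, rb)
})

test_that("an empty gene set yields no genes and no gene-linked elements", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1e5,
                    n_genes = 0, n_intragenic_enh = 0, n_extragenic_enh = 2,
                    n_decoys = 0, n_mask_loci = 0, n_blacklist = 0,
                    read_depth = 5e3, n_spike_genes = 3)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$annotation$genes), 0)
  expect_false(any(sim$truth$class %in% c("gene", "DAT",
                                          "intragenic_enhancer")))
})

test_that("requesting more elements than the genome can hold is an error", {
  expect_error(simulate_genome(
    sim_config(seed = 1, n_chroms = 1, chrom_length = 5e4, n_genes = 40,
               n_intragenic_enh = 0, n_extragenic_enh = 0, n_decoys = 0,
               n_mask_loci = 0, n_blacklist = 0)),
    "too short")
})

test_that("planted intragenic enhancers sit inside their host gene body", {
  sim <- small_sim()
  tr <- sim$truth[sim$truth$class == "intragenic_enhancer", ]
  expect_equal(nrow(tr), small_cfg()$n_intragenic_enh)
  g <- sim$annotation$genes
  for (i in seq_len(nrow(tr))) {
    host <- g[g$gene_id == tr$host_gene[i], ]
    expect_true(tr$start[i] >= host$start && tr$end[i] <= host$end)
    expect_equal(tr$chrom[i], host$chrom)
  }
  ## every planted enhancer carries both marks; decoys carry neither
  hits_peaks <- function(rows, pk) vapply(seq_len(nrow(rows)), function(i)
    any(rows$chrom[i] == pk$chrom & rows$start[i] < pk$end &
          rows$end[i] > pk$start), logical(1))
  enh <- sim$truth[sim$truth$class %in% c("intragenic_enhancer",
                                          "extragenic_enhancer"), ]
  expect_true(all(hits_peaks(enh, sim$peaks$H3K27ac)))
  expect_true(all(hits_peaks(enh, sim$peaks$H3K4me1)))
  dec <- sim$truth[sim$truth$class == "decoy", ]
  expect_false(any(hits_peaks(dec, sim$peaks$H3K4me1)))
})

test_that("pausing index 1 gives matching proximal and body densities", {
  cfg <- small_cfg()
  cfg$pausing_index <- 1
  sim <- simulate_genome(cfg)
  occ <- simulate_occupancy(sim, cfg, n_replicates = 1)
  int <- occ$intensity
  gene_prox <- int$compartment == "proximal" &
    int$element_id %in% sim$gene_info$gene_id
  gene_body <- int$compartment == "distal" &
    int$element_id %in% sim$gene_info$gene_id
  expect_equal(mean(int$rate[gene_prox]), mean(int$rate[gene_body]),
               tolerance = 0.05)
})

test_that("full bidirectionality puts two opposite-strand origins on every enhancer", {
  cfg <- small_cfg()
  cfg$enh_bidirectional_fraction <- 1
  sim <- simulate_genome(cfg)
  enh <- sim$truth[sim$truth$class %in% c("intragenic_enhancer",
                                          "extragenic_enhancer"), ]
  expect_true(all(!is.na(enh$origin2)))
  expect_true(all(enh$strand != enh$strand2))
  expect_true(all(abs(enh$origin - enh$origin2) < 500))
})

test_that("doubling read depth doubles track totals within Poisson error", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  t1 <- track_total(simulate_occupancy(sim, cfg, n_replicates = 1)$tracks[[1]])
  cfg2 <- cfg; cfg2$read_depth <- 2 * cfg$read_depth
  t2 <- track_total(simulate_occupancy(sim, cfg2, n_replicates = 1)$tracks[[1]])
  tol <- 3 * sqrt(6 * cfg$read_depth)  # sd of t2 - 2 t1 under Poisson
  expect_lt(abs(t2 - 2 * t1), tol)
})

test_that("spike reads arrive at the configured 1:8 ratio", {
  sim <- small_sim()
  occ <- fixture("small_occ", simulate_occupancy(small_sim()))
  reads <- fixture("small_reads", simulate_reads(occ$tracks[[1]], small_sim()))
  n_spike <- sum(reads$label == "spike")
  n_prim <- sum(reads$label != "spike")
  p <- n_spike / n_prim
  se <- sqrt(0.125 / n_prim)  # Poisson-ratio standard error
  expect_lt(abs(p - 0.125), 3 * se + 0.003)
})

test_that("labels partition the reads and duplication is exactly undone by collapse", {
  cfg <- sim_config(seed = 21, n_chroms = 1, chrom_length = 1.5e5,
                    n_genes = 10, n_intragenic_enh = 2, n_extragenic_enh = 2,
                    n_decoys = 1, n_mask_loci = 1, n_blacklist = 1,
                    read_depth = 1e4, n_spike_genes = 4, dup_factor = 3)
  sim <- simulate_genome(cfg)
  occ <- simulate_occupancy(sim, cfg, n_replicates = 1)
  reads <- simulate_reads(occ$tracks[[1]], sim, cfg)
  expect_true(all(reads$label %in% c("genuine", "spike", "mispriming",
                                     "intermediate", "duplicate")))
  n_unique <- sum(reads$label != "duplicate")
  expect_equal(nrow(reads), 3L * n_unique)
  expect_equal(nrow(collapse_duplicates(reads)), n_unique)
})

test_that("a null perturbation leaves regional counts distributionally unchanged", {
  sim <- small_sim()
  occ <- fixture("small_occ", simulate_occupancy(small_sim()))
  pert <- simulate_perturbation(occ, sim)  # default fold changes are 1
  g <- sim$gene_info[sim$gene_info$transcribed, ]
  regions <- data.frame(region_id = g$gene_id, chrom = g$chrom,
                        start = g$start, end = g$end, strand = g$strand)
  qc <- quantify_regions(occ$tracks[[1]], regions, "sense")
  qt <- quantify_regions(pert$treated$tracks[[1]], regions, "sense")
  expect_gt(suppressWarnings(stats::ks.test(qc, qt)$p.value), 0.01)
  expect_true(all(pert$truth$expected_body_dir[
    pert$truth$class == "gene"] == "unchanged"))
})

test_that("a 4-fold body loss is recorded as expected direction down", {
  cfg <- small_cfg()
  cfg$perturbation_body_fc <- 0.25
  sim <- simulate_genome(cfg)
  occ <- simulate_occupancy(sim, cfg, n_replicates = 1)
  pert <- simulate_perturbation(occ, sim, cfg, n_replicates = 1)
  expect_identical(log2(cfg$perturbation_body_fc), -2)
  expect_true(all(pert$truth$expected_body_dir[
    pert$truth$class == "gene"] == "down"))
  ## treated body intensity is exactly 1/4 of control
  ctrl <- occ$intensity; trt <- pert$treated$intensity
  body <- ctrl$compartment == "distal"
  expect_equal(trt$rate[body], ctrl$rate[body] / 4)
})

test_that("decoy contact fraction 0.5 with 10 enhancers yields exactly 10 true pairs", {
  cfg <- sim_config(seed = 13, n_chroms = 2, chrom_length = 2.5e5,
                    n_genes = 24, n_intragenic_enh = 5, n_extragenic_enh = 5,
                    n_decoys = 2, n_mask_loci = 1, n_blacklist = 1,
                    read_depth = 3e4, n_spike_genes = 4,
                    decoy_contact_fraction = 0.5)
  sim <- simulate_genome(cfg)
  occ <- simulate_occupancy(sim, cfg, n_replicates = 1)
  pert <- simulate_perturbation(occ, sim, cfg, n_replicates = 1)
  tc <- pert$contacts[pert$contacts$label == "true", ]
  expect_equal(nrow(tc), 10L)
  expect_equal(sum(pert$contacts$label == "decoy"), 10L)
  expect_true(all(tc$padj < 0.01))
})
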