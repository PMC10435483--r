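mini_genome <- function() {
  ## deterministic 200-bp toy chromosome
  set.seed(99)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  Biostrings::DNAStringSet(c(chrT = s))
}

read_df <- function(chrom, start, end, strand, umi) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, umi = umi,
             stringsAsFactors = FALSE)
}

test_that("duplicate collapse keeps one read per position-UMI key, order-independently", {
  r <- read_df(rep("chr1", 3), rep(100L, 3), rep(130L, 3), rep("+", 3),
               rep("ACGTACGTAC", 3))
  expect_equal(nrow(collapse_duplicates(r)), 1L)
  r2 <- read_df(rep("chr1", 2), rep(100L, 2), rep(130L, 2), rep("+", 2),
                c("ACGTACGTAC", "ACGTACGTAA"))
  expect_equal(nrow(collapse_duplicates(r2)), 2L)
  big <- rbind(r, r2, read_df("chr2", 5L, 35L, "-", "TTTTTTTTTT"))
  shuffled <- big[sample(nrow(big)), ]
  expect_identical(collapse_duplicates(big), collapse_duplicates(shuffled))
})

test_that("mispriming removal matches the adjacent genomic k-mer exactly", {
  gen <- mini_genome()
  s <- as.character(gen[[1]])
  ## plus strand: UMI equal to the 10 bases following the read end
  adj <- substr(s, 131, 140)
  r <- read_df("chrT", 100L, 130L, "+", adj)
  out <- filter_mispriming(r, gen)
  expect_equal(out$removed, 1L)
  expect_equal(nrow(out$reads), 0L)
  ## one mismatching base rescues the read
  bad <- adj
  substr(bad, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(adj, 1, 1))[1]
  out2 <- filter_mispriming(read_df("chrT", 100L, 130L, "+", bad), gen)
  expect_equal(out2$removed, 0L)
  ## minus strand: reverse complement of the 10 bases preceding start
  up <- substr(s, 41, 50)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(up)))
  out3 <- filter_mispriming(read_df("chrT", 50L, 80L, "-", rc), gen)
  expect_equal(out3$removed, 1L)
  ## window past the chromosome end: kept, with a warning
  expect_warning(
    out4 <- filter_mispriming(read_df("chrT", 165L, 195L, "+",
                                      "ACGTACGTAC"), gen),
    "kept")
  expect_equal(out4$removed, 0L)
  expect_equal(nrow(out4$reads), 1L)
})

test_that("occupancy extraction takes the 5'-most aligned base and flips strand", {
  r <- read_df("chr1", 100L, 150L, "+", "AAAAAAAAAA")
  tr <- extract_occupancy(r, flip = TRUE)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$pos, 100L)
  expect_equal(tr$strand, "-")
  ## minus-strand read: 5'-most aligned base is end - 1
  r2 <- read_df("chr1", 100L, 150L, "-", "AAAAAAAAAA")
  tr2 <- extract_occupancy(r2, flip = TRUE)
  expect_equal(tr2$pos, 149L)
  expect_equal(tr2$strand, "+")
  expect_equal(nrow(extract_occupancy(r[0, ])), 0L)
  ## toggling flip mirrors every count onto the other strand (involution)
  reads <- fixture("small_reads", simulate_reads(
    fixture("small_occ", simulate_occupancy(small_sim()))$tracks[[1]],
    small_sim()))
  flipped <- extract_occupancy(reads, flip = TRUE)
  unflipped <- extract_occupancy(reads, flip = FALSE)
  mirror <- occupancy_track(unflipped$chrom, unflipped$pos,
                            ifelse(unflipped$strand == "+", "-", "+"),
                            unflipped$count)
  expect_true(tracks_identical(flipped, mirror))
  expect_equal(track_total(flipped), nrow(reads))
})

test_that("intermediate masking removes exon/intron 3' ends and polyA sites strand-specifically", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(100L, 1000L), end = c(200L, 1100L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  gm <- toy_gm(genes)
  ipos <- intermediate_positions(gm)
  expect_true(all(c(199L, 1000L) %in% ipos$pos))
  tr <- occupancy_track(rep("chr1", 4), c(199L, 199L, 1000L, 150L),
                        c("+", "-", "-", "+"), c(5L, 2L, 3L, 1L))
  out <- mask_intermediates(tr, gm)
  ## + gene masks 199 on + only; - gene masks 1000 on - only
  expect_equal(track_total(out$track), 2L + 1L)
  expect_true(all(out$mask$class == "intermediate"))
  kept <- paste(out$track$pos, out$track$strand)
  expect_setequal(kept, c("199 -", "150 +"))
})

test_that("region masking deletes masked positions and conserves the remainder", {
  tr <- occupancy_track(rep("chr1", 5), c(10L, 20L, 30L, 40L, 50L),
                        rep("+", 5), 1:5)
  whole <- data.frame(chrom = "chr1", start = 0L, end = 100L, strand = "*")
  expect_equal(nrow(mask_regions(tr, whole)), 0L)
  m1 <- data.frame(chrom = "chr1", start = 9L, end = 11L, strand = "*")
  m2 <- data.frame(chrom = "chr1", start = 39L, end = 41L, strand = "*")
  a <- mask_regions(mask_regions(tr, m1), m2)
  b <- mask_regions(mask_regions(tr, m2), m1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(track_total(a), track_total(tr) - 1L - 4L)
})

test_that("species split partitions reads exhaustively by reference prefix", {
  r <- read_df(c("chr1", "spike_chr1", "chr2"), c(1L, 2L, 3L),
               c(31L, 32L, 33L), c("+", "+", "-"),
               rep("ACGTACGTAC", 3))
  sp <- split_species(r)
  expect_equal(nrow(sp$primary), 2L)
  expect_equal(nrow(sp$spike), 1L)
  all_spike <- split_species(r[r$chrom == "spike_chr1", ])
  expect_equal(nrow(all_spike$primary), 0L)
  empty <- split_species(r[0, ])
  expect_equal(nrow(empty$primary) + nrow(empty$spike), 0L)
  expect_error(split_species(r, known_chroms = "chr1"), "unknown reference")
})

test_that("the processing chain never increases counts and is the identity on clean input", {
  sim <- small_sim()
  occ <- fixture("small_occ", simulate_occupancy(small_sim()))
  reads <- fixture("small_reads", simulate_reads(occ$tracks[[1]], small_sim()))
  res <- process_reads(reads, genome = sim$genome, gm = sim$annotation,
                       masks = sim$masks)
  expect_true(all(diff(as.numeric(res$stats)) <= 0))
  ## artifact-free reads reproduce the source track exactly
  cfg0 <- small_cfg(mispriming_rate = 0, intermediate_rate = 0)
  sim0 <- fixture("clean_sim", simulate_genome(cfg0))
  occ0 <- fixture("clean_occ", simulate_occupancy(sim0, cfg0,
                                                  n_replicates = 1))
  reads0 <- simulate_reads(occ0$tracks[[1]], sim0, cfg0)
  expect_true(tracks_identical(extract_occupancy(reads0, flip = TRUE),
                               occ0$tracks[[1]]))
})
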