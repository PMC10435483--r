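test_that("region quantification sums the selected strands and conserves totals", {
  tr <- occupancy_track(rep("chr1", 4), c(10L, 20L, 30L, 40L),
                        c("+", "+", "-", "-"), c(1L, 2L, 4L, 8L))
  reg <- data.frame(region_id = "all", chrom = "chr1", start = 0L,
                    end = 100L, strand = "+")
  expect_equal(unname(quantify_regions(tr, reg, "both")), 15)
  expect_equal(unname(quantify_regions(tr, reg, "sense")), 3)
  expect_equal(unname(quantify_regions(tr, reg, "antisense")), 12)
  empty <- occupancy_track()
  expect_equal(unname(quantify_regions(empty, reg, "both")), 0)
  expect_error(quantify_regions(tr, reg, "both",
                                chrom_lengths = c(chr1 = 50L)),
               "outside")
  ## split regions sharing an id are summed
  reg2 <- data.frame(region_id = c("r", "r"), chrom = "chr1",
                     start = c(0L, 25L), end = c(15L, 45L),
                     strand = c("+", "+"))
  expect_equal(unname(quantify_regions(tr, reg2, "both")), 1 + 4 + 8)
})

test_that("normalization closures hold: RPM identity, TPM of one region, scale invariance", {
  m <- matrix(c(10, 20, 30, 40), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  one <- matrix(c(123, 7), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_true(all(normalize_counts(one, "TPM", lengths = 2500) == 1e6))
  id <- matrix(c(2e5, 8e5), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(normalize_counts(id, "RPM"), id)
  expect_equal(normalize_counts(m, "RPM"), normalize_counts(2 * m, "RPM"))
  expect_equal(normalize_counts(m, "TPM", lengths = c(500, 1500)),
               normalize_counts(3 * m, "TPM", lengths = c(500, 1500)))
  expect_equal(normalize_counts(m, "RLE", size_factors = c(1, 2))[, 2],
               m[, 2] / 2)
  expect_error(normalize_counts(m * 0, "RPM"), "zero")
})

test_that("spike-in size factors follow the median-of-ratios closed form", {
  sp <- matrix(rep(c(50, 80, 120, 200), 2), 4, 2,
               dimnames = list(paste0("s", 1:4), c("A", "B")))
  f <- spikein_size_factors(sp, rep(TRUE, 4))
  expect_equal(unname(f), c(1, 1))
  sp2 <- sp; sp2[, "B"] <- 2 * sp2[, "A"]
  f2 <- spikein_size_factors(sp2, rep(TRUE, 4))
  expect_equal(unname(f2["B"] / f2["A"]), 2)
  ## scale equivariance: scaling one sample's spike counts scales its factor
  sp3 <- sp2; sp3[, "A"] <- sp3[, "A"] * 3
  f3 <- spikein_size_factors(sp3, rep(TRUE, 4))
  expect_equal(unname(f3["A"] / f2["A"] / (f3["B"] / f2["B"])), 3,
               tolerance = 1e-12)
  ## zero-containing spike rows are dropped; all-zero is an error
  sp4 <- sp2; sp4[1, 1] <- 0
  expect_equal(unname(spikein_size_factors(sp4, rep(TRUE, 4))["B"] /
                        spikein_size_factors(sp4, rep(TRUE, 4))["A"]), 2)
  expect_error(spikein_size_factors(sp * 0, rep(TRUE, 4)), "spike")
})

test_that("regions under six total raw reads are excluded from testing", {
  cm <- rbind(low = c(1, 1, 1, 1, 1, 0),   # 5 reads: excluded
              six = c(1, 1, 1, 1, 1, 1),   # 6 reads: tested
              big = c(50, 60, 55, 20, 25, 22))
  colnames(cm) <- paste0("s", 1:6)
  design <- setNames(rep(c("control", "treated"), each = 3),
                     colnames(cm))
  res <- test_differential(cm, design)
  expect_setequal(res$region_id, c("six", "big"))
  expect_false("low" %in% res$region_id)
  expect_true(all(res$padj >= 0 & res$padj <= 1))
  expect_identical(res$significant, res$padj < 0.05)
})

test_that("identical conditions give zero fold change and honest p-values", {
  cm <- matrix(rep(c(40, 80, 120), each = 6), 3, 6, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  design <- setNames(rep(c("control", "treated"), each = 3),
                     colnames(cm))
  res <- test_differential(cm, design)
  expect_true(all(res$log2fc == 0))
  expect_false(any(res$significant))
  ## single replicate per side: Poisson fallback with a warning
  expect_warning(test_differential(cm[, c(1, 4)],
                                   setNames(c("control", "treated"),
                                            colnames(cm)[c(1, 4)])),
                 "Poisson")
  expect_error(test_differential(cm, setNames(rep("control", 6),
                                              colnames(cm))),
               "both conditions")
})

test_that("the null NB simulation is calibrated and planted changes are detected", {
  s <- simulate_count_matrix(2000, 3, 3, dispersion = 0.05, fc = 1,
                             seed = 101)
  r <- test_differential(s$counts, s$design)
  t1 <- mean(r$pvalue < 0.05)
  expect_gt(t1, 0.02); expect_lt(t1, 0.09)
  s2 <- simulate_count_matrix(300, 3, 3, mu_range = c(200, 2000),
                              dispersion = 0.05, fc = 4, seed = 102)
  r2 <- test_differential(s2$counts, s2$design)
  expect_gt(mean(r2$significant & r2$log2fc > 0), 0.9)
  expect_equal(median(r2$log2fc), 2, tolerance = 0.1)
})

test_that("pausing cells pair fold changes and map zeros to unchanged", {
  prox <- data.frame(region_id = c("g1", "g2", "g3"),
                     log2fc = c(0.5, 0, -1))
  dist <- data.frame(region_id = c("g1", "g2", "g3"),
                     log2fc = c(-1.2, 0, 2))
  pm <- pausing_matrix(prox, dist)
  expect_equal(pm$quadrant[pm$region_id == "g1"], "up/down")
  expect_true(is.na(pm$quadrant[pm$region_id == "g2"]))
  expect_match(pm$note[pm$region_id == "g2"], "unchanged")
  expect_equal(pm$quadrant[pm$region_id == "g3"], "down/up")
  expect_error(pausing_matrix(prox, dist[1:2, ]), "same region ids")
})

test_that("signal stratification splits into near-equal ranked groups deterministically", {
  q <- stratify_by_signal(sprintf("r%03d", 1:100), 1:100, k = 4)
  expect_equal(unname(table(q)), rep(25L, 4), ignore_attr = TRUE)
  expect_true(all(q[76:100] == "Q4"))
  q8 <- stratify_by_signal(paste0("r", 1:8), c(5, 1, 9, 2, 8, 3, 7, 4),
                           k = 4)
  expect_equal(as.vector(table(q8)), rep(2L, 4))
  ## ties break by id order, so the split is reproducible
  tied <- stratify_by_signal(paste0("r", 1:6), rep(1, 6), k = 3)
  expect_identical(tied, stratify_by_signal(paste0("r", 1:6), rep(1, 6),
                                            k = 3))
  expect_equal(as.vector(table(tied)), rep(2L, 3))
  expect_error(stratify_by_signal("a", 1, k = 4), "more groups")
})
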