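# host gene on + strand: [10000, 18000), TSS 10000, polyA 17999
host_gm <- function(extra_genes = NULL, extra_iso = NULL, active = NULL) {
  genes <- data.frame(gene_id = "host", chrom = "c", start = 10000L,
                      end = 18000L, strand = "+", stringsAsFactors = FALSE)
  if (!is.null(extra_genes)) genes <- rbind(genes, extra_genes)
  gm <- toy_gm(genes, active = active)
  if (!is.null(extra_iso)) {
    gm0 <- gene_models(genes = {
      g <- genes
      g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
      g$polya <- ifelse(g$strand == "+", g$end - 1L, g$start)
      g
    }, isoforms = extra_iso, exons = data.frame(
      gene_id = extra_iso$gene_id, isoform_id = extra_iso$isoform_id,
      chrom = extra_iso$chrom, strand = extra_iso$strand,
      start = pmin(extra_iso$tss, extra_iso$polya),
      end = pmax(extra_iso$tss, extra_iso$polya) + 1L))
    gm0$genes$active <- if (is.null(active)) TRUE else active
    gm <- refine_active_isoforms(gm0)
  }
  gm
}

test_that("antisense candidacy requires an overlapping (or upstream-window) active gene", {
  gm <- host_gm()
  inside <- tu_row("c", 12000L, 12400L, "-")      # inside host, opposite
  sense <- tu_row("c", 12000L, 12400L, "+")       # same strand: no
  nowhere <- tu_row("c", 40000L, 40400L, "-")     # overlaps nothing
  atus <- find_antisense_units(rbind(inside, sense, nowhere), gm)
  expect_equal(atus$tu_id, inside$tu_id)
  expect_equal(atus$host_gene, "host")
  ## an inactive gene hosts nothing
  gm_off <- host_gm(active = FALSE)
  expect_equal(nrow(find_antisense_units(inside, gm_off)), 0L)
})

test_that("the DAT window is strict at 1000 bp and CATs lie inside the host span", {
  gm <- host_gm()
  at999 <- tu_row("c", 8702L, 9002L, "-")    # origin 9001 = TSS - 999
  at1000 <- tu_row("c", 8701L, 9001L, "-")   # origin 9000 = TSS - 1000
  mid <- tu_row("c", 13000L, 13400L, "-")    # origin 13399, mid-gene
  out <- classify_antisense(rbind(at999, at1000, mid), gm)
  got <- setNames(out$cls, out$tu_id)
  expect_equal(unname(got[at999$tu_id]), "DAT")
  expect_equal(unname(got[mid$tu_id]), "CAT")
  ## exactly 1000 bp upstream is not a DAT and cannot be a CAT either
  if (at1000$tu_id %in% names(got)) {
    expect_equal(unname(got[at1000$tu_id]), "discarded")
    expect_equal(out$discard_reason[out$tu_id == at1000$tu_id],
                 "alt_promoter")
  }
})

test_that("CAT-looking units upstream of a downstream alternative TSS become DATs", {
  iso <- data.frame(gene_id = "host", isoform_id = c("host.1", "host.2"),
                    chrom = "c", strand = "+",
                    tss = c(10000L, 14000L), polya = c(17999L, 17999L),
                    tpm = c(60, 40), stringsAsFactors = FALSE)
  gm <- host_gm(extra_iso = iso)
  ## origin 400 bp upstream of the active alternative TSS, mid-gene
  tu <- tu_row("c", 13300L, 13601L, "-")  # origin 13600 = 14000 - 400
  out <- classify_antisense(tu, gm)
  expect_equal(out$cls, "DAT")
  ## same geometry but the second isoform below the 10% share stays a CAT
  iso$tpm <- c(95, 4)
  gm2 <- host_gm(extra_iso = iso)
  out2 <- classify_antisense(tu, gm2)
  expect_equal(out2$cls, "CAT")
})

test_that("overlap with same-strand genes discards at 50% of the unit or 90% of the gene", {
  ## gene B on the unit's strand, overlapping the host tail
  mkB <- function(b_start, b_end)
    data.frame(gene_id = "geneB", chrom = "c", start = b_start,
               end = b_end, strand = "-", stringsAsFactors = FALSE)
  ## unit of length 600 with exactly 300 (50%) inside geneB
  gm1 <- host_gm(mkB(17000L, 19000L), active = c(TRUE, FALSE))
  tu50 <- tu_row("c", 16700L, 17300L, "-")
  out1 <- classify_antisense(tu50, gm1)
  expect_equal(out1$discard_reason, "overlapping_gene")
  ## 299/600 (49.8%) and geneB large: kept
  tu49 <- tu_row("c", 16699L, 17299L, "-")
  out2 <- classify_antisense(tu49, gm1)
  expect_equal(out2$discard_reason, "none")
  expect_equal(out2$cls, "CAT")
  ## 90% of a short same-strand gene discards even when <50% of the unit
  gm3 <- host_gm(mkB(17000L, 17300L), active = c(TRUE, FALSE))
  tu90 <- tu_row("c", 16400L, 17270L, "-")   # covers 270/300 = 90% of B
  expect_equal(classify_antisense(tu90, gm3)$discard_reason,
               "overlapping_gene")
  tu89 <- tu_row("c", 16400L, 17269L, "-")   # 269/300 just under
  expect_equal(classify_antisense(tu89, gm3)$discard_reason, "none")
})

test_that("units covering the whole host span are discarded", {
  genes <- data.frame(gene_id = "short", chrom = "c", start = 30000L,
                      end = 30400L, strand = "+", stringsAsFactors = FALSE)
  gm <- toy_gm(genes)
  tu <- tu_row("c", 29900L, 30500L, "-")
  out <- classify_antisense(tu, gm)
  expect_equal(out$discard_reason, "covers_antisense_gene")
})

test_that("intragenic enhancer calls require both histone marks", {
  gm <- host_gm()
  cat_tu <- tu_row("c", 13000L, 13400L, "-")
  atus <- classify_antisense(cat_tu, gm)
  pk <- both_marks("c", 13399L)
  out <- call_intragenic_enhancers(atus, pk)
  expect_equal(nrow(out), 1L)
  expect_equal(out$center, 13399L)
  expect_equal(out$kind, "intragenic")
  expect_equal(out$host_gene, "host")
  ## one mark only: no call
  pk_half <- pk; pk_half$H3K4me1 <- pk_half$H3K4me1[0, ]
  expect_equal(nrow(call_intragenic_enhancers(atus, pk_half)), 0L)
  expect_error(call_intragenic_enhancers(atus, list(H3K27ac = pk$H3K27ac)),
               "H3K4me1")
})

test_that("bidirectional pairing is strict at 500 bp origin distance", {
  gm <- host_gm()  # active gene far away at [10000, 18000)
  minus <- tu_row("c", 39701L, 40001L, "-")        # origin 40000
  plus499 <- tu_row("c", 40499L, 40799L, "+")      # origin 40499
  plus500 <- tu_row("c", 40500L, 40800L, "+")      # origin 40500
  pk <- both_marks("c", 40250L, hw27 = 700L, hw4 = 900L)
  bid <- call_extragenic_enhancers(rbind(minus, plus499), gm, pk)
  expect_equal(nrow(bid), 1L)
  expect_equal(bid$directionality, "bidirectional")
  expect_equal(bid$center, floor((40000 + 40499) / 2))
  uni <- call_extragenic_enhancers(rbind(minus, plus500), gm, pk)
  expect_equal(nrow(uni), 2L)
  expect_true(all(uni$directionality == "unidirectional"))
})

test_that("termination-zone and promoter exclusions remove otherwise eligible units", {
  gm <- host_gm()  # + gene, polyA 17999
  pkAll <- both_marks("c", 19999L, hw27 = 3000L, hw4 = 3200L)
  at1999 <- tu_row("c", 19998L, 20300L, "+")  # origin 19998 = polyA + 1999
  expect_equal(nrow(call_extragenic_enhancers(at1999, gm, pkAll)), 0L)
  at2000 <- tu_row("c", 19999L, 20301L, "+")  # origin polyA + 2000: eligible
  out <- call_extragenic_enhancers(at2000, gm, pkAll)
  expect_equal(nrow(out), 1L)
  ## promoter exclusion hits origins within 500 bp of any annotated TSS,
  ## even of an inactive gene
  genes2 <- data.frame(gene_id = "dead", chrom = "c", start = 40000L,
                       end = 44000L, strand = "+", stringsAsFactors = FALSE)
  gm2 <- host_gm(genes2, active = c(TRUE, FALSE))
  pk2 <- both_marks("c", 39500L, hw27 = 1500L, hw4 = 1700L)
  at500 <- tu_row("c", 39500L, 39800L, "+")   # origin 39500, |d| = 500
  expect_equal(nrow(call_extragenic_enhancers(at500, gm2, pk2)), 0L)
  at501 <- tu_row("c", 39499L, 39799L, "+")   # origin 39499, |d| = 501
  expect_equal(nrow(call_extragenic_enhancers(at501, gm2, pk2)), 1L)
})

test_that("every candidate ends in exactly one class and calls always carry both marks", {
  for (seed in 1:10) {
    toy <- random_toy_genome(seed + 500)
    atus <- classify_antisense(toy$tus, toy$gm)
    expect_true(all(atus$cls %in% c("CAT", "DAT", "discarded")))
    expect_true(all(atus$discard_reason[atus$cls == "discarded"] %in%
                      c("overlapping_gene", "covers_antisense_gene",
                        "alt_promoter")))
    expect_true(all(atus$discard_reason[atus$cls != "discarded"] == "none"))
    calls <- rbind(call_intragenic_enhancers(atus, toy$peaks),
                   call_extragenic_enhancers(toy$tus, toy$gm, toy$peaks))
    for (i in seq_len(nrow(calls)))
      expect_true(.has_both_marks(calls$chrom[i], calls$start[i],
                                  calls$end[i], toy$peaks))
  }
})

test_that("classification agrees with the brute-force oracle on random toy genomes", {
  for (seed in 1:15) {
    toy <- random_toy_genome(seed)
    atus <- classify_antisense(toy$tus, toy$gm)
    want <- oracle_classify(toy$tus, toy$gm)
    cand <- want[!is.na(want$host), ]
    expect_setequal(atus$tu_id, cand$tu_id)
    m <- merge(atus[, c("tu_id", "host_gene", "cls", "discard_reason")],
               cand, by = "tu_id", suffixes = c("_got", "_want"))
    expect_equal(m$host_gene, m$host)
    expect_equal(m$cls_got, m$cls_want)
    expect_equal(m$discard_reason[m$cls_got == "discarded"],
                 m$reason[m$cls_got == "discarded"])
    got_ex <- call_extragenic_enhancers(toy$tus, toy$gm, toy$peaks)
    want_ex <- oracle_extragenic(toy$tus, toy$gm, toy$peaks)
    expect_equal(nrow(got_ex), nrow(want_ex))
    if (nrow(got_ex)) {
      got_sort <- got_ex[order(got_ex$center), ]
      expect_equal(got_sort$center, want_ex$center)
      expect_equal(got_sort$directionality, want_ex$directionality)
      expect_equal(got_sort$tu_ids, want_ex$members)
    }
  }
})
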