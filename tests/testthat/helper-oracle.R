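# Independent brute-force oracles: plain all-pairs loops re-deriving the
# antisense / enhancer classification rules and the transcription-unit
# runs, kept free of any code shared with the package implementation.

.ov_len <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

.first_tss <- function(g) {
  tss <- g$active_tss[[1]]
  if (g$strand == "+") min(tss) else max(tss)
}

# per-TU classification: list(host, cls, reason) per row of tus
oracle_classify <- function(tus, gm, dat_window = 1000, frac_tu = 0.5,
                            frac_gene = 0.9) {
  genes <- gm$genes
  out <- data.frame(tu_id = tus$tu_id, host = NA_character_,
                    cls = NA_character_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tus))) {
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (!isTRUE(g$active)) next
      if (g$chrom != tus$chrom[i] || g$strand == tus$strand[i]) next
      es <- if (g$strand == "+") g$eff_start - dat_window else g$eff_start
      ee <- if (g$strand == "+") g$eff_end else g$eff_end + dat_window
      ov <- .ov_len(tus$start[i], tus$end[i], es, ee)
      if (ov <= 0) next
      d <- abs(tus$origin[i] - .first_tss(g))
      cand <- list(gid = g$gene_id, ov = ov, d = d)
      if (is.null(best) || cand$ov > best$ov ||
          (cand$ov == best$ov && cand$d < best$d) ||
          (cand$ov == best$ov && cand$d == best$d && cand$gid < best$gid))
        best <- cand
    }
    if (is.null(best)) next
    out$host[i] <- best$gid
    reason <- "none"
    tu_len <- tus$end[i] - tus$start[i]
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (g$chrom != tus$chrom[i] || g$strand != tus$strand[i]) next
      ov <- .ov_len(tus$start[i], tus$end[i], g$start, g$end)
      if (ov <= 0) next
      if (ov / tu_len >= frac_tu || ov / (g$end - g$start) >= frac_gene)
        reason <- "overlapping_gene"
    }
    h <- genes[genes$gene_id == best$gid, ]
    hs <- if (!is.na(h$eff_start)) h$eff_start else h$start
    he <- if (!is.na(h$eff_end)) h$eff_end else h$end
    if (reason == "none" && tus$start[i] <= hs && tus$end[i] >= he)
      reason <- "covers_antisense_gene"
    if (reason != "none") {
      out$cls[i] <- "discarded"; out$reason[i] <- reason
      next
    }
    out$reason[i] <- "none"
    dirp <- if (h$strand == "+") 1L else -1L
    o <- tus$origin[i]
    is_dat <- FALSE
    for (t0 in h$active_tss[[1]]) {
      up <- (t0 - o) * dirp
      if (up > 0 && up < dat_window) is_dat <- TRUE
    }
    if (is_dat) {
      out$cls[i] <- "DAT"
    } else {
      ft <- .first_tss(h)
      if ((o - ft) * dirp > 0 && o >= hs && o < he) {
        out$cls[i] <- "CAT"
      } else {
        out$cls[i] <- "discarded"; out$reason[i] <- "alt_promoter"
      }
    }
  }
  out
}

.has_both_marks <- function(chrom, s, e, peaks) {
  for (mark in c("H3K27ac", "H3K4me1")) {
    p <- peaks[[mark]]
    hit <- FALSE
    for (j in seq_len(nrow(p))) {
      if (p$chrom[j] == chrom && .ov_len(s, e, p$start[j], p$end[j]) > 0)
        hit <- TRUE
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# extragenic enhancer calls: data.frame(center, directionality, members)
oracle_extragenic <- function(tus, gm, peaks, prom_hw = 500,
                              term_len = 2000, pair_maxdist = 500) {
  genes <- gm$genes
  ok <- rep(TRUE, nrow(tus))
  for (i in seq_len(nrow(tus))) {
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (!isTRUE(g$active) || g$chrom != tus$chrom[i]) next
      if (.ov_len(tus$start[i], tus$end[i], g$eff_start, g$eff_end) > 0)
        ok[i] <- FALSE
      dirp <- if (g$strand == "+") 1L else -1L
      for (pa in g$active_polya[[1]]) {
        d <- (tus$origin[i] - pa) * dirp
        if (d >= 0 && d < term_len) ok[i] <- FALSE
      }
    }
    for (j in seq_len(nrow(gm$isoforms))) {
      if (gm$isoforms$chrom[j] == tus$chrom[i] &&
          abs(tus$origin[i] - gm$isoforms$tss[j]) <= prom_hw)
        ok[i] <- FALSE
    }
  }
  el <- tus[ok, , drop = FALSE]
  n <- nrow(el)
  cand <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || el$chrom[i] != el$chrom[j] ||
          el$strand[i] == el$strand[j]) next
      d <- abs(el$origin[i] - el$origin[j])
      if (d < pair_maxdist)
        cand <- rbind(cand, c(i, j, d, min(el$origin[i], el$origin[j])))
    }
  }
  used <- rep(FALSE, n)
  calls <- list()
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 3], cand[, 4], cand[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      s <- min(el$start[i], el$start[j]); e <- max(el$end[i], el$end[j])
      if (!.has_both_marks(el$chrom[i], s, e, peaks)) next
      calls[[length(calls) + 1L]] <- data.frame(
        center = floor((el$origin[i] + el$origin[j]) / 2),
        directionality = "bidirectional",
        members = paste(sort(c(el$tu_id[i], el$tu_id[j])), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  for (i in which(!used)) {
    if (!.has_both_marks(el$chrom[i], el$start[i], el$end[i], peaks)) next
    calls[[length(calls) + 1L]] <- data.frame(
      center = el$origin[i], directionality = "unidirectional",
      members = el$tu_id[i], stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(center = integer(), directionality = character(),
                      members = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out[order(out$center), , drop = FALSE]
}

# brute-force transcription-unit caller: expands to a coverage vector and
# scans it positionally
oracle_tus <- function(track, max_gap = 250, min_count = 10,
                       min_body = 150) {
  res <- list()
  for (ch in unique(track$chrom)) {
    for (st in c("+", "-")) {
      sub <- track[track$chrom == ch & track$strand == st, , drop = FALSE]
      if (!nrow(sub)) next
      cov <- integer(max(sub$pos) + 1L)
      cov[sub$pos + 1L] <- sub$count
      run_start <- NA; last_cov <- NA
      flush <- function(s, e) {
        tot <- sum(cov[(s:e) + 1L])
        if ((e - s + 1L) >= min_body && tot >= min_count)
          res[[length(res) + 1L]] <<- data.frame(
            chrom = ch, strand = st, start = s, end = e + 1L,
            origin = if (st == "+") s else e, total_count = tot,
            stringsAsFactors = FALSE)
      }
      for (p in sort(sub$pos)) {
        if (is.na(run_start)) {
          run_start <- p
        } else if (p - last_cov > max_gap) {
          flush(run_start, last_cov)
          run_start <- p
        }
        last_cov <- p
      }
      if (!is.na(run_start)) flush(run_start, last_cov)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), origin = integer(),
                      total_count = integer()))
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Random toy genome (single <= 50 kb chromosome) stuffed with boundary
# cases of every classification rule: DAT window 999/1000, bidirectional
# distance 499/500, same-strand overlap 50%/49.8% of the unit and 90% of
# the gene, termination-zone offsets 0/1999/2000, promoter offsets
# 500/501.  Returns tus, gm, peaks.
random_toy_genome <- function(seed) {
  set.seed(seed)
  ch <- "t"
  slots <- c(4000, 18000, 32000) + round(runif(3, -500, 500))
  n_genes <- sample(2:3, 1)
  genes <- data.frame(gene_id = sprintf("tg%02d", seq_len(n_genes)),
                      chrom = ch, start = 0L, end = 0L,
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      stringsAsFactors = FALSE)
  glen <- round(runif(n_genes, 3000, 5000))
  genes$start <- as.integer(slots[seq_len(n_genes)])
  genes$end <- as.integer(genes$start + glen)
  active <- runif(n_genes) < 0.8
  if (!any(active)) active[1] <- TRUE

  iso <- NULL
  for (i in seq_len(n_genes)) {
    tss0 <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
    pa0 <- if (genes$strand[i] == "+") genes$end[i] - 1L else genes$start[i]
    iso <- rbind(iso, data.frame(
      gene_id = genes$gene_id[i],
      isoform_id = paste0(genes$gene_id[i], ".1"), chrom = ch,
      strand = genes$strand[i], tss = tss0, polya = pa0, tpm = 10,
      stringsAsFactors = FALSE))
    if (active[i] && runif(1) < 0.4) {
      dirp <- if (genes$strand[i] == "+") 1L else -1L
      off <- round(runif(1, 900, 1500))
      iso <- rbind(iso, data.frame(
        gene_id = genes$gene_id[i],
        isoform_id = paste0(genes$gene_id[i], ".2"), chrom = ch,
        strand = genes$strand[i], tss = as.integer(tss0 + dirp * off),
        polya = pa0, tpm = if (runif(1) < 0.7) 5 else 0.1,
        stringsAsFactors = FALSE))
    }
  }

  tus <- NULL; pk <- no_marks(); k <- 0L
  add_tu <- function(start, end, strand) {
    k <<- k + 1L
    tus <<- rbind(tus, tu_row(ch, start, end, strand,
                              id = sprintf("ttu%03d", k)))
  }
  give_marks <- function(center) {
    p <- runif(1)
    if (p < 0.6) {
      pk <<- merge_peaks(pk, both_marks(ch, center))
    } else if (p < 0.8) {
      pk$H3K27ac <<- rbind(pk$H3K27ac,
                           data.frame(chrom = ch, start = center - 600,
                                      end = center + 600))
    }
  }

  for (i in seq_len(n_genes)) {
    if (!active[i]) next
    g <- genes[i, ]
    dirp <- if (g$strand == "+") 1L else -1L
    tss0 <- if (g$strand == "+") g$start else g$end - 1L
    ## antisense units at boundary offsets around the TSS (oriented:
    ## negative = upstream)
    offs <- sample(c(-2000L, -1000L, -999L, -500L, -100L, 300L, 900L,
                     1800L), sample(2:3, 1))
    for (off in offs) {
      o <- tss0 + dirp * off
      len <- round(runif(1, 200, 400))
      if (g$strand == "+") add_tu(o - len + 1L, o + 1L, "-")
      else add_tu(o, o + len, "+")
      if (runif(1) < 0.5) give_marks(o)
    }
    ## termination-zone units
    pa0 <- if (g$strand == "+") g$end - 1L else g$start
    toff <- sample(c(0L, 1000L, 1999L, 2000L, 2600L), 1)
    o <- pa0 + dirp * toff
    len <- round(runif(1, 200, 350))
    st <- sample(c("+", "-"), 1)
    if (st == "+") add_tu(o, o + len, "+") else add_tu(o - len + 1L, o + 1L, "-")
    give_marks(o)
  }

  ## promoter-offset singles around a random annotated TSS
  j <- sample(nrow(iso), 1)
  poff <- sample(c(-501L, -500L, 500L, 501L, 700L), 1)
  o <- iso$tss[j] + poff
  add_tu(o, o + 250L, "+")
  give_marks(o)

  ## extragenic pairs at boundary origin distances, placed in the tail gap
  base <- max(genes$end) + 4000L
  for (d in sample(c(99L, 300L, 499L, 500L, 800L), 2)) {
    c0 <- base; base <- base + 2500L
    if (base > 49000L) break
    len1 <- round(runif(1, 200, 350)); len2 <- round(runif(1, 200, 350))
    add_tu(c0 - len1 + 1L, c0 + 1L, "-")       # origin c0
    add_tu(c0 + d, c0 + d + len2, "+")         # origin c0 + d
    give_marks(c0 + floor(d / 2))
  }

  ## same-strand overlapping-gene boundary construct
  if (runif(1) < 0.7) {
    hosts <- which(active & (genes$end - genes$start) >= 3500)
    if (length(hosts)) {
      i <- hosts[1]
      g <- genes[i, ]
      tstrand <- if (g$strand == "+") "-" else "+"
      b <- as.integer(g$end - 1000L)
      variant <- sample(1:3, 1)
      if (variant == 1) {        # exactly 50% of the unit inside gene B
        genes <- rbind(genes, data.frame(
          gene_id = "tgB", chrom = ch, start = b, end = b + 2000L,
          strand = tstrand, stringsAsFactors = FALSE))
        active <- c(active, FALSE)
        iso <- rbind(iso, data.frame(
          gene_id = "tgB", isoform_id = "tgB.1", chrom = ch,
          strand = tstrand,
          tss = if (tstrand == "+") b else b + 1999L,
          polya = if (tstrand == "+") b + 1999L else b, tpm = 0.1,
          stringsAsFactors = FALSE))
        add_tu(b - 300L, b + 300L, tstrand)
      } else if (variant == 2) { # just under 50%
        genes <- rbind(genes, data.frame(
          gene_id = "tgB", chrom = ch, start = b, end = b + 2000L,
          strand = tstrand, stringsAsFactors = FALSE))
        active <- c(active, FALSE)
        iso <- rbind(iso, data.frame(
          gene_id = "tgB", isoform_id = "tgB.1", chrom = ch,
          strand = tstrand,
          tss = if (tstrand == "+") b else b + 1999L,
          polya = if (tstrand == "+") b + 1999L else b, tpm = 0.1,
          stringsAsFactors = FALSE))
        add_tu(b - 301L, b + 299L, tstrand)
      } else {                   # 90% of a short same-strand gene
        genes <- rbind(genes, data.frame(
          gene_id = "tgB", chrom = ch, start = b, end = b + 300L,
          strand = tstrand, stringsAsFactors = FALSE))
        active <- c(active, FALSE)
        iso <- rbind(iso, data.frame(
          gene_id = "tgB", isoform_id = "tgB.1", chrom = ch,
          strand = tstrand,
          tss = if (tstrand == "+") b else b + 299L,
          polya = if (tstrand == "+") b + 299L else b, tpm = 0.1,
          stringsAsFactors = FALSE))
        if (runif(1) < 0.5) add_tu(b - 330L, b + 270L, tstrand)  # 270/600
        else add_tu(b - 331L, b + 269L, tstrand)                  # 269/600
      }
    }
  }

  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$polya <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  exons <- data.frame(gene_id = iso$gene_id, isoform_id = iso$isoform_id,
                      chrom = iso$chrom, strand = iso$strand,
                      start = pmin(iso$tss, iso$polya),
                      end = pmax(iso$tss, iso$polya) + 1L,
                      stringsAsFactors = FALSE)
  gm <- gene_models(genes, iso, exons)
  gm$genes$active <- active
  gm <- refine_active_isoforms(gm)
  list(tus = tus, gm = gm, peaks = pk)
}
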