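mkgenes <- function(...) tibble::tibble(...)

test_that("de-redundanting keeps the longest locus per symbol", {
  g <- mkgenes(chrom = "c", start = c(0, 100, 5000), end = c(5000, 7100, 6000),
               strand = "+", symbol = c("X", "X", "Y"),
               tss = list(0, 100, 5000))
  out <- deredundant_loci(g)
  expect_equal(nrow(out), 2)
  expect_equal(out$end[out$symbol == "X"], 7100)
  # all unique -> unchanged
  expect_equal(deredundant_loci(g[2:3, ]), g[2:3, ])
  # equal lengths -> smaller start kept
  g2 <- mkgenes(chrom = "c", start = c(100, 0), end = c(600, 500),
                strand = "+", symbol = "Z", tss = list(100, 0))
  expect_equal(deredundant_loci(g2)$start, 0)
})

test_that("enhancer calling is the per-base AND of the two marks", {
  me1 <- genomic_intervals("c", 100, 500)
  ac <- genomic_intervals("c", 400, 800)
  enh <- call_active_enhancers(me1, ac)
  expect_equal(c(enh$start, enh$end), c(400, 500))
  # disjoint sets -> no enhancers
  expect_equal(nrow(call_active_enhancers(genomic_intervals("c", 0, 100),
                                          genomic_intervals("c", 200, 300))), 0)
  withr::with_seed(37, {
    for (i in 1:100) {
      me1 <- rand_intervals(sample(1:12, 1))
      ac <- rand_intervals(sample(1:12, 1))
      got <- call_active_enhancers(me1, ac)
      want <- oracle_enhancers(me1, ac)
      expect_equal(got[, c("start", "end")],
                   tibble::as_tibble(want), ignore_attr = TRUE)
    }
  })
})

test_that("active-TSS calling follows the peak-count-then-signal-then-5' rule", {
  g <- mkgenes(chrom = "c", start = 0, end = 10000, strand = "+", symbol = "X",
               tss = list(c(0, 5000)))
  pk <- function(s, e, sig) {
    tibble::tibble(chrom = "c", start = s, end = e, name = NA, score = 0,
                   strand = "*", signal = sig, pvalue = -1, qvalue = -1,
                   summit_offset = NA)
  }
  # peaks over the second TSS only
  out <- call_active_tss(g, pk(4500, 5500, 3))
  expect_equal(out$position, 5000)
  expect_equal(out$n_supporting_peaks, 1L)
  # no peaks -> empty
  expect_equal(nrow(call_active_tss(g, pk(4500, 5500, 3)[0, ])), 0)
  # equal counts, signals 10 vs 5 -> signal-10 TSS wins
  peaks <- dplyr::bind_rows(pk(0, 100, 5), pk(4900, 5100, 10))
  out2 <- call_active_tss(g, peaks)
  expect_equal(out2$position, 5000)
  # minus-strand 5'-most tie-break: equal count and signal
  gm <- mkgenes(chrom = "c", start = 0, end = 10000, strand = "-", symbol = "M",
                tss = list(c(1000, 9000)))
  peaks3 <- dplyr::bind_rows(pk(900, 1100, 2), pk(8900, 9100, 2))
  expect_equal(call_active_tss(gm, peaks3)$position, 9000)
})

test_that("element counting in bin-pairs uses midpoints for intervals", {
  pairs <- tibble::tibble(chrom = "c", start_i = 0, start_j = 40000,
                          frequency = 1, bin_size = 40000)
  # midpoint inside bin i
  e1 <- genomic_intervals("c", 1000, 2000)
  expect_equal(count_in_binpair(e1, pairs), 1L)
  # straddles the region edge, midpoint outside
  e2 <- genomic_intervals("c", 79500, 81500)
  expect_equal(count_in_binpair(e2, pairs), 0L)
  # point elements count when inside either bin
  pts <- tibble::tibble(chrom = "c", pos = c(100, 50000, 90000))
  expect_equal(count_in_binpair(pts, pairs), 2L)
  withr::with_seed(41, {
    e <- rand_intervals(500, chrom = "c", max_pos = 200000, max_len = 3000)
    mids <- floor((e$start + e$end) / 2)
    want <- sum(mids >= 0 & mids < 40000) + sum(mids >= 40000 & mids < 80000)
    expect_equal(count_in_binpair(e, pairs), want)
  })
})

test_that("coverage grouping makes equal-count groups with monotone means", {
  bins <- tibble::tibble(chrom = "c", start = seq(0, 9) * 40000,
                         bin_size = 40000)
  alu <- genomic_intervals("c", c(0, 40000, 80000), c(30000, 50000, 84000))
  grp <- group_bins_by_coverage(bins, alu, k = 5)
  expect_equal(unname(table(grp$bins$group)), rep(2L, 5), ignore_attr = TRUE)
  expect_true(all(diff(grp$group_means$mean_coverage) >= 0))
  # all equal coverage -> groups by genomic order
  grp2 <- group_bins_by_coverage(bins, alu[0, ], k = 5)
  expect_equal(grp2$bins$group, rep(1:5, each = 2))
  expect_error(group_bins_by_coverage(bins[1:3, ], alu, k = 5), "fewer bins")
  withr::with_seed(43, {
    bins50 <- tibble::tibble(chrom = "c", start = seq(0, 49) * 40000,
                             bin_size = 40000)
    alu50 <- rand_intervals(300, chrom = "c", max_pos = 2e6, max_len = 400)
    g <- group_bins_by_coverage(bins50, alu50, k = 5)
    expect_true(all(diff(g$group_means$mean_coverage) >= 0))
    # group of the max-coverage bin is k, of the min is 1
    expect_equal(g$bins$group[which.max(g$bins$coverage)], 5L)
    expect_equal(g$bins$group[which.min(g$bins$coverage)], 1L)
  })
})

test_that("group correlation agrees with the shared Pearson machinery", {
  bins <- tibble::tibble(chrom = "c", start = seq(0, 19) * 40000,
                         bin_size = 40000)
  withr::with_seed(47, {
    alu <- rand_intervals(150, chrom = "c", max_pos = 800000, max_len = 350)
    elements <- rand_intervals(100, chrom = "c", max_pos = 800000, max_len = 500)
    grp <- group_bins_by_coverage(bins, alu, k = 5)
    cr <- element_coverage_correlation(grp, elements)
    # same (x, y) through correlate_bins
    bs <- 40000
    mids <- floor((elements$start + elements$end) / 2)
    key <- paste(elements$chrom, floor(mids / bs) * bs)
    tab <- table(key)
    hit <- match(paste(grp$bins$chrom, grp$bins$start), names(tab))
    grp$bins$ne <- ifelse(is.na(hit), 0, as.numeric(tab[hit]))
    pts <- dplyr::summarise(dplyr::group_by(grp$bins, group),
                            x = mean(coverage), y = mean(ne))
    fake <- tibble::tibble(index = 1:5, left = 0, right = 1, n_pairs = 1,
                           mean_frequency = pts$x, mean_metric = pts$y)
    cr2 <- correlate_bins(fake)
    expect_equal(cr$r, cr2$r, tolerance = 1e-12)
    expect_equal(cr$p, cr2$p, tolerance = 1e-12)
  })
  # counts exactly linear in coverage -> r = 1: bins in group g have
  # coverage g/10 and carry g point elements each
  alu_lin <- dplyr::bind_rows(lapply(1:10, function(i) {
    g <- ceiling(i / 2)
    genomic_intervals("c", (i - 1) * 40000, (i - 1) * 40000 + g * 4000)
  }))
  bins10 <- tibble::tibble(chrom = "c", start = (0:9) * 40000, bin_size = 40000)
  grp <- group_bins_by_coverage(bins10, alu_lin, k = 5)
  pts <- dplyr::bind_rows(lapply(seq_len(nrow(grp$bins)), function(i) {
    g <- grp$bins$group[i]
    tibble::tibble(chrom = "c", pos = rep(grp$bins$start[i] + 5, g))
  }))
  cr <- element_coverage_correlation(grp, pts)
  expect_equal(cr$r, 1, tolerance = 1e-9)
})

test_that("enhancer origin uses summit-else-midpoint inside Alu", {
  alu <- genomic_intervals("c", 1000, 1300)
  enh <- tibble::tibble(chrom = "c", start = c(900, 2000, 1100), end = c(1400, 2400, 1250),
                        summit_offset = c(200, NA, NA))
  out <- classify_enhancer_origin(enh, alu)
  expect_equal(out$origin, c("Alu_derived", "non_Alu", "Alu_derived"))
})

test_that("flank windows are clipped to the chromosome", {
  alu <- genomic_intervals("c", 0, 10000)
  el <- tibble::tibble(chrom = "c", start = 4000, end = 6000,
                       summit_offset = 1000)
  out <- flank_coverage(el, alu, c(c = 25000), flank = 20000)
  expect_equal(c(out$window_start, out$window_end), c(0, 25000))
  expect_equal(out$alu_coverage, 10000 / 25000)
  # element far from both ends: full 40-kb window
  el2 <- tibble::tibble(chrom = "c", start = 99000, end = 101000,
                        summit_offset = 1000)
  out2 <- flank_coverage(el2, alu, c(c = 1e6), flank = 20000)
  expect_equal(out2$window_end - out2$window_start, 40000)
  expect_equal(c(out2$window_start, out2$window_end), c(80000, 120000))
})

test_that("background windows are seeded, in bounds and converge to genome Alu fraction", {
  b <- sim_bundle(small_config(seed = 61), sequence = FALSE)
  alu <- b$repeats[b$repeats$family == "Alu", ]
  lens <- b$chrom_lengths
  w1 <- background_coverage(lens, alu, n_windows = 500, seed = 7)
  w2 <- background_coverage(lens, alu, n_windows = 500, seed = 7)
  expect_identical(w1, w2)
  expect_true(all(w1$start >= 0))
  expect_true(all(w1$end <= lens[w1$chrom]))
  # sampling-theory bound on the mean
  w <- background_coverage(lens, alu, n_windows = 4000, seed = 11)
  genome_frac <- sum(merge_intervals(alu[alu$chrom == "chr1", ])$end -
                       merge_intervals(alu[alu$chrom == "chr1", ])$start) /
    lens[["chr1"]]
  se <- sd(w$coverage) / sqrt(nrow(w))
  expect_lt(abs(mean(w$coverage) - genome_frac), 4 * se + 1e-3)
  expect_error(background_coverage(c(a = 1000), alu, width = 40000),
               "exceeds")
})

test_that("the binomial enrichment tail has its closed form", {
  withr::with_seed(53, {
    background <- runif(2000)
    # all 20 observed windows above the background mean, p0 ~ 0.5
    obs <- runif(20, mean(background) + 0.01, 1)
    res <- coverage_enrichment_test(obs, background, n_perm = 200)
    p0 <- mean(background > mean(background))
    expect_equal(res$p_value, p0^20, tolerance = 1e-12)
    expect_equal(res$p_value, 9.5e-7, tolerance = 0.5)
    expect_equal(res$k_above_background, 20)
    expect_error(coverage_enrichment_test(numeric(), background), "no observed")
    expect_error(coverage_enrichment_test(obs, rep(0.5, 100)), "degenerate")
  })
})

test_that("peak matching is symmetric and follows the strict 250-bp rule", {
  pk <- function(pos) {
    tibble::tibble(chrom = "c", start = pos - 50, end = pos + 50,
                   summit_offset = 50)
  }
  a <- dplyr::bind_rows(lapply(c(1000, 5000, 9000), pk))
  res <- match_peak_sets(a, a)
  expect_equal(res$shared, 3L)
  expect_equal(c(res$frac_a, res$frac_b), c(1, 1))
  # two peaks 260 bp apart are NOT the same element
  res2 <- match_peak_sets(pk(1000), pk(1260))
  expect_equal(res2$shared, 0L)
  res3 <- match_peak_sets(pk(1000), pk(1249))
  expect_equal(res3$shared, 1L)
  withr::with_seed(59, {
    for (i in 1:50) {
      pa <- sort(sample(0:20000, sample(2:15, 1)))
      pb <- sort(sample(0:20000, sample(2:15, 1)))
      A <- dplyr::bind_rows(lapply(pa, pk)); B <- dplyr::bind_rows(lapply(pb, pk))
      got <- match_peak_sets(A, B)
      rev <- match_peak_sets(B, A)
      expect_equal(got$shared, oracle_match_peaks(pa, pb))
      expect_equal(got$shared, rev$shared)
      expect_equal(got$frac_a, rev$frac_b)
    }
  })
})

test_that("expression comparison separates active genes and errors on empty groups", {
  withr::with_seed(61, {
    expr <- tibble::tibble(symbol = paste0("g", 1:60),
                           value = c(rnorm(30, 8), rnorm(30, 2)))
    res <- compare_active_expression(expr, paste0("g", 1:30))
    expect_equal(res$direction, 1)
    expect_lt(res$p, 0.01)
    expect_error(compare_active_expression(expr, character()), "empty group")
    # identical distributions -> roughly uniform p over seeded draws
    ps <- vapply(1:60, function(i) {
      e <- tibble::tibble(symbol = paste0("g", 1:40), value = rnorm(40))
      compare_active_expression(e, paste0("g", 1:20))$p
    }, numeric(1))
    expect_gt(mean(ps > 0.05), 0.75)
  })
})
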