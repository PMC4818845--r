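# tiny deterministic genome helpers -----------------------------------------

mini_pair <- function(bin_size = 1000) {
  tibble::tibble(chrom = "chrA", start_i = 0, start_j = bin_size,
                 frequency = 5, bin_size = bin_size)
}

test_that("partition assigns bases with Alu > SINE/non-Alu > non-SINE precedence", {
  pair <- list(chrom = "chrA", start_i = 0, start_j = 40000, bin_size = 40000)
  ann <- tibble::tibble(
    chrom = "chrA", start = c(0, 300), end = c(300, 400), strand = "+",
    subfamily = c("AluSx", "MIRb"), te_class = "SINE",
    family = c("Alu", "MIR"), divergence = 10)
  part <- partition_binpair(pair, ann)
  lens <- tapply(part$end - part$start, part$class, sum)
  expect_equal(as.numeric(lens[c("Alu", "SINE_non_Alu", "non_SINE")]),
               c(300, 100, 79600))
  # overlapping Alu and MIR: overlap bases go to Alu
  ann2 <- tibble::tibble(
    chrom = "chrA", start = c(100, 150), end = c(200, 250), strand = "+",
    subfamily = c("AluSx", "MIRb"), te_class = "SINE",
    family = c("Alu", "MIR"), divergence = 10)
  part2 <- partition_binpair(pair, ann2)
  lens2 <- tapply(part2$end - part2$start, part2$class, sum)
  expect_equal(as.numeric(lens2["Alu"]), 100)
  expect_equal(as.numeric(lens2["SINE_non_Alu"]), 50)
  # no SINE records: everything non_SINE
  part3 <- partition_binpair(pair, ann[0, ])
  expect_equal(unique(part3$class), "non_SINE")
  expect_equal(sum(part3$end - part3$start), 80000)
})

test_that("partition matches a per-base oracle and is an exact cover", {
  withr::with_seed(19, {
    for (i in 1:30) {
      pair <- list(chrom = "chrA", start_i = 0, start_j = 2000, bin_size = 2000)
      n <- sample(0:10, 1)
      st <- floor(runif(n) * 3800)
      ann <- tibble::tibble(
        chrom = "chrA", start = st, end = st + sample(50:400, max(n, 1))[seq_len(n)],
        strand = "+",
        subfamily = sample(c("AluSx", "MIRb"), n, replace = TRUE),
        te_class = "SINE", family = NA, divergence = 10)
      ann$family <- ifelse(startsWith(ann$subfamily, "Alu"), "Alu", "MIR")
      part <- partition_binpair(pair, ann)
      want <- oracle_partition(pair, ann)
      for (cls in names(want)) {
        got <- oracle_base_set(part[part$class == cls, ])
        expect_setequal(got, want[[cls]])
      }
      expect_equal(sum(part$end - part$start), 4000)
    }
  })
})

test_that("composition counts follow the stated definitions on literal sequence", {
  # genome: bin0 = "CGCG" + A-fill; Alu covers the CGCG stretch
  seq1 <- paste0("CGCG", strrep("A", 1996), strrep("T", 2000))
  genome <- c(chrA = seq1)
  pair <- list(chrom = "chrA", start_i = 0, start_j = 2000, bin_size = 2000)
  ann <- tibble::tibble(chrom = "chrA", start = 0, end = 4, strand = "+",
                        subfamily = "AluSx", te_class = "SINE", family = "Alu",
                        divergence = 10)
  cpg <- tibble::tibble(chrom = "chrA", pos = c(0, 2), methylated = c(TRUE, TRUE))
  part <- partition_binpair(pair, ann)
  cs <- composition_summary(genome, part, cpg)
  alu <- cs[cs$class == "Alu", ]
  expect_equal(alu$total_len, 4)
  expect_equal(alu$gc_count, 4)
  expect_equal(alu$cpg_count, 2)
  expect_equal(alu$meth_cpg_count, 2)
  expect_equal(cs$gc_count[cs$class == "non_SINE"], 0)
  # conservation: class lengths cover the pair exactly
  expect_equal(sum(cs$total_len), 4000)
  # inconsistent bundle: call at a non-CG position errors
  bad <- tibble::tibble(chrom = "chrA", pos = 10, methylated = TRUE)
  expect_error(composition_summary(genome, part, bad), "not a CG")
})

test_that("a CpG site belongs to the class of its C position", {
  # C is last base of the Alu interval, G outside -> counted in Alu
  seq1 <- paste0(strrep("A", 99), "CG", strrep("A", 3899))
  genome <- c(chrA = seq1)
  pair <- list(chrom = "chrA", start_i = 0, start_j = 2000, bin_size = 2000)
  ann <- tibble::tibble(chrom = "chrA", start = 0, end = 100, strand = "+",
                        subfamily = "AluSx", te_class = "SINE", family = "Alu",
                        divergence = 10)
  cpg <- tibble::tibble(chrom = "chrA", pos = 99, methylated = FALSE)
  cs <- composition_summary(genome, partition_binpair(pair, ann), cpg)
  expect_equal(cs$cpg_count[cs$class == "Alu"], 1)
  expect_equal(cs$cpg_count[cs$class == "non_SINE"], 0)
})

test_that("composition_summary equals a naive per-base scan on random fixtures", {
  withr::with_seed(29, {
    for (i in 1:100) {
      len <- 4000 # two 2-kb bins
      chars <- sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                      prob = c(0.3, 0.22, 0.22, 0.25, 0.01))
      g <- paste(chars, collapse = "")
      # CpG calls at actual CG dinucleotides
      cgpos <- gregexpr("CG", g, fixed = TRUE)[[1]]
      cpg <- if (cgpos[1] == -1) {
        tibble::tibble(chrom = "chrA", pos = numeric(), methylated = logical())
      } else {
        tibble::tibble(chrom = "chrA", pos = as.numeric(cgpos) - 1,
                       methylated = runif(length(cgpos)) < 0.7)
      }
      n <- sample(0:6, 1)
      st <- floor(runif(n) * 3600)
      ann <- tibble::tibble(
        chrom = "chrA", start = st, end = st + sample(50:400, max(n, 1))[seq_len(n)],
        strand = "+", subfamily = sample(c("AluY", "MIRb"), n, replace = TRUE),
        te_class = "SINE", family = NA, divergence = 5)
      ann$family <- ifelse(startsWith(ann$subfamily, "Alu"), "Alu", "MIR")
      pair <- list(chrom = "chrA", start_i = 0, start_j = 2000, bin_size = 2000)
      part <- partition_binpair(pair, ann)
      cs <- composition_summary(c(chrA = g), part, cpg)
      want <- oracle_composition(g, part, cpg)
      for (cls in names(want)) {
        row <- cs[cs$class == cls, ]
        expect_equal(unname(unlist(row[, c("total_len", "gc_count", "cpg_count",
                                           "meth_cpg_count")])),
                     unname(want[[cls]]))
      }
      # conservation identities
      expect_equal(sum(cs$total_len), 4000)
      expect_equal(sum(cs$cpg_count), nrow(cpg[cpg$pos < 3999, ]))
    }
  })
})

test_that("GC contributions are conserved and densities follow the ratios", {
  cs <- tibble::tibble(class = c("Alu", "SINE_non_Alu", "non_SINE"),
                       total_len = c(50, 0, 50), gc_count = c(30, 0, 20),
                       cpg_count = c(6, 0, 1), meth_cpg_count = c(5, 0, 0))
  gc <- gc_contribution(cs)
  expect_equal(gc$contribution[gc$class == "Alu"], 0.30)
  expect_equal(gc$contribution[gc$class == "SINE_non_Alu"], 0)
  expect_equal(gc$contribution[gc$class == "non_SINE"], 0.20)
  expect_equal(gc$contribution[gc$class == "background"], 0.50)
  expect_equal(cpg_density(cs, "Alu"), 0.2)
  expect_equal(cpg_density(cs, "overall"), 7 / 50)
  expect_true(is.na(cpg_density(cs, "SINE_non_Alu")))
  # Alu density 0.5 vs non-Alu 0.25 -> ratio 2
  cs2 <- tibble::tibble(class = c("Alu", "SINE_non_Alu", "non_SINE"),
                        total_len = c(10, 10, 10), gc_count = c(4, 4, 4),
                        cpg_count = c(2, 1, 1), meth_cpg_count = c(2, 1, 0))
  expect_equal(cpg_ratio_alu_vs_nonalu(cs2), 2)
  expect_equal(methylation_density(cs2, "Alu"), 1)
  expect_equal(methylation_density(cs, "overall"), 5 / 7)
  expect_true(is.na(methylation_density(cs[2, ], "SINE_non_Alu")))
})

test_that("methylation density of 9/10 sites is 0.9", {
  cs <- tibble::tibble(class = "Alu", total_len = 100, gc_count = 50,
                       cpg_count = 10, meth_cpg_count = 9)
  expect_equal(methylation_density(cs, "Alu"), 0.9)
})

test_that("subfamily methylation assigns sites to the containing copy", {
  ann <- tibble::tibble(
    chrom = "chrA", start = c(0, 1000, 2000), end = c(300, 1300, 2300),
    strand = "+", subfamily = c("AluJb", "AluSx", "AluY"), te_class = "SINE",
    family = "Alu", divergence = 10)
  cpg <- tibble::tibble(
    chrom = "chrA",
    pos = c(10, 20, 1010, 1020, 2010, 2020, 5000),
    methylated = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  sm <- subfamily_methylation(cpg, ann)
  expect_equal(sm$meth_density[sm$group == "AluJ"], 1)
  expect_equal(sm$meth_density[sm$group == "AluS"], 0.5)
  expect_equal(sm$meth_density[sm$group == "AluY"], 0)
  # no AluY copies -> AluY absent
  sm2 <- subfamily_methylation(cpg, ann[ann$subfamily != "AluY", ])
  expect_false("AluY" %in% sm2$group)
})

test_that("methylation-rate estimate is the difference quotient", {
  expect_equal(estimate_methylation_rate(0.92, 81, 0.90, 36),
               0.02 / 45)
  expect_equal(estimate_methylation_rate(0.92, 81, 0.90, 36),
               4.44e-4, tolerance = 1e-3)
  expect_equal(estimate_methylation_rate(0.9, 81, 0.9, 36), 0)
  # swapping both pairs consistently negates numerator and denominator alike
  expect_equal(estimate_methylation_rate(0.90, 36, 0.92, 81),
               estimate_methylation_rate(0.92, 81, 0.90, 36))
  # swapping only the densities flips the sign
  expect_equal(estimate_methylation_rate(0.90, 81, 0.92, 36),
               -estimate_methylation_rate(0.92, 81, 0.90, 36))
  expect_error(estimate_methylation_rate(0.9, 50, 0.8, 50), "equal ages")
})

test_that("pair_composition conserves lengths, GC and CpG counts exactly", {
  b <- sim_bundle(small_config(seed = 51), sequence = TRUE)
  strat <- stratify_and_filter(b$binpairs, b$domains)
  pr <- strat$intra[seq_len(min(200, nrow(strat$intra))), ]
  pq <- pair_composition(pr, b$genome, b$repeats, b$cpg)
  bs <- pr$bin_size[1]
  expect_true(all(pq$len_total == 2 * bs))
  expect_equal(pq$gc_total, pq$gc_Alu + pq$gc_SINE_non_Alu + pq$gc_non_SINE)
  expect_equal(pq$cpg_total, pq$cpg_Alu + pq$cpg_SINE_non_Alu + pq$cpg_non_SINE)
  # spot-check three pairs against the single-pair path
  for (i in c(1, 2, 3)) {
    part <- partition_binpair(pr[i, ], b$repeats)
    cs <- composition_summary(b$genome, part, b$cpg)
    expect_equal(pq$gc_Alu[i], cs$gc_count[cs$class == "Alu"])
    expect_equal(pq$cpg_total[i], sum(cs$cpg_count))
    expect_equal(pq$meth_total[i], sum(cs$meth_cpg_count))
  }
})

test_that("composition-frequency correlations recover the planted GC coupling", {
  b <- sim_bundle(small_config(seed = 53), sequence = TRUE)
  strat <- stratify_and_filter(b$binpairs, b$domains)
  res <- composition_vs_frequency(strat$intra, b$genome, b$repeats, b$cpg,
                                  n_bins = 30)
  alu_gc <- res[res$quantity == "gc_contribution" & res$class == "Alu", ]
  expect_gt(alu_gc$r, 0)
  expect_lt(alu_gc$p, 0.01)
  bg <- res[res$quantity == "gc_background", ]
  expect_gt(bg$r, 0)
})
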