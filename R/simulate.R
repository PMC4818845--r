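#' Default synthetic-bundle configuration
#'
#' Builds the configuration of the seeded generator. Defaults describe a
#' desk-scale study: two 8-Mb chromosomes at 40-kb resolution, ~1-Mb
#' lognormal topological domains tiling each chromosome, exponential
#' inter-domain contact frequencies (mean 2) and distance-decaying lognormal
#' intra-domain frequencies (mean about 15), Alu copies (~300 bp) planted per
#' bin as Poisson with mean `alu_rate_intercept + alu_rate_slope * f` where
#' `f` is the bin's mean intra-domain contact frequency, frequency-independent
#' L1/LTR/DNA/MIR placement, elevated GC (0.60 vs 0.41) and CpG placement
#' (0.06 vs 0.01 per position) inside Alu insertions, subfamily-specific CpG
#' methylation rates (AluJ 0.92, AluS 0.90, AluY 0.78), frequency-coupled
#' enhancer and TSS peak rates, and a 6.68% bin drop emulating coordinates
#' lost in a genome-assembly remap.
#'
#' @param overrides Named list of fields to override; unknown names error.
#' @return A validated list of class `sim_config`.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    n_chrom = 2,
    chrom_length = 8e6,
    bin_size = 40000,
    domain_length_mean = 1e6,
    domain_length_log_sd = 0.5,
    inter_freq_mean = 2.0,
    intra_freq_base = 16.3,
    intra_freq_decay = 0.65,     # per Mb
    intra_freq_noise_sd = 0.55,
    activity_sd = 0.45,          # spread of the per-bin contact propensity
    alu_rate_intercept = 2,
    alu_rate_slope = 0.4,
    alu_length_mean = 300,
    alu_length_sd = 30,
    subfamily_mix = c(AluJ = 0.25, AluS = 0.55, AluY = 0.20),
    l1_rate = 7.0,
    ltr_rate = 6.0,
    dna_rate = 3.0,
    mir_rate = 5.0,
    gc_background = 0.41,
    gc_alu = 0.60,
    cpg_rate_alu = 0.06,
    cpg_rate_background = 0.01,
    meth_rate = c(AluJ = 0.92, AluS = 0.90, AluY = 0.78,
                  promoter = 0.20, gene_body = 0.70, other = 0.75),
    enhancer_rate_intercept = 0.3,
    enhancer_rate_slope = 0.1,
    enhancer_alu_fraction = 0.6,
    tss_rate_intercept = 0.1,
    tss_rate_slope = 0.12,
    genes_per_chrom = 120,
    max_pair_distance = 2e6,
    far_pair_fraction = 0.1,
    liftover_drop_fraction = 0.0668,
    seed = 1
  )
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    stop("default_config: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_config <- function(cfg) {
  rates <- c("inter_freq_mean", "intra_freq_base", "alu_rate_intercept",
             "l1_rate", "ltr_rate", "dna_rate", "mir_rate",
             "enhancer_rate_intercept", "enhancer_rate_slope",
             "tss_rate_intercept", "tss_rate_slope")
  for (f in rates) {
    if (cfg[[f]] < 0) stop("default_config: ", f, " must be >= 0", call. = FALSE)
  }
  probs <- c(cfg$gc_background, cfg$gc_alu, cfg$cpg_rate_alu,
             cfg$cpg_rate_background, cfg$meth_rate, cfg$subfamily_mix,
             cfg$enhancer_alu_fraction, cfg$far_pair_fraction,
             cfg$liftover_drop_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("default_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$subfamily_mix) - 1) > 1e-8) {
    stop("default_config: subfamily_mix must sum to 1", call. = FALSE)
  }
  invisible(cfg)
}

# ---- sequence construction -------------------------------------------------

# Base-composition GC solving the target *final* GC given CpG implant rate:
# iid bases at GC g, scrub every CG (G -> A), implant CG at effective density
# d per position. final = GC1 (1 - 2d) + 2d with GC1 = g - (g/2)^2.
base_gc_for <- function(target_gc, cpg_rate) {
  d <- cpg_rate * (1 - cpg_rate)    # greedy thinning of adjacent picks
  gc1 <- (target_gc - 2 * d) / (1 - 2 * d)
  stopifnot(gc1 > 0, gc1 < 1)
  2 * (1 - sqrt(1 - gc1))
}

# Random sequence (raw vector) with a target GC and controlled CpG placement:
# no incidental CG survives; every CG is an implanted site.
gen_seq_raw <- function(len, target_gc, cpg_rate) {
  g <- base_gc_for(target_gc, cpg_rate)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))
  s <- gsub("CG", "CA", paste(chars, collapse = ""), fixed = TRUE)
  r <- charToRaw(s)
  if (len >= 2) {
    cand <- which(stats::runif(len - 1) < cpg_rate)
    if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) >= 2)]
    if (length(cand) > 0) {
      r[cand] <- charToRaw("C")
      r[cand + 1] <- charToRaw("G")
    }
  }
  r
}

# ---- placement helpers -----------------------------------------------------

# Draw per-bin Poisson counts and uniform placements, then greedily drop
# copies overlapping a previously kept copy of the same family.
place_family <- function(bin_tbl, lambda, len_mean, len_sd, min_len = 50) {
  counts <- stats::rpois(nrow(bin_tbl), lambda)
  if (sum(counts) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  idx <- rep(seq_len(nrow(bin_tbl)), counts)
  len <- pmax(min_len, round(stats::rnorm(length(idx), len_mean, len_sd)))
  bs <- bin_tbl$bin_size[1]
  len <- pmin(len, bs)
  start <- bin_tbl$start[idx] + floor(stats::runif(length(idx)) * (bs - len + 1))
  d <- tibble::tibble(chrom = bin_tbl$chrom[idx], start = start, end = start + len)
  d <- d[order(d$chrom, d$start), ]
  keep <- logical(nrow(d))
  last_end <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(d))) {
    if (d$chrom[i] != last_chrom || d$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- d$end[i]; last_chrom <- d$chrom[i]
    }
  }
  d[keep, , drop = FALSE]
}

subfamily_names <- list(
  AluJ = c("AluJb", "AluJo"),
  AluS = c("AluSx", "AluSz", "AluSq2"),
  AluY = c("AluY", "AluYa5", "AluYb8")
)

# ---- the generator ---------------------------------------------------------

#' Generate a synthetic input bundle in memory
#'
#' Produces domains, bin-pair frequencies, TE annotation, genome sequence,
#' CpG methylation calls, histone-mark peak sets, gene loci and the truth
#' manifest, all deterministically from `config$seed`.
#'
#' @param config A `sim_config` from [default_config()].
#' @param sequence Generate the genome sequence, CpG calls, genes and peaks
#'   (set `FALSE` for frequency/TE-only replicates, which is much faster).
#' @return A list with elements `chrom_lengths`, `domains`, `binpairs`,
#'   `repeats`, `genome`, `cpg`, `peaks` (list of `h3k4me1`, `h3k27ac`,
#'   `h3k4me3`), `genes`, `truth`.
#' @export
sim_bundle <- function(config = default_config(), sequence = TRUE) {
  withr::with_seed(config$seed, sim_bundle_impl(config, sequence))
}

sim_bundle_impl <- function(cfg, sequence) {
  bs <- cfg$bin_size
  chrom_len <- floor(cfg$chrom_length / bs) * bs
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_lengths <- stats::setNames(rep(chrom_len, cfg$n_chrom), chroms)
  n_bins <- chrom_len / bs

  # domains tile each chromosome; lognormal lengths snapped to the bin grid
  domains <- purrr::map_dfr(chroms, function(cm) {
    starts <- c(); ends <- c(); pos <- 0
    while (pos < chrom_len) {
      len <- stats::rlnorm(1, log(cfg$domain_length_mean) -
                                cfg$domain_length_log_sd^2 / 2,
                           cfg$domain_length_log_sd)
      len <- max(2 * bs, round(len / bs) * bs)
      end <- min(pos + len, chrom_len)
      if (chrom_len - end < 2 * bs) end <- chrom_len
      starts <- c(starts, pos); ends <- c(ends, end)
      pos <- end
    }
    tibble::tibble(chrom = cm, start = starts, end = ends)
  })
  domains <- genomic_intervals(domains$chrom, domains$start, domains$end)

  bins <- tibble::tibble(
    chrom = rep(chroms, each = n_bins),
    start = rep(seq(0, chrom_len - bs, by = bs), cfg$n_chrom),
    bin_size = bs
  )
  # bounded contact propensity: same spread as a Gaussian of sd activity_sd
  # but without extreme bins that would monopolise the top frequency strata
  bins$activity <- stats::runif(nrow(bins), -sqrt(3) * cfg$activity_sd,
                                sqrt(3) * cfg$activity_sd)
  # domain id per bin (domains tile, so findInterval works)
  bins$domain <- NA_integer_
  for (cm in chroms) {
    d <- domains[domains$chrom == cm, ]
    sel <- bins$chrom == cm
    bins$domain[sel] <- paste0(cm, "_", findInterval(bins$start[sel], d$start))
  }

  # bin-pairs: all intra-chromosomal pairs within max_pair_distance plus a
  # random fraction of farther ones
  pairs <- purrr::map_dfr(chroms, function(cm) {
    b <- bins[bins$chrom == cm, ]
    ij <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
    si <- b$start[ij[, 1]]; sj <- b$start[ij[, 2]]
    dist <- abs(sj - si)
    keep <- dist <= cfg$max_pair_distance |
      stats::runif(length(dist)) < cfg$far_pair_fraction
    tibble::tibble(chrom = cm,
                   start_i = pmin(si, sj)[keep], start_j = pmax(si, sj)[keep],
                   i = pmin(ij[, 1], ij[, 2])[keep],
                   j = pmax(ij[, 1], ij[, 2])[keep])
  })
  bkey <- paste(bins$chrom, bins$start)
  pi_ <- match(paste(pairs$chrom, pairs$start_i), bkey)
  pj_ <- match(paste(pairs$chrom, pairs$start_j), bkey)
  same_domain <- bins$domain[pi_] == bins$domain[pj_]
  d_mb <- (pairs$start_j - pairs$start_i) / 1e6
  f_intra <- cfg$intra_freq_base * exp(-cfg$intra_freq_decay * d_mb) *
    exp((bins$activity[pi_] + bins$activity[pj_]) / 2) *
    exp(stats::rnorm(nrow(pairs), 0, cfg$intra_freq_noise_sd))
  f_inter <- stats::rexp(nrow(pairs), rate = 1 / cfg$inter_freq_mean)
  pairs$frequency <- ifelse(same_domain, f_intra, f_inter)
  pairs$bin_size <- bs
  pairs$same_domain <- same_domain

  # per-bin mean intra-domain frequency drives the planted couplings
  intra_idx <- which(same_domain)
  fsum <- numeric(nrow(bins)); fcnt <- numeric(nrow(bins))
  for (v in list(pi_[intra_idx], pj_[intra_idx])) {
    t1 <- tapply(pairs$frequency[intra_idx], v, sum)
    t2 <- table(v)
    fsum[as.integer(names(t1))] <- fsum[as.integer(names(t1))] + as.numeric(t1)
    fcnt[as.integer(names(t2))] <- fcnt[as.integer(names(t2))] + as.numeric(t2)
  }
  bins$mean_freq <- ifelse(fcnt > 0, fsum / fcnt,
                           mean(pairs$frequency[intra_idx]))

  # remap-loss mask drawn here so bundles with and without sequence share the
  # same bin-pair list under one seed
  drop_mask <- stats::runif(nrow(bins)) < cfg$liftover_drop_fraction

  # ---- TE annotation -------------------------------------------------------
  alu <- place_family(bins, cfg$alu_rate_intercept +
                        cfg$alu_rate_slope * bins$mean_freq,
                      cfg$alu_length_mean, cfg$alu_length_sd)
  if (nrow(alu) > 0) {
    grp <- sample(names(cfg$subfamily_mix), nrow(alu), replace = TRUE,
                  prob = cfg$subfamily_mix)
    alu$subfamily <- vapply(grp, function(g) sample(subfamily_names[[g]], 1), "")
    alu$te_class <- "SINE"; alu$family <- "Alu"
    alu$divergence <- round(c(AluJ = 15, AluS = 10, AluY = 3)[grp] +
                              stats::runif(nrow(alu), -2, 2), 1)
  }
  mk <- function(d, cls, fam, subs, div_lo = 5, div_hi = 25) {
    if (nrow(d) == 0) return(NULL)
    d$subfamily <- sample(subs, nrow(d), replace = TRUE)
    d$te_class <- cls; d$family <- fam
    d$divergence <- round(stats::runif(nrow(d), div_lo, div_hi), 1)
    d
  }
  l1 <- mk(place_family(bins, cfg$l1_rate, 1000, 300, 100),
           "LINE", "L1", c("L1PA2", "L1MB7", "L1HS"))
  mir <- mk(place_family(bins, cfg$mir_rate, 200, 40),
            "SINE", "MIR", c("MIRb", "MIR3"))
  ltr <- mk(place_family(bins, cfg$ltr_rate, 500, 100),
            "LTR", "ERVL", c("MLT1C", "ERVL-E"))
  dna <- mk(place_family(bins, cfg$dna_rate, 400, 80),
            "DNA", "hAT-Charlie", c("Charlie1", "MER5A"))
  repeats <- dplyr::bind_rows(
    if (nrow(alu) > 0) dplyr::mutate(alu, strand = sample(c("+", "-"), nrow(alu),
                                                          replace = TRUE)) else NULL,
    purrr::map(list(l1, mir, ltr, dna), function(d) {
      if (is.null(d)) return(NULL)
      dplyr::mutate(d, strand = sample(c("+", "-"), nrow(d), replace = TRUE))
    })
  )
  repeats <- repeats[order(repeats$chrom, repeats$start),
                     c("chrom", "start", "end", "strand", "subfamily",
                       "te_class", "family", "divergence")]

  genome <- NULL; cpg <- NULL; genes <- NULL; peaks <- NULL
  if (sequence) {
    # ---- genome sequence with planted Alu composition ----------------------
    seqs <- lapply(chroms, function(cm) {
      r <- gen_seq_raw(chrom_len, cfg$gc_background, cfg$cpg_rate_background)
      a <- repeats[repeats$chrom == cm & repeats$family == "Alu", , drop = FALSE]
      for (i in seq_len(nrow(a))) {
        len <- a$end[i] - a$start[i]
        r[(a$start[i] + 1):a$end[i]] <- gen_seq_raw(len, cfg$gc_alu,
                                                    cfg$cpg_rate_alu)
      }
      rawToChar(r)
    })
    genome <- Biostrings::DNAStringSet(stats::setNames(unlist(seqs), chroms))

    # ---- gene loci ---------------------------------------------------------
    genes <- purrr::map_dfr(chroms, function(cm) {
      len <- pmax(5000, round(stats::rlnorm(cfg$genes_per_chrom,
                                            log(3e4), 0.5)))
      start <- sort(floor(stats::runif(cfg$genes_per_chrom) *
                            (chrom_len - max(len))))
      end <- pmin(start + len, chrom_len)
      keep <- c(TRUE, start[-1] >= cummax(end)[-length(end)])
      start <- start[keep]; end <- end[keep]
      strand <- sample(c("+", "-"), length(start), replace = TRUE)
      tss <- lapply(seq_along(start), function(i) {
        primary <- if (strand[i] == "+") start[i] else end[i] - 1
        n_extra <- sample(0:2, 1)
        extra <- primary + (if (strand[i] == "+") 1 else -1) *
          floor(stats::runif(n_extra) * (end[i] - start[i]) * 0.3)
        sort(unique(pmin(pmax(c(primary, extra), start[i]), end[i] - 1)))
      })
      tibble::tibble(chrom = cm, start = start, end = end, strand = strand,
                     symbol = paste0("G", cm, "_", seq_along(start)), tss = tss)
    })

    # ---- CpG methylation calls --------------------------------------------
    cpg <- purrr::map_dfr(chroms, function(cm) {
      pos <- Biostrings::start(Biostrings::matchPattern("CG", genome[[cm]])) - 1
      tibble::tibble(chrom = cm, pos = as.numeric(pos))
    })
    # context: Alu subfamily > promoter (TSS +/- 1 kb) > gene body > other
    cpg$context <- "other"
    gene_iv <- genes
    tss_all <- tidyr::unnest(genes[, c("chrom", "tss")], cols = "tss")
    for (cm in chroms) {
      sel <- which(cpg$chrom == cm)
      pt <- IRanges::IRanges(cpg$pos[sel] + 1L, width = 1L)
      g <- gene_iv[gene_iv$chrom == cm, ]
      if (nrow(g) > 0) {
        ing <- !is.na(IRanges::findOverlaps(pt, to_iranges(g), select = "first"))
        cpg$context[sel][ing] <- "gene_body"
      }
      t_cm <- tss_all$tss[tss_all$chrom == cm]
      if (length(t_cm) > 0) {
        pr <- IRanges::reduce(IRanges::IRanges(pmax(0, t_cm - 1000) + 1L,
                                               t_cm + 1000))
        inp <- !is.na(IRanges::findOverlaps(pt, pr, select = "first"))
        cpg$context[sel][inp] <- "promoter"
      }
      a <- repeats[repeats$chrom == cm & repeats$family == "Alu", ]
      if (nrow(a) > 0) {
        hit <- IRanges::findOverlaps(pt, to_iranges(a), select = "first")
        ina <- !is.na(hit)
        cpg$context[sel][ina] <- subfamily_group(a$subfamily[hit[ina]])
      }
    }
    cpg$methylated <- stats::runif(nrow(cpg)) < cfg$meth_rate[cpg$context]

    # ---- histone-mark peaks -----------------------------------------------
    np <- function(chrom, start, end, summit, signal) {
      tibble::tibble(chrom = chrom, start = start, end = end,
                     name = NA_character_, score = round(signal * 10),
                     strand = "*", signal = signal, pvalue = -1, qvalue = -1,
                     summit_offset = summit - start)
    }
    enh_counts <- stats::rpois(nrow(bins), cfg$enhancer_rate_intercept +
                                 cfg$enhancer_rate_slope * bins$mean_freq)
    ev_bin <- rep(seq_len(nrow(bins)), enh_counts)
    n_ev <- length(ev_bin)
    alu_all <- repeats[repeats$family == "Alu", , drop = FALSE]
    # Alu-derived events sit inside a copy drawn uniformly over all copies, so
    # they concentrate where Alus are dense; the rest are uniform in their bin
    in_alu <- stats::runif(n_ev) < cfg$enhancer_alu_fraction & nrow(alu_all) > 0
    ev_chrom <- bins$chrom[ev_bin]
    center <- bins$start[ev_bin] + floor(stats::runif(n_ev) * bs)
    if (any(in_alu)) {
      ci <- sample.int(nrow(alu_all), sum(in_alu), replace = TRUE)
      ev_chrom[in_alu] <- alu_all$chrom[ci]
      center[in_alu] <- alu_all$start[ci] +
        floor(stats::runif(sum(in_alu)) * (alu_all$end[ci] - alu_all$start[ci]))
    }
    w1 <- round(stats::rnorm(n_ev, 1400, 200))
    w2 <- round(stats::rnorm(n_ev, 800, 150))
    sg1 <- stats::rlnorm(n_ev, log(10), 0.5)
    sg2 <- stats::rlnorm(n_ev, log(10), 0.5)
    s1 <- pmax(0, center - w1 %/% 2); e1 <- pmin(chrom_len, center + w1 %/% 2)
    s2 <- pmax(0, center - w2 %/% 2); e2 <- pmin(chrom_len, center + w2 %/% 2)
    me1 <- np(ev_chrom, s1, e1, pmin(center, e1 - 1), sg1)
    ac <- np(ev_chrom, s2, e2, pmin(center, e2 - 1), sg2)
    # unpaired noise peaks keep the mark intersection non-trivial
    noise <- function(rate, width) {
      k <- stats::rpois(nrow(bins), rate)
      purrr::map_dfr(which(k > 0), function(b) {
        pos <- bins$start[b] + floor(stats::runif(k[b]) * bs)
        s <- pmax(0, pos - width %/% 2); e <- pmin(chrom_len, pos + width %/% 2)
        np(bins$chrom[b], s, e, pmin(pos, e - 1), stats::rlnorm(k[b], log(5), 0.5))
      })
    }
    me1 <- dplyr::bind_rows(me1, noise(0.3, 1400))
    ac <- dplyr::bind_rows(ac, noise(0.3, 800))

    tss_counts <- stats::rpois(nrow(bins), cfg$tss_rate_intercept +
                                 cfg$tss_rate_slope * bins$mean_freq)
    me3 <- purrr::map_dfr(which(tss_counts > 0), function(b) {
      cm <- bins$chrom[b]
      t_cm <- tss_all$tss[tss_all$chrom == cm &
                            tss_all$tss >= bins$start[b] &
                            tss_all$tss < bins$start[b] + bs]
      pos <- if (length(t_cm) > 0) {
        t_cm[sample.int(length(t_cm), tss_counts[b], replace = TRUE)]
      } else {
        bins$start[b] + floor(stats::runif(tss_counts[b]) * bs)
      }
      s <- pmax(0, pos - 500); e <- pmin(chrom_len, pos + 500)
      np(cm, s, e, pmin(pos, e - 1), stats::rlnorm(length(pos), log(10), 0.5))
    })
    fix_order <- function(d) d[order(d$chrom, d$start), , drop = FALSE]
    peaks <- list(h3k4me1 = fix_order(me1), h3k27ac = fix_order(ac),
                  h3k4me3 = fix_order(me3))
  }

  # ---- remap loss ----------------------------------------------------------
  dropped_bins <- character()
  if (cfg$liftover_drop_fraction > 0) {
    dropped_bins <- bkey[drop_mask]
    keep <- !(paste(pairs$chrom, pairs$start_i) %in% dropped_bins |
                paste(pairs$chrom, pairs$start_j) %in% dropped_bins)
    pairs <- pairs[keep, , drop = FALSE]
  }

  binpairs <- pairs[, c("chrom", "start_i", "start_j", "frequency", "bin_size")]
  sub_grp <- subfamily_group(repeats$subfamily[repeats$family == "Alu"])
  realized_meth <- if (!is.null(cpg)) {
    sm <- subfamily_methylation(cpg[, c("chrom", "pos", "methylated")], repeats)
    stats::setNames(sm$meth_density, sm$group)
  } else NULL

  truth <- list(
    config = unclass(cfg),
    coupling_sign = list(
      Alu = if (cfg$alu_rate_slope > 0) "+" else if (cfg$alu_rate_slope < 0) "-" else "0",
      SINE = if (cfg$alu_rate_slope > 0) "+" else "0",
      L1 = "0", LINE = "0", LTR = "0", DNA = "0", SINE_non_Alu = "0"
    ),
    realized_alu_count = sum(repeats$family == "Alu"),
    realized_subfamily_counts = as.list(table(sub_grp)),
    realized_meth_rates = as.list(realized_meth),
    expected_positive = if (cfg$alu_rate_slope > 0)
      c("Alu", "SINE", "AluJ", "AluS", "AluY") else character(0),
    intra_mean_frequency = mean(pairs$frequency[pairs$same_domain]),
    inter_mean_frequency = mean(pairs$frequency[!pairs$same_domain]),
    n_dropped_bins = length(dropped_bins)
  )

  list(chrom_lengths = chrom_lengths, domains = domains, binpairs = binpairs,
       repeats = repeats, genome = genome,
       cpg = if (!is.null(cpg)) cpg[, c("chrom", "pos", "methylated")] else NULL,
       genes = genes, peaks = peaks, truth = truth)
}

#' Generate a bundle and write it to disk
#'
#' Writes `genome.fasta`, `domains.bed`, `binpairs.tsv`, `repeats.out`,
#' `cpg.tsv`, `peaks_h3k4me1.narrowPeak`, `peaks_h3k27ac.narrowPeak`,
#' `peaks_h3k4me3.narrowPeak`, `genes.tsv` and `truth.json` into `out_dir`.
#' Identical seeds give byte-identical bundles.
#'
#' @inheritParams sim_bundle
#' @param out_dir Output directory (created if missing).
#' @return The bundle list, invisibly, with a `paths` element added.
#' @export
simulate_all <- function(config = default_config(), out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("simulate_all: cannot write to ", out_dir, call. = FALSE)
  }
  bundle <- sim_bundle(config, sequence = TRUE)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fasta"), width = 80)
  write_records(bundle$domains, p("domains.bed"), "domain_bed")
  write_records(bundle$binpairs, p("binpairs.tsv"), "binpair_tsv")
  write_records(bundle$repeats, p("repeats.out"), "rmsk_out")
  write_records(bundle$cpg, p("cpg.tsv"), "cpg_tsv")
  write_records(bundle$peaks$h3k4me1, p("peaks_h3k4me1.narrowPeak"), "narrowPeak")
  write_records(bundle$peaks$h3k27ac, p("peaks_h3k27ac.narrowPeak"), "narrowPeak")
  write_records(bundle$peaks$h3k4me3, p("peaks_h3k4me3.narrowPeak"), "narrowPeak")
  write_records(bundle$genes, p("genes.tsv"), "genes_tsv")
  jsonlite::write_json(bundle$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$paths <- stats::setNames(
    p(c("genome.fasta", "domains.bed", "binpairs.tsv", "repeats.out", "cpg.tsv",
        "peaks_h3k4me1.narrowPeak", "peaks_h3k27ac.narrowPeak",
        "peaks_h3k4me3.narrowPeak", "genes.tsv", "truth.json")),
    c("genome", "domains", "binpairs", "repeats", "cpg",
      "h3k4me1", "h3k27ac", "h3k4me3", "genes", "truth"))
  invisible(bundle)
}

#' Expected sign and magnitude band of planted binned correlations
#'
#' Reads the planted coupling signs from a truth manifest and, for the Alu
#' density correlation, estimates a Monte-Carlo band for the binned Pearson r
#' by replaying the generative model (frequencies and TE placement only) under
#' fresh seeds.
#'
#' @param truth Truth manifest (list, from `sim_bundle()$truth` or
#'   `truth.json`).
#' @param n_rep Monte-Carlo replicates (default 100).
#' @param n_bins Frequency bins used in the replicate analyses.
#' @param level Band coverage (default 0.95).
#' @param seed Base seed for the replicates.
#' @return List with `signs` (tibble of selector, expected_sign) and `band`
#'   (quantiles of the replicate Alu density r), plus the replicate values.
#' @export
planted_binned_correlation <- function(truth, n_rep = 100, n_bins = 50,
                                       level = 0.95, seed = 100) {
  signs <- tibble::tibble(
    selector = names(truth$coupling_sign),
    expected_sign = unlist(truth$coupling_sign, use.names = FALSE)
  )
  cfg_fields <- truth$config
  # tolerate a manifest round-tripped through JSON (vectors become lists)
  for (f in c("subfamily_mix", "meth_rate")) {
    if (is.list(cfg_fields[[f]])) cfg_fields[[f]] <- unlist(cfg_fields[[f]])
  }
  rs <- vapply(seq_len(n_rep), function(i) {
    cfg <- default_config(cfg_fields[setdiff(names(cfg_fields), "seed")])
    cfg$seed <- seed + i
    b <- sim_bundle(cfg, sequence = FALSE)
    cls <- classify_binpairs(b$binpairs, b$domains)
    intra <- cls[cls$stratum == "intra", , drop = FALSE]
    non_intra <- cls[cls$stratum == "non_intra", , drop = FALSE]
    lower <- if (nrow(non_intra) > 0) mean_interdomain_frequency(non_intra) else 0
    upper <- detect_upper_threshold(intra$frequency)
    # at replicate scale the empty-window detector can degenerate below the
    # lower threshold; such replicates are analysed without the upper cut
    if (upper <= lower) upper <- Inf
    pr <- filter_binpairs(intra, lower, upper)$retained
    pr$metric <- te_metric(pr, b$repeats, "Alu", kind = "density")
    correlate_bins(bin_by_frequency(pr, "metric", n_bins))$r
  }, numeric(1))
  alpha <- (1 - level) / 2
  list(signs = signs,
       band = stats::quantile(rs, c(alpha, 1 - alpha)),
       replicates = rs)
}
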