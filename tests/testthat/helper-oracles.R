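# Brute-force oracles and random fixtures used across the suite. Every oracle
# works on explicit per-base sets so it shares no code with the implementation.

rand_intervals <- function(n, chrom = "chrA", max_pos = 5000, max_len = 400) {
  start <- floor(runif(n) * (max_pos - 1))
  len <- 1 + floor(runif(n) * max_len)
  genomic_intervals(chrom = rep(chrom, n), start = start,
                    end = pmin(start + len, max_pos))
}

# set of 0-based positions covered by intervals
oracle_base_set <- function(intervals) {
  if (nrow(intervals) == 0) return(integer())
  unique(unlist(lapply(seq_len(nrow(intervals)), function(i) {
    seq(intervals$start[i], intervals$end[i] - 1)
  })))
}

oracle_region_coverage <- function(intervals, region) {
  covered <- oracle_base_set(intervals[intervals$chrom == region$chrom, ])
  sum(covered >= region$start & covered < region$end)
}

# per-base class assignment with Alu > SINE_non_Alu > non_SINE precedence
oracle_partition <- function(pair, annotations) {
  reg <- binpair_region(pair)
  bases <- oracle_base_set(reg)
  sine <- annotations[annotations$te_class == "SINE" &
                        annotations$chrom == pair$chrom, ]
  alu_set <- oracle_base_set(sine[sine$family == "Alu", ])
  mir_set <- oracle_base_set(sine[sine$family != "Alu", ])
  cls <- rep("non_SINE", length(bases))
  cls[bases %in% mir_set] <- "SINE_non_Alu"
  cls[bases %in% alu_set] <- "Alu"
  split(bases, factor(cls, levels = c("Alu", "SINE_non_Alu", "non_SINE")))
}

# naive per-base composition scan over a partition
oracle_composition <- function(genome_chr, partition, cpg_calls) {
  chars <- strsplit(genome_chr, "")[[1]]
  out <- list()
  for (cls in c("Alu", "SINE_non_Alu", "non_SINE")) {
    p <- partition[partition$class == cls, ]
    bases <- oracle_base_set(p)
    sites <- cpg_calls[cpg_calls$pos %in% bases, ]
    out[[cls]] <- c(
      total_len = length(bases),
      gc_count = sum(chars[bases + 1] %in% c("C", "G")),
      cpg_count = nrow(sites),
      meth_cpg_count = sum(sites$methylated)
    )
  }
  out
}

oracle_enhancers <- function(me1, ac, max_pos = 5000) {
  m1 <- rep(FALSE, max_pos); m2 <- rep(FALSE, max_pos)
  m1[oracle_base_set(me1) + 1] <- TRUE
  m2[oracle_base_set(ac) + 1] <- TRUE
  both <- m1 & m2
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep] - 1, end = ends[keep])
}

oracle_match_peaks <- function(pa, pb, max_dist = 250) {
  if (length(pa) == 0 || length(pb) == 0) return(0L)
  d <- abs(outer(pa, pb, "-"))
  shared <- 0L
  for (i in seq_along(pa)) {
    j <- which.min(d[i, ])
    if (d[i, j] < max_dist && which.min(d[, j]) == i) shared <- shared + 1L
  }
  shared
}

oracle_upper_threshold <- function(freqs, step = 1) {
  k <- floor(min(freqs))
  repeat {
    if (k > max(freqs)) return(floor(max(freqs)) + step)
    if (sum(freqs >= k & freqs < k + step) == 0) return(k)
    k <- k + step
  }
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# small single-chromosome bundle for fast unit tests
small_config <- function(seed = 1, ...) {
  default_config(c(list(n_chrom = 1, chrom_length = 4e6, genes_per_chrom = 30,
                        seed = seed), list(...)))
}
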