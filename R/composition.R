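origin_classes <- c("Alu", "SINE_non_Alu", "non_SINE")

# Resolve one chromosome sequence from a DNAStringSet or named character vector.
genome_seq <- function(genome, chrom) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("no sequence for ", chrom, call. = FALSE)
    return(Biostrings::DNAString(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) stop("no sequence for ", chrom, call. = FALSE)
  genome[[chrom]]
}

# Class ranges (IRanges, 1-based) for one chromosome: Alu, then other SINE
# minus Alu, applying the Alu > SINE_non_Alu > non_SINE precedence.
class_ranges <- function(annotations, chrom) {
  a <- annotations[annotations$chrom == chrom, , drop = FALSE]
  alu <- a[a$te_class == "SINE" & a$family == "Alu", , drop = FALSE]
  oth <- a[a$te_class == "SINE" & a$family != "Alu", , drop = FALSE]
  A <- if (nrow(alu) > 0) IRanges::reduce(to_iranges(alu)) else IRanges::IRanges()
  S <- if (nrow(oth) > 0) IRanges::setdiff(IRanges::reduce(to_iranges(oth)), A)
       else IRanges::IRanges()
  list(Alu = A, SINE_non_Alu = S)
}

#' Partition a bin-pair's bases by origin class
#'
#' Decomposes the two 40-kb bin intervals into three disjoint interval sets:
#' bases covered by Alu-family SINE records, bases covered by other SINE
#' records and not by Alu, and the remainder. Overlaps are resolved with the
#' precedence Alu > SINE/non-Alu > non-SINE; the union equals the pair region
#' exactly.
#'
#' @param pair One-row bin-pair tibble (or list).
#' @param annotations TE annotation tibble.
#' @return Interval tibble with a `class` column in
#'   `{"Alu", "SINE_non_Alu", "non_SINE"}`.
#' @export
partition_binpair <- function(pair, annotations) {
  region <- binpair_region(pair)
  cr <- class_ranges(annotations, region$chrom[1])
  out <- list()
  for (k in seq_len(nrow(region))) {
    bin <- IRanges::IRanges(region$start[k] + 1L, region$end[k])
    A <- IRanges::intersect(cr$Alu, bin)
    S <- IRanges::intersect(cr$SINE_non_Alu, bin)
    N <- IRanges::setdiff(IRanges::setdiff(bin, A), S)
    for (cls in origin_classes) {
      ir <- switch(cls, Alu = A, SINE_non_Alu = S, non_SINE = N)
      if (length(ir) > 0) {
        d <- from_iranges(ir, region$chrom[1])
        d$class <- cls
        out[[length(out) + 1]] <- d
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res[order(res$start), c("chrom", "start", "end", "class")]
}

count_gc <- function(seq, ir) {
  if (length(ir) == 0) return(0)
  v <- Biostrings::Views(seq, ir)
  sum(Biostrings::letterFrequency(v, letters = c("C", "G")))
}

#' Per-class GC / CpG / methylation accounting for one bin-pair partition
#'
#' Counts, per origin class: total bases, G or C bases (ambiguous `N` bases
#' count toward length but never toward GC), CpG sites whose C position lies in
#' the class, and the subset of those sites called methylated. CpG sites come
#' from the call table; every call position must be a `CG` dinucleotide in the
#' genome, otherwise the bundle is inconsistent and an error is raised.
#'
#' @param genome Named `DNAStringSet` (or named character vector) of chromosome
#'   sequences.
#' @param partition Output of [partition_binpair()].
#' @param cpg_calls CpG call tibble (`chrom`, `pos`, `methylated`).
#' @return Tibble with one row per class: `class`, `total_len`, `gc_count`,
#'   `cpg_count`, `meth_cpg_count`.
#' @export
composition_summary <- function(genome, partition, cpg_calls) {
  chrom <- partition$chrom[1]
  seq <- genome_seq(genome, chrom)
  sites <- cpg_calls[cpg_calls$chrom == chrom, , drop = FALSE]
  lo <- min(partition$start); hi <- max(partition$end)
  sites <- sites[sites$pos >= lo & sites$pos < hi, , drop = FALSE]
  if (nrow(sites) > 0) {
    din <- as.character(Biostrings::Views(seq,
      IRanges::IRanges(sites$pos + 1L, sites$pos + 2L)))
    if (any(din != "CG")) {
      bad <- which(din != "CG")[1]
      stop("composition_summary: CpG call at ", chrom, ":", sites$pos[bad],
           " is not a CG dinucleotide (inconsistent bundle)", call. = FALSE)
    }
  }
  purrr::map_dfr(origin_classes, function(cls) {
    part <- partition[partition$class == cls, , drop = FALSE]
    if (nrow(part) == 0) {
      return(tibble::tibble(class = cls, total_len = 0, gc_count = 0,
                            cpg_count = 0, meth_cpg_count = 0))
    }
    ir <- to_iranges(part)
    in_cls <- !is.na(IRanges::findOverlaps(
      IRanges::IRanges(sites$pos + 1L, width = 1L), ir, select = "first"))
    tibble::tibble(
      class = cls,
      total_len = sum(part$end - part$start),
      gc_count = count_gc(seq, ir),
      cpg_count = sum(in_cls),
      meth_cpg_count = sum(in_cls & sites$methylated)
    )
  })
}

#' Per-class GC contribution to the whole pair region
#'
#' `contribution_c = gc_count_c / region_length`; the contributions sum exactly
#' to the background (total) GC fraction.
#'
#' @param summary Output of [composition_summary()].
#' @return Tibble with `class`, `contribution`, plus a `background` attribute
#'   (also returned as a row with class `"background"`).
#' @export
gc_contribution <- function(summary) {
  len <- sum(summary$total_len)
  contrib <- summary$gc_count / len
  out <- tibble::tibble(class = c(summary$class, "background"),
                        contribution = c(contrib, sum(contrib)))
  out
}

#' CpG sites per G/C nucleotide
#'
#' @param summary Output of [composition_summary()].
#' @param class One origin class, or `"overall"` to pool all classes.
#' @return The density, or `NA` when the class has no G/C bases (undefined,
#'   not zero).
#' @export
cpg_density <- function(summary, class = "overall") {
  if (class == "overall") {
    gc <- sum(summary$gc_count); cpg <- sum(summary$cpg_count)
  } else {
    row <- summary[summary$class == class, , drop = FALSE]
    gc <- sum(row$gc_count); cpg <- sum(row$cpg_count)
  }
  if (gc == 0) return(NA_real_)
  cpg / gc
}

#' Ratio of Alu CpG density to non-Alu CpG density
#'
#' Non-Alu pools the SINE/non-Alu and non-SINE classes.
#'
#' @param summary Output of [composition_summary()].
#' @return The ratio, `NA` when either density is undefined or the non-Alu
#'   density is zero.
#' @export
cpg_ratio_alu_vs_nonalu <- function(summary) {
  alu <- cpg_density(summary, "Alu")
  rest <- summary[summary$class != "Alu", , drop = FALSE]
  gc <- sum(rest$gc_count)
  if (gc == 0 || is.na(alu)) return(NA_real_)
  non <- sum(rest$cpg_count) / gc
  if (non == 0) return(NA_real_)
  alu / non
}

#' Methylated fraction of CpG sites
#'
#' @inheritParams cpg_density
#' @return The methylation density, `NA` when the class has no CpG sites.
#' @export
methylation_density <- function(summary, class = "overall") {
  if (class == "overall") {
    cpg <- sum(summary$cpg_count); meth <- sum(summary$meth_cpg_count)
  } else {
    row <- summary[summary$class == class, , drop = FALSE]
    cpg <- sum(row$cpg_count); meth <- sum(row$meth_cpg_count)
  }
  if (cpg == 0) return(NA_real_)
  meth / cpg
}

#' Methylation density per Alu subfamily group
#'
#' Each CpG call is assigned to the subfamily group (AluJ/AluS/AluY) of the Alu
#' copy containing its C position; groups with no sites are absent from the
#' result.
#'
#' @param cpg_calls CpG call tibble.
#' @param annotations TE annotation tibble with Alu subfamily names.
#' @return Tibble with `group`, `n_sites`, `meth_density`.
#' @export
subfamily_methylation <- function(cpg_calls, annotations) {
  alu <- annotations[annotations$family == "Alu", , drop = FALSE]
  if (nrow(alu) == 0 || nrow(cpg_calls) == 0) {
    return(tibble::tibble(group = character(), n_sites = integer(),
                          meth_density = numeric()))
  }
  alu$group <- subfamily_group(alu$subfamily)
  res <- list()
  for (cm in unique(alu$chrom)) {
    a <- alu[alu$chrom == cm, , drop = FALSE]
    s <- cpg_calls[cpg_calls$chrom == cm, , drop = FALSE]
    if (nrow(s) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(s$pos + 1L, width = 1L), to_iranges(a), select = "first")
    keep <- !is.na(hit)
    if (!any(keep)) next
    res[[cm]] <- tibble::tibble(group = a$group[hit[keep]],
                                methylated = s$methylated[keep])
  }
  if (length(res) == 0) {
    return(tibble::tibble(group = character(), n_sites = integer(),
                          meth_density = numeric()))
  }
  dplyr::bind_rows(res) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     meth_density = mean(.data$methylated), .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Methylation-density change per million years
#'
#' Difference quotient between an older and a younger Alu group:
#' `(d_old - d_young) / (age_old - age_young)`.
#'
#' @param d_old,d_young Methylation densities.
#' @param age_old,age_young Mean subfamily ages in Myr (81 for AluJ, 36 for
#'   AluS in the standard chronology).
#' @return Density change per Myr.
#' @export
estimate_methylation_rate <- function(d_old, age_old, d_young, age_young) {
  if (age_old == age_young) {
    stop("estimate_methylation_rate: equal ages", call. = FALSE)
  }
  (d_old - d_young) / (age_old - age_young)
}

# Per-40kb-bin composition table: one row per (chrom, start, class) with
# total_len, gc, cpg, meth. Exact per-base accounting; bin-level sums let the
# per-pair quantities be assembled by joining the two member bins.
bin_composition <- function(genome, annotations, cpg_calls, bins) {
  bs <- bins$bin_size[1]
  out <- list()
  for (cm in unique(bins$chrom)) {
    seq <- genome_seq(genome, cm)
    bsel <- bins[bins$chrom == cm, , drop = FALSE]
    cr <- class_ranges(annotations, cm)
    br <- IRanges::IRanges(bsel$start + 1L, bsel$start + bs)
    sites <- cpg_calls[cpg_calls$chrom == cm, , drop = FALSE]
    site_bin <- floor(sites$pos / bs) * bs
    site_cls <- rep("non_SINE", nrow(sites))
    if (nrow(sites) > 0) {
      pt <- IRanges::IRanges(sites$pos + 1L, width = 1L)
      inA <- !is.na(IRanges::findOverlaps(pt, cr$Alu, select = "first"))
      inS <- !is.na(IRanges::findOverlaps(pt, cr$SINE_non_Alu, select = "first"))
      site_cls[inS] <- "SINE_non_Alu"
      site_cls[inA] <- "Alu"
    }
    for (cls in origin_classes) {
      clsr <- switch(cls, Alu = cr$Alu, SINE_non_Alu = cr$SINE_non_Alu,
                     non_SINE = NULL)
      # per-bin lengths and GC
      if (cls == "non_SINE") {
        # complement within each bin
        other <- IRanges::union(cr$Alu, cr$SINE_non_Alu)
        ov <- IRanges::findOverlaps(br, other)
        covered <- numeric(length(br))
        gc_other <- numeric(length(br))
        if (length(ov) > 0) {
          pint <- IRanges::pintersect(br[S4Vectors::queryHits(ov)],
                                      other[S4Vectors::subjectHits(ov)])
          w <- IRanges::width(pint)
          gcv <- Biostrings::letterFrequency(Biostrings::Views(seq, pint),
                                             letters = c("C", "G"))
          agg_w <- tapply(w, S4Vectors::queryHits(ov), sum)
          agg_g <- tapply(rowSums(gcv), S4Vectors::queryHits(ov), sum)
          covered[as.integer(names(agg_w))] <- as.numeric(agg_w)
          gc_other[as.integer(names(agg_g))] <- as.numeric(agg_g)
        }
        gc_bin <- rowSums(Biostrings::letterFrequency(
          Biostrings::Views(seq, br), letters = c("C", "G")))
        total_len <- bs - covered
        gc <- gc_bin - gc_other
      } else {
        ov <- IRanges::findOverlaps(br, clsr)
        total_len <- numeric(length(br))
        gc <- numeric(length(br))
        if (length(ov) > 0) {
          pint <- IRanges::pintersect(br[S4Vectors::queryHits(ov)],
                                      clsr[S4Vectors::subjectHits(ov)])
          w <- IRanges::width(pint)
          gcv <- rowSums(Biostrings::letterFrequency(
            Biostrings::Views(seq, pint), letters = c("C", "G")))
          agg_w <- tapply(w, S4Vectors::queryHits(ov), sum)
          agg_g <- tapply(gcv, S4Vectors::queryHits(ov), sum)
          total_len[as.integer(names(agg_w))] <- as.numeric(agg_w)
          gc[as.integer(names(agg_g))] <- as.numeric(agg_g)
        }
      }
      key <- paste(cm, bsel$start)
      cls_sites <- site_cls == cls
      cpg <- numeric(length(br)); meth <- numeric(length(br))
      if (any(cls_sites)) {
        skey <- paste(cm, site_bin[cls_sites])
        tab_c <- table(skey)
        tab_m <- tapply(sites$methylated[cls_sites], skey, sum)
        hit <- match(key, names(tab_c))
        cpg <- ifelse(is.na(hit), 0, as.numeric(tab_c[hit]))
        meth <- ifelse(is.na(hit), 0, as.numeric(tab_m[match(key, names(tab_m))]))
      }
      out[[paste(cm, cls)]] <- tibble::tibble(
        chrom = cm, start = bsel$start, class = cls,
        total_len = total_len, gc = gc, cpg = cpg, meth = meth)
    }
  }
  dplyr::bind_rows(out)
}

comp_quantities <- c("gc_background", "gc_contribution", "cpg_density",
                     "cpg_share", "methylation_density")

#' Correlate sequence-composition quantities with contact frequency
#'
#' Computes, per retained bin-pair: background GC fraction, per-class GC
#' contribution, per-class and overall CpG density, the Alu vs non-Alu CpG
#' density ratio (`cpg_share`), and overall plus per-class methylation density;
#' bins each quantity by contact frequency with the same binning as the TE
#' analysis and reports a Pearson correlation per (quantity, class).
#'
#' @param pairs Retained bin-pair tibble.
#' @param genome Named `DNAStringSet` or character vector.
#' @param annotations TE annotation tibble.
#' @param cpg_calls CpG call tibble.
#' @param n_bins Number of frequency bins.
#' @return Tibble with `quantity`, `class`, `n`, `r`, `p`.
#' @export
composition_vs_frequency <- function(pairs, genome, annotations, cpg_calls,
                                     n_bins = 50) {
  pq <- pair_composition(pairs, genome, annotations, cpg_calls)
  run <- function(values, quantity, class) {
    pairs$metric <- values
    bins <- bin_by_frequency(pairs, "metric", n_bins)
    cr <- correlate_bins(bins, label = paste(quantity, class))
    tibble::tibble(quantity = quantity, class = class, n = cr$n, r = cr$r, p = cr$p)
  }
  res <- list(run(pq$gc_total / pq$len_total, "gc_background", "all"))
  for (cls in origin_classes) {
    res[[length(res) + 1]] <-
      run(pq[[paste0("gc_", cls)]] / pq$len_total, "gc_contribution", cls)
    res[[length(res) + 1]] <-
      run(ifelse(pq[[paste0("gc_", cls)]] > 0,
                 pq[[paste0("cpg_", cls)]] / pq[[paste0("gc_", cls)]], NA_real_),
          "cpg_density", cls)
  }
  res[[length(res) + 1]] <-
    run(pq$cpg_total / pq$gc_total, "cpg_density", "all")
  non_gc <- pq$gc_total - pq$gc_Alu
  non_cpg <- pq$cpg_total - pq$cpg_Alu
  share <- ifelse(pq$gc_Alu > 0 & non_gc > 0 & non_cpg > 0,
                  (pq$cpg_Alu / pq$gc_Alu) / (non_cpg / non_gc), NA_real_)
  res[[length(res) + 1]] <- run(share, "cpg_share", "Alu_vs_nonAlu")
  res[[length(res) + 1]] <-
    run(ifelse(pq$cpg_total > 0, pq$meth_total / pq$cpg_total, NA_real_),
        "methylation_density", "all")
  res[[length(res) + 1]] <-
    run(ifelse(pq$cpg_Alu > 0, pq$meth_Alu / pq$cpg_Alu, NA_real_),
        "methylation_density", "Alu")
  dplyr::bind_rows(res)
}

#' Per-pair composition quantities (wide table)
#'
#' One row per bin-pair with per-class and total base, GC, CpG and methylated
#' CpG counts, assembled from an exact per-40kb-bin accounting.
#'
#' @inheritParams composition_vs_frequency
#' @return Tibble aligned with `pairs`.
#' @export
pair_composition <- function(pairs, genome, annotations, cpg_calls) {
  validate_binpairs(pairs)
  bs <- pairs$bin_size[1]
  bins <- dplyr::distinct(tibble::tibble(
    chrom = rep(pairs$chrom, 2),
    start = c(pairs$start_i, pairs$start_j),
    bin_size = bs))
  bc <- bin_composition(genome, annotations, cpg_calls, bins)
  wide <- bc |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("total_len", "gc", "cpg", "meth"),
                       values_fill = 0)
  key <- paste(wide$chrom, wide$start)
  ki <- match(paste(pairs$chrom, pairs$start_i), key)
  kj <- match(paste(pairs$chrom, pairs$start_j), key)
  grab <- function(col) wide[[col]][ki] + wide[[col]][kj]
  out <- tibble::tibble(.rows = nrow(pairs))
  for (cls in origin_classes) {
    out[[paste0("len_", cls)]] <- grab(paste0("total_len_", cls))
    out[[paste0("gc_", cls)]] <- grab(paste0("gc_", cls))
    out[[paste0("cpg_", cls)]] <- grab(paste0("cpg_", cls))
    out[[paste0("meth_", cls)]] <- grab(paste0("meth_", cls))
  }
  out$len_total <- out$len_Alu + out$len_SINE_non_Alu + out$len_non_SINE
  out$gc_total <- out$gc_Alu + out$gc_SINE_non_Alu + out$gc_non_SINE
  out$cpg_total <- out$cpg_Alu + out$cpg_SINE_non_Alu + out$cpg_non_SINE
  out$meth_total <- out$meth_Alu + out$meth_SINE_non_Alu + out$meth_non_SINE
  out
}
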