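# Reference point of a peak/element: summit position if present, else midpoint.
ref_point <- function(x) {
  mid <- floor((x$start + x$end) / 2)
  if ("summit_offset" %in% names(x)) {
    ifelse(is.na(x$summit_offset), mid, x$start + x$summit_offset)
  } else {
    mid
  }
}

#' Keep one locus per gene symbol (the longest)
#'
#' Ties in length are broken by the smaller start coordinate.
#'
#' @param genes Gene locus tibble (`chrom`, `start`, `end`, `strand`, `symbol`,
#'   `tss` list column).
#' @return De-redundanted tibble, input order of first appearance preserved.
#' @export
deredundant_loci <- function(genes) {
  if (nrow(genes) == 0) return(genes)
  len <- genes$end - genes$start
  ord <- order(genes$symbol, -len, genes$start)
  keep <- ord[!duplicated(genes$symbol[ord])]
  genes[sort(keep), , drop = FALSE]
}

#' Call active enhancers from H3K4me1 and H3K27ac peaks
#'
#' Active enhancer regions are the overlapping regions of the two marks:
#' the per-base AND of the two peak masks, merged into maximal disjoint
#' regions.
#'
#' @param me1_peaks,ac_peaks Peak tibbles (narrowPeak columns or plain
#'   intervals).
#' @return Interval tibble of enhancer regions with an `origin` column set to
#'   `NA` (classify with [classify_enhancer_origin()]).
#' @export
call_active_enhancers <- function(me1_peaks, ac_peaks) {
  chroms <- intersect(unique(me1_peaks$chrom), unique(ac_peaks$chrom))
  out <- list()
  for (cm in chroms) {
    a <- IRanges::reduce(to_iranges(me1_peaks[me1_peaks$chrom == cm, ]))
    b <- IRanges::reduce(to_iranges(ac_peaks[ac_peaks$chrom == cm, ]))
    ov <- IRanges::reduce(IRanges::intersect(a, b))
    if (length(ov) > 0) out[[cm]] <- from_iranges(ov, cm)
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else
    genomic_intervals(character(), numeric(), numeric())
  res$origin <- NA_character_
  res
}

#' Call active TSSs from H3K4me3 peaks
#'
#' A TSS is active when at least one H3K4me3 peak overlaps it (point in
#' interval). For a gene with several active TSSs, the TSS overlapped by the
#' most peaks wins; ties go to the larger summed peak signal, then to the
#' 5'-most TSS (smallest coordinate on `+`, largest on `-`). Genes with no
#' active TSS are absent from the result.
#'
#' @param genes De-redundanted gene tibble.
#' @param me3_peaks H3K4me3 peak tibble (needs `signal` for the tie-break;
#'   missing signal counts as 0).
#' @return Tibble with `symbol`, `position`, `n_supporting_peaks`, `strand`.
#' @export
call_active_tss <- function(genes, me3_peaks) {
  empty <- tibble::tibble(symbol = character(), position = numeric(),
                          n_supporting_peaks = integer(), strand = character())
  if (nrow(genes) == 0 || nrow(me3_peaks) == 0) return(empty)
  sig <- if ("signal" %in% names(me3_peaks)) me3_peaks$signal else
    rep(0, nrow(me3_peaks))
  tss <- tidyr::unnest(genes[, c("chrom", "strand", "symbol", "tss")],
                       cols = "tss")
  res <- list()
  for (cm in unique(tss$chrom)) {
    t_cm <- tss[tss$chrom == cm, , drop = FALSE]
    p_cm <- me3_peaks[me3_peaks$chrom == cm, , drop = FALSE]
    s_cm <- sig[me3_peaks$chrom == cm]
    if (nrow(p_cm) == 0) next
    pt <- IRanges::IRanges(t_cm$tss + 1L, width = 1L)
    ov <- IRanges::findOverlaps(pt, to_iranges(p_cm))
    qh <- S4Vectors::queryHits(ov)
    t_cm$n_supporting_peaks <- as.integer(tabulate(qh, nrow(t_cm)))
    t_cm$sum_signal <- 0
    if (length(qh) > 0) {
      agg <- tapply(s_cm[S4Vectors::subjectHits(ov)], qh, sum)
      t_cm$sum_signal[as.integer(names(agg))] <- as.numeric(agg)
    }
    res[[cm]] <- t_cm[t_cm$n_supporting_peaks > 0, , drop = FALSE]
  }
  if (length(res) == 0) return(empty)
  cand <- dplyr::bind_rows(res)
  cand$five_prime_rank <- ifelse(cand$strand == "-", -cand$tss, cand$tss)
  cand |>
    dplyr::group_by(.data$symbol) |>
    dplyr::arrange(dplyr::desc(.data$n_supporting_peaks),
                   dplyr::desc(.data$sum_signal), .data$five_prime_rank,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(symbol = .data$symbol, position = .data$tss,
                     n_supporting_peaks = .data$n_supporting_peaks,
                     strand = .data$strand)
}

#' Count elements in each bin-pair
#'
#' An interval element counts when its midpoint lies in either 40-kb bin; a
#' point element (tibble with `pos` or `position`) counts when it lies in
#' either bin.
#'
#' @param elements Interval tibble, or point tibble with `chrom` and
#'   `pos`/`position`.
#' @param pairs Bin-pair tibble.
#' @return Integer vector of counts, one per pair.
#' @export
count_in_binpair <- function(elements, pairs) {
  validate_binpairs(pairs)
  if (nrow(pairs) == 0) return(integer())
  bs <- pairs$bin_size[1]
  if ("pos" %in% names(elements)) {
    pt <- elements$pos
  } else if ("position" %in% names(elements)) {
    pt <- elements$position
  } else {
    pt <- floor((elements$start + elements$end) / 2)
  }
  if (nrow(elements) == 0) return(integer(nrow(pairs)))
  key <- paste(elements$chrom, floor(pt / bs) * bs)
  tab <- table(key)
  look <- function(k) {
    hit <- match(k, names(tab))
    ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  look(paste(pairs$chrom, pairs$start_i)) + look(paste(pairs$chrom, pairs$start_j))
}

#' Assign genome bins to coverage groups
#'
#' Ranks 40-kb bins by Alu coverage (ties broken by genomic order) and splits
#' them into `k` equal-count groups, the remainder going to the lowest groups;
#' group mean coverages are non-decreasing in group index.
#'
#' @param bins Tibble of genome bins (`chrom`, `start`, `bin_size`).
#' @param alu_annotations Alu interval tibble.
#' @param k Number of groups (default 5).
#' @return List with `bins` (input plus `coverage` and `group`) and
#'   `group_means` tibble (`group`, `mean_coverage`, `n_bins`).
#' @export
group_bins_by_coverage <- function(bins, alu_annotations, k = 5) {
  stopifnot(k >= 2)
  if (nrow(bins) < k) stop("group_bins_by_coverage: fewer bins than groups",
                           call. = FALSE)
  bs <- bins$bin_size[1]
  st <- bin_te_stats(dplyr::mutate(bins, bin_size = bs), alu_annotations)
  bins$coverage <- st$covered[match(paste(bins$chrom, bins$start), st$key)] / bs
  ord <- order(bins$coverage, bins$chrom, bins$start)
  n <- nrow(bins)
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  grp <- rep(seq_len(k), times = sizes)
  bins$group <- integer(n)
  bins$group[ord] <- grp
  gm <- bins |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_coverage = mean(.data$coverage),
                     n_bins = dplyr::n(), .groups = "drop")
  list(bins = bins, group_means = gm)
}

#' Correlate element abundance with Alu-coverage groups
#'
#' x = per-group mean Alu coverage, y = per-group mean element count per bin;
#' Pearson r with a two-sided t p-value on `k - 2` degrees of freedom.
#'
#' @param groups Output of [group_bins_by_coverage()].
#' @param elements Interval or point tibble of elements (enhancers, TSSs).
#' @return A `ci_corr` object.
#' @export
element_coverage_correlation <- function(groups, elements) {
  bins <- groups$bins
  bs <- bins$bin_size[1]
  if (nrow(elements) == 0) stop("no elements", call. = FALSE)
  if ("pos" %in% names(elements)) {
    pt <- elements$pos
  } else if ("position" %in% names(elements)) {
    pt <- elements$position
  } else {
    pt <- floor((elements$start + elements$end) / 2)
  }
  key <- paste(elements$chrom, floor(pt / bs) * bs)
  tab <- table(key)
  hit <- match(paste(bins$chrom, bins$start), names(tab))
  bins$n_elements <- ifelse(is.na(hit), 0, as.numeric(tab[hit]))
  pts <- bins |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(x = mean(.data$coverage), y = mean(.data$n_elements),
                     .groups = "drop")
  if (nrow(pts) < 3) stop("need >= 3 groups", call. = FALSE)
  if (stats::sd(pts$y) == 0) stop("constant element counts", call. = FALSE)
  res <- pearson_rp(pts$x, pts$y)
  structure(list(r = res$r, p = res$p, n = res$n, label = "coverage_groups"),
            class = "ci_corr")
}

#' Classify enhancers as Alu-derived or not
#'
#' An enhancer is Alu-derived when its reference point (summit if present,
#' else midpoint) lies inside any Alu copy.
#'
#' @param enhancers Enhancer/peak tibble.
#' @param alu_annotations Alu interval tibble.
#' @return `enhancers` with `origin` set to `"Alu_derived"` or `"non_Alu"`.
#' @export
classify_enhancer_origin <- function(enhancers, alu_annotations) {
  if (nrow(enhancers) == 0) {
    enhancers$origin <- character(0)
    return(enhancers)
  }
  pt <- ref_point(enhancers)
  inside <- rep(FALSE, nrow(enhancers))
  for (cm in unique(enhancers$chrom)) {
    a <- alu_annotations[alu_annotations$chrom == cm, , drop = FALSE]
    sel <- which(enhancers$chrom == cm)
    if (nrow(a) == 0) next
    hit <- IRanges::findOverlaps(IRanges::IRanges(pt[sel] + 1L, width = 1L),
                                 to_iranges(a), select = "first")
    inside[sel] <- !is.na(hit)
  }
  enhancers$origin <- ifelse(inside, "Alu_derived", "non_Alu")
  enhancers
}

#' Alu coverage in windows flanking elements
#'
#' The window is `[ref - flank, ref + flank)` around each element's reference
#' point, clipped to the chromosome.
#'
#' @param elements Element tibble.
#' @param alu_annotations Alu interval tibble.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param flank Flank size in bases (default 20000, i.e. a 40-kb window).
#' @return `elements` with `window_start`, `window_end`, `alu_coverage` added.
#' @export
flank_coverage <- function(elements, alu_annotations, chrom_lengths,
                           flank = 20000) {
  stopifnot(flank > 0)
  pt <- ref_point(elements)
  ws <- pmax(0, pt - flank)
  we <- pmin(as.numeric(chrom_lengths[elements$chrom]), pt + flank)
  cov <- vapply(seq_len(nrow(elements)), function(i) {
    region_coverage(alu_annotations,
                    list(chrom = elements$chrom[i], start = ws[i], end = we[i]))$fraction
  }, numeric(1))
  elements$window_start <- ws
  elements$window_end <- we
  elements$alu_coverage <- cov
  elements
}

#' Alu coverage of random genome windows
#'
#' Draws `n_windows` seeded uniform windows fully inside chromosomes, the
#' chromosome chosen proportional to its length, and returns each window's
#' Alu coverage fraction.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param alu_annotations Alu interval tibble.
#' @param n_windows Number of windows.
#' @param width Window width (default 40000).
#' @param seed Integer seed (local; the global RNG state is untouched).
#' @return Tibble with `chrom`, `start`, `end`, `coverage`.
#' @export
background_coverage <- function(chrom_lengths, alu_annotations,
                                n_windows = 10000, width = 40000, seed = 1) {
  if (width > max(chrom_lengths)) {
    stop("background_coverage: width exceeds the longest chromosome", call. = FALSE)
  }
  ok <- chrom_lengths >= width
  lens <- chrom_lengths[ok]
  wins <- withr::with_seed(seed, {
    cm <- sample(names(lens), n_windows, replace = TRUE, prob = lens / sum(lens))
    start <- floor(stats::runif(n_windows) * (lens[cm] - width + 1))
    tibble::tibble(chrom = cm, start = start, end = start + width)
  })
  # vectorised coverage per chromosome
  wins$coverage <- 0
  for (cmu in unique(wins$chrom)) {
    a <- alu_annotations[alu_annotations$chrom == cmu, , drop = FALSE]
    sel <- which(wins$chrom == cmu)
    if (nrow(a) == 0) next
    red <- IRanges::reduce(to_iranges(a))
    wr <- IRanges::IRanges(wins$start[sel] + 1L, wins$end[sel])
    ov <- IRanges::findOverlaps(wr, red)
    if (length(ov) > 0) {
      w <- IRanges::width(IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                              red[S4Vectors::subjectHits(ov)]))
      agg <- tapply(w, S4Vectors::queryHits(ov), sum)
      wins$coverage[sel[as.integer(names(agg))]] <- as.numeric(agg) / width
    }
  }
  wins
}

#' Test observed window coverages against a background distribution
#'
#' Binomial route: a success is an observed window whose coverage exceeds the
#' background mean; the null success rate `p0` is the fraction of background
#' windows exceeding their own mean; p is the one-sided binomial tail
#' `P(K >= k | n, p0)`. Permutation cross-check: the fraction of seeded
#' resamples (size n from the background) whose mean is at least the observed
#' mean.
#'
#' @param observed Numeric vector of observed window coverages.
#' @param background Numeric vector of background coverages (non-degenerate).
#' @param n_perm Number of permutation resamples (default 10000).
#' @param seed Seed for the permutation resamples.
#' @return Object of class `ci_enrichtest`: a list with `n_windows`,
#'   `k_above_background`, `background_p0`, `p_value` (binomial),
#'   `p_permutation`, `observed_mean`, `background_mean`, `method`.
#' @export
coverage_enrichment_test <- function(observed, background, n_perm = 10000,
                                     seed = 1) {
  if (length(observed) == 0) stop("coverage_enrichment_test: no observed windows",
                                  call. = FALSE)
  if (stats::sd(background) == 0) {
    stop("coverage_enrichment_test: degenerate background", call. = FALSE)
  }
  bg_mean <- mean(background)
  p0 <- mean(background > bg_mean)
  n <- length(observed)
  k <- sum(observed > bg_mean)
  p_binom <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  obs_mean <- mean(observed)
  p_perm <- withr::with_seed(seed, {
    means <- vapply(seq_len(n_perm),
                    function(i) mean(sample(background, n, replace = TRUE)),
                    numeric(1))
    mean(means >= obs_mean)
  })
  structure(list(
    n_windows = n, k_above_background = k, background_p0 = p0,
    p_value = p_binom, p_permutation = p_perm,
    observed_mean = obs_mean, background_mean = bg_mean,
    method = "binomial"
  ), class = "ci_enrichtest")
}

#' @export
print.ci_enrichtest <- function(x, ...) {
  cat("Coverage enrichment test\n",
      " ", x$k_above_background, "of", x$n_windows,
      "windows above background mean (p0 =", signif(x$background_p0, 3), ")\n",
      "  binomial p =", signif(x$p_value, 3),
      "; permutation p =", signif(x$p_permutation, 3), "\n")
  invisible(x)
}

#' Match two peak sets by reference-point distance
#'
#' Two peaks are the same element when their reference points (summit if
#' present, else midpoint) are mutually nearest and less than `max_dist` apart.
#' One-to-one mutual-nearest matching makes the shared count symmetric and
#' deterministic.
#'
#' @param setA,setB Peak tibbles.
#' @param max_dist Distance threshold in bases (default 250; matching requires
#'   distance strictly below it).
#' @return Tibble with `shared`, `frac_a`, `frac_b`.
#' @export
match_peak_sets <- function(setA, setB, max_dist = 250) {
  if (nrow(setA) == 0 || nrow(setB) == 0) {
    return(tibble::tibble(shared = 0L,
                          frac_a = if (nrow(setA)) 0 else NA_real_,
                          frac_b = if (nrow(setB)) 0 else NA_real_))
  }
  pa <- ref_point(setA); pb <- ref_point(setB)
  shared <- 0L
  for (cm in union(unique(setA$chrom), unique(setB$chrom))) {
    ia <- which(setA$chrom == cm); ib <- which(setB$chrom == cm)
    if (length(ia) == 0 || length(ib) == 0) next
    a <- pa[ia]; b <- pb[ib]
    d <- abs(outer(a, b, "-"))
    nb <- apply(d, 1, which.min)       # nearest b for each a (ties: first)
    na_ <- apply(d, 2, which.min)      # nearest a for each b
    mutual <- which(na_[nb] == seq_along(a) &
                      d[cbind(seq_along(a), nb)] < max_dist)
    shared <- shared + length(mutual)
  }
  tibble::tibble(shared = shared,
                 frac_a = shared / nrow(setA),
                 frac_b = shared / nrow(setB))
}

#' Compare expression of active vs non-active genes
#'
#' Two-sided Mann-Whitney rank-sum test of expression in genes with an active
#' TSS against the rest; direction is the sign of the median difference
#' (active minus non-active).
#'
#' @param expression Tibble with `symbol` and `value`.
#' @param active_symbols Character vector of active gene symbols.
#' @return One-row tibble with `statistic`, `p`, `direction`, `n_active`,
#'   `n_inactive`.
#' @export
compare_active_expression <- function(expression, active_symbols) {
  act <- expression$value[expression$symbol %in% active_symbols]
  ina <- expression$value[!expression$symbol %in% active_symbols]
  if (length(act) == 0 || length(ina) == 0) {
    stop("compare_active_expression: empty group", call. = FALSE)
  }
  wt <- stats::wilcox.test(act, ina, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  tibble::tibble(
    statistic = unname(wt$statistic),
    p = wt$p.value,
    direction = sign(stats::median(act) - stats::median(ina)),
    n_active = length(act),
    n_inactive = length(ina)
  )
}
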