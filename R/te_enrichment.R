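#' Select TE annotation records by family/class selector
#'
#' Selectors: the four classes `"SINE"`, `"LINE"`, `"LTR"`, `"DNA"`; the
#' families `"Alu"`, `"L1"`; `"SINE_non_Alu"` (SINE class minus Alu family);
#' and the Alu subfamily groups `"AluJ"`, `"AluS"`, `"AluY"`.
#'
#' @param annotations TE annotation tibble (from `read_records(..., "rmsk_out")`).
#' @param selector Selector string.
#' @return The matching subset of `annotations`.
#' @export
select_te <- function(annotations, selector) {
  a <- annotations
  switch(selector,
    SINE = , LINE = , LTR = , DNA = a[a$te_class == selector, , drop = FALSE],
    Alu = a[a$family == "Alu", , drop = FALSE],
    L1 = a[a$family == "L1", , drop = FALSE],
    SINE_non_Alu = a[a$te_class == "SINE" & a$family != "Alu", , drop = FALSE],
    AluJ = , AluS = , AluY = {
      alu <- a[a$family == "Alu", , drop = FALSE]
      alu[subfamily_group(alu$subfamily) == selector, , drop = FALSE]
    },
    stop("select_te: unknown selector '", selector, "'", call. = FALSE)
  )
}

#' Genome-wide mean copy length for a selector
#'
#' @inheritParams select_te
#' @return Mean of `end - start` over all matching copies.
#' @export
mean_family_length <- function(annotations, selector) {
  sel <- select_te(annotations, selector)
  if (nrow(sel) == 0) return(NA_real_)
  mean(sel$end - sel$start)
}

# Per-40kb-bin copy count (midpoint rule) and merged covered bases for a
# selector, over the bins referenced by `bins` (tibble chrom, start, bin_size).
bin_te_stats <- function(bins, sel) {
  bs <- bins$bin_size[1]
  key <- paste(bins$chrom, bins$start)
  count <- numeric(nrow(bins))
  covered <- numeric(nrow(bins))
  if (nrow(sel) > 0) {
    mid <- (sel$start + sel$end) / 2
    mkey <- paste(sel$chrom, floor(mid / bs) * bs)
    tab <- table(mkey)
    hit <- match(key, names(tab))
    count <- ifelse(is.na(hit), 0, as.numeric(tab[hit]))
    for (cm in unique(bins$chrom)) {
      bsel <- which(bins$chrom == cm)
      asel <- sel[sel$chrom == cm, , drop = FALSE]
      if (nrow(asel) == 0) next
      red <- IRanges::reduce(to_iranges(asel))
      br <- IRanges::IRanges(bins$start[bsel] + 1L, bins$start[bsel] + bs)
      ov <- IRanges::findOverlaps(br, red)
      if (length(ov) > 0) {
        w <- IRanges::width(IRanges::pintersect(
          br[S4Vectors::queryHits(ov)], red[S4Vectors::subjectHits(ov)]))
        agg <- tapply(w, S4Vectors::queryHits(ov), sum)
        covered[bsel[as.integer(names(agg))]] <- as.numeric(agg)
      }
    }
  }
  tibble::tibble(key = key, count = count, covered = covered)
}

#' Per-bin-pair TE metric
#'
#' Three metrics over the 80-kb pair region:
#' \describe{
#'   \item{coverage}{merged covered bases / (2 x bin_size).}
#'   \item{enrichment_score}{count of copies whose midpoint lies in the region.}
#'   \item{density}{`enrichment_score * mean_family_length / (2 x bin_size)`,
#'     i.e. copy count over the maximum possible number of same-family copies.}
#' }
#'
#' @param pairs Bin-pair tibble.
#' @param annotations TE annotation tibble.
#' @param selector See [select_te()].
#' @param kind One of `"coverage"`, `"density"`, `"enrichment_score"`.
#' @param mean_len Mean copy length for the density normalisation; by default
#'   computed genome-wide from `annotations` for the selector.
#' @return Numeric vector of metric values, one per pair.
#' @export
te_metric <- function(pairs, annotations, selector, kind = "density",
                      mean_len = NULL) {
  kind <- match.arg(kind, c("coverage", "density", "enrichment_score"))
  sel <- select_te(annotations, selector)
  if (is.null(mean_len)) mean_len <- mean_family_length(annotations, selector)
  if (kind == "density" && (is.na(mean_len) || mean_len <= 0)) {
    stop("te_metric: mean family length must be positive for density", call. = FALSE)
  }
  validate_binpairs(pairs)
  if (nrow(pairs) == 0) return(numeric())
  bs <- pairs$bin_size[1]
  bins <- dplyr::distinct(tibble::tibble(
    chrom = rep(pairs$chrom, 2),
    start = c(pairs$start_i, pairs$start_j),
    bin_size = bs
  ))
  st <- bin_te_stats(bins, sel)
  ki <- match(paste(pairs$chrom, pairs$start_i), st$key)
  kj <- match(paste(pairs$chrom, pairs$start_j), st$key)
  count <- st$count[ki] + st$count[kj]
  covered <- st$covered[ki] + st$covered[kj]
  switch(kind,
    coverage = covered / (2 * bs),
    enrichment_score = count,
    density = count * mean_len / (2 * bs)
  )
}

#' Bin pairs by contact frequency and summarise a metric
#'
#' Equal-width bins spanning `[min, max]` of the frequencies; the last bin is
#' right-closed; empty bins are dropped. The per-bin x value is the mean
#' frequency of member pairs (not the bin midpoint) and the y value is the mean
#' metric.
#'
#' @param pairs Bin-pair tibble carrying a metric column.
#' @param metric Name of the metric column (default `"metric"`).
#' @param n_bins Number of frequency bins (>= 2); 50 in the canonical analysis,
#'   20 and 100 for robustness.
#' @return Tibble with `index`, `left`, `right`, `n_pairs`, `mean_frequency`,
#'   `mean_metric`.
#' @export
bin_by_frequency <- function(pairs, metric = "metric", n_bins = 50) {
  stopifnot(n_bins >= 2)
  if (nrow(pairs) < 3) stop("bin_by_frequency: need >= 3 pairs", call. = FALSE)
  f <- pairs$frequency
  if (diff(range(f)) == 0) {
    stop("bin_by_frequency: all frequencies identical, no binning possible",
         call. = FALSE)
  }
  edges <- seq(min(f), max(f), length.out = n_bins + 1)
  idx <- findInterval(f, edges, rightmost.closed = TRUE)
  y <- pairs[[metric]]
  out <- tibble::tibble(index = idx, frequency = f, y = y) |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_frequency = mean(.data$frequency),
      mean_metric = mean(.data$y, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$index)
  out$left <- edges[out$index]
  out$right <- edges[out$index + 1]
  out$mean_metric[is.nan(out$mean_metric)] <- NA_real_
  out[, c("index", "left", "right", "n_pairs", "mean_frequency", "mean_metric")]
}

# Closed-form Pearson r and two-sided t p-value (df = n - 2).
pearson_rp <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Pearson correlation over binned summary points
#'
#' Correlates per-bin mean frequency against per-bin mean metric; significance
#' is a two-sided t test with `n - 2` degrees of freedom, `n` the number of
#' non-empty bins entering the fit.
#'
#' @param bins Output of [bin_by_frequency()] (bins with undefined metric are
#'   dropped).
#' @param label Optional label carried into the result.
#' @return An object of class `ci_corr` with fields `r`, `p`, `n`, `label`.
#'   Use [generics::tidy()] for a one-row tibble.
#' @export
correlate_bins <- function(bins, label = NA_character_) {
  keep <- !is.na(bins$mean_metric)
  x <- bins$mean_frequency[keep]
  y <- bins$mean_metric[keep]
  if (length(x) < 3) stop("correlate_bins: need >= 3 non-empty bins", call. = FALSE)
  if (stats::sd(y) == 0) stop("correlate_bins: constant metric", call. = FALSE)
  res <- pearson_rp(x, y)
  structure(list(r = res$r, p = res$p, n = res$n, label = label),
            class = "ci_corr")
}

#' @export
print.ci_corr <- function(x, ...) {
  cat("Binned Pearson correlation", if (!is.na(x$label)) paste0("[", x$label, "]"),
      "\n  r =", signif(x$r, 3), " p =", signif(x$p, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Compare two correlation coefficients (Fisher z test)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a two-sided
#' normal p-value.
#'
#' @param res1,res2 `ci_corr` objects (or lists with `r` and `n`).
#' @return A one-row tibble with `z` and `p`.
#' @export
compare_correlations <- function(res1, res2) {
  r1 <- res1$r; n1 <- res1$n; r2 <- res2$r; n2 <- res2$n
  if (n1 < 4 || n2 < 4) stop("compare_correlations: need n >= 4", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("compare_correlations: |r| = 1, Fisher transform diverges", call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

profile_selectors <- c("SINE", "LINE", "LTR", "DNA",
                       "Alu", "SINE_non_Alu", "L1", "AluJ", "AluS", "AluY")

#' Correlation profile across TE families and Alu subfamily groups
#'
#' Runs the metric / bin / correlate chain for each of the four TE classes,
#' Alu, SINE/non-Alu, L1 and the three Alu subfamily groups. Selectors with no
#' copies in the annotation are flagged absent rather than reported as zero.
#'
#' @param pairs Retained bin-pair tibble (one stratum).
#' @param annotations TE annotation tibble.
#' @param n_bins Number of frequency bins.
#' @param kind Metric kind, see [te_metric()].
#' @param selectors Selector subset (defaults to the full profile).
#' @return Tibble with `selector`, `kind`, `n_bins`, `absent`, `n`, `r`, `p`.
#' @export
family_profile <- function(pairs, annotations, n_bins = 50, kind = "density",
                           selectors = profile_selectors) {
  purrr::map_dfr(selectors, function(s) {
    sel <- select_te(annotations, s)
    if (nrow(sel) == 0) {
      return(tibble::tibble(selector = s, kind = kind, n_bins = n_bins,
                            absent = TRUE, n = NA_integer_, r = NA_real_,
                            p = NA_real_))
    }
    pairs$metric <- te_metric(pairs, annotations, s, kind = kind)
    bins <- bin_by_frequency(pairs, "metric", n_bins)
    cr <- correlate_bins(bins, label = s)
    tibble::tibble(selector = s, kind = kind, n_bins = n_bins, absent = FALSE,
                   n = cr$n, r = cr$r, p = cr$p)
  })
}
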