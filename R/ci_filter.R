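#' Stratify bin-pairs by topological-domain membership
#'
#' A pair is `intra` when both 40-kb bins are fully contained in one common
#' domain, `non_intra` when both bins are fully contained in domains but not
#' the same one, and `boundary` otherwise (either bin straddles a domain edge
#' or lies outside every domain). Pairs on chromosomes absent from the domain
#' set are classified `boundary` and counted in the `"missing_chrom"`
#' attribute.
#'
#' @param pairs Bin-pair tibble (`chrom`, `start_i`, `start_j`, `frequency`,
#'   `bin_size`).
#' @param domains Domain interval tibble; validated non-overlapping.
#' @return `pairs` with a `stratum` factor column added.
#' @export
classify_binpairs <- function(pairs, domains) {
  validate_domains(domains)
  validate_binpairs(pairs)
  n <- nrow(pairs)
  if (n == 0) {
    pairs$stratum <- factor(character(), levels = c("intra", "non_intra", "boundary"))
    return(pairs)
  }
  # domain index containing a whole bin, NA if none
  bin_domain <- function(chrom, start, bs) {
    idx <- rep(NA_integer_, length(start))
    for (cm in unique(chrom)) {
      d <- domains[domains$chrom == cm, , drop = FALSE]
      sel <- which(chrom == cm)
      if (nrow(d) == 0) next
      ir <- IRanges::IRanges(start[sel] + 1L, start[sel] + bs[sel])
      dr <- IRanges::IRanges(d$start + 1L, d$end)
      hit <- IRanges::findOverlaps(ir, dr, type = "within", select = "first")
      glob <- which(domains$chrom == cm) # global domain row ids
      idx[sel] <- glob[hit]
    }
    idx
  }
  di <- bin_domain(pairs$chrom, pairs$start_i, pairs$bin_size)
  dj <- bin_domain(pairs$chrom, pairs$start_j, pairs$bin_size)
  stratum <- dplyr::case_when(
    is.na(di) | is.na(dj) ~ "boundary",
    di == dj ~ "intra",
    TRUE ~ "non_intra"
  )
  missing_chrom <- sum(!pairs$chrom %in% domains$chrom)
  pairs$stratum <- factor(stratum, levels = c("intra", "non_intra", "boundary"))
  attr(pairs, "missing_chrom") <- missing_chrom
  pairs
}

#' Mean inter-domain contact frequency (the lower threshold)
#'
#' The arithmetic mean frequency of the non-intra-domain stratum; used as the
#' lower retention threshold for intra-domain pairs on the assumption that
#' inter-domain contacts are background noise.
#'
#' @param pairs Bin-pair tibble (the non-intra stratum).
#' @return A single numeric threshold.
#' @export
mean_interdomain_frequency <- function(pairs) {
  if (nrow(pairs) == 0) {
    stop("mean_interdomain_frequency: empty stratum, no threshold derivable",
         call. = FALSE)
  }
  mean(pairs$frequency)
}

#' Detect the upper frequency threshold (first empty window)
#'
#' Scans integer-aligned windows `[k, k + step)` upward from
#' `floor(min(frequency))` and returns the left edge of the first window that
#' contains no frequencies. If no empty window exists below the maximum, the
#' value `floor(max) + step` (just past the occupied range) is returned.
#'
#' @param frequencies Numeric vector of intra-domain frequencies.
#' @param step Window width (default 1).
#' @return The upper threshold.
#' @export
detect_upper_threshold <- function(frequencies, step = 1) {
  if (length(frequencies) == 0) stop("detect_upper_threshold: empty input", call. = FALSE)
  stopifnot(step > 0)
  k <- floor(min(frequencies))
  top <- max(frequencies)
  while (k <= top) {
    if (!any(frequencies >= k & frequencies < k + step)) return(k)
    k <- k + step
  }
  floor(top) + step
}

#' Filter intra-domain pairs by the lower/upper thresholds
#'
#' Retains pairs with `lower <= frequency < upper`. The high-side removal
#' fraction is reported relative to "valid" pairs, i.e. those surviving the
#' lower threshold.
#'
#' @param pairs Bin-pair tibble (intra stratum).
#' @param lower,upper Frequency thresholds with `lower < upper`.
#' @return A list with `retained` (tibble), `removed_low_count`,
#'   `removed_high_count`, `removed_high_fraction_of_valid`, `lower`, `upper`.
#' @export
filter_binpairs <- function(pairs, lower, upper) {
  if (lower >= upper) stop("filter_binpairs: need lower < upper", call. = FALSE)
  low <- pairs$frequency < lower
  valid <- !low
  high <- valid & pairs$frequency >= upper
  retained <- pairs[valid & !high, , drop = FALSE]
  list(
    retained = retained,
    removed_low_count = sum(low),
    removed_high_count = sum(high),
    removed_high_fraction_of_valid = if (sum(valid) > 0) sum(high) / sum(valid) else NA_real_,
    lower = lower,
    upper = upper
  )
}

#' Stratify and threshold bin-pairs in one step
#'
#' Runs [classify_binpairs()], derives the lower threshold from the non-intra
#' stratum and the upper threshold from the intra stratum, and filters the
#' intra stratum. The same thresholds are applied to the non-intra stratum so
#' both strata run through identical downstream code.
#'
#' @param pairs Bin-pair tibble.
#' @param domains Domain tibble.
#' @param step Window width for [detect_upper_threshold()].
#' @return A list with `intra`, `non_intra` (threshold-filtered tibbles),
#'   `boundary`, `lower_threshold`, `upper_threshold`, `removed_low_count`,
#'   `removed_high_count`, `removed_high_fraction_of_valid`.
#' @export
stratify_and_filter <- function(pairs, domains, step = 1) {
  cls <- classify_binpairs(pairs, domains)
  intra <- cls[cls$stratum == "intra", , drop = FALSE]
  non_intra <- cls[cls$stratum == "non_intra", , drop = FALSE]
  boundary <- cls[cls$stratum == "boundary", , drop = FALSE]
  lower <- mean_interdomain_frequency(non_intra)
  upper <- detect_upper_threshold(intra$frequency, step = step)
  flt <- filter_binpairs(intra, lower, upper)
  nflt <- filter_binpairs(non_intra, lower, upper)
  list(
    intra = flt$retained,
    non_intra = nflt$retained,
    boundary = boundary,
    lower_threshold = lower,
    upper_threshold = upper,
    removed_low_count = flt$removed_low_count,
    removed_high_count = flt$removed_high_count,
    removed_high_fraction_of_valid = flt$removed_high_fraction_of_valid
  )
}
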