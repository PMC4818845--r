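#' Construct a tibble of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)` everywhere in this package;
#' readers for 1-based dialects (RepeatMasker `.out`) convert on the way in.
#'
#' @param chrom Chromosome identifiers (non-empty strings).
#' @param start,end Integer base offsets with `0 <= start < end`.
#' @param strand Optional strand in `{"+", "-", "*"}` (`"*"` = unknown).
#' @param name Optional labels.
#' @param score Optional numeric scores.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`,
#'   `score`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NA_character_,
                              score = NA_real_) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    name = as.character(name),
    score = as.numeric(score)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop(what, ": chrom must be non-empty", call. = FALSE)
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(what, ": need 0 <= start < end (first offender at row ", bad[1], ")",
         call. = FALSE)
  }
  invisible(x)
}

# IRanges on a single-chromosome tibble (shift to 1-based closed internally).
to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

from_iranges <- function(ir, chrom) {
  tibble::tibble(
    chrom = chrom,
    start = as.numeric(IRanges::start(ir)) - 1,
    end = as.numeric(IRanges::end(ir)),
    strand = "*",
    name = NA_character_,
    score = NA_real_
  )
}

#' Merge intervals on one chromosome into a disjoint sorted set
#'
#' Overlapping and abutting intervals are merged; the output covers exactly the
#' union of input bases. Counting operations elsewhere in the package always use
#' raw records, never merged ones.
#'
#' @param intervals Interval tibble, all rows on a single chromosome.
#' @return Tibble of disjoint, sorted intervals.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  chroms <- unique(intervals$chrom)
  if (length(chroms) > 1) {
    stop("merge_intervals: intervals span multiple chromosomes: ",
         paste(chroms, collapse = ", "), call. = FALSE)
  }
  validate_intervals(intervals)
  red <- IRanges::reduce(to_iranges(intervals))
  from_iranges(red, chroms)
}

#' Bases of a region covered by a set of intervals
#'
#' Coverage is computed on the merged union, so overlapping records are not
#' double counted.
#'
#' @param intervals Interval tibble (any chromosomes; only rows matching the
#'   region's chromosome contribute).
#' @param region A single-row interval tibble (or list with `chrom`, `start`,
#'   `end`).
#' @return A one-row tibble with `bases` covered and `fraction` of the region.
#' @export
region_coverage <- function(intervals, region) {
  region <- as.list(region)
  len <- region$end - region$start
  stopifnot(len > 0)
  if (nrow(intervals) == 0) {
    return(tibble::tibble(bases = 0, fraction = 0))
  }
  keep <- intervals[intervals$chrom == region$chrom, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble::tibble(bases = 0, fraction = 0))
  }
  red <- IRanges::reduce(to_iranges(keep))
  reg <- IRanges::IRanges(region$start + 1L, region$end)
  bases <- sum(IRanges::width(IRanges::intersect(red, reg)))
  tibble::tibble(bases = as.numeric(bases), fraction = bases / len)
}

#' The two 40-kb intervals of a bin-pair
#'
#' @param pair A one-row bin-pair tibble (or list) with `chrom`, `start_i`,
#'   `start_j`, `bin_size`.
#' @return A two-row interval tibble. Self pairs (`start_i == start_j`) are
#'   rejected: the density normalisation assumes an 80-kb pair region.
#' @export
binpair_region <- function(pair) {
  pair <- as.list(pair)
  bs <- if (is.null(pair$bin_size)) 40000 else pair$bin_size
  if (pair$start_i == pair$start_j) {
    stop("binpair_region: self pair (start_i == start_j) is not a valid bin-pair",
         call. = FALSE)
  }
  if (pair$start_i > pair$start_j) {
    stop("binpair_region: start_i must be < start_j", call. = FALSE)
  }
  genomic_intervals(
    chrom = rep(pair$chrom, 2),
    start = c(pair$start_i, pair$start_j),
    end = c(pair$start_i + bs, pair$start_j + bs)
  )
}

#' Assign an Alu repeat name to its subfamily group
#'
#' Longest-prefix match on AluJ / AluS / AluY; anything else (FLAM, MIR, ...)
#' maps to `"other"`.
#'
#' @param subfamily Character vector of repeat names (e.g. `"AluYb8"`).
#' @return Character vector in `{"AluJ", "AluS", "AluY", "other"}`.
#' @export
subfamily_group <- function(subfamily) {
  stopifnot(all(nzchar(subfamily)))
  out <- rep("other", length(subfamily))
  out[startsWith(subfamily, "AluJ")] <- "AluJ"
  out[startsWith(subfamily, "AluS")] <- "AluS"
  out[startsWith(subfamily, "AluY")] <- "AluY"
  out
}

#' Validate a topological-domain set
#'
#' Domains on one chromosome must be pairwise non-overlapping.
#' @param domains Interval tibble of domains.
#' @return The input, invisibly; errors on overlap.
#' @export
validate_domains <- function(domains) {
  validate_intervals(domains, "domain")
  by_chrom <- split(domains, domains$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("validate_domains: overlapping domains on ", d$chrom[1], call. = FALSE)
    }
  }
  invisible(domains)
}
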