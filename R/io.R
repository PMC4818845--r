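#' Read typed genomic records from one of the pipeline's file dialects
#'
#' Supported dialects:
#' \describe{
#'   \item{bed, domain_bed}{BED3/BED6, 0-based half-open.}
#'   \item{narrowPeak}{10-column ENCODE narrowPeak; column 10 is the summit
#'     offset from `start` (`-1` = unknown, returned as `NA`).}
#'   \item{rmsk_out}{RepeatMasker `.out` (15 columns, whitespace-delimited, 3
#'     header lines). 1-based inclusive coordinates are converted to 0-based
#'     half-open. Records whose class is outside SINE/LINE/LTR/DNA (uncertain
#'     categories) are skipped; the skipped count is attached as attribute
#'     `"skipped"` and reported with a message.}
#'   \item{binpair_tsv}{Tab-delimited `chrom, start_i, start_j, frequency`;
#'     `#` comments.}
#'   \item{cpg_tsv}{Tab-delimited `chrom, pos, methylated` with methylated in
#'     `{0,1}`; a site present in the file is a CpG site.}
#'   \item{genes_tsv}{Tab-delimited `chrom, start, end, strand, symbol, tss`
#'     with `tss` a comma-separated list of TSS coordinates.}
#' }
#'
#' @param path File path.
#' @param dialect One of `"bed"`, `"narrowPeak"`, `"rmsk_out"`,
#'   `"binpair_tsv"`, `"domain_bed"`, `"cpg_tsv"`, `"genes_tsv"`.
#' @param bin_size Bin size attached to bin-pair records (default 40000).
#' @return A tibble of typed records; order is preserved.
#' @export
read_records <- function(path, dialect, bin_size = 40000) {
  dialect <- match.arg(dialect, c("bed", "narrowPeak", "rmsk_out", "binpair_tsv",
                                  "domain_bed", "cpg_tsv", "genes_tsv"))
  if (!file.exists(path)) stop("read_records: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  switch(dialect,
    bed = parse_bed(lines),
    domain_bed = parse_bed(lines),
    narrowPeak = parse_narrowpeak(lines),
    rmsk_out = parse_rmsk(lines),
    binpair_tsv = parse_binpairs(lines, bin_size),
    cpg_tsv = parse_cpg(lines),
    genes_tsv = parse_genes(lines)
  )
}

line_fail <- function(i, msg) {
  stop("malformed line ", i, ": ", msg, call. = FALSE)
}

data_lines <- function(lines, skip = 0) {
  idx <- seq_along(lines)
  if (skip > 0) idx <- idx[-seq_len(min(skip, length(idx)))]
  keep <- idx[!startsWith(trimws(lines[idx]), "#") & nzchar(trimws(lines[idx]))]
  keep
}

num_or_fail <- function(x, i, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) line_fail(i[which(is.na(v))[1]], paste("non-numeric", what))
  v
}

parse_bed <- function(lines) {
  idx <- data_lines(lines)
  if (length(idx) == 0) return(genomic_intervals(character(), numeric(), numeric()))
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3)) line_fail(idx[which(nf < 3)[1]], "BED needs >= 3 fields")
  chrom <- vapply(parts, `[`, "", 1)
  start <- num_or_fail(vapply(parts, `[`, "", 2), idx, "start")
  end <- num_or_fail(vapply(parts, `[`, "", 3), idx, "end")
  name <- ifelse(nf >= 4, vapply(parts, function(p) p[4], ""), ".")
  score <- ifelse(nf >= 5, vapply(parts, function(p) p[min(5, length(p))], ""), ".")
  strand <- ifelse(nf >= 6, vapply(parts, function(p) p[min(6, length(p))], ""), ".")
  x <- tibble::tibble(
    chrom = chrom, start = start, end = end,
    strand = ifelse(strand %in% c("+", "-"), strand, "*"),
    name = ifelse(name == ".", NA_character_, name),
    score = suppressWarnings(as.numeric(ifelse(score == ".", NA, score)))
  )
  validate_intervals(x, "bed")
  x
}

parse_narrowpeak <- function(lines) {
  idx <- data_lines(lines)
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character(),
    signal = numeric(), pvalue = numeric(), qvalue = numeric(),
    summit_offset = numeric()
  )
  if (length(idx) == 0) return(empty)
  parts <- strsplit(trimws(lines[idx]), "\t")
  nf <- lengths(parts)
  if (any(nf != 10)) line_fail(idx[which(nf != 10)[1]], "narrowPeak needs 10 fields")
  m <- do.call(rbind, parts)
  x <- tibble::tibble(
    chrom = m[, 1],
    start = num_or_fail(m[, 2], idx, "start"),
    end = num_or_fail(m[, 3], idx, "end"),
    name = ifelse(m[, 4] == ".", NA_character_, m[, 4]),
    score = num_or_fail(m[, 5], idx, "score"),
    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"),
    signal = num_or_fail(m[, 7], idx, "signal"),
    pvalue = num_or_fail(m[, 8], idx, "pvalue"),
    qvalue = num_or_fail(m[, 9], idx, "qvalue"),
    summit_offset = num_or_fail(m[, 10], idx, "summit")
  )
  x$summit_offset[x$summit_offset < 0] <- NA_real_
  bad <- which(!is.na(x$summit_offset) &
                 (x$summit_offset < 0 | x$summit_offset >= x$end - x$start))
  if (length(bad) > 0) line_fail(idx[bad[1]], "summit offset outside peak")
  validate_intervals(x, "narrowPeak")
  x
}

te_classes <- c("SINE", "LINE", "LTR", "DNA")

parse_rmsk <- function(lines) {
  idx <- data_lines(lines, skip = 3)
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(), strand = character(),
    subfamily = character(), te_class = character(), family = character(),
    divergence = numeric()
  )
  attr(empty, "skipped") <- 0L
  if (length(idx) == 0) return(empty)
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 15)) line_fail(idx[which(nf < 15)[1]], "RepeatMasker .out needs 15 fields")
  m <- do.call(rbind, lapply(parts, `[`, 1:15))
  cls_fam <- strsplit(m[, 11], "/", fixed = TRUE)
  te_class <- vapply(cls_fam, `[`, "", 1)
  family <- vapply(cls_fam, function(p) if (length(p) >= 2) p[2] else p[1], "")
  keep <- te_class %in% te_classes
  skipped <- sum(!keep)
  if (skipped > 0) {
    message("read_records: skipped ", skipped,
            " repeat record(s) with uncertain class")
  }
  m <- m[keep, , drop = FALSE]
  idx <- idx[keep]
  x <- tibble::tibble(
    chrom = m[, 5],
    start = num_or_fail(m[, 6], idx, "begin") - 1, # 1-based inclusive -> half-open
    end = num_or_fail(m[, 7], idx, "end"),
    strand = ifelse(m[, 9] == "C", "-", "+"),
    subfamily = m[, 10],
    te_class = te_class[keep],
    family = family[keep],
    divergence = num_or_fail(m[, 2], idx, "divergence")
  )
  validate_intervals(x, "rmsk")
  attr(x, "skipped") <- as.integer(skipped)
  x
}

parse_binpairs <- function(lines, bin_size) {
  idx <- data_lines(lines)
  empty <- tibble::tibble(chrom = character(), start_i = numeric(),
                          start_j = numeric(), frequency = numeric(),
                          bin_size = numeric())
  if (length(idx) == 0) return(empty)
  parts <- strsplit(trimws(lines[idx]), "\t")
  nf <- lengths(parts)
  if (any(nf != 4)) line_fail(idx[which(nf != 4)[1]], "bin-pair line needs 4 fields")
  m <- do.call(rbind, parts)
  x <- tibble::tibble(
    chrom = m[, 1],
    start_i = num_or_fail(m[, 2], idx, "start_i"),
    start_j = num_or_fail(m[, 3], idx, "start_j"),
    frequency = num_or_fail(m[, 4], idx, "frequency"),
    bin_size = bin_size
  )
  validate_binpairs(x)
  x
}

#' @keywords internal
validate_binpairs <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bs <- x$bin_size
  if (any(x$start_i %% bs != 0 | x$start_j %% bs != 0)) {
    stop("bin-pair starts must be multiples of bin_size", call. = FALSE)
  }
  if (any(x$start_i >= x$start_j)) {
    stop("bin-pairs need start_i < start_j (self pairs are excluded)", call. = FALSE)
  }
  if (any(x$frequency < 0)) stop("bin-pair frequency must be >= 0", call. = FALSE)
  invisible(x)
}

parse_cpg <- function(lines) {
  idx <- data_lines(lines)
  empty <- tibble::tibble(chrom = character(), pos = numeric(), methylated = logical())
  if (length(idx) == 0) return(empty)
  parts <- strsplit(trimws(lines[idx]), "\t")
  nf <- lengths(parts)
  if (any(nf != 3)) line_fail(idx[which(nf != 3)[1]], "CpG line needs 3 fields")
  m <- do.call(rbind, parts)
  meth <- m[, 3]
  if (any(!meth %in% c("0", "1"))) {
    line_fail(idx[which(!meth %in% c("0", "1"))[1]], "methylated must be 0 or 1")
  }
  x <- tibble::tibble(
    chrom = m[, 1],
    pos = num_or_fail(m[, 2], idx, "pos"),
    methylated = meth == "1"
  )
  if (any(x$pos < 0)) line_fail(idx[which(x$pos < 0)[1]], "negative position")
  if (anyDuplicated(paste(x$chrom, x$pos))) {
    stop("cpg_tsv: duplicate (chrom, pos) record", call. = FALSE)
  }
  x
}

parse_genes <- function(lines) {
  idx <- data_lines(lines)
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          strand = character(), symbol = character(), tss = list())
  if (length(idx) == 0) return(empty)
  parts <- strsplit(trimws(lines[idx]), "\t")
  nf <- lengths(parts)
  if (any(nf != 6)) line_fail(idx[which(nf != 6)[1]], "gene line needs 6 fields")
  m <- do.call(rbind, parts)
  if (any(!m[, 4] %in% c("+", "-"))) {
    line_fail(idx[which(!m[, 4] %in% c("+", "-"))[1]], "gene strand must be + or -")
  }
  tss <- lapply(strsplit(m[, 6], ",", fixed = TRUE), as.numeric)
  x <- tibble::tibble(
    chrom = m[, 1],
    start = num_or_fail(m[, 2], idx, "start"),
    end = num_or_fail(m[, 3], idx, "end"),
    strand = m[, 4],
    symbol = m[, 5],
    tss = tss
  )
  validate_intervals(x, "gene")
  bad <- which(vapply(seq_len(nrow(x)), function(i) {
    any(is.na(x$tss[[i]])) || any(x$tss[[i]] < x$start[i] | x$tss[[i]] > x$end[i])
  }, TRUE))
  if (length(bad) > 0) line_fail(idx[bad[1]], "TSS outside gene locus")
  x
}

#' Write typed genomic records to a file dialect
#'
#' Round trip contract: `read_records(write_records(x, path, d), d)` reproduces
#' `x` field-for-field for every dialect.
#'
#' @param records A tibble of records matching the dialect's type.
#' @param path Output path.
#' @param dialect See [read_records()].
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, dialect) {
  dialect <- match.arg(dialect, c("bed", "narrowPeak", "rmsk_out", "binpair_tsv",
                                  "domain_bed", "cpg_tsv", "genes_tsv"))
  lines <- switch(dialect,
    bed = format_bed(records),
    domain_bed = format_bed(records),
    narrowPeak = format_narrowpeak(records),
    rmsk_out = format_rmsk(records),
    binpair_tsv = format_binpairs(records),
    cpg_tsv = format_cpg(records),
    genes_tsv = format_genes(records)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_records: cannot write ", path, call. = FALSE)
  invisible(path)
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

format_bed <- function(x) {
  header <- "# chrom\tstart\tend[\tname\tscore\tstrand]"
  if (nrow(x) == 0) return(header)
  bed3 <- all(is.na(x$name)) && all(is.na(x$score)) && all(x$strand == "*")
  if (bed3) {
    body <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end), sep = "\t")
  } else {
    body <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                  ifelse(is.na(x$name), ".", x$name),
                  ifelse(is.na(x$score), ".", fmt_num(x$score)),
                  ifelse(x$strand == "*", ".", x$strand), sep = "\t")
  }
  c(header, body)
}

format_narrowpeak <- function(x) {
  header <- "# narrowPeak: chrom start end name score strand signal pvalue qvalue summit"
  if (nrow(x) == 0) return(header)
  body <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                ifelse(is.na(x$name), ".", x$name), fmt_num(x$score),
                ifelse(x$strand == "*", ".", x$strand),
                fmt_num(x$signal), fmt_num(x$pvalue), fmt_num(x$qvalue),
                fmt_num(ifelse(is.na(x$summit_offset), -1, x$summit_offset)),
                sep = "\t")
  c(header, body)
}

format_rmsk <- function(x) {
  header <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)   repeat    class/family  begin  end  (left)  ID",
    ""
  )
  if (nrow(x) == 0) return(header)
  fam <- ifelse(is.na(x$family) | x$family == x$te_class | x$family == "",
                x$te_class, paste0(x$te_class, "/", x$family))
  body <- paste(
    "1000", fmt_num(ifelse(is.na(x$divergence), 0, x$divergence)), "0.0", "0.0",
    x$chrom, fmt_num(x$start + 1), fmt_num(x$end), "(0)",
    ifelse(x$strand == "-", "C", "+"), x$subfamily, fam,
    "1", fmt_num(x$end - x$start), "(0)", seq_len(nrow(x))
  )
  c(header, body)
}

format_binpairs <- function(x) {
  header <- "# chrom\tstart_i\tstart_j\tfrequency"
  if (nrow(x) == 0) return(header)
  c(header, paste(x$chrom, fmt_num(x$start_i), fmt_num(x$start_j),
                  fmt_num(x$frequency), sep = "\t"))
}

format_cpg <- function(x) {
  header <- "# chrom\tpos\tmethylated"
  if (nrow(x) == 0) return(header)
  c(header, paste(x$chrom, fmt_num(x$pos), as.integer(x$methylated), sep = "\t"))
}

format_genes <- function(x) {
  header <- "# chrom\tstart\tend\tstrand\tsymbol\ttss"
  if (nrow(x) == 0) return(header)
  tss <- vapply(x$tss, function(v) paste(fmt_num(v), collapse = ","), "")
  c(header, paste(x$chrom, fmt_num(x$start), fmt_num(x$end), x$strand,
                  x$symbol, tss, sep = "\t"))
}
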