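#' Load a bundle of analysis inputs from disk
#'
#' @param paths Named list/vector with elements `genome`, `domains`,
#'   `binpairs`, `repeats`, `cpg`, `h3k4me1`, `h3k27ac`, `h3k4me3`, `genes`
#'   (any subset; missing elements are left `NULL`).
#' @return A bundle list as produced by [sim_bundle()].
#' @export
load_bundle <- function(paths) {
  paths <- as.list(paths)
  grab <- function(nm, dialect) {
    if (is.null(paths[[nm]])) return(NULL)
    read_records(paths[[nm]], dialect)
  }
  genome <- NULL
  if (!is.null(paths$genome)) {
    genome <- Biostrings::readDNAStringSet(paths$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  peaks <- list(h3k4me1 = grab("h3k4me1", "narrowPeak"),
                h3k27ac = grab("h3k27ac", "narrowPeak"),
                h3k4me3 = grab("h3k4me3", "narrowPeak"))
  list(
    chrom_lengths = if (!is.null(genome)) {
      stats::setNames(Biostrings::width(genome), names(genome))
    } else NULL,
    domains = grab("domains", "domain_bed"),
    binpairs = grab("binpairs", "binpair_tsv"),
    repeats = grab("repeats", "rmsk_out"),
    genome = genome,
    cpg = grab("cpg", "cpg_tsv"),
    genes = grab("genes", "genes_tsv"),
    peaks = peaks,
    truth = if (!is.null(paths$truth) && file.exists(paths$truth)) {
      jsonlite::read_json(paths$truth, simplifyVector = FALSE)
    } else NULL
  )
}

#' Check cross-file consistency of an input bundle
#'
#' Verifies, without aborting: every CpG call sits on a CG dinucleotide in the
#' genome; domains align to the bin grid and lie within their chromosome;
#' TE records lie within their chromosome; bin-pair starts are on the grid and
#' within bounds. Unknown chromosomes are reported as violations.
#'
#' @param bundle A bundle list (from [sim_bundle()] or [load_bundle()]).
#' @param bin_size Bin size for grid checks (taken from the bin-pairs when
#'   present).
#' @return Tibble of violations (`check`, `chrom`, `detail`); zero rows means
#'   a consistent bundle.
#' @export
validate_bundle <- function(bundle, bin_size = NULL) {
  v <- list()
  flag <- function(check, chrom, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(check = check, chrom = chrom,
                                          detail = detail)
  }
  lens <- bundle$chrom_lengths
  if (is.null(lens) && !is.null(bundle$genome)) {
    lens <- stats::setNames(Biostrings::width(bundle$genome),
                            names(bundle$genome))
  }
  if (is.null(bin_size) && !is.null(bundle$binpairs) &&
      nrow(bundle$binpairs) > 0) {
    bin_size <- bundle$binpairs$bin_size[1]
  }
  in_bounds <- function(d, what) {
    for (cm in unique(d$chrom)) {
      if (is.null(lens)) break
      if (!cm %in% names(lens)) {
        flag(what, cm, "chromosome absent from genome")
        next
      }
      n_out <- sum(d$end[d$chrom == cm] > lens[[cm]])
      if (n_out > 0) flag(what, cm, paste(n_out, "record(s) beyond chromosome end"))
    }
  }
  if (!is.null(bundle$repeats)) in_bounds(bundle$repeats, "te_within_chrom")
  if (!is.null(bundle$domains)) {
    in_bounds(bundle$domains, "domain_within_chrom")
    if (!is.null(bin_size)) {
      off <- bundle$domains$start %% bin_size != 0 |
        bundle$domains$end %% bin_size != 0
      if (any(off)) {
        flag("domain_grid", bundle$domains$chrom[which(off)[1]],
             paste(sum(off), "domain(s) off the bin grid"))
      }
    }
  }
  if (!is.null(bundle$binpairs) && !is.null(lens) && nrow(bundle$binpairs) > 0) {
    bp <- bundle$binpairs
    for (cm in unique(bp$chrom)) {
      if (!cm %in% names(lens)) { flag("binpair_chrom", cm, "unknown chromosome"); next }
      n_out <- sum(bp$start_j[bp$chrom == cm] + bp$bin_size[1] > lens[[cm]])
      if (n_out > 0) flag("binpair_bounds", cm, paste(n_out, "pair(s) out of bounds"))
    }
  }
  if (!is.null(bundle$cpg) && !is.null(bundle$genome) && nrow(bundle$cpg) > 0) {
    for (cm in unique(bundle$cpg$chrom)) {
      if (!cm %in% names(bundle$genome)) {
        flag("cpg_chrom", cm, "chromosome absent from genome")
        next
      }
      pos <- bundle$cpg$pos[bundle$cpg$chrom == cm]
      seq <- bundle$genome[[cm]]
      ok <- pos + 2 <= length(seq)
      if (any(!ok)) flag("cpg_bounds", cm, paste(sum(!ok), "site(s) out of bounds"))
      din <- as.character(Biostrings::Views(seq,
        IRanges::IRanges(pos[ok] + 1L, pos[ok] + 2L)))
      bad <- which(din != "CG")
      if (length(bad) > 0) {
        flag("cpg_is_cg", cm,
             paste0(length(bad), " site(s) not CG; first at pos ",
                    pos[ok][bad[1]]))
      }
    }
  }
  if (length(v) == 0) {
    return(tibble::tibble(check = character(), chrom = character(),
                          detail = character()))
  }
  dplyr::bind_rows(v)
}

#' Run the full analysis end to end
#'
#' Stages, in order: simulate or load the bundle, validate it, stratify and
#' threshold the bin-pairs, TE family/subfamily correlation profiles for the
#' requested strata, origin-partitioned sequence-composition correlations,
#' per-subfamily methylation, and the regulatory-element analyses (enhancer
#' and active-TSS calling, count-vs-frequency correlations, Alu-coverage
#' grouping, and the Alu-coverage enrichment test for Alu-derived enhancers).
#'
#' @param sim A `sim_config` to generate inputs from, or `NULL` when `paths`
#'   is given.
#' @param paths Named list of input files (see [load_bundle()]); ignored when
#'   `sim` is given.
#' @param n_bins Frequency bins (50 canonical; 20/100 for robustness).
#' @param kind TE metric kind.
#' @param strata Strata to profile (subset of `c("intra", "non_intra")`).
#' @param flank Flank for enhancer-window coverage (default 20000).
#' @param groups Number of Alu-coverage groups (default 5).
#' @param n_background Background windows for the enrichment test.
#' @param seed Seed for background sampling / permutation.
#' @param out_dir Optional directory for the JSON report.
#' @return A run-report list.
#' @export
run_all <- function(sim = NULL, paths = NULL, n_bins = 50, kind = "density",
                    strata = c("intra", "non_intra"), flank = 20000,
                    groups = 5, n_background = 2000, seed = 1, out_dir = NULL) {
  if (is.null(sim) && is.null(paths)) {
    stop("run_all: provide either a sim config or input paths", call. = FALSE)
  }
  if (!is.null(paths)) {
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing) > 0) {
      stop("run_all: missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  bundle <- if (!is.null(sim)) sim_bundle(sim, sequence = TRUE) else
    load_bundle(paths)
  violations <- validate_bundle(bundle)

  strat <- stratify_and_filter(bundle$binpairs, bundle$domains)
  profiles <- purrr::map_dfr(strata, function(s) {
    dplyr::mutate(family_profile(strat[[s]], bundle$repeats, n_bins, kind),
                  stratum = s)
  })
  composition <- NULL; subfam_meth <- NULL
  if (!is.null(bundle$genome) && !is.null(bundle$cpg)) {
    composition <- composition_vs_frequency(strat$intra, bundle$genome,
                                            bundle$repeats, bundle$cpg, n_bins)
    subfam_meth <- subfamily_methylation(bundle$cpg, bundle$repeats)
  }

  regulatory <- NULL
  if (!is.null(bundle$peaks$h3k4me1) && !is.null(bundle$peaks$h3k27ac)) {
    enh <- call_active_enhancers(bundle$peaks$h3k4me1, bundle$peaks$h3k27ac)
    alu <- bundle$repeats[bundle$repeats$family == "Alu", , drop = FALSE]
    enh <- classify_enhancer_origin(enh, alu)
    pr <- strat$intra
    pr$metric <- count_in_binpair(enh, pr)
    enh_corr <- correlate_bins(bin_by_frequency(pr, "metric", n_bins),
                               label = "enhancers")
    tss <- NULL; tss_corr <- NULL
    if (!is.null(bundle$genes) && !is.null(bundle$peaks$h3k4me3)) {
      tss <- call_active_tss(deredundant_loci(bundle$genes),
                             bundle$peaks$h3k4me3)
      tss$chrom <- bundle$genes$chrom[match(tss$symbol, bundle$genes$symbol)]
      pr$metric <- count_in_binpair(tss, pr)
      tss_corr <- correlate_bins(bin_by_frequency(pr, "metric", n_bins),
                                 label = "active_tss")
    }
    lens <- bundle$chrom_lengths
    bs <- bundle$binpairs$bin_size[1]
    all_bins <- purrr::map_dfr(names(lens), function(cm) {
      tibble::tibble(chrom = cm,
                     start = seq(0, floor(lens[[cm]] / bs) * bs - bs, by = bs),
                     bin_size = bs)
    })
    grp <- group_bins_by_coverage(all_bins, alu, k = groups)
    cov_corr_enh <- element_coverage_correlation(grp, enh)
    cov_corr_tss <- if (!is.null(tss)) element_coverage_correlation(grp, tss)
                    else NULL
    bg <- background_coverage(lens, alu, n_windows = n_background,
                              width = 2 * flank, seed = seed)
    alu_enh <- enh[enh$origin == "Alu_derived", , drop = FALSE]
    enrich <- NULL
    if (nrow(alu_enh) > 0) {
      fc <- flank_coverage(alu_enh, alu, lens, flank = flank)
      enrich <- coverage_enrichment_test(fc$alu_coverage, bg$coverage,
                                         seed = seed)
    }
    regulatory <- list(
      enhancers = enh, active_tss = tss,
      enhancer_frequency_corr = enh_corr, tss_frequency_corr = tss_corr,
      coverage_groups = grp$group_means,
      enhancer_coverage_corr = cov_corr_enh, tss_coverage_corr = cov_corr_tss,
      alu_enhancer_enrichment = enrich
    )
  }

  report <- list(
    package_version = as.character(utils::packageVersion("alucontact")),
    config = list(n_bins = n_bins, kind = kind, strata = strata, flank = flank,
                  groups = groups, n_background = n_background, seed = seed,
                  simulated = !is.null(sim)),
    thresholds = list(lower = strat$lower_threshold,
                      upper = strat$upper_threshold,
                      removed_low_count = strat$removed_low_count,
                      removed_high_count = strat$removed_high_count,
                      removed_high_fraction_of_valid =
                        strat$removed_high_fraction_of_valid),
    n_pairs = list(intra = nrow(strat$intra), non_intra = nrow(strat$non_intra),
                   boundary = nrow(strat$boundary)),
    validation = violations,
    te_profiles = profiles,
    composition = composition,
    subfamily_methylation = subfam_meth,
    regulatory = regulatory,
    strata = strat,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ser <- report[c("package_version", "config", "thresholds", "n_pairs",
                    "timestamp")]
    ser$te_profiles <- profiles
    ser$composition <- composition
    ser$subfamily_methylation <- subfam_meth
    ser$validation_violations <- nrow(violations)
    jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
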