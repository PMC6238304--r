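# Cohort-level statistics over diplotype calls: allele/diplotype/SNP
# frequencies under hemizygote masking, function-class burden, per-locus
# Hardy-Weinberg tests, and cross-population frequency comparison.

#' Summarise a cohort of diplotype calls
#'
#' Computes allele counts and frequencies (each sample contributes exactly
#' two allele slots; the whole-gene deletion allele occupies a slot),
#' diplotype counts and frequencies, SNP frequencies derived from allele
#' composition (the frequency of a variant is the summed frequency of the
#' alleles carrying it, over all 2n slots), function-class burden, and an
#' exact Hardy-Weinberg p-value per informative locus computed from the
#' apparent (assay-level, hemizygote-masked) genotypes of the called pairs.
#'
#' Only calls with status `unique` enter the summary; the number excluded is
#' recorded in `n_excluded`.
#'
#' @param calls a `cyp2d6_calls` object (or list of diplotype calls).
#' @param table the `cyp2d6_allele_table` the calls were made under.
#' @return an object of class `cyp2d6_popsummary` with elements `n_samples`,
#'   `n_excluded`, `allele_counts`, `allele_freqs`, `diplotype_counts`,
#'   `diplotype_freqs`, `derived_snp_freqs`, `function_burden`, `hwe`.
#' @examples
#' tab <- load_allele_table()
#' cohort <- reconstruct_karen_cohort(tab)
#' calls <- call_batch(cohort, tab, quiet = TRUE)
#' summarize_cohort(calls, tab)
#' @export
summarize_cohort <- function(calls, table) {
  if (length(calls) == 0L) stop("empty call list")
  status <- vapply(calls, `[[`, "", "status")
  keep <- calls[status == "unique"]
  n_excluded <- length(calls) - length(keep)
  if (n_excluded > 0)
    message("excluding ", n_excluded, " non-unique call(s) from summary")
  if (length(keep) == 0L) stop("no uniquely called samples to summarise")

  n <- length(keep)
  anames <- names(table$alleles)
  pairs <- lapply(keep, `[[`, "best_pair")

  allele_counts <- stats::setNames(integer(length(anames)), anames)
  for (p in pairs) {
    allele_counts[p[1]] <- allele_counts[p[1]] + 1L
    allele_counts[p[2]] <- allele_counts[p[2]] + 1L
  }
  allele_freqs <- allele_counts / (2 * n)

  dip <- vapply(pairs, pair_label, "")
  diplotype_counts <- table(dip)
  diplotype_counts <- stats::setNames(as.integer(diplotype_counts),
                                      names(diplotype_counts))
  # canonical ascending star-number order (*1/*1 ... *10/*10)
  ord <- order(vapply(strsplit(names(diplotype_counts), "/"), function(p)
    star_number(p[1]) * 1000 + star_number(p[2]), 0))
  diplotype_counts <- diplotype_counts[ord]
  diplotype_freqs <- diplotype_counts / n

  derived_snp_freqs <- vapply(table$variants$id, function(v)
    sum(allele_freqs[vapply(table$alleles, function(a)
      v %in% a$all_variants, NA)]), 0)

  cls <- function_summary(table)
  function_burden <- vapply(.FUNCTION_CLASSES, function(k)
    sum(allele_freqs[names(cls)[cls == k]]), 0)

  hwe <- vapply(table$informative_loci, function(locus) {
    g <- vapply(pairs, predict_genotype, "", locus = locus, table = table)
    cnt <- c(sum(g == "ref_ref"), sum(g == "ref_alt"), sum(g == "alt_alt"))
    if (sum(cnt) == 0) return(NA_real_)
    hwe_exact(cnt[1], cnt[2], cnt[3])
  }, 0)

  structure(list(n_samples = n,
                 n_excluded = n_excluded,
                 allele_counts = allele_counts,
                 allele_freqs = allele_freqs,
                 diplotype_counts = diplotype_counts,
                 diplotype_freqs = diplotype_freqs,
                 derived_snp_freqs = derived_snp_freqs,
                 function_burden = function_burden,
                 hwe = hwe),
            class = "cyp2d6_popsummary")
}

#' @export
print.cyp2d6_popsummary <- function(x, ...) {
  cat("CYP2D6 population summary:", x$n_samples, "samples")
  if (x$n_excluded) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat(", ", sum(x$allele_counts), " allele slots\n", sep = "")
  cat("Allele frequencies:\n")
  af <- x$allele_freqs
  for (a in names(af))
    cat(sprintf("  %-4s n=%3d  %.3f\n", a, x$allele_counts[[a]], af[[a]]))
  cat("Derived SNP frequencies (2-dp):\n  ")
  cat(paste(names(x$derived_snp_freqs),
            sprintf("%.2f", x$derived_snp_freqs), sep = "="), sep = "  ")
  cat("\nFunction-class burden:",
      paste(names(x$function_burden),
            sprintf("%.3f", x$function_burden), sep = "="), "\n")
  invisible(x)
}

#' Proportion of alleles in given function classes
#'
#' The summed allele frequency over alleles whose function class falls in
#' `classes`; with the default `{decreased, none}` this is the burden of
#' alleles conferring a reduced (intermediate-or-worse) metabolizer
#' phenotype.
#'
#' @param summary a `cyp2d6_popsummary`.
#' @param table the allele table used for the summary.
#' @param classes subset of `c("normal", "decreased", "none")`.
#' @return a proportion in \[0, 1\].
#' @export
reduced_function_fraction <- function(summary, table,
                                      classes = c("decreased", "none")) {
  stopifnot(all(classes %in% .FUNCTION_CLASSES))
  cls <- function_summary(table)
  sum(summary$allele_freqs[names(cls)[cls %in% classes]])
}

#' Read the bundled cross-population frequency panel
#'
#' Literature allele/variant frequencies for CYP2D6 across populations
#' (Asian, Caucasian and African cohorts typed by various methods), with
#' `ND` marking frequencies not determined by a study. Frequencies follow
#' the defining-variant convention: the `C100T`, `G1846A`, `C2850T`,
#' `exon9_conversion` and `deletion` columns are the *10, *4, *2, *36 and *5
#' allele frequencies respectively.
#'
#' @param path optional path to a panel TSV with the same columns; default
#'   the bundled panel.
#' @return data.frame with population metadata columns and numeric frequency
#'   columns (NA where not determined).
#' @export
read_population_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "population_panel_table4.tsv",
                        package = "cyp2d6star", mustWork = TRUE)
  panel <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  meta <- c("population", "region", "year", "n", "method")
  for (col in setdiff(names(panel), meta)) {
    panel[[col]] <- suppressWarnings(as.numeric(
      ifelse(panel[[col]] == "ND", NA, panel[[col]])))
    bad <- !is.na(panel[[col]]) & (panel[[col]] < 0 | panel[[col]] > 1)
    if (any(bad)) stop("panel frequency out of [0,1] in column ", col)
  }
  panel
}

# Extract, from a population summary, the frequency vector in the panel's
# defining-variant convention (C100T column = *10 frequency, etc.), falling
# back to derived SNP frequencies for columns without a proxy allele.
.PANEL_PROXY <- c(C100T = "*10", G1846A = "*4", C2850T = "*2",
                  exon9_conversion = "*36", deletion = "*5")

#' Panel-convention frequencies of a cohort summary
#'
#' @param summary a `cyp2d6_popsummary`.
#' @param variants which panel columns to extract.
#' @return named numeric vector.
#' @export
panel_frequencies <- function(summary,
                              variants = c("C100T", "G1846A", "C2850T",
                                           "G4180C")) {
  vapply(variants, function(v) {
    proxy <- .PANEL_PROXY[v]
    if (!is.na(proxy) && proxy %in% names(summary$allele_freqs))
      summary$allele_freqs[[proxy]]
    else if (v %in% names(summary$derived_snp_freqs))
      summary$derived_snp_freqs[[v]]
    else NA_real_
  }, 0)
}

#' Compare a cohort against the cross-population panel
#'
#' Per-population absolute frequency differences at the requested variants,
#' plus a scalar divergence: the mean absolute difference over the variants
#' determined in that row (ND columns are excluded from the row's mean).
#' Sorting the result by divergence reproduces the qualitative
#' closest-populations ordering.
#'
#' @param target a `cyp2d6_popsummary`, or a named numeric vector of
#'   frequencies in panel convention (as from [panel_frequencies()]).
#' @param panel data.frame from [read_population_panel()].
#' @param variants panel columns to compare on.
#' @return data.frame: population, region, one `d_<variant>` column per
#'   variant (absolute difference, NA where not determined), `n_compared`,
#'   and `divergence`, sorted ascending by divergence.
#' @export
compare_populations <- function(target, panel = read_population_panel(),
                                variants = c("C100T", "G1846A", "C2850T",
                                             "G4180C")) {
  tv <- if (inherits(target, "cyp2d6_popsummary"))
    panel_frequencies(target, variants)
  else target[variants]
  if (any(is.na(tv))) stop("target lacks requested variant(s)")
  missing_cols <- setdiff(variants, names(panel))
  if (length(missing_cols))
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "))

  diffs <- sapply(variants, function(v) abs(panel[[v]] - tv[[v]]))
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = nrow(panel))
  colnames(diffs) <- paste0("d_", variants)
  out <- data.frame(population = panel$population,
                    region = panel$region,
                    diffs,
                    n_compared = rowSums(!is.na(diffs)),
                    divergence = rowMeans(diffs, na.rm = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$divergence[out$n_compared == 0] <- NA
  out[order(out$divergence), , drop = FALSE]
}

#' Write a population summary as TSV + JSON report
#'
#' Presentation rounding is applied only here: two decimals for allele and
#' derived-SNP frequencies, three decimals for per-diplotype frequencies;
#' internal objects keep full precision.
#'
#' @param summary a `cyp2d6_popsummary`.
#' @param path_prefix output prefix; writes `<prefix>_alleles.tsv`,
#'   `<prefix>_diplotypes.tsv`, `<prefix>_snps.tsv` and `<prefix>.json`.
#' @param reproducibility optional named list (seed, config hash, ...)
#'   embedded in the JSON report.
#' @return invisible character vector of files written.
#' @export
write_summary <- function(summary, path_prefix, reproducibility = list()) {
  af <- data.frame(allele = names(summary$allele_freqs),
                   n = as.integer(summary$allele_counts),
                   frequency = sprintf("%.2f", summary$allele_freqs))
  df <- data.frame(diplotype = names(summary$diplotype_counts),
                   n = as.integer(summary$diplotype_counts),
                   frequency = sprintf("%.3f", summary$diplotype_freqs))
  sf <- data.frame(variant = names(summary$derived_snp_freqs),
                   frequency = sprintf("%.2f", summary$derived_snp_freqs),
                   hwe_p = sapply(names(summary$derived_snp_freqs), function(v)
                     if (v %in% names(summary$hwe))
                       sprintf("%.4g", summary$hwe[[v]]) else ""))
  files <- paste0(path_prefix, c("_alleles.tsv", "_diplotypes.tsv",
                                 "_snps.tsv", ".json"))
  utils::write.table(af, files[1], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(df, files[2], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sf, files[3], sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_samples = summary$n_samples,
         n_excluded = summary$n_excluded,
         allele_counts = as.list(summary$allele_counts),
         allele_freqs = as.list(round(summary$allele_freqs, 4)),
         diplotype_counts = as.list(summary$diplotype_counts),
         derived_snp_freqs = as.list(round(summary$derived_snp_freqs, 4)),
         function_burden = as.list(round(summary$function_burden, 4)),
         hwe = as.list(summary$hwe),
         reproducibility = reproducibility),
    files[4], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}
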