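# Diplotype caller: enumerate star-allele pairs consistent with a sample's
# unphased genotypes and structural band flags, and rank a best call.
#
# The assay is dose-blind beyond three states per SNP (wild-type hom, het,
# mutant hom), and whole-gene deletion (*5) masks the second haplotype, so a
# hemizygote's single allele appears homozygous at every locus.

#' Construct a sample record
#'
#' One individual's unphased genotype calls at the informative loci plus the
#' structural assay flags (XL-PCR deletion/duplication bands, exon-9
#' conversion evidence from sequencing).
#'
#' @param sample_id sample identifier.
#' @param genotypes named character vector over variant-catalog loci; values
#'   in `ref_ref`, `ref_alt`, `alt_alt`, `missing`.
#' @param deletion_band logical: 3.5 kb deletion product observed.
#' @param duplication_band logical: duplication/multiplication product
#'   observed (annotation only; copy number is not resolved).
#' @param exon9_conversion exon-9 gene-conversion evidence from sequencing:
#'   `"het"` (double peaks: one converted copy), `"hom"` (only converted
#'   sequence), `"present"` (conversion seen, zygosity unresolved),
#'   `"absent"`, or `"untested"`.
#' @param meta optional list of pass-through metadata.
#' @return an object of class `cyp2d6_sample`.
#' @export
sample_record <- function(sample_id, genotypes,
                          deletion_band = FALSE, duplication_band = FALSE,
                          exon9_conversion = "untested", meta = list()) {
  stopifnot(is.character(genotypes), !is.null(names(genotypes)))
  bad <- !genotypes %in% .GENO_CALLS
  if (any(bad))
    stop("invalid genotype call(s): ", paste(genotypes[bad], collapse = ", "))
  exon9_conversion <- match.arg(exon9_conversion,
                                c("present", "het", "hom", "absent",
                                  "untested"))
  structure(list(sample_id = as.character(sample_id),
                 genotypes = genotypes,
                 deletion_band = isTRUE(deletion_band),
                 duplication_band = isTRUE(duplication_band),
                 exon9_conversion = exon9_conversion,
                 meta = meta),
            class = "cyp2d6_sample")
}

#' @export
print.cyp2d6_sample <- function(x, ...) {
  cat("Sample", x$sample_id, "\n  ")
  cat(paste(names(x$genotypes), x$genotypes, sep = "="), sep = "  ")
  cat("\n  deletion_band:", x$deletion_band,
      " duplication_band:", x$duplication_band,
      " exon9:", x$exon9_conversion, "\n")
  invisible(x)
}

#' Apparent genotype of an allele pair at a locus
#'
#' Computes the genotype the assay would report for a given diplotype at one
#' locus: the alt-allele dose is the number of alleles in the pair carrying
#' the variant, mapped to `ref_ref`/`ref_alt`/`alt_alt`. For hemizygous
#' pairs (one member the whole-gene deletion allele) the single remaining
#' haplotype appears homozygous: dose 0 maps to `ref_ref`, dose 1 to
#' `alt_alt`.
#'
#' @param pair character(2), star-allele names (unordered).
#' @param locus variant id from the catalog.
#' @param table a `cyp2d6_allele_table`.
#' @return one of `"ref_ref"`, `"ref_alt"`, `"alt_alt"`; `"missing"` for the
#'   fully deleted homozygous-deletion pair.
#' @examples
#' tab <- load_allele_table()
#' predict_genotype(c("*2", "*10"), "C100T", tab)   # ref_alt
#' predict_genotype(c("*2", "*5"), "C2850T", tab)   # alt_alt (hemizygote)
#' @export
predict_genotype <- function(pair, locus, table) {
  if (!locus %in% table$variants$id) stop("unknown locus: ", locus)
  if (!all(pair %in% names(table$alleles)))
    stop("unknown allele(s): ",
         paste(setdiff(pair, names(table$alleles)), collapse = ", "))
  del <- deletion_allele(table)
  is_del <- !is.na(del) & pair == del
  if (all(is_del)) return("missing")  # no gene copy to genotype
  carriers <- vapply(pair, function(a)
    locus %in% table$alleles[[a]]$all_variants, NA)
  dose <- sum(carriers & !is_del)
  if (any(is_del)) {
    # hemizygous: single haplotype appears homozygous
    if (dose == 0) "ref_ref" else "alt_alt"
  } else {
    c("ref_ref", "ref_alt", "alt_alt")[dose + 1L]
  }
}

# All unordered candidate pairs for a sample, before genotype filtering:
# deletion-band samples pair every non-deletion allele with *5; others take
# all unordered pairs (with replacement) of non-deletion alleles.
candidate_pairs <- function(sample, table) {
  del <- deletion_allele(table)
  nondel <- allele_names(table, include_deletion = FALSE)
  if (sample$deletion_band) {
    if (is.na(del)) return(list())
    lapply(nondel, function(a) canonical_pair(c(a, del)))
  } else {
    pairs <- list()
    for (i in seq_along(nondel))
      for (j in i:length(nondel))
        pairs[[length(pairs) + 1L]] <- canonical_pair(c(nondel[i], nondel[j]))
    pairs
  }
}

#' Enumerate allele pairs consistent with a sample
#'
#' Brute-force enumeration over the allele universe. A candidate pair
#' survives iff its predicted genotype matches every non-missing informative
#' locus, and the exon-9 constraint holds. Conversion evidence comes from
#' exon-9 sequencing, which resolves zygosity like any sequenced variant, so
#' it is matched as an apparent dose under the same hemizygote masking as
#' the SNPs: `het` requires exactly one conversion allele (*36) in a
#' two-copy pair, `hom` requires a conversion dose that appears homozygous
#' (two *36, or *36 over a deletion), `present` accepts either (zygosity
#' unresolved), `absent` excludes conversion carriers, and `untested`
#' excludes them by default (the SNP panel alone cannot see the conversion,
#' so proposing *36 without evidence would leave nearly every *10 call
#' ambiguous) unless `allow_untested_exon9_ambiguity = TRUE`, which leaves
#' *36 an unconstrained candidate. The duplication band never filters pairs.
#'
#' A deletion-band sample with every informative locus missing is the
#' defined homozygous-deletion case and returns the (*5, *5) pair alone.
#'
#' @inheritParams predict_genotype
#' @param sample a `cyp2d6_sample`.
#' @param allow_untested_exon9_ambiguity logical; see Details.
#' @return list of character(2) canonical pairs (possibly empty).
#' @export
consistent_pairs <- function(sample, table,
                             allow_untested_exon9_ambiguity = FALSE) {
  unknown <- setdiff(names(sample$genotypes), table$variants$id)
  if (length(unknown))
    stop("sample genotypes at loci unknown to the catalog: ",
         paste(unknown, collapse = ", "))
  loci <- intersect(table$informative_loci, names(sample$genotypes))
  g <- sample$genotypes[loci]
  del <- deletion_allele(table)

  # hemizygotes cannot be heterozygous
  if (sample$deletion_band && any(g == "ref_alt")) return(list())

  # defined degenerate case: homozygous whole-gene deletion
  if (sample$deletion_band && length(loci) && all(g == "missing") && !is.na(del))
    return(list(c(del, del)))

  conv <- conversion_alleles(table)
  # apparent conversion dose of a pair, masked like the SNPs: a conversion
  # allele over a whole-gene deletion sequences as homozygous-converted
  apparent_conv <- function(pair) {
    is_del <- !is.na(del) & pair == del
    dose <- sum(pair %in% conv & !is_del)
    if (any(is_del)) {
      if (dose == 0) "absent" else "hom"
    } else {
      c("absent", "het", "hom")[dose + 1L]
    }
  }
  e9 <- sample$exon9_conversion

  Filter(function(pair) {
    app <- apparent_conv(pair)
    ok <- switch(e9,
                 het = app == "het",
                 hom = app == "hom",
                 present = app %in% c("het", "hom"),
                 absent = app == "absent",
                 untested = allow_untested_exon9_ambiguity || app == "absent")
    if (!ok) return(FALSE)
    for (locus in loci) {
      if (g[[locus]] == "missing") next
      if (predict_genotype(pair, locus, table) != g[[locus]]) return(FALSE)
    }
    TRUE
  }, candidate_pairs(sample, table))
}

#' Call a diplotype for one sample
#'
#' Ranks the consistent pairs under per-allele prior weights (default
#' uniform): a pair's score is `prior(a) * prior(b)`, doubled for
#' heterozygous pairs (two orderings), with ties broken lexicographically on
#' the canonical pair label. Status is `unique` (exactly one consistent
#' pair), `ambiguous` (several, no informative locus missing),
#' `insufficient_data` (not a singleton and at least one informative locus
#' missing), or `inconsistent` (no pair and nothing missing, or an
#' inadmissible record such as a heterozygous call alongside the deletion
#' band).
#'
#' @inheritParams consistent_pairs
#' @param priors named non-negative weights covering all alleles, or `NULL`
#'   for uniform.
#' @return an object of class `cyp2d6_diplotype_call`: list with
#'   `sample_id`, `consistent_pairs`, `best_pair`, `status`, `notes`.
#' @examples
#' tab <- load_allele_table()
#' s <- sample_record("S1", c(C100T = "ref_alt", G1846A = "ref_ref",
#'                            C2850T = "ref_alt", G4180C = "alt_alt"))
#' call_diplotype(s, tab)   # unique *2/*10
#' @export
call_diplotype <- function(sample, table, priors = NULL,
                           allow_untested_exon9_ambiguity = FALSE) {
  nm <- names(table$alleles)
  if (is.null(priors)) priors <- stats::setNames(rep(1, length(nm)), nm)
  if (!all(nm %in% names(priors)))
    stop("priors must cover all alleles")
  if (any(priors < 0)) stop("priors must be non-negative")

  notes <- character()
  loci <- intersect(table$informative_loci, names(sample$genotypes))
  g <- sample$genotypes[loci]
  missing_any <- length(loci) == 0L || any(g == "missing")

  if (sample$deletion_band && any(g == "ref_alt")) {
    return(new_call(sample$sample_id, list(), NULL, "inconsistent",
                    "het_call_with_deletion_band"))
  }

  pairs <- consistent_pairs(sample, table, allow_untested_exon9_ambiguity)
  if (sample$duplication_band)
    notes <- c(notes, "duplication_present_copy_number_unresolved")
  del <- deletion_allele(table)
  if (sample$deletion_band && length(pairs) == 1L && !is.na(del) &&
      all(pairs[[1]] == del))
    notes <- c(notes, "homozygous_whole_gene_deletion")

  if (length(pairs) == 1L) {
    status <- "unique"
    best <- pairs[[1]]
  } else if (missing_any) {
    status <- "insufficient_data"
    best <- NULL
  } else if (length(pairs) == 0L) {
    status <- "inconsistent"
    best <- NULL
  } else {
    status <- "ambiguous"
    score <- vapply(pairs, function(p)
      priors[[p[1]]] * priors[[p[2]]] * (if (p[1] == p[2]) 1 else 2), 0)
    labels <- vapply(pairs, pair_label, "")
    best <- pairs[order(-score, labels)][[1]]
  }
  new_call(sample$sample_id, pairs, best, status, notes)
}

new_call <- function(sample_id, pairs, best, status, notes) {
  structure(list(sample_id = sample_id,
                 consistent_pairs = pairs,
                 best_pair = best,
                 status = status,
                 notes = notes),
            class = "cyp2d6_diplotype_call")
}

#' @export
print.cyp2d6_diplotype_call <- function(x, ...) {
  best <- if (is.null(x$best_pair)) "-" else pair_label(x$best_pair)
  cat(sprintf("%s: %s [%s]", x$sample_id, best, x$status))
  if (length(x$consistent_pairs) > 1L)
    cat("  candidates:",
        paste(vapply(x$consistent_pairs, pair_label, ""), collapse = " "))
  if (length(x$notes)) cat("  (", paste(x$notes, collapse = "; "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Call diplotypes for a batch of samples
#'
#' Order-preserving, with per-sample isolation: a sample whose record errors
#' is reported as `inconsistent` with a diagnostic note rather than aborting
#' the batch.
#'
#' @inheritParams call_diplotype
#' @param samples list of `cyp2d6_sample` records.
#' @param quiet suppress the per-status summary message.
#' @return an object of class `cyp2d6_calls` (list of
#'   `cyp2d6_diplotype_call`, one per input sample).
#' @export
call_batch <- function(samples, table, priors = NULL,
                       allow_untested_exon9_ambiguity = FALSE, quiet = FALSE) {
  calls <- lapply(samples, function(s) {
    tryCatch(
      call_diplotype(s, table, priors, allow_untested_exon9_ambiguity),
      error = function(e) new_call(s$sample_id %||% "?", list(), NULL,
                                   "inconsistent",
                                   paste0("record_error: ", conditionMessage(e))))
  })
  calls <- structure(calls, class = "cyp2d6_calls")
  if (!quiet) {
    st <- table(factor(vapply(calls, `[[`, "", "status"),
                       levels = c("unique", "ambiguous", "inconsistent",
                                  "insufficient_data")))
    message("called ", length(calls), " samples: ",
            paste(names(st), st, sep = "=", collapse = " "))
  }
  calls
}

#' @export
print.cyp2d6_calls <- function(x, n = 10L, ...) {
  cat("CYP2D6 diplotype calls:", length(x), "samples\n")
  for (cl in utils::head(x, n)) print(cl)
  if (length(x) > n) cat("  ... and", length(x) - n, "more\n")
  invisible(x)
}

#' @export
summary.cyp2d6_calls <- function(object, ...) {
  status <- vapply(object, `[[`, "", "status")
  dip <- vapply(object, function(cl)
    if (is.null(cl$best_pair)) NA_character_ else pair_label(cl$best_pair), "")
  list(n = length(object),
       status = table(status),
       diplotypes = sort(table(dip[status == "unique"]), decreasing = TRUE))
}

#' Tabulate diplotype calls
#'
#' @param x a `cyp2d6_calls` object.
#' @param ... unused.
#' @return data.frame with sample_id, best_call, status, n_candidates, notes.
#' @export
as.data.frame.cyp2d6_calls <- function(x, ...) {
  data.frame(
    sample_id = vapply(x, `[[`, "", "sample_id"),
    best_call = vapply(x, function(cl)
      if (is.null(cl$best_pair)) NA_character_ else pair_label(cl$best_pair), ""),
    status = vapply(x, `[[`, "", "status"),
    n_candidates = vapply(x, function(cl) length(cl$consistent_pairs), 0L),
    notes = vapply(x, function(cl) paste(cl$notes, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
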