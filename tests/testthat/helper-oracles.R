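# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive expected behaviour along a different code
# path from the package implementation.

default_table <- function() load_allele_table()

# --- naive diplotype enumeration oracle ------------------------------------
# Recomputes consistent pairs from first principles: build each allele's
# variant set straight from the table, derive the apparent genotype of a
# pair by counting carriers (with hemizygote masking), and keep pairs whose
# rendered profile matches the record. Written without calling
# predict_genotype()/consistent_pairs().
oracle_consistent_pairs <- function(sample, table,
                                    allow_untested_exon9_ambiguity = FALSE) {
  anames <- names(table$alleles)
  has_del <- vapply(table$alleles, function(a)
    "whole_gene_deletion" %in% a$structural, NA)
  has_conv <- vapply(table$alleles, function(a)
    "exon9_conversion" %in% a$structural, NA)
  del <- anames[has_del][1]
  loci <- intersect(table$informative_loci, names(sample$genotypes))

  if (sample$deletion_band && any(sample$genotypes[loci] == "ref_alt"))
    return(list())
  if (sample$deletion_band && length(loci) &&
      all(sample$genotypes[loci] == "missing"))
    return(list(c(del, del)))

  all_pairs <- list()
  for (a in anames[!has_del]) for (b in anames[!has_del])
    if (which(anames == a) <= which(anames == b))
      all_pairs[[length(all_pairs) + 1]] <- c(a, b)
  if (sample$deletion_band)
    all_pairs <- lapply(anames[!has_del], function(a) sort(c(a, del)))

  ok <- vapply(all_pairs, function(p) {
    # apparent conversion state, independently derived: count conversion
    # alleles among the pair's gene copies, collapsing to hom when the
    # other copy is deleted
    nconv <- sum(has_conv[p] & !has_del[p])
    ndel <- sum(has_del[p])
    app <- if (ndel > 0) {
      if (nconv > 0) "hom" else "absent"
    } else if (nconv == 2) "hom" else if (nconv == 1) "het" else "absent"
    e9 <- sample$exon9_conversion
    bad <- switch(e9,
                  het = app != "het",
                  hom = app != "hom",
                  present = app == "absent",
                  absent = app != "absent",
                  untested = app != "absent" && !allow_untested_exon9_ambiguity)
    if (bad) return(FALSE)
    for (locus in loci) {
      obs <- sample$genotypes[[locus]]
      if (obs == "missing") next
      carry <- vapply(p, function(a)
        locus %in% table$alleles[[a]]$all_variants & !has_del[[a]], NA)
      if (sample$deletion_band) {
        apparent <- if (sum(carry) == 0) "ref_ref" else "alt_alt"
      } else {
        apparent <- c("ref_ref", "ref_alt", "alt_alt")[sum(carry) + 1]
      }
      if (apparent != obs) return(FALSE)
    }
    TRUE
  }, NA)
  lapply(all_pairs[ok], function(p) canon(p))
}

canon <- function(p) p[order(as.numeric(sub("^\\*", "", p)))]

# canonical sortable string set for pair-list comparison
pair_set <- function(pairs) {
  sort(vapply(pairs, function(p) paste(canon(p), collapse = "/"), ""))
}

# --- random sample records --------------------------------------------------
random_sample_record <- function(table, id = "r") {
  loci <- table$informative_loci
  g <- sample(c("ref_ref", "ref_alt", "alt_alt", "missing"),
              length(loci), replace = TRUE,
              prob = c(0.35, 0.25, 0.25, 0.15))
  names(g) <- loci
  delb <- runif(1) < 0.2
  if (delb && runif(1) < 0.5) g[g == "ref_alt"] <- "alt_alt"
  sample_record(id, g,
                deletion_band = delb,
                duplication_band = runif(1) < 0.1,
                exon9_conversion = sample(c("present", "het", "hom",
                                            "absent", "untested"),
                                          1, prob = c(0.05, 0.1, 0.05,
                                                      0.3, 0.5)))
}

# --- direct-formula HWE oracle ----------------------------------------------
# Exact conditional probability of each heterozygote count from the closed
# form P(h | n, n_rare) = n! 2^h / (naa! nab! nbb!) * n_ref! n_alt! / (2n)!,
# evaluated with log-factorials; two-sided p sums P over configurations no
# more probable than the observed one.
oracle_hwe_exact <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  n_alt <- nab + 2 * nbb
  n_ref <- nab + 2 * naa
  rare <- min(n_ref, n_alt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    a <- (n_ref - h) / 2
    b <- (n_alt - h) / 2
    lfactorial(n) + h * log(2) - lfactorial(a) - lfactorial(h) -
      lfactorial(b) + lfactorial(n_ref) + lfactorial(n_alt) -
      lfactorial(2 * n)
  }, 0)
  p <- exp(lp)
  obs <- p[match(nab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# small VCF fixture writer (4 catalog rsIDs, arbitrary GT matrix)
write_test_vcf <- function(path, gt, ids = rownames(gt)) {
  samples <- colnames(gt)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  pos <- c(rs1065852 = 100, rs3892097 = 1846, rs16947 = 2850,
           rs1135840 = 4180)
  ref <- c(rs1065852 = "C", rs3892097 = "G", rs16947 = "C", rs1135840 = "G")
  alt <- c(rs1065852 = "T", rs3892097 = "A", rs16947 = "T", rs1135840 = "C")
  rows <- vapply(ids, function(id)
    paste(c("CYP2D6", pos[[id]], id, ref[[id]], alt[[id]], ".", "PASS", ".",
            "GT", gt[id, ]), collapse = "\t"), "")
  writeLines(c(meta, rows), path)
  path
}
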