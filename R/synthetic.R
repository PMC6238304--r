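# Synthetic cohorts with the statistical structure the analysis assumes:
# Hardy-Weinberg diplotype sampling from an allele-frequency vector,
# assay-level rendering with hemizygote masking, the deterministic 70-sample
# Karen cohort reconstruction from the published genotype counts, and
# divergence-controlled sequence mutation for the identity classifier.

# Allele-frequency truth used as simulation default: the Karen cohort vector.
.KAREN_ALLELE_FREQS <- c("*1" = 30 / 140, "*2" = 46 / 140, "*4" = 3 / 140,
                         "*5" = 4 / 140, "*10" = 56 / 140, "*36" = 1 / 140)

# Published Karen diplotype counts (11 genotype classes, 70 samples).
.KAREN_DIPLOTYPE_COUNTS <- c(
  "*1/*1" = 3, "*1/*2" = 8, "*1/*4" = 3, "*1/*5" = 2, "*1/*10" = 10,
  "*1/*36" = 1, "*2/*2" = 7, "*2/*5" = 1, "*2/*10" = 23, "*5/*10" = 1,
  "*10/*10" = 11)

#' Karen cohort allele-frequency vector
#'
#' The six-allele frequency vector of the 70-sample Karen cohort (counts
#' 30/46/3/4/56/1 over 140 allele slots), used as the simulation default.
#'
#' @return named numeric vector summing to 1.
#' @export
karen_allele_freqs <- function() .KAREN_ALLELE_FREQS

#' Render the assay output for a known diplotype
#'
#' Produces the `cyp2d6_sample` the genotyping assay would report for a
#' given allele pair: predicted genotypes at every informative locus
#' (hemizygote masking applied for deletion carriers), the deletion band for
#' *5 carriers, and exon-9 conversion evidence per policy. Conversion
#' evidence is rendered with the same masking as the SNPs: one conversion
#' allele in a two-copy pair sequences as `het`, two (or one over a
#' deletion) as `hom`, none as `absent`. A homozygous deletion pair renders
#' all loci `missing` with the deletion band set.
#'
#' @param pair character(2) of star-allele names.
#' @param table a `cyp2d6_allele_table`.
#' @param exon9_policy `"render"` (report the sequencing evidence
#'   truthfully) or `"untested"` (evidence withheld, as for a
#'   SNP-panel-only assay).
#' @param sample_id identifier for the record.
#' @return a `cyp2d6_sample`.
#' @examples
#' tab <- load_allele_table()
#' render_sample(c("*5", "*10"), tab)  # hemizygote: 100 and 4180 appear hom
#' @export
render_sample <- function(pair, table, exon9_policy = c("render", "untested"),
                          sample_id = pair_label(pair)) {
  exon9_policy <- match.arg(exon9_policy)
  if (!all(pair %in% names(table$alleles)))
    stop("unknown allele(s): ",
         paste(setdiff(pair, names(table$alleles)), collapse = ", "))
  pair <- canonical_pair(pair)
  del <- deletion_allele(table)
  genotypes <- vapply(table$informative_loci, predict_genotype, "",
                      pair = pair, table = table)
  conv_n <- sum(pair %in% conversion_alleles(table))
  hemi <- !is.na(del) && del %in% pair
  exon9 <- if (exon9_policy == "untested") "untested"
           else if (conv_n == 0) "absent"
           else if (conv_n == 2 || hemi) "hom"
           else "het"
  sample_record(sample_id, genotypes,
                deletion_band = !is.na(del) && del %in% pair,
                duplication_band = FALSE,
                exon9_conversion = exon9)
}

#' Simulate a cohort under Hardy-Weinberg equilibrium
#'
#' Draws each sample's two alleles i.i.d. from `allele_freqs` (random union
#' of gametes), renders the assay output with [render_sample()], then applies
#' per-locus no-calls and duplication-band flags. Sampling uses inverse-CDF
#' draws under R's default RNG from the single supplied seed, so cohorts are
#' fully reproducible.
#'
#' @param table a `cyp2d6_allele_table`.
#' @param n_samples cohort size (> 0).
#' @param allele_freqs named frequency vector over the table's alleles
#'   (default the Karen vector); must sum to 1 within 1e-9.
#' @param seed integer seed; all randomness flows from it.
#' @param nocall_rate per-locus probability that a genotype is reported
#'   `missing` (default 0).
#' @param p_duplication probability a sample is flagged with the
#'   duplication band (annotation only; default 0).
#' @param exon9_policy passed to [render_sample()].
#' @return list with `samples` (list of `cyp2d6_sample`) and `truth`
#'   (data.frame sample_id, true_diplotype).
#' @examples
#' tab <- load_allele_table()
#' sim <- simulate_population(tab, n_samples = 50, seed = 1)
#' @export
simulate_population <- function(table, n_samples,
                                allele_freqs = karen_allele_freqs(),
                                seed = 1L, nocall_rate = 0,
                                p_duplication = 0,
                                exon9_policy = c("render", "untested")) {
  exon9_policy <- match.arg(exon9_policy)
  if (n_samples <= 0) stop("n_samples must be positive")
  if (abs(sum(allele_freqs) - 1) > 1e-9)
    stop("allele_freqs must sum to 1")
  if (nocall_rate < 0 || nocall_rate > 1 || p_duplication < 0 ||
      p_duplication > 1)
    stop("rates must be in [0, 1]")
  unknown <- setdiff(names(allele_freqs), names(table$alleles))
  if (length(unknown))
    stop("allele_freqs names unknown to table: ",
         paste(unknown, collapse = ", "))

  anames <- names(allele_freqs)
  cdf <- cumsum(allele_freqs)
  with_seed(seed, {
    # inverse-CDF draws: 2 alleles per sample
    u <- matrix(stats::runif(2 * n_samples), ncol = 2)
    idx <- matrix(findInterval(u, cdf) + 1L, ncol = 2)
    dup <- stats::runif(n_samples) < p_duplication
    samples <- vector("list", n_samples)
    truth <- character(n_samples)
    for (i in seq_len(n_samples)) {
      pair <- canonical_pair(anames[idx[i, ]])
      truth[i] <- pair_label(pair)
      s <- render_sample(pair, table, exon9_policy,
                         sample_id = sprintf("sim%04d", i))
      if (nocall_rate > 0) {
        drop <- stats::runif(length(s$genotypes)) < nocall_rate
        s$genotypes[drop] <- "missing"
      }
      s$duplication_band <- dup[i]
      samples[[i]] <- s
    }
    list(samples = samples,
         truth = data.frame(sample_id = vapply(samples, `[[`, "", "sample_id"),
                            true_diplotype = truth,
                            stringsAsFactors = FALSE))
  })
}

#' Deterministically reconstruct the 70-sample Karen cohort
#'
#' Expands the published 11 diplotype counts (3, 8, 3, 2, 10, 1, 7, 1, 23,
#' 1, 11 samples for *1/*1 through *10/*10) into assay-level sample records
#' via [render_sample()] with truthful exon-9 rendering. Duplication flags
#' are left unset: the study does not identify which samples carried
#' duplications, and the flag affects no frequency. Sample ids are stable
#' (`KAR001`...`KAR070`).
#'
#' @param table a `cyp2d6_allele_table`.
#' @return list of 70 `cyp2d6_sample` records.
#' @export
reconstruct_karen_cohort <- function(table) {
  counts <- .KAREN_DIPLOTYPE_COUNTS
  if (sum(counts) != 70)
    stop("corrupt diplotype counts: expected 70 samples, got ", sum(counts))
  i <- 0L
  samples <- list()
  for (lbl in names(counts)) {
    pair <- strsplit(lbl, "/", fixed = TRUE)[[1]]
    for (k in seq_len(counts[[lbl]])) {
      i <- i + 1L
      samples[[i]] <- render_sample(pair, table, exon9_policy = "render",
                                    sample_id = sprintf("KAR%03d", i))
    }
  }
  samples
}

#' Mutate a sequence to a controlled divergence
#'
#' Substitutes bases at `round(divergence * n)` positions chosen without
#' replacement, each to a uniformly chosen different base; reproducible from
#' `seed`.
#'
#' @param reference DNA string.
#' @param divergence proportion of positions to substitute, in \[0, 1\].
#' @param seed integer seed.
#' @return mutated DNA string of the same length.
#' @examples
#' mutate_sequence("ACGTACGTAC", 0.2, seed = 1)
#' @export
mutate_sequence <- function(reference, divergence, seed = 1L) {
  s <- .check_dna(reference, "reference")
  if (divergence < 0 || divergence > 1)
    stop("divergence must be in [0, 1]")
  chars <- strsplit(s, "")[[1]]
  k <- round(divergence * length(chars))
  if (k == 0) return(s)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    pos <- sample.int(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(bases, b), 1L), "")
  })
  paste(chars, collapse = "")
}
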