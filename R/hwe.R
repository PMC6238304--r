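# Exact test of Hardy-Weinberg proportions from genotype counts.

#' Exact Hardy-Weinberg test
#'
#' Two-sided exact test of Hardy-Weinberg proportions at a biallelic locus,
#' conditioning on the observed allele counts: the p-value is the sum of the
#' probabilities of all heterozygote counts (same parity as the observed
#' one, allele counts fixed) whose conditional probability does not exceed
#' that of the observed configuration. Probabilities are computed by the
#' standard recurrence over heterozygote counts started from the modal
#' configuration, so the test is exact for any sample size.
#'
#' @param n_ref_hom count of reference homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_alt_hom count of alternate homozygotes.
#' @return p-value in (0, 1]. A monomorphic locus returns 1.
#' @examples
#' hwe_exact(25, 50, 25)  # maximally HWE-consistent: p = 1
#' hwe_exact(10, 0, 10)   # strong heterozygote deficit
#' @export
hwe_exact <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_alt <- n_het + 2 * n_alt_hom
  n_ref <- n_het + 2 * n_ref_hom
  rare <- min(n_ref, n_alt)
  if (rare == 0) return(1)  # monomorphic

  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)

  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2)*(h+1))
  # computed outward from the modal heterozygote count for stability
  lp <- numeric(length(hets))
  # mode of the conditional distribution
  mode_h <- round(n_ref * n_alt / (2 * n - 1))
  if ((mode_h %% 2) != (rare %% 2)) mode_h <- mode_h + 1
  mode_h <- min(max(mode_h, min(hets)), max(hets))
  mid_idx <- match(mode_h, hets)

  lp[mid_idx] <- 0
  if (mid_idx < length(hets)) {
    for (i in (mid_idx + 1):length(hets)) {
      h <- hets[i - 1]
      naa <- (n_ref - h) / 2
      nbb <- (n_alt - h) / 2
      lp[i] <- lp[i - 1] + log(4 * naa * nbb) - log((h + 2) * (h + 1))
    }
  }
  if (mid_idx > 1) {
    for (i in (mid_idx - 1):1) {
      h <- hets[i + 1]
      naa <- (n_ref - h) / 2 + 1
      nbb <- (n_alt - h) / 2 + 1
      lp[i] <- lp[i + 1] + log(h * (h - 1)) - log(4 * naa * nbb)
    }
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}
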