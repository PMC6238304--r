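#' @keywords internal
"_PACKAGE"

# Valid genotype call tokens, in increasing alt-allele dose order.
.GENO_CALLS <- c("ref_ref", "ref_alt", "alt_alt", "missing")

# Canonical star-allele ordering: numeric star number, so "*4" < "*10".
star_number <- function(name) {
  as.numeric(sub("^\\*", "", name))
}

#' Order an allele pair canonically (ascending star number)
#'
#' @param pair character vector of two star-allele names.
#' @return character(2) with the smaller star number first.
#' @keywords internal
canonical_pair <- function(pair) {
  stopifnot(length(pair) == 2L)
  pair[order(star_number(pair))]
}

pair_label <- function(pair) {
  p <- canonical_pair(pair)
  paste(p, collapse = "/")
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. All stochastic
# operations in the package flow through this scope.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round half up (the convention used for reported GC percentages, where
# base R's round() would round half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
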