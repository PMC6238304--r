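# Assay quality control: primer/probe metrics (length, GC content, melting
# temperature) and gene-versus-pseudogene discrimination of sequenced
# amplicons by pairwise identity.

.check_dna <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop(what, " must be a single non-empty string")
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s))
    stop(what, " contains non-ACGT characters")
  s
}

#' GC content of a DNA sequence
#'
#' @param sequence DNA string (A/C/G/T).
#' @return percent G+C, rounded half-up to one decimal.
#' @examples
#' gc_percent("CCTGGGAAGGCCCCATGGAAG")  # 66.7
#' @export
gc_percent <- function(sequence) {
  s <- .check_dna(sequence)
  n_gc <- nchar(gsub("[AT]", "", s))
  round_half_up(100 * n_gc / nchar(s), 1)
}

# Nearest-neighbor thermodynamic tables (kcal/mol; cal/(mol K)), keyed by
# the 5'->3' top-strand dinucleotide. Breslauer et al. 1986 is the default
# (the parameter set behind classic primer-design Tm columns); SantaLucia
# 1998 unified parameters are the alternative.
.NN_TABLES <- list(
  breslauer1986 = list(
    dh = c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5, CT = -7.8,
           GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0,
           TT = -9.1, TG = -5.8, AC = -6.5, AG = -7.8, TC = -5.6, CC = -11.0),
    ds = c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
           CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6,
           TT = -24.0, TG = -12.9, AC = -17.3, AG = -20.8, TC = -13.5,
           CC = -26.6),
    # initiation: entropy penalty depends only on whether any G/C is present
    init = function(s) {
      if (grepl("[GC]", s)) c(dh = 0, ds = -16.8) else c(dh = 0, ds = -20.1)
    },
    salt = "schildkraut"),
  santalucia1998 = list(
    dh = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0),
    ds = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9),
    # terminal-basepair initiation terms
    init = function(s) {
      ends <- substr(c(s, s), c(1, nchar(s)), c(1, nchar(s)))
      at <- sum(ends %in% c("A", "T"))
      gc <- 2 - at
      c(dh = 0.1 * gc + 2.3 * at, ds = -2.8 * gc + 4.1 * at)
    },
    salt = "entropy")
)

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Nearest-neighbor primer melting temperature
#'
#' Duplex melting temperature from nearest-neighbor thermodynamics,
#' `Tm = 1000 * dH / (dS + R * ln(C)) - 273.15`, with `C` the annealing
#' oligonucleotide concentration. The default parameter set is Breslauer
#' 1986 with Schildkraut-Lifson salt correction (`+16.6 log10[Na+]`), the
#' convention of classic primer-design software; `method = "santalucia1998"`
#' uses the unified parameters with entropic salt correction
#' (`dS + 0.368 (N-1) ln[Na+]`).
#'
#' @param sequence DNA string, length >= 8.
#' @param Na monovalent cation concentration, mM.
#' @param primer_nM annealing oligonucleotide concentration, nM.
#' @param method `"breslauer1986"` (default) or `"santalucia1998"`.
#' @return melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("GTTATCCCAGAAGGCTTTGCAGGCTTCA")
#' @export
melting_temperature <- function(sequence, Na = 50, primer_nM = 50,
                                method = c("breslauer1986", "santalucia1998")) {
  s <- .check_dna(sequence)
  if (nchar(s) < 8) stop("sequence too short for nearest-neighbor Tm (< 8 nt)")
  method <- match.arg(method)
  tab <- .NN_TABLES[[method]]

  nn <- substring(s, 1:(nchar(s) - 1), 2:nchar(s))
  dh <- sum(tab$dh[nn])
  ds <- sum(tab$ds[nn])
  init <- tab$init(s)
  dh <- dh + init[["dh"]]
  ds <- ds + init[["ds"]]
  selfcomp <- identical(s, revcomp(s))
  if (selfcomp) ds <- ds - 1.4  # symmetry correction

  R <- 1.987
  # annealing-oligo-in-excess convention: C = primer concentration
  conc <- primer_nM * 1e-9
  na_M <- Na / 1000

  if (tab$salt == "entropy")
    ds <- ds + 0.368 * (nchar(s) - 1) * log(na_M)
  tm <- 1000 * dh / (ds + R * log(conc)) - 273.15
  if (tab$salt == "schildkraut")
    tm <- tm + 16.6 * log10(na_M)
  tm
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1) via Biostrings; identity is 100 * matches / alignment
#' columns, gap columns included in the denominator.
#'
#' @param query,reference DNA strings.
#' @return percent identity in \[0, 100\].
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")  # 100
#' @export
pairwise_identity <- function(query, reference) {
  q <- .check_dna(query, "query")
  r <- .check_dna(reference, "reference")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    q, r, type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  100 * sum(pc == sc & pc != "-") / length(pc)
}

#' Classify an amplicon as gene or pseudogene by identity
#'
#' Computes percent identity of the query against a labelled reference set
#' that must contain a `CYP2D6` reference and at least one pseudogene
#' reference. Classification is `CYP2D6` iff identity to the CYP2D6
#' reference strictly exceeds the threshold and strictly exceeds the
#' identity to every pseudogene reference; `pseudogene` iff a pseudogene
#' reference wins and exceeds the threshold; otherwise `indeterminate`.
#'
#' @param query DNA string (e.g. a sequenced intron-2 amplicon).
#' @param references named character vector of reference sequences; the
#'   CYP2D6 reference is the element whose name contains `"CYP2D6"`.
#' @param threshold percent identity required for a confident call
#'   (default 95; calls require identity strictly greater).
#' @param query_id identifier recorded in the result.
#' @return object of class `cyp2d6_identity`: list with `query_id`,
#'   `identities` (named percent vector), `classification`, `threshold`.
#' @export
classify_amplicon <- function(query, references, threshold = 95,
                              query_id = "query") {
  if (length(references) < 2 || is.null(names(references)))
    stop("need >= 2 labelled references")
  is_gene <- grepl("CYP2D6", names(references))
  if (!any(is_gene)) stop("missing CYP2D6 reference")
  ids <- vapply(references, function(r) pairwise_identity(query, r), 0)
  gene_id <- max(ids[is_gene])
  pseudo_id <- if (any(!is_gene)) max(ids[!is_gene]) else -Inf
  classification <-
    if (gene_id > threshold && gene_id > pseudo_id) "CYP2D6"
    else if (pseudo_id > threshold && pseudo_id > gene_id) "pseudogene"
    else "indeterminate"
  structure(list(query_id = query_id, identities = ids,
                 classification = classification, threshold = threshold),
            class = "cyp2d6_identity")
}

#' @export
print.cyp2d6_identity <- function(x, ...) {
  cat(x$query_id, "->", x$classification,
      sprintf("(threshold %g%%)\n", x$threshold))
  for (nm in names(x$identities))
    cat(sprintf("  %-24s %6.2f%%\n", nm, x$identities[[nm]]))
  invisible(x)
}

#' Read the bundled primer/probe panel
#'
#' The 36 primer and probe sequences of the genotyping assay (XL-PCR outer
#' primers, nested sequencing primers, and allele-specific wild-type/mutant
#' probes per SNP) with their reported length, GC%, Tm and amplicon size.
#'
#' @param path optional path to a primer TSV with columns name, analysis,
#'   role, sequence and reported_* columns; default the bundled panel.
#' @return data.frame of primer records.
#' @export
read_primer_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "primers_table2.tsv",
                        package = "cyp2d6star", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Compute the primer QC metrics table
#'
#' For each primer/probe: length, GC% ([gc_percent()]) and nearest-neighbor
#' Tm ([melting_temperature()]), alongside any reported values present in
#' the input.
#'
#' @param primers data.frame from [read_primer_table()], or a named
#'   character vector of sequences.
#' @param ... passed to [melting_temperature()].
#' @return data.frame with name, role, sequence, length, gc, tm and any
#'   reported_* columns.
#' @export
primer_qc <- function(primers = read_primer_table(), ...) {
  if (is.character(primers))
    primers <- data.frame(name = names(primers), sequence = unname(primers),
                          stringsAsFactors = FALSE)
  out <- primers
  out$length <- nchar(primers$sequence)
  out$gc <- vapply(primers$sequence, gc_percent, 0, USE.NAMES = FALSE)
  out$tm <- round(vapply(primers$sequence, melting_temperature, 0, ...,
                         USE.NAMES = FALSE), 1)
  out
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*", "", names(x)))
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Bundled intron-2 reference sequences (synthetic)
#'
#' A 1101-base synthetic stand-in for the CYP2D6 intron-2 amplicon together
#' with synthetic CYP2D7 (~93% identity) and CYP2D8 (~91% identity)
#' pseudogene counterparts, for exercising the identity classifier without
#' external downloads. These are generated stand-ins, not GenBank sequences.
#'
#' @return named character vector of three sequences.
#' @export
intron2_references <- function() {
  read_fasta_sequences(system.file(
    "extdata", "intron2_references_synthetic.fasta",
    package = "cyp2d6star", mustWork = TRUE))
}
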