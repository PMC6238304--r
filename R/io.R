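# Genotype-table and VCF ingestion, and the TSV dialect writers.
#
# Genotype-table dialect: one row per sample; columns sample_id, one column
# per informative locus, deletion_band, duplication_band, exon9_conversion.
# Genotype tokens are dose letters R/R, R/A, A/A (NA = no call); a bases
# dialect ("C/T") is auto-detected against the catalog.

.token_to_call <- function(token, ref, alt, row, col) {
  if (is.na(token) || token %in% c("NA", "", ".", "./.")) return("missing")
  parts <- strsplit(token, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("malformed genotype token '", token, "' at row ", row,
         ", column ", col)
  lut <- c(R = "R", A = "A")
  lut[ref] <- "R"
  lut[alt] <- "A"
  coded <- lut[parts]
  if (any(is.na(coded)))
    stop("malformed genotype token '", token, "' at row ", row,
         ", column ", col)
  dose <- sum(coded == "A")
  c("ref_ref", "ref_alt", "alt_alt")[dose + 1L]
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(isTRUE(x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a genotype table TSV
#'
#' Parses the sample-per-row genotype dialect into `cyp2d6_sample` records.
#' Locus columns not in the catalog's informative loci but present in the
#' catalog are read normally; columns unknown to the catalog are preserved
#' as pass-through metadata with a warning.
#'
#' @param path TSV file.
#' @param table a `cyp2d6_allele_table` (for locus names and ref/alt bases).
#' @return list of `cyp2d6_sample` records.
#' @export
read_genotype_table <- function(path, table) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column")
  flag_cols <- c("deletion_band", "duplication_band", "exon9_conversion")
  known <- table$variants$id
  locus_cols <- setdiff(names(df), c("sample_id", flag_cols))
  unknown <- setdiff(locus_cols, known)
  if (length(unknown)) {
    warning("unknown locus column(s) kept as metadata: ",
            paste(unknown, collapse = ", "))
    locus_cols <- intersect(locus_cols, known)
  }
  vinfo <- table$variants[match(locus_cols, table$variants$id), ]

  lapply(seq_len(nrow(df)), function(i) {
    g <- vapply(seq_along(locus_cols), function(j)
      .token_to_call(df[[locus_cols[j]]][i], vinfo$ref_base[j],
                     vinfo$alt_base[j], i, locus_cols[j]), "")
    names(g) <- locus_cols
    exon9 <- if ("exon9_conversion" %in% names(df)) {
      v <- tolower(df$exon9_conversion[i])
      if (v %in% c("present", "het", "hom", "absent", "untested")) v
      else if (.parse_flag(v)) "present"
      else if (v %in% c("false", "f", "0", "no")) "absent"
      else "untested"
    } else "untested"
    sample_record(
      df$sample_id[i], g,
      deletion_band = "deletion_band" %in% names(df) &&
        .parse_flag(df$deletion_band[i]),
      duplication_band = "duplication_band" %in% names(df) &&
        .parse_flag(df$duplication_band[i]),
      exon9_conversion = exon9,
      meta = as.list(df[i, unknown, drop = FALSE]))
  })
}

#' Write sample records as a genotype table TSV
#'
#' @param samples list of `cyp2d6_sample` records.
#' @param path output file.
#' @param table a `cyp2d6_allele_table`; loci written in informative order.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(samples, path, table) {
  loci <- table$informative_loci
  tok <- c(ref_ref = "R/R", ref_alt = "R/A", alt_alt = "A/A", missing = "NA")
  rows <- lapply(samples, function(s) {
    g <- vapply(loci, function(l)
      tok[[s$genotypes[l] %||% "missing"]], "")
    c(sample_id = s$sample_id, g,
      deletion_band = tolower(s$deletion_band),
      duplication_band = tolower(s$duplication_band),
      exon9_conversion = s$exon9_conversion)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF restricted to the catalog rsIDs
#'
#' Matches biallelic VCF records to catalog variants by the ID field
#' (dbSNP rsIDs), maps GT to genotype calls, and defaults structural flags
#' (no band data in VCF): deletion/duplication bands `FALSE`, exon-9
#' conversion `untested`. A sidecar TSV with columns `sample_id` and any of
#' `deletion_band`, `duplication_band`, `exon9_conversion` overrides the
#' defaults. An rsID absent from the VCF yields `missing` at that locus.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param table a `cyp2d6_allele_table` whose variants carry rsIDs.
#' @param sidecar optional path to the structural-flag TSV.
#' @return list of `cyp2d6_sample` records, one per VCF sample column.
#' @export
read_vcf_genotypes <- function(path, table, sidecar = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  rsids <- table$variants$rsid
  keep_loci <- table$variants$id[rsids != "" &
                                   table$variants$id %in% table$informative_loci]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  if (is.null(sample_ids)) stop("VCF has no sample columns")

  calls <- matrix("missing", nrow = length(keep_loci), ncol = length(sample_ids),
                  dimnames = list(keep_loci, sample_ids))
  for (locus in keep_loci) {
    rsid <- table$variants$rsid[table$variants$id == locus]
    row <- which(fix$ID == rsid)
    if (length(row) == 0) next
    if (length(row) > 1 || grepl(",", fix$ALT[row]))
      stop("multiallelic record at catalog rsID ", rsid)
    g <- gt[row, ]
    g <- gsub("|", "/", g, fixed = TRUE)
    calls[locus, ] <- ifelse(
      is.na(g) | g %in% c("./.", "."), "missing",
      ifelse(g == "0/0", "ref_ref",
             ifelse(g %in% c("0/1", "1/0"), "ref_alt",
                    ifelse(g == "1/1", "alt_alt", "missing"))))
  }

  side <- NULL
  if (!is.null(sidecar)) {
    side <- utils::read.delim(sidecar, stringsAsFactors = FALSE,
                              colClasses = "character")
    if (!"sample_id" %in% names(side)) stop("sidecar missing sample_id")
  }

  lapply(sample_ids, function(sid) {
    delb <- FALSE; dupb <- FALSE; exon9 <- "untested"
    if (!is.null(side) && sid %in% side$sample_id) {
      r <- side[side$sample_id == sid, , drop = FALSE][1, ]
      if ("deletion_band" %in% names(side)) delb <- .parse_flag(r$deletion_band)
      if ("duplication_band" %in% names(side)) dupb <- .parse_flag(r$duplication_band)
      if ("exon9_conversion" %in% names(side)) {
        v <- tolower(r$exon9_conversion)
        if (v %in% c("present", "het", "hom", "absent", "untested"))
          exon9 <- v
      }
    }
    sample_record(sid, calls[, sid], deletion_band = delb,
                  duplication_band = dupb, exon9_conversion = exon9)
  })
}

#' Write a simulation truth table
#'
#' @param truth data.frame (sample_id, true_diplotype) from
#'   [simulate_population()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
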