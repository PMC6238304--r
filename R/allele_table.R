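# Allele-definition model: the variant catalog and star-allele table that
# every downstream stage (caller, population statistics, simulator) consumes.

.FUNCTION_CLASSES <- c("normal", "decreased", "none")
.STRUCTURAL_KINDS <- c("whole_gene_deletion", "duplication", "exon9_conversion")

#' Load a star-allele definition table
#'
#' Reads an allele-definition document (JSON) describing the variant catalog,
#' the star alleles with their defining variants and structural events, the
#' informative loci the caller may use, and activity scores per function
#' class. The bundled default table (`cyp2d6_karen6.json`) encodes the
#' six-allele CYP2D6 panel (*1, *2, *4, *5, *10, *36) over the four
#' informative SNPs C100T, G1846A, C2850T and G4180C, with the whole-gene
#' deletion (*5) and exon-9 CYP2D7 gene-conversion (*36) structural events.
#'
#' @param source path to a JSON document, or an already-parsed list with the
#'   same structure. `NULL` (default) loads the bundled table.
#' @return an object of class `cyp2d6_allele_table`: a list with elements
#'   `variants` (data.frame: id, position, ref_base, alt_base, rsid, region,
#'   effect), `alleles` (named list; each allele has `name`, `key_variants`,
#'   `all_variants`, `structural`, `function_class`, `activity_value`),
#'   `informative_loci` (character), `activity_scores` (named numeric) and
#'   `name`.
#' @examples
#' tab <- load_allele_table()
#' tab$alleles[["*4"]]$all_variants
#' @export
load_allele_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "cyp2d6_karen6.json",
                          package = "cyp2d6star", mustWork = TRUE)
  }
  doc <- if (is.character(source)) {
    jsonlite::read_json(source, simplifyVector = FALSE)
  } else if (is.list(source)) {
    source
  } else {
    stop("`source` must be a file path or a list")
  }

  variants <- do.call(rbind, lapply(doc$variants, function(v) {
    data.frame(id = v$id, position = as.integer(v$position),
               ref_base = v$ref_base, alt_base = v$alt_base,
               rsid = v$rsid %||% "", region = v$region %||% "",
               effect = v$effect %||% "", stringsAsFactors = FALSE)
  }))

  scores <- unlist(doc$activity_scores %||%
                     list(normal = 1.0, decreased = 0.5, none = 0.0))

  alleles <- lapply(doc$alleles, function(a) {
    cls <- a$function_class
    list(name = a$name,
         key_variants = sort(as.character(unlist(a$key_variants))),
         all_variants = sort(as.character(unlist(a$all_variants))),
         structural = sort(as.character(unlist(a$structural))),
         function_class = cls,
         activity_value = as.numeric(a$activity_value %||% scores[[cls]]))
  })
  names(alleles) <- vapply(alleles, `[[`, "", "name")

  tab <- structure(
    list(name = doc$name %||% "allele_table",
         reference = doc$reference %||% "",
         variants = variants,
         alleles = alleles,
         informative_loci = as.character(unlist(doc$informative_loci)),
         activity_scores = scores),
    class = "cyp2d6_allele_table")
  validate_allele_table(tab)
  tab
}

#' Validate an allele table
#'
#' Checks the structural invariants of an allele-definition table: variant
#' ids consistent with ref/position/alt, unique positions, allele names
#' unique, every referenced variant present in the catalog, key variants a
#' subset of all variants, legal function classes and structural kinds,
#' activity consistency (no-function alleles score 0), and signature
#' uniqueness (no two alleles share both variant content and structural
#' events).
#'
#' @param table a `cyp2d6_allele_table`.
#' @return the table, invisibly; stops with an informative error otherwise.
#' @export
validate_allele_table <- function(table) {
  v <- table$variants
  if (anyDuplicated(v$id))
    stop("duplicate variant ids: ", paste(v$id[duplicated(v$id)], collapse = ", "))
  if (anyDuplicated(v$position))
    stop("duplicate variant positions")
  bad <- v$ref_base == v$alt_base
  if (any(bad)) stop("ref_base equals alt_base for: ", paste(v$id[bad], collapse = ", "))
  expect_id <- paste0(v$ref_base, v$position, v$alt_base)
  if (any(expect_id != v$id))
    stop("variant id inconsistent with ref/position/alt: ",
         paste(v$id[expect_id != v$id], collapse = ", "))
  if (!all(v$ref_base %in% c("A", "C", "G", "T")) ||
      !all(v$alt_base %in% c("A", "C", "G", "T")))
    stop("variant bases must be A/C/G/T")

  al <- table$alleles
  nm <- vapply(al, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate allele names: ", paste(nm[duplicated(nm)], collapse = ", "))
  for (a in al) {
    unknown <- setdiff(a$all_variants, v$id)
    if (length(unknown))
      stop("allele ", a$name, " references unknown variant(s): ",
           paste(unknown, collapse = ", "))
    if (!all(a$key_variants %in% a$all_variants))
      stop("allele ", a$name, ": key_variants not a subset of all_variants")
    if (!a$function_class %in% .FUNCTION_CLASSES)
      stop("allele ", a$name, ": unknown function class '", a$function_class, "'")
    if (!all(a$structural %in% .STRUCTURAL_KINDS))
      stop("allele ", a$name, ": unknown structural kind")
    if (a$function_class == "none" && a$activity_value != 0)
      stop("allele ", a$name, ": function class 'none' requires activity 0")
    if (a$activity_value < 0)
      stop("allele ", a$name, ": negative activity value")
  }
  sig <- vapply(al, function(a)
    paste(paste(a$all_variants, collapse = ","), "|",
          paste(a$structural, collapse = ",")), "")
  if (anyDuplicated(sig)) {
    i <- which(sig == sig[duplicated(sig)][1])
    stop("signature collision: alleles ", paste(nm[i], collapse = " and "),
         " share the same variant content and structural events")
  }
  unknown_loci <- setdiff(table$informative_loci, v$id)
  if (length(unknown_loci))
    stop("informative loci not in catalog: ", paste(unknown_loci, collapse = ", "))
  invisible(table)
}

#' Map allele names to function classes
#'
#' @param table a `cyp2d6_allele_table`.
#' @return named character vector, allele name -> function class
#'   (`normal`, `decreased`, `none`).
#' @examples
#' function_summary(load_allele_table())
#' @export
function_summary <- function(table) {
  vapply(table$alleles, `[[`, "", "function_class")
}

#' Star-allele names in a table
#' @param table a `cyp2d6_allele_table`.
#' @param include_deletion keep whole-gene-deletion alleles (default TRUE).
#' @return character vector of allele names in table order.
#' @export
allele_names <- function(table, include_deletion = TRUE) {
  nm <- names(table$alleles)
  if (!include_deletion) {
    del <- vapply(table$alleles,
                  function(a) "whole_gene_deletion" %in% a$structural, NA)
    nm <- nm[!del]
  }
  nm
}

# Name of the whole-gene-deletion allele (e.g. "*5"), or NA if none defined.
deletion_allele <- function(table) {
  del <- vapply(table$alleles,
                function(a) "whole_gene_deletion" %in% a$structural, NA)
  if (!any(del)) return(NA_character_)
  names(table$alleles)[del][1]
}

# Names of exon-9 conversion alleles (e.g. "*36").
conversion_alleles <- function(table) {
  conv <- vapply(table$alleles,
                 function(a) "exon9_conversion" %in% a$structural, NA)
  names(table$alleles)[conv]
}

#' Serialize an allele table to JSON
#'
#' Writes a document that [load_allele_table()] reads back to an identical
#' table (field-by-field round trip).
#'
#' @param table a `cyp2d6_allele_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path) {
  doc <- list(
    name = table$name,
    reference = table$reference,
    variants = lapply(seq_len(nrow(table$variants)), function(i)
      as.list(table$variants[i, ])),
    informative_loci = as.list(table$informative_loci),
    activity_scores = as.list(table$activity_scores),
    alleles = lapply(unname(table$alleles), function(a)
      list(name = a$name,
           key_variants = as.list(a$key_variants),
           all_variants = as.list(a$all_variants),
           structural = as.list(a$structural),
           function_class = a$function_class,
           activity_value = a$activity_value))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cyp2d6_allele_table <- function(x, ...) {
  cat("CYP2D6 allele-definition table '", x$name, "' (", x$reference, ")\n",
      sep = "")
  cat(" ", nrow(x$variants), "catalogued variants;",
      length(x$informative_loci), "informative loci:",
      paste(x$informative_loci, collapse = ", "), "\n")
  for (a in x$alleles) {
    content <- c(a$all_variants, a$structural)
    cat(sprintf("  %-4s %-9s  %s\n", a$name, a$function_class,
                if (length(content)) paste(content, collapse = ", ")
                else "(reference)"))
  }
  invisible(x)
}
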