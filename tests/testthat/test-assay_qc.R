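test_that("gc_percent matches reported values and rejects bad input", {
  expect_equal(gc_percent("GTTATCCCAGAAGGCTTTGCAGGCTTCA"), 50.0)
  expect_equal(gc_percent("CCTGGGAAGGCCCCATGGAAG"), 66.7)
  expect_equal(gc_percent("ATAT"), 0.0)
  expect_equal(gc_percent("GCGC"), 100.0)
  expect_error(gc_percent(""), "non-empty")
  expect_error(gc_percent("ACGN"), "non-ACGT")
})

test_that("gc_percent is reverse-complement invariant and length-weighted", {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1),
                      replace = TRUE), collapse = "")
    expect_equal(gc_percent(s), gc_percent(rc(s)))
  }
  a <- "GGGGGGGGGG"; b <- "ATATATATATATATATATAT"
  w <- (nchar(a) * gc_percent(a) + nchar(b) * gc_percent(b)) /
    (nchar(a) + nchar(b))
  expect_equal(gc_percent(paste0(a, b)), round(w, 1), tolerance = 0.05)
})

test_that("the bundled primer panel reproduces the printed metrics", {
  qc <- primer_qc(read_primer_table())
  expect_equal(nrow(qc), 36)
  probe <- grepl("probe", qc$role)

  expect_equal(qc$length, qc$reported_length)
  # primers: printed GC has one decimal; probes are printed as integers
  expect_true(all(abs(qc$gc - qc$reported_gc)[!probe] <= 0.1))
  expect_true(all(abs(qc$gc - qc$reported_gc)[probe] <= 0.5))
  # primer Tm within the documented +/- 5 degC of the printed column
  expect_true(all(abs(qc$tm - qc$reported_tm)[!probe] <= 5))
})

test_that("melting temperature obeys thermodynamic sanity properties", {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_gt(melting_temperature("GCGCGCGCGCGC"),
            melting_temperature("ATATATATATAT"))
  set.seed(5)
  for (m in c("breslauer1986", "santalucia1998")) {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
      expect_equal(melting_temperature(s, method = m),
                   melting_temperature(rc(s), method = m),
                   tolerance = 1e-9)
    }
  }
  expect_error(melting_temperature("ACGTACG"), "too short")
  # salt dependence: lower ionic strength destabilises the duplex
  s <- "GTTATCCCAGAAGGCTTTGCAGGCTTCA"
  expect_lt(melting_temperature(s, Na = 10), melting_temperature(s, Na = 200))
})

test_that("both NN parameter sets reproduce frozen thermodynamic values", {
  # reference values computed independently with Biopython MeltingTemp
  # (Tm_NN; DNA_NN1 + Schildkraut for breslauer1986, DNA_NN3 + entropy salt
  # correction for santalucia1998; 50 mM Na+, 50 nM oligo)
  frozen <- list(
    list(seq = "GTTATCCCAGAAGGCTTTGCAGGCTTCA", brs = 70.1221, sl = 62.4989),
    list(seq = "GCCGACTGAGCCCTGGGAGGTAGGTA",   brs = 71.3592, sl = 65.8529),
    list(seq = "CCTGGGAAGGCCCCATGGAAG",        brs = 68.5336, sl = 60.6971),
    list(seq = "TTTTGCACTGTGGGTCCTC",          brs = 56.7964, sl = 54.1082),
    list(seq = "CCTGAGAGCAGCTTCAATGATGA",      brs = 61.5269, sl = 56.4425))
  for (f in frozen) {
    expect_equal(melting_temperature(f$seq), f$brs, tolerance = 1e-3)
    expect_equal(melting_temperature(f$seq, method = "santalucia1998"),
                 f$sl, tolerance = 1e-3)
  }
  expect_equal(melting_temperature("GTTATCCCAGAAGGCTTTGCAGGCTTCA"),
               67.8, tolerance = 5)
})

test_that("pairwise identity is exact on forced cases", {
  refs <- intron2_references()
  d6 <- refs[["CYP2D6_INT2_synthetic"]]
  expect_equal(pairwise_identity(d6, d6), 100)
  s <- strrep("ACGT", 25)
  s1 <- paste0(substr(s, 1, 49), "T", substr(s, 51, 100))  # one substitution
  expect_equal(pairwise_identity(s, s1), 99.0)
  expect_error(pairwise_identity("ACGT", "ACNN"), "non-ACGT")
})

test_that("8% divergence drops identity below the 95% threshold", {
  refs <- intron2_references()
  d6 <- refs[["CYP2D6_INT2_synthetic"]]
  below <- 0
  for (i in 1:100) {
    q <- mutate_sequence(d6, 0.08, seed = 1000 + i)
    if (pairwise_identity(q, d6) < 95) below <- below + 1
  }
  expect_gte(below, 99)
})

test_that("5% divergence lands near 95% identity", {
  refs <- intron2_references()
  d6 <- refs[["CYP2D6_INT2_synthetic"]]
  ids <- vapply(1:20, function(i)
    pairwise_identity(mutate_sequence(d6, 0.05, seed = i), d6), 0)
  expect_true(all(abs(ids - 95) <= 1))
})

test_that("amplicon classification separates gene from pseudogenes", {
  refs <- intron2_references()
  d6 <- refs[["CYP2D6_INT2_synthetic"]]
  d7 <- refs[["CYP2D7_INT2_synthetic"]]

  expect_equal(classify_amplicon(d6, refs)$classification, "CYP2D6")
  expect_equal(classify_amplicon(d7, refs)$classification, "pseudogene")
  # a mildly mutated gene amplicon still classifies as CYP2D6
  q <- mutate_sequence(d6, 0.02, seed = 9)
  expect_equal(classify_amplicon(q, refs)$classification, "CYP2D6")
  # a sequence far from both references is indeterminate
  far <- mutate_sequence(d6, 0.3, seed = 10)
  expect_equal(classify_amplicon(far, refs)$classification, "indeterminate")
  expect_error(classify_amplicon(d6, c(x = d6, y = d7)), "CYP2D6 reference")
})

test_that("classifier never calls CYP2D6 at identity <= threshold", {
  refs <- intron2_references()
  d6 <- refs[["CYP2D6_INT2_synthetic"]]
  for (div in c(0.04, 0.06, 0.08, 0.12)) {
    for (i in 1:10) {
      q <- mutate_sequence(d6, div, seed = 100 * div * 1000 + i)
      res <- classify_amplicon(q, refs)
      if (res$identities[["CYP2D6_INT2_synthetic"]] <= res$threshold)
        expect_false(res$classification == "CYP2D6")
    }
  }
})
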