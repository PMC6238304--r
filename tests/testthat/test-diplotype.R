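tab <- default_table()

test_that("predict_genotype composes allele content with dose", {
  # *2/*10 heterozygous compound: het at 100 and 2850, hom at 4180
  expect_equal(predict_genotype(c("*2", "*10"), "C100T", tab), "ref_alt")
  expect_equal(predict_genotype(c("*2", "*10"), "C2850T", tab), "ref_alt")
  expect_equal(predict_genotype(c("*2", "*10"), "G4180C", tab), "alt_alt")
  expect_equal(predict_genotype(c("*2", "*10"), "G1846A", tab), "ref_ref")
  # reference pair
  for (locus in tab$informative_loci)
    expect_equal(predict_genotype(c("*1", "*1"), locus, tab), "ref_ref")
  # errors
  expect_error(predict_genotype(c("*2", "*10"), "X1Y", tab), "unknown locus")
  expect_error(predict_genotype(c("*2", "*77"), "C100T", tab),
               "unknown allele")
})

test_that("hemizygotes appear homozygous at every locus", {
  expect_equal(predict_genotype(c("*2", "*5"), "C2850T", tab), "alt_alt")
  expect_equal(predict_genotype(c("*2", "*5"), "C100T", tab), "ref_ref")
  expect_equal(predict_genotype(c("*5", "*10"), "C100T", tab), "alt_alt")
  expect_equal(predict_genotype(c("*5", "*5"), "C100T", tab), "missing")
})

test_that("consistent_pairs matches the worked profiles", {
  s <- sample_record("a", c(C100T = "ref_alt", G1846A = "ref_ref",
                            C2850T = "ref_alt", G4180C = "alt_alt"))
  expect_equal(pair_set(consistent_pairs(s, tab)), "*2/*10")

  s <- sample_record("b", c(C100T = "ref_ref", G1846A = "ref_ref",
                            C2850T = "ref_ref", G4180C = "ref_ref"),
                     deletion_band = TRUE)
  expect_equal(pair_set(consistent_pairs(s, tab)), "*1/*5")

  # *4 requires co-occurring C100T: an isolated 1846 homozygote is impossible
  s <- sample_record("c", c(C100T = "ref_ref", G1846A = "alt_alt",
                            C2850T = "ref_ref", G4180C = "ref_ref"))
  expect_length(consistent_pairs(s, tab), 0)
})

test_that("exon-9 policy gates the conversion allele", {
  g10 <- c(C100T = "alt_alt", G1846A = "ref_ref",
           C2850T = "ref_ref", G4180C = "alt_alt")
  untested <- sample_record("u", g10)
  present <- sample_record("p", g10, exon9_conversion = "present")
  absent <- sample_record("n", g10, exon9_conversion = "absent")

  expect_equal(pair_set(consistent_pairs(untested, tab)), "*10/*10")
  expect_equal(pair_set(consistent_pairs(absent, tab)), "*10/*10")
  # zygosity-unresolved evidence keeps both conversion-bearing pairs
  expect_equal(pair_set(consistent_pairs(present, tab)),
               c("*10/*36", "*36/*36"))
  # sequencing-resolved zygosity separates them
  het <- sample_record("ht", g10, exon9_conversion = "het")
  hom <- sample_record("hm", g10, exon9_conversion = "hom")
  expect_equal(pair_set(consistent_pairs(het, tab)), "*10/*36")
  expect_equal(pair_set(consistent_pairs(hom, tab)), "*36/*36")
  # ambiguity switch restores *36 as an unconstrained candidate
  expect_equal(pair_set(consistent_pairs(untested, tab,
                                         allow_untested_exon9_ambiguity = TRUE)),
               c("*10/*10", "*10/*36", "*36/*36"))
})

test_that("call_diplotype ranks, breaks ties, and assigns status", {
  s <- sample_record("a", c(C100T = "ref_alt", G1846A = "ref_ref",
                            C2850T = "ref_alt", G4180C = "alt_alt"))
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "unique")
  expect_equal(cl$best_pair, c("*2", "*10"))

  s <- sample_record("d", c(C100T = "alt_alt", G1846A = "ref_ref",
                            C2850T = "ref_ref", G4180C = "alt_alt"),
                     deletion_band = TRUE)
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "unique")
  expect_equal(cl$best_pair, c("*5", "*10"))

  s <- sample_record("e", c(C100T = "alt_alt", G1846A = "ref_alt",
                            C2850T = "ref_ref", G4180C = "alt_alt"))
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "unique")
  expect_equal(cl$best_pair, c("*4", "*10"))

  # ambiguous profile under the ambiguity switch: priors decide (the
  # heterozygous pair counts twice under random union), ties break
  # lexicographically on the canonical label
  g10 <- c(C100T = "alt_alt", G1846A = "ref_ref",
           C2850T = "ref_ref", G4180C = "alt_alt")
  cl <- call_diplotype(sample_record("f", g10), tab,
                       allow_untested_exon9_ambiguity = TRUE)
  expect_equal(cl$status, "ambiguous")
  expect_equal(pair_set(cl$consistent_pairs),
               c("*10/*10", "*10/*36", "*36/*36"))
  expect_equal(cl$best_pair, c("*10", "*36"))
  skew <- c("*1" = 1, "*2" = 1, "*4" = 1, "*5" = 1, "*10" = 1, "*36" = 5)
  cl <- call_diplotype(sample_record("g", g10), tab, priors = skew,
                       allow_untested_exon9_ambiguity = TRUE)
  expect_equal(cl$best_pair, c("*36", "*36"))
  # exact tie between *10/*36 (2*1*2) and *36/*36 (2*2): lexicographic win
  tie <- c("*1" = 1, "*2" = 1, "*4" = 1, "*5" = 1, "*10" = 1, "*36" = 2)
  cl <- call_diplotype(sample_record("h", g10), tab, priors = tie,
                       allow_untested_exon9_ambiguity = TRUE)
  expect_equal(cl$best_pair, c("*10", "*36"))
})

test_that("inadmissible and degenerate records get diagnostic statuses", {
  # heterozygous call with the deletion band: impossible hemizygote
  s <- sample_record("x", c(C100T = "ref_alt", G1846A = "ref_ref",
                            C2850T = "ref_ref", G4180C = "ref_alt"),
                     deletion_band = TRUE)
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "inconsistent")
  expect_match(cl$notes, "het_call_with_deletion_band", all = FALSE)

  # homozygous whole-gene deletion: all loci missing + band
  s <- sample_record("y", c(C100T = "missing", G1846A = "missing",
                            C2850T = "missing", G4180C = "missing"),
                     deletion_band = TRUE)
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "unique")
  expect_equal(cl$best_pair, c("*5", "*5"))
  expect_match(cl$notes, "homozygous_whole_gene_deletion", all = FALSE)

  # missing loci with several survivors: insufficient data
  s <- sample_record("z", c(C100T = "missing", G1846A = "ref_ref",
                            C2850T = "ref_ref", G4180C = "missing"))
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "insufficient_data")
  expect_null(cl$best_pair)
  expect_gt(length(cl$consistent_pairs), 1)

  # a single missing locus can still leave a unique survivor
  s <- sample_record("z2", c(C100T = "missing", G1846A = "ref_ref",
                             C2850T = "ref_ref", G4180C = "alt_alt"))
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "unique")
  expect_equal(cl$best_pair, c("*10", "*10"))

  # duplication band annotates but never filters
  s <- sample_record("w", c(C100T = "ref_alt", G1846A = "ref_ref",
                            C2850T = "ref_alt", G4180C = "alt_alt"),
                     duplication_band = TRUE)
  cl <- call_diplotype(s, tab)
  expect_equal(cl$status, "unique")
  expect_match(cl$notes, "duplication_present_copy_number_unresolved",
               all = FALSE)
})

test_that("render-then-call round-trips every diplotype in the universe", {
  nondel <- c("*1", "*2", "*4", "*10", "*36")
  pairs <- list()
  for (i in seq_along(nondel)) for (j in i:length(nondel))
    pairs[[length(pairs) + 1]] <- c(nondel[i], nondel[j])
  for (a in nondel) pairs[[length(pairs) + 1]] <- c(a, "*5")
  expect_length(pairs, 20)

  for (p in pairs) {
    s <- render_sample(p, tab, exon9_policy = "render")
    cl <- call_diplotype(s, tab)
    expect_equal(cl$status, "unique", info = paste(p, collapse = "/"))
    expect_equal(cl$best_pair, canon(p), info = paste(p, collapse = "/"))
  }
})

test_that("consistent_pairs agrees with the independent oracle", {
  set.seed(42)
  for (i in 1:1000) {
    s <- random_sample_record(tab, id = paste0("r", i))
    ambig <- i %% 2 == 0
    got <- consistent_pairs(s, tab, allow_untested_exon9_ambiguity = ambig)
    want <- oracle_consistent_pairs(s, tab,
                                    allow_untested_exon9_ambiguity = ambig)
    expect_equal(pair_set(got), pair_set(want), info = paste("case", i))
  }
})

test_that("masking a locus never shrinks the consistent set", {
  set.seed(7)
  for (i in 1:200) {
    s <- random_sample_record(tab)
    base <- pair_set(consistent_pairs(s, tab))
    for (locus in tab$informative_loci) {
      if (s$genotypes[[locus]] == "missing") next
      s2 <- s
      s2$genotypes[[locus]] <- "missing"
      # the homozygous-deletion collapse (deletion band + all loci
      # missing -> *5/*5) is a defined degenerate case, not a masking step
      if (s2$deletion_band && all(s2$genotypes == "missing")) next
      expect_true(all(base %in% pair_set(consistent_pairs(s2, tab))))
    }
  }
})

test_that("unique calls are invariant to priors", {
  set.seed(11)
  skew <- c("*1" = 9, "*2" = 0.1, "*4" = 3, "*5" = 0.5, "*10" = 1, "*36" = 7)
  for (i in 1:200) {
    s <- random_sample_record(tab)
    c1 <- call_diplotype(s, tab)
    if (c1$status != "unique") next
    c2 <- call_diplotype(s, tab, priors = skew)
    expect_equal(c2$best_pair, c1$best_pair)
  }
})

test_that("call_batch preserves order and isolates bad samples", {
  good <- render_sample(c("*2", "*10"), tab, sample_id = "g1")
  bad <- sample_record("b1", c(C100T = "ref_alt", G1846A = "ref_ref",
                               C2850T = "ref_ref", G4180C = "ref_alt"),
                       deletion_band = TRUE)
  calls <- call_batch(list(good, bad, good), tab, quiet = TRUE)
  expect_length(calls, 3)
  expect_equal(vapply(calls, `[[`, "", "sample_id"), c("g1", "b1", "g1"))
  expect_equal(vapply(calls, `[[`, "", "status"),
               c("unique", "inconsistent", "unique"))
  expect_length(call_batch(list(), tab, quiet = TRUE), 0)
})
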