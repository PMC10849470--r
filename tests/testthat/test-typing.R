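test_that("translation reports protein and ORF status", {
  expect_equal(translate_cds("ATGTGA"), list(protein = "M", orf_status = "complete"))
  expect_equal(translate_cds("ATGAAA"), list(protein = "MK", orf_status = "no_stop"))
  expect_equal(translate_cds("ATGAAAG")$orf_status, "not_multiple_of_3")
  expect_equal(translate_cds("ATGTAAAAATGA")$orf_status, "internal_stop")
})

# toy db with a partial-CDS record added
typing_db <- function() {
  db <- toy_db()
  recs <- unname(db$alleles)
  partial <- allele_record(parse_allele_name("HLX9*01:04"),
                           cds_seq = "AAATGG",   # middle chunk of base CDS
                           completeness = "partial_cds")
  reference_db(c(recs, list(partial)), version = db$version)
}

template_for <- function(db, priority = "b_cds_gapless",
                         raw = "HLX9*01:01:01:01") {
  list(allele = db$alleles[[raw]],
       alignment = gapless_aln(raw, qlen = 18L, mismatches = 1L),
       priority = priority)
}

test_that("a perfect template is called directly", {
  db <- typing_db()
  call <- type_allele(template_for(db, "a_perfect"), "ATGAAATGGTGA", db)
  expect_equal(call$call_string, "HLX9*01:01:01:01")
  expect_equal(call$novelty, "none")
  expect_equal(call$edit_distance, 0L)
})

test_that("CDS identical to the database but imperfect gene gives a field-4 call", {
  db <- typing_db()
  call <- type_allele(template_for(db), "ATGAAATGGTGA", db)
  # base and its intronic sibling share this CDS; a full-length allele beats
  # the contained partial by alignment length
  expect_equal(call$best_matches, c("HLX9*01:01:01:01", "HLX9*01:01:01:02"))
  expect_equal(call$call_string, "HLX9*01:01:01:new")
  expect_equal(call$novelty, "field4")
})

test_that("equidistant alleles of equal length are all reported", {
  db <- typing_db()
  target <- "ATGAAATGCTGA"  # TGG->TGC: distance 1 to the CDS-identical
                            # base pair, distance 2 to the AAG variant
  call <- type_allele(template_for(db), target, db)
  expect_equal(call$best_matches, c("HLX9*01:01:01:01", "HLX9*01:01:01:02"))

  # equidistant across allele groups -> gene-level novelty
  db2 <- reference_db(list(
    allele_record(parse_allele_name("HLX8*01:01"), cds_seq = "ATGAAATGGTGA",
                  completeness = "full_cds_only"),
    allele_record(parse_allele_name("HLX8*02:05"), cds_seq = "ATGAAGTGGTGA",
                  completeness = "full_cds_only")))
  tpl <- list(allele = db2$alleles[["HLX8*01:01"]],
              alignment = gapless_aln("HLX8*01:01", qlen = 18L, mismatches = 1L),
              priority = "b_cds_gapless")
  call2 <- type_allele(tpl, "ATGAACTGGTGA", db2)  # distance 1 to both groups
  expect_equal(call2$novelty, "gene_only")
  expect_equal(call2$call_string, "HLX8*new")
})

test_that("partial CDS records require exact containment and lose ties on length", {
  db <- typing_db()
  # mismatch within the partial's span: partial inadmissible
  target <- "ATGTAATGGTGA"
  call <- type_allele(template_for(db), target, db)
  expect_false("HLX9*01:04" %in% call$best_matches)
  # novel CDS where the partial is contained but every full allele is
  # distance >= 2: the partial wins at distance 0
  target2 <- "ATAAAATGGTGG"
  expect_true(grepl("AAATGG", target2, fixed = TRUE))
  call2 <- type_allele(template_for(db), target2, db)
  expect_equal(call2$best_matches, "HLX9*01:04")
})

test_that("typing agrees with the brute-force oracle on mutated toy CDSs", {
  db <- typing_db()
  set.seed(8)
  base <- "ATGAAATGGTGA"
  for (i in 1:25) {
    target <- base
    for (k in seq_len(sample(0:2, 1))) {
      p <- sample(nchar(target), 1)
      substr(target, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    call <- type_allele(template_for(db), target, db)
    oracle <- type_bruteforce(target, db, "HLX9")
    expect_equal(call$best_matches, oracle)
  }
})

test_that("novel names put 'new' in the affected field with prefix truncation", {
  db <- typing_db()
  # protein affected -> field 2, deeper fields dropped
  nv <- name_novel(c("HLX9*01:01:01:01", "HLX9*01:01:01:02"),
                   "ATGCAATGGTGA", FALSE, db)  # K->Q nonsynonymous
  expect_equal(nv$call_string, "HLX9*01:new")
  expect_equal(nv$novelty, "field2")
  # synonymous CDS change -> field 3
  nv3 <- name_novel(c("HLX9*01:01:01:01", "HLX9*01:01:01:02"),
                    "ATGAAGTGGTGA", FALSE, db)
  expect_equal(nv3$call_string, "HLX9*01:01:new")
  expect_equal(nv3$novelty, "field3")
  # non-coding only -> field 4
  nv4 <- name_novel(c("HLX9*01:01:01:01", "HLX9*01:01:01:02"),
                    "ATGAAATGGTGA", FALSE, db)
  expect_equal(nv4$call_string, "HLX9*01:01:01:new")
  expect_equal(nv4$novelty, "field4")
  # perfect gene match: no novelty
  nv0 <- name_novel("HLX9*01:01:01:01", "ATGAAATGGTGA", TRUE, db)
  expect_equal(nv0$novelty, "none")
})

test_that("short best-match names cap the 'new' field at depth + 1", {
  db2 <- reference_db(list(
    allele_record(parse_allele_name("HLX7*01:01"), cds_seq = "ATGAAATGGTGA",
                  completeness = "full_cds_only")))
  # non-coding difference, but the best match has only two fields
  nv <- name_novel("HLX7*01:01", "ATGAAATGGTGA", FALSE, db2)
  expect_equal(nv$call_string, "HLX7*01:01:new")
  expect_equal(nv$novelty, "field4")
})

test_that("pseudogene novelty never reaches the protein field", {
  db3 <- reference_db(list(
    allele_record(parse_allele_name("HLX6*01:01:01"), cds_seq = "ATGTAGAAATGA",
                  completeness = "full_cds_only", is_pseudogene = TRUE),
    allele_record(parse_allele_name("HLX6*01:01:02"), cds_seq = "ATGTAGAAATGA",
                  completeness = "full_cds_only", is_pseudogene = TRUE)))
  # a CDS change on a pseudogene is field 3, not field 2
  nv <- name_novel(c("HLX6*01:01:01", "HLX6*01:01:02"), "ATGTAGAACTGA",
                   FALSE, db3)
  expect_equal(nv$novelty, "field3")
  expect_equal(nv$call_string, "HLX6*01:01:new")
})

test_that("an untranslatable CDS of a coding gene is named at the CDS layer", {
  db <- typing_db()
  nv <- name_novel(c("HLX9*01:01:01:01", "HLX9*01:01:01:02"),
                   "ATGTAATGGTGA", FALSE, db)   # internal stop
  expect_true(nv$incomplete_orf)
  expect_equal(nv$novelty, "field3")
})
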