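# candidates built around the toy database: gene with exons [0,6) and
# [12,18) on an 18-bp allele
toy_candidate <- function(ops, q_start = 0L, q_end = 18L, strand = "+") {
  db <- toy_db()
  rec <- db$alleles[["HLX9*01:01:01:01"]]
  a <- alignment_record(rec$name$raw, 18L, "c", strand, q_start, q_end,
                        100L, 100L + sum(ops$len[ops$op != "I"]), ops)
  list(allele = rec, alignment = a, priority = NA_character_)
}

test_that("coverage and identity thresholds gate template candidates", {
  db <- toy_db()
  good <- gapless_aln("HLX9*01:01:01:01", qlen = 1000L, mismatches = 10L)
  lowcov <- gapless_aln("HLX9*01:01:01:01", qlen = 1000L, q_end = 890L)
  lowid <- gapless_aln("HLX9*01:01:01:01", qlen = 1000L, mismatches = 31L)
  cluster <- list(target_contig = "c", span = c(0, 1000),
                  members = list(good, lowcov, lowid))
  kept <- filter_candidates(cluster, db)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$alignment$query_cov, 1.0)
  # boundary: exactly 0.90 coverage and 0.97 identity are kept
  edge <- gapless_aln("HLX9*01:01:01:01", qlen = 1000L, q_end = 900L,
                      mismatches = 27L)
  expect_equal(edge$query_cov, 0.90)
  expect_length(filter_candidates(list(target_contig = "c", span = c(0, 1000),
                                       members = list(edge)), db), 1)
})

test_that("priority tiers follow the perfect/gapless/frameshift/incomplete scheme", {
  perfect <- toy_candidate(data.frame(op = "=", len = 18L))
  expect_equal(classify_priority(perfect)$priority, "a_perfect")

  # one intronic SNP only (position 8 is inside the intron [6,12))
  intronic <- toy_candidate(data.frame(op = c("=", "X", "="),
                                       len = c(8L, 1L, 9L)))
  expect_equal(classify_priority(intronic)$priority, "b_cds_gapless")

  # 1-bp deletion inside exon 2 (query base 14 missing from the target)
  fs <- toy_candidate(data.frame(op = c("=", "I", "="),
                                 len = c(14L, 1L, 3L)))
  expect_equal(classify_priority(fs)$priority, "c_cds_frameshift")

  # 3-bp in-frame indel inside an exon is neither gapless nor a frameshift
  inframe <- toy_candidate(data.frame(op = c("=", "I", "="),
                                      len = c(13L, 3L, 2L)))
  expect_equal(classify_priority(inframe)$priority, "d_cds_incomplete")

  # an indel confined to the intron leaves the CDS gapless
  intron_gap <- toy_candidate(data.frame(op = c("=", "D", "="),
                                         len = c(8L, 5L, 10L)))
  expect_equal(classify_priority(intron_gap)$priority, "b_cds_gapless")

  # CDS bases beyond the aligned range make the template incomplete
  clipped <- toy_candidate(data.frame(op = "=", len = 15L), q_end = 15L)
  expect_equal(classify_priority(clipped)$priority, "d_cds_incomplete")
})

test_that("template selection prefers tier, then differences, then length, then name", {
  b1 <- toy_candidate(data.frame(op = c("=", "X", "="), len = c(8L, 1L, 9L)))
  c1 <- toy_candidate(data.frame(op = c("=", "I", "="), len = c(14L, 1L, 3L)))
  b1 <- classify_priority(b1); c1 <- classify_priority(c1)
  expect_equal(select_template(list(c1, b1))$priority, "b_cds_gapless")

  d1 <- gapless_aln("A*01", qlen = 1000L, mismatches = 1L)
  d3 <- gapless_aln("A*02", qlen = 1000L, mismatches = 3L)
  cd1 <- list(allele = toy_db()$alleles[[1]], alignment = d1, priority = "b_cds_gapless")
  cd3 <- list(allele = toy_db()$alleles[[2]], alignment = d3, priority = "b_cds_gapless")
  expect_equal(select_template(list(cd3, cd1))$alignment$d, 1L)

  tie1 <- list(allele = toy_db()$alleles[["HLX9*01:01:01:02"]],
               alignment = d1, priority = "b_cds_gapless")
  tie2 <- list(allele = toy_db()$alleles[["HLX9*01:01:01:01"]],
               alignment = d1, priority = "b_cds_gapless")
  expect_equal(select_template(list(tie1, tie2))$allele$name$raw,
               "HLX9*01:01:01:01")
})

test_that("identity alignments lift exons by a constant offset", {
  cand <- toy_candidate(data.frame(op = "=", len = 18L))
  ann <- lift_structure(classify_priority(cand))
  expect_equal(ann$exons, cbind(start = c(100L, 112L), end = c(106L, 118L)))
  expect_length(ann$flags, 0)
})

test_that("a target insertion before an exon shifts later exons only", {
  # 10-bp insertion in the target inside the intron (after query base 8)
  cand <- toy_candidate(data.frame(op = c("=", "D", "="),
                                   len = c(8L, 10L, 10L)))
  ann <- lift_structure(classify_priority(cand))
  expect_equal(ann$exons[1, ], c(start = 100L, end = 106L))
  expect_equal(ann$exons[2, ], c(start = 122L, end = 128L))  # +10 shift
  expect_equal(ann$exons[, 2] - ann$exons[, 1], c(6L, 6L))   # lengths kept
})

test_that("boundaries in a target deletion snap to the exon interior", {
  # target deletion removes query bases 12..13 (start of exon 2)
  cand <- toy_candidate(data.frame(op = c("=", "I", "="),
                                   len = c(12L, 2L, 4L)))
  ann <- lift_structure(classify_priority(cand))
  # exon 2 starts at the first aligned base after the deletion
  expect_equal(unname(ann$exons[2, 1]), 112L)
  expect_true("partial" %in% ann$flags)
})

test_that("minus-strand annotation reports forward coordinates in transcription order", {
  dbt <- make_db(n_genes = 1, seed = 13)
  raw <- "HLX1*01:01:01:01"
  rec <- dbt$db$alleles[[raw]]
  contig <- paste0(random_dna(1000), revcomp(rec$gene_seq), random_dna(1000))
  res <- annotate_contigs(c(ctg = contig), dbt$db)
  expect_length(res$annotations, 1)
  ann <- res$annotations[[1]]
  expect_equal(ann$strand, "-")
  # transcription order means genomic coordinates descend across exons
  expect_true(all(diff(ann$exons[, 1]) < 0))
  # exon sizes match the template's
  expect_equal(sort(ann$exons[, 2] - ann$exons[, 1]),
               sort(rec$exons[, 2] - rec$exons[, 1]))
  expect_equal(ann$call$call_string, raw)
})

test_that("extract_cds reproduces the reference CDS for planted alleles", {
  set.seed(5)
  for (s in c(31, 32)) {
    dbt <- make_db(n_genes = 2, gene_len_range = c(3000, 6000), seed = s)
    pl <- data.frame(gene = c("HLX1", "HLX2"),
                     allele = c("HLX1*01:01:01:01", "HLX2*01:01:01:02"),
                     strand = sample(c("+", "-"), 2, replace = TRUE),
                     mutation = "none")
    fx <- plant(dbt, pl, seed = s + 100)
    res <- annotate_contigs(fx$contigs, dbt$db)
    expect_length(res$annotations, 2)
    for (ann in res$annotations) {
      cds <- extract_cds(ann, fx$contigs[[1]])
      tmpl <- dbt$db$alleles[[ann$template]]
      expect_identical(cds, tmpl$cds_seq)
    }
  }
})

test_that("lifted exon lengths differ from the template by net exonic indels", {
  # 2-bp target deletion inside exon 2: lifted exon sum = template sum - 2
  cand <- toy_candidate(data.frame(op = c("=", "I", "="),
                                   len = c(13L, 2L, 3L)))
  ann <- lift_structure(classify_priority(cand))
  tmpl_sum <- 12L
  lifted_sum <- sum(ann$exons[, 2] - ann$exons[, 1])
  expect_equal(tmpl_sum - lifted_sum, 2L)
})
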