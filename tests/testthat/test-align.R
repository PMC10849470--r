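test_that("gap-compressed identity follows m/(m+d)", {
  expect_equal(gci(97, 3), 0.97)
  expect_equal(gci(100, 0), 1.0)
  expect_error(gci(0, 0), "empty")
  # one 10-bp deletion and one substitution over 11,000 matched bases:
  # the deletion is one gap-compressed difference regardless of length
  ops <- data.frame(op = c("=", "D", "=", "X", "="),
                    len = c(5000L, 10L, 3000L, 1L, 3000L))
  a <- alignment_record("A*01", 11001L, "c", "+", 0L, 11001L, 0L, 11011L, ops)
  expect_equal(a$d, 2L)
  expect_equal(a$gci, 11000 / 11002)
})

test_that("m and d agree with recounting from an independent pairwise alignment", {
  set.seed(41)
  for (i in 1:5) {
    q <- random_dna(400)
    # mutate: two SNPs and one 4-bp deletion
    t <- q
    substr(t, 50, 50) <- if (substr(t, 50, 50) == "A") "C" else "A"
    substr(t, 300, 300) <- if (substr(t, 300, 300) == "G") "T" else "G"
    t <- paste0(substr(t, 1, 150), substr(t, 155, 400))
    contig <- paste0(random_dna(300), t, random_dna(300))
    dbrec <- allele_record(parse_allele_name(sprintf("T%d*01", i)),
                           gene_seq = q,
                           exons = cbind(start = 0L, end = 400L),
                           cds_seq = q, completeness = "full_gene")
    db <- reference_db(list(dbrec))
    alns <- align_alleles(db, c(ctg = contig))
    expect_length(alns, 1)
    # oracle: affine-gap pairwise alignment of the two raw sequences
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(t), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 1)
    md <- md_from_gapped(as.character(Biostrings::alignedPattern(pa)),
                         as.character(Biostrings::alignedSubject(pa)))
    expect_equal(alns[[1]]$m, md$m)
    expect_equal(alns[[1]]$d, md$d)
  }
})

test_that("planted copies are found exactly, on both strands and in tandem", {
  dbt <- make_db(n_genes = 1, gene_len_range = c(3000L, 5000L), seed = 9)
  raw <- "HLX1*01:01:01:01"
  g <- dbt$db$alleles[[raw]]$gene_seq
  contig <- paste0(random_dna(2000), g, random_dna(1500), g,
                   random_dna(2000), revcomp(g), random_dna(1000))
  alns <- align_alleles(dbt$db, c(ctg = contig))
  mine <- Filter(function(a) a$query == raw, alns)
  expect_length(mine, 3)
  strands <- vapply(mine, `[[`, "", "strand")
  expect_equal(sum(strands == "-"), 1L)
  expect_equal(sum(strands == "+"), 2L)
  for (a in mine) {
    expect_equal(a$gci, 1.0)
    expect_equal(a$query_cov, 1.0)
  }
  spans <- t(vapply(mine, function(a) c(a$t_start, a$t_end), c(0, 0)))
  expect_equal(nrow(unique(spans)), 3)
})

test_that("ranking is by identity, then aligned length, then name", {
  a1 <- gapless_aln("B*02", qlen = 3000L, mismatches = 30L)   # gci ~.99, len 3000
  a2 <- gapless_aln("A*01", qlen = 4000L, mismatches = 40L)   # gci ~.99, len 4000
  a3 <- gapless_aln("C*03", qlen = 4000L, mismatches = 0L)    # gci 1
  r <- rank_alignments(list(a1, a2, a3))
  expect_equal(vapply(r, `[[`, "", "query"), c("C*03", "A*01", "B*02"))
  # exact tie broken lexicographically
  t1 <- gapless_aln("Z*09", qlen = 1000L, mismatches = 10L)
  t2 <- gapless_aln("A*01", qlen = 1000L, mismatches = 10L)
  r2 <- rank_alignments(list(t1, t2))
  expect_equal(r2[[1]]$query, "A*01")
  expect_length(rank_alignments(list(a1)), 1)
})

test_that("greedy clustering merges overlaps, skips bridges, keeps loci apart", {
  mk <- function(q, t0, len) gapless_aln(q, qlen = len, t_start = t0)
  three <- list(mk("A*01", 0L, 500L), mk("A*02", 100L, 500L),
                mk("A*03", 300L, 500L))
  cl <- cluster_alignments(three)
  expect_length(cl$clusters, 1)
  expect_length(cl$clusters[[1]]$members, 3)
  expect_equal(cl$clusters[[1]]$span, c(0, 800))

  far <- list(mk("A*01", 0L, 500L), mk("A*02", 100000L, 500L))
  expect_length(cluster_alignments(far)$clusters, 2)

  # a worse alignment bridging two established clusters is skipped
  bridge <- list(mk("A*01", 0L, 500L), mk("A*02", 2000L, 500L),
                 gapless_aln("A*03", qlen = 3000L, t_start = 100L,
                             mismatches = 200L))
  cl3 <- cluster_alignments(rank_alignments(bridge))
  expect_length(cl3$clusters, 2)
  expect_length(cl3$skipped, 1)
  expect_equal(cl3$skipped[[1]]$query, "A*03")
})

test_that("cluster spans stay pairwise disjoint on random inputs", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    alns <- lapply(seq_len(n), function(i)
      gapless_aln(sprintf("G%d*01", i), qlen = sample(200:800, 1),
                  t_start = sample(0:5000, 1),
                  mismatches = sample(0:5, 1)))
    cl <- cluster_alignments(rank_alignments(alns))
    spans <- t(vapply(cl$clusters, `[[`, c(0, 0), "span"))
    if (nrow(spans) > 1) {
      o <- order(spans[, 1])
      expect_true(all(spans[o, 1][-1] >= spans[o, 2][-nrow(spans)]))
    }
    n_assigned <- sum(vapply(cl$clusters, function(x) length(x$members), 0L))
    expect_equal(n_assigned + length(cl$skipped), n)
  }
})

test_that("PAF records with cs tags are parsed into the oriented convention", {
  paf <- tempfile(fileext = ".paf")
  writeLines(paste(
    c("Q*01", "100", "0", "100", "+", "ctg", "5000", "200", "299",
      "98", "100", "60", "cs:Z::40*ac:19-gg:39"), collapse = "\t"), paf)
  a <- read_paf(paf)[[1]]
  expect_equal(a$m, 98L)
  expect_equal(a$d, 2L)      # one mismatch + one 2-bp deletion (one gap)
  expect_equal(a$t_start, 200L)
  expect_equal(a$strand, "+")
  unlink(paf)
})

test_that("the minimap2 engine agrees with the internal engine on a fixture", {
  skip_if(Sys.which("minimap2") == "", "minimap2 not on PATH")
  dbt <- make_db(n_genes = 2, gene_len_range = c(3000L, 6000L), seed = 21)
  fx <- plant(dbt, data.frame(gene = c("HLX1", "HLX2"),
                              allele = c("HLX1*01:01:01:01", "HLX2*01:01:01:01"),
                              strand = c("+", "-"), mutation = "none"),
              seed = 22)
  internal <- align_alleles(dbt$db, fx$contigs, engine = "internal")
  mm2 <- align_alleles(dbt$db, fx$contigs, engine = "minimap2")
  key <- function(a) sprintf("%s:%d-%d:%s", a$query, a$t_start, a$t_end, a$strand)
  perfect <- function(alns) sort(vapply(Filter(function(a) a$d == 0 &&
                                                 a$query_cov == 1, alns), key, ""))
  expect_equal(perfect(mm2), perfect(internal))
})
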