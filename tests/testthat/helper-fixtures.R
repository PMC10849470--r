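# shared fixture builders (all generated in code; nothing on disk)

# tiny three-allele database of one toy gene, hand-assembled
toy_db <- function() {
  mk <- function(raw, gene_seq, exons, cds, completeness = "full_gene",
                 pseudo = FALSE) {
    allele_record(parse_allele_name(raw), gene_seq = gene_seq, exons = exons,
                  cds_seq = cds, completeness = completeness,
                  is_pseudogene = pseudo)
  }
  # gene: exon1 [0,6) intron [6,12) exon2 [12,18); CDS = ATGAAA + TGGTGA
  ex <- cbind(start = c(0L, 12L), end = c(6L, 18L))
  g1 <- paste0("ATGAAA", "TTTTTT", "TGGTGA")
  g2 <- paste0("ATGAAA", "TTTATT", "TGGTGA")          # intronic SNP
  g3 <- paste0("ATGAAG", "TTTTTT", "TGGTGA")          # synonymous K codon SNP
  reference_db(list(
    mk("HLX9*01:01:01:01", g1, ex, "ATGAAATGGTGA"),
    mk("HLX9*01:01:01:02", g2, ex, "ATGAAATGGTGA"),
    mk("HLX9*01:01:02", g3, ex, "ATGAAGTGGTGA")),
    version = "toy")
}

# simple gapless alignment record over a planted query
gapless_aln <- function(query = "HLX9*01:01:01:01", qlen = 100L,
                        contig = "c", strand = "+", t_start = 0L,
                        mismatches = 0L, q_start = 0L, q_end = qlen) {
  alen <- q_end - q_start
  ops <- if (mismatches == 0L) data.frame(op = "=", len = alen)
         else data.frame(op = c("=", "X", "="),
                         len = c(alen - mismatches - 1L, mismatches, 1L))
  alignment_record(query, qlen, contig, strand, q_start, q_end,
                   t_start, t_start + alen, ops)
}

# standard ladder placement table over the five default genes
ladder_placements <- function(genes = sprintf("HLX%d", 1:5)) {
  data.frame(
    gene = genes,
    allele = paste0(genes, "*01:01:01:01"),
    strand = rep(c("+", "-"), length.out = length(genes)),
    mutation = rep(c("none", "intronic", "synonymous", "nonsynonymous",
                     "group_ambiguous"), length.out = length(genes)))
}

# match pipeline calls against planted truth; returns fraction correct
score_against_truth <- function(res, truth) {
  ok <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (isTRUE(tr$truncated)) {
      hit <- any(vapply(res$untypable, function(u)
        u$contig == tr$contig && u$span[1L] < tr$end && tr$start < u$span[2L],
        TRUE))
      ok <- ok + hit
      next
    }
    s <- res$summary
    row <- s[!is.na(s$gene) & s$gene == tr$gene & s$contig == tr$contig &
               s$start < tr$end & tr$start < s$end, , drop = FALSE]
    if (nrow(row) == 1L &&
        identical(row$allele, tr$expected_call) &&
        identical(row$novelty, tr$expected_novelty) &&
        identical(row$strand, tr$strand))
      ok <- ok + 1L
  }
  ok / nrow(truth)
}
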