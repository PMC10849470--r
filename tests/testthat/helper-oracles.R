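# Independent oracles used to cross-check the implementation on small
# instances.  These deliberately avoid the code paths (and, where
# possible, the libraries) used by the package itself.

# plain dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  a <- strsplit(a, "")[[1L]]
  b <- strsplit(b, "")[[1L]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- numeric(length(b) + 1L)
    cur[1L] <- i
    for (j in seq_along(b)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[length(b) + 1L]
}

# recount m (matches) and d (mismatches + gap openings) directly from the
# gapped strings of a pairwise alignment
md_from_gapped <- function(pat, sub) {
  p <- strsplit(pat, "")[[1L]]
  s <- strsplit(sub, "")[[1L]]
  state <- ifelse(p == "-", "D", ifelse(s == "-", "I",
                                        ifelse(p == s, "=", "X")))
  r <- rle(state)
  list(m = sum(r$lengths[r$values == "="]),
       d = sum(r$lengths[r$values == "X"]) +
         sum(r$values == "I") + sum(r$values == "D"))
}

# O(n^2 L) double-loop mean pairwise Hamming fraction
diversity_bruteforce <- function(seqs) {
  n <- length(seqs)
  L <- unname(nchar(seqs[1L]))
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- strsplit(seqs[i], "")[[1L]]; b <- strsplit(seqs[j], "")[[1L]]
    tot <- tot + sum(a != b) / L
    cnt <- cnt + 1L
  }
  tot / cnt
}

# brute-force allele typing: full Levenshtein of every full CDS, partials
# by exact containment; rank by distance then query length
type_bruteforce <- function(target_cds, db, gene) {
  rows <- NULL
  for (raw in db$by_gene[[gene]]) {
    rec <- db$alleles[[raw]]
    if (rec$completeness == "partial_cds") {
      if (!grepl(rec$cds_seq, target_cds, fixed = TRUE)) next
      rows <- rbind(rows, data.frame(raw = raw, dist = 0,
                                     alen = nchar(rec$cds_seq)))
    } else {
      rows <- rbind(rows, data.frame(raw = raw,
                                     dist = lev_dp(rec$cds_seq, target_cds),
                                     alen = nchar(rec$cds_seq)))
    }
  }
  if (is.null(rows)) return(NULL)
  rows <- rows[rows$dist == min(rows$dist), , drop = FALSE]
  rows <- rows[rows$alen == max(rows$alen), , drop = FALSE]
  sort(rows$raw)
}
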