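# Alignment op convention (query -> target, both walked forward):
#   "=" match, "X" mismatch, "I" query base absent from target (insertion
#   relative to the target), "D" target base absent from query.
# Query coordinates are on the *oriented* query: for strand "-" the query
# was reverse-complemented before alignment, so target coordinates always
# ascend with query coordinates.

#' Gap-compressed identity
#'
#' Identity of an alignment computed as `m / (m + d)`, where `m` is the
#' number of matching bases and `d` the number of mismatching bases plus
#' the number of gaps, each gap counted once regardless of its length
#' ("gap-compressed").  A long indel therefore costs the same as a single
#' substitution, which keeps structurally equivalent alleles close.
#'
#' @param m number of matching bases (>= 0).
#' @param d number of mismatching bases plus gap openings (>= 0).
#' @return identity in `[0, 1]`.
#' @examples
#' gci(97, 3)    # 0.97
#' gci(11000, 2) # one 10-bp deletion + one substitution over 11 kb
#' @export
gci <- function(m, d) {
  if (m < 0 || d < 0) stop("m and d must be non-negative")
  if (m + d == 0) stop("empty alignment: m + d == 0")
  m / (m + d)
}

# summary statistics of an op table
ops_stats <- function(ops) {
  len <- ops$len
  op <- ops$op
  m <- sum(len[op == "="])
  x <- sum(len[op == "X"])
  list(m = m,
       d = x + sum(op == "I") + sum(op == "D"),
       alen = m + x,                        # aligned query bases, gaps excluded
       n_ins = sum(op == "I"), n_del = sum(op == "D"))
}

# collapse per-base match vector into an op table
ops_from_match <- function(match_vec) {
  r <- rle(ifelse(match_vec, "=", "X"))
  data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

# op table from gapped aligned strings (characters, '-' for gaps)
ops_from_aligned_strings <- function(pat, sub) {
  p <- strsplit(pat, "")[[1L]]
  s <- strsplit(sub, "")[[1L]]
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I", ifelse(p == s, "=", "X")))
  r <- rle(op)
  data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

#' Construct an alignment record
#'
#' @param query raw allele name of the query.
#' @param qlen query length in bases.
#' @param target_contig contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param q_start,q_end aligned range on the oriented query (0-based,
#'   half-open; the query is reverse-complemented first on strand `"-"`).
#' @param t_start,t_end aligned range on the forward contig (0-based,
#'   half-open).
#' @param ops data.frame with columns `op` (`=`/`X`/`I`/`D`) and `len`.
#' @return object of class `alignment_record` with derived fields `m`,
#'   `d`, `gci`, `alen` (aligned query bases) and `query_cov`.
#' @export
alignment_record <- function(query, qlen, target_contig, strand,
                             q_start, q_end, t_start, t_end, ops) {
  st <- ops_stats(ops)
  structure(list(query = query, qlen = qlen, target_contig = target_contig,
                 strand = strand, q_start = q_start, q_end = q_end,
                 t_start = t_start, t_end = t_end, ops = ops,
                 m = st$m, d = st$d, gci = gci(st$m, st$d),
                 alen = st$alen, query_cov = st$alen / qlen),
            class = "alignment_record")
}

#' @export
print.alignment_record <- function(x, ...) {
  cat(sprintf("<alignment> %s -> %s:%d-%d (%s)  gci=%.4f cov=%.3f d=%d\n",
              x$query, x$target_contig, x$t_start, x$t_end, x$strand,
              x$gci, x$query_cov, x$d))
  invisible(x)
}

# ---- internal seed-and-extend engine -------------------------------------

# Align one oriented query against one contig; returns list of
# (q_start, q_end, t_start, t_end, ops).  Loci are found by exact-seed
# diagonal voting; a single consistent diagonal is resolved gaplessly,
# inconsistent diagonals (indels) fall back to affine-gap dynamic
# programming restricted to a window (sequences <= 50 kb).
seed_extend <- function(qseq, tseq_ds, seed_k = 21L, diag_tol = 400L,
                        dp_pad = 200L) {
  qlen <- nchar(qseq)
  tlen <- length(tseq_ds)
  if (qlen < seed_k) return(list())
  qpos <- unique(c(seq(1L, qlen - seed_k + 1L,
                       by = max(150L, qlen %/% 40L)), qlen - seed_k + 1L))
  hits_q <- integer(0); hits_t <- integer(0)
  for (qp in qpos) {
    seed <- Biostrings::DNAString(substr(qseq, qp, qp + seed_k - 1L))
    mt <- Biostrings::matchPattern(seed, tseq_ds)
    if (length(mt)) {
      hits_q <- c(hits_q, rep(qp, length(mt)))
      hits_t <- c(hits_t, BiocGenerics::start(mt))
    }
  }
  if (!length(hits_q)) return(list())
  diag <- hits_t - hits_q                      # 1-based; == 0-based offset
  ord <- order(diag, hits_q)
  diag <- diag[ord]; hq <- hits_q[ord]; ht <- hits_t[ord]
  grp <- cumsum(c(1L, diff(diag) > diag_tol))
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    dg <- diag[sel]
    if (max(dg) == min(dg)) {
      d0 <- dg[1L]                             # 0-based target offset of query base 0
      q_start <- max(0L, -d0)
      q_end <- min(qlen, tlen - d0)
      if (q_end - q_start < seed_k) next
      t_start <- d0 + q_start
      t_end <- d0 + q_end
      tsub <- as.character(Biostrings::subseq(tseq_ds, t_start + 1L, t_end))
      qsub <- substr0(qseq, q_start, q_end)
      mm <- charToRaw(qsub) == charToRaw(tsub)
      out[[length(out) + 1L]] <- list(q_start = q_start, q_end = q_end,
                                      t_start = t_start, t_end = t_end,
                                      ops = ops_from_match(mm))
    } else {
      w_lo <- max(0L, min(dg) - dp_pad)
      w_hi <- min(tlen, max(dg) + qlen + dp_pad)
      if (qlen > 50000L || (w_hi - w_lo) > 60000L) {
        warning("indel-containing locus exceeds the dynamic-programming ",
                "size limit; locus skipped")
        next
      }
      win <- Biostrings::subseq(tseq_ds, w_lo + 1L, w_hi)
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                      baseOnly = TRUE)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(qseq), win, type = "global-local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
      ops <- ops_from_aligned_strings(
        as.character(Biostrings::alignedPattern(pa)),
        as.character(Biostrings::alignedSubject(pa)))
      sub_rng <- Biostrings::subject(pa)
      t_start <- w_lo + BiocGenerics::start(sub_rng) - 1L
      t_end <- w_lo + BiocGenerics::end(sub_rng)
      out[[length(out) + 1L]] <- list(q_start = 0L, q_end = qlen,
                                      t_start = t_start, t_end = t_end,
                                      ops = ops)
    }
  }
  out
}

#' Align reference alleles to contigs
#'
#' Maps every full-length gene sequence in the database to the contigs,
#' on both strands, allowing one query to align to multiple loci (genes
#' such as KIR2DL4 or C4 occur in several copies).  The default
#' `"internal"` engine seeds exact 21-mers, resolves each seeded locus
#' either gaplessly (consistent diagonal) or by affine-gap dynamic
#' programming (match 1, mismatch -2, gap open -4, gap extend -1) for
#' sequences up to 50 kb.  The `"minimap2"` engine shells out to minimap2
#' and parses its PAF + cs output; any engine honouring the same contract
#' (base-level ops) can be substituted.
#'
#' @param db a `reference_db`; only `full_gene` records are aligned.
#' @param contigs named character vector or `DNAStringSet` of contigs.
#' @param engine `"internal"` or `"minimap2"`.
#' @return list of `alignment_record`s.
#' @export
align_alleles <- function(db, contigs, engine = c("internal", "minimap2")) {
  engine <- match.arg(engine)
  if (is.character(contigs))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be named")
  full <- Filter(function(r) r$completeness == "full_gene", db$alleles)
  if (engine == "minimap2")
    return(minimap2_align(full, contigs))
  out <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[ci]
    tds <- contigs[[ci]]
    for (rec in full) {
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") rec$gene_seq else revcomp(rec$gene_seq)
        for (hit in seed_extend(qseq, tds)) {
          out[[length(out) + 1L]] <- alignment_record(
            query = rec$name$raw, qlen = nchar(qseq), target_contig = cname,
            strand = strand, q_start = hit$q_start, q_end = hit$q_end,
            t_start = hit$t_start, t_end = hit$t_end, ops = hit$ops)
        }
      }
    }
  }
  out
}

# minimap2 engine: requires the minimap2 executable on PATH
minimap2_align <- function(full_records, contigs) {
  if (Sys.which("minimap2") == "")
    stop("minimap2 executable not found on PATH")
  qfa <- tempfile(fileext = ".fa"); tfa <- tempfile(fileext = ".fa")
  paf <- tempfile(fileext = ".paf")
  on.exit(unlink(c(qfa, tfa, paf)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    vapply(full_records, function(r) r$gene_seq, "")), qfa)
  Biostrings::writeXStringSet(contigs, tfa)
  status <- system2("minimap2",
                    c("-c", "--cs", "-x", "asm10", "-N", "50", "-p", "0.2",
                      shQuote(tfa), shQuote(qfa)),
                    stdout = paf, stderr = FALSE)
  if (!identical(status, 0L))
    stop("minimap2 failed with exit status ", status)
  read_paf(paf)
}

#' Read alignments from a PAF file
#'
#' Parses minimap2-style PAF (columns 1--12 plus a `cs` or `cg` tag) into
#' `alignment_record`s, so pre-computed alignments can be injected into
#' the pipeline.  Query coordinates are converted to the oriented-query
#' convention used throughout the package.
#'
#' @param path PAF file.
#' @return list of `alignment_record`s.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) next
    qlen <- as.integer(f[2L]); qs <- as.integer(f[3L]); qe <- as.integer(f[4L])
    strand <- f[5L]
    ts <- as.integer(f[8L]); te <- as.integer(f[9L])
    tags <- f[-(1:12)]
    cs <- sub("^cs:Z:", "", grep("^cs:Z:", tags, value = TRUE))
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    ops <- if (length(cs)) ops_from_cs(cs[1L])
           else if (length(cg)) ops_from_cigar(cg[1L])
           else next
    if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    out[[length(out) + 1L]] <- alignment_record(
      query = f[1L], qlen = qlen, target_contig = f[6L], strand = strand,
      q_start = qs, q_end = qe, t_start = ts, t_end = te, ops = ops)
  }
  out
}

# cs tag (short form) -> op table
ops_from_cs <- function(cs) {
  toks <- regmatches(cs, gregexpr(":[0-9]+|\\*[a-z][a-z]|\\+[a-z]+|-[a-z]+", cs))[[1L]]
  op <- character(length(toks)); len <- integer(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    c1 <- substr(t, 1L, 1L)
    if (c1 == ":") { op[i] <- "="; len[i] <- as.integer(substr(t, 2L, nchar(t))) }
    else if (c1 == "*") { op[i] <- "X"; len[i] <- 1L }
    else if (c1 == "+") { op[i] <- "I"; len[i] <- nchar(t) - 1L }
    else { op[i] <- "D"; len[i] <- nchar(t) - 1L }
  }
  r <- rle(op)
  # merge adjacent single-base mismatches while keeping run lengths right
  out <- data.frame(op = character(0), len = integer(0))
  i <- 1L
  for (j in seq_along(r$values)) {
    n <- r$lengths[j]
    l <- sum(len[i:(i + n - 1L)])
    out <- rbind(out, data.frame(op = r$values[j], len = l))
    i <- i + n
  }
  out
}

# cigar string (with =/X or M) -> op table; M is not resolvable to =/X
ops_from_cigar <- function(cg) {
  toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  if (any(op == "M"))
    stop("CIGAR contains 'M'; need =/X resolution (use a cs tag)")
  keep <- op %in% c("=", "X", "I", "D")
  data.frame(op = op[keep], len = len[keep], stringsAsFactors = FALSE)
}

#' Rank alignments best-first
#'
#' Orders alignments by descending gap-compressed identity, then by
#' descending aligned length (aligned query bases, gaps excluded), then
#' by query allele name (lexicographic) so that equally good alignments
#' are processed deterministically.
#'
#' @param alns list of `alignment_record`s.
#' @return the same records, reordered.
#' @export
rank_alignments <- function(alns) {
  if (!length(alns)) return(alns)
  g <- vapply(alns, `[[`, 0, "gci")
  l <- vapply(alns, `[[`, 0, "alen")
  n <- vapply(alns, `[[`, "", "query")
  alns[order(-g, -l, n, method = "radix")]
}

#' Greedily cluster ranked alignments into candidate loci
#'
#' Iterates alignments from best to worst.  An alignment overlapping
#' exactly one existing cluster (>= 1 shared target base, same contig)
#' joins it and extends its span; an alignment overlapping none seeds a
#' new cluster; an alignment bridging two or more established clusters is
#' skipped.  Each resulting cluster ideally represents one candidate
#' gene, assuming genes are well separated on the contig.
#'
#' @param alns list of `alignment_record`s, already ranked
#'   (see [rank_alignments()]).
#' @return list with elements `clusters` (each a list with `target_contig`,
#'   `span`, `members`) and `skipped` (alignments dropped for
#'   multi-cluster overlap).
#' @export
cluster_alignments <- function(alns) {
  clusters <- list()
  skipped <- list()
  for (a in alns) {
    hit <- integer(0)
    for (i in seq_along(clusters)) {
      cl <- clusters[[i]]
      if (cl$target_contig == a$target_contig &&
          a$t_start < cl$span[2L] && cl$span[1L] < a$t_end)
        hit <- c(hit, i)
    }
    if (length(hit) == 0L) {
      clusters[[length(clusters) + 1L]] <-
        list(target_contig = a$target_contig,
             span = c(a$t_start, a$t_end), members = list(a))
    } else if (length(hit) == 1L) {
      i <- hit
      clusters[[i]]$span <- c(min(clusters[[i]]$span[1L], a$t_start),
                              max(clusters[[i]]$span[2L], a$t_end))
      clusters[[i]]$members <- c(clusters[[i]]$members, list(a))
    } else {
      skipped <- c(skipped, list(a))
    }
  }
  list(clusters = clusters, skipped = skipped)
}
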