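# Priority tiers for template selection, best first:
#   a_perfect        perfect full-length alignment, zero differences
#   b_cds_gapless    every CDS base aligned, no indel inside CDS
#   c_cds_frameshift CDS fully aligned but contains a frameshifting indel
#   d_cds_incomplete some CDS bases unaligned (or in-frame indels only)
PRIORITY_LEVELS <- c("a_perfect", "b_cds_gapless", "c_cds_frameshift",
                     "d_cds_incomplete")

# exon intervals of a record on the *oriented* query (0-based half-open),
# rows kept in transcription order; on the minus strand transcription-first
# exons sit at high oriented coordinates
oriented_exons <- function(rec, strand) {
  ex <- rec$exons
  if (strand == "+") return(ex)
  qlen <- nchar(rec$gene_seq)
  cbind(start = qlen - ex[, 2L], end = qlen - ex[, 1L])
}

# per-base map oriented-query position (0-based) -> target position, NA if
# the query base is unaligned (outside the aligned range or inside an
# insertion relative to the target)
query_target_map <- function(aln) {
  qmap <- rep(NA_integer_, aln$qlen)
  q <- aln$q_start; t <- aln$t_start
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "=" || op == "X") {
      qmap[(q + 1L):(q + len)] <- t:(t + len - 1L)
      q <- q + len; t <- t + len
    } else if (op == "I") {
      q <- q + len
    } else {
      t <- t + len
    }
  }
  qmap
}

# q-coordinates covered by each op (list of [start, end) on oriented query)
op_query_ranges <- function(aln) {
  n <- nrow(aln$ops)
  qs <- integer(n); qe <- integer(n)
  q <- aln$q_start
  for (i in seq_len(n)) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    qs[i] <- q
    if (op != "D") q <- q + len
    qe[i] <- q                       # D ops have an empty q range at a boundary
  }
  cbind(start = qs, end = qe)
}

#' Filter cluster members into template candidates
#'
#' A full-length gene sequence qualifies as a template candidate only
#' when at least `min_query_cov` of it is mapped and its gap-compressed
#' identity is at least `min_gci`; more divergent or fragmentary
#' alignments never define gene structure.  A cluster whose members all
#' fail is reported as detected but untypable.
#'
#' @param cluster one cluster from [cluster_alignments()].
#' @param db a `reference_db`.
#' @param min_query_cov minimum mapped fraction of the gene sequence
#'   (default 0.90).
#' @param min_gci minimum gap-compressed identity (default 0.97).
#' @return list of candidates (each: `allele` record, `alignment`,
#'   `priority` = `NA` until classified); empty when none qualify.
#' @export
filter_candidates <- function(cluster, db, min_query_cov = 0.90,
                              min_gci = 0.97) {
  out <- list()
  for (a in cluster$members) {
    rec <- db$alleles[[a$query]]
    if (is.null(rec) || rec$completeness != "full_gene") next
    if (a$query_cov < min_query_cov || a$gci < min_gci) next
    out[[length(out) + 1L]] <- list(allele = rec, alignment = a,
                                    priority = NA_character_)
  }
  out
}

#' Classify a template candidate into a priority tier
#'
#' @param candidate list with `allele` record and `alignment`.
#' @return the candidate with `priority` filled in (see
#'   `PRIORITY_LEVELS`).
#' @export
classify_priority <- function(candidate) {
  a <- candidate$alignment
  rec <- candidate$allele
  perfect <- a$q_start == 0L && a$q_end == a$qlen && a$d == 0L
  if (perfect) {
    candidate$priority <- "a_perfect"
    return(candidate)
  }
  ex <- oriented_exons(rec, a$strand)
  # "all CDS aligned" means every CDS base falls inside the aligned query
  # range; bases sitting in an insertion op still count as aligned here
  all_aligned <- all(ex[, 1L] >= a$q_start & ex[, 2L] <= a$q_end)
  if (!all_aligned) {
    candidate$priority <- "d_cds_incomplete"
    return(candidate)
  }
  qr <- op_query_ranges(a)
  indel <- a$ops$op %in% c("I", "D")
  in_cds <- function(i) {
    # an op intersects the CDS if its q range overlaps an exon interval;
    # deletions (empty q range at position p) count when p lies strictly
    # inside an exon
    s <- qr[i, 1L]; e <- qr[i, 2L]
    if (s == e) any(s > ex[, 1L] & s < ex[, 2L])
    else any(pmax(s, ex[, 1L]) < pmin(e, ex[, 2L]))
  }
  cds_indels <- which(indel & vapply(seq_len(nrow(qr)), in_cds, TRUE))
  if (length(cds_indels) == 0L) {
    candidate$priority <- "b_cds_gapless"
  } else if (any(a$ops$len[cds_indels] %% 3L != 0L)) {
    candidate$priority <- "c_cds_frameshift"
  } else {
    candidate$priority <- "d_cds_incomplete"
  }
  candidate
}

#' Select the template allele among classified candidates
#'
#' The highest priority tier wins; within a tier the candidate with the
#' fewest gap-compressed differences, then the longest aligned length,
#' then the lexicographically smallest allele name is chosen.
#'
#' @param candidates non-empty list of candidates with `priority` set.
#' @return the selected candidate.
#' @export
select_template <- function(candidates) {
  stopifnot(length(candidates) >= 1L)
  pri <- match(vapply(candidates, `[[`, "", "priority"), PRIORITY_LEVELS)
  d <- vapply(candidates, function(x) x$alignment$d, 0)
  alen <- vapply(candidates, function(x) x$alignment$alen, 0)
  nm <- vapply(candidates, function(x) x$allele$name$raw, "")
  candidates[[order(pri, d, -alen, nm, method = "radix")[1L]]]
}

#' Lift the template gene structure onto the contig
#'
#' Projects each exon/CDS boundary of the template allele through the
#' alignment onto contig coordinates.  Boundaries whose query base has no
#' aligned target base (inside a target deletion or outside the aligned
#' range) snap to the nearest aligned base on the exon-interior side,
#' keeping exons maximal within their aligned portion.  Minus-strand
#' genes are reported in contig forward coordinates with `strand == "-"`;
#' exons are listed in transcription order (genomic order reversed).
#' An exon with no aligned base at all flags the annotation `partial`.
#'
#' @param template selected template candidate ([select_template()]).
#' @param alignment the template's `alignment_record` (defaults to
#'   `template$alignment`).
#' @return object of class `gene_annotation`: list with `contig`, `gene`,
#'   `strand`, `exons` (matrix of genomic 0-based half-open intervals in
#'   transcription order; `NA` rows for unaligned exons), `cds`
#'   (identical to `exons` in this database dialect), `template`, `call`
#'   (`NULL` until typed) and `flags`.
#' @export
lift_structure <- function(template, alignment = template$alignment) {
  rec <- template$allele
  a <- alignment
  ex <- oriented_exons(rec, a$strand)
  qmap <- query_target_map(a)
  flags <- character(0)
  lifted <- matrix(NA_integer_, nrow = nrow(ex), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(nrow(ex))) {
    pos <- seq.int(ex[i, 1L], ex[i, 2L] - 1L)
    tp <- qmap[pos + 1L]
    tp <- tp[!is.na(tp)]
    if (!length(tp)) { flags <- union(flags, "partial"); next }
    lifted[i, ] <- c(min(tp), max(tp) + 1L)
    if (length(tp) < length(pos)) flags <- union(flags, "partial")
  }
  if (a$q_start > 0L || a$q_end < a$qlen) flags <- union(flags, "partial")
  structure(list(contig = a$target_contig, gene = rec$name$gene,
                 strand = a$strand, exons = lifted, cds = lifted,
                 template = rec$name$raw, call = NULL, flags = flags),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  rng <- range(x$exons, na.rm = TRUE)
  cat(sprintf("<gene_annotation> %s %s:%d-%d (%s) template=%s%s\n",
              x$gene, x$contig, rng[1L], rng[2L], x$strand, x$template,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Extract the annotated CDS from the contig
#'
#' Concatenates the CDS intervals in transcription order,
#' reverse-complementing minus-strand genes.
#'
#' @param annotation a `gene_annotation`.
#' @param contig_seq contig sequence (character or `DNAString`).
#' @return nucleotide string.
#' @export
extract_cds <- function(annotation, contig_seq) {
  contig_seq <- as.character(contig_seq)
  parts <- vapply(seq_len(nrow(annotation$cds)), function(i) {
    iv <- annotation$cds[i, ]
    if (anyNA(iv)) return("")
    s <- substr0(contig_seq, iv[1L], iv[2L])
    if (annotation$strand == "-") revcomp(s) else s
  }, "")
  paste(parts, collapse = "")
}
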