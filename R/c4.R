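# Complement component 4 (C4) is annotated differently from the
# HLA/KIR-style genes: a single reference transcript (41 exons, ~5.4 kb)
# is placed onto the contig exon-by-exon with colinear chaining
# (a spliced alignment), the A/B isotype is read from four diagnostic
# amino-acid positions on exon 26, and the long/short form from the
# length of intron 9 (the long form carries a ~6.2 kb endogenous
# retrovirus insertion there).

#' Default C4 typing configuration
#'
#' The diagnostic exon-26 residue positions and the A/B motifs are
#' configuration data, not hard-coded: the mechanism (four amino-acid
#' differences on exon 26) is fixed, the residues travel with the
#' reference.  Defaults use the isotypic C4A motif `PCLD` and C4B motif
#' `LSIH` at codon positions 24, 25, 28, 29 of the exon-26 peptide.
#'
#' @param diag_codons 1-based codon indices within the exon-26 peptide
#'   (first complete codon = 1).
#' @param a_motif,b_motif expected residues (one character per diagnostic
#'   position) for C4A and C4B.
#' @param long_form_threshold intron-9 length (bases) strictly above
#'   which a gene is long-form (default 5000).
#' @param min_transcript_cov minimum fraction of transcript bases placed
#'   for a locus to be typed (default 0.90).
#' @param max_intron maximum intron length allowed when chaining exon
#'   placements into one gene copy.
#' @param max_mismatch_frac per-exon mismatch budget for placement, as a
#'   fraction of exon length.
#' @return a list of class `c4_config`.
#' @export
c4_config <- function(diag_codons = c(24L, 25L, 28L, 29L),
                      a_motif = "PCLD", b_motif = "LSIH",
                      long_form_threshold = 5000L,
                      min_transcript_cov = 0.90,
                      max_intron = 50000L,
                      max_mismatch_frac = 0.06) {
  stopifnot(nchar(a_motif) == length(diag_codons),
            nchar(b_motif) == length(diag_codons),
            long_form_threshold > 0)
  structure(list(diag_codons = diag_codons, a_motif = a_motif,
                 b_motif = b_motif,
                 long_form_threshold = long_form_threshold,
                 min_transcript_cov = min_transcript_cov,
                 max_intron = max_intron,
                 max_mismatch_frac = max_mismatch_frac),
            class = "c4_config")
}

#' Long/short form from intron-9 length
#'
#' A C4 gene is long-form (`"L"`) when intron 9 is strictly longer than
#' the threshold (default 5 kb), otherwise short-form (`"S"`).
#'
#' @param intron9_len intron-9 length in bases.
#' @param long_form_threshold threshold in bases.
#' @return `"L"` or `"S"` (`NA` for missing input).
#' @examples
#' call_form(6200) # "L"
#' call_form(5000) # "S" (strictly greater than)
#' @export
call_form <- function(intron9_len, long_form_threshold = 5000L) {
  if (is.na(intron9_len)) return(NA_character_)
  if (intron9_len > long_form_threshold) "L" else "S"
}

#' C4A/C4B call from the exon-26 sequence
#'
#' Translates the exon-26 region in the template frame and compares the
#' diagnostic residues to the A and B motifs.  Only an exact match to one
#' motif types the gene; anything else (chimeric motifs, frames broken by
#' indels, truncated exons) is `ambiguous` with a reason.
#'
#' @param exon26_target_seq contig sequence of the placed exon 26, in
#'   transcript orientation.
#' @param config a [c4_config()].
#' @param phase_skip number of leading bases belonging to a codon begun
#'   in the previous exon (0--2).
#' @return list with `ab_type` (`"C4A"`, `"C4B"` or `"ambiguous"`),
#'   `residues` and `reason`.
#' @export
call_ab <- function(exon26_target_seq, config = c4_config(), phase_skip = 0L) {
  need <- phase_skip + max(config$diag_codons) * 3L
  if (nchar(exon26_target_seq) < need)
    return(list(ab_type = "ambiguous", residues = NA_character_,
                reason = "exon 26 too short for diagnostic codons"))
  pep <- translate_cds(substr(exon26_target_seq, phase_skip + 1L,
                              nchar(exon26_target_seq)))$protein
  res <- paste(strsplit(pep, "")[[1L]][config$diag_codons], collapse = "")
  if (identical(res, config$a_motif))
    list(ab_type = "C4A", residues = res, reason = NA_character_)
  else if (identical(res, config$b_motif))
    list(ab_type = "C4B", residues = res, reason = NA_character_)
  else
    list(ab_type = "ambiguous", residues = res,
         reason = "diagnostic residues match neither motif")
}

# chain exon placements (data.frame exon, start, end) into colinear gene
# copies; placements on the given strand, genomic order must follow
# transcription order (+: exon index ascends with position, -: descends)
chain_exon_placements <- function(pl, strand, max_intron) {
  if (!nrow(pl)) return(list())
  pl <- pl[order(pl$start), , drop = FALSE]
  if (strand == "-") pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
  chains <- list()
  cur <- NULL
  for (i in seq_len(nrow(pl))) {
    row <- pl[i, ]
    newchain <- is.null(cur) ||
      row$exon <= cur$exon[nrow(cur)] ||
      (strand == "+" && row$start - cur$end[nrow(cur)] > max_intron) ||
      (strand == "-" && cur$start[nrow(cur)] - row$end > max_intron)
    if (newchain) {
      if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
      cur <- row
    } else cur <- rbind(cur, row)
  }
  if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
  chains
}

#' Annotate C4 genes on a contig
#'
#' Places each exon of the reference C4 transcript onto the contig
#' (both strands, allowing a small mismatch budget per exon), chains
#' colinear placements into gene copies, and types each copy: A/B from
#' exon 26 ([call_ab()]) and long/short form from the intron-9 length
#' ([call_form()]).  Loci with less than `min_transcript_cov` of the
#' transcript placed are reported as partial and left untyped.  Multiple
#' C4 copies per contig are returned in genomic order.
#'
#' @param contig contig sequence (character or `DNAString`).
#' @param transcript reference C4 transcript sequence (character).
#' @param exons integer matrix of 0-based half-open exon intervals on the
#'   transcript (41 rows for a complete C4 gene).
#' @param config a [c4_config()].
#' @return list of `c4_call` objects: `locus` (0-based half-open contig
#'   interval), `strand`, `ab_type`, `form`, `intron9_len`, `exon_count`,
#'   `exon26_residues`, `exon_placements`, `flags`.
#' @export
annotate_c4 <- function(contig, transcript, exons, config = c4_config()) {
  contig_ds <- if (is(contig, "DNAString")) contig
               else Biostrings::DNAString(as.character(contig))
  n_exon <- nrow(exons)
  exon_seqs <- vapply(seq_len(n_exon), function(i)
    substr0(transcript, exons[i, 1L], exons[i, 2L]), "")
  calls <- list()
  for (strand in c("+", "-")) {
    pl <- data.frame(exon = integer(0), start = integer(0), end = integer(0))
    for (i in seq_len(n_exon)) {
      es <- if (strand == "+") exon_seqs[i] else revcomp(exon_seqs[i])
      mm <- max(2L, ceiling(config$max_mismatch_frac * nchar(es)))
      hits <- Biostrings::matchPattern(Biostrings::DNAString(es), contig_ds,
                                       max.mismatch = mm, with.indels = TRUE)
      if (length(hits))
        pl <- rbind(pl, data.frame(exon = i,
                                   start = BiocGenerics::start(hits) - 1L,
                                   end = BiocGenerics::end(hits)))
    }
    for (chain in chain_exon_placements(pl, strand, config$max_intron)) {
      cov <- sum(exons[chain$exon, 2L] - exons[chain$exon, 1L]) / nchar(transcript)
      locus <- c(min(chain$start), max(chain$end))
      flags <- character(0)
      if (cov < config$min_transcript_cov) {
        calls[[length(calls) + 1L]] <- structure(
          list(locus = locus, strand = strand, ab_type = NA_character_,
               form = NA_character_, intron9_len = NA_integer_,
               exon_count = nrow(chain), exon26_residues = NA_character_,
               exon_placements = chain, flags = "partial"),
          class = "c4_call")
        next
      }
      i9 <- NA_integer_
      if (all(c(9L, 10L) %in% chain$exon)) {
        e9 <- chain[chain$exon == 9L, ]; e10 <- chain[chain$exon == 10L, ]
        i9 <- if (strand == "+") e10$start - e9$end else e9$start - e10$end
      }
      ab <- list(ab_type = NA_character_, residues = NA_character_)
      if (26L %in% chain$exon) {
        e26 <- chain[chain$exon == 26L, ]
        s26 <- as.character(Biostrings::subseq(contig_ds, e26$start + 1L, e26$end))
        if (strand == "-") s26 <- revcomp(s26)
        phase_skip <- (3L - exons[26L, 1L] %% 3L) %% 3L
        ab <- call_ab(s26, config, phase_skip = phase_skip)
      }
      calls[[length(calls) + 1L]] <- structure(
        list(locus = locus, strand = strand, ab_type = ab$ab_type,
             form = call_form(i9, config$long_form_threshold),
             intron9_len = i9, exon_count = nrow(chain),
             exon26_residues = ab$residues, exon_placements = chain,
             flags = flags),
        class = "c4_call")
    }
  }
  starts <- vapply(calls, function(x) x$locus[1L], 0)
  calls[order(starts)]
}

#' @export
print.c4_call <- function(x, ...) {
  cat(sprintf("<c4_call> %s%s %d-%d (%s) intron9=%s exons=%d%s\n",
              x$ab_type %||% "?", x$form %||% "", x$locus[1L], x$locus[2L],
              x$strand, x$intron9_len, x$exon_count,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
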