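#' Translate a coding sequence
#'
#' Standard-table translation starting at position 0, with an ORF status
#' describing how well the sequence behaves as a complete coding frame.
#' The returned protein omits the terminal stop; internal stops are kept
#' as `*` so that protein comparison still works for degenerate frames.
#'
#' @param cds nucleotide string.
#' @return list with `protein` (amino-acid string) and `orf_status`, one
#'   of `"complete"`, `"no_stop"`, `"internal_stop"`,
#'   `"not_multiple_of_3"`.
#' @examples
#' translate_cds("ATGTGA")  # "M", complete
#' translate_cds("ATGAAA")  # "MK", no_stop
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  n_codon <- n %/% 3L
  if (n_codon == 0L)
    return(list(protein = "", orf_status = "not_multiple_of_3"))
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  status <- if (n %% 3L != 0L) "not_multiple_of_3"
    else if (any(aa[-n_codon] == "*")) "internal_stop"
    else if (aa[n_codon] != "*") "no_stop"
    else "complete"
  if (status %in% c("complete")) aa <- aa[-n_codon]
  else if (aa[n_codon] == "*" && status != "internal_stop") aa <- aa[-n_codon]
  list(protein = paste(aa, collapse = ""), orf_status = status)
}

# edit distance between two nucleotide strings (unit-cost Levenshtein)
edit_distance <- function(a, b) {
  if (identical(a, b)) return(0L)
  as.integer(adist(a, b))
}

#' Call the allele of an annotated gene from its extracted CDS
#'
#' If the template allele aligned perfectly over its full length, the
#' template is the final call.  Otherwise every CDS record of the gene --
#' full-length and partial -- is compared against the CDS extracted from
#' the contig: full-length records by unit-cost Levenshtein edit
#' distance, partial records admitted only when they are contained in the
#' target CDS without any mismatch (in which case they score distance 0
#' over their own length).  Records are ranked by edit distance, then by
#' alignment length (aligned query-CDS bases, so a full-length record
#' outranks an equally distant partial), and all co-optimal records are
#' reported.  Novel alleles are then named by [name_novel()].
#'
#' @param template a template candidate as produced by
#'   [select_template()] (list with `allele` record, `alignment`,
#'   `priority`).
#' @param target_cds CDS extracted from the contig ([extract_cds()]).
#' @param db a `reference_db`.
#' @return object of class `allele_call`: list with `best_matches` (raw
#'   names, ties allowed), `call_string`, `novelty` (`none`, `field2`,
#'   `field3`, `field4`, `gene_only`), `edit_distance` and
#'   `incomplete_orf`.
#' @export
type_allele <- function(template, target_cds, db) {
  gene <- template$allele$name$gene
  if (identical(template$priority, "a_perfect")) {
    return(structure(list(best_matches = template$allele$name$raw,
                          call_string = template$allele$name$raw,
                          novelty = "none", edit_distance = 0L,
                          incomplete_orf = FALSE),
                     class = "allele_call"))
  }
  raws <- db$by_gene[[gene]]
  cand <- data.frame(raw = character(0), dist = integer(0), alen = integer(0))
  for (raw in raws) {
    rec <- db$alleles[[raw]]
    if (rec$completeness == "partial_cds") {
      if (!grepl(rec$cds_seq, target_cds, fixed = TRUE)) next
      cand <- rbind(cand, data.frame(raw = raw, dist = 0L,
                                     alen = nchar(rec$cds_seq)))
    } else {
      cand <- rbind(cand, data.frame(raw = raw,
                                     dist = edit_distance(rec$cds_seq, target_cds),
                                     alen = nchar(rec$cds_seq)))
    }
  }
  if (nrow(cand) == 0L) {
    return(structure(list(best_matches = character(0),
                          call_string = paste0(gene, "*new"),
                          novelty = "gene_only", edit_distance = NA_integer_,
                          incomplete_orf = FALSE),
                     class = "allele_call"))
  }
  cand <- cand[cand$dist == min(cand$dist), , drop = FALSE]
  cand <- cand[cand$alen == max(cand$alen), , drop = FALSE]
  best <- sort(cand$raw)
  nv <- name_novel(best, target_cds, target_full_match = FALSE, db = db)
  structure(list(best_matches = best, call_string = nv$call_string,
                 novelty = nv$novelty, edit_distance = cand$dist[1L],
                 incomplete_orf = nv$incomplete_orf),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("<allele_call> %s (novelty=%s, edit=%s)\n", x$call_string,
              x$novelty, x$edit_distance))
  invisible(x)
}

#' Name a novel allele from its best database matches
#'
#' When an annotated gene does not perfectly match any reference allele,
#' it receives a consensus name with `new` in the naming field of the
#' affected layer.  If the best matches come from multiple allele groups
#' (different first fields) the call is `<gene>*new`.  Otherwise the
#' field-wise longest common prefix of the best-match names is kept and
#' `new` replaces the field of the deepest affected layer: field 2 when
#' the protein differs, field 3 when only the CDS differs and field 4
#' when the CDS is identical but the full-length gene is not.  When the
#' common prefix is shorter than the affected field, `new` goes to the
#' field after the deepest shared field (capped at field 4).  Pseudogenes
#' have no protein layer, so their deepest distinction is field 3 versus
#' field 4.
#'
#' @param best_matches raw names of the best-matching alleles (non-empty,
#'   all from one gene).
#' @param target_cds extracted CDS of the annotated gene.
#' @param target_full_match logical; `TRUE` when the full-length gene
#'   matched a reference allele perfectly (no novelty).
#' @param db a `reference_db`.
#' @return list with `call_string`, `novelty` and `incomplete_orf`.
#' @export
name_novel <- function(best_matches, target_cds, target_full_match, db) {
  stopifnot(length(best_matches) >= 1L)
  if (isTRUE(target_full_match))
    return(list(call_string = paste(best_matches, collapse = "/"),
                novelty = "none", incomplete_orf = FALSE))
  recs <- db$alleles[best_matches]
  names_parsed <- lapply(recs, `[[`, "name")
  gene <- names_parsed[[1L]]$gene
  firsts <- vapply(names_parsed, function(n) n$fields[1L], "")
  if (length(unique(firsts)) > 1L)
    return(list(call_string = paste0(gene, "*new"), novelty = "gene_only",
                incomplete_orf = FALSE))
  # field-wise longest common prefix
  fl <- lapply(names_parsed, `[[`, "fields")
  lcp <- fl[[1L]]
  for (f in fl[-1L]) {
    k <- 0L
    while (k < min(length(lcp), length(f)) && lcp[k + 1L] == f[k + 1L])
      k <- k + 1L
    lcp <- lcp[seq_len(k)]
  }
  full <- Filter(function(r) r$completeness != "partial_cds", recs)
  pseudo <- any(vapply(recs, `[[`, TRUE, "is_pseudogene"))
  incomplete_orf <- FALSE
  cds_identical <- any(vapply(full, function(r)
    identical(r$cds_seq, target_cds), TRUE))
  layer <- NULL
  if (!pseudo && length(full)) {
    tt <- translate_cds(target_cds)
    if (tt$orf_status %in% c("internal_stop", "not_multiple_of_3")) {
      incomplete_orf <- TRUE
      layer <- if (cds_identical) "noncoding" else "cds"
    } else {
      prot_same <- any(vapply(full, function(r) {
        bp <- if (!is.na(r$protein_seq)) r$protein_seq
              else translate_cds(r$cds_seq)$protein
        identical(bp, tt$protein)
      }, TRUE))
      layer <- if (!prot_same) "protein"
               else if (cds_identical) "noncoding" else "cds"
    }
  } else {
    layer <- if (cds_identical) "noncoding" else "cds"
  }
  field <- c(protein = 2L, cds = 3L, noncoding = 4L)[[layer]]
  k <- max(2L, min(field, length(lcp) + 1L))
  sep <- if (identical(names_parsed[[1L]]$nomenclature, "fixed_width")) ":" else ":"
  call_string <- paste0(gene, "*",
                        paste(c(lcp[seq_len(k - 1L)], "new"), collapse = sep))
  list(call_string = call_string, novelty = paste0("field", field),
       incomplete_orf = incomplete_orf)
}
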