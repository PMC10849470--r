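#' Run configuration
#'
#' Bundles the pipeline thresholds and engine choice into a validated,
#' serializable object.  `as_manifest()` turns it into a JSON run
#' manifest for reproducibility.
#'
#' @param min_query_cov minimum mapped fraction of a gene sequence
#'   (default 0.90).
#' @param min_gci minimum gap-compressed identity (default 0.97).
#' @param c4_long_threshold intron-9 length threshold for the C4 long
#'   form, bases (default 5000).
#' @param engine alignment engine (`"internal"` or `"minimap2"`).
#' @param nomenclature allele-name dialect per gene family.
#' @param seed integer seed recorded in the manifest.
#' @param threads reserved for engines that parallelize.
#' @return object of class `run_config`.
#' @export
run_config <- function(min_query_cov = 0.90, min_gci = 0.97,
                       c4_long_threshold = 5000L,
                       engine = c("internal", "minimap2"),
                       nomenclature = "colon_delimited",
                       seed = 1L, threads = 1L) {
  engine <- match.arg(engine)
  stopifnot(min_query_cov > 0, min_query_cov <= 1,
            min_gci > 0, min_gci <= 1,
            c4_long_threshold > 0, threads >= 1L)
  structure(list(min_query_cov = min_query_cov, min_gci = min_gci,
                 c4_long_threshold = c4_long_threshold, engine = engine,
                 nomenclature = nomenclature, seed = as.integer(seed),
                 threads = as.integer(threads)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
as_manifest <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, pretty = TRUE)
}

#' Annotate and type immune genes on contigs
#'
#' The full pipeline: align all full-length reference alleles to the
#' contigs, rank alignments by gap-compressed identity, cluster them
#' greedily into candidate loci, and for each locus select a template
#' allele (four-tier priority), lift its exon/CDS structure onto the
#' contig, extract the CDS and call the allele, naming novel alleles
#' with the hierarchical `new` convention.  Loci whose candidates all
#' fail the coverage/identity filters are reported as detected but
#' untypable; annotations flagged `partial` (e.g. genes cut by contig
#' ends) are reported but not typed.
#'
#' @param contigs named character vector or `DNAStringSet`.
#' @param db a `reference_db`.
#' @param config a [run_config()].
#' @return list of class `annotation_result`: `annotations` (list of
#'   `gene_annotation`s with `call` filled), `untypable` (list of loci),
#'   `summary` (one data.frame row per locus).
#' @export
annotate_contigs <- function(contigs, db, config = run_config()) {
  if (is.character(contigs))
    contigs <- Biostrings::DNAStringSet(contigs)
  alns <- align_alleles(db, contigs, engine = config$engine)
  ranked <- rank_alignments(alns)
  cl <- cluster_alignments(ranked)
  annotations <- list()
  untypable <- list()
  rows <- list()
  for (cluster in cl$clusters) {
    cands <- filter_candidates(cluster, db,
                               min_query_cov = config$min_query_cov,
                               min_gci = config$min_gci)
    if (!length(cands)) {
      untypable <- c(untypable, list(list(contig = cluster$target_contig,
                                          span = cluster$span)))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cluster$target_contig, start = cluster$span[1L],
        end = cluster$span[2L], strand = NA_character_, gene = NA_character_,
        template = NA_character_, allele = NA_character_,
        novelty = NA_character_, edit_distance = NA_integer_,
        flags = "untypable")
      next
    }
    cands <- lapply(cands, classify_priority)
    template <- select_template(cands)
    ann <- lift_structure(template)
    if (!("partial" %in% ann$flags)) {
      cds <- extract_cds(ann, contigs[[ann$contig]])
      ann$call <- type_allele(template, cds, db)
    }
    annotations <- c(annotations, list(ann))
    rng <- range(ann$exons, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = ann$contig, start = rng[1L], end = rng[2L],
      strand = ann$strand, gene = ann$gene, template = ann$template,
      allele = if (is.null(ann$call)) NA_character_ else ann$call$call_string,
      novelty = if (is.null(ann$call)) NA_character_ else ann$call$novelty,
      edit_distance = if (is.null(ann$call)) NA_integer_
                      else ann$call$edit_distance,
      flags = if (length(ann$flags)) paste(ann$flags, collapse = ",") else "")
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), gene = character(0),
               template = character(0), allele = character(0),
               novelty = character(0), edit_distance = integer(0),
               flags = character(0))
  structure(list(annotations = annotations, untypable = untypable,
                 summary = summary),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result>", length(x$annotations), "annotated loci,",
      length(x$untypable), "untypable\n")
  invisible(x)
}

gtf_attr <- function(...) {
  kv <- c(...)
  paste(vapply(names(kv), function(k)
    sprintf('%s "%s";', k, kv[[k]]), ""), collapse = " ")
}

#' Write annotations as GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` features with 1-based
#' inclusive coordinates (the only place the package leaves its 0-based
#' half-open convention).  Attribute order is fixed: `gene_id`,
#' `transcript_id`, `gene_name`, then `template_allele`, `allele`,
#' `novelty`, `flags` (and `form` for C4 calls).  CDS frame is derived
#' from the running CDS length in transcription order.
#'
#' @param result an `annotation_result`, or a bare list of
#'   `gene_annotation`s.
#' @param file output path.
#' @param c4_calls optional list of `c4_call`s (with a `contig` element)
#'   to append to the same stream.
#' @param source GTF source column.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(result, file, c4_calls = NULL, source = "hlakir") {
  anns <- if (inherits(result, "annotation_result")) result$annotations
          else result
  lines <- c("##format: gtf", paste0("##source: ", source))
  gid <- 0L
  for (ann in anns) {
    gid <- gid + 1L
    gene_id <- sprintf("%s_g%04d", ann$gene, gid)
    tx_id <- paste0(gene_id, ".1")
    keep <- !is.na(ann$exons[, 1L])
    if (!any(keep)) next
    rng <- range(ann$exons[keep, , drop = FALSE])
    call <- ann$call
    base_attr <- c(gene_id = gene_id, transcript_id = tx_id,
                   gene_name = ann$gene,
                   template_allele = ann$template,
                   allele = if (is.null(call)) "NA" else call$call_string,
                   novelty = if (is.null(call)) "NA" else call$novelty,
                   flags = if (length(ann$flags))
                     paste(ann$flags, collapse = ",") else ".")
    feat <- function(type, start0, end0, frame = ".", extra = character(0)) {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              ann$contig, source, type, start0 + 1L, end0, ann$strand,
              frame, gtf_attr(c(base_attr, extra)))
    }
    lines <- c(lines, feat("gene", rng[1L], rng[2L]),
               feat("transcript", rng[1L], rng[2L]))
    cum <- 0L
    for (i in which(keep)) {
      iv <- ann$exons[i, ]
      frame <- as.character((3L - cum %% 3L) %% 3L)
      lines <- c(lines,
                 feat("exon", iv[1L], iv[2L],
                      extra = c(exon_number = as.character(i))),
                 feat("CDS", iv[1L], iv[2L], frame = frame,
                      extra = c(exon_number = as.character(i))))
      cum <- cum + (iv[2L] - iv[1L])
    }
  }
  for (cc in c4_calls %||% list()) {
    gid <- gid + 1L
    gname <- if (is.na(cc$ab_type)) "C4" else cc$ab_type
    gene_id <- sprintf("%s_g%04d", gname, gid)
    attrs <- c(gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
               gene_name = gname,
               form = cc$form %||% "NA",
               flags = if (length(cc$flags))
                 paste(cc$flags, collapse = ",") else ".")
    attrs[is.na(attrs)] <- "NA"
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              cc$contig %||% "contig", source,
                              cc$locus[1L] + 1L, cc$locus[2L], cc$strand,
                              gtf_attr(attrs)))
    for (j in seq_len(nrow(cc$exon_placements))) {
      ep <- cc$exon_placements[j, ]
      lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                                cc$contig %||% "contig", source,
                                ep$start + 1L, ep$end, cc$strand,
                                gtf_attr(c(attrs,
                                           exon_number = as.character(ep$exon)))))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Percentage of novel calls
#'
#' @param n_novel novel count(s).
#' @param n_total total count(s).
#' @return percentage rounded to one decimal (the convention used for
#'   reported fractions), e.g. `novel_fraction(4068, 9931)` is `41.0`.
#' @export
novel_fraction <- function(n_novel, n_total) {
  if (any(n_total == 0)) stop("empty category: total count is zero")
  round(100 * n_novel / n_total, 1)
}

#' Summarize novel-allele fractions
#'
#' Two input forms are supported.  A count table with columns
#' `category`, `n_novel`, `n_total` gains a `pct_novel` column.  A
#' pipeline summary (from [annotate_contigs()]) is aggregated per gene
#' into gene-level counts (annotated loci), unique-allele-level counts
#' (distinct call strings) and the fraction novel at each level; a locus
#' is novel when its `novelty` is not `none`.
#'
#' @param x count table or `annotation_result` summary data.frame.
#' @return data.frame of per-category fractions.  Empty input gives an
#'   empty data.frame (no division by zero).
#' @export
summarize_novelty <- function(x) {
  if (inherits(x, "annotation_result")) x <- x$summary
  if (all(c("n_novel", "n_total") %in% names(x))) {
    x$pct_novel <- novel_fraction(x$n_novel, x$n_total)
    return(x)
  }
  x <- x[!is.na(x$gene) & !is.na(x$novelty), , drop = FALSE]
  if (!nrow(x))
    return(data.frame(category = character(0), n_total = integer(0),
                      n_novel = integer(0), pct_novel = numeric(0),
                      n_unique_alleles = integer(0),
                      n_novel_unique = integer(0)))
  out <- do.call(rbind, lapply(split(x, x$gene), function(d) {
    novel <- d$novelty != "none"
    data.frame(category = d$gene[1L], n_total = nrow(d),
               n_novel = sum(novel),
               pct_novel = novel_fraction(sum(novel), nrow(d)),
               n_unique_alleles = length(unique(d$allele)),
               n_novel_unique = length(unique(d$allele[novel])))
  }))
  rownames(out) <- NULL
  out
}

#' Run annotation from files
#'
#' Thin file-level wrapper: reads contigs (FASTA) and a reference
#' database directory, runs [annotate_contigs()], writes the GTF, a
#' summary TSV and a JSON run manifest.  An input without any detected
#' locus yields a header-only GTF.
#'
#' @param config a [run_config()].
#' @param contigs_fasta path to the contig FASTA.
#' @param db_path reference database directory ([load_reference()]).
#' @param out_gtf,out_summary,out_manifest output paths (`NULL` to skip).
#' @return the `annotation_result`, invisibly.
#' @export
run_annotate <- function(config, contigs_fasta, db_path, out_gtf,
                         out_summary = NULL, out_manifest = NULL) {
  contigs <- Biostrings::readDNAStringSet(contigs_fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  db <- load_reference(db_path, nomenclature = config$nomenclature)
  res <- annotate_contigs(contigs, db, config)
  write_gtf(res, out_gtf)
  if (!is.null(out_summary))
    write.table(res$summary, out_summary, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(out_manifest))
    writeLines(as_manifest(config), out_manifest)
  invisible(res)
}
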