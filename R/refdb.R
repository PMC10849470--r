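#' Construct a reference allele record
#'
#' One entry of the reference allele database.  A `full_gene` record
#' carries the genomic allele sequence plus its exon map; records known
#' only at the coding level carry a full (`full_cds_only`) or partial
#' (`partial_cds`) CDS.  In the on-disk dialect exons are the coding
#' exons, so the concatenation of the exon subsequences of `gene_seq`
#' equals `cds_seq`; untranslated flanks are not modelled.
#'
#' @param name an `allele_name` (see [parse_allele_name()]).
#' @param gene_seq full genomic allele sequence, or `NA`.
#' @param exons integer matrix with columns `start`, `end`: 0-based
#'   half-open intervals on `gene_seq`, sorted, non-overlapping.  `NULL`
#'   for CDS-only records.
#' @param cds_seq coding sequence (possibly partial).
#' @param completeness one of `"full_gene"`, `"full_cds_only"`,
#'   `"partial_cds"`.
#' @param is_pseudogene logical; pseudogenes carry CDS annotations but no
#'   protein layer.
#' @return an object of class `allele_record`.
#' @export
allele_record <- function(name, gene_seq = NA_character_, exons = NULL,
                          cds_seq, completeness, is_pseudogene = FALSE) {
  rec <- structure(
    list(name = name, gene_seq = gene_seq, exons = exons, cds_seq = cds_seq,
         completeness = completeness, is_pseudogene = is_pseudogene,
         protein_seq = NA_character_),
    class = "allele_record")
  if (completeness == "full_gene" || completeness == "full_cds_only") {
    if (!is_pseudogene) {
      tr <- translate_cds(cds_seq)
      if (tr$orf_status == "complete") rec$protein_seq <- tr$protein
    }
  }
  rec
}

#' Validate an allele record
#'
#' @param rec an `allele_record`.
#' @return character vector of problems (empty when valid).
#' @export
validate_allele_record <- function(rec) {
  problems <- character(0)
  if (length(rec$name$fields) < 1L)
    problems <- c(problems, "allele name has no fields")
  if (rec$completeness == "full_gene") {
    if (is.na(rec$gene_seq))
      problems <- c(problems, "full_gene record lacks gene_seq")
    else {
      ex <- rec$exons
      if (is.null(ex) || nrow(ex) < 1L)
        problems <- c(problems, "full_gene record lacks exons")
      else {
        if (any(ex[, 1L] < 0L) || any(ex[, 2L] > nchar(rec$gene_seq)))
          problems <- c(problems, "exon outside gene sequence")
        if (any(ex[, 2L] <= ex[, 1L]))
          problems <- c(problems, "empty or inverted exon")
        if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
          problems <- c(problems, "exons unsorted or overlapping")
        if (length(problems) == 0L) {
          got <- paste(vapply(seq_len(nrow(ex)), function(i)
            substr0(rec$gene_seq, ex[i, 1L], ex[i, 2L]), ""), collapse = "")
          if (!identical(got, rec$cds_seq))
            problems <- c(problems, "exon concatenation does not equal cds_seq")
        }
      }
    }
  }
  if (!nzchar(rec$cds_seq %||% "") || is.na(rec$cds_seq))
    problems <- c(problems, "missing cds_seq")
  problems
}

#' Assemble a reference database from allele records
#'
#' @param records list of `allele_record`s.
#' @param version free-form version string.
#' @return object of class `reference_db` with elements `alleles` (named
#'   by raw allele name), `by_gene` (gene -> raw names) and `version`.
#' @export
reference_db <- function(records, version = "0") {
  raws <- vapply(records, function(r) r$name$raw, "")
  if (anyDuplicated(raws))
    stop("duplicate allele names: ",
         paste(unique(raws[duplicated(raws)]), collapse = ", "))
  names(records) <- raws
  genes <- vapply(records, function(r) r$name$gene, "")
  structure(list(alleles = records,
                 by_gene = split(raws, genes),
                 version = version),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> version", x$version, "-", length(x$alleles),
      "alleles across", length(x$by_gene), "genes\n")
  invisible(x)
}

db_genes <- function(db) names(db$by_gene)

#' Load a reference allele database from disk
#'
#' Reads the package's FASTA + TSV dialect: `gene.fasta` (full-length
#' allele sequences), `cds.fasta` (full and partial coding sequences) and
#' `structure.tsv` with columns `allele_name`, `gene`, `exon_starts`,
#' `exon_ends`, `cds_phase`, `completeness`, `pseudogene`.  Exon
#' coordinates are 0-based half-open, comma-separated.  Records that fail
#' validation (e.g. an exon running past the gene end) are skipped with a
#' warning; missing files are fatal.
#'
#' @param db_path directory containing the three files.
#' @param nomenclature passed to [parse_allele_name()].
#' @return a validated `reference_db`.  The number of skipped records is
#'   available as `attr(db, "n_skipped")`.
#' @export
load_reference <- function(db_path, nomenclature = "colon_delimited") {
  files <- file.path(db_path, c("gene.fasta", "cds.fasta", "structure.tsv"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("reference database incomplete, missing: ",
         paste(basename(missing), collapse = ", "))
  gene_fa <- Biostrings::readDNAStringSet(files[1L])
  cds_fa <- Biostrings::readDNAStringSet(files[2L])
  first <- readLines(files[3L], n = 1L)
  version <- if (startsWith(first, "#version=")) sub("^#version=", "", first) else "0"
  tab <- read.delim(files[3L], colClasses = "character", comment.char = "#")
  need <- c("allele_name", "gene", "exon_starts", "exon_ends", "cds_phase",
            "completeness", "pseudogene")
  if (!all(need %in% names(tab)))
    stop("structure.tsv lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))

  records <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    rec <- tryCatch({
      nm <- parse_allele_name(row$allele_name, nomenclature)
      if (!identical(nm$gene, row$gene))
        stop("gene column disagrees with allele name")
      has_gene <- row$allele_name %in% names(gene_fa)
      if (!row$allele_name %in% names(cds_fa))
        stop("no CDS sequence for allele")
      completeness <- row$completeness
      if (completeness == "full_gene" && !has_gene)
        completeness <- "full_cds_only"
      exons <- NULL
      gseq <- NA_character_
      if (completeness == "full_gene") {
        gseq <- as.character(gene_fa[[row$allele_name]])
        starts <- as.integer(strsplit(row$exon_starts, ",")[[1L]])
        ends <- as.integer(strsplit(row$exon_ends, ",")[[1L]])
        if (length(starts) != length(ends) || anyNA(starts) || anyNA(ends))
          stop("malformed exon coordinate lists")
        exons <- cbind(start = starts, end = ends)
      }
      rec <- allele_record(nm, gene_seq = gseq, exons = exons,
                           cds_seq = as.character(cds_fa[[row$allele_name]]),
                           completeness = completeness,
                           is_pseudogene = identical(row$pseudogene, "1") ||
                             identical(tolower(row$pseudogene), "true"))
      problems <- validate_allele_record(rec)
      if (length(problems))
        stop(paste(problems, collapse = "; "))
      rec
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      skipped <- c(skipped, paste0(row$allele_name, ": ", conditionMessage(rec)))
    } else records[[length(records) + 1L]] <- rec
  }
  if (length(skipped))
    warning(length(skipped), " structure record(s) skipped:\n  ",
            paste(skipped, collapse = "\n  "))
  db <- reference_db(records, version = version)
  attr(db, "n_skipped") <- length(skipped)
  db
}

#' Write a reference database in the on-disk dialect
#'
#' Inverse of [load_reference()]; `load_reference(write_reference(db, p))`
#' reproduces `db`.
#'
#' @param db a `reference_db`.
#' @param db_path output directory (created if needed).
#' @return `db_path`, invisibly.
#' @export
write_reference <- function(db, db_path) {
  dir.create(db_path, recursive = TRUE, showWarnings = FALSE)
  full <- Filter(function(r) r$completeness == "full_gene", db$alleles)
  gene_fa <- Biostrings::DNAStringSet(vapply(full, function(r) r$gene_seq, ""))
  cds_fa <- Biostrings::DNAStringSet(vapply(db$alleles, function(r) r$cds_seq, ""))
  Biostrings::writeXStringSet(gene_fa, file.path(db_path, "gene.fasta"))
  Biostrings::writeXStringSet(cds_fa, file.path(db_path, "cds.fasta"))
  tab <- do.call(rbind, lapply(db$alleles, function(r) {
    data.frame(allele_name = r$name$raw, gene = r$name$gene,
               exon_starts = if (is.null(r$exons)) "" else
                 paste(r$exons[, 1L], collapse = ","),
               exon_ends = if (is.null(r$exons)) "" else
                 paste(r$exons[, 2L], collapse = ","),
               cds_phase = "0",
               completeness = r$completeness,
               pseudogene = as.integer(r$is_pseudogene))
  }))
  con <- file.path(db_path, "structure.tsv")
  writeLines(paste0("#version=", db$version), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(db_path)
}
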