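#' Parse a hierarchical allele name
#'
#' Immune-gene nomenclature names an allele as `<gene>*<fields>`, where the
#' fields form a hierarchy: field 1 distinguishes allele groups, field 2
#' protein sequences, field 3 synonymous coding changes and field 4
#' non-coding changes.  HLA-style names separate fields with colons
#' (`A*03:01:01:02`); KIR-style names concatenate digits with fixed widths
#' 3, 2, 2 after the gene symbol (`2DL4*00501`).
#'
#' @param raw allele name string, e.g. `"A*03:01:01:02"` or `"2DL4*005"`.
#' @param nomenclature `"colon_delimited"` (default) or `"fixed_width"`.
#'   Fixed-width splits the post-`*` digit string into widths 3, 2, 2.
#' @return an object of class `allele_name`: a list with elements `gene`,
#'   `fields` (character vector, 1--4 elements), `raw` and `nomenclature`.
#' @examples
#' parse_allele_name("DRB1*03:01:01:02")
#' parse_allele_name("2DL4*00501", nomenclature = "fixed_width")
#' @export
parse_allele_name <- function(raw,
                              nomenclature = c("colon_delimited", "fixed_width")) {
  nomenclature <- match.arg(nomenclature)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("allele name must be a non-empty string")
  star <- regexpr("*", raw, fixed = TRUE)
  if (star < 2L || star == nchar(raw))
    stop("cannot split allele name ", sQuote(raw), ": expected '<gene>*<fields>'")
  gene <- substr(raw, 1L, star - 1L)
  rest <- substr(raw, star + 1L, nchar(raw))
  if (nomenclature == "colon_delimited") {
    fields <- strsplit(rest, ":", fixed = TRUE)[[1L]]
    if (length(fields) < 1L || any(!nzchar(fields)))
      stop("cannot split allele name ", sQuote(raw), ": empty field")
  } else {
    if (!grepl("^[0-9]+$", rest))
      stop("cannot split allele name ", sQuote(raw),
           ": fixed-width fields must be digits")
    widths <- c(3L, 2L, 2L)
    fields <- character(0)
    pos <- 1L
    for (w in widths) {
      if (pos > nchar(rest)) break
      fields <- c(fields, substr(rest, pos, min(nchar(rest), pos + w - 1L)))
      pos <- pos + w
    }
    if (pos <= nchar(rest))
      stop("cannot split allele name ", sQuote(raw), ": too many digits")
  }
  if (length(fields) > 4L)
    stop("cannot split allele name ", sQuote(raw), ": more than four fields")
  structure(list(gene = gene, fields = fields, raw = raw,
                 nomenclature = nomenclature),
            class = "allele_name")
}

#' Format an allele name back to its string form
#'
#' Inverse of [parse_allele_name()]: `format_allele_name(parse_allele_name(x))`
#' reproduces `x`.
#'
#' @param name an `allele_name`, or a list with `gene`, `fields` and
#'   optionally `nomenclature`.
#' @return character scalar.
#' @export
format_allele_name <- function(name) {
  sep <- if (identical(name$nomenclature, "fixed_width")) "" else ":"
  paste0(name$gene, "*", paste(name$fields, collapse = sep))
}

#' @export
print.allele_name <- function(x, ...) {
  cat("<allele_name> ", x$raw, "  gene=", x$gene,
      "  fields=[", paste(x$fields, collapse = ","), "]\n", sep = "")
  invisible(x)
}

# gene symbol of a raw allele name (text before '*')
allele_gene <- function(raw) sub("\\*.*$", "", raw)
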