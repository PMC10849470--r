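# Synthetic fixtures with known ground truth.  The generator's defaults
# define the study conditions used throughout the test suite: 5 genes x 4
# alleles, gene lengths 3-15 kb with multi-exon structure and CDS lengths
# inside the range seen for real immune genes (a one-exon 161-bp CDS at
# the short end, a 5.4-kb transcript at the long end).  Background
# sequence is i.i.d. nucleotides at a configurable GC content; repeats
# and recombination are deliberately not simulated.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  sample(codons, n, replace = TRUE)
}

# random CDS: ATG + non-stop codons + stop (coding) or with one internal
# stop (pseudogene)
random_cds <- function(n_codons, pseudogene = FALSE) {
  body <- random_codons(n_codons - 2L)
  if (pseudogene)
    body[sample(seq_along(body), 1L)] <- sample(STOP_CODONS, 1L)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# split total into n parts, each >= minimum
random_composition <- function(total, n, minimum) {
  stopifnot(total >= n * minimum)
  extra <- total - n * minimum
  if (n == 1L) return(total)
  cuts <- sort(sample.int(extra + 1L, n - 1L, replace = TRUE) - 1L)
  minimum + diff(c(0L, cuts, extra))
}

# substitute one base at 0-based position
substitute_base <- function(seq, pos0, base) {
  paste0(substr(seq, 1L, pos0), base, substr(seq, pos0 + 2L, nchar(seq)))
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

# find codon indices (1-based, excluding start and stop codon) where a
# substitution of the requested effect exists; returns list(codon, pos0
# within cds, alt base)
find_codon_site <- function(cds, effect = c("synonymous", "nonsynonymous"),
                            exclude_codons = integer(0)) {
  effect <- match.arg(effect)
  n_codon <- nchar(cds) %/% 3L
  for (ci in sample(2:(n_codon - 1L))) {
    if (ci %in% exclude_codons) next
    codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    aa <- Biostrings::GENETIC_CODE[[codon]]
    offsets <- if (effect == "synonymous") 3L else c(1L, 2L)
    for (off in sample(offsets)) {
      for (alt in sample(other_bases(substr(codon, off, off)))) {
        mut <- codon
        substr(mut, off, off) <- alt
        maa <- Biostrings::GENETIC_CODE[[mut]]
        ok <- if (effect == "synonymous") identical(maa, aa)
              else !identical(maa, aa) && maa != "*"
        if (ok)
          return(list(codon = ci, pos0 = (ci - 1L) * 3L + off - 1L, alt = alt))
      }
    }
  }
  stop("no ", effect, " site found")
}

# build gene sequence from CDS split into exons with given intron lengths
assemble_gene <- function(cds, exon_lens, intron_lens) {
  stopifnot(sum(exon_lens) == nchar(cds),
            length(intron_lens) == length(exon_lens) - 1L)
  pieces <- character(0)
  exons <- matrix(0L, nrow = length(exon_lens), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cpos <- 0L; gpos <- 0L
  for (i in seq_along(exon_lens)) {
    ex <- substr0(cds, cpos, cpos + exon_lens[i])
    pieces <- c(pieces, ex)
    exons[i, ] <- c(gpos, gpos + exon_lens[i])
    cpos <- cpos + exon_lens[i]; gpos <- gpos + exon_lens[i]
    if (i < length(exon_lens)) {
      pieces <- c(pieces, random_dna(intron_lens[i]))
      gpos <- gpos + intron_lens[i]
    }
  }
  list(gene_seq = paste(pieces, collapse = ""), exons = exons)
}

# map CDS position (0-based) to gene position through the exon map
cds_to_gene_pos <- function(exons, cds_pos0) {
  cum <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons[i, 2L] - exons[i, 1L]
    if (cds_pos0 < cum + w) return(exons[i, 1L] + (cds_pos0 - cum))
    cum <- cum + w
  }
  stop("CDS position outside exon map")
}

#' Generate a synthetic reference allele database with ground truth
#'
#' Each gene gets four alleles spanning the nomenclature hierarchy:
#' `*01:01:01:01` (base), `*01:01:01:02` (one intronic SNP, identical
#' CDS), `*01:01:02` (one synonymous exonic SNP) and `*02:01` (a second
#' allele group, two nonsynonymous SNPs).  The truth object records the
#' allele-defining sites plus pools of fresh mutable sites (intronic,
#' synonymous, nonsynonymous and the group-diagnostic sites) that
#' [plant()] draws from, so expected calls are derived from the naming
#' rules rather than hand-typed.  Regeneration with the same seed is
#' byte-identical.
#'
#' @param n_genes number of genes (default 5).
#' @param alleles_per_gene 2--4 alleles, taken in the ladder order above.
#' @param gene_len_range genomic allele length range in bases.
#' @param cds_len_range CDS length range in bases (rounded to codons).
#' @param n_exons_range exon count range.
#' @param pseudogene_genes indices of genes to make pseudogenes (internal
#'   stop in the CDS, no protein layer).
#' @param seed integer seed.
#' @return list with `db` (a `reference_db`) and `truth` (per-gene site
#'   bookkeeping plus the seed).
#' @export
make_db <- function(n_genes = 5L, alleles_per_gene = 4L,
                    gene_len_range = c(3000L, 15000L),
                    cds_len_range = c(300L, 1500L),
                    n_exons_range = c(3L, 8L),
                    pseudogene_genes = integer(0),
                    seed = 1L) {
  stopifnot(alleles_per_gene >= 2L, alleles_per_gene <= 4L)
  set.seed(seed)
  records <- list()
  truth_genes <- list()
  for (g in seq_len(n_genes)) {
    gene <- sprintf("HLX%d", g)
    pseudo <- g %in% pseudogene_genes
    n_codons <- sample(seq(cds_len_range[1L] %/% 3L,
                           cds_len_range[2L] %/% 3L), 1L)
    cds <- random_cds(n_codons, pseudogene = pseudo)
    cds_len <- nchar(cds)
    n_exons <- sample(seq(n_exons_range[1L], n_exons_range[2L]), 1L)
    exon_lens <- random_composition(cds_len, n_exons, 30L)
    glen <- sample(seq(max(gene_len_range[1L], cds_len + 250L * (n_exons - 1L)),
                       gene_len_range[2L]), 1L)
    intron_total <- glen - cds_len
    intron_lens <- if (n_exons > 1L)
      random_composition(intron_total, n_exons - 1L, 250L) else integer(0)
    base <- assemble_gene(cds, exon_lens, intron_lens)

    # allele-defining sites
    intron_pool0 <- setdiff(seq_len(nchar(base$gene_seq)) - 1L,
                            unlist(lapply(seq_len(n_exons), function(i)
                              seq.int(base$exons[i, 1L] - 3L,
                                      base$exons[i, 2L] + 2L))))
    intron_pool0 <- intron_pool0[intron_pool0 > 5L &
                                   intron_pool0 < nchar(base$gene_seq) - 5L]
    used_codons <- integer(0)
    site_intron_def <- sample(intron_pool0, 1L)
    syn_def <- find_codon_site(cds, "synonymous")
    used_codons <- c(used_codons, syn_def$codon)
    grp1 <- find_codon_site(cds, "nonsynonymous", used_codons)
    used_codons <- c(used_codons, grp1$codon)
    grp2 <- find_codon_site(cds, "nonsynonymous", used_codons)
    used_codons <- c(used_codons, grp2$codon)

    # fresh pools for planting
    fresh_introns <- sample(setdiff(intron_pool0, site_intron_def),
                            min(12L, length(intron_pool0) - 1L))
    fresh_syn <- list(); fresh_nonsyn <- list()
    for (k in 1:8) {
      s <- try(find_codon_site(cds, "synonymous", used_codons), silent = TRUE)
      if (!inherits(s, "try-error")) {
        fresh_syn[[length(fresh_syn) + 1L]] <- s
        used_codons <- c(used_codons, s$codon)
      }
      s <- try(find_codon_site(cds, "nonsynonymous", used_codons), silent = TRUE)
      if (!inherits(s, "try-error")) {
        fresh_nonsyn[[length(fresh_nonsyn) + 1L]] <- s
        used_codons <- c(used_codons, s$codon)
      }
    }

    mk_name <- function(fields) {
      raw <- paste0(gene, "*", paste(fields, collapse = ":"))
      parse_allele_name(raw)
    }
    alleles <- list()
    # base allele
    alleles[["base"]] <- allele_record(
      mk_name(c("01", "01", "01", "01")), gene_seq = base$gene_seq,
      exons = base$exons, cds_seq = cds, completeness = "full_gene",
      is_pseudogene = pseudo)
    # intronic sibling: identical CDS
    g2 <- substitute_base(base$gene_seq, site_intron_def,
                          sample(other_bases(substr0(
                            base$gene_seq, site_intron_def,
                            site_intron_def + 1L)), 1L))
    alleles[["intronic"]] <- allele_record(
      mk_name(c("01", "01", "01", "02")), gene_seq = g2, exons = base$exons,
      cds_seq = cds, completeness = "full_gene", is_pseudogene = pseudo)
    # synonymous sibling
    if (alleles_per_gene >= 3L) {
      cds_syn <- substitute_base(cds, syn_def$pos0, syn_def$alt)
      gsyn <- assemble_gene_with_cds(base, cds_syn)
      alleles[["synonymous"]] <- allele_record(
        mk_name(c("01", "01", "02")), gene_seq = gsyn, exons = base$exons,
        cds_seq = cds_syn, completeness = "full_gene", is_pseudogene = pseudo)
    }
    # second allele group: two nonsynonymous changes
    if (alleles_per_gene >= 4L) {
      cds_grp <- substitute_base(substitute_base(cds, grp1$pos0, grp1$alt),
                                 grp2$pos0, grp2$alt)
      ggrp <- assemble_gene_with_cds(base, cds_grp)
      alleles[["group2"]] <- allele_record(
        mk_name(c("02", "01")), gene_seq = ggrp, exons = base$exons,
        cds_seq = cds_grp, completeness = "full_gene", is_pseudogene = pseudo)
    }
    records <- c(records, unname(alleles))
    truth_genes[[gene]] <- list(
      gene = gene, pseudogene = pseudo, exons = base$exons,
      cds_len = cds_len, gene_len = nchar(base$gene_seq),
      alleles = vapply(alleles, function(r) r$name$raw, ""),
      group_sites = list(grp1, grp2),
      fresh_introns = fresh_introns,
      fresh_syn = fresh_syn, fresh_nonsyn = fresh_nonsyn)
  }
  db <- reference_db(records, version = sprintf("synthetic-%d", seed))
  list(db = db, truth = list(genes = truth_genes, seed = seed))
}

# rebuild a gene sequence around a modified CDS, keeping introns
assemble_gene_with_cds <- function(base, new_cds) {
  g <- base$gene_seq
  cum <- 0L
  for (i in seq_len(nrow(base$exons))) {
    w <- base$exons[i, 2L] - base$exons[i, 1L]
    substr(g, base$exons[i, 1L] + 1L, base$exons[i, 2L]) <-
      substr0(new_cds, cum, cum + w)
    cum <- cum + w
  }
  g
}

# ladder mutation types understood by plant()
MUTATION_TYPES <- c("none", "intronic", "synonymous", "nonsynonymous",
                    "group_ambiguous")

# expected call for planting the base allele with one ladder mutation
expected_ladder_call <- function(gene_truth, allele_raw, mutation) {
  gene <- gene_truth$gene
  base_fields <- c("01", "01", "01", "01")
  if (mutation == "none")
    return(list(call = allele_raw, novelty = "none"))
  pseudo <- gene_truth$pseudogene
  switch(mutation,
    intronic = list(call = paste0(gene, "*01:01:01:new"), novelty = "field4"),
    synonymous = list(call = paste0(gene, "*01:01:new"), novelty = "field3"),
    nonsynonymous = if (pseudo)
      list(call = paste0(gene, "*01:01:new"), novelty = "field3")
    else list(call = paste0(gene, "*01:new"), novelty = "field2"),
    group_ambiguous = list(call = paste0(gene, "*new"), novelty = "gene_only"))
}

#' Plant alleles into a synthetic contig
#'
#' Places allele sequences (either strand, optionally mutated or
#' truncated) into random background sequence and records the expected
#' annotation and allele call for every placement.  Ladder mutations are
#' applied to the base allele at fresh sites reserved by [make_db()]:
#' `intronic` (CDS untouched, expect a field-4 `new` call), `synonymous`
#' (field-3), `nonsynonymous` (field-2; field-3 for pseudogenes) and
#' `group_ambiguous` (one of the two group-diagnostic sites, making the
#' CDS equidistant from both allele groups, expect `<gene>*new`).  A
#' `truncate_frac` placement keeps only that leading fraction of the gene
#' and is put at the very end of the contig, emulating a gene cut by a
#' contig break; below the 90% mapping rule it is expected to be
#' detected but untypable.
#'
#' @param dbt result of [make_db()] (list with `db` and `truth`).
#' @param placements data.frame with columns `gene`, `allele` (raw name),
#'   `strand`, `mutation` (one of `none`, `intronic`, `synonymous`,
#'   `nonsynonymous`, `group_ambiguous`), and optionally `truncate_frac`.
#' @param gap_range flanking/background gap length range between genes.
#' @param contig_name contig identifier.
#' @param seed integer seed.
#' @return list with `contigs` (named character vector of length 1) and
#'   `truth` (data.frame: placement coordinates, mutation, expected call
#'   and novelty; truncated placements expect `untypable`).
#' @export
plant <- function(dbt, placements, gap_range = c(1000L, 3000L),
                  contig_name = "ctg1", seed = 1L) {
  set.seed(seed)
  db <- dbt$db
  if (is.null(placements$truncate_frac))
    placements$truncate_frac <- NA_real_
  # truncated placements must sit at the contig end
  if (sum(!is.na(placements$truncate_frac)) > 1L)
    stop("at most one truncated placement per contig")
  ord <- order(!is.na(placements$truncate_frac))
  placements <- placements[ord, , drop = FALSE]
  pieces <- character(0)
  truth <- NULL
  pos <- 0L
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    gt <- dbt$truth$genes[[p$gene]]
    rec <- db$alleles[[p$allele]]
    seq <- rec$gene_seq
    mutation <- p$mutation
    if (mutation != "none" && p$allele != gt$alleles[["base"]])
      stop("ladder mutations are applied to the base allele")
    if (mutation == "intronic") {
      site <- sample(gt$fresh_introns, 1L)
      seq <- substitute_base(seq, site,
                             sample(other_bases(substr0(seq, site, site + 1L)), 1L))
    } else if (mutation %in% c("synonymous", "nonsynonymous")) {
      pool <- if (mutation == "synonymous") gt$fresh_syn else gt$fresh_nonsyn
      site <- pool[[sample(length(pool), 1L)]]
      gpos <- cds_to_gene_pos(gt$exons, site$pos0)
      seq <- substitute_base(seq, gpos, site$alt)
    } else if (mutation == "group_ambiguous") {
      site <- gt$group_sites[[sample(2L, 1L)]]
      gpos <- cds_to_gene_pos(gt$exons, site$pos0)
      seq <- substitute_base(seq, gpos, site$alt)
    }
    expected <- expected_ladder_call(gt, p$allele, mutation)
    truncated <- !is.na(p$truncate_frac)
    if (truncated) {
      seq <- substr(seq, 1L, floor(nchar(seq) * p$truncate_frac))
      expected <- list(call = NA_character_, novelty = "untypable")
    }
    if (p$strand == "-") seq <- revcomp(seq)
    gap <- sample(seq(gap_range[1L], gap_range[2L]), 1L)
    pieces <- c(pieces, random_dna(gap), seq)
    start <- pos + gap
    pos <- start + nchar(seq)
    truth <- rbind(truth, data.frame(
      contig = contig_name, start = start, end = pos, strand = p$strand,
      gene = p$gene, allele = p$allele, mutation = mutation,
      truncated = truncated, expected_call = expected$call,
      expected_novelty = expected$novelty))
  }
  last_truncated <- nrow(placements) && !is.na(
    placements$truncate_frac[nrow(placements)])
  if (!last_truncated)
    pieces <- c(pieces, random_dna(sample(seq(gap_range[1L], gap_range[2L]), 1L)))
  contig <- paste(pieces, collapse = "")
  contigs <- setNames(contig, contig_name)
  list(contigs = contigs, truth = truth)
}

#' Synthetic C4 reference and contig fixture
#'
#' Builds a 41-exon reference transcript (~5.4 kb) whose exon 26 carries
#' the diagnostic A-motif codons at the configured positions, plus a
#' contig with planted C4 gene copies.  Introns are uniform (230 bp), so
#' a short-form gene lands in the 14.6-kb class; a long-form gene gets a
#' 6.2-kb insertion in intron 9 and lands in the 20.6-kb class.
#'
#' @param copies data.frame with columns `type` (`"C4A"`/`"C4B"`) and
#'   `form` (`"L"`/`"S"`), one row per planted copy, in genomic order.
#' @param n_exons number of exons (default 41).
#' @param transcript_len approximate transcript length (default 5400;
#'   rounded to codons).
#' @param intron_len uniform intron length (default 230).
#' @param insertion_len intron-9 insertion for long forms (default 6200).
#' @param config a [c4_config()].
#' @param seed integer seed.
#' @return list with `transcript`, `exons` (0-based matrix), `contig`
#'   (character), `truth` (the `copies` table with planted coordinates
#'   and gene lengths) and `config`.
#' @export
make_c4_fixture <- function(copies = data.frame(type = c("C4A", "C4B"),
                                                form = c("L", "S")),
                            n_exons = 41L, transcript_len = 5400L,
                            intron_len = 230L, insertion_len = 6200L,
                            config = c4_config(), seed = 1L) {
  set.seed(seed)
  n_codons <- transcript_len %/% 3L
  tx <- paste(random_codons(n_codons), collapse = "")
  # every exon long enough to hold the diagnostic codons of exon 26
  min_exon <- max(95L, (max(config$diag_codons) + 2L) * 3L + 5L)
  exon_lens <- random_composition(nchar(tx), n_exons, min_exon)
  bounds <- cumsum(c(0L, exon_lens))
  exons <- cbind(start = bounds[-length(bounds)], end = bounds[-1L])
  # write the A-motif into exon 26 at the configured codon positions
  phase_skip <- (3L - exons[26L, 1L] %% 3L) %% 3L
  codon_start0 <- function(ci) exons[26L, 1L] + phase_skip + (ci - 1L) * 3L
  a_res <- strsplit(config$a_motif, "")[[1L]]
  b_res <- strsplit(config$b_motif, "")[[1L]]
  codon_for <- function(aa) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa][1L]
  }
  # B-motif codons closest to the A codons (isotype differences are SNPs)
  closest_codon <- function(aa, ref) {
    cands <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
    mm <- vapply(cands, function(cc)
      sum(charToRaw(cc) != charToRaw(ref)), 0L)
    cands[which.min(mm)]
  }
  a_codons <- vapply(a_res, codon_for, "")
  for (k in seq_along(config$diag_codons)) {
    s0 <- codon_start0(config$diag_codons[k])
    stopifnot(s0 + 3L <= exons[26L, 2L])
    substr(tx, s0 + 1L, s0 + 3L) <- a_codons[k]
  }
  b_codons <- vapply(seq_along(b_res), function(k)
    closest_codon(b_res[k], a_codons[k]), "")

  build_gene <- function(type, form) {
    t2 <- tx
    if (type == "C4B")
      for (k in seq_along(config$diag_codons)) {
        s0 <- codon_start0(config$diag_codons[k])
        substr(t2, s0 + 1L, s0 + 3L) <- b_codons[k]
      }
    pieces <- character(0)
    for (i in seq_len(n_exons)) {
      pieces <- c(pieces, substr0(t2, exons[i, 1L], exons[i, 2L]))
      if (i < n_exons) {
        il <- intron_len + if (i == 9L && form == "L") insertion_len else 0L
        pieces <- c(pieces, random_dna(il))
      }
    }
    paste(pieces, collapse = "")
  }

  pieces <- character(0)
  pos <- 0L
  truth <- NULL
  for (i in seq_len(nrow(copies))) {
    gseq <- build_gene(copies$type[i], copies$form[i])
    gap <- 2000L
    pieces <- c(pieces, random_dna(gap), gseq)
    start <- pos + gap
    pos <- start + nchar(gseq)
    truth <- rbind(truth, data.frame(type = copies$type[i],
                                     form = copies$form[i],
                                     start = start, end = pos,
                                     gene_len = nchar(gseq)))
  }
  pieces <- c(pieces, random_dna(2000L))
  list(transcript = tx, exons = exons,
       contig = paste(pieces, collapse = ""), truth = truth, config = config)
}

#' Simulate a read-depth cohort with hemizygous deletions
#'
#' Emulates the quantity the genotyper consumes: the *median* per-base
#' read depth over a region.  Per-base depths are Poisson draws around a
#' per-sample haploid depth (the per-sample depth varies across the
#' cohort, so step-1 normalization has real work to do); a fraction of
#' samples carries a hemizygous deletion of the gene (half depth), and
#' the reported depth of every region is the median over `region_len`
#' positions.
#'
#' @param n_samples cohort size (default 100).
#' @param del_frac fraction of hemizygous carriers (default 0.20).
#' @param mean_depth diploid sequencing depth (default 30).
#' @param n_controls number of diploid control regions (default 50).
#' @param region_len positions per region over which the median is taken
#'   (default 200).
#' @param seed integer seed.
#' @return list with `gene_depths` (matrix n x 1), `control_depths`
#'   (matrix), `truth` (character vector `"deleted"`/`"present"`).
#' @export
simulate_depth_cohort <- function(n_samples = 100L, del_frac = 0.20,
                                  mean_depth = 30, n_controls = 50L,
                                  region_len = 200L, seed = 1L) {
  set.seed(seed)
  sample_depth <- mean_depth * runif(n_samples, 0.6, 1.4)
  deleted <- seq_len(n_samples) %in%
    sample.int(n_samples, round(del_frac * n_samples))
  copies <- ifelse(deleted, 1L, 2L)
  region_median <- function(lambda)
    vapply(lambda, function(l) median(rpois(region_len, l)), 0)
  gene <- region_median(sample_depth / 2 * copies)
  ctrl <- vapply(seq_len(n_controls), function(j) region_median(sample_depth),
                 numeric(n_samples))
  rownames(ctrl) <- sprintf("s%03d", seq_len(n_samples))
  gene_depths <- matrix(gene, ncol = 1L,
                        dimnames = list(rownames(ctrl), "HLX1"))
  list(gene_depths = gene_depths, control_depths = ctrl,
       truth = ifelse(deleted, "deleted", "present"))
}

#' Simulate genotyper allele abundances with known copy numbers
#'
#' Transformed (square-root) abundances are drawn from
#' `Normal(c * mu, c * sigma)` per allele, with true copy numbers drawn
#' uniformly from `c_values`.
#'
#' @param n_alleles number of alleles (default 300).
#' @param mu single-copy mean on the square-root scale (default 1).
#' @param sigma_frac sigma as a fraction of `mu` (default 0.1).
#' @param c_values candidate copy numbers (default 1:3).
#' @param c_probs sampling probabilities (default uniform).
#' @param seed integer seed.
#' @return data.frame with `allele`, `gene`, `abundance`, `true_c`.
#' @export
simulate_abundance <- function(n_alleles = 300L, mu = 1, sigma_frac = 0.1,
                               c_values = 1:3,
                               c_probs = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(c_probs)) c_probs <- rep(1 / length(c_values), length(c_values))
  true_c <- sample(c_values, n_alleles, replace = TRUE, prob = c_probs)
  x <- rnorm(n_alleles, mean = true_c * mu, sd = true_c * sigma_frac * mu)
  x <- pmax(x, 1e-6)
  data.frame(allele = sprintf("HLX%d*%02d", sample(1:5, n_alleles, TRUE),
                              seq_len(n_alleles)),
             gene = sprintf("HLX%d", sample(1:5, n_alleles, TRUE)),
             abundance = x^2, true_c = true_c)
}
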