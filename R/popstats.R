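#' Pairwise Hamming distance matrix of aligned sequences
#'
#' @param seqs named character vector of equal-length (aligned) sequences.
#' @return symmetric matrix of mismatch fractions (per alignment column).
#' @export
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must be aligned (equal length)")
  raws <- lapply(seqs, charToRaw)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- sum(raws[[i]] != raws[[j]]) / L
  D
}

#' Population CDS diversity and divergence
#'
#' For each population, the pairwise difference of a sample is the
#' average Hamming distance (fraction of alignment columns) to the other
#' samples of that population, and the gene diversity is the average of
#' all within-population pairwise differences.  Between-population
#' divergence is the average distance across all cross-population pairs.
#' Populations with a single sequence have undefined diversity and are
#' reported as `NA`.
#'
#' @param aligned_cds named character vector of aligned CDS sequences
#'   (equal length), or a `DNAStringSet`.
#' @param labels population label per sequence (same order/names).
#' @return list with `within` (per population: `gene_diversity` and
#'   `per_sample_mean_distance`), `between` (matrix of mean
#'   cross-population distances) and `dist` (the full distance matrix).
#' @export
cds_diversity <- function(aligned_cds, labels) {
  if (!is.character(aligned_cds))
    aligned_cds <- as.character(aligned_cds)
  if (length(aligned_cds) < 2L)
    stop("need at least two sequences")
  stopifnot(length(labels) == length(aligned_cds))
  D <- hamming_matrix(aligned_cds)
  pops <- unique(labels)
  within <- lapply(pops, function(p) {
    idx <- which(labels == p)
    if (length(idx) < 2L)
      return(list(gene_diversity = NA_real_,
                  per_sample_mean_distance = setNames(
                    rep(NA_real_, length(idx)), names(aligned_cds)[idx])))
    Dp <- D[idx, idx, drop = FALSE]
    per_sample <- rowSums(Dp) / (length(idx) - 1L)
    list(gene_diversity = mean(Dp[upper.tri(Dp)]),
         per_sample_mean_distance = per_sample)
  })
  names(within) <- pops
  between <- matrix(NA_real_, length(pops), length(pops),
                    dimnames = list(pops, pops))
  if (length(pops) > 1L)
    for (i in seq_along(pops)) for (j in seq_along(pops)) if (i != j)
      between[i, j] <- mean(D[labels == pops[i], labels == pops[j], drop = FALSE])
  list(within = within, between = between, dist = D)
}

#' Permutation test for between- vs within-population divergence
#'
#' Tests whether two populations are distinguishable in terms of pairwise
#' distance.  The statistic is the mean between-group distance minus the
#' mean within-group distance; the null distribution is built by
#' permuting the group labels.  The p-value uses add-one smoothing,
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`, so it is never zero.
#'
#' @param distmatrix symmetric distance matrix (zero diagonal).
#' @param labels binary group labels (two levels, both non-empty).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed optional integer seed for the permutations.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(distmatrix, labels, n_perm = 10000L, seed = NULL) {
  D <- as.matrix(distmatrix)
  n <- nrow(D)
  stopifnot(length(labels) == n, isTRUE(all.equal(D, t(D))))
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("labels must have exactly two non-empty groups")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  z <- as.numeric(labels == lev[1L])
  n1 <- sum(z); n0 <- n - n1
  total <- sum(D)
  n_between <- n1 * n0
  n_within <- choose(n1, 2) + choose(n0, 2)
  stat_of <- function(Z) {
    # between-pair sum b = z' D (1 - z); within-pair sum = total/2 - b
    b <- colSums(Z * (rowSums(D) - D %*% Z))
    b / n_between - (total / 2 - b) / n_within
  }
  obs <- stat_of(matrix(z, ncol = 1L))
  if (!is.null(seed)) set.seed(seed)
  Z <- vapply(seq_len(n_perm), function(i) sample(z), numeric(n))
  perm <- stat_of(Z)
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Permutation tests across genes with Bonferroni adjustment
#'
#' @param dist_list named list of distance matrices (one per gene), all
#'   over the same samples.
#' @param labels binary group labels.
#' @param n_perm permutations per gene.
#' @param seed optional integer seed.
#' @return data.frame with `gene`, `statistic`, `p_value`, `p_adj`
#'   (Bonferroni).
#' @export
divergence_permutation_tests <- function(dist_list, labels,
                                         n_perm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(dist_list, function(D)
    permutation_test(D, labels, n_perm = n_perm))
  data.frame(gene = names(dist_list),
             statistic = vapply(res, `[[`, 0, "statistic"),
             p_value = vapply(res, `[[`, 0, "p_value"),
             p_adj = p.adjust(vapply(res, `[[`, 0, "p_value"), "bonferroni"),
             row.names = NULL)
}

#' Two-step read-depth normalization and deletion genotyping
#'
#' Step 1 removes within-sample variation: each gene depth is divided by
#' half the median depth of that sample's control (diploid) regions, so a
#' two-copy gene maps near 2 regardless of the sample's sequencing depth.
#' Step 2 removes residual between-sample variation: each gene's step-1
#' values are divided by their cross-sample median and rescaled so the
#' cohort median maps to 2, assuming most samples carry two copies.
#' Copy-number calls use midpoint thresholds on the normalized value.
#'
#' @param gene_depths numeric matrix samples x genes (rownames =
#'   samples).
#' @param control_depths numeric matrix samples x control regions.
#' @param thresholds named vector: below `deleted` -> `"deleted"`, at or
#'   above `amplified` -> `"amplified"`, otherwise `"present"`.
#' @return data.frame with `sample`, `gene`, `normalized_cn`, `call`;
#'   the step-1 values are attached as `attr(, "step1")`.  Samples with a
#'   zero control median are excluded with a warning.
#' @export
normalize_depth <- function(gene_depths, control_depths,
                            thresholds = c(deleted = 1.5, amplified = 2.5)) {
  gene_depths <- as.matrix(gene_depths)
  control_depths <- as.matrix(control_depths)
  stopifnot(nrow(gene_depths) == nrow(control_depths),
            ncol(control_depths) >= 1L)
  if (nrow(gene_depths) < 3L)
    stop("need at least three samples for the cross-sample median")
  ctrl_med <- apply(control_depths, 1L, median)
  bad <- ctrl_med <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) excluded: zero control-region median")
    gene_depths <- gene_depths[!bad, , drop = FALSE]
    ctrl_med <- ctrl_med[!bad]
  }
  step1 <- gene_depths / (ctrl_med / 2)
  step2 <- sweep(step1, 2L, apply(step1, 2L, median), "/") * 2
  call <- ifelse(step2 < thresholds[["deleted"]], "deleted",
                 ifelse(step2 >= thresholds[["amplified"]], "amplified",
                        "present"))
  out <- data.frame(sample = rep(rownames(step2) %||%
                                   as.character(seq_len(nrow(step2))),
                                 ncol(step2)),
                    gene = rep(colnames(step2) %||%
                                 as.character(seq_len(ncol(step2))),
                               each = nrow(step2)),
                    normalized_cn = as.vector(step2),
                    call = as.vector(call))
  attr(out, "step1") <- step1
  out
}

#' Fit the copy-number abundance model
#'
#' Allele abundances from a short-read genotyper are square-root
#' transformed so they are approximately normal.  The single-copy
#' component `(mu, sigma)` is estimated from the smallest
#' `calibration_fraction` of transformed abundances, pooled with the
#' abundances of user-provided anchor genes expected to carry two copies
#' (one per haplotype, so one copy per heterozygous allele): HLA-A/B/C
#' for HLA panels, the 3DL3/2DL4/3DP1/3DL2 framework genes for KIR.
#'
#' @param abundance numeric vector of per-allele abundances.
#' @param genes optional gene symbol per allele (needed for anchors).
#' @param anchor_genes genes whose alleles are pooled into the
#'   calibration set.
#' @param calibration_fraction fraction of smallest transformed
#'   abundances used (default 0.30).
#' @details The smallest-30% subset is a lower tail, so its naive sample
#' mean and standard deviation systematically underestimate the
#' single-copy component's parameters.  The fit therefore maximizes the
#' likelihood of a normal truncated at the calibration cut-off for the
#' tail points (anchor-gene points, which are not truncated, enter with
#' the full normal density), initialized at the naive moments.
#'
#' @return object of class `cn_model`: `mu`, `sigma`, `transform`,
#'   `calibration_fraction`, `anchor_genes`.
#' @export
fit_copynumber_model <- function(abundance, genes = NULL,
                                 anchor_genes = character(0),
                                 calibration_fraction = 0.30) {
  x <- sqrt(abundance)
  k <- max(2L, floor(calibration_fraction * length(x)))
  tail_idx <- order(x)[seq_len(k)]
  anchor_idx <- integer(0)
  if (length(anchor_genes)) {
    if (is.null(genes)) stop("anchor_genes given but no per-allele genes")
    anchor_idx <- setdiff(which(genes %in% anchor_genes), tail_idx)
  }
  xt <- x[tail_idx]
  xa <- x[anchor_idx]
  if (sd(c(xt, xa)) <= 0 || !is.finite(sd(c(xt, xa))))
    stop("calibration set has non-positive spread")
  cut <- max(xt)
  nll <- function(par) {
    mu <- par[1L]; sigma <- exp(par[2L])
    ll <- sum(dnorm(xt, mu, sigma, log = TRUE)) -
      length(xt) * pnorm(cut, mu, sigma, log.p = TRUE)
    if (length(xa)) ll <- ll + sum(dnorm(xa, mu, sigma, log = TRUE))
    -ll
  }
  init <- c(mean(c(xt, xa)), log(max(sd(c(xt, xa)), 1e-6)))
  fit <- optim(init, nll, method = "Nelder-Mead")
  structure(list(mu = fit$par[1L], sigma = exp(fit$par[2L]),
                 transform = "sqrt",
                 calibration_fraction = calibration_fraction,
                 anchor_genes = anchor_genes),
            class = "cn_model")
}

#' @export
print.cn_model <- function(x, ...) {
  cat(sprintf("<cn_model> mu=%.4f sigma=%.4f (sqrt scale, smallest %d%% + %d anchors)\n",
              x$mu, x$sigma, round(100 * x$calibration_fraction),
              length(x$anchor_genes)))
  invisible(x)
}

#' Copy-number likelihood of a transformed abundance
#'
#' `L(x, c) = 1 / (sqrt(2 pi) c sigma) exp(-((x - c mu) / (c sigma))^2 / 2)`,
#' i.e. a normal density with mean `c mu` and standard deviation
#' `c sigma`.
#'
#' @param x transformed (square-root) abundance; vectorized.
#' @param c copy number (positive integer).
#' @param model a `cn_model`.
#' @return likelihood value(s).
#' @export
copynumber_likelihood <- function(x, c, model) {
  if (model$sigma <= 0) stop("model sigma must be positive")
  if (any(c < 1L)) stop("copy number must be >= 1")
  dnorm(x, mean = c * model$mu, sd = c * model$sigma)
}

#' Maximum-likelihood copy number
#'
#' @param x transformed (square-root) abundance(s).
#' @param model a `cn_model`.
#' @param c_max maximum copy number scanned (default 6).
#' @return integer copy number(s), the `c` in `1..c_max` maximizing
#'   [copynumber_likelihood()].
#' @export
estimate_cn <- function(x, model, c_max = 6L) {
  lik <- vapply(seq_len(c_max), function(c)
    copynumber_likelihood(x, c, model), numeric(length(x)))
  if (length(x) == 1L) lik <- matrix(lik, nrow = 1L)
  as.integer(apply(lik, 1L, which.max))
}
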