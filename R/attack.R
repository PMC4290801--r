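# Likelihood-ratio membership attack.  For each individual, the statistic
#   Lbar = sum_j x_j * log(phat_j / p_j) + (1 - x_j) * log((1-phat_j)/(1-p_j))
# compares the pool allele frequencies phat (here: frequencies recovered from
# a release, or a cohort's empirical frequencies) against the population
# frequencies p.  Pool members score systematically higher; power is the
# fraction of true members above the (1 - fpr) quantile of non-member scores.

#' Assign minor alleles and estimate population frequencies
#'
#' From a reference cohort (individuals unrelated to case and control, used
#' as the population baseline), counts allele copies per SNP and designates
#' the lower-frequency letter as the minor allele (ties broken towards the
#' lexicographically smaller letter).  Frequencies are clamped to
#' `[1/(2n+1), 1 - 1/(2n+1)]` so that the log terms of the attack statistic
#' stay finite even for monomorphic SNPs.
#'
#' @param reference a [genotype_table()] of the reference group.
#' @param alleles optional data frame with columns `major` and `minor` (one
#'   row per SNP) fixing the allele assignment externally, e.g. from a known
#'   panel; frequencies are still estimated from `reference`.
#' @return A `frequency_panel`: data frame with columns `snp`, `major`,
#'   `minor`, `p` (clamped minor-allele frequency), plus attribute `n`.
#' @export
assign_minor_alleles <- function(reference, alleles = NULL) {
  stopifnot(inherits(reference, "genotype_table"))
  n <- length(reference$record_ids)
  if (n == 0) stop2("reference group is empty")
  m <- length(reference$snp_ids)
  a1 <- substr(reference$genotypes, 1, 1)
  a2 <- substr(reference$genotypes, 2, 2)
  dim(a1) <- dim(a2) <- dim(reference$genotypes)
  major <- character(m); minor <- character(m); p <- numeric(m)
  for (j in seq_len(m)) {
    tab <- table(c(a1[, j], a2[, j]))
    letters_j <- csort(names(tab))
    if (length(letters_j) > 2)
      stop2("SNP '", reference$snp_ids[j], "' has ", length(letters_j),
            " alleles; only biallelic SNPs are supported")
    if (!is.null(alleles)) {
      major[j] <- alleles$major[j]; minor[j] <- alleles$minor[j]
      cnt_minor <- if (minor[j] %in% names(tab)) tab[[minor[j]]] else 0
    } else if (length(letters_j) == 1) {
      major[j] <- letters_j
      minor[j] <- csort(setdiff(c("A", "C", "G", "T"), major[j]))[1]
      cnt_minor <- 0
    } else {
      cnts <- as.numeric(tab[letters_j])
      # lower count = minor; tie -> lexicographically smaller letter
      mi <- if (cnts[1] <= cnts[2]) 1L else 2L
      minor[j] <- letters_j[mi]; major[j] <- letters_j[3L - mi]
      cnt_minor <- cnts[mi]
    }
    p[j] <- clamp_freq(cnt_minor / (2 * n), n)
  }
  structure(data.frame(snp = reference$snp_ids, major = major,
                       minor = minor, p = p),
            n = n, class = c("frequency_panel", "data.frame"))
}

#' Binarize genotypes against a minor-allele map
#'
#' Converts genotypes to the 0/1 entries `x_j` of the attack statistic.
#' `per_allele` (default) treats each of the two allele copies as one entry
#' (1 if that copy is the minor allele), doubling the panel length — the
#' natural reading when `p_j` is an allele frequency.  `dominant` emits one
#' entry per SNP, 1 if the individual carries at least one minor allele.
#'
#' @param table a [genotype_table()].
#' @param panel a [assign_minor_alleles()] frequency panel (columns `major`,
#'   `minor` aligned with the table's SNPs).
#' @param mode `"per_allele"` or `"dominant"`.
#' @return Integer 0/1 matrix with one row per record and `2m`
#'   (`per_allele`) or `m` (`dominant`) columns.
#' @export
binarize <- function(table, panel, mode = c("per_allele", "dominant")) {
  stopifnot(inherits(table, "genotype_table"))
  mode <- match.arg(mode)
  m <- length(table$snp_ids)
  if (nrow(panel) != m)
    stop2("panel has ", nrow(panel), " SNPs but table has ", m)
  a1 <- substr(table$genotypes, 1, 1)
  a2 <- substr(table$genotypes, 2, 2)
  dim(a1) <- dim(a2) <- dim(table$genotypes)
  minor <- matrix(panel$minor, nrow = nrow(a1), ncol = m, byrow = TRUE)
  major <- matrix(panel$major, nrow = nrow(a1), ncol = m, byrow = TRUE)
  bad <- (a1 != minor & a1 != major) | (a2 != minor & a2 != major)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop2("genotype '", table$genotypes[w[1], w[2]], "' at record '",
          table$record_ids[w[1]], "', SNP '", table$snp_ids[w[2]],
          "' contains an allele outside {major, minor} = {",
          major[1, w[2]], ",", minor[1, w[2]], "}")
  }
  x1 <- (a1 == minor) * 1L
  x2 <- (a2 == minor) * 1L
  if (mode == "dominant") {
    out <- (x1 | x2) * 1L
  } else {
    out <- matrix(0L, nrow(a1), 2L * m)
    out[, seq(1, 2 * m, by = 2)] <- x1
    out[, seq(2, 2 * m, by = 2)] <- x2
  }
  rownames(out) <- table$record_ids
  out
}

# Expand a per-SNP frequency vector to the per-allele layout of binarize().
expand_per_allele <- function(p) rep(p, each = 2)

#' Likelihood-ratio membership statistic
#'
#' Evaluates `sum_j x_j log(phat_j/p_j) + (1-x_j) log((1-phat_j)/(1-p_j))`
#' for one binary vector `x`.
#'
#' @param x 0/1 vector (one entry per allele copy or per SNP, matching how
#'   `p` and `phat` were expanded).
#' @param p population frequencies, strictly inside (0, 1).
#' @param phat pool frequencies, strictly inside (0, 1).
#' @return The statistic (a single number).
#' @seealso [lr_statistics()] for the vectorized per-individual version.
#' @export
lr_statistic <- function(x, p, phat) {
  if (length(x) != length(p) || length(p) != length(phat))
    stop2("x, p and phat must have equal length")
  if (any(p <= 0 | p >= 1) || any(phat <= 0 | phat >= 1))
    stop2("frequencies must lie strictly inside (0, 1)")
  sum(x * log(phat / p) + (1 - x) * log((1 - phat) / (1 - p)))
}

#' Membership statistics for every row of a binarized matrix
#'
#' @param X 0/1 matrix from [binarize()].
#' @param p,phat frequency vectors matching `ncol(X)`.
#' @return Named numeric vector of per-individual statistics.
#' @export
lr_statistics <- function(X, p, phat) {
  if (ncol(X) != length(p) || length(p) != length(phat))
    stop2("X, p and phat dimensions disagree")
  if (any(p <= 0 | p >= 1) || any(phat <= 0 | phat >= 1))
    stop2("frequencies must lie strictly inside (0, 1)")
  drop(X %*% log(phat / p) + (1 - X) %*% log((1 - phat) / (1 - p)))
}

#' Attack power at a fixed false-positive rate
#'
#' The detection threshold is the nearest-rank `(1 - fpr)` percentile of the
#' non-member (test group) statistics; power is the fraction of case
#' statistics strictly greater than it.
#'
#' @param case_stats statistics of the attacked (case) individuals.
#' @param test_stats statistics of individuals unrelated to the pool.
#' @param fpr nominal false-positive rate, in (0, 1).
#' @return A `power_result`: list with `threshold`, `power` and `fpr`.
#' @export
power_at_fpr <- function(case_stats, test_stats, fpr = 0.05) {
  if (!is.numeric(fpr) || length(fpr) != 1 || fpr <= 0 || fpr >= 1)
    stop2("'fpr' must lie in (0, 1)")
  if (!length(case_stats) || !length(test_stats))
    stop2("both groups must be nonempty")
  k <- ceiling((1 - fpr) * length(test_stats))  # nearest-rank percentile
  threshold <- sort(test_stats)[k]
  structure(list(threshold = threshold,
                 power = mean(case_stats > threshold), fpr = fpr),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power %.3f at %.0f%% FPR (threshold %.4g)\n",
              x$power, 100 * x$fpr, x$threshold))
  invisible(x)
}

#' Pool frequencies recovered from a release
#'
#' Reconstructs per-SNP allele counts from the anonymized release (see
#' [reconstruct_snp_counts()]: nonnegative-clamped row counts spread
#' uniformly over the leaf values under each generalized label) and converts
#' them to minor-allele frequencies under the given panel, clamped strictly
#' inside (0, 1).
#'
#' @param release a `dp_release`.
#' @param forest the `taxonomy_forest` the release was produced under.
#' @param blocks the matching [make_blocks()] spec.
#' @param panel a [assign_minor_alleles()] frequency panel.
#' @return Numeric vector of pool minor-allele frequency estimates, one per
#'   SNP.
#' @export
pool_frequencies_from_release <- function(release, forest, blocks, panel) {
  counts <- reconstruct_snp_counts(release, forest, blocks)
  ac <- allele_counts(counts)
  m <- length(counts$snps)
  phat <- numeric(m)
  for (j in seq_len(m)) {
    cj <- ac[[j]]
    total <- sum(cj)
    if (total <= 0) { phat[j] <- 0.5; next }
    minor_ct <- if (panel$minor[j] %in% names(cj)) cj[[panel$minor[j]]] else 0
    phat[j] <- clamp_freq(minor_ct / total, total / 2)
  }
  phat
}
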