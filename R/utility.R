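# Utility evaluation: chi-square case-control association per SNP, on the
# original data and on counts reconstructed from an anonymized release, with
# significant-SNP recovery scored as accuracy / sensitivity / precision / F1.

#' Per-SNP genotype counts of a genotype table
#'
#' @param table a [genotype_table()].
#' @return A `snp_count_table`: list with `snps` and `genotype` (one named
#'   numeric vector of genotype counts per SNP).
#' @export
snp_counts <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  genotype <- lapply(seq_along(table$snp_ids), function(j) {
    tab <- table(table$genotypes[, j])
    stats::setNames(as.numeric(tab), names(tab))
  })
  structure(list(snps = table$snp_ids, genotype = genotype),
            class = "snp_count_table")
}

#' Per-SNP allele counts
#'
#' Each genotype contributes one count per allele copy.
#'
#' @param counts a `snp_count_table` from [snp_counts()] or
#'   [reconstruct_snp_counts()].
#' @return List (one per SNP) of named numeric allele-count vectors.
#' @export
allele_counts <- function(counts) {
  stopifnot(inherits(counts, "snp_count_table"))
  lapply(counts$genotype, function(g) {
    if (!length(g)) return(stats::setNames(numeric(), character()))
    al <- c(substr(names(g), 1, 1), substr(names(g), 2, 2))
    out <- tapply(c(g, g), al, sum)
    stats::setNames(as.numeric(out), names(out))
  })
}

#' Reconstruct per-SNP counts from an anonymized release
#'
#' The release publishes counts of generalized rows, not genotypes, so a
#' per-SNP association test needs a reconstruction rule.  The rule here is
#' maximum-entropy: each row's count (clamped to be nonnegative; fractional
#' mass allowed) is spread uniformly over the leaf block values under each of
#' its generalized labels, independently per block, and the resulting leaf
#' masses are accumulated into per-SNP genotype counts.  Fully specialized
#' rows contribute their whole count to their literal genotypes.  The rule is
#' recorded in the returned object's `reconstruction` attribute so competing
#' rules can be compared.
#'
#' @param release a `dp_release`.
#' @param forest the `taxonomy_forest` the release was produced under (the
#'   taxonomy digest is checked).
#' @param blocks the matching [make_blocks()] spec.
#' @return A `snp_count_table` with fractional genotype counts.
#' @export
reconstruct_snp_counts <- function(release, forest, blocks) {
  stopifnot(inherits(release, "dp_release"),
            inherits(forest, "taxonomy_forest"),
            inherits(blocks, "block_spec"))
  if (!identical(release$meta$taxonomy_digest, forest_digest(forest)))
    stop2("taxonomy digest mismatch: the release was not produced under ",
          "this forest")
  counts <- pmax(0, release$rows$noisy_count)
  B <- n_blocks(blocks)
  m <- blocks$m
  genotype <- vector("list", m)
  for (b in seq_len(B)) {
    tree <- forest$trees[[b]]
    ids <- release$nodes[, b]
    if (any(ids < 1 | ids > length(tree$label)))
      stop2("release references node ids outside block ", b, "'s tree")
    snps <- (blocks$intervals$start[b] + 1):blocks$intervals$end[b]
    acc <- lapply(snps, function(s) new.env(parent = emptyenv()))
    # mass per distinct generalized node, then uniform over its leaves
    mass <- tapply(counts, ids, sum)
    for (u in seq_along(mass)) {
      node <- as.integer(names(mass)[u])
      if (mass[u] <= 0) next
      leaves <- leaves_under(tree, node)
      share <- as.numeric(mass[u]) / length(leaves)
      gmat <- do.call(rbind, strsplit(leaves, " ", fixed = TRUE))
      for (k in seq_along(snps)) {
        gt <- tapply(rep(share, nrow(gmat)), gmat[, k], sum)
        e <- acc[[k]]
        for (gname in names(gt))
          assign(gname, (get0(gname, envir = e) %||% 0) + gt[[gname]],
                 envir = e)
      }
    }
    for (k in seq_along(snps)) {
      e <- acc[[k]]
      gnames <- csort(ls(e))
      genotype[[snps[k]]] <- stats::setNames(
        vapply(gnames, get, numeric(1), envir = e), gnames)
    }
  }
  structure(list(snps = paste0("snp", seq_len(m)), genotype = genotype,
                 reconstruction = "uniform_over_leaves"),
            class = "snp_count_table")
}

#' Chi-square test of an r x c contingency table
#'
#' Computes `chi2 = sum_ij (O_ij - E_ij)^2 / E_ij` with expected frequencies
#' `E_ij = row_i * col_j / N` and the upper-tail p-value on
#' `(r - 1)(c - 1)` degrees of freedom.  All-zero rows and columns are
#' dropped first (reducing the degrees of freedom); if fewer than two rows or
#' columns remain there is nothing to test and `chi2 = 0, df = 0, p = 1`.
#' Fractional counts (from reconstructed releases) are allowed.
#'
#' @param observed numeric matrix of nonnegative observed counts.
#' @return List with `chi2`, `df` and `p`.
#' @export
chi_square <- function(observed) {
  if (!is.matrix(observed) || !is.numeric(observed))
    stop2("'observed' must be a numeric matrix")
  if (any(observed < 0)) stop2("observed counts must be nonnegative")
  N <- sum(observed)
  if (N <= 0) stop2("chi-square is undefined for an all-zero table")
  observed <- observed[rowSums(observed) > 0, colSums(observed) > 0,
                       drop = FALSE]
  r <- nrow(observed); c_ <- ncol(observed)
  if (r < 2 || c_ < 2) return(list(chi2 = 0, df = 0L, p = 1))
  expected <- outer(rowSums(observed), colSums(observed)) / N
  chi2 <- sum((observed - expected)^2 / expected)
  df <- (r - 1L) * (c_ - 1L)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-SNP case-control association scan
#'
#' For each SNP builds the case/control contingency table — alleles
#' (`allelic_2x2`, default) or genotypes (`genotypic_2x3`) — and applies
#' [chi_square()].  The allelic test matches the attack model's
#' allele-frequency view of the data; the genotypic variant is provided
#' because the chi-square formula is generic in the table shape.
#'
#' @param case_counts,control_counts `snp_count_table`s over the same SNP
#'   panel ([snp_counts()] or [reconstruct_snp_counts()]).
#' @param mode `"allelic_2x2"` or `"genotypic_2x3"`.
#' @return An `association_result`: data frame with columns `snp`, `chi2`,
#'   `df`, `p`.
#' @export
association_scan <- function(case_counts, control_counts,
                             mode = c("allelic_2x2", "genotypic_2x3")) {
  mode <- match.arg(mode)
  stopifnot(inherits(case_counts, "snp_count_table"),
            inherits(control_counts, "snp_count_table"))
  m <- length(case_counts$snps)
  if (m != length(control_counts$snps))
    stop2("case and control SNP panels differ in size")
  if (mode == "allelic_2x2") {
    ca <- allele_counts(case_counts); co <- allele_counts(control_counts)
  } else {
    ca <- case_counts$genotype; co <- control_counts$genotype
  }
  res <- lapply(seq_len(m), function(j) {
    cols <- csort(union(names(ca[[j]]), names(co[[j]])))
    O <- rbind(case = ifelse(cols %in% names(ca[[j]]), ca[[j]][cols], 0),
               control = ifelse(cols %in% names(co[[j]]), co[[j]][cols], 0))
    O[is.na(O)] <- 0
    cs <- chi_square(O)
    data.frame(snp = case_counts$snps[j], chi2 = cs$chi2, df = cs$df,
               p = cs$p)
  })
  structure(do.call(rbind, res), class = c("association_result",
                                           "data.frame"))
}

#' SNPs significant at a p-value cutoff
#'
#' @param result an [association_scan()] result.
#' @param cutoff p-value cutoff in (0, 1]; significance is `p <= cutoff`
#'   (no multiple-testing correction, matching the raw-cutoff convention of
#'   the utility tables).
#' @return Character vector of significant SNP ids.
#' @export
significant_snps <- function(result, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop2("'cutoff' must lie in (0, 1]")
  result$snp[result$p <= cutoff]
}

#' Significant-SNP recovery metrics
#'
#' Scores a predicted significant-SNP set against the truth over a panel of
#' `m` SNPs: TP/FP/TN/FN, accuracy `(TP+TN)/m`, sensitivity `TP/(TP+FN)`,
#' precision `TP/(TP+FP)` (0 for an empty prediction), and F1 (0 when
#' precision and sensitivity are both 0).
#'
#' @param truth SNP ids significant in the original data.
#' @param predicted SNP ids significant in the reconstructed release.
#' @param panel all SNP ids (or the panel size `m`, in which case sets are
#'   not checked for membership).
#' @return A one-row data frame with the counts and metrics.
#' @export
confusion_metrics <- function(truth, predicted, panel) {
  if (length(panel) == 1 && is.numeric(panel)) {
    m <- as.integer(panel)
  } else {
    m <- length(panel)
    if (!all(truth %in% panel) || !all(predicted %in% panel))
      stop2("truth/predicted sets contain SNPs outside the panel")
  }
  truth <- unique(truth); predicted <- unique(predicted)
  tp <- length(intersect(truth, predicted))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- m - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
             accuracy = (tp + tn) / m, sensitivity = sens,
             precision = prec, f1 = f1)
}

#' Utility report: significant-SNP recovery across cutoffs
#'
#' Truth is the set of SNPs significant in the original case/control data;
#' the prediction is the set significant in the counts reconstructed from the
#' anonymized case/control releases.  One metrics row per cutoff, plus the
#' number of significant SNPs in the truth.
#'
#' @param case_table,control_table original [genotype_table()]s.
#' @param case_release,control_release `dp_release`s of the two groups (each
#'   group is a disjoint dataset, so each is anonymized at the full budget
#'   under parallel composition).
#' @param case_forest,control_forest the forests the releases were produced
#'   under.
#' @param blocks the common [make_blocks()] spec.
#' @param cutoffs p-value cutoffs (default: the conventional
#'   `5e-2, 1e-2, 1e-3, 1e-5` ladder).
#' @param mode association test mode, see [association_scan()].
#' @return Data frame with one row per cutoff: `cutoff`, recovery metrics,
#'   and `n_significant_truth`.
#' @export
utility_report <- function(case_table, control_table, case_release,
                           control_release, case_forest, control_forest,
                           blocks, cutoffs = c(5e-2, 1e-2, 1e-3, 1e-5),
                           mode = "allelic_2x2") {
  truth_scan <- association_scan(snp_counts(case_table),
                                 snp_counts(control_table), mode)
  pred_scan <- association_scan(
    reconstruct_snp_counts(case_release, case_forest, blocks),
    reconstruct_snp_counts(control_release, control_forest, blocks), mode)
  # reconstructed panel uses positional snp ids; align to the table's ids
  pred_scan$snp <- truth_scan$snp
  m <- length(truth_scan$snp)
  out <- lapply(cutoffs, function(ct) {
    truth <- significant_snps(truth_scan, ct)
    pred <- significant_snps(pred_scan, ct)
    cm <- confusion_metrics(truth, pred, truth_scan$snp)
    cbind(data.frame(cutoff = ct), cm,
          data.frame(n_significant_truth = length(truth),
                     no_significant_snps = length(truth) == 0))
  })
  do.call(rbind, out)
}
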