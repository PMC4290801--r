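# Differential-privacy audit.  Conditioned on a fixed specialization trace
# (selection is data-independent, so conditioning is sound), the release is a
# Laplace mechanism on the leaf-count vector, whose log density ratio between
# a dataset and a one-record-removed neighbor is analytically bounded by
# epsilon.  The audit checks that bound exactly on small instances and, as a
# black-box cross-check, by Monte-Carlo histogram comparison of actual runs.

#' True count vectors of a dataset and a removal neighbor
#'
#' Computes the leaf-partition count vectors of `table` and of `table` with
#' one record removed, under the identical specialization trace and leaf
#' ordering.  The two vectors differ in exactly one coordinate, by exactly 1.
#'
#' @param table a [genotype_table()].
#' @param forest a `taxonomy_forest`.
#' @param blocks a [make_blocks()] spec.
#' @param trace forced specialization trace (data frame `block`, `label`).
#' @param removed_id record ID to remove for the neighbor.
#' @return A `neighbor_pair`: list with `labels`, `counts_D`, `counts_Dprime`
#'   and `diff_index` (the coordinate that changed).
#' @export
neighbor_counts <- function(table, forest, blocks, trace, removed_id) {
  stopifnot(inherits(table, "genotype_table"))
  i <- match(removed_id, table$record_ids)
  if (is.na(i)) stop2("unknown record ID: ", removed_id)
  keep <- setdiff(seq_along(table$record_ids), i)
  neighbor <- genotype_table(table$genotypes[keep, , drop = FALSE],
                             record_ids = table$record_ids[keep],
                             snp_ids = table$snp_ids)
  cd <- partition_counts(table, forest, blocks, trace)
  cdp <- partition_counts(neighbor, forest, blocks, trace)
  if (!identical(cd$label, cdp$label))
    stop2("internal error: neighbor leaf ordering diverged")
  d <- cd$count - cdp$count
  if (sum(d != 0) != 1 || sum(d) != 1)
    stop2("internal error: neighbor counts do not differ by a single record")
  structure(list(labels = cd$label, counts_D = cd$count,
                 counts_Dprime = cdp$count, diff_index = which(d != 0),
                 removed_id = removed_id),
            class = "neighbor_pair")
}

#' Log density ratio of the Laplace release at an output
#'
#' For the Laplace mechanism with per-count scale `1/epsilon`, the log of
#' `density(output | D) / density(output | D')` is
#' `sum_i epsilon * (|y_i - c'_i| - |y_i - c_i|)`.  By the triangle
#' inequality this is bounded by `epsilon * sum_i |c_i - c'_i|`, which equals
#' `epsilon` for a removal neighbor — the differential-privacy guarantee in
#' closed form.
#'
#' @param pair a [neighbor_counts()] result.
#' @param output numeric vector, one released value per leaf partition.
#' @param epsilon privacy budget used by the release.
#' @return The log density ratio (a single number in `[-epsilon, epsilon]`
#'   for a valid neighbor pair).
#' @export
log_density_ratio <- function(pair, output, epsilon) {
  stopifnot(inherits(pair, "neighbor_pair"))
  if (length(output) != length(pair$counts_D))
    stop2("output length ", length(output), " does not match ",
          length(pair$counts_D), " leaf counts")
  sum(epsilon * (abs(output - pair$counts_Dprime) -
                   abs(output - pair$counts_D)))
}

# Analytic supremum of the log density ratio over all outputs.
log_ratio_bound <- function(pair, epsilon) {
  epsilon * sum(abs(pair$counts_D - pair$counts_Dprime))
}

#' Monte-Carlo differential-privacy check
#'
#' Runs [anonymize()] `n_runs` times on the dataset and on a removal
#' neighbor, with the specialization trace pinned and fresh noise each run,
#' histograms the released count at the coordinate where the two datasets
#' differ, and returns the largest absolute log ratio of bin frequencies.
#' Under epsilon-differential privacy this cannot exceed `epsilon` beyond
#' sampling error; bins with fewer than `min_bin` observations on either side
#' are excluded as too noisy to compare.
#'
#' @inheritParams neighbor_counts
#' @param epsilon privacy budget.
#' @param n_runs number of Monte-Carlo releases per dataset (>= 10^4 for a
#'   meaningful comparison).
#' @param bins number of histogram bins.
#' @param min_bin minimum bin occupancy on both sides for a bin to count.
#' @param seed base seed; run `i` uses `seed + i`.
#' @return List with `max_log_ratio`, `se_at_max` (binomial standard error of
#'   that log ratio), `epsilon`, `n_runs`, and the per-bin table.
#' @export
empirical_ratio_mc <- function(table, forest, blocks, trace, removed_id,
                               epsilon, n_runs = 10000L, bins = 25L,
                               min_bin = 20L, seed = 1L) {
  if (n_runs < 10000L) stop2("'n_runs' must be at least 10^4")
  pair <- neighbor_counts(table, forest, blocks, trace, removed_id)
  i <- match(removed_id, table$record_ids)
  keep <- setdiff(seq_along(table$record_ids), i)
  neighbor <- genotype_table(table$genotypes[keep, , drop = FALSE],
                             record_ids = table$record_ids[keep],
                             snp_ids = table$snp_ids)
  coord <- pair$diff_index
  draw <- function(tab, offset) {
    vapply(seq_len(n_runs), function(r) {
      rel <- anonymize(tab, forest, blocks, epsilon = epsilon, h = 0L,
                       seed = offset + r, trace = trace)
      rel$rows$noisy_count[coord]
    }, numeric(1))
  }
  y1 <- draw(table, seed)
  y2 <- draw(neighbor, seed + n_runs)
  rng <- range(c(y1, y2))
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1)
  c1 <- tabulate(findInterval(y1, breaks, all.inside = TRUE), nbins = bins)
  c2 <- tabulate(findInterval(y2, breaks, all.inside = TRUE), nbins = bins)
  ok <- c1 >= min_bin & c2 >= min_bin
  log_ratio <- log(c1[ok] / c2[ok])
  se <- sqrt(1 / c1[ok] + 1 / c2[ok])
  j <- which.max(abs(log_ratio))
  list(max_log_ratio = abs(log_ratio[j]), se_at_max = se[j],
       epsilon = epsilon, n_runs = n_runs,
       bins = data.frame(lo = breaks[-length(breaks)][ok],
                         hi = breaks[-1][ok], n_D = c1[ok], n_Dprime = c2[ok],
                         log_ratio = log_ratio, se = se))
}

#' Audit the privacy guarantee on a small instance
#'
#' Exhaustive analytic audit: for every removable record and `n_traces`
#' random specialization traces, verifies that the supremum of the log
#' density ratio equals `epsilon * 1` and that the ratio evaluated at
#' `n_outputs` random outputs never exceeds `epsilon`.
#'
#' @inheritParams neighbor_counts
#' @param epsilon privacy budget to audit.
#' @param h trace length for the random traces.
#' @param n_traces number of random traces to try.
#' @param n_outputs random outputs per neighbor pair.
#' @param seed RNG seed.
#' @return List with `pass`, `max_ratio`, `bound` (= epsilon), and the
#'   per-pair results.
#' @export
dp_audit <- function(table, forest, blocks, epsilon, h = 2L, n_traces = 20L,
                     n_outputs = 200L, seed = 1L) {
  set.seed(seed)
  results <- list()
  max_ratio <- -Inf
  for (t in seq_len(n_traces)) {
    tr <- random_trace(table, forest, blocks, h)
    for (id in table$record_ids) {
      pair <- neighbor_counts(table, forest, blocks, tr, id)
      sup <- log_ratio_bound(pair, epsilon)
      k <- length(pair$counts_D)
      sampled <- vapply(seq_len(n_outputs), function(r) {
        y <- pair$counts_D + laplace_noise(k, 1 / epsilon)
        log_density_ratio(pair, y, epsilon)
      }, numeric(1))
      mx <- max(abs(sampled))
      max_ratio <- max(max_ratio, mx, sup)
      results[[length(results) + 1L]] <-
        data.frame(trace = t, removed = id, sup = sup, max_sampled = mx)
    }
  }
  results <- do.call(rbind, results)
  list(pass = max_ratio <= epsilon + 1e-9, max_ratio = max_ratio,
       bound = epsilon, results = results)
}

# Draw a random specialization trace without touching the records (uses the
# current RNG stream).
random_trace <- function(table, forest, blocks, h) {
  ptree <- initialize_root(table, forest, blocks)
  for (i in seq_len(h)) {
    cand <- select_candidate(ptree)
    if (is.null(cand)) break
    ptree <- specialize(ptree, cand$block, cand$node)
  }
  ptree$trace
}
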