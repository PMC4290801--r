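# Core anonymization: maintain a tree of record partitions keyed by
# generalized block values, push the taxonomy cut down by randomly chosen
# specializations, then release every leaf partition's count with Laplace
# noise.  Only the final counts touch the privacy budget: blocking is
# data-independent, the taxonomy is supplied (or stamped non-private), and
# candidate selection is uniform over the cut, never informed by the records.

#' Draw Laplace noise
#'
#' Samples from the Laplace distribution with location 0 and the given scale
#' (density `exp(-|x|/scale) / (2*scale)`, variance `2*scale^2`), using the
#' current RNG stream.  Adding `Lap(sensitivity / epsilon)` noise to a count
#' query of sensitivity 1 yields an epsilon-differentially-private count.
#'
#' @param n number of draws.
#' @param scale positive scale parameter (`sensitivity / epsilon`).
#' @return Numeric vector of `n` draws.
#' @export
laplace_noise <- function(n, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    stop2("'scale' must be a positive number")
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Initialize the partition tree
#'
#' Creates the single root partition holding every record, generalized to the
#' root (`Any_i`) of every block's taxonomy tree; the cut starts at the roots.
#'
#' @param table a [genotype_table()].
#' @param forest a `taxonomy_forest` covering the table (see
#'   [validate_coverage()]).
#' @param blocks a [make_blocks()] spec.
#' @return A `partition_tree` object; see [specialize()].
#' @export
initialize_root <- function(table, forest, blocks) {
  uncovered <- validate_coverage(forest, table, blocks)
  if (nrow(uncovered))
    stop2("taxonomy does not cover the data; uncovered block values: ",
          paste0("(block ", uncovered$block, ", '", uncovered$value, "')",
                 collapse = ", "))
  B <- n_blocks(blocks)
  n <- length(table$record_ids)
  # leaf position of each record's block value, per block
  leaf_pos <- matrix(0L, n, B)
  if (n) {
    bv <- block_values(table, blocks)
    for (b in seq_len(B)) {
      tree <- forest$trees[[b]]
      leaves <- tree$label[tree$leaf_ids]
      leaf_pos[, b] <- match(bv[, b], leaves)
    }
  }
  structure(list(
    forest = forest, blocks = blocks, n_records = n,
    record_ids = table$record_ids, leaf_pos = leaf_pos,
    cut = replicate(B, 1L, simplify = FALSE),  # node id 1 = root
    nodes = matrix(1L, 1, B),                  # leaf partitions x blocks
    members = list(seq_len(n)),
    trace = data.frame(block = integer(), label = character())),
    class = "partition_tree")
}

#' @export
print.partition_tree <- function(x, ...) {
  cat("partition_tree:", nrow(x$nodes), "leaf partitions over", x$n_records,
      "records;", nrow(x$trace), "specializations applied\n")
  invisible(x)
}

#' Select a specialization candidate from the cut
#'
#' Draws uniformly at random (from the current RNG stream) over all non-leaf
#' nodes currently in the cut, enumerated in canonical (block, node) order.
#' The draw consults only the taxonomy structure, never the records, so it
#' consumes no privacy budget.
#'
#' @param ptree a `partition_tree`.
#' @return A list `(block, node, label)`, or `NULL` if every cut node is a
#'   leaf (nothing left to specialize).
#' @export
select_candidate <- function(ptree) {
  stopifnot(inherits(ptree, "partition_tree"))
  cand_block <- integer(); cand_node <- integer()
  for (b in seq_along(ptree$cut)) {
    ids <- ptree$cut[[b]]
    keep <- !ptree$forest$trees[[b]]$is_leaf[ids]
    cand_block <- c(cand_block, rep.int(b, sum(keep)))
    cand_node <- c(cand_node, ids[keep])
  }
  if (!length(cand_block)) return(NULL)
  i <- if (length(cand_block) == 1) 1L else
    sample.int(length(cand_block), 1L)
  list(block = cand_block[i], node = cand_node[i],
       label = ptree$forest$trees[[cand_block[i]]]$label[cand_node[i]])
}

#' Specialize a cut node
#'
#' Replaces node `v` by its children in the cut and splits every leaf
#' partition generalized to `v` into one child partition per child of `v`,
#' routing each record to the child whose subtree contains its block value.
#' Empty child partitions are retained: they are part of the cut-defined leaf
#' set and receive noise at release time, so the released support set leaks
#' nothing about the data.
#'
#' @param ptree a `partition_tree`.
#' @param block block index of the node to specialize.
#' @param node node id or label within that block's tree; must be a non-leaf
#'   node currently in the cut.
#' @param max_rows safety cap on the number of leaf partitions.
#' @return The updated `partition_tree`.
#' @export
specialize <- function(ptree, block, node, max_rows = 65536L) {
  stopifnot(inherits(ptree, "partition_tree"))
  tree <- ptree$forest$trees[[block]]
  id <- resolve_node(tree, node)
  pos <- match(id, ptree$cut[[block]])
  if (is.na(pos))
    stop2("node '", tree$label[id], "' (block ", block,
          ") is not in the current cut")
  if (tree$is_leaf[id])
    stop2("node '", tree$label[id], "' is a leaf and cannot be specialized")
  kids <- tree$children[[id]]
  k <- length(kids)
  affected <- which(ptree$nodes[, block] == id)
  new_total <- nrow(ptree$nodes) + length(affected) * (k - 1L)
  if (new_total > max_rows)
    stop2("specialization would create ", new_total, " leaf partitions, ",
          "exceeding max_rows = ", max_rows,
          "; use a lower-branching taxonomy (see build_prefix_taxonomy) ",
          "or fewer specializations")
  # route members of affected partitions: child index by leaf-range lookup
  child_lo <- tree$leaf_lo[kids]
  keep_nodes <- ptree$nodes[-affected, , drop = FALSE]
  keep_members <- ptree$members[-affected]
  add_nodes <- vector("list", length(affected))
  add_members <- vector("list", length(affected))
  for (ai in seq_along(affected)) {
    p <- affected[ai]
    mem <- ptree$members[[p]]
    ci <- findInterval(ptree$leaf_pos[mem, block], child_lo)
    nodes_rep <- ptree$nodes[rep.int(p, k), , drop = FALSE]
    nodes_rep[, block] <- kids
    add_nodes[[ai]] <- nodes_rep
    add_members[[ai]] <- lapply(seq_len(k), function(j) mem[ci == j])
  }
  ptree$nodes <- rbind(keep_nodes, do.call(rbind, add_nodes))
  ptree$members <- c(keep_members, do.call(c, add_members))
  ptree$cut[[block]] <- c(ptree$cut[[block]][-pos], kids)
  ptree$trace <- rbind(ptree$trace,
                       data.frame(block = block, label = tree$label[id]))
  ptree
}

# Leaf-partition labels (P x B) and canonical row order.
partition_labels <- function(ptree) {
  B <- ncol(ptree$nodes)
  lab <- matrix("", nrow(ptree$nodes), B)
  for (b in seq_len(B))
    lab[, b] <- ptree$forest$trees[[b]]$label[ptree$nodes[, b]]
  lab
}

canonical_row_order <- function(labels) {
  do.call(corder, lapply(seq_len(ncol(labels)), function(b) labels[, b]))
}

#' True leaf-partition counts under a fixed specialization trace
#'
#' Runs the deterministic part of the anonymization (no noise) under a given
#' trace and returns the true count of every leaf partition in canonical row
#' order.  Used by the differential-privacy audit, where the count vectors of
#' a dataset and a neighbor must be compared under the identical trace.
#'
#' @param table a [genotype_table()].
#' @param forest a `taxonomy_forest`.
#' @param blocks a [make_blocks()] spec.
#' @param trace data frame with columns `block` and `label` (or `node`), in
#'   application order, e.g. the `trace` element of a release's metadata.
#' @param max_rows safety cap on leaf partitions.
#' @return Data frame with per-block label columns, a joined `label` column
#'   and an integer `count` column.
#' @export
partition_counts <- function(table, forest, blocks, trace,
                             max_rows = 65536L) {
  ptree <- initialize_root(table, forest, blocks)
  ptree <- apply_trace(ptree, trace, max_rows)
  lab <- partition_labels(ptree)
  o <- canonical_row_order(lab)
  data.frame(label = apply(lab[o, , drop = FALSE], 1, paste, collapse = " "),
             count = lengths(ptree$members)[o])
}

apply_trace <- function(ptree, trace, max_rows = 65536L) {
  if (is.null(trace) || nrow(as.data.frame(trace)) == 0) return(ptree)
  trace <- as.data.frame(trace)
  for (i in seq_len(nrow(trace))) {
    node <- if ("node" %in% names(trace)) trace$node[i] else trace$label[i]
    ptree <- specialize(ptree, trace$block[i], node, max_rows = max_rows)
  }
  ptree
}

#' Anonymize a genotype table
#'
#' Runs the full release pipeline: initialize the root partition, perform
#' `h` uniformly random specializations of the taxonomy cut (stopping early,
#' with a message, if every cut node is already a leaf), then emit one row
#' per leaf partition with `noisy_count = true count + Lap(sensitivity /
#' epsilon)`.  The leaf partitions are disjoint, so by parallel composition
#' the single noising pass costs the full budget `epsilon` and nothing more;
#' all earlier steps are data-independent and cost 0.
#'
#' Randomness is split into two independent streams derived from `seed`: one
#' for candidate selection, one for noise.  The same (table, forest,
#' parameters) therefore reproduce the identical release, and an audit can
#' replay the selection trace on a neighboring dataset while varying only the
#' noise.
#'
#' @param table a [genotype_table()].
#' @param forest a `taxonomy_forest` covering the table.
#' @param blocks a [make_blocks()] spec (default: blocks of 6 SNPs, a size
#'   that balances within-block detail against the number of blocks for
#'   typical SNP panels; tune per dataset).
#' @param epsilon privacy budget, > 0.
#' @param h number of specializations, >= 0.
#' @param seed integer seed for the run.
#' @param rounding `"raw"` (default) releases the real-valued noisy counts;
#'   `"rounded_nonnegative"` additionally stores a presentation column with
#'   counts clamped to nonnegative integers (see [postprocess_counts()]).
#' @param trace optional forced specialization trace (data frame with
#'   `block` and `label`), overriding random selection; used by audits and
#'   worked examples.
#' @param max_rows safety cap on the number of released rows.
#' @return A `dp_release`: list with `rows` (data frame: `label`,
#'   `noisy_count`, optionally `rounded_count`), `labels` (per-block label
#'   matrix), and `meta` (privacy parameters, block spec, taxonomy digest and
#'   provenance stamp, specialization trace, budget ledger).
#' @examples
#' gt <- toy_genotypes()
#' blocks <- make_blocks(8, 2)
#' forest <- build_flat_taxonomy(gt, blocks)
#' rel <- anonymize(gt, forest, blocks, epsilon = 1, h = 2, seed = 7)
#' rel$rows
#' @export
anonymize <- function(table, forest, blocks = make_blocks(length(table$snp_ids),
                                                          min(6L, length(table$snp_ids))),
                      epsilon, h, seed = 1L,
                      rounding = c("raw", "rounded_nonnegative"),
                      trace = NULL, max_rows = 65536L) {
  rounding <- match.arg(rounding)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon <= 0)
    stop2("'epsilon' must be a positive number")
  if (!is_count(h) || h < 0) stop2("'h' must be a nonnegative integer")
  seeds <- derive_seeds(seed, 2)
  ptree <- initialize_root(table, forest, blocks)
  early_stop <- FALSE
  if (is.null(trace)) {
    set.seed(seeds[1])  # selection stream
    for (i in seq_len(h)) {
      cand <- select_candidate(ptree)
      if (is.null(cand)) {
        early_stop <- TRUE
        message("specialization stopped early at step ", i - 1,
                " of ", h, ": all cut nodes are leaves")
        break
      }
      ptree <- specialize(ptree, cand$block, cand$node, max_rows = max_rows)
    }
  } else {
    ptree <- apply_trace(ptree, trace, max_rows)
  }
  lab <- partition_labels(ptree)
  o <- canonical_row_order(lab)
  lab <- lab[o, , drop = FALSE]
  counts <- lengths(ptree$members)[o]
  set.seed(seeds[2])  # noise stream, independent of selection
  noisy <- counts + laplace_noise(length(counts), scale = 1 / epsilon)
  rows <- data.frame(
    label = apply(lab, 1, paste, collapse = " "),
    noisy_count = noisy)
  release <- structure(list(
    rows = rows,
    labels = lab,
    nodes = ptree$nodes[o, , drop = FALSE],
    meta = list(
      epsilon = epsilon, h = h, h_performed = nrow(ptree$trace),
      sensitivity = 1, seed = as.integer(seed), rounding = rounding,
      early_stop = early_stop,
      block_spec = ptree$blocks$intervals,
      block_size = ptree$blocks$block_size, m = ptree$blocks$m,
      taxonomy_digest = forest_digest(forest),
      taxonomy_provenance = forest$provenance,
      taxonomy_stamp = if (forest$provenance == "data_derived")
        "taxonomy: non-private" else "taxonomy: public",
      trace = ptree$trace,
      budget = data.frame(
        step = c("blocking", "taxonomy", "specialization", "noisy counts"),
        epsilon = c(0, 0, 0, epsilon)))),
    class = "dp_release")
  if (rounding == "rounded_nonnegative")
    release <- postprocess_counts(release, rounding)
  release
}

#' @export
print.dp_release <- function(x, ...) {
  cat("dp_release:", nrow(x$rows), "rows; epsilon =", x$meta$epsilon,
      ", h =", x$meta$h_performed, "of", x$meta$h, "(",
      x$meta$taxonomy_stamp, ")\n")
  print(utils::head(x$rows, 10))
  if (nrow(x$rows) > 10) cat("...\n")
  invisible(x)
}

#' Post-process released counts
#'
#' `rounded_nonnegative` adds a presentation column `rounded_count =
#' max(0, round(noisy_count))` (round-half-to-even), leaving the raw noisy
#' counts intact.  Post-processing of a differentially private output cannot
#' weaken the guarantee and consumes no budget.
#'
#' @param release a `dp_release`.
#' @param mode `"raw"` (identity) or `"rounded_nonnegative"`.
#' @return The (possibly augmented) release.
#' @export
postprocess_counts <- function(release,
                               mode = c("raw", "rounded_nonnegative")) {
  stopifnot(inherits(release, "dp_release"))
  mode <- match.arg(mode)
  if (mode == "rounded_nonnegative")
    release$rows$rounded_count <- pmax(0, round(release$rows$noisy_count))
  release
}
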