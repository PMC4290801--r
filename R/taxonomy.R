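# Generalization (taxonomy) trees: one tree per SNP block.  The root of the
# tree for block i is the fully generalized value "Any_i"; leaves are concrete
# block values ("AG CC").  A *cut* of the forest is a set of nodes containing
# exactly one node on every root-to-leaf path; specialization pushes the cut
# from the roots towards the leaves.
#
# Internal representation: each tree is flattened in preorder into parallel
# vectors (label, parent, children, is_leaf) plus, for every node, the
# contiguous range [leaf_lo, leaf_hi] of the left-to-right leaf order covered
# by its subtree.  Contiguity of leaf ranges is what makes record routing and
# cut validation O(log) / O(cut size) instead of repeated subtree walks.

flatten_tree <- function(nested) {
  label <- character(); parent <- integer(); children <- list()
  is_leaf <- logical()
  add <- function(node, par) {
    if (is.null(node$label) || !nzchar(node$label))
      stop2("taxonomy node without a label")
    id <- length(label) + 1L
    label[[id]] <<- node$label
    parent[[id]] <<- par
    children[[id]] <<- integer()
    kids <- node$children
    is_leaf[[id]] <<- is.null(kids) || length(kids) == 0
    if (!is_leaf[[id]]) {
      for (k in kids) {
        cid <- add(k, id)
        children[[id]] <<- c(children[[id]], cid)
      }
    }
    id
  }
  add(nested, 0L)
  n <- length(label)
  leaf_ids <- integer(); leaf_lo <- integer(n); leaf_hi <- integer(n)
  walk <- function(id) {
    if (is_leaf[id]) {
      leaf_ids[[length(leaf_ids) + 1L]] <<- id
      leaf_lo[id] <<- leaf_hi[id] <<- length(leaf_ids)
    } else {
      lo <- length(leaf_ids) + 1L
      for (c_ in children[[id]]) walk(c_)
      leaf_lo[id] <<- lo; leaf_hi[id] <<- length(leaf_ids)
    }
    invisible(NULL)
  }
  walk(1L)
  structure(list(label = label, parent = parent, children = children,
                 is_leaf = is_leaf, leaf_ids = leaf_ids,
                 leaf_lo = leaf_lo, leaf_hi = leaf_hi),
            class = "taxonomy_tree")
}

validate_tree <- function(tree, block) {
  where <- paste0("block ", block, ": ")
  leaves <- tree$label[tree$leaf_ids]
  if (anyDuplicated(leaves))
    stop2(where, "duplicate leaf labels: ",
          paste(unique(leaves[duplicated(leaves)]), collapse = ", "))
  internal <- tree$label[!tree$is_leaf]
  if (anyDuplicated(internal))
    stop2(where, "duplicate internal-node labels: ",
          paste(unique(internal[duplicated(internal)]), collapse = ", "))
  if (tree$label[1] != paste0("Any_", block))
    stop2(where, "root must be labelled 'Any_", block, "', found '",
          tree$label[1], "'")
  if (tree$is_leaf[1])
    stop2(where, "root has no children")
  nch <- lengths(tree$children)
  bad <- which(!tree$is_leaf & nch < 2 & seq_along(nch) != 1L)
  if (length(bad))
    stop2(where, "internal node '", tree$label[bad[1]],
          "' has fewer than 2 children")
  invisible(tree)
}

new_forest <- function(trees, provenance) {
  for (b in seq_along(trees)) validate_tree(trees[[b]], b)
  structure(list(trees = trees, provenance = provenance),
            class = "taxonomy_forest")
}

#' @export
print.taxonomy_forest <- function(x, ...) {
  cat("taxonomy_forest:", length(x$trees), "trees, provenance:",
      x$provenance, "\n")
  for (b in seq_along(x$trees)) {
    t <- x$trees[[b]]
    cat("  block", b, ":", sum(t$is_leaf), "leaves,",
        length(t$label), "nodes\n")
  }
  invisible(x)
}

#' Build a two-level (flat) taxonomy forest from the data
#'
#' For each block, creates a root `Any_<i>` with one leaf per distinct block
#' value observed in the table, in lexicographic order.  Because the leaf set
#' depends on the data, a release produced under such a forest is stamped
#' `taxonomy: non-private` in its metadata: a strictly private release needs a
#' data-independent (user-supplied) forest.
#'
#' @param table a [genotype_table()] (must be nonempty).
#' @param blocks a [make_blocks()] spec.
#' @return A `taxonomy_forest` with `provenance = "data_derived"`.
#' @seealso [build_prefix_taxonomy()], [load_taxonomy()]
#' @export
build_flat_taxonomy <- function(table, blocks) {
  stopifnot(inherits(table, "genotype_table"), inherits(blocks, "block_spec"))
  if (length(table$record_ids) == 0)
    stop2("cannot derive a taxonomy from an empty table")
  bv <- block_values(table, blocks)
  trees <- lapply(seq_len(n_blocks(blocks)), function(b) {
    vals <- csort(unique(bv[, b]))
    flatten_tree(list(label = paste0("Any_", b),
                      children = lapply(vals, function(v)
                        list(label = v, children = NULL))))
  })
  new_forest(trees, "data_derived")
}

#' Build a multilevel prefix (trie) taxonomy forest
#'
#' For each block, arranges the distinct observed block values into a
#' hierarchy that refines one SNP position at a time: the root `Any_<i>`
#' splits on the first SNP of the block, its children on the next SNP, and so
#' on (single-child levels are compressed away).  Internal nodes are labelled
#' by their genotype prefix with `*` for still-generalized positions, e.g.
#' `"AG * *"`.  Branching is at most the number of genotypes per SNP (three
#' for a biallelic SNP), which keeps the partition count of a release small
#' even after many specializations — unlike a flat forest, whose single
#' specialization step jumps straight to all observed values.
#'
#' Like [build_flat_taxonomy()] this is data-derived, so releases under it are
#' stamped `taxonomy: non-private`.
#'
#' @inheritParams build_flat_taxonomy
#' @return A `taxonomy_forest` with `provenance = "data_derived"`.
#' @export
build_prefix_taxonomy <- function(table, blocks) {
  stopifnot(inherits(table, "genotype_table"), inherits(blocks, "block_spec"))
  if (length(table$record_ids) == 0)
    stop2("cannot derive a taxonomy from an empty table")
  bv <- block_values(table, blocks)
  trees <- lapply(seq_len(n_blocks(blocks)), function(b) {
    vals <- csort(unique(bv[, b]))
    width <- blocks$intervals$end[b] - blocks$intervals$start[b]
    vmat <- do.call(rbind, strsplit(vals, " ", fixed = TRUE))
    build <- function(rows, pos) {
      if (length(rows) == 1)
        return(list(label = vals[rows], children = NULL))
      while (pos <= width && length(unique(vmat[rows, pos])) == 1)
        pos <- pos + 1  # compress single-genotype levels
      stopifnot(pos <= width)  # rows distinct => some position differs
      groups <- split(rows, vmat[rows, pos])
      groups <- groups[csort(names(groups))]
      kids <- lapply(groups, function(g) build(g, pos + 1))
      # pattern label: fixed genotypes where all covered values agree, else *
      pat <- vapply(seq_len(width), function(j) {
        u <- unique(vmat[rows, j]); if (length(u) == 1) u else "*"
      }, character(1))
      list(label = paste(pat, collapse = " "), children = unname(kids))
    }
    kids <- if (length(vals) == 1) {
      list(list(label = vals, children = NULL))
    } else {
      root <- build(seq_along(vals), 1)
      root$children
    }
    flatten_tree(list(label = paste0("Any_", b), children = kids))
  })
  new_forest(trees, "data_derived")
}

#' Load a user-supplied taxonomy forest from JSON
#'
#' The config is a JSON array with one tree per block; each tree is a nested
#' `{"label": ..., "children": [...]}` object.  Roots must be labelled
#' `Any_1 ... Any_B`.  Multilevel trees are allowed; every non-root internal
#' node needs at least two children, leaf labels must be unique within a tree
#' and internal labels must be unique within a tree (an internal node may
#' share its label with a leaf in its subtree, the usual convention when a
#' category is named after its prototype value).
#'
#' @param config path to a JSON file, or the equivalent nested list.
#' @param blocks a [make_blocks()] spec; the tree count must match.
#' @return A `taxonomy_forest` with `provenance = "user_supplied"`.
#' @export
load_taxonomy <- function(config, blocks) {
  stopifnot(inherits(blocks, "block_spec"))
  if (is.character(config)) {
    if (!file.exists(config)) stop2("taxonomy config not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (length(config) != n_blocks(blocks))
    stop2("taxonomy config has ", length(config), " trees but the block spec",
          " has ", n_blocks(blocks), " blocks")
  new_forest(lapply(config, flatten_tree), "user_supplied")
}

# Nested-list form (inverse of flatten_tree); canonical input for digests and
# JSON serialization.
tree_to_nested <- function(tree, id = 1L) {
  if (tree$is_leaf[id])
    list(label = tree$label[id], children = NULL)
  else
    list(label = tree$label[id],
         children = lapply(tree$children[[id]], function(c_)
           tree_to_nested(tree, c_)))
}

#' Write a taxonomy forest to a JSON config
#'
#' @param forest a `taxonomy_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(forest, path) {
  stopifnot(inherits(forest, "taxonomy_forest"))
  jsonlite::write_json(lapply(forest$trees, tree_to_nested), path,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

# Content digest of the forest structure (labels + shape), independent of the
# in-memory representation.
forest_digest <- function(forest) {
  digest::digest(lapply(forest$trees, tree_to_nested), algo = "md5")
}

#' List the leaf labels under a taxonomy node
#'
#' @param tree one tree of a `taxonomy_forest` (e.g. `forest$trees[[1]]`).
#' @param node a node id (integer) or node label (string).  For a label shared
#'   by an internal node and a leaf, the internal node is returned.
#' @return Character vector of leaf labels in left-to-right order; a leaf node
#'   returns itself.
#' @export
leaves_under <- function(tree, node) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  id <- resolve_node(tree, node)
  tree$label[tree$leaf_ids[tree$leaf_lo[id]:tree$leaf_hi[id]]]
}

resolve_node <- function(tree, node) {
  if (is.numeric(node)) {
    id <- as.integer(node)
    if (id < 1 || id > length(tree$label)) stop2("node id out of range")
    return(id)
  }
  hits <- which(tree$label == node)
  if (!length(hits)) stop2("no node labelled '", node, "' in tree")
  if (length(hits) > 1) hits <- hits[!tree$is_leaf[hits]]
  hits[1]
}

#' Check that a forest's leaves cover the observed block values
#'
#' Specialization can only place a record if its block value is a leaf of the
#' corresponding tree.  This reports (and does not raise on) every observed
#' block value missing from the tree's leaf set.
#'
#' @param forest a `taxonomy_forest`.
#' @param table a [genotype_table()].
#' @param blocks a [make_blocks()] spec.
#' @return Data frame with columns `block` and `value`; zero rows means full
#'   coverage.
#' @export
validate_coverage <- function(forest, table, blocks) {
  stopifnot(inherits(forest, "taxonomy_forest"),
            inherits(table, "genotype_table"), inherits(blocks, "block_spec"))
  out <- list()
  if (length(table$record_ids)) {
    bv <- block_values(table, blocks)
    for (b in seq_len(n_blocks(blocks))) {
      tree <- forest$trees[[b]]
      missing <- csort(setdiff(unique(bv[, b]), tree$label[tree$leaf_ids]))
      if (length(missing))
        out[[length(out) + 1L]] <- data.frame(block = b, value = missing)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(block = integer(), value = character())
}

# A valid cut contains exactly one node on each root-to-leaf path, i.e. the
# leaf ranges of its nodes tile [1, L] exactly.
cut_is_valid <- function(tree, node_ids) {
  if (!length(node_ids)) return(FALSE)
  lo <- tree$leaf_lo[node_ids]; hi <- tree$leaf_hi[node_ids]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  lo[1] == 1 && hi[length(hi)] == sum(tree$is_leaf) &&
    all(lo[-1] == hi[-length(hi)] + 1)
}
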