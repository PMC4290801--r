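flat_forest <- build_flat_taxonomy(toy, toy_blocks)
`%+%` <- function(a, b) paste0(a, b)

test_that("the root partition holds all records at the topmost values", {
  ptree <- initialize_root(toy, flat_forest, toy_blocks)
  expect_equal(nrow(ptree$nodes), 1L)
  expect_equal(ptree$members[[1]], 1:10)
  expect_equal(unname(snpdp:::partition_labels(ptree)[1, ]),
               paste0("Any_", 1:4))
  expect_equal(ptree$cut, list(1L, 1L, 1L, 1L))  # cut = the four roots

  empty <- genotype_table(matrix(character(), 0, 8),
                          snp_ids = paste0("snp", 1:8))
  pe <- initialize_root(empty, flat_forest, toy_blocks)
  expect_length(pe$members[[1]], 0L)
})

test_that("initialization fails when the taxonomy does not cover the data", {
  nested <- lapply(flat_forest$trees, snpdp:::tree_to_nested)
  nested[[2]] <- list(label = "Any_2", children = list(
    list(label = "CC GG", children = NULL),
    list(label = "CT AG", children = NULL)))
  restricted <- load_taxonomy(nested, toy_blocks)
  expect_error(initialize_root(toy, restricted, toy_blocks), "TT AG")
})

test_that("candidate selection is uniform over non-leaf cut nodes", {
  ptree <- initialize_root(toy, flat_forest, toy_blocks)
  set.seed(99)
  draws <- vapply(1:10000, function(i) select_candidate(ptree)$block,
                  numeric(1))
  gof <- chisq.test(tabulate(draws, 4), p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.001)

  # identical selection sequence under the same seed
  seq1 <- { set.seed(7); vapply(1:50, function(i)
    select_candidate(ptree)$block, numeric(1)) }
  seq2 <- { set.seed(7); vapply(1:50, function(i)
    select_candidate(ptree)$block, numeric(1)) }
  expect_identical(seq1, seq2)

  # exhausted cut -> no candidate
  p2 <- ptree
  for (b in 1:4) p2 <- specialize(p2, b, "Any_" %+% b)
  expect_null(select_candidate(p2))
})

test_that("specializing a category splits partitions per the worked example", {
  ml <- toy_multilevel_forest()
  ptree <- initialize_root(toy, ml, toy_blocks)
  ptree <- specialize(ptree, 2L, "Any_2")
  expect_equal(nrow(ptree$nodes), 2L)
  lab <- snpdp:::partition_labels(ptree)
  members <- lapply(seq_len(2), function(i)
    sort(ptree$members[[which(lab[, 2] == c("CC GG", "CT AG")[i])]]))
  expect_equal(members[[1]], c(1L, 2L, 3L, 6L, 8L))  # records with CC GG
  expect_equal(members[[2]], c(4L, 5L, 7L, 9L, 10L)) # routed via subtree
})

test_that("forced specializations reproduce the hand-derived partition", {
  pc <- partition_counts(toy, flat_forest, toy_blocks, toy_trace)
  expect_equal(nrow(pc), 8L)  # 4 block-2 leaves x 2 block-4 leaves
  got <- pc$count
  names(got) <- sub("^Any_1 (.*) Any_3 (.*)$", "\\1|\\2", pc$label)
  expect_equal(got[names(toy_hand_counts)], toy_hand_counts)
  expect_equal(sum(got), 10)
  expect_true(all(got[setdiff(names(got), names(toy_hand_counts))] == 0))
})

test_that("records route to one child when other children are unobserved", {
  # add an unobserved sibling leaf to block 4's tree
  nested <- lapply(flat_forest$trees, snpdp:::tree_to_nested)
  nested[[4]] <- list(label = "Any_4", children = list(
    list(label = "AA CC", children = NULL),
    list(label = "AG CT", children = NULL),
    list(label = "GG TT", children = NULL)))
  forest <- load_taxonomy(nested, toy_blocks)
  pc <- partition_counts(toy, forest, toy_blocks,
                         data.frame(block = 4L, label = "Any_4"))
  counts <- setNames(pc$count, sub(".* ", "", pc$label))
  expect_equal(unname(counts[c("CC", "CT", "TT")]), c(8, 2, 0))
})

test_that("Laplace noise is calibrated", {
  set.seed(1)
  x <- laplace_noise(50000, 1)
  expect_lt(abs(mean(x)), 0.03)
  expect_lt(abs(var(x) - 2), 0.15)
  expect_lt(abs(mean(x <= 0) - 0.5), 0.01)
  y <- laplace_noise(50000, 1 / 10)
  expect_lt(abs(var(y) / 0.02 - 1), 0.2)
  expect_error(laplace_noise(10, 0), "positive")
})

test_that("anonymize with h = 0 releases a single noisy total", {
  rel <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 0,
                   seed = 5)
  expect_equal(nrow(rel$rows), 1L)
  expect_equal(rel$rows$label, "Any_1 Any_2 Any_3 Any_4")
  means <- mean(vapply(1:300, function(s)
    anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 0,
              seed = s)$rows$noisy_count, numeric(1)))
  expect_lt(abs(means - 10), 0.35)  # E[noisy count] = |D|; SE ~ 0.08
})

test_that("near-zero noise recovers the true counts after rounding", {
  rel <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1e6, h = 2,
                   seed = 11, trace = toy_trace,
                   rounding = "rounded_nonnegative")
  got <- setNames(rel$rows$rounded_count,
                  sub("^Any_1 (.*) Any_3 (.*)$", "\\1|\\2", rel$rows$label))
  expect_equal(got[names(toy_hand_counts)], toy_hand_counts)
  expect_equal(sum(got), 10)
})

test_that("the same inputs and seed reproduce the identical release", {
  r1 <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 3, seed = 21)
  r2 <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 3, seed = 21)
  expect_identical(r1$rows, r2$rows)
  expect_identical(r1$meta$trace, r2$meta$trace)
  r3 <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 3, seed = 22)
  expect_false(identical(r1$rows$noisy_count, r3$rows$noisy_count))
})

test_that("binary trees give at least 2^h leaf rows; exhaustion stops early", {
  # binary multilevel forest over the toy data via prefix construction
  forest <- build_prefix_taxonomy(toy, toy_blocks)
  rel <- anonymize(toy, forest, toy_blocks, epsilon = 1, h = 2, seed = 2)
  expect_gte(nrow(rel$rows), 2^2)
  expect_false(rel$meta$early_stop)

  # more specializations than the forest supports -> early stop, logged
  expect_message(
    rel2 <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 10,
                      seed = 3),
    "stopped early")
  expect_true(rel2$meta$early_stop)
  expect_lt(rel2$meta$h_performed, 10)
  expect_equal(nrow(rel2$rows), 4 * 4 * 5 * 2)  # fully specialized cross product
})

test_that("leaf partitions always partition the record set exactly", {
  for (rep in 1:8) {
    gt <- random_genotype_table(n = 40, m = 6, seed = 300 + rep)
    blocks <- make_blocks(6, 3)
    forest <- build_prefix_taxonomy(gt, blocks)
    ptree <- initialize_root(gt, forest, blocks)
    set.seed(rep)
    for (step in 1:5) {
      cand <- select_candidate(ptree)
      if (is.null(cand)) break
      ptree <- specialize(ptree, cand$block, cand$node)
      all_members <- sort(unlist(ptree$members))
      expect_equal(all_members, 1:40)  # disjoint and exhaustive
    }
  }
})

test_that("leaf membership equals a brute-force group-by of records", {
  for (rep in 1:6) {
    gt <- random_genotype_table(n = 30, m = 6, seed = 400 + rep)
    blocks <- make_blocks(6, 2)
    forest <- build_prefix_taxonomy(gt, blocks)
    set.seed(rep)
    tr <- snpdp:::random_trace(gt, forest, blocks, h = 3)
    pc <- partition_counts(gt, forest, blocks, tr)
    oracle <- bf_partition_counts(gt, forest, blocks, tr)
    nz <- pc[pc$count > 0, ]
    expect_equal(setNames(nz$count, nz$label),
                 setNames(as.numeric(oracle), names(oracle))[nz$label])
    expect_equal(sum(pc$count), 30)
  }
})

test_that("the budget ledger charges only the noisy-count step", {
  rel <- anonymize(toy, flat_forest, toy_blocks, epsilon = 0.7, h = 2,
                   seed = 1)
  b <- rel$meta$budget
  expect_equal(b$epsilon[b$step != "noisy counts"], c(0, 0, 0))
  expect_equal(b$epsilon[b$step == "noisy counts"], 0.7)
  expect_equal(sum(b$epsilon), 0.7)
})

test_that("count post-processing clamps and rounds half-to-even", {
  rel <- anonymize(toy, flat_forest, toy_blocks, epsilon = 1, h = 0, seed = 1)
  rel$rows$noisy_count <- -0.7
  expect_equal(postprocess_counts(rel, "rounded_nonnegative")$rows$rounded_count, 0)
  rel$rows$noisy_count <- 2.5
  expect_equal(postprocess_counts(rel, "rounded_nonnegative")$rows$rounded_count, 2)
  expect_identical(postprocess_counts(rel, "raw")$rows, rel$rows)
  expect_error(postprocess_counts(rel, "unknown"))
})

test_that("the partition-count guard rejects explosive specializations", {
  gt <- random_genotype_table(n = 60, m = 8, seed = 77)
  blocks <- make_blocks(8, 2)
  forest <- build_flat_taxonomy(gt, blocks)
  ptree <- initialize_root(gt, forest, blocks)
  expect_error(specialize(ptree, 1L, "Any_1", max_rows = 3L), "max_rows")
})
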