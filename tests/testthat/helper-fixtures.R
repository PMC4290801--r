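# Shared fixtures and independent oracles, built in code at test time.

toy <- toy_genotypes()
toy_blocks <- make_blocks(8, 2)

toy_taxonomy_path <- system.file("extdata", "toy_taxonomy.json",
                                 package = "snpdp")

# The multilevel forest behind the worked example: block 2 groups its four
# observed values under the two category nodes "CC GG" and "CT AG".
toy_multilevel_forest <- function() {
  load_taxonomy(toy_taxonomy_path, toy_blocks)
}

toy_trace <- data.frame(block = c(2L, 4L), label = c("Any_2", "Any_4"))

# Hand-derived leaf membership of the toy table under the forced trace
# (Any_2, Any_4) with the flat forest: nonzero (block2-value, block4-value)
# cells only.
toy_hand_counts <- c("CC GG|AA CC" = 5, "CT AG|AA CC" = 1,
                     "CT AG|AG CT" = 2, "CT GG|AA CC" = 1,
                     "TT AG|AA CC" = 1)

random_genotype_table <- function(n, m, seed, letters_pool = c("A", "C",
                                                              "G", "T")) {
  set.seed(seed)
  pairs <- replicate(m, sort(sample(letters_pool, 2)))
  g <- vapply(seq_len(m), function(j) {
    dose <- sample(0:2, n, replace = TRUE)
    c(paste0(pairs[1, j], pairs[1, j]),
      paste0(pairs[1, j], pairs[2, j]),
      paste0(pairs[2, j], pairs[2, j]))[dose + 1]
  }, character(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  genotype_table(g)
}

# Independent brute-force oracles ------------------------------------------

bf_lr <- function(x, p, phat) {
  total <- 0
  for (j in seq_along(x)) {
    total <- total + x[j] * log(phat[j] / p[j]) +
      (1 - x[j]) * log((1 - phat[j]) / (1 - p[j]))
  }
  total
}

bf_chisq <- function(O) {
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  if (nrow(O) < 2 || ncol(O) < 2) return(list(chi2 = 0, df = 0L, p = 1))
  N <- sum(O)
  chi2 <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    E <- sum(O[i, ]) * sum(O[, j]) / N
    chi2 <- chi2 + (O[i, j] - E)^2 / E
  }
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Group-by oracle for leaf membership: generalize each record's block values
# to their cut ancestor (via leaf sets), then count groups.  Independent of
# the incremental partition-splitting implementation.
bf_partition_counts <- function(table, forest, blocks, trace) {
  ptree <- initialize_root(table, forest, blocks)
  for (i in seq_len(nrow(trace)))
    ptree <- specialize(ptree, trace$block[i], trace$label[i])
  bv <- block_values(table, blocks)
  gen <- bv
  for (b in seq_len(ncol(bv))) {
    tree <- forest$trees[[b]]
    map <- character()
    for (id in ptree$cut[[b]]) {
      for (leaf in leaves_under(tree, id)) map[leaf] <- tree$label[id]
    }
    gen[, b] <- map[bv[, b]]
  }
  key <- apply(gen, 1, paste, collapse = " ")
  table(key)
}
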