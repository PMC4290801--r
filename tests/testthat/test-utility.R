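test_that("chi-square matches the printed formula and closed forms", {
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square(even), list(chi2 = 0, df = 1L, p = 1))

  res <- chi_square(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$chi2, 20)  # N(ad-bc)^2 / (r1 r2 c1 c2) = 80*800^2/40^4
  expect_equal(res$df, 1L)
  expect_equal(res$p, 7.744216e-06, tolerance = 1e-6)

  frac <- matrix(c(15.5, 5.5, 4.5, 14.5), 2)
  expect_equal(chi_square(frac)$chi2, bf_chisq(frac)$chi2,
               tolerance = 1e-12)

  expect_error(chi_square(matrix(0, 2, 2)), "all-zero")
  # empty column dropped in both groups -> df reduces
  res3 <- chi_square(matrix(c(5, 10, 0, 0, 10, 5), 2))
  expect_equal(res3$df, 1L)
})

test_that("chi-square agrees with brute force on random tables", {
  set.seed(11)
  for (i in 1:500) {
    r <- sample(2:4, 1); c_ <- sample(2:4, 1)
    O <- matrix(rexp(r * c_, 0.1), r, c_)
    got <- chi_square(O); want <- bf_chisq(O)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("reconstruction is lossless for fully specialized noise-free releases", {
  gt <- random_genotype_table(n = 25, m = 4, seed = 70)
  blocks <- make_blocks(4, 2)
  forest <- build_prefix_taxonomy(gt, blocks)
  rel <- suppressMessages(anonymize(gt, forest, blocks, epsilon = 1e9,
                                    h = 1000, seed = 1))
  rec <- reconstruct_snp_counts(rel, forest, blocks)
  direct <- snp_counts(gt)
  for (j in 1:4)
    expect_equal(rec$genotype[[j]], direct$genotype[[j]], tolerance = 1e-6)
})

test_that("generalized mass spreads uniformly over leaf values", {
  flat <- build_flat_taxonomy(toy, toy_blocks)
  rel <- anonymize(toy, flat, toy_blocks, epsilon = 1, h = 0, seed = 1)
  rel$rows$noisy_count <- 10  # pin the count: one row <Any_1..Any_4> of 10
  rec <- reconstruct_snp_counts(rel, flat, toy_blocks)
  # block 1 has leaves {AA CC, AG CC, AG CT, GG CT}: 2.5 each; SNP 1 sees
  # AG in two leaves -> 5, AA and GG in one each -> 2.5
  expect_equal(rec$genotype[[1]][c("AA", "AG", "GG")],
               c(AA = 2.5, AG = 5, GG = 2.5))
  expect_equal(sum(rec$genotype[[3]]), 10)

  # negative counts contribute nothing
  rel$rows$noisy_count <- -0.4
  rec2 <- reconstruct_snp_counts(rel, flat, toy_blocks)
  expect_equal(sum(rec2$genotype[[1]]), 0)
})

test_that("reconstruction conserves clamped mass per SNP", {
  for (rep in 1:5) {
    gt <- random_genotype_table(n = 30, m = 6, seed = 500 + rep)
    blocks <- make_blocks(6, 3)
    forest <- build_prefix_taxonomy(gt, blocks)
    rel <- anonymize(gt, forest, blocks, epsilon = 0.5, h = 3, seed = rep)
    rec <- reconstruct_snp_counts(rel, forest, blocks)
    total <- sum(pmax(0, rel$rows$noisy_count))
    for (j in 1:6)
      expect_equal(sum(rec$genotype[[j]]), total, tolerance = 1e-9)
  }
})

test_that("reconstruction refuses a mismatched forest", {
  gt <- random_genotype_table(n = 10, m = 4, seed = 71)
  blocks <- make_blocks(4, 2)
  forest <- build_prefix_taxonomy(gt, blocks)
  rel <- anonymize(gt, forest, blocks, epsilon = 1, h = 1, seed = 1)
  other <- build_flat_taxonomy(gt, blocks)
  expect_error(reconstruct_snp_counts(rel, other, blocks), "digest")
})

test_that("association scans behave at the edges and match the 2x2 form", {
  gt <- random_genotype_table(n = 20, m = 3, seed = 72)
  counts <- snp_counts(gt)
  same <- association_scan(counts, counts)
  expect_true(all(same$chi2 == 0))
  expect_true(all(same$p == 1))

  # genotype counts whose allele counts give case 120/280 vs control 40/360
  case <- structure(list(snps = "s", genotype = list(c(AA = 140, AG = 0,
                                                       GG = 60))),
                    class = "snp_count_table")
  ctrl <- structure(list(snps = "s", genotype = list(c(AA = 180, AG = 0,
                                                       GG = 20))),
                    class = "snp_count_table")
  res <- association_scan(case, ctrl, "allelic_2x2")
  want <- bf_chisq(matrix(c(280, 120, 360, 40), 2, byrow = TRUE))
  expect_equal(res$chi2, want$chi2)

  # genotypic mode with a genotype absent from both groups: df drops to 1
  case2 <- structure(list(snps = "s", genotype = list(c(AA = 30, AG = 10))),
                     class = "snp_count_table")
  ctrl2 <- structure(list(snps = "s", genotype = list(c(AA = 10, AG = 30))),
                     class = "snp_count_table")
  expect_equal(association_scan(case2, ctrl2, "genotypic_2x3")$df, 1L)
})

test_that("significance cutoffs select by p <= cutoff", {
  res <- structure(data.frame(snp = c("a", "b", "c"),
                              chi2 = c(4, 3, 30), df = 1,
                              p = c(0.04, 0.06, 1e-6)),
                   class = c("association_result", "data.frame"))
  expect_equal(significant_snps(res, 0.05), c("a", "c"))
  expect_equal(significant_snps(res, 1), c("a", "b", "c"))
  res$p <- rep(1, 3)
  expect_length(significant_snps(res, 0.05), 0L)
})

test_that("confusion metrics follow the stated conventions", {
  m100 <- as.character(1:100)
  cm <- confusion_metrics(as.character(1:10),
                          as.character(c(1:5, 11:20)), m100)
  expect_equal(cm$TP, 5); expect_equal(cm$FP, 10)
  expect_equal(cm$FN, 5); expect_equal(cm$TN, 80)
  expect_equal(cm$accuracy, 0.85)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$precision, 1 / 3)
  expect_equal(cm$f1, 0.4)

  perfect <- confusion_metrics(c("a", "b"), c("a", "b"), c("a", "b", "c"))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "precision",
                                   "f1")]) == 1))

  none <- confusion_metrics(c("a"), character(), c("a", "b"))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$precision, 0)
  expect_equal(none$f1, 0)
  expect_equal(none$accuracy * 2, none$TP + none$TN)

  expect_error(confusion_metrics("z", "a", c("a", "b")), "outside")
})

test_that("utility reports hit the lossless limit and flag empty truth", {
  model <- generate_population(8, c(0.2, 0.4), n_effect = 4, delta = 0.4,
                               seed = 42)
  case <- sample_cohort(model, 80, "case", seed = 1)
  control <- sample_cohort(model, 80, "control", seed = 2)
  blocks <- make_blocks(8, 4)
  cf <- build_prefix_taxonomy(case, blocks)
  of <- build_prefix_taxonomy(control, blocks)
  # near-zero noise and exhaustive specialization: predictions equal truth
  ca_rel <- suppressMessages(anonymize(case, cf, blocks, epsilon = 1e9,
                                       h = 10000, seed = 3))
  co_rel <- suppressMessages(anonymize(control, of, blocks, epsilon = 1e9,
                                       h = 10000, seed = 4))
  rep_ <- utility_report(case, control, ca_rel, co_rel, cf, of, blocks,
                         cutoffs = c(5e-2, 1e-2))
  expect_true(all(rep_$sensitivity == 1))
  expect_true(all(rep_$precision == 1))
  expect_gt(rep_$n_significant_truth[1], 0)

  # null truth is flagged, not an error
  null_rep <- utility_report(case, case, ca_rel, ca_rel, cf, cf, blocks,
                             cutoffs = 0.05)
  expect_true(null_rep$no_significant_snps)
  expect_equal(null_rep$n_significant_truth, 0)
})
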