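# Synthetic cohort generator.  Emulates the shape of a case/control/test SNP
# panel study: m biallelic SNPs with population minor-allele frequencies,
# Hardy-Weinberg independent allele sampling, and a subset of "effect" SNPs
# whose minor-allele frequency is shifted additively in the case group.  No
# linkage disequilibrium or population structure is modelled: the attack and
# utility statistics both treat SNPs independently, so LD would change none
# of the tested contracts.

#' Generate a population model
#'
#' @param m number of SNPs.
#' @param maf_range range for the uniform draw of minor-allele frequencies,
#'   a sub-interval of (0, 0.5].
#' @param n_effect number of effect SNPs (drawn without replacement).
#' @param delta additive shift of the minor-allele frequency at effect SNPs
#'   in the case group; `p + delta` must stay below 1.
#' @param seed RNG seed.
#' @return A `population_model`: list with `m`, `p`, `effect_snps` (1-based
#'   indices), `delta`, `alleles` (data frame `major`/`minor`) and `seed`.
#' @export
generate_population <- function(m, maf_range = c(0.05, 0.5), n_effect = 0,
                                delta = 0.15, seed = 1L) {
  if (!is_count(m) || m < 1) stop2("'m' must be a positive integer")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop2("'maf_range' must lie inside (0, 0.5]")
  if (!is_count(n_effect) || n_effect < 0 || n_effect > m)
    stop2("'n_effect' must be an integer in [0, m]")
  if (maf_range[2] + delta >= 1)
    stop2("infeasible delta: p + delta can reach ", maf_range[2] + delta)
  set.seed(as.integer(seed))
  p <- stats::runif(m, maf_range[1], maf_range[2])
  effect <- if (n_effect) csort(sample.int(m, n_effect)) else integer()
  pairs <- t(vapply(seq_len(m), function(j)
    sample(c("A", "C", "G", "T"), 2), character(2)))
  structure(list(m = as.integer(m), p = p,
                 effect_snps = as.integer(effect), delta = delta,
                 alleles = data.frame(major = pairs[, 1], minor = pairs[, 2]),
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("population_model:", x$m, "SNPs,", length(x$effect_snps),
      "effect SNPs (delta =", paste0(x$delta, ")"), "\n")
  invisible(x)
}

#' Sample a cohort from a population model
#'
#' Each individual's two allele copies per SNP are independent Bernoulli
#' minor-allele indicators with frequency `q_j` (Hardy-Weinberg sampling);
#' `q_j = p_j + delta` at effect SNPs for the case group, `p_j` otherwise.
#'
#' @param model a [generate_population()] model.
#' @param n cohort size.
#' @param group `"case"`, `"control"` or `"test"`.
#' @param seed RNG seed.
#' @return A [genotype_table()] with record ids `<group>_<i>`.
#' @export
sample_cohort <- function(model, n, group = c("case", "control", "test"),
                          seed = 1L) {
  stopifnot(inherits(model, "population_model"))
  group <- match.arg(group)
  if (!is_count(n) || n < 1) stop2("'n' must be a positive integer")
  set.seed(as.integer(seed))
  q <- model$p
  if (group == "case" && length(model$effect_snps))
    q[model$effect_snps] <- q[model$effect_snps] + model$delta
  m <- model$m
  # genotype spelled with sorted letters, indexed by minor-allele dose 0/1/2
  geno_by_dose <- cbind(
    paste0(model$alleles$major, model$alleles$major),
    normalize_genotypes(matrix(paste0(model$alleles$major,
                                      model$alleles$minor), ncol = 1)),
    paste0(model$alleles$minor, model$alleles$minor))
  dose <- matrix(stats::rbinom(n * m, 2L, rep(q, each = n)), nrow = n)
  g <- matrix(geno_by_dose[cbind(rep(seq_len(m), each = n),
                                 as.vector(dose) + 1L)], nrow = n)
  genotype_table(g, record_ids = sprintf("%s_%03d", group, seq_len(n)),
                 snp_ids = paste0("snp", seq_len(m)))
}

#' Pre-configured study scenarios
#'
#' Two panels emulating the shape of the chromosome-2 and chromosome-10
#' case/control panels commonly used to benchmark genomic privacy methods:
#' 311 or 610 SNPs, three groups of 200 individuals, minor-allele frequencies
#' uniform on (0.05, 0.5), and an effect-SNP fraction of roughly 6% with an
#' additive case-group frequency shift of 0.15 — strong enough that most
#' effect SNPs are detectable at a 5e-2 cutoff and about half survive 1e-5,
#' matching the scale of significant-SNP counts such panels show.  Model
#' seeds are fixed (311 and 610) so the scenario is the same panel in every
#' run; cohort sampling is seeded by the caller.
#'
#' @param name `"chr2_like"` (m = 311, 20 effect SNPs) or `"chr10_like"`
#'   (m = 610, 40 effect SNPs).
#' @return List with `model` (a `population_model`) and `n_per_group` (200).
#' @export
challenge_scenario <- function(name = c("chr2_like", "chr10_like")) {
  name <- match.arg(name)
  model <- switch(name,
    chr2_like = generate_population(311L, c(0.05, 0.5), n_effect = 20L,
                                    delta = 0.15, seed = 311L),
    chr10_like = generate_population(610L, c(0.05, 0.5), n_effect = 40L,
                                     delta = 0.15, seed = 610L))
  list(name = name, model = model, n_per_group = 200L)
}

#' Write a population model as JSON (ground truth for downstream checks)
#'
#' @param model a `population_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_model <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  jsonlite::write_json(
    list(m = model$m, p = model$p, effect_snps = model$effect_snps,
         delta = model$delta, maf_range = model$maf_range,
         alleles = model$alleles, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
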