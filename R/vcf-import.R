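#' Import biallelic SNP genotypes from a VCF file
#'
#' Reads a VCF (via the vcfR package) and renders each sample's GT call as a
#' two-letter genotype in REF/ALT space, alphabetically ordered within the
#' genotype (REF=A, ALT=G, GT=0/1 -> `"AG"`).  Records that are not biallelic
#' SNPs (multiallelic ALT, indels, symbolic alleles) are skipped with a
#' single summary warning; missing genotypes are an error naming the sample
#' and site.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample_subset optional character vector of sample names to keep.
#' @return A [genotype_table()] with one record per sample and one column per
#'   retained site (SNP ids from the VCF ID column, or `chrom:pos` where the
#'   ID is missing).
#' @export
import_vcf <- function(path, sample_subset = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("the 'vcfR' package is required for VCF import")
  if (!file.exists(path)) stop2("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCF comes back as a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp_ok <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp_ok))
    warning(sum(!snp_ok), " non-SNP or multiallelic record(s) skipped",
            call. = FALSE)
  if (!any(snp_ok)) stop2("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp_ok, , drop = FALSE]
  ref <- ref[snp_ok]; alt <- alt[snp_ok]
  ids <- fix[snp_ok, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[snp_ok, "CHROM"][noid], ":", fix[snp_ok, "POS"][noid])
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing))
      stop2("sample(s) not in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  bad <- is.na(gt) | !grepl("^[01][/|][01]", gt)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop2("missing or unsupported genotype '",
          ifelse(is.na(gt[w[1], w[2]]), ".", gt[w[1], w[2]]),
          "' for sample '", samples[w[2]], "' at site '", ids[w[1]], "'")
  }
  allele <- function(code, j) ifelse(code == "0", ref[j], alt[j])
  n_site <- nrow(gt)
  geno <- matrix("", nrow = length(samples), ncol = n_site)
  for (j in seq_len(n_site)) {
    a1 <- allele(substr(gt[j, ], 1, 1), j)
    a2 <- allele(substr(gt[j, ], 3, 3), j)
    geno[, j] <- paste0(a1, a2)
  }
  genotype_table(geno, record_ids = samples, snp_ids = ids)
}
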