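#' Construct a genotype table
#'
#' A `genotype_table` holds the raw data to be anonymized: one row per
#' individual, one column per SNP, each cell a diploid genotype written as two
#' allele letters from `{A,C,G,T}` (e.g. `"AG"`).  Genotypes are normalized so
#' that the two letters are in alphabetical order (`"GA"` is stored as
#' `"AG"`): diploid genotypes are unordered and all downstream matching of
#' block values against taxonomy labels relies on a canonical spelling.
#'
#' @param genotypes character matrix (records x SNPs) of two-letter genotypes.
#' @param record_ids character vector of unique record identifiers; defaults
#'   to the matrix rownames or `"r1"..."rn"`.
#' @param snp_ids character vector of SNP names; defaults to the matrix
#'   colnames or `"snp1"..."snpm"`.
#' @return An object of class `genotype_table` with fields `record_ids`,
#'   `snp_ids` and `genotypes` (a normalized character matrix).
#' @examples
#' gt <- genotype_table(matrix(c("AG", "CC", "GA", "CT"), 2, 2))
#' gt$genotypes[2, 1]  # "AG" — normalized
#' @export
genotype_table <- function(genotypes, record_ids = NULL, snp_ids = NULL) {
  if (!is.matrix(genotypes) || !is.character(genotypes))
    stop2("'genotypes' must be a character matrix")
  n <- nrow(genotypes); m <- ncol(genotypes)
  record_ids <- record_ids %||% rownames(genotypes) %||%
    (if (n) paste0("r", seq_len(n)) else character())
  snp_ids <- snp_ids %||% colnames(genotypes) %||%
    (if (m) paste0("snp", seq_len(m)) else character())
  record_ids <- as.character(record_ids); snp_ids <- as.character(snp_ids)
  if (length(record_ids) != n) stop2("record_ids length != number of rows")
  if (length(snp_ids) != m) stop2("snp_ids length != number of columns")
  if (anyDuplicated(record_ids))
    stop2("duplicate record IDs: ",
          paste(unique(record_ids[duplicated(record_ids)]), collapse = ", "))
  bad <- which(!grepl("^[ACGT][ACGT]$", genotypes))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% n) + 1; j <- ((bad[1] - 1) %/% n) + 1
    stop2("malformed genotype '", genotypes[bad[1]], "' at record '",
          record_ids[i], "', SNP '", snp_ids[j],
          "' (expected two letters from ACGT)")
  }
  genotypes <- normalize_genotypes(genotypes)
  dimnames(genotypes) <- list(record_ids, snp_ids)
  structure(list(record_ids = record_ids, snp_ids = snp_ids,
                 genotypes = genotypes),
            class = "genotype_table")
}

# Alphabetical allele order within each genotype ("GA" -> "AG").
normalize_genotypes <- function(g) {
  a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
  swap <- a1 > a2
  out <- g
  out[swap] <- paste0(a2[swap], a1[swap])
  dim(out) <- dim(g)
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$record_ids), "records x",
      length(x$snp_ids), "SNPs\n")
  if (length(x$record_ids)) {
    k <- min(5, length(x$record_ids)); l <- min(6, length(x$snp_ids))
    print(x$genotypes[seq_len(k), seq_len(l), drop = FALSE])
    if (length(x$record_ids) > k || length(x$snp_ids) > l) cat("...\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$record_ids), length(x$snp_ids))

#' Read a genotype table from TSV
#'
#' The expected format is a UTF-8 tab-separated file with a header line
#' `ID<TAB><snp1><TAB>...<TAB><snpm>` followed by one line per record.  Lines
#' starting with `#` are ignored.  Cells must be two-letter `ACGT` genotypes.
#'
#' @param path path to a TSV file.
#' @return A [genotype_table()].
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop2("no header line in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 1 || header[1] != "ID")
    stop2("header must start with 'ID': ", path)
  m <- length(header) - 1
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != m + 1)) {
    r <- which(widths != m + 1)[1]
    stop2("ragged row ", r, " in ", path, ": expected ", m + 1,
          " fields, found ", widths[r])
  }
  if (length(body)) {
    mat <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
    genotype_table(mat[, -1, drop = FALSE], record_ids = mat[, 1],
                   snp_ids = header[-1])
  } else {
    genotype_table(matrix(character(), 0, m), record_ids = character(),
                   snp_ids = header[-1])
  }
}

#' Write a genotype table to TSV
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  header <- paste(c("ID", table$snp_ids), collapse = "\t")
  rows <- if (length(table$record_ids)) {
    paste(table$record_ids,
          apply(table$genotypes, 1, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Small worked-example genotype table
#'
#' A 10-record, 8-SNP toy table used throughout the documentation and tests:
#' large enough to show blocking, taxonomy construction and specialization,
#' small enough to verify every partition by hand.
#'
#' @return A [genotype_table()] with 10 records and 8 SNPs.
#' @export
toy_genotypes <- function() {
  rows <- c(
    "AG CC CC GG CT GG AA CC",
    "AG CC CC GG TT GG AA CC",
    "AA CC CC GG TT GG AA CC",
    "AG CT CT AG CT AG AG CT",
    "GG CT CT AG CC GG AA CC",
    "AA CC CC GG TT GG AA CC",
    "AG CT CT AG CT AG AG CT",
    "AA CC CC GG TT GG AA CC",
    "GG CT TT AG CC AG AA CC",
    "AG CT CT GG CT AG AA CC")
  mat <- do.call(rbind, strsplit(rows, " ", fixed = TRUE))
  genotype_table(mat, record_ids = as.character(seq_len(10)),
                 snp_ids = paste0("snp", 1:8))
}
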