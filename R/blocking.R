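#' Partition SNPs into contiguous blocks
#'
#' Splits the `m` SNP columns into contiguous blocks of `block_size` SNPs in
#' input order.  Any remainder `m %% block_size` is absorbed into the final
#' block, so all blocks except possibly the last have identical length and the
#' last can be larger.  Blocking is data-independent: it looks only at `m` and
#' `block_size`, never at genotypes, and therefore consumes no privacy budget.
#'
#' @param m total number of SNPs.
#' @param block_size SNPs per block, `1 <= block_size <= m`.
#' @return A `block_spec`: list with `intervals` (data frame of 0-based
#'   half-open `[start, end)` ranges), `m` and `block_size`.
#' @examples
#' make_blocks(8, 2)   # 4 blocks of 2
#' make_blocks(9, 2)   # sizes 2,2,2,3 — remainder folded into the last block
#' @export
make_blocks <- function(m, block_size) {
  if (!is_count(m) || m < 1) stop2("'m' must be a positive integer")
  if (!is_count(block_size) || block_size < 1 || block_size > m)
    stop2("'block_size' must be an integer in [1, m]; got ", block_size,
          " for m = ", m)
  k <- m %/% block_size
  start <- (seq_len(k) - 1L) * block_size
  end <- start + block_size
  end[k] <- m  # remainder goes to the final block
  structure(list(intervals = data.frame(start = as.integer(start),
                                        end = as.integer(end)),
                 m = as.integer(m), block_size = as.integer(block_size)),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat("block_spec:", nrow(x$intervals), "blocks over", x$m,
      "SNPs (block size", paste0(x$block_size, ")"), "\n")
  invisible(x)
}

n_blocks <- function(blocks) nrow(blocks$intervals)

#' Render the block value of one record
#'
#' The block value is the record's genotypes over the block's SNPs joined by
#' single spaces, in SNP order (e.g. `"AG CC"` for a two-SNP block).
#'
#' @param table a [genotype_table()].
#' @param record_index 1-based record index.
#' @param interval length-2 numeric, 0-based half-open `[start, end)` range
#'   (one row of `blocks$intervals`, or any such range).
#' @return A single block-value string.
#' @export
block_value <- function(table, record_index, interval) {
  stopifnot(inherits(table, "genotype_table"))
  if (record_index < 1 || record_index > nrow(table$genotypes))
    stop2("record_index out of range")
  interval <- as.integer(unlist(interval))
  if (interval[1] < 0 || interval[2] > ncol(table$genotypes) ||
      interval[1] >= interval[2])
    stop2("interval out of range")
  paste(table$genotypes[record_index, (interval[1] + 1):interval[2]],
        collapse = " ")
}

#' Render all block values of a table
#'
#' @param table a [genotype_table()].
#' @param blocks a [make_blocks()] spec for `ncol(table)` SNPs.
#' @return Character matrix, records x blocks, of block-value strings.
#' @export
block_values <- function(table, blocks) {
  stopifnot(inherits(table, "genotype_table"), inherits(blocks, "block_spec"))
  if (blocks$m != length(table$snp_ids))
    stop2("block spec is for ", blocks$m, " SNPs but table has ",
          length(table$snp_ids))
  B <- n_blocks(blocks)
  n <- length(table$record_ids)
  out <- matrix(character(n * B), nrow = n)
  for (b in seq_len(B)) {
    cols <- (blocks$intervals$start[b] + 1):blocks$intervals$end[b]
    g <- table$genotypes[, cols, drop = FALSE]
    out[, b] <- do.call(paste, c(as.data.frame(g, stringsAsFactors = FALSE),
                                 sep = " "))
  }
  out
}
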