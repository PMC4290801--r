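# Serialization of anonymized releases.  The body is a two-column TSV
# mirroring the presentation form (generalized block labels joined by single
# spaces, then the noisy count in full decimal precision); everything needed
# to reconstruct the release exactly — per-block labels, node ids, privacy
# parameters, block spec, taxonomy digest, trace — lives in a JSON sidecar
# written next to the body as <path>.json.

fmt_count <- function(x) sprintf("%.17g", x)

#' Write an anonymized release
#'
#' @param release a `dp_release` from [anonymize()].
#' @param path output path for the TSV body; the metadata sidecar is written
#'   to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @seealso [read_release()]
#' @export
write_release <- function(release, path) {
  stopifnot(inherits(release, "dp_release"))
  if (nrow(release$rows) < 1) stop2("release has no rows")
  header <- c("genomic_data", "noisy_count",
              if (!is.null(release$rows$rounded_count)) "rounded_count")
  body <- paste(release$rows$label, fmt_count(release$rows$noisy_count),
                sep = "\t")
  if (!is.null(release$rows$rounded_count))
    body <- paste(body, fmt_count(release$rows$rounded_count), sep = "\t")
  writeLines(c(paste(header, collapse = "\t"), body), path, useBytes = TRUE)
  meta <- release$meta
  sidecar <- list(
    format = "snpdp-release/1",
    epsilon = meta$epsilon, h = meta$h, h_performed = meta$h_performed,
    sensitivity = meta$sensitivity, seed = meta$seed,
    rounding = meta$rounding, early_stop = meta$early_stop,
    block_spec = meta$block_spec, block_size = meta$block_size, m = meta$m,
    taxonomy_digest = meta$taxonomy_digest,
    taxonomy_provenance = meta$taxonomy_provenance,
    taxonomy_stamp = meta$taxonomy_stamp,
    trace = meta$trace,
    budget = meta$budget,
    labels = unname(apply(release$labels, 1, as.list)),
    nodes = unname(apply(release$nodes, 1, as.list)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an anonymized release
#'
#' Reconstructs a release written by [write_release()], checking that the
#' TSV body and the metadata sidecar agree.
#'
#' @param path path to the TSV body (the sidecar `paste0(path, ".json")` must
#'   exist).
#' @return A `dp_release`.
#' @export
read_release <- function(path) {
  if (!file.exists(path)) stop2("release body not found: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop2("release metadata sidecar not found: ", side_path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "genomic_data" || header[2] != "noisy_count")
    stop2("unexpected release header in ", path)
  n_col <- length(header)
  body <- fields[-1]
  if (any(lengths(body) != n_col))
    stop2("release body/metadata mismatch: row with wrong column count in ",
          path)
  side <- jsonlite::read_json(side_path, simplifyVector = FALSE)
  labels <- do.call(rbind, lapply(side$labels, function(r)
    vapply(r, as.character, character(1))))
  nodes <- do.call(rbind, lapply(side$nodes, function(r)
    vapply(r, function(v) as.integer(v), integer(1))))
  lab_str <- vapply(body, `[[`, character(1), 1)
  counts <- as.numeric(vapply(body, `[[`, character(1), 2))
  if (length(lab_str) != nrow(labels))
    stop2("release body/metadata mismatch: ", length(lab_str),
          " body rows vs ", nrow(labels), " metadata rows")
  joined <- apply(labels, 1, paste, collapse = " ")
  if (!identical(unname(joined), unname(lab_str)))
    stop2("release body/metadata mismatch: row labels disagree")
  rows <- data.frame(label = lab_str, noisy_count = counts)
  if (n_col >= 3 && header[3] == "rounded_count")
    rows$rounded_count <- as.numeric(vapply(body, `[[`, character(1), 3))
  meta <- list(
    epsilon = side$epsilon, h = side$h, h_performed = side$h_performed,
    sensitivity = side$sensitivity, seed = side$seed,
    rounding = side$rounding, early_stop = isTRUE(side$early_stop),
    block_spec = as.data.frame(do.call(rbind, lapply(side$block_spec,
      function(r) data.frame(start = r$start, end = r$end)))),
    block_size = side$block_size, m = side$m,
    taxonomy_digest = side$taxonomy_digest,
    taxonomy_provenance = side$taxonomy_provenance,
    taxonomy_stamp = side$taxonomy_stamp,
    trace = if (length(side$trace))
      do.call(rbind, lapply(side$trace, function(r)
        data.frame(block = r$block, label = r$label)))
    else data.frame(block = integer(), label = character()),
    budget = do.call(rbind, lapply(side$budget, function(r)
      data.frame(step = r$step, epsilon = r$epsilon))))
  structure(list(rows = rows, labels = labels, nodes = nodes, meta = meta),
            class = "dp_release")
}
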