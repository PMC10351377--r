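# File formats: tab-separated UTF-8 with a header row and the row
# identifier in the first column; GMT per the Broad convention (set name,
# description, members); JSON for structured records.  Writers emit the
# shortest round-trippable representation of doubles so every shipped
# object survives a write/read cycle unchanged.

#' Read / write a miRNA-gene pairs table
#'
#' @param path File path.
#' @return `read_pairs()`: tibble with columns `mirna_id`, `gene_id`.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2L) {
    abort(sprintf("%s: expected two tab-separated columns", path),
          class = "mirimmune_format_error")
  }
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed row at line %d", path, bad[1] + 1L),
          class = "mirimmune_format_error")
  }
  stats::setNames(df[, 1:2], c("mirna_id", "gene_id"))
}

#' @rdname read_pairs
#' @param pairs Two-column data frame (miRNA id, gene id).
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(stats::setNames(as.data.frame(pairs)[, 1:2],
                                   c("mirna_id", "gene_id")), path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write a one-identifier-per-line list
#'
#' @param path File path.
#' @return `read_id_list()`: character vector.
#' @export
read_id_list <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids[nzchar(trimws(ids))]
}

#' @rdname read_id_list
#' @param ids Character vector.
#' @export
write_id_list <- function(ids, path) {
  readr::write_lines(ids, path)
  invisible(path)
}

#' Read / write a numeric matrix as TSV
#'
#' First column holds the row identifiers; remaining columns are numeric.
#' Duplicate row identifiers are rejected.
#'
#' @param path File path.
#' @return `read_matrix_tsv()`: numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = "d", readr::col_character()), progress = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicated row identifier '%s'", path, dup[1]),
          class = "mirimmune_format_error")
  }
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("%s: malformed value at line %d", path, prob$row[1] + 1L),
          class = "mirimmune_format_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with dimnames.
#' @param id_column Header name for the row-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "id") {
  df <- tibble::as_tibble(m, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write survival metadata
#'
#' Columns `sample_id`, `time`, `event` (0/1).
#'
#' @param path File path.
#' @return `read_survival()`: tibble with those three columns.
#' @export
read_survival <- function(path) {
  df <- readr::read_tsv(path, col_types = "cdi", progress = FALSE)
  if (!identical(names(df)[1:3], c("sample_id", "time", "event"))) {
    abort(sprintf("%s: expected columns sample_id, time, event", path),
          class = "mirimmune_format_error")
  }
  if (any(duplicated(df$sample_id))) {
    abort(sprintf("%s: duplicated sample_id '%s'", path,
                  df$sample_id[duplicated(df$sample_id)][1]),
          class = "mirimmune_format_error")
  }
  df
}

#' @rdname read_survival
#' @param survival Data frame with `sample_id`, `time`, `event`.
#' @export
write_survival <- function(survival, path) {
  readr::write_tsv(survival[, c("sample_id", "time", "event")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
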