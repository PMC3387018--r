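# Flat result rows and the deterministic tabular report writer.

.REPORT_NUM_FMT <- list(
  input_mz = "%.5f", neutral_mass = "%.5f", query_neutral_mass = "%.5f",
  best_ppm_error = "%.2f"
)

#' Flatten an identification result into report rows
#'
#' One row per (query, merged identification); queries without any hit
#' contribute one row with empty identification fields, so the row count is
#' the sum over queries of `max(1, number of identifications)`. Rows are
#' ordered by query (input order), then ascending |best ppm error|, then
#' merge key. A presence flag column `in_<SOURCE>` is emitted for every
#' selected source.
#'
#' @param x An `mz_id` result from [run_mz_list()] or [run_camera()].
#' @return A tibble of result rows.
#' @export
result_rows <- function(x) {
  stopifnot(inherits(x, "mz_id"))
  ids <- x$identifications
  group_col <- if ("group_id" %in% names(ids)) "group_id" else NULL
  keep <- c("query_id", group_col, "merge_key", "name", "kegg_id",
            "pubchem_cid", "pubchem_sid", "hmdb_ids", "inchi", "inchi_key",
            "source_dbs", "native_ids", "stereoisomer_count", "n_hits",
            "id_conflicts", "query_neutral_mass", "best_ppm_error")
  ids <- ids[intersect(keep, names(ids))]
  if (is.null(group_col)) ids$group_id <- NA_character_
  qcols <- x$queries[c("query_id", "input_mz",
                       intersect("group_ids", names(x$queries)))]
  rows <- dplyr::left_join(qcols, ids, by = "query_id")
  rows <- dplyr::rename(rows, neutral_mass = "query_neutral_mass")
  if (!"group_ids" %in% names(rows)) rows$group_ids <- rows$group_id
  for (s in x$params$sources) {
    rows[[paste0("in_", s)]] <- !is.na(rows$source_dbs) &
      vapply(strsplit(ifelse(is.na(rows$source_dbs), "", rows$source_dbs), ";"),
             function(v) s %in% v, logical(1))
  }
  front <- c("query_id", "input_mz", "group_id", "neutral_mass", "merge_key",
             "name", "kegg_id", "pubchem_cid", "pubchem_sid", "hmdb_ids",
             "inchi", "inchi_key", "source_dbs", "native_ids",
             "stereoisomer_count", "n_hits", "id_conflicts", "best_ppm_error")
  rows <- rows[c(front, paste0("in_", x$params$sources))]
  ord <- order(match(rows$query_id, x$queries$query_id),
               abs(rows$best_ppm_error), rows$merge_key, method = "radix")
  rows[ord, ]
}

.format_report <- function(rows) {
  out <- rows
  for (col in names(.REPORT_NUM_FMT)) {
    if (col %in% names(out)) {
      out[[col]] <- ifelse(is.na(out[[col]]),
                           NA_character_,
                           sprintf(.REPORT_NUM_FMT[[col]], out[[col]]))
    }
  }
  out[] <- lapply(out, function(x) {
    if (is.logical(x)) x <- as.integer(x)
    ifelse(is.na(x), "", as.character(x))
  })
  tibble::as_tibble(out)
}

#' Write an identification report
#'
#' Deterministic: fixed column order, rows ordered by query then ascending
#' |best ppm error| then merge key, numbers printed with fixed precision —
#' re-running on identical input produces byte-identical TSV. The `xlsx`
#' format requires a spreadsheet writer package (`writexl`) to be installed.
#'
#' @param x An `mz_id` result, or an already-formatted character tibble as
#'   returned by [read_report()] (written back verbatim).
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "xlsx")) {
  format <- match.arg(format)
  rows <- if (inherits(x, "mz_id")) .format_report(result_rows(x)) else {
    stopifnot(is.data.frame(x))
    tibble::as_tibble(x)
  }
  if (format == "xlsx") {
    if (!requireNamespace("writexl", quietly = TRUE)) {
      rlang::abort(paste0(
        "spreadsheet output requires the 'writexl' package, which is not ",
        "installed; use format = \"tsv\""
      ))
    }
    writexl::write_xlsx(rows, path)
  } else {
    readr::write_tsv(rows, path, progress = FALSE)
  }
  invisible(path)
}

#' Read back a written TSV report
#'
#' All columns are read as character, so `write_report(read_report(p), p2)`
#' reproduces the file byte-for-byte.
#'
#' @param path Path to a TSV report written by [write_report()].
#' @return Character tibble of report rows.
#' @export
read_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE)
}

#' Write the un-merged per-source hit tables
#'
#' The per-database view of the results: one TSV per source with the raw
#' hits before identifier fill-in and merging.
#'
#' @param x An `mz_id` result produced with `keep_per_source = TRUE`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_per_source <- function(x, dir) {
  stopifnot(inherits(x, "mz_id"))
  if (is.null(x$per_source)) {
    rlang::abort("result was produced with keep_per_source = FALSE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(x$per_source, function(hits, nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    out <- hits
    out$monoisotopic_mass <- sprintf("%.5f", out$monoisotopic_mass)
    out$query_neutral_mass <- sprintf("%.5f", out$query_neutral_mass)
    out$ppm_error <- sprintf("%.2f", out$ppm_error)
    out[] <- lapply(out, function(v) ifelse(is.na(v), "", as.character(v)))
    readr::write_tsv(tibble::as_tibble(out), p, progress = FALSE)
    p
  })
  invisible(paths)
}
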