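# Metabolite record model: tabular backend files, per-source profiles,
# loading with schema/row validation, lossless re-serialization.

.BACKEND_COLS <- c(
  "native_id", "name", "monoisotopic_mass", "kegg_id", "pubchem_cid",
  "pubchem_sid", "hmdb_ids", "inchi", "inchi_key"
)
.SOURCES <- c("HMDB", "MMCD", "METLIN", "LIPIDMAPS", "OTHER")
.ID_FIELDS <- c("kegg_id", "pubchem_cid", "pubchem_sid", "hmdb_ids",
                "inchi", "inchi_key")
.INCHIKEY_RE <- "^[A-Z]{14}(-[A-Z0-9]+)*$"

#' Describe a metabolite record source
#'
#' A profile records which identifier fields a source never supplies and, for
#' the fixture generators, which it supplies only part of the time. The
#' Metlin-style profile always lacks InChI strings and keys, which is what
#' makes cross-referencing necessary before skeleton-based merging.
#'
#' @param source_db Source label, one of `"HMDB"`, `"MMCD"`, `"METLIN"`,
#'   `"LIPIDMAPS"`, `"OTHER"`.
#' @param fields_always_missing Character vector of identifier fields the
#'   source never provides.
#' @param fields_partially_missing Named numeric vector: per-field probability
#'   that a generated record lacks the field (fixtures only).
#' @return A `source_profile` object.
#' @export
#' @examples
#' source_profile("METLIN", fields_always_missing = c("inchi", "inchi_key"))
source_profile <- function(source_db,
                           fields_always_missing = character(),
                           fields_partially_missing = numeric()) {
  source_db <- match.arg(source_db, .SOURCES)
  stopifnot(all(fields_always_missing %in% .ID_FIELDS))
  if (length(fields_partially_missing)) {
    stopifnot(
      !is.null(names(fields_partially_missing)),
      all(names(fields_partially_missing) %in% .ID_FIELDS),
      all(fields_partially_missing >= 0 & fields_partially_missing <= 1)
    )
  }
  structure(
    list(
      source_db = source_db,
      fields_always_missing = fields_always_missing,
      fields_partially_missing = fields_partially_missing
    ),
    class = "source_profile"
  )
}

#' @export
print.source_profile <- function(x, ...) {
  cat("<source_profile> ", x$source_db, "\n", sep = "")
  cat("  always missing:   ",
      if (length(x$fields_always_missing)) paste(x$fields_always_missing, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (length(x$fields_partially_missing)) {
    cat("  partially missing:",
        paste(sprintf("%s (%.0f%%)", names(x$fields_partially_missing),
                      100 * x$fields_partially_missing), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default source profiles
#'
#' Emulates the identifier coverage patterns of the four classical metabolite
#' record sources: Metlin provides neither InChI nor InChIKey and often lacks
#' PubChem CIDs; MMCD rarely carries PubChem or KEGG ids; LIPID MAPS is the
#' usual supplier of PubChem SIDs; HMDB carries KEGG ids but not SIDs.
#'
#' @return Named list of [source_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    HMDB = source_profile(
      "HMDB",
      fields_partially_missing = c(pubchem_cid = 0.4, kegg_id = 0.2,
                                   pubchem_sid = 0.85)
    ),
    MMCD = source_profile(
      "MMCD",
      fields_partially_missing = c(kegg_id = 0.6, pubchem_cid = 0.6,
                                   pubchem_sid = 0.9)
    ),
    METLIN = source_profile(
      "METLIN",
      fields_always_missing = c("inchi", "inchi_key"),
      fields_partially_missing = c(pubchem_cid = 0.7, kegg_id = 0.5)
    ),
    LIPIDMAPS = source_profile(
      "LIPIDMAPS",
      fields_partially_missing = c(kegg_id = 0.7, pubchem_cid = 0.5)
    )
  )
}

.as_profile <- function(profile) {
  if (inherits(profile, "source_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1) {
    defaults <- default_profiles()
    if (profile %in% names(defaults)) return(defaults[[profile]])
    return(source_profile(profile))
  }
  rlang::abort("profile must be a source_profile or a source name")
}

# Uppercase, strip whitespace; keys failing the pattern become NA (keyless).
.normalize_inchi_key <- function(key, context = "record") {
  key <- toupper(gsub("\\s+", "", key))
  key[!is.na(key) & key == ""] <- NA_character_
  bad <- !is.na(key) & !grepl(.INCHIKEY_RE, key)
  if (any(bad)) {
    rlang::warn(paste0(
      sum(bad), " ", context, "(s) with malformed InChIKey treated as keyless (e.g. \"",
      key[bad][1], "\")"
    ))
    key[bad] <- NA_character_
  }
  key
}

#' Load a metabolite record backend file
#'
#' Reads a tab-separated backend table with the canonical columns
#' `native_id`, `name`, `monoisotopic_mass`, `kegg_id`, `pubchem_cid`,
#' `pubchem_sid`, `hmdb_ids`, `inchi`, `inchi_key` (empty cell = missing;
#' multi-valued cells `;`-separated). Rows with a non-numeric or non-positive
#' mass are skipped with a warning naming the row; values present in a column
#' the profile declares the source can never supply are kept but flagged with
#' a warning; malformed InChIKeys are dropped (record becomes keyless) with a
#' warning.
#'
#' @param path Path to a TSV backend file with a header row.
#' @param profile A [source_profile()] or source name; defaults to `"OTHER"`.
#' @return A tibble of records with a `source_db` column first.
#' @export
load_backend <- function(path, profile = "OTHER") {
  profile <- .as_profile(profile)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing_cols <- setdiff(.BACKEND_COLS, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "backend file ", path, " lacks mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[.BACKEND_COLS]
  raw[raw == ""] <- NA

  mass <- suppressWarnings(as.numeric(raw$monoisotopic_mass))
  bad_mass <- is.na(mass) | mass <= 0
  if (any(bad_mass)) {
    rlang::warn(paste0(
      "skipping ", sum(bad_mass), " row(s) with invalid monoisotopic_mass: row ",
      paste(which(bad_mass), collapse = ", ")
    ))
  }
  rec <- dplyr::mutate(raw, monoisotopic_mass = mass)[!bad_mass, , drop = FALSE]

  violated <- intersect(profile$fields_always_missing, names(rec))
  for (f in violated) {
    n_bad <- sum(!is.na(rec[[f]]))
    if (n_bad > 0) {
      rlang::warn(paste0(
        profile$source_db, " backend provides ", n_bad, " value(s) for `", f,
        "`, which this source cannot supply; values kept but flagged"
      ))
    }
  }

  rec$inchi_key <- .normalize_inchi_key(rec$inchi_key, context = "record")
  dup <- duplicated(rec$native_id)
  if (any(dup)) {
    rlang::warn(paste0(
      "duplicated native_id within ", profile$source_db, " backend: ",
      paste(unique(rec$native_id[dup]), collapse = ", ")
    ))
  }
  dplyr::bind_cols(
    tibble::tibble(source_db = rep(profile$source_db, nrow(rec))),
    tibble::as_tibble(rec)
  )
}

#' Write records back to the canonical backend format
#'
#' Inverse of [load_backend()]: writing then re-loading is lossless for all
#' populated fields. Masses are printed with five decimals, the convention
#' used throughout the package's tabular output.
#'
#' @param records Record tibble as returned by [load_backend()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_backend <- function(records, path) {
  out <- records[.BACKEND_COLS]
  out$monoisotopic_mass <- sprintf("%.5f", out$monoisotopic_mass)
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Split a `;`-joined multi-valued cell into a clean character vector.
.split_multi <- function(x) {
  if (length(x) == 0 || all(is.na(x))) return(character())
  v <- unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE), use.names = FALSE)
  v <- trimws(v)
  v[v != ""]
}

# Stable union preserving first-encounter order.
.union_encounter <- function(...) {
  v <- unlist(list(...), use.names = FALSE)
  v <- v[!is.na(v) & v != ""]
  v[!duplicated(v)]
}
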