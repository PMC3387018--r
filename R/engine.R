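# The computation core: per-source ppm tolerance search over a mass-sorted
# index, identifier fill-in, InChIKey-skeleton merging, and the two entry
# points (bare m/z list, CAMERA-style annotated table).

#' Search one record source by neutral mass within a ppm tolerance
#'
#' Binary search over a mass-sorted index with a window of
#' `query * tol * 1e-6`, followed by the exact relative-tolerance test of
#' [ppm_match()] (record mass is the reference). Hits are ordered by
#' ascending absolute ppm error, ties broken by `native_id`.
#'
#' @param records Record tibble for one source ([load_backend()] output).
#' @param query_neutral_mass Neutral monoisotopic mass (Da) to search;
#'   vectorised.
#' @param tol_ppm Tolerance in ppm.
#' @param query_ref Optional parallel vector of query labels, carried into
#'   the `query_ref` column (defaults to the query index).
#' @return Hit tibble: the record columns plus `query_ref`,
#'   `query_neutral_mass` and signed `ppm_error`.
#' @export
search_source <- function(records, query_neutral_mass, tol_ppm = 10,
                          query_ref = NULL) {
  stopifnot(is.numeric(query_neutral_mass), tol_ppm >= 0)
  if (is.null(query_ref)) query_ref <- as.character(seq_along(query_neutral_mass))
  if (nrow(records) == 0 || length(query_neutral_mass) == 0) {
    out <- dplyr::mutate(records[0, ], query_ref = character(),
                         query_neutral_mass = numeric(), ppm_error = numeric())
    return(out)
  }
  ord <- order(records$monoisotopic_mass, method = "radix")
  sorted <- records[ord, ]
  v <- sorted$monoisotopic_mass
  t <- tol_ppm * 1e-6
  # |q - m| / m <= t  <=>  q / (1 + t) <= m <= q / (1 - t)
  lo <- query_neutral_mass / (1 + t)
  hi <- if (t < 1) query_neutral_mass / (1 - t) else rep(Inf, length(lo))
  start <- findInterval(lo, v, left.open = TRUE) + 1L
  end <- findInterval(hi, v)
  n_hit <- pmax(end - start + 1L, 0L)
  if (sum(n_hit) == 0) {
    out <- dplyr::mutate(sorted[0, ], query_ref = character(),
                         query_neutral_mass = numeric(), ppm_error = numeric())
    return(out)
  }
  rec_idx <- sequence(n_hit[n_hit > 0], from = start[n_hit > 0])
  q_idx <- rep(which(n_hit > 0), n_hit[n_hit > 0])
  hits <- sorted[rec_idx, ]
  hits$query_ref <- query_ref[q_idx]
  hits$query_neutral_mass <- query_neutral_mass[q_idx]
  pm <- ppm_match(hits$query_neutral_mass, hits$monoisotopic_mass, tol_ppm)
  hits$ppm_error <- pm$ppm_error
  hits <- hits[pm$match, ]
  hits[order(hits$query_ref, abs(hits$ppm_error), hits$native_id,
             method = "radix"), ]
}

.SOURCE_ORDER <- c("HMDB", "MMCD", "METLIN", "LIPIDMAPS", "OTHER")

.sort_sources <- function(x) {
  known <- intersect(.SOURCE_ORDER, x)
  c(known, sort(setdiff(x, .SOURCE_ORDER), method = "radix"))
}

#' Merge search hits into non-redundant identifications by InChIKey skeleton
#'
#' Hits carrying an InChIKey are partitioned by its first 14 characters (the
#' connectivity skeleton), so the same compound and its stereoisomers from
#' different sources collapse into one entry while structural isomers stay
#' apart. Hits without a key — even after cross-referencing — each form a
#' source-local entry under the fallback key `SOURCE:native_id`, since
#' cross-source identity cannot be asserted without a structure code.
#'
#' Per entry: names and HMDB ids are the `;`-joined, deduplicated union in
#' first-encounter order over canonically ordered hits (ascending |ppm
#' error|, then `native_id`); single-valued identifiers are the union with
#' disagreements flagged in `id_conflicts`; the representative InChI
#' key/string is the lexicographically smallest full key among members; the
#' stereoisomer count is the number of distinct full keys sharing the
#' skeleton (at least 1); `best_ppm_error` is the signed error of smallest
#' magnitude. The canonical pre-sort makes merging order-invariant and
#' idempotent.
#'
#' @param hits Hit tibble (any number of sources bound together, one query).
#' @return Tibble with one row per merged identification, ordered by
#'   ascending |best_ppm_error| then merge key.
#' @export
merge_hits <- function(hits) {
  cols <- c("merge_key", "name", "kegg_id", "pubchem_cid", "pubchem_sid",
            "hmdb_ids", "inchi", "inchi_key", "source_dbs", "native_ids",
            "stereoisomer_count", "n_hits", "id_conflicts",
            "query_neutral_mass", "best_ppm_error")
  if (nrow(hits) == 0) {
    return(tibble::as_tibble(stats::setNames(
      list(character(), character(), character(), character(), character(),
           character(), character(), character(), character(), character(),
           integer(), integer(), character(), numeric(), numeric()),
      cols
    )))
  }
  hits <- hits[order(abs(hits$ppm_error), hits$native_id, hits$source_db,
                     method = "radix"), ]
  hits$merge_key <- ifelse(
    !is.na(hits$inchi_key),
    substr(hits$inchi_key, 1, 14),
    paste0(hits$source_db, ":", hits$native_id)
  )
  union_single <- function(x) {
    v <- unique(x[!is.na(x)])
    list(value = if (length(v)) paste(v, collapse = ";") else NA_character_,
         conflict = length(v) > 1)
  }
  one <- function(df) {
    keys <- sort(unique(df$inchi_key[!is.na(df$inchi_key)]), method = "radix")
    rep_key <- if (length(keys)) keys[1] else NA_character_
    rep_inchi <- if (!is.na(rep_key)) {
      cand <- df$inchi[!is.na(df$inchi_key) & df$inchi_key == rep_key & !is.na(df$inchi)]
      if (length(cand)) cand[1] else {
        other <- df$inchi[!is.na(df$inchi)]
        if (length(other)) sort(other, method = "radix")[1] else NA_character_
      }
    } else {
      other <- df$inchi[!is.na(df$inchi)]
      if (length(other)) sort(other, method = "radix")[1] else NA_character_
    }
    kegg <- union_single(df$kegg_id)
    cid <- union_single(df$pubchem_cid)
    sid <- union_single(df$pubchem_sid)
    conflicted <- c("kegg_id", "pubchem_cid", "pubchem_sid")[
      c(kegg$conflict, cid$conflict, sid$conflict)
    ]
    tibble::tibble(
      merge_key = df$merge_key[1],
      name = paste(.union_encounter(lapply(df$name, .split_multi)), collapse = ";"),
      kegg_id = kegg$value, pubchem_cid = cid$value, pubchem_sid = sid$value,
      hmdb_ids = {
        u <- .union_encounter(lapply(df$hmdb_ids, .split_multi))
        if (length(u)) paste(u, collapse = ";") else NA_character_
      },
      inchi = rep_inchi, inchi_key = rep_key,
      source_dbs = paste(.sort_sources(unique(df$source_db)), collapse = ";"),
      native_ids = paste(
        .union_encounter(paste0(df$source_db, ":", df$native_id)),
        collapse = ";"
      ),
      stereoisomer_count = max(1L, length(keys)),
      n_hits = nrow(df),
      id_conflicts = paste(conflicted, collapse = ";"),
      query_neutral_mass = df$query_neutral_mass[1],
      best_ppm_error = df$ppm_error[1]
    )
  }
  parts <- split(hits, factor(hits$merge_key, levels = unique(hits$merge_key)))
  out <- dplyr::bind_rows(lapply(parts, one))
  out[order(abs(out$best_ppm_error), out$merge_key, method = "radix"), ]
}

# Merge hits within each level of a grouping column.
.merge_by <- function(hits, by) {
  if (nrow(hits) == 0) {
    out <- merge_hits(hits)
    out[[by]] <- character()
    return(out[c(by, setdiff(names(out), by))])
  }
  parts <- split(hits, factor(hits[[by]], levels = unique(hits[[by]])))
  out <- dplyr::bind_rows(lapply(names(parts), function(g) {
    m <- merge_hits(parts[[g]])
    m[[by]] <- g
    m
  }))
  out[c(by, setdiff(names(out), by))]
}

.check_sources <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  if (!is.list(sources) || length(sources) == 0) {
    rlang::abort("no sources selected")
  }
  if (is.null(names(sources)) || any(names(sources) == "")) {
    nm <- vapply(sources, function(s) {
      if (nrow(s) > 0) s$source_db[1] else "OTHER"
    }, character(1))
    names(sources) <- make.unique(nm)
  }
  sources
}

.search_all_sources <- function(sources, neutral, query_ref, tol_ppm) {
  per_source <- purrr::imap(sources, function(recs, nm) {
    search_source(recs, neutral, tol_ppm, query_ref = query_ref)
  })
  list(per_source = per_source, hits = dplyr::bind_rows(per_source))
}

.new_mz_id <- function(queries, identifications, per_source, params,
                       groups = NULL, membership = NULL) {
  structure(
    list(queries = queries, identifications = identifications,
         per_source = per_source, groups = groups, membership = membership,
         params = params),
    class = "mz_id"
  )
}

#' Identify a plain list of m/z values
#'
#' Every m/z value is treated as a monoisotopic, singly charged
#' (de)protonated ion according to the ionization mode; its neutral mass is
#' searched against every selected record source within the ppm tolerance,
#' missing identifiers are filled by cross-referencing, and hits are merged
#' by InChIKey skeleton into non-redundant identifications.
#'
#' @param mz Numeric vector of observed m/z values.
#' @param polarity Ionization mode, `"positive"` or `"negative"`.
#' @param sources Named list of record tibbles (see [load_backend()]), or a
#'   single record tibble.
#' @param tol_ppm Mass tolerance in ppm (default 10, the usual setting for
#'   Q-TOF accuracy).
#' @param xref Optional [build_crossref()] index for identifier fill-in.
#' @param keep_per_source Retain the raw, un-merged per-source hit tables in
#'   the result (the per-database view of the results).
#' @return An `mz_id` result object; see [tidy.mz_id()] for the flat table.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   source_db = "HMDB", native_id = "HMDB00122", name = "Glucose",
#'   monoisotopic_mass = 180.06339, kegg_id = "C00031",
#'   pubchem_cid = "5793", pubchem_sid = NA, hmdb_ids = "HMDB00122",
#'   inchi = NA, inchi_key = "WQZGKKKJIJFFOK-GASJEMHNSA-N"
#' )
#' res <- run_mz_list(181.0707, "positive", list(HMDB = recs))
#' tidy(res)
run_mz_list <- function(mz, polarity = c("positive", "negative"), sources,
                        tol_ppm = 10, xref = NULL, keep_per_source = TRUE) {
  polarity <- match.arg(polarity)
  sources <- .check_sources(sources)
  if (length(mz) == 0) rlang::abort("no m/z values supplied")
  if (any(is.na(mz) | mz <= 0)) {
    rlang::abort(paste0("non-positive m/z value in input: ",
                        mz[is.na(mz) | mz <= 0][1]))
  }
  prot <- protonation_adduct(polarity)
  neutral <- neutral_mass(mz, prot)
  query_ref <- as.character(seq_along(mz))
  searched <- .search_all_sources(sources, neutral, query_ref, tol_ppm)
  hits <- fill_identifiers(searched$hits, xref)
  ids <- .merge_by(dplyr::rename(hits, query_id = "query_ref"), "query_id")
  queries <- tibble::tibble(
    query_id = query_ref, input_mz = mz, neutral_mass = neutral,
    n_identifications = vapply(query_ref, function(q) {
      sum(ids$query_id == q)
    }, integer(1), USE.NAMES = FALSE)
  )
  .new_mz_id(
    queries, ids,
    per_source = if (keep_per_source) searched$per_source else NULL,
    params = list(input = "mz_list", polarity = polarity, tol_ppm = tol_ppm,
                  sources = names(sources))
  )
}

#' Identify peaks from a CAMERA-style annotated table
#'
#' The annotation file is parsed, ions deriving from the same compound are
#' assembled into annotation groups (a peak with conflicting annotations
#' joins every group that claims it), each group's monoisotopic
#' (de)protonated query m/z is computed, the query is searched / filled /
#' merged exactly as in [run_mz_list()], and finally the per-group results
#' are recombined so each input peak appears once with the union of its
#' groups' identifications.
#'
#' @param path Path to the peak table (TSV/CSV/xlsx) or a data frame.
#' @inheritParams run_mz_list
#' @return An `mz_id` result object keyed by peak; `$groups` holds the
#'   per-group neutral masses and query m/z values.
#' @export
run_camera <- function(path, polarity = c("positive", "negative"), sources,
                       tol_ppm = 10, xref = NULL, keep_per_source = TRUE) {
  polarity <- match.arg(polarity)
  sources <- .check_sources(sources)
  peaks <- parse_camera(path, polarity)
  membership <- build_groups(peaks, polarity)
  groups <- group_query_mz(membership, polarity)
  searched <- .search_all_sources(sources, groups$neutral_mass,
                                  groups$group_id, tol_ppm)
  hits <- fill_identifiers(searched$hits, xref)
  group_results <- .merge_by(dplyr::rename(hits, group_id = "query_ref"),
                             "group_id")
  per_peak <- recombine(group_results, membership)
  ids <- dplyr::mutate(
    per_peak[!is.na(per_peak$merge_key), ],
    query_id = as.character(.data$peak_id), .before = 1
  )
  ids$peak_id <- NULL
  ids$mz <- NULL
  peak_tbl <- dplyr::summarise(
    dplyr::group_by(membership, .data$peak_id),
    input_mz = .data$mz[1],
    group_ids = paste(sort(unique(.data$group_id), method = "radix"),
                      collapse = ";"),
    .groups = "drop"
  )
  queries <- tibble::tibble(
    query_id = as.character(peak_tbl$peak_id),
    input_mz = peak_tbl$input_mz,
    group_ids = peak_tbl$group_ids,
    n_identifications = vapply(as.character(peak_tbl$peak_id), function(q) {
      sum(ids$query_id == q)
    }, integer(1), USE.NAMES = FALSE)
  )
  .new_mz_id(
    queries, ids,
    per_source = if (keep_per_source) searched$per_source else NULL,
    groups = groups, membership = membership,
    params = list(input = "camera", polarity = polarity, tol_ppm = tol_ppm,
                  sources = names(sources))
  )
}
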