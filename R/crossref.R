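# Identifier cross-referencing: bundles of chemical identifiers built by
# transitive closure over shared ids, used to fill missing fields on hits
# from sources with incomplete identifier coverage.

.XREF_KEY_TYPES <- c("hmdb_id", "kegg_id", "pubchem_cid", "native_id")
.BUNDLE_SINGLE <- c("kegg_id", "pubchem_cid", "pubchem_sid", "inchi")

.empty_bundle <- function() {
  list(
    kegg_id = character(), pubchem_cid = character(), pubchem_sid = character(),
    inchi = character(), inchi_key = character(), hmdb_ids = character(),
    native_id = character()
  )
}

.bundle_is_empty <- function(b) all(lengths(b) == 0)

.bundle_keys <- function(b) {
  c(
    if (length(b$kegg_id)) paste0("kegg:", b$kegg_id),
    if (length(b$pubchem_cid)) paste0("cid:", b$pubchem_cid),
    if (length(b$hmdb_ids)) paste0("hmdb:", b$hmdb_ids),
    if (length(b$native_id)) paste0("native:", b$native_id)
  )
}

.bundle_serialize <- function(b) {
  paste(vapply(b[sort(names(b))], function(v) paste(sort(v), collapse = ","),
               character(1)), collapse = "|")
}

# NULL when the merge would conflict; otherwise the merged bundle. Keys that
# differ only in the InChIKey stereo suffix (same 14-char skeleton) merge.
.bundle_merge <- function(a, b) {
  for (f in .BUNDLE_SINGLE) {
    if (length(a[[f]]) && length(b[[f]]) && !setequal(a[[f]], b[[f]])) {
      return(list(conflict = f, values = sort(unique(c(a[[f]], b[[f]])))))
    }
  }
  if (length(a$inchi_key) && length(b$inchi_key)) {
    sk <- unique(substr(c(a$inchi_key, b$inchi_key), 1, 14))
    if (length(sk) > 1) {
      return(list(conflict = "inchi_key",
                  values = sort(unique(c(a$inchi_key, b$inchi_key)))))
    }
  }
  merged <- .empty_bundle()
  for (f in names(merged)) merged[[f]] <- sort(unique(c(a[[f]], b[[f]])))
  merged
}

.record_bundle <- function(source_db, native_id, kegg_id, pubchem_cid,
                           pubchem_sid, hmdb_ids, inchi, inchi_key) {
  b <- .empty_bundle()
  take <- function(x) if (length(x) == 1 && !is.na(x)) x else character()
  b$kegg_id <- take(kegg_id)
  b$pubchem_cid <- take(pubchem_cid)
  b$pubchem_sid <- take(pubchem_sid)
  b$inchi <- take(inchi)
  b$inchi_key <- take(inchi_key)
  b$hmdb_ids <- .split_multi(hmdb_ids)
  b$native_id <- paste0(source_db, ":", native_id)
  b
}

#' Build a cross-reference index from records and an optional mapping table
#'
#' Every identifier carried by any record (or mapping row) keys a bundle of
#' all identifiers known for that compound; bundles are formed by transitive
#' closure over shared identifiers. Two bundles that share an identifier but
#' disagree on a single-valued field (KEGG id, PubChem CID/SID, InChI, or the
#' InChIKey skeleton) are never merged silently: the conflict is recorded and
#' both bundles are retained. InChIKeys differing only in the stereochemistry
#' suffix do not block a merge; the bundle keeps all full keys.
#'
#' Closure is computed by repeated pairwise merging to a fixed point in a
#' canonical order, so the result does not depend on input row order.
#'
#' @param records Record tibble ([load_backend()] output, any number of
#'   sources bound together), or `NULL`.
#' @param extra Optional mapping tibble or TSV path with columns `key_type`
#'   (`hmdb_id`, `kegg_id`, `pubchem_cid`, `native_id` — the latter as
#'   `SOURCE:id`), `key_value`, `field` (any identifier field), `value`.
#' @return An `mz_xref` object: bundles, a key lookup map, and a tibble of
#'   recorded conflicts.
#' @export
build_crossref <- function(records = NULL, extra = NULL) {
  bundles <- list()
  if (!is.null(records) && nrow(records) > 0) {
    bundles <- purrr::pmap(
      records[c("source_db", "native_id", "kegg_id", "pubchem_cid",
                "pubchem_sid", "hmdb_ids", "inchi", "inchi_key")],
      .record_bundle
    )
  }
  if (!is.null(extra)) {
    if (is.character(extra)) {
      extra <- readr::read_tsv(
        extra, col_types = readr::cols(.default = readr::col_character()),
        na = character(), progress = FALSE
      )
    }
    need <- c("key_type", "key_value", "field", "value")
    if (!all(need %in% names(extra))) {
      rlang::abort(paste0("mapping table lacks column(s): ",
                          paste(setdiff(need, names(extra)), collapse = ", ")))
    }
    bad <- !extra$key_type %in% .XREF_KEY_TYPES
    if (any(bad)) {
      rlang::abort(paste0("unknown key_type in mapping table: ",
                          unique(extra$key_type[bad])[1]))
    }
    map_bundles <- purrr::pmap(
      extra[need],
      function(key_type, key_value, field, value) {
        b <- .empty_bundle()
        slot <- if (key_type == "hmdb_id") "hmdb_ids" else key_type
        b[[slot]] <- key_value
        if (!field %in% names(b)) {
          rlang::abort(paste0("unknown field in mapping table: ", field))
        }
        if (field == "inchi_key") value <- .normalize_inchi_key(value, "mapping row")
        b[[field]] <- unique(c(b[[field]], value[!is.na(value)]))
        b
      }
    )
    bundles <- c(bundles, map_bundles)
  }

  bundles <- bundles[!vapply(bundles, .bundle_is_empty, logical(1))]
  conflicts <- list()

  # Key-sharing components (ignoring conflicts), via union-find; merging can
  # only happen inside a component, so each is closed independently.
  n <- length(bundles)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key_of <- lapply(bundles, .bundle_keys)
  key_groups <- split(
    rep(seq_len(n), lengths(key_of)),
    unlist(key_of, use.names = FALSE)
  )
  for (idx in key_groups) {
    if (length(idx) > 1) {
      r <- find(idx[1])
      for (j in idx[-1]) parent[find(j)] <- r
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  # Within a component, repeatedly merge the first compatible key-sharing
  # pair in canonical (sorted-serialization) order until no merge is
  # possible; refused merges of the final bundles are the reported
  # conflicts. The canonical order makes the outcome input-order-invariant.
  close_component <- function(bs) {
    repeat {
      bs <- bs[order(vapply(bs, .bundle_serialize, character(1)),
                     method = "radix")]
      k <- length(bs)
      if (k < 2) break
      merged <- FALSE
      for (i in seq_len(k - 1)) {
        for (j in seq((i + 1), k)) {
          if (!length(intersect(.bundle_keys(bs[[i]]), .bundle_keys(bs[[j]])))) next
          res <- .bundle_merge(bs[[i]], bs[[j]])
          if (is.null(res$conflict)) {
            bs[[i]] <- res
            bs[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    # record conflicts among the surviving bundles
    k <- length(bs)
    if (k >= 2) {
      for (i in seq_len(k - 1)) {
        for (j in seq((i + 1), k)) {
          shared <- intersect(.bundle_keys(bs[[i]]), .bundle_keys(bs[[j]]))
          if (!length(shared)) next
          res <- .bundle_merge(bs[[i]], bs[[j]])
          if (!is.null(res$conflict)) {
            conflicts[[length(conflicts) + 1]] <<- tibble::tibble(
              key = shared[1], field = res$conflict,
              values = paste(res$values, collapse = ";")
            )
          }
        }
      }
    }
    bs
  }
  bundles <- unname(unlist(
    lapply(split(seq_len(n), comp), function(ix) close_component(bundles[ix])),
    recursive = FALSE
  ))
  bundles <- bundles[order(vapply(bundles, .bundle_serialize, character(1)),
                           method = "radix")]

  key_of <- lapply(bundles, .bundle_keys)
  key_map <- split(
    rep(seq_along(bundles), lengths(key_of)),
    unlist(key_of, use.names = FALSE)
  )
  conflicts <- if (length(conflicts)) {
    dplyr::distinct(dplyr::bind_rows(conflicts))
  } else {
    tibble::tibble(key = character(), field = character(), values = character())
  }
  structure(
    list(bundles = bundles, key_map = key_map, conflicts = conflicts),
    class = "mz_xref"
  )
}

#' @export
print.mz_xref <- function(x, ...) {
  cat("<mz_xref> ", length(x$bundles), " identifier bundle(s), ",
      length(x$key_map), " key(s), ", nrow(x$conflicts),
      " recorded conflict(s)\n", sep = "")
  invisible(x)
}

#' Look up the identifier bundles reachable from a set of keys
#'
#' @param xref An `mz_xref` from [build_crossref()].
#' @param keys Namespaced keys (`kegg:`, `cid:`, `hmdb:`, `native:` prefixes).
#' @return Integer vector of bundle indices (may be empty).
#' @keywords internal
xref_lookup <- function(xref, keys) {
  sort(unique(unlist(xref$key_map[keys], use.names = FALSE)))
}

.hit_keys <- function(source_db, native_id, kegg_id, pubchem_cid, hmdb_ids) {
  c(
    if (!is.na(kegg_id)) paste0("kegg:", kegg_id),
    if (!is.na(pubchem_cid)) paste0("cid:", pubchem_cid),
    paste0("hmdb:", .split_multi(hmdb_ids)),
    paste0("native:", source_db, ":", native_id)
  )
}

#' Fill missing identifiers on search hits by cross-referencing
#'
#' For each hit, every missing identifier field that any of its present
#' identifiers resolves in the index is filled in; present fields are never
#' overwritten. When different bundles offer different values for the same
#' field the field is left missing and the conflict is logged — except for
#' InChIKeys that share the 14-character skeleton (stereoisomer-level
#' ambiguity), where the lexicographically smallest key is taken because
#' downstream merging only consumes the skeleton.
#'
#' @param hits Hit tibble from [search_source()] (or any record tibble).
#' @param xref An `mz_xref` from [build_crossref()], or `NULL` (no-op).
#' @return `hits` with missing fields filled; unresolved conflicts are
#'   attached as the `"xref_conflicts"` attribute.
#' @export
fill_identifiers <- function(hits, xref = NULL) {
  if (is.null(xref) || nrow(hits) == 0) return(hits)
  stopifnot(inherits(xref, "mz_xref"))
  conflicts <- list()
  for (i in seq_len(nrow(hits))) {
    keys <- .hit_keys(hits$source_db[i], hits$native_id[i], hits$kegg_id[i],
                      hits$pubchem_cid[i], hits$hmdb_ids[i])
    idx <- xref_lookup(xref, keys)
    if (!length(idx)) next
    bs <- xref$bundles[idx]
    cand <- function(f) sort(unique(unlist(lapply(bs, `[[`, f), use.names = FALSE)))
    for (f in .BUNDLE_SINGLE) {
      if (!is.na(hits[[f]][i])) next
      v <- cand(f)
      if (length(v) == 1) {
        hits[[f]][i] <- v
      } else if (length(v) > 1) {
        conflicts[[length(conflicts) + 1]] <- tibble::tibble(
          native_id = hits$native_id[i], field = f,
          values = paste(v, collapse = ";")
        )
      }
    }
    if (is.na(hits$inchi_key[i])) {
      v <- cand("inchi_key")
      if (length(v) >= 1) {
        if (length(unique(substr(v, 1, 14))) == 1) {
          hits$inchi_key[i] <- v[1] # sorted: lexicographically smallest
        } else {
          conflicts[[length(conflicts) + 1]] <- tibble::tibble(
            native_id = hits$native_id[i], field = "inchi_key",
            values = paste(v, collapse = ";")
          )
        }
      }
    }
    if (is.na(hits$hmdb_ids[i])) {
      v <- cand("hmdb_ids")
      if (length(v)) hits$hmdb_ids[i] <- paste(v, collapse = ";")
    }
  }
  if (length(conflicts)) {
    conflicts <- dplyr::distinct(dplyr::bind_rows(conflicts))
    rlang::inform(paste0(
      "cross-referencing left ", nrow(conflicts),
      " field(s) unfilled due to conflicting mapped values"
    ))
    attr(hits, "xref_conflicts") <- conflicts
  }
  hits
}
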