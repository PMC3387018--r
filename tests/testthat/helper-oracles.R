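# Shared helpers: independent oracles and compact fixture constructors.

# Atomic / particle monoisotopic masses for the element-summation oracle
# (most abundant isotopes).
EM <- list(
  H = 1.00782503207, C12 = 12, C13 = 13.0033548378, O = 15.99491461956,
  Na = 22.98976928, K = 38.96370649, e = 0.000548579909
)

# Brute-force linear-scan search oracle: indices of records matching the
# query within tol ppm of the record (reference) mass.
brute_search <- function(masses, query, tol_ppm) {
  which(abs(query - masses) / masses <= tol_ppm * 1e-6)
}

# Minimal record tibble with sensible defaults for engine tests.
make_record <- function(native_id, mass, source_db = "OTHER", name = native_id,
                        kegg_id = NA, pubchem_cid = NA, pubchem_sid = NA,
                        hmdb_ids = NA, inchi = NA, inchi_key = NA) {
  tibble::tibble(
    source_db = source_db, native_id = native_id, name = name,
    monoisotopic_mass = mass, kegg_id = as.character(kegg_id),
    pubchem_cid = as.character(pubchem_cid),
    pubchem_sid = as.character(pubchem_sid),
    hmdb_ids = as.character(hmdb_ids), inchi = as.character(inchi),
    inchi_key = as.character(inchi_key)
  )
}

# Turn records into hits at zero ppm error for merge tests.
as_hits <- function(records, ppm_error = 0) {
  dplyr::mutate(records,
    query_ref = "1",
    query_neutral_mass = monoisotopic_mass,
    ppm_error = ppm_error
  )
}

# Write a small backend TSV from raw cell values (masses given as strings so
# malformed cells can be planted).
write_raw_backend <- function(path, rows) {
  header <- c("native_id", "name", "monoisotopic_mass", "kegg_id",
              "pubchem_cid", "pubchem_sid", "hmdb_ids", "inchi", "inchi_key")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(r, collapse = "\t"), character(1)))
  writeLines(lines, path)
  path
}

# Brute-force crossref closure oracle: naive repeated pairwise merging of
# identifier bundles in canonical order, refusing single-valued conflicts
# (same rule as the package, independently and quadratically implemented).
brute_crossref_bundles <- function(records) {
  bundle_of <- function(i) {
    r <- records[i, ]
    b <- list(
      kegg_id = if (!is.na(r$kegg_id)) r$kegg_id else character(),
      pubchem_cid = if (!is.na(r$pubchem_cid)) r$pubchem_cid else character(),
      pubchem_sid = if (!is.na(r$pubchem_sid)) r$pubchem_sid else character(),
      inchi = if (!is.na(r$inchi)) r$inchi else character(),
      inchi_key = if (!is.na(r$inchi_key)) r$inchi_key else character(),
      hmdb_ids = if (!is.na(r$hmdb_ids)) {
        strsplit(r$hmdb_ids, ";", fixed = TRUE)[[1]]
      } else character(),
      native_id = paste0(r$source_db, ":", r$native_id)
    )
    b
  }
  keys <- function(b) {
    # recycle0: a missing field must yield no key, not a bare "cid:" stub
    c(paste0("kegg:", b$kegg_id, recycle0 = TRUE),
      paste0("cid:", b$pubchem_cid, recycle0 = TRUE),
      paste0("hmdb:", b$hmdb_ids, recycle0 = TRUE),
      paste0("native:", b$native_id, recycle0 = TRUE))
  }
  compatible <- function(a, b) {
    for (f in c("kegg_id", "pubchem_cid", "pubchem_sid", "inchi")) {
      if (length(a[[f]]) && length(b[[f]]) && !setequal(a[[f]], b[[f]])) {
        return(FALSE)
      }
    }
    if (length(a$inchi_key) && length(b$inchi_key) &&
        length(unique(substr(c(a$inchi_key, b$inchi_key), 1, 14))) > 1) {
      return(FALSE)
    }
    TRUE
  }
  ser <- function(b) {
    paste(vapply(b[sort(names(b))], function(v) paste(sort(v), collapse = ","),
                 character(1)), collapse = "|")
  }
  bundles <- lapply(seq_len(nrow(records)), bundle_of)
  repeat {
    bundles <- bundles[order(vapply(bundles, ser, character(1)),
                             method = "radix")]
    merged <- FALSE
    for (i in seq_along(bundles)) {
      if (merged) break
      for (j in seq_along(bundles)) {
        if (j <= i) next
        if (length(intersect(keys(bundles[[i]]), keys(bundles[[j]]))) &&
            compatible(bundles[[i]], bundles[[j]])) {
          for (f in names(bundles[[i]])) {
            bundles[[i]][[f]] <- sort(unique(c(bundles[[i]][[f]],
                                               bundles[[j]][[f]])))
          }
          bundles[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  sort(vapply(bundles, ser, character(1)), method = "radix")
}

xref_bundle_serials <- function(xref) {
  ser <- function(b) {
    paste(vapply(b[sort(names(b))], function(v) paste(sort(v), collapse = ","),
                 character(1)), collapse = "|")
  }
  sort(vapply(xref$bundles, ser, character(1)), method = "radix")
}

# Worked-example sources shipped with the package.
load_worked_example <- function() {
  dir <- system.file("extdata", "worked_example", package = "mzident")
  files <- c(HMDB = "hmdb.tsv", MMCD = "mmcd.tsv", METLIN = "metlin.tsv",
             LIPIDMAPS = "lipidmaps.tsv")
  sources <- purrr::imap(files, function(f, p) {
    load_backend(file.path(dir, f), p)
  })
  list(dir = dir, sources = sources,
       xref = build_crossref(dplyr::bind_rows(sources),
                             extra = file.path(dir, "xref.tsv")))
}

# Random valid ion annotations for round-trip properties.
random_annotations <- function(n) {
  pol <- sample(c("positive", "negative"), n, replace = TRUE,
                prob = c(0.8, 0.2))
  adduct <- ifelse(pol == "negative", "[M-H]-",
                   sample(adducts("positive"), n, replace = TRUE))
  charge <- ifelse(adduct == "[M+H]+" & stats::runif(n) < 0.3, 2L, 1L)
  iso <- ifelse(adduct %in% c("[M+H]+", "[M-H]-"),
                sample(0:4, n, replace = TRUE), 0L)
  tibble::tibble(adduct = adduct, charge = charge, isotope_order = iso)
}
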