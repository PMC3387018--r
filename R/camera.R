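# Parsing of CAMERA-style annotated peak tables: adduct/isotope grammar,
# annotation-group assembly (with conflicting-annotation splitting), group
# neutral masses, and recombination of split peaks.

.ADDUCT_TOKEN_RE <- "\\[[^\\]]*\\][0-9]*[+-]"
.ISOTOPE_RE <- "^\\[([0-9]+)\\]\\[M(\\+([1-4]))?\\]([0-9]?)([+-])$"

# Parse one adduct cell into a tibble of (adduct, charge, isotope_order)
# hypotheses; NULL when the cell is blank, NA when any token is unparseable.
.parse_adduct_cell <- function(cell, polarity) {
  if (is.na(cell) || trimws(cell) == "") return(NULL)
  tokens <- unlist(stringr::str_extract_all(cell, .ADDUCT_TOKEN_RE))
  leftover <- stringr::str_replace_all(cell, .ADDUCT_TOKEN_RE, " ")
  leftover <- stringr::str_remove_all(leftover, "[0-9.\\s]+") # mass estimates
  if (length(tokens) == 0 || nchar(leftover) > 0) return(NA)
  if (!all(tokens %in% adducts(polarity))) return(NA)
  tibble::tibble(adduct = tokens, charge = 1L, isotope_order = 0L)
}

# Parse one isotope cell like "[12][M+1]+" or "[5][M]2+".
.parse_isotope_cell <- function(cell, polarity) {
  if (is.na(cell) || trimws(cell) == "") return(NULL)
  m <- stringr::str_match(trimws(cell), .ISOTOPE_RE)
  if (is.na(m[1, 1])) return(NA)
  sign <- m[1, 6]
  if ((polarity == "positive" && sign != "+") ||
      (polarity == "negative" && sign != "-")) {
    return(NA)
  }
  charge <- if (m[1, 5] == "") 1L else as.integer(m[1, 5])
  if (!charge %in% c(1L, 2L)) return(NA)
  if (charge == 2L && polarity == "negative") return(NA)
  iso <- if (is.na(m[1, 4])) 0L else as.integer(m[1, 4])
  tibble::tibble(
    adduct = protonation_adduct(polarity), charge = charge, isotope_order = iso
  )
}

.read_peak_table <- function(path) {
  if (is.data.frame(path)) return(tibble::as_tibble(path))
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      rlang::abort("reading spreadsheet peak tables requires the 'readxl' package")
    }
    out <- readxl::read_excel(path)
    out[] <- lapply(out, function(x) if (is.numeric(x)) x else as.character(x))
    return(tibble::as_tibble(out))
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
}

#' Parse a CAMERA-style annotated peak table
#'
#' Accepts TSV or CSV (sniffed from the header line) or xlsx, with at least
#' an `mz` column and optional `rt`, `isotopes`, `adduct` and `pcgroup`
#' columns (extra columns are ignored). An adduct cell may list several
#' hypotheses, each an adduct code optionally followed by a neutral-mass
#' estimate (e.g. `"[M+Na]+ 180.0634"`); an isotopes cell follows CAMERA's
#' `"[cluster][M+n]z+"` style. A `pcgroup` cell may carry several
#' `;`-separated labels aligned one-to-one with the adduct hypotheses (a
#' single label applies to all of them). Unparseable annotation cells raise a
#' warning and leave the peak unannotated; they never abort the run.
#'
#' @param path Path to the peak table, or a data frame.
#' @param polarity Ionization mode, `"positive"` or `"negative"`.
#' @return A tibble with one row per (peak, annotation hypothesis):
#'   `peak_id`, `mz`, `rt`, `annotated`, `adduct`, `charge`, `isotope_order`,
#'   `pcgroup`. Unannotated peaks contribute one row with `annotated = FALSE`.
#' @export
parse_camera <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  raw <- .read_peak_table(path)
  if (!"mz" %in% names(raw)) {
    rlang::abort("peak table lacks mandatory column: mz")
  }
  for (col in c("rt", "isotopes", "adduct", "pcgroup")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  mz <- suppressWarnings(as.numeric(raw$mz))
  if (any(is.na(mz) | mz <= 0)) {
    rlang::abort(paste0("non-positive or non-numeric mz at row ",
                        which(is.na(mz) | mz <= 0)[1]))
  }
  rt <- suppressWarnings(as.numeric(raw$rt))

  n_warn <- 0L
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ann <- NULL
    bad <- FALSE
    ad <- .parse_adduct_cell(as.character(raw$adduct[i]), polarity)
    iso <- .parse_isotope_cell(as.character(raw$isotopes[i]), polarity)
    if (identical(ad, NA) || identical(iso, NA)) {
      bad <- TRUE
    } else {
      groups_raw <- as.character(raw$pcgroup[i])
      labels <- if (is.na(groups_raw) || trimws(groups_raw) == "") {
        character()
      } else {
        trimws(unlist(strsplit(groups_raw, ";", fixed = TRUE)))
      }
      if (!is.null(ad)) {
        grp <- if (length(labels) == nrow(ad)) {
          labels
        } else if (length(labels) == 1) {
          rep(labels, nrow(ad))
        } else if (length(labels) == 0) {
          rep(NA_character_, nrow(ad))
        } else {
          bad <- TRUE
          NULL
        }
        if (!bad) ann <- dplyr::mutate(ad, pcgroup = grp)
      }
      if (!bad && !is.null(iso)) {
        iso$pcgroup <- if (length(labels) >= 1) labels[1] else NA_character_
        ann <- dplyr::bind_rows(ann, iso)
      }
    }
    if (bad) {
      n_warn <- n_warn + 1L
      ann <- NULL
    }
    base <- tibble::tibble(peak_id = i, mz = mz[i], rt = rt[i])
    rows[[i]] <- if (is.null(ann)) {
      dplyr::mutate(base,
        annotated = FALSE, adduct = NA_character_, charge = NA_integer_,
        isotope_order = NA_integer_, pcgroup = NA_character_
      )
    } else {
      dplyr::bind_cols(base[rep(1, nrow(ann)), ],
                       dplyr::mutate(ann, annotated = TRUE, .before = 1))
    }
  }
  if (n_warn > 0) {
    rlang::warn(paste0(
      n_warn, " peak(s) with unparseable adduct/isotope annotation treated as unannotated"
    ))
  }
  dplyr::bind_rows(rows)
}

#' Assemble annotation groups from parsed peaks
#'
#' One group per `pcgroup` label with at least one annotated member. A peak
#' carrying k conflicting (annotation, group) hypotheses appears in k groups
#' and is identified separately in each; it is put back together by
#' [recombine()]. Peaks without any usable annotation each form a singleton
#' group (labelled `p<peak_id>`) annotated as the monoisotopic
#' (de)protonated singly charged ion — the default assumption for bare m/z
#' values. Annotated peaks lacking a group label are likewise singletons.
#'
#' @param peaks Long tibble from [parse_camera()].
#' @param polarity Ionization mode.
#' @return Membership tibble: `group_id`, `peak_id`, `mz`, `adduct`,
#'   `charge`, `isotope_order`.
#' @export
build_groups <- function(peaks, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  prot <- protonation_adduct(polarity)
  out <- dplyr::mutate(
    peaks,
    adduct = dplyr::if_else(annotated, adduct, prot),
    charge = dplyr::if_else(annotated, charge, 1L),
    isotope_order = dplyr::if_else(annotated, isotope_order, 0L),
    group_id = dplyr::if_else(
      annotated & !is.na(pcgroup), pcgroup, paste0("p", peak_id)
    )
  )
  dplyr::arrange(
    out[c("group_id", "peak_id", "mz", "adduct", "charge", "isotope_order")],
    .data$group_id, .data$peak_id
  )
}

#' Representative neutral mass and query m/z of an annotation group
#'
#' The group's neutral monoisotopic mass is the median of the neutral masses
#' implied by its members' annotations (robust to one mis-annotated member);
#' the query m/z is that of its monoisotopic (de)protonated singly charged
#' ion, which is what gets searched against the record sources.
#'
#' @param members Membership rows of one group (columns `mz`, `adduct`,
#'   `charge`, `isotope_order`), or the full membership tibble from
#'   [build_groups()] — every group is then summarised.
#' @param polarity Ionization mode.
#' @return A tibble with `group_id` (when present), `n_members`,
#'   `neutral_mass` and `query_mz`.
#' @export
group_query_mz <- function(members, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(nrow(members) > 0)
  prot <- protonation_adduct(polarity)
  implied <- dplyr::mutate(
    members,
    .neutral = purrr::pmap_dbl(
      list(mz, adduct, charge, isotope_order),
      function(mz, adduct, charge, isotope_order) {
        neutral_mass(mz, adduct, charge, isotope_order)
      }
    )
  )
  grouping <- if ("group_id" %in% names(members)) "group_id" else character()
  out <- dplyr::summarise(
    dplyr::group_by(implied, dplyr::across(dplyr::all_of(grouping))),
    n_members = dplyr::n(),
    neutral_mass = stats::median(.neutral),
    .groups = "drop"
  )
  dplyr::mutate(out, query_mz = mz_of(neutral_mass, prot))
}

#' Recombine per-group identifications into per-peak identifications
#'
#' A peak split across several annotation groups (conflicting annotations)
#' is represented once in the output, with the deduplicated union of all its
#' groups' identifications; duplicates (same merge key) keep the entry with
#' the smallest absolute ppm error. Peaks whose groups produced no hits are
#' retained with an empty identification set, so peak count is conserved.
#'
#' @param group_results Identification tibble carrying a `group_id` column
#'   (one row per merged identification, e.g. [merge_hits()] output).
#' @param membership Membership tibble from [build_groups()].
#' @return Tibble with one row per (peak, identification); peaks without any
#'   identification contribute one row with an `NA` merge key.
#' @export
recombine <- function(group_results, membership) {
  peaks <- dplyr::distinct(membership[c("peak_id", "mz")])
  links <- dplyr::distinct(membership[c("peak_id", "group_id")])
  joined <- dplyr::inner_join(links, group_results, by = "group_id",
                              relationship = "many-to-many")
  if (nrow(joined) > 0) {
    joined <- dplyr::slice_min(
      dplyr::group_by(joined, .data$peak_id, .data$merge_key),
      abs(best_ppm_error), n = 1, with_ties = FALSE
    )
    joined <- dplyr::ungroup(joined)
  }
  out <- dplyr::left_join(peaks, joined, by = "peak_id")
  dplyr::arrange(out, .data$peak_id, abs(.data$best_ppm_error), .data$merge_key)
}
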