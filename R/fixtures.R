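# Seeded synthetic-data generators: record backends with per-source
# identifier missingness, a cross-reference table resolving a stated
# fraction of the gaps, and CAMERA-style peak tables with ground truth, so
# every stage of the pipeline is testable offline.

.rand_letters <- function(n, k) {
  m <- matrix(sample(LETTERS, n * k, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Synthetic InChIKeys: structurally valid (14 + 10 + 1 blocks) but random —
# the merge logic only consumes string structure.
.synth_key <- function(skeleton, n_suffix = length(skeleton)) {
  suffix <- paste0(.rand_letters(n_suffix, 8), "SA")
  paste0(skeleton, "-", suffix, "-N")
}

#' Generate synthetic metabolite record backends with ground truth
#'
#' Emulates a multi-source search universe: metabolite monoisotopic masses
#' uniform in 50-1000 Da; a configurable fraction of metabolites present in
#' 2-4 sources (same InChIKey skeleton everywhere); stereoisomer clusters
#' (same 14-character skeleton, distinct suffixes) at a stated rate;
#' per-source identifier missingness applied according to each source
#' profile; and a cross-reference mapping table that resolves a stated
#' fraction of the records whose source withholds InChI data (keyed by the
#' record's own native id). Mass collisions are possible by design so that
#' ambiguous-hit behaviour gets exercised. Identical seeds give byte-identical
#' files.
#'
#' @param n_metabolites Number of distinct metabolites (>= 1).
#' @param seed Integer seed (required; all randomness flows from it).
#' @param dir Directory to write the backend and mapping TSVs into.
#' @param profiles Named list of [source_profile()]s; default the four
#'   classical sources.
#' @param p_multi_source Fraction of metabolites present in 2-4 sources.
#' @param stereoisomer_rate Fraction of metabolites sharing the previous
#'   metabolite's skeleton (forming stereoisomer clusters).
#' @param xref_coverage Fraction of key-withheld records (e.g. the
#'   Metlin-style source) that the mapping table resolves.
#' @return List with `paths` (named backend files plus `xref`), `truth`
#'   (metabolite table: `met_id`, `monoisotopic_mass`, `skeleton`,
#'   `inchi_key`, `kegg_id`, `pubchem_cid`, `pubchem_sid`, `hmdb_id`),
#'   `membership` (per-record table with a `resolvable` flag), and the
#'   `profiles` used.
#' @export
generate_databases <- function(n_metabolites, seed, dir = tempfile("dbs"),
                               profiles = default_profiles(),
                               p_multi_source = 0.6,
                               stereoisomer_rate = 0.1,
                               xref_coverage = 0.8) {
  stopifnot(n_metabolites >= 1, length(profiles) >= 1)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_metabolites

  skeleton <- .rand_letters(n, 14)
  if (n > 1 && stereoisomer_rate > 0) {
    reuse <- which(stats::runif(n - 1) < stereoisomer_rate) + 1L
    for (i in reuse) skeleton[i] <- skeleton[i - 1L]
  }
  inchi_key <- .synth_key(skeleton)
  while (anyDuplicated(inchi_key)) { # same-cluster suffix collision
    dup <- duplicated(inchi_key)
    inchi_key[dup] <- .synth_key(skeleton[dup])
  }
  truth <- tibble::tibble(
    met_id = sprintf("MET%05d", seq_len(n)),
    monoisotopic_mass = round(stats::runif(n, 50, 1000), 5),
    skeleton = skeleton,
    inchi_key = inchi_key,
    inchi = paste0("InChI=1S/SYN", seq_len(n)),
    kegg_id = sprintf("C%05d", sample.int(99999, n)),
    pubchem_cid = as.character(sample.int(9e7, n)),
    pubchem_sid = as.character(sample.int(9e7, n) + 1e8),
    hmdb_id = sprintf("HMDB%05d", sample.int(99999, n)),
    name = paste0("Compound_", sprintf("%05d", seq_len(n)))
  )
  truth$name <- ifelse(
    stats::runif(n) < 0.3,
    paste0(truth$name, ";", truth$name, "_syn"),
    truth$name
  )

  src_names <- names(profiles)
  n_src <- ifelse(stats::runif(n) < p_multi_source,
                  sample(2:min(4, length(src_names)), n, replace = TRUE), 1L)
  n_src <- pmin(n_src, length(src_names))
  membership <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(met_id = truth$met_id[i],
                   source_db = sort(sample(src_names, n_src[i])))
  }))
  native_for <- function(source_db, k) {
    switch(source_db,
      HMDB = truth$hmdb_id[k],
      MMCD = sprintf("cq_%05d", k),
      METLIN = sprintf("%05d", 10000L + k),
      LIPIDMAPS = sprintf("LM%06d", 100000L + k),
      paste0(source_db, "_", sprintf("%05d", k))
    )
  }
  membership$native_id <- unname(mapply(
    native_for, membership$source_db, match(membership$met_id, truth$met_id)
  ))

  # Per-record identifier missingness per the source profile.
  recs <- dplyr::left_join(membership, truth, by = "met_id")
  recs$hmdb_ids <- recs$hmdb_id
  for (s in src_names) {
    prof <- profiles[[s]]
    rows <- which(recs$source_db == s)
    for (f in prof$fields_always_missing) recs[[f]][rows] <- NA_character_
    for (f in names(prof$fields_partially_missing)) {
      drop <- rows[stats::runif(length(rows)) < prof$fields_partially_missing[[f]]]
      recs[[f]][drop] <- NA_character_
    }
  }

  # Mapping rows resolving a stated fraction of the records whose source
  # withholds the InChIKey (and, for those records, the other gaps too).
  key_withheld <- vapply(recs$source_db, function(s) {
    "inchi_key" %in% profiles[[s]]$fields_always_missing
  }, logical(1))
  recs$resolvable <- FALSE
  cand <- which(key_withheld)
  if (length(cand)) {
    n_res <- round(xref_coverage * length(cand))
    recs$resolvable[sample(cand, n_res)] <- TRUE
  }
  xref_rows <- dplyr::bind_rows(lapply(which(recs$resolvable), function(i) {
    k <- match(recs$met_id[i], truth$met_id)
    fields <- c("inchi", "inchi_key", "kegg_id", "pubchem_cid", "pubchem_sid")
    fields <- fields[vapply(fields, function(f) is.na(recs[[f]][i]), logical(1))]
    tibble::tibble(
      key_type = "native_id",
      key_value = paste0(recs$source_db[i], ":", recs$native_id[i]),
      field = fields,
      value = vapply(fields, function(f) truth[[f]][k], character(1))
    )
  }))
  xref_path <- file.path(dir, "xref.tsv")
  if (is.null(xref_rows) || nrow(xref_rows) == 0) {
    xref_rows <- tibble::tibble(key_type = character(), key_value = character(),
                                field = character(), value = character())
  }
  readr::write_tsv(xref_rows, xref_path, progress = FALSE)

  paths <- c(vapply(src_names, function(s) {
    backend <- recs[recs$source_db == s, c("source_db", .BACKEND_COLS)]
    p <- file.path(dir, paste0(tolower(s), ".tsv"))
    write_backend(backend, p)
    p
  }, character(1)), xref = xref_path)

  list(
    paths = paths,
    truth = truth,
    membership = recs[c("met_id", "source_db", "native_id", "resolvable")],
    profiles = profiles
  )
}

#' Generate a CAMERA-style annotated peak table with ground truth
#'
#' Each annotation group is drawn from one metabolite of the supplied
#' database fixture; member m/z values are the exact ion m/z perturbed by at
#' most `ppm_jitter` ppm. Positive-mode species are drawn from `adduct_mix`
#' (which may include `"[M+2H]2+"` for doubly charged ions); members of the
#' protonated series may additionally carry an isotope annotation of order
#' 1-4. A stated fraction of peaks is given a second, conflicting annotation
#' pointing into another group; a stated fraction is written with blank
#' annotation cells. A peak is only stripped of its annotation when it is a
#' monoisotopic (de)protonated singly charged ion or its group keeps another
#' annotated member, so every generated group remains recoverable from the
#' file by construction (residual failures are mass collisions, which the
#' truth table exposes).
#'
#' @param db Database fixture from [generate_databases()].
#' @param n_groups Number of annotation groups (<= metabolites in `db`).
#' @param seed Integer seed.
#' @param path Output file path (TSV).
#' @param polarity Ionization mode; negative mode uses deprotonated ions
#'   only.
#' @param adduct_mix Named probabilities over ion species (positive mode).
#' @param size_probs Probabilities of group sizes 1..4; the default mean of
#'   about 1.5 ions per compound mirrors typical LC-MS annotation output.
#' @param p_isotope Probability that a protonated member is an isotope peak
#'   (order sampled from 1..4).
#' @param conflict_fraction Fraction of eligible peaks given a second,
#'   conflicting annotation.
#' @param unannotated_fraction Fraction of eligible peaks written without
#'   annotation cells.
#' @param ppm_jitter Maximum |mass error| applied to each m/z, in ppm.
#' @return List with `path`, `truth` (per-peak: `peak_id`, `met_id`,
#'   `group_id`, `adduct`, `charge`, `isotope_order`, `conflict_group`,
#'   `stripped`) and `groups` (per-group: `group_id`, `met_id`, true mass).
#' @export
generate_camera_file <- function(db, n_groups, seed,
                                 path = tempfile("camera", fileext = ".tsv"),
                                 polarity = c("positive", "negative"),
                                 adduct_mix = c(
                                   "[M+H]+" = 0.45, "[M+Na]+" = 0.2,
                                   "[M+K]+" = 0.1, "[M+H-H2O]+" = 0.1,
                                   "[M+2H]2+" = 0.15
                                 ),
                                 size_probs = c(0.55, 0.25, 0.12, 0.08),
                                 p_isotope = 0.25,
                                 conflict_fraction = 0.1,
                                 unannotated_fraction = 0.1,
                                 ppm_jitter = 2) {
  polarity <- match.arg(polarity)
  stopifnot(n_groups >= 1, n_groups <= nrow(db$truth), ppm_jitter >= 0,
            abs(sum(adduct_mix) - 1) < 1e-8)
  set.seed(seed)
  if (polarity == "negative") adduct_mix <- c("[M-H]-" = 1)
  prot <- protonation_adduct(polarity)

  mets <- db$truth[sample.int(nrow(db$truth), n_groups), ]
  groups <- tibble::tibble(
    group_id = as.character(seq_len(n_groups)),
    met_id = mets$met_id,
    monoisotopic_mass = mets$monoisotopic_mass,
    rt = round(stats::runif(n_groups, 60, 900), 1)
  )

  species <- names(adduct_mix)
  peaks <- dplyr::bind_rows(lapply(seq_len(n_groups), function(g) {
    size <- sample(seq_along(size_probs), 1, prob = size_probs)
    sp <- sample(species, size, replace = TRUE, prob = adduct_mix)
    adduct <- ifelse(sp == "[M+2H]2+", prot, sp)
    charge <- ifelse(sp == "[M+2H]2+", 2L, 1L)
    iso <- integer(size)
    protonated <- adduct == prot & charge == 1L
    iso[protonated] <- ifelse(stats::runif(sum(protonated)) < p_isotope,
                              sample(1:4, sum(protonated), replace = TRUE), 0L)
    tibble::tibble(
      group_id = groups$group_id[g], met_id = groups$met_id[g],
      adduct = adduct, charge = charge, isotope_order = iso,
      rt = round(groups$rt[g] + stats::runif(size, -2, 2), 1)
    )
  }))
  true_mass <- groups$monoisotopic_mass[match(peaks$group_id, groups$group_id)]
  exact_mz <- purrr::pmap_dbl(
    list(true_mass, peaks$adduct, peaks$charge, peaks$isotope_order), mz_of
  )
  jitter <- stats::runif(nrow(peaks), -ppm_jitter, ppm_jitter) * 1e-6
  peaks$mz <- round(exact_mz * (1 + jitter), 5)

  n_peaks <- nrow(peaks)

  peaks$stripped <- FALSE
  strip_cand <- sample.int(n_peaks)
  n_strip <- round(unannotated_fraction * n_peaks)
  ann_left <- table(peaks$group_id)
  for (i in strip_cand) {
    if (sum(peaks$stripped) >= n_strip) break
    g <- peaks$group_id[i]
    harmless <- peaks$adduct[i] == prot && peaks$charge[i] == 1L &&
      peaks$isotope_order[i] == 0L
    if (harmless || ann_left[[g]] > 1L) {
      peaks$stripped[i] <- TRUE
      ann_left[[g]] <- ann_left[[g]] - 1L
    }
  }

  # Conflicting second annotations: at most one per target group, and only
  # into groups keeping >= 2 genuinely annotated members, so the target's
  # median neutral mass stays pinned by its true members.
  peaks$conflict_group <- NA_character_
  peaks$conflict_adduct <- NA_character_
  targets <- names(which(ann_left >= 2L))
  eligible <- which(!peaks$stripped & peaks$charge == 1L &
                    peaks$isotope_order == 0L)
  n_conf <- min(round(conflict_fraction * n_peaks), length(eligible))
  if (n_conf > 0 && length(targets) > 0) {
    chosen <- sample(eligible, n_conf)
    for (i in chosen) {
      others <- setdiff(targets, peaks$group_id[i])
      alt <- setdiff(adducts(polarity), peaks$adduct[i])
      if (!length(others) || !length(alt)) next
      g2 <- if (length(others) == 1) others else sample(others, 1)
      peaks$conflict_group[i] <- g2
      targets <- setdiff(targets, g2)
      peaks$conflict_adduct[i] <- if (length(alt) == 1) alt else sample(alt, 1)
    }
  }

  est_neutral <- function(mz, adduct, charge, iso) {
    sprintf("%.4f", neutral_mass(mz, adduct, charge, iso))
  }
  cells <- purrr::pmap(
    peaks[c("mz", "adduct", "charge", "isotope_order", "group_id",
            "conflict_group", "conflict_adduct", "stripped")],
    function(mz, adduct, charge, isotope_order, group_id,
             conflict_group, conflict_adduct, stripped) {
      if (stripped) return(list(isotopes = "", adduct = "", pcgroup = ""))
      if (charge == 2L || isotope_order > 0L) {
        sign <- if (polarity == "positive") "+" else "-"
        iso_part <- if (isotope_order > 0L) paste0("+", isotope_order) else ""
        z_part <- if (charge == 2L) "2" else ""
        return(list(
          isotopes = paste0("[", group_id, "][M", iso_part, "]", z_part, sign),
          adduct = "", pcgroup = group_id
        ))
      }
      ad <- paste0(adduct, " ", est_neutral(mz, adduct, 1L, 0L))
      grp <- group_id
      if (!is.na(conflict_group) && !is.na(conflict_adduct)) {
        ad <- paste0(ad, " ", conflict_adduct, " ",
                     est_neutral(mz, conflict_adduct, 1L, 0L))
        grp <- paste0(grp, ";", conflict_group)
      }
      list(isotopes = "", adduct = ad, pcgroup = grp)
    }
  )
  out <- tibble::tibble(
    mz = sprintf("%.5f", peaks$mz),
    rt = sprintf("%.1f", peaks$rt),
    isotopes = vapply(cells, `[[`, character(1), "isotopes"),
    adduct = vapply(cells, `[[`, character(1), "adduct"),
    pcgroup = vapply(cells, `[[`, character(1), "pcgroup")
  )
  ord <- order(as.numeric(out$rt), out$mz, method = "radix")
  out <- out[ord, ]
  peaks <- peaks[ord, ]
  peaks$peak_id <- seq_len(n_peaks)
  readr::write_tsv(out, path, progress = FALSE)

  list(
    path = path,
    truth = peaks[c("peak_id", "met_id", "group_id", "mz", "adduct", "charge",
                    "isotope_order", "conflict_group", "stripped")],
    groups = groups
  )
}

#' Score recovery of ground truth by an identification run
#'
#' A peak counts as correctly identified when one of its merged
#' identifications contains a record of its true metabolite (matched through
#' the per-source native ids recorded in the database fixture). Group
#' recovery is the fraction of generated annotation groups with at least one
#' correctly identified member peak.
#'
#' @param result An `mz_id` result over the generated peak file.
#' @param camera_truth `truth` element from [generate_camera_file()].
#' @param db Database fixture from [generate_databases()].
#' @return List: `peak_correct` (logical per peak, named by peak id),
#'   `n_peaks_correct`, `group_recovery` (fraction of truth groups
#'   recovered).
#' @export
score_recovery <- function(result, camera_truth, db) {
  stopifnot(inherits(result, "mz_id"))
  native_keys <- dplyr::mutate(
    db$membership, key = paste0(source_db, ":", native_id)
  )
  truth_keys <- split(native_keys$key, native_keys$met_id)
  id_natives <- split(
    strsplit(result$identifications$native_ids, ";", fixed = TRUE),
    result$identifications$query_id
  )
  peak_correct <- vapply(seq_len(nrow(camera_truth)), function(i) {
    pid <- as.character(camera_truth$peak_id[i])
    found <- unlist(id_natives[[pid]], use.names = FALSE)
    any(found %in% truth_keys[[camera_truth$met_id[i]]])
  }, logical(1))
  names(peak_correct) <- as.character(camera_truth$peak_id)
  by_group <- tapply(peak_correct, camera_truth$group_id, any)
  list(
    peak_correct = peak_correct,
    n_peaks_correct = sum(peak_correct),
    group_recovery = mean(by_group)
  )
}
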