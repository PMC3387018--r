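# Synthetic-data generators: determinism, profile missingness, planted
# structure, and ground-truth recoverability.

test_that("database generation is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a <- generate_databases(60, seed = 1, dir = d1)
  b <- generate_databases(60, seed = 1, dir = d2)
  for (nm in names(a$paths)) {
    expect_identical(readLines(a$paths[[nm]]), readLines(b$paths[[nm]]),
                     label = nm)
  }
  expect_true(sum(vapply(a$paths[names(a$paths) != "xref"], function(p) {
    nrow(suppressWarnings(load_backend(p)))
  }, numeric(1))) >= 60)
})

test_that("the Metlin-profile backend has entirely empty InChI columns", {
  db <- generate_databases(80, seed = 2, dir = withr::local_tempdir())
  metlin <- load_backend(db$paths[["METLIN"]], "METLIN")
  expect_gt(nrow(metlin), 0)
  expect_true(all(is.na(metlin$inchi)))
  expect_true(all(is.na(metlin$inchi_key)))
})

test_that("stereoisomer rate zero makes all skeletons distinct", {
  db <- generate_databases(120, seed = 3, dir = withr::local_tempdir(),
                           stereoisomer_rate = 0)
  expect_equal(anyDuplicated(db$truth$skeleton), 0)
  db2 <- generate_databases(200, seed = 4, dir = withr::local_tempdir(),
                            stereoisomer_rate = 0.3)
  expect_gt(sum(duplicated(db2$truth$skeleton)), 0)
  # full keys stay unique even within skeleton clusters
  expect_equal(anyDuplicated(db2$truth$inchi_key), 0)
})

test_that("peak-table generation is deterministic and honours the adduct mix", {
  db <- generate_databases(100, seed = 5, dir = withr::local_tempdir())
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  c1 <- generate_camera_file(db, 60, seed = 7, path = p1)
  c2 <- generate_camera_file(db, 60, seed = 7, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(nrow(c1$truth), nrow(c2$truth))

  # degenerate mix at zero jitter: every m/z is the exact protonated ion
  p3 <- withr::local_tempfile(fileext = ".tsv")
  c3 <- generate_camera_file(
    db, 40, seed = 8, path = p3, adduct_mix = c("[M+H]+" = 1),
    p_isotope = 0, conflict_fraction = 0, unannotated_fraction = 0,
    ppm_jitter = 0
  )
  truth_mass <- db$truth$monoisotopic_mass[match(c3$truth$met_id, db$truth$met_id)]
  expect_equal(c3$truth$mz, round(mz_of(truth_mass, "[M+H]+"), 5),
               tolerance = 1e-9)
})

test_that("the stated conflict fraction of peaks carries two annotations", {
  db <- generate_databases(150, seed = 6, dir = withr::local_tempdir())
  cam <- generate_camera_file(db, 100, seed = 9,
                              path = withr::local_tempfile(fileext = ".tsv"),
                              conflict_fraction = 0.1,
                              unannotated_fraction = 0)
  n <- nrow(cam$truth)
  n_conf <- sum(!is.na(cam$truth$conflict_group))
  expect_gt(n_conf, 0)
  expect_lt(abs(n_conf - 0.1 * n), 0.05 * n + 3)
  p <- suppressWarnings(parse_camera(cam$path, "positive"))
  two_ann <- sum(table(p$peak_id[p$annotated]) == 2)
  expect_equal(two_ann, n_conf)
})

test_that("generated groups recover their metabolite at low jitter", {
  db <- generate_databases(100, seed = 10, dir = withr::local_tempdir())
  srcs <- purrr::imap(db$paths[setdiff(names(db$paths), "xref")],
                      function(p, nm) load_backend(p, nm))
  cam <- generate_camera_file(db, 40, seed = 11,
                              path = withr::local_tempfile(fileext = ".tsv"))
  res <- run_camera(cam$path, "positive", srcs, tol_ppm = 10)
  sc <- score_recovery(res, cam$truth, db)
  expect_gte(sc$group_recovery, 0.99)
})

test_that("suppressing annotations only moves masses of non-protonated peaks", {
  db <- generate_databases(100, seed = 12, dir = withr::local_tempdir())
  cam <- generate_camera_file(db, 40, seed = 13,
                              path = withr::local_tempfile(fileext = ".tsv"),
                              conflict_fraction = 0)
  peaks <- parse_camera(cam$path, "positive")
  membership <- build_groups(peaks, "positive")
  groups <- group_query_mz(membership, "positive")
  g_of_peak <- membership$group_id[match(cam$truth$peak_id, membership$peak_id)]
  annotated_neutral <- groups$neutral_mass[match(g_of_peak, groups$group_id)]
  bare_neutral <- neutral_mass(cam$truth$mz, "[M+H]+")
  rel <- abs(bare_neutral - annotated_neutral) / annotated_neutral * 1e6
  protonated <- cam$truth$adduct == "[M+H]+" & cam$truth$charge == 1L &
    cam$truth$isotope_order == 0L
  kept <- !cam$truth$stripped # stripped peaks are protonated singletons anyway
  expect_true(all(rel[protonated] < 10))
  expect_true(all(rel[!protonated & kept] > 100))
})
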