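# Tolerance search, skeleton merging, and the two end-to-end entry points.

test_that("search retrieves exactly the records within tolerance, ordered by |ppm|", {
  recs <- make_record(c("a", "b", "c"), c(625.3470, 625.3480, 625.3600))
  hits <- search_source(recs, 625.34738, tol_ppm = 10)
  expect_equal(hits$native_id, c("a", "b"))
  expect_true(all(abs(hits$ppm_error) <= 10))
  expect_true(all(diff(abs(hits$ppm_error)) >= 0))

  exact <- search_source(recs, 625.3480, tol_ppm = 0)
  expect_equal(exact$native_id, "b")
  expect_equal(exact$ppm_error, 0)

  empty <- search_source(recs[0, ], 625.34738, tol_ppm = 10)
  expect_equal(nrow(empty), 0)
})

test_that("indexed search equals a brute-force linear scan on random fixtures", {
  set.seed(11)
  masses <- stats::runif(800, 50, 1000)
  recs <- make_record(sprintf("r%04d", seq_along(masses)), masses)
  queries <- c(stats::runif(100, 50, 1000),
               sample(masses, 100) * (1 + stats::runif(100, -25, 25) * 1e-6))
  for (tol in c(5, 10, 20)) {
    hits <- search_source(recs, queries, tol_ppm = tol)
    got <- split(hits$native_id, hits$query_ref)
    for (q in seq_along(queries)) {
      want <- sort(recs$native_id[brute_search(masses, queries[q], tol)])
      have <- got[[as.character(q)]]
      expect_identical(sort(if (is.null(have)) character() else have), want)
    }
  }
})

test_that("skeleton merging collapses stereoisomers and keeps structural isomers apart", {
  sk1 <- "AAAAAAAAAAAAAA"
  sk2 <- "CCCCCCCCCCCCCC"
  hits <- as_hits(dplyr::bind_rows(
    make_record("h1", 625.34738, "HMDB", hmdb_ids = "HMDB02618",
                inchi_key = paste0(sk1, "-XXXXXXXXSA-N")),
    make_record("m1", 625.34738, "MMCD", hmdb_ids = "HMDB02618;HMDB02579",
                inchi_key = paste0(sk1, "-YYYYYYYYSA-N")),
    make_record("t1", 625.34738, "METLIN",
                inchi_key = paste0(sk1, "-XXXXXXXXSA-N")),
    make_record("l1", 625.34738, "LIPIDMAPS",
                inchi_key = paste0(sk1, "-YYYYYYYYSA-N")),
    make_record("z1", 625.34740, "HMDB",
                inchi_key = paste0(sk2, "-XXXXXXXXSA-N"))
  ))
  m <- merge_hits(hits)
  expect_equal(nrow(m), 2)
  e1 <- m[m$merge_key == sk1, ]
  expect_equal(e1$stereoisomer_count, 2L)
  expect_equal(e1$n_hits, 4L)
  expect_equal(e1$source_dbs, "HMDB;MMCD;METLIN;LIPIDMAPS")
  expect_equal(e1$inchi_key, paste0(sk1, "-XXXXXXXXSA-N")) # smallest full key
  expect_equal(m[m$merge_key == sk2, ]$stereoisomer_count, 1L)
})

test_that("keyless hits stay source-local, one entry each", {
  hits <- as_hits(dplyr::bind_rows(
    make_record("k1", 100, "METLIN"),
    make_record("k2", 100, "METLIN"),
    make_record("k3", 100, "METLIN")
  ))
  m <- merge_hits(hits)
  expect_equal(nrow(m), 3)
  expect_setequal(m$merge_key, paste0("METLIN:", c("k1", "k2", "k3")))
  expect_true(all(m$stereoisomer_count == 1L))
})

test_that("merging partitions the hits and is order-invariant and local", {
  set.seed(5)
  sks <- replicate(6, paste(sample(LETTERS, 14, TRUE), collapse = ""))
  hits <- as_hits(dplyr::bind_rows(lapply(1:40, function(i) {
    keyed <- stats::runif(1) < 0.8
    make_record(
      paste0("n", i), 300 + i * 1e-4,
      source_db = sample(c("HMDB", "MMCD", "METLIN", "LIPIDMAPS"), 1),
      inchi_key = if (keyed) {
        paste0(sample(sks, 1), "-", paste(sample(LETTERS, 8, TRUE), collapse = ""), "SA-N")
      } else NA
    )
  })), ppm_error = stats::runif(40, -10, 10))
  m <- merge_hits(hits)
  expect_equal(sum(m$n_hits), nrow(hits))               # partition: counts
  all_natives <- unlist(strsplit(m$native_ids, ";"))
  expect_equal(sort(all_natives),
               sort(paste0(hits$source_db, ":", hits$native_id)))
  perm <- hits[sample.int(nrow(hits)), ]
  expect_equal(merge_hits(perm), m)                     # order-invariance
  by_key <- split(seq_len(nrow(hits)),
                  ifelse(is.na(hits$inchi_key),
                         paste0(hits$source_db, ":", hits$native_id),
                         substr(hits$inchi_key, 1, 14)))
  local <- dplyr::bind_rows(lapply(by_key, function(ix) merge_hits(hits[ix, ])))
  local <- local[order(abs(local$best_ppm_error), local$merge_key,
                       method = "radix"), ]
  expect_equal(local, m)                                # locality/idempotence
})

test_that("hit sets grow monotonically with tolerance", {
  set.seed(3)
  recs <- make_record(sprintf("r%03d", 1:300), stats::runif(300, 50, 1000))
  queries <- sample(recs$monoisotopic_mass, 50) *
    (1 + stats::runif(50, -15, 15) * 1e-6)
  prev <- NULL
  for (tol in c(5, 10, 20)) {
    hits <- search_source(recs, queries, tol_ppm = tol)
    cur <- paste(hits$query_ref, hits$native_id)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("adding a source never removes identifications, only adds or enriches", {
  we <- load_worked_example()
  subset_res <- run_mz_list(624.3401, "negative", we$sources["HMDB"],
                            tol_ppm = 10, xref = we$xref)
  full_res <- run_mz_list(624.3401, "negative", we$sources,
                          tol_ppm = 10, xref = we$xref)
  sub <- subset_res$identifications
  full <- full_res$identifications
  for (k in sub$merge_key) {
    expect_true(k %in% full$merge_key)
    sub_natives <- strsplit(sub$native_ids[sub$merge_key == k], ";")[[1]]
    full_natives <- strsplit(full$native_ids[full$merge_key == k], ";")[[1]]
    expect_true(all(sub_natives %in% full_natives))
  }
})

test_that("run_mz_list treats each value as a (de)protonated ion end to end", {
  recs <- make_record("cpd", 625.34738, "HMDB")
  res <- run_mz_list(624.3401, "negative", list(HMDB = recs), tol_ppm = 10)
  expect_equal(nrow(res$identifications), 1)
  expect_equal(res$identifications$merge_key, "HMDB:cpd")
  expect_lt(abs(res$identifications$best_ppm_error), 1)

  expect_error(run_mz_list(624.3401, "negative", list()), "no sources")
  expect_error(run_mz_list(c(100, -2), "negative", list(HMDB = recs)), "-2")

  miss <- run_mz_list(c(624.3401, 111.111), "negative", list(HMDB = recs))
  expect_equal(miss$queries$n_identifications, c(1L, 0L))
  expect_equal(nrow(tidy(miss)), 2) # hitless query still emits a row
})

test_that("a bare-mz CAMERA file is equivalent to run_mz_list on those values", {
  recs <- make_record(c("a", "b"), c(625.34738, 180.06339), "HMDB")
  mzs <- c(624.3401, 100.5)
  tab <- tibble::tibble(mz = sprintf("%.5f", mzs))
  cam <- run_camera(tab, "negative", list(HMDB = recs), tol_ppm = 10)
  lst <- run_mz_list(mzs, "negative", list(HMDB = recs), tol_ppm = 10)
  cam_ids <- cam$identifications[setdiff(names(cam$identifications), c("group_id", "query_id"))]
  lst_ids <- lst$identifications[setdiff(names(lst$identifications), "query_id")]
  expect_equal(as.data.frame(cam_ids), as.data.frame(lst_ids))
  expect_equal(cam$queries$n_identifications, lst$queries$n_identifications)
})

test_that("a 3-member group yields one shared identification list per peak", {
  M <- 340.2614
  recs <- make_record("cpd", M, "HMDB",
                      inchi_key = "AAAAAAAAAAAAAA-AAAAAAAASA-N")
  tab <- tibble::tibble(
    mz = sprintf("%.5f", c(mz_of(M, "[M+H]+"), mz_of(M, "[M+Na]+"),
                           mz_of(M, "[M+K]+"))),
    adduct = c(sprintf("[M+H]+ %.4f", M), sprintf("[M+Na]+ %.4f", M),
               sprintf("[M+K]+ %.4f", M)),
    pcgroup = c("1", "1", "1")
  )
  res <- run_camera(tab, "positive", list(HMDB = recs), tol_ppm = 10)
  expect_equal(nrow(res$groups), 1)
  expect_equal(res$queries$n_identifications, rep(1L, 3))
  expect_equal(unique(res$identifications$merge_key), "AAAAAAAAAAAAAA")
})
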