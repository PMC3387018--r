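# CAMERA-style table parsing, group assembly, group query masses,
# and recombination of split peaks.

camera_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    mz = vapply(rows, `[[`, character(1), 1),
    rt = vapply(rows, `[[`, character(1), 2),
    isotopes = vapply(rows, `[[`, character(1), 3),
    adduct = vapply(rows, `[[`, character(1), 4),
    pcgroup = vapply(rows, `[[`, character(1), 5)
  )
}

test_that("adduct cells parse against the grammar with mass cross-check", {
  tab <- camera_tbl(list("203.0526", "100", "", "[M+Na]+ 180.0634", "7"))
  p <- parse_camera(tab, "positive")
  expect_equal(nrow(p), 1)
  expect_true(p$annotated)
  expect_equal(p$adduct, "[M+Na]+")
  expect_equal(p$charge, 1L)
  expect_equal(p$isotope_order, 0L)
  expect_equal(p$pcgroup, "7")
  # the printed neutral-mass estimate is consistent with the arithmetic
  expect_equal(neutral_mass(203.0526, "[M+Na]+"), 180.0634, tolerance = 1e-4)
})

test_that("blank cells yield unannotated peaks; isotope cells parse", {
  tab <- camera_tbl(
    list("181.07070", "100", "", "", ""),
    list("182.07406", "101", "[12][M+1]+", "", "12"),
    list("91.04060", "102", "[5][M]2+", "", "5")
  )
  p <- parse_camera(tab, "positive")
  expect_equal(p$annotated, c(FALSE, TRUE, TRUE))
  expect_equal(p$isotope_order[2], 1L)
  expect_equal(p$charge[2:3], c(1L, 2L))
  expect_equal(p$adduct[2:3], c("[M+H]+", "[M+H]+"))
})

test_that("unparseable annotation tokens warn and leave the peak unannotated", {
  tab <- camera_tbl(
    list("100.1", "10", "", "[M+NH4]+ 82.07", "3"),
    list("100.2", "11", "garbage", "", "3"),
    list("100.3", "12", "", "[M+H]+ 99.29", "3")
  )
  expect_warning(p <- parse_camera(tab, "positive"), "unannotated")
  expect_equal(p$annotated, c(FALSE, FALSE, TRUE))
})

test_that("a multi-adduct cell with aligned groups splits the peak", {
  tab <- camera_tbl(
    list("203.0526", "10", "", "[M+H]+ 202.05 [M+Na]+ 180.06", "2;5")
  )
  p <- parse_camera(tab, "positive")
  expect_equal(nrow(p), 2)
  expect_equal(p$peak_id, c(1L, 1L))
  expect_equal(p$adduct, c("[M+H]+", "[M+Na]+"))
  expect_equal(p$pcgroup, c("2", "5"))
  g <- build_groups(p, "positive")
  expect_setequal(g$group_id, c("2", "5"))
})

test_that("groups assemble per label; unannotated peaks become singletons", {
  M <- 180.06339
  tab <- camera_tbl(
    list(sprintf("%.5f", mz_of(M, "[M+H]+")), "10", "",
         sprintf("[M+H]+ %.4f", M), "1"),
    list(sprintf("%.5f", mz_of(M, "[M+Na]+")), "10", "",
         sprintf("[M+Na]+ %.4f", M), "1"),
    list(sprintf("%.5f", mz_of(M, "[M+K]+")), "10", "",
         sprintf("[M+K]+ %.4f", M), "1"),
    list("624.34010", "20", "", "", ""),
    list("101.00000", "30", "", "", "")
  )
  p <- parse_camera(tab, "positive")
  g <- build_groups(p, "positive")
  expect_setequal(unique(g$group_id), c("1", "p4", "p5"))
  expect_equal(sum(g$group_id == "1"), 3)
  # singletons are treated as protonated monoisotopic singly charged ions
  expect_equal(g$adduct[g$group_id == "p4"], "[M+H]+")
  expect_equal(g$isotope_order[g$group_id == "p4"], 0L)
})

test_that("group query mass is the median-implied neutral, reported as (de)protonated m/z", {
  g <- tibble::tibble(
    group_id = "1", peak_id = 1:2, mz = c(181.0707, 203.0526),
    adduct = c("[M+H]+", "[M+Na]+"), charge = 1L, isotope_order = 0L
  )
  s <- group_query_mz(g, "positive")
  expect_equal(s$neutral_mass, 180.0634, tolerance = 1e-4)
  expect_equal(s$query_mz, 181.0707, tolerance = 1e-4)

  # negative-mode singleton round-trips to its own m/z
  g2 <- tibble::tibble(group_id = "p1", peak_id = 1, mz = 624.3401,
                       adduct = "[M-H]-", charge = 1L, isotope_order = 0L)
  s2 <- group_query_mz(g2, "negative")
  expect_equal(s2$neutral_mass, 625.34738, tolerance = 1e-7)
  expect_equal(s2$query_mz, 624.3401, tolerance = 1e-9)

  # identical implied masses: the median is that mass
  g3 <- tibble::tibble(group_id = "x", peak_id = 1:2,
                       mz = mz_of(c(300, 300), "[M+H]+"),
                       adduct = "[M+H]+", charge = 1L, isotope_order = 0L)
  expect_equal(group_query_mz(g3, "positive")$neutral_mass, 300)
})

test_that("recombine unions identifications across a peak's groups and conserves peaks", {
  membership <- tibble::tibble(
    group_id = c("G1", "G1", "G2", "G2", "G3"),
    peak_id = c(1L, 2L, 2L, 3L, 4L),
    mz = c(100, 101, 101, 102, 103)
  )
  ids <- tibble::tibble(
    group_id = c("G1", "G1", "G1", "G2", "G2"),
    merge_key = c("A", "B", "C", "C", "D"),
    best_ppm_error = c(1, 2, 3, 0.5, 4)
  )
  out <- recombine(ids, membership)
  expect_setequal(unique(out$peak_id), 1:4)                  # conservation
  p2 <- out[out$peak_id == 2L & !is.na(out$merge_key), ]
  expect_setequal(p2$merge_key, c("A", "B", "C", "D"))       # 3 + 2 with 1 shared
  expect_equal(p2$best_ppm_error[p2$merge_key == "C"], 0.5)  # dedup keeps best
  p1 <- out[out$peak_id == 1L & !is.na(out$merge_key), ]
  expect_setequal(p1$merge_key, c("A", "B", "C"))            # single group unchanged
  expect_true(is.na(out$merge_key[out$peak_id == 4L]))       # hitless peak present
})
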