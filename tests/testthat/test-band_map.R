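test_that("the packaged band table loads into a validated partonomy", {
  expect_s3_class(the_map, "band_map")
  expect_setequal(unique(the_map$entries$chromosome), CHROMOSOME_NAMES)
  expect_length(the_map$chromosomes, 24L)
  # every chromosome carries at least one band per arm
  arms <- table(the_map$entries$chromosome, the_map$entries$arm)
  expect_true(all(arms >= 1L))
})

test_that("chromosome 1 p-arm runs pter to centromere in idiogram order", {
  p1 <- the_map$entries[the_map$entries$chromosome == "1" &
                        the_map$entries$arm == "p", ]
  expect_equal(p1$label[order(p1$leaf_start)],
               paste0("1p", c(36, 35, 34, 33, 32, 31, 22, 21, 13, 12, 11)))
  # exactly 1p22 lies strictly between 1p31 and 1p21
  expect_equal(setdiff(bands_between(the_map, "1p31", "1p21"),
                       c("1p31", "1p21")),
               "1p22")
})

test_that("malformed band tables are rejected at load time", {
  write_tab <- function(rows) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("chromosome\tarm\tband\tparent\tresolutions", rows), f)
    f
  }
  # duplicate label
  expect_error(
    load_band_map(write_tab(c("1\tp\t36\t\t300", "1\tp\t36\t\t300",
                              "1\tq\t11\t\t300"))),
    class = "iscn_format_error")
  # child before parent
  expect_error(
    load_band_map(write_tab(c("17\tp\t11\t\t300", "17\tq\t21.1\t21\t550",
                              "17\tq\t21\t\t300"))),
    class = "iscn_format_error")
  # out-of-order p-arm rows
  expect_error(
    load_band_map(write_tab(c("1\tp\t21\t\t300", "1\tp\t36\t\t300",
                              "1\tq\t11\t\t300"))),
    class = "iscn_format_error")
  # q rows before p rows
  expect_error(
    load_band_map(write_tab(c("1\tq\t11\t\t300", "1\tp\t36\t\t300"))),
    class = "iscn_format_error")
})

test_that("band existence canonicalizes text and never throws", {
  expect_true(band_exists(the_map, "1p35"))
  expect_true(band_exists(the_map, "17q21.1"))
  expect_true(band_exists(the_map, " 17 Q 21.31 "))
  expect_true(band_exists(the_map, "X"))
  expect_true(band_exists(the_map, "1p"))
  expect_false(band_exists(the_map, "1p99"))
  expect_false(band_exists(the_map, "25q11"))
  expect_false(band_exists(the_map, "banana"))
  expect_false(band_exists(the_map, ""))
})

test_that("sub-band queries return ordered descendants, empty for leaves", {
  subs <- sub_bands(the_map, "17q21")
  expect_gte(length(subs), 2L)
  expect_true(all(startsWith(subs, "17q21.")))
  expect_true(all(vapply(subs, band_exists, logical(1), map = the_map)))
  expect_identical(sub_bands(the_map, "1p22"), character(0))
  expect_error(sub_bands(the_map, "1p99"), class = "iscn_lookup_error")
})

test_that("band visibility is cumulative across resolution levels", {
  expect_true(seen_at_resolution(the_map, "1p36", 300L))
  expect_true(seen_at_resolution(the_map, "1p36", 850L))
  expect_false(seen_at_resolution(the_map, "17q21.31", 300L))
  expect_true(seen_at_resolution(the_map, "17q21.31", 550L))
  expect_true(seen_at_resolution(the_map, "17q21.31", 850L))
  expect_error(seen_at_resolution(the_map, "1p99", 300L),
               class = "iscn_lookup_error")
})

test_that("band comparison is a strict total order per chromosome", {
  expect_identical(compare_bands(the_map, "1p31", "1p21"), -1L)
  expect_identical(compare_bands(the_map, "1p22", "1p22"), 0L)
  expect_identical(compare_bands(the_map, "15q11", "15q12"), -1L)
  expect_error(compare_bands(the_map, "1p31", "2p21"),
               class = "iscn_domain_error")
  # exhaustive antisymmetry and transitivity-by-sorting on chromosome 17
  # (the chromosome with nested sub-bands)
  labs <- the_map$entries$label[the_map$entries$chromosome == "17"]
  cmp <- outer(labs, labs, Vectorize(function(a, b)
    compare_bands(the_map, a, b)))
  expect_true(all(cmp == -t(cmp)))
  expect_true(all(diag(cmp) == 0L))
  # consistency: a<b and b<c implies a<c
  for (i in seq_along(labs)) for (j in seq_along(labs)) for (k in seq_along(labs)) {
    if (cmp[i, j] < 0L && cmp[j, k] < 0L) expect_lt(cmp[i, k], 0L)
  }
})

test_that("interval queries are inclusive, symmetric and centromere-crossing", {
  expect_equal(bands_between(the_map, "1p31", "1p21"),
               c("1p31", "1p22", "1p21"))
  expect_equal(bands_between(the_map, "1p34", "1p32"),
               oracle_between("1p34", "1p32"))
  expect_equal(bands_between(the_map, "1p22", "1p22"), "1p22")
  # symmetric in the endpoints
  expect_setequal(bands_between(the_map, "1p21", "1p31"),
                  bands_between(the_map, "1p31", "1p21"))
  # spans the centromere
  expect_equal(bands_between(the_map, "15p11", "15q11"),
               c("15p11", "15q11"))
  expect_error(bands_between(the_map, "1p31", "2q11"),
               class = "iscn_domain_error")
})

test_that("interval queries across all same-chromosome pairs are symmetric and adjacent pairs span two bands", {
  for (ch in c("1", "15", "17", "X")) {
    labs <- the_map$entries$label[the_map$entries$chromosome == ch]
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      expect_identical(sort(bands_between(the_map, labs[i], labs[j], 850L)),
                       sort(bands_between(the_map, labs[j], labs[i], 850L)))
    }
    leaves <- bands_between(the_map, labs[1], labs[length(labs)], 850L)
    for (i in seq_len(length(leaves) - 1L)) {
      expect_length(bands_between(the_map, leaves[i], leaves[i + 1L], 850L), 2L)
    }
  }
})

test_that("mixed-resolution endpoints expand; invisible ones error", {
  # a parent band queried at a level where its sub-bands are visible
  expect_equal(bands_between(the_map, "17q21", "17q22", res = 550L),
               c("17q21.1", "17q21.2", "17q21.31", "17q21.32", "17q21.33",
                 "17q22"))
  # a sub-band queried below the level where it appears
  expect_error(bands_between(the_map, "17q21.31", "17q22", res = 300L),
               class = "iscn_resolution_error")
  # at the coarse level the parent is the leaf
  expect_equal(bands_between(the_map, "17q21", "17q22", res = 300L),
               c("17q21", "17q22"))
})
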