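test_that("tokenization splits on top-level commas and ignores whitespace", {
  pd <- tokenize_iscn("46,XY,del(15)(q11q12)")
  expect_equal(pd$declared_total, 46L)
  expect_equal(pd$sex_field, "XY")
  expect_length(pd$raw_event_fields, 1L)

  pd <- tokenize_iscn("45, X,-Y")
  expect_equal(pd$declared_total, 45L)
  expect_equal(pd$sex_field, "X")
  expect_equal(pd$raw_event_fields, "-Y")

  # commas inside parentheses are part of the field, not separators
  pd <- tokenize_iscn("46,XX,t(2;5)(q21;q31)")
  expect_length(pd$raw_event_fields, 1L)

  expect_error(tokenize_iscn("abc"), class = "iscn_parse_error")
  expect_error(tokenize_iscn(""), class = "iscn_parse_error")
  expect_error(tokenize_iscn("46"), class = "iscn_parse_error")
  expect_error(tokenize_iscn("46,ZZ"), class = "iscn_parse_error")
})

test_that("out-of-dialect ISCN notation is rejected with a clear error", {
  expect_error(tokenize_iscn("46,XX/47,XX,+21"), class = "iscn_unsupported_error")
  expect_error(tokenize_iscn("45~48,XY"), class = "iscn_unsupported_error")
  expect_error(tokenize_iscn("46,XY,del(15)(q11?)"),
               class = "iscn_unsupported_error")
})

test_that("event parsing dispatches on prefix and validates bands", {
  e <- parse_event("del(15)(q11q12)", the_map)
  expect_equal(e$kind, "del")
  expect_equal(e$level, "band")
  expect_equal(e$chromosomes, "15")
  expect_equal(e$breakpoints, c("15q11", "15q12"))

  e <- parse_event("-Y", the_map)
  expect_equal(e$kind, "loss")
  expect_equal(e$level, "chromosome")
  expect_equal(e$chromosomes, "Y")
  expect_equal(e$multiplicity, 1L)

  e <- parse_event("t(2;5)(q21;q31)", the_map)
  expect_equal(e$kind, "t")
  expect_setequal(e$breakpoints, c("2q21", "5q31"))

  expect_error(parse_event("del(15)(q99q12)", the_map),
               class = "iscn_validation_error")
  expect_error(parse_event("xyz(15)(q11)", the_map),
               class = "iscn_unsupported_error")
  expect_error(parse_event("t(2)(q21)", the_map),
               class = "iscn_structure_error")
  expect_error(parse_event("t(2;5)(q21)", the_map),
               class = "iscn_structure_error")
  expect_error(parse_event("inv(2)()", the_map),
               class = "iscn_structure_error")
})

test_that("every event abbreviation is accepted in at least one form", {
  forms <- c(
    add = "add(1)(p13)",
    del = "del(15)(q11q12)",
    der = "der(1)t(1;5)(p22;q31)",
    dic = "dic(17;15)(p11;q11)",
    dup = "dup(1)(q21q31)",
    fis = "fis(1)(p11)",
    fra = "fra(X)(q27)",
    hsr = "hsr(1)(q21)",
    ins = "ins(2;5)(q21;q31q33)",
    inv = "inv(2)(p21q31)",
    i = "i(17)(q11)",
    mar = "+mar",
    neo = "neo(2)(q21)",
    qdp = "qdp(1)(q21q22)",
    r = "r(2)(p21q31)",
    tas = "tas(17;21)(p13;q22)",
    t = "t(2;5)(q21;q31)",
    trc = "trc(1;2;5)(p11;q11;q11)",
    trp = "trp(1)(q21q31)"
  )
  expect_length(forms, nrow(event_kinds()))
  for (kind in names(forms)) {
    e <- parse_event(forms[[kind]], the_map)
    expect_equal(e$kind, kind, info = forms[[kind]])
  }
})

test_that("derivative chromosomes parse as containers over constituents", {
  e <- parse_event("der(1)t(1;5)(p22;q31)", the_map)
  expect_equal(e$kind, "der")
  expect_length(e$constituents, 1L)
  expect_equal(e$constituents[[1]]$kind, "t")
  expect_setequal(e$chromosomes, c("1", "5"))
  expect_setequal(e$breakpoints, c("1p22", "5q31"))
  # two constituents
  e2 <- parse_event("der(1)t(1;5)(p22;q31)del(1)(q42)", the_map)
  expect_length(e2$constituents, 2L)
  expect_error(parse_event("der(1)", the_map), class = "iscn_structure_error")
})

test_that("full designations parse with base inference", {
  k <- parse_iscn("46,XY", the_map)
  expect_equal(k$base$sex_complement, "XY")
  expect_equal(k$base$ploidy, 2L)
  expect_length(k$events, 0L)

  k <- parse_iscn("45,X,-Y", the_map)
  expect_equal(k$base$sex_complement, "XY")
  expect_equal(k$computed_total, 45L)

  k <- parse_iscn("47,XX,+21", the_map)
  expect_equal(k$base$sex_complement, "XX")
  expect_equal(chromosome_count(k), 47L)

  # a missing allosome with no event derives from the unknown-allosome base
  k <- parse_iscn("45,X", the_map)
  expect_equal(k$base$sex_complement, "XN")
  expect_true(any(vapply(k$events, `[[`, logical(1), "implicit")))

  # surplus allosome becomes a gain on the XY base
  k <- parse_iscn("47,XXY", the_map)
  expect_equal(k$base$sex_complement, "XY")

  # triploid
  k <- parse_iscn("69,XXY", the_map)
  expect_equal(k$base$ploidy, 3L)

  expect_error(parse_iscn("47,XY", the_map), class = "iscn_consistency_error")
  expect_error(parse_iscn("46,XY,del(15)(q99q12)", the_map),
               class = "iscn_validation_error")
})

test_that("canonical emission round-trips and is idempotent", {
  expect_equal(canonical_iscn(parse_iscn("45, X,-Y", the_map)), "45,X,-Y")
  expect_equal(canonical_iscn(parse_iscn("46,XY", the_map)), "46,XY")
  # the implicit unknown-allosome bookkeeping never leaks into the string
  expect_equal(canonical_iscn(parse_iscn("45,X", the_map)), "45,X")
  # events are sorted by chromosome
  s <- canonical_iscn(parse_iscn("47,XY,+21,del(1)(p31p21)", the_map))
  expect_equal(s, "47,XY,del(1)(p31p21),+21")
  # idempotence: parse . canonical . parse == parse
  for (x in c("46,XY,del(15)(q11q12)", "45,X,-Y", "47,XXY",
              "46,XX,t(2;5)(q21;q31)", "48,XY,+mar,+mar")) {
    k <- parse_iscn(x, the_map)
    expect_equal(canonical_iscn(parse_iscn(canonical_iscn(k), the_map)),
                 canonical_iscn(k))
  }
})

test_that("repeated identical fields accumulate into multiplicity", {
  k <- parse_iscn("48,XY,+21,+21", the_map)
  visible <- Filter(function(e) !e$implicit, k$events)
  expect_length(visible, 1L)
  expect_equal(visible[[1]]$multiplicity, 2L)
  expect_equal(copy_number(k, "21"), 4L)
  expect_equal(canonical_iscn(k), "48,XY,+21,+21")
})
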