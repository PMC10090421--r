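test_that("TSV loading drops incomplete properties and keeps file order", {
  tbl <- suppressMessages(readAAIndexTSV(
    system.file("extdata", "aaindex_mini.tsv", package = "acpGBDT")))
  expect_s4_class(tbl, "AAIndexTable")
  expect_length(tbl, 6L)                      # the NA row is dropped
  expect_false("INCOMPLETE_EXAMPLE" %in% propertyIds(tbl))
  expect_identical(propertyIds(tbl)[1], "HYDROPATHY_KD")
  expect_message(readAAIndexTSV(
    system.file("extdata", "aaindex_mini.tsv", package = "acpGBDT")),
    "dropped")
  # loading twice gives identical property order
  expect_identical(propertyIds(aaindexMini()), propertyIds(aaindexMini()))
})

test_that("AAindex1 flat files parse by H/I record structure", {
  # two entries in database residue order A R N D C Q E G H I / L K M F P S T V W Y
  flat <- tempfile()
  writeLines(c(
    "H FAKE000001",
    "D synthetic flat-file fixture",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y",
    "     1.      2.      3.      4.      5.      6.      7.      8.      9.     10.",
    "    11.     12.     13.     14.     15.     16.     17.     18.     19.     20.",
    "//",
    "H FAKE000002",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y",
    "     1.      1.      1.      1.      NA      1.      1.      1.      1.      1.",
    "     1.      1.      1.      1.      1.      1.      1.      1.      1.      1.",
    "//"), flat)
  tbl <- suppressMessages(readAAIndex1(flat))
  expect_identical(propertyIds(tbl), "FAKE000001")
  v <- tbl@values["FAKE000001", ]
  expect_equal(unname(v[c("A", "R", "Y")]), c(1, 2, 20))
  expect_error(readAAIndex1(tempfile()), ".")
})

test_that("the full bundled database retains 531 complete properties", {
  full <- aaindexFull()
  expect_length(full, 531L)
  expect_true(all(is.finite(full@values)))
})

test_that("truncation keeps first ten plus last ten residues", {
  s30 <- paste(rep(c("A", "C", "D"), 10), collapse = "")
  t30 <- truncate20(s30)
  expect_identical(t30$residues,
                   paste0(substr(s30, 1, 10), substr(s30, 21, 30)))
  expect_false(any(t30$padMask))

  s20 <- strrep("AC", 10)
  expect_identical(truncate20(s20)$residues, s20)      # fixed point
  expect_identical(truncate20(truncate20(s20)$residues)$residues, s20)

  # overlap duplicated for 10 <= L < 20
  t12 <- truncate20("ACDEFGHIKLMN")
  expect_identical(t12$residues, "ACDEFGHIKLDEFGHIKLMN")
  expect_false(any(t12$padMask))

  # L < 10: literal rule then right-padding, flagged in the mask
  t3 <- truncate20("ACD")
  expect_identical(substr(t3$residues, 1, 6), "ACDACD")
  expect_identical(t3$padMask, c(rep(FALSE, 6), rep(TRUE, 14)))
  expect_error(truncate20(""), "empty")
})

test_that("AAindex encoding is a position-major pure lookup", {
  tbl <- aaindexMini()
  P <- length(tbl)
  v <- encodeAAIndex(strrep("A", 20), tbl)
  expect_length(v, 20L * P)
  expect_equal(unname(v), rep(unname(tbl@values[, "A"]), 20L))

  small <- aaindexTable(tbl@values[1:3, ])
  expect_length(encodeAAIndex("ACDEFGHIKLMNPQRSTVWY", small), 60L)

  # changing residue i changes at most the P entries of position i
  # (A and D differ in every bundled property)
  a <- encodeAAIndex(strrep("A", 20), tbl)
  b <- encodeAAIndex(paste0(strrep("A", 7), "D", strrep("A", 12)), tbl)
  expect_identical(unname(which(a != b)), 7L * P + seq_len(P))

  # pad positions contribute zero for every property
  vShort <- encodeAAIndex("ACD", tbl)
  expect_true(all(vShort[(6 * P + 1):(20 * P)] == 0))

  # invariant to everything outside the first/last ten residues
  s1 <- paste0(strrep("K", 10), strrep("A", 15), strrep("R", 10))
  s2 <- paste0(strrep("K", 10), strrep("W", 4), strrep("R", 10))
  expect_identical(encodeAAIndex(s1, tbl), encodeAAIndex(s2, tbl))
})

test_that("full-database encoding has the documented width", {
  full <- aaindexFull()
  expect_length(encodeAAIndex("GLFDIIKKIAESF", full), 20L * 531L)
})
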