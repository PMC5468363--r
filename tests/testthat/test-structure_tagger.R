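# Ordered-SMARTS series tagging. Match outcomes in these tests were
# confirmed with an independent substructure matcher (OpenBabel's
# obabel -s filter) on the same SMILES.

tagTable <- function(...) {
  rows <- list(...)
  data.frame(SMARTS = vapply(rows, `[[`, "", 1L),
             TagName = vapply(rows, `[[`, "", 2L),
             TagSetName = vapply(rows, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

test_that("loadTags filters by set, preserves order, validates patterns", {
  tab <- tagTable(c("c1ccccc1", "Aryl", "main"),
                  c("c1ccncc1", "Pyridine", "main"),
                  c("C(=O)N", "Amide", "sub"),
                  c("[OH]", "Hydroxyl", "main"),
                  c("N", "AnyN", "sub"))
  ts <- loadTags(tab, "main")
  expect_s4_class(ts, "TagSet")
  expect_identical(tagDefinitions(ts)$tagName,
                   c("Aryl", "Pyridine", "Hydroxyl"))
  expect_error(loadTags(tab, "missing"), "main, sub")
  bad <- tagTable(c("[qq", "Broken", "main"))
  expect_error(loadTags(bad, "main"), "row 1")
})

test_that("a scaffold SMARTS tags its molecule (azaindole)", {
  tab <- tagTable(c("c1ccc2[nH]ccc2n1", "Azaindole", "S"))
  ts <- loadTags(tab, "S")
  rec <- embedSmiles("c1ccc2[nH]ccc2n1", "7-azaindole")
  out <- streamCollect(tagRecords(list(rec), ts, mode = "first"))
  expect_identical(sdField(out[[1L]], "StructureTag"), "Azaindole")
})

test_that("order decides among matches; non-matching patterns are skipped", {
  # pyridine does not match the benzene pattern, so the second
  # definition provides the first (and only) match
  ts <- loadTags(tagTable(c("c1ccccc1", "Aryl", "m"),
                          c("c1ccncc1", "Pyridine", "m")), "m")
  pyr <- embedSmiles("c1ccncc1", "pyridine")
  out <- streamCollect(tagRecords(list(pyr), ts, mode = "both"))
  expect_identical(sdField(out[[1L]], "StructureTag"), "Pyridine")
  expect_identical(sdField(out[[1L]], "AllStructureTags"), "Pyridine")

  # acetanilide matches both the generic amide and the phenyl-amide
  # pattern: the first definition in file order wins, not the more
  # specific one
  ts2 <- loadTags(tagTable(c("C(=O)N", "Amide", "m"),
                           c("c1ccccc1NC(=O)", "PhenylAmide Series", "m")),
                  "m")
  aa <- embedSmiles("CC(=O)Nc1ccccc1", "acetanilide")
  out2 <- streamCollect(tagRecords(list(aa), ts2, mode = "both"))
  expect_identical(sdField(out2[[1L]], "StructureTag"), "Amide")
  expect_identical(sdField(out2[[1L]], "AllStructureTags"),
                   "Amide; PhenylAmide Series")
})

test_that("no-match molecules pass through unchanged; counts are preserved", {
  ts <- loadTags(tagTable(c("c1ccccc1", "Aryl", "m")), "m")
  recs <- list(embedSmiles("CCCC", "butane"),
               embedSmiles("c1ccccc1", "benzene"),
               embedSmiles("CO", "methanol"))
  out <- streamCollect(tagRecords(recs, ts, mode = "first"))
  expect_length(out, 3L)
  expect_true(is.na(sdField(out[[1L]], "StructureTag")))
  expect_identical(sdField(out[[2L]], "StructureTag"), "Aryl")
  expect_true(is.na(sdField(out[[3L]], "StructureTag")))
})

test_that("duplicate tag names collapse in all mode; data-only records warn", {
  ts <- loadTags(tagTable(c("[CH3]", "Alkyl", "m"),
                          c("[CH2]", "Alkyl", "m"),
                          c("[OH]", "Hydroxyl", "m")), "m")
  eg <- embedSmiles("OCCO", "glycol")
  out <- streamCollect(tagRecords(list(eg), ts, mode = "all"))
  expect_identical(sdField(out[[1L]], "AllStructureTags"),
                   "Alkyl; Hydroxyl")
  expect_warning(
    out2 <- streamCollect(tagRecords(list(sdRecord(title = "empty")), ts)),
    "untagged")
  expect_length(out2, 1L)
  expect_length(sdFields(out2[[1L]]), 0L)
})

test_that("tagging identical input twice yields identical output bytes", {
  ts <- loadTags(tagTable(c("c1ccccc1", "Aryl", "m"),
                          c("C(=O)O", "Acid", "m")), "m")
  recs <- lapply(c("CC(=O)Oc1ccccc1C(=O)O", "Cc1ccccc1", "CCCC"),
                 embedSmiles)
  run <- function() sdLines(streamCollect(tagRecords(recs, ts, "both")))
  expect_identical(run(), run())
})
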