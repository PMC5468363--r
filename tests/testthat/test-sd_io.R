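# SD reading/writing: round trips, order preservation, laziness,
# malformed input.

test_that("empty input yields an empty stream", {
  expect_length(streamCollect(readSD(character())), 0L)
  expect_length(streamCollect(readSD("")), 0L)
})

test_that("a written record reads back identically", {
  r <- toyRecord(fields = list(MW = "16.04"))
  f <- tempfile(fileext = ".sdf")
  expect_identical(writeSD(list(r), f), 1L)
  back <- streamCollect(readSD(f))
  expect_length(back, 1L)
  expect_true(sameRecord(r, back[[1L]]))
  expect_identical(sdFields(back[[1L]]), list(MW = "16.04"))
})

test_that("multi-record files keep file order and agree with a line-level delimiter count", {
  recs <- lapply(c("A", "B", "C"), function(t) toyRecord(title = t))
  lines <- sdLines(recs)
  expect_identical(sum(lines == "$$$$"), 3L)  # independent splitter
  back <- streamCollect(readSD(lines))
  expect_identical(vapply(back, sdTitle, ""), c("A", "B", "C"))
})

test_that("field order is preserved on write, in-place update keeps position", {
  r <- toyRecord(fields = list(b = "2", a = "1"))
  lines <- sdLines(list(r))
  headers <- grep("^> <", lines, value = TRUE)
  expect_identical(headers, c("> <b>", "> <a>"))
  sdField(r, "b") <- "9"
  expect_identical(names(sdFields(r)), c("b", "a"))
  expect_identical(sdField(r, "b"), "9")
})

test_that("multi-line values and indexed data headers survive parsing", {
  r <- toyRecord(fields = list(note = "line one\nline two"))
  back <- streamCollect(readSD(sdLines(list(r))))[[1L]]
  expect_identical(sdField(back, "note"), "line one\nline two")
  # the indexed header form is accepted on input
  lines <- sdLines(list(toyRecord()))
  lines <- append(lines, c(">  <EXT>  (1)", "val", ""),
                  after = which(lines == "M  END"))
  back2 <- streamCollect(readSD(lines))[[1L]]
  expect_identical(sdField(back2, "EXT"), "val")
})

test_that("write -> read -> write is byte-identical over many generated records", {
  recs <- toyRecords(100L)
  for (i in seq_along(recs))
    sdField(recs[[i]], "Payload") <- paste0("v", i, "\nextra ", i)
  first <- sdLines(recs)
  back <- streamCollect(readSD(first))
  expect_true(all(mapply(sameRecord, recs, back)))
  expect_identical(sdLines(back), first)
})

test_that("reading is lazy: pulling N records materializes at most N+1", {
  env <- new.env()
  recs <- toyRecords(50L)
  lines <- sdLines(recs)
  # a connection-backed stream must not be exhausted by a partial pull
  f <- tempfile(fileext = ".sdf")
  writeLines(lines, f)
  stream <- readSD(f)
  got <- streamCollect(stream, n = 3L)
  expect_length(got, 3L)
  expect_identical(sdTitle(got[[3L]]), "R3")
  # and a stage pipeline over a counting stream pulls one-by-one
  src <- countingStream(recs, env)
  mapped <- streamMap(src, function(r, i) r)
  streamCollect(mapped, n = 4L)
  expect_lte(env$pulled, 5L)
})

test_that("data-only chunks and malformed molblocks are handled", {
  dataOnly <- c("> <KEY>", "value", "", "$$$$")
  expect_warning(recs <- streamCollect(readSD(dataOnly)), "data-only")
  expect_identical(atomCount(recs[[1L]]), 0L)
  expect_identical(sdField(recs[[1L]], "KEY"), "value")

  truncated <- c("t", "", "", "  5  0  0  0  0  0  0  0  0  0999 V2000",
                 "    0.0  0.0  0.0 C", "$$$$")
  expect_error(streamCollect(readSD(truncated)), "truncated.*record 1")

  v3k <- c("t", "", "", "  0  0  0     0  0            999 V3000", "$$$$")
  expect_error(streamCollect(readSD(v3k)), "V3000")
})

test_that("records beyond the V2000 atom limit are rejected on write", {
  big <- sdRecord(title = "big",
                  atoms = data.frame(elem = rep("C", 1000L), x = 0, y = 0,
                                     z = 0, charge = 0L))
  expect_error(writeSD(list(big), tempfile()), "V2000")
})

test_that("charges round-trip through M CHG lines", {
  r <- toyRecord()
  r@atoms$charge[1L] <- 1L
  back <- streamCollect(readSD(sdLines(list(r))))[[1L]]
  expect_identical(atomTable(back)$charge[1L], 1L)
})
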