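test_that("out dialect rows parse by mark and column", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("1\t0.525\t\t71.3",
               "1\t0.810\t/\t",
               "1\t1.100\t\t68.2",
               "2\t0.300\t//\t60.0",
               "2\t0.650\t\t70.0"), f)
  s <- read_out_file(f, "abc", "yz")
  expect_equal(s$language_iso, "abc")
  expect_equal(s$events$kind,
               c("nucleus", "phrase_break", "nucleus", "sentence_break",
                 "nucleus"))
  expect_equal(s$events$time[1], 0.525)
  expect_equal(s$events$intensity[1], 71.3)
  expect_true(is.na(s$events$intensity[2]))
  expect_equal(s$events$part, c(1L, 1L, 1L, 2L, 2L))
})

test_that("empty file and error paths", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(character(), f)
  expect_equal(nrow(read_out_file(f)$events), 0L)

  writeLines(c("1\t0.5\t\t70", "1\tabc\t\t70"), f)
  expect_error(read_out_file(f), "line 2.*non-numeric time|non-numeric time.*line 2")

  writeLines(c("1\t0.9\t\t70", "1\t0.5\t\t70"), f)
  expect_error(read_out_file(f), "sorted|strictly increasing")

  expect_error(read_out_file(file.path(tempdir(), "nope.out")), "no such file")
})

test_that("out and TextGrid writers round-trip generated fixtures", {
  for (seed in c(2L, 9L)) {
    g <- generate_language(synth_config(n_nuclei = 40L, n_phrases = 5L,
                                        seed = seed))
    f <- withr::local_tempfile(fileext = ".out")
    write_out_file(g$seq, f)
    expect_identical(read_out_file(f, "xxx", "syn")$events, g$seq$events)

    tg <- withr::local_tempfile(fileext = ".TextGrid")
    write_textgrid(g$seq, tg)
    s <- read_textgrid(tg)
    expect_identical(s$events$time, g$seq$events$time)
    expect_identical(s$events$kind, g$seq$events$kind)
    expect_true(all(is.na(s$events$intensity)))  # TextGrids carry none
  }
})

test_that("TextGrid label mapping, short form, and error messages", {
  mk_long <- function(path) {
    s <- make_seq(c(0.1, 0.3, 0.9), breaks = 0.45)
    write_textgrid(s, path, tier_name = "nuclei")
  }
  f <- withr::local_tempfile(fileext = ".TextGrid")
  mk_long(f)
  s <- read_textgrid(f, "nuclei")
  expect_equal(sum(s$events$kind == "nucleus"), 3L)
  expect_equal(sum(s$events$kind == "phrase_break"), 1L)

  expect_error(read_textgrid(f, "syllables"), "available tiers.*nuclei")

  # hand-written short form with a point tier and an interval tier
  short <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "0", "2", "<exists>", "2",
             '"IntervalTier"', '"words"', "0", "2", "1",
             "0", "2", '"hello"',
             '"TextTier"', '"nuclei"', "0", "2", "4",
             "0.1", '"1"', "0.3", '"2"', "0.45", '"/"', "0.9", '"3"')
  f2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short, f2)
  s2 <- read_textgrid(f2, "nuclei")
  expect_equal(s2$events$time, c(0.1, 0.3, 0.45, 0.9))
  expect_equal(s2$events$kind[3], "phrase_break")
  expect_error(read_textgrid(f2, "words"), "point tiers")

  # zero-point tier
  short0 <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
              "0", "2", "<exists>", "1",
              '"TextTier"', '"nuclei"', "0", "2", "0")
  f3 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short0, f3)
  expect_equal(nrow(read_textgrid(f3, "nuclei")$events), 0L)
})

test_that("concatenated files group by (language, annotator) and round-trip", {
  a <- generate_language(synth_config(n_nuclei = 20L, n_phrases = 3L,
                                      language_iso = "aaa", annotator = "p1",
                                      seed = 1L))$seq
  b <- generate_language(synth_config(n_nuclei = 25L, n_phrases = 4L,
                                      language_iso = "bbb", annotator = "p2",
                                      seed = 2L))$seq
  f <- withr::local_tempfile(fileext = ".out")
  write_concatenated(list(a, b), f)
  back <- read_concatenated(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]$events, a$events)
  expect_identical(back[[2]]$events, b$events)
  expect_equal(back[[2]]$language_iso, "bbb")

  # equals reading per-language files individually
  fa <- withr::local_tempfile(); write_out_file(a, fa)
  expect_identical(read_out_file(fa, "aaa", "p1"), back[[1]])

  # wrong column count
  writeLines("1\t0.5\t\t70", f)
  expect_error(read_concatenated(f), "6 columns")
})

test_that("sequence validation enforces ordering and intensities", {
  bad <- data.frame(part = 1L, time = c(0.2, 0.1),
                    kind = "nucleus", intensity = 70)
  expect_error(annotation_seq(bad), "sorted|strictly increasing")
  bad2 <- data.frame(part = 1L, time = 0.5, kind = "nucleus",
                     intensity = NA_real_)
  expect_error(annotation_seq(bad2), "intensity")
})
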