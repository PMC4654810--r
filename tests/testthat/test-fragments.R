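test_that("digestion cuts at site starts and tiles the sequence", {
  # no cut sites: single fragment covering everything
  fm <- digest_sequence("ACGTACGTAC", "TTTT")
  expect_equal(nrow(fm), 1L)
  expect_equal(c(fm$start, fm$end), c(0, 10))

  # cut-at-site-start convention
  fm <- digest_sequence("AAAAAAGCTTAAAAAAGCTTAA", "AAGCTT")
  expect_equal(fm$start, c(0, 4, 14))
  expect_equal(fm$end, c(4, 14, 22))

  # overlapping occurrences resolved left-to-right, non-overlapping:
  # independent sliding-scan oracle
  seq <- "CCAAACCAAAAACC"
  site <- "AA"
  scan_count <- local({
    i <- 1L; hits <- 0L
    while (i <= nchar(seq) - nchar(site) + 1L) {
      if (substr(seq, i, i + nchar(site) - 1L) == site) {
        hits <- hits + 1L; i <- i + nchar(site)
      } else i <- i + 1L
    }
    hits
  })
  fm <- digest_sequence(seq, site)
  expect_equal(nrow(fm), scan_count + 1L)

  expect_error(digest_sequence("ACGTX", "AC"), "A/C/G/T/N")
  expect_error(digest_sequence("", "AC"))
  expect_error(digest_sequence("ACG", "ACGT"), "shorter")
})

test_that("digestion fragment lengths always sum to sequence length", {
  for (seed in 1:5) {
    s <- random_dna(500, seed = seed)
    fm <- digest_sequence(s, "GATC")
    expect_equal(sum(fm$length), nchar(s))
    expect_true(all(diff(fm$mid) > 0))
    expect_true(all(fm$length > 0))
  }
})

test_that("fragment maps validate ordering and positivity", {
  expect_error(fragment_map("c", c(0, 10), c(10, 10)), "length")
  expect_error(fragment_map("c", c(0, 5), c(10, 15)), "overlap")
  fm <- fragment_map("c", c(10, 0), c(20, 10))  # sorted on construction
  expect_equal(fm$start, c(0, 10))
})

test_that("capture tables round-trip through TSV and report rejects", {
  fm <- fragment_map("chr4", c(0, 100, 250), c(100, 250, 400))
  path <- withr::local_tempfile(fileext = ".tsv")

  # empty file -> empty table
  writeLines("chrom\tstart\tend\tcount", path)
  ct <- read_capture_table(path, fm)
  expect_equal(nrow(ct), 0L)

  # identity round-trip plus one row spanning two fragments -> reject
  df <- data.frame(chrom = "chr4", start = c(0, 100, 250, 0),
                   end = c(100, 250, 400, 250), count = c(5, 0, 9, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- read_capture_table(path, fm, viewpoint = "vp1")
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$count, c(5, 0, 9))
  expect_equal(ct$fragment, 1:3)
  expect_equal(nrow(attr(ct, "rejects")), 1L)
  expect_equal(attr(ct, "rejects")$end, 250)

  expect_error(capture_table("v", 1L, "1", "WT", -1), "non-negative")
  expect_error(capture_table("v", 1L, "1", "WT", 1.5), "integers")
})

test_that("tracks round-trip and omit non-finite values", {
  tr <- data.frame(start = seq(0, 100, by = 20)[1:6],
                   end = seq(20, 120, by = 20)[1:6],
                   value = c(1.5, NA, 2.25, NaN, -0.5, 0))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(tr, path, chrom = "chr4")
  back <- read_track(path)
  expect_equal(nrow(back), 4L)            # the 2 non-finite rows are omitted
  keep <- is.finite(tr$value)
  expect_equal(back$value, tr$value[keep])
  expect_equal(back$start, tr$start[keep])

  # grid track of 5 bins -> 5 lines
  g <- grid_track(c(10, 30, 50, 70, 90), 1:5, 20)
  path2 <- withr::local_tempfile()
  write_track(g, path2)
  expect_equal(nrow(read_track(path2)), 5L)
})
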