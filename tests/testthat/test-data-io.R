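# Segment/metadata/map readers, relatedness filter, generation grouping.

test_that("segment table round trip and validation", {
  segs <- data.frame(id1 = c("X1", "X2"), id2 = c("X2", "X3"),
                     chrom = c("c1", "c2"), length_cm = c(9.5, 12.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ibd_segments(segs, path)
  back <- read_ibd_segments(path)
  expect_equal(back, segs)
  # malformed rows are rejected with line numbers
  bad <- rbind(segs, data.frame(id1 = "X4", id2 = "X4", chrom = "c1",
                                length_cm = 10))
  write_ibd_segments(bad, path)
  expect_error(read_ibd_segments(path), "line\\(s\\): 4")
  bad2 <- rbind(segs, data.frame(id1 = "X4", id2 = "X5", chrom = "c1",
                                 length_cm = -3))
  write_ibd_segments(bad2, path)
  expect_error(read_ibd_segments(path), "malformed")
  writeLines("id1\tid2\tchrom", path)
  expect_error(read_ibd_segments(path), "length_cm")
  expect_error(read_ibd_segments(file.path(tempdir(), "nope.tsv")), "not found")
  # packaged synthetic fixture parses
  fx <- read_ibd_segments(system.file("extdata", "ibd_constant_ne_synthetic.tsv",
                                      package = "ibdtransect"))
  expect_gt(nrow(fx), 50)
  expect_true(all(fx$length_cm >= 8 & fx$length_cm < 20))
})

test_that("start/end consistency is enforced when present", {
  path <- withr::local_tempfile(fileext = ".tsv")
  segs <- data.frame(id1 = "X1", id2 = "X2", chrom = "c1", length_cm = 10,
                     start_cm = 5, end_cm = 15)
  write_ibd_segments(segs, path)
  expect_silent(read_ibd_segments(path))
  segs$end_cm <- 20
  write_ibd_segments(segs, path)
  expect_error(read_ibd_segments(path), "malformed")
})

test_that("relatedness filter applies both kin thresholds and keeps coverage", {
  meta <- data.frame(id = c("P1", "P2", "Q1", "Q2", "R1", "R2"),
                     date = 0, date_unit = "BP",
                     coverage = c(2.0, 0.5, 1.0, 3.0, 1.0, 1.0))
  seg <- function(a, b, l) data.frame(id1 = a, id2 = b, chrom = "c1", length_cm = l)
  segs <- rbind(
    seg("P1", "P2", 13), seg("P1", "P2", 14), seg("P1", "P2", 15), # 3 segments > 12
    seg("Q1", "Q2", 101),                                          # sum > 100
    seg("R1", "R2", 12.5), seg("R1", "R2", 12.5))                  # neither rule
  res <- relatedness_filter(segs, meta)
  expect_setequal(res$removed, c("P2", "Q1"))  # lower coverage goes
  expect_true(all(c("P1", "Q2", "R1", "R2") %in% res$kept))
  expect_equal(nrow(res$flagged_pairs), 2)
  # exactly at the boundary: two 12.5 cM segments (2 < 3 segments, 25 < 100)
  expect_false(any(res$flagged_pairs$id1 == "R1"))
})

test_that("generation grouping: windows, anchoring, translation invariance", {
  meta1 <- data.frame(id = c("a", "b", "c"), date = c(500, 500, 500),
                      date_unit = "BP", coverage = 1)
  s1 <- group_by_generations(meta1)
  expect_equal(s1$n_sets, 1L)
  expect_equal(s1$times, 0L)
  # 150 years at 29 yr/gen = 5.17 generations -> window [5, 10) -> time 5
  meta2 <- data.frame(id = c("young", "old"), date = c(0, 150),
                      date_unit = "BP", coverage = 1)
  s2 <- group_by_generations(meta2)
  expect_equal(s2$times, c(0L, 5L))
  expect_equal(unlist(s2$ids), c("young", "old"), ignore_attr = TRUE)
  # uniform date translation leaves the grouping unchanged
  meta3 <- meta2
  meta3$date <- meta3$date + 2300
  s3 <- group_by_generations(meta3)
  expect_equal(s3$times, s2$times)
  # CE dates convert via 1950
  meta4 <- data.frame(id = c("young", "old"), date = c(1950, 1800),
                      date_unit = "CE", coverage = 1)
  expect_equal(group_by_generations(meta4)$times, c(0L, 5L))
  expect_error(group_by_generations(meta1[0, ]), "empty")
})

test_that("time-transect grouping reproduces a four-cluster design", {
  # metadata engineered so grouping by five generations at 29 yr/gen yields
  # four sets of 12, 12, 10 and 7 individuals
  sizes <- c(12, 12, 10, 7)
  windows <- c(0, 1, 2, 4)   # window indices (the third window is empty)
  dates <- unlist(mapply(function(w, n) 4600 + w * 5 * 29 + seq(0, 140, length.out = n),
                         windows, sizes))
  meta <- data.frame(id = sprintf("CW%02d", seq_along(dates)), date = dates,
                     date_unit = "BP", coverage = 1)
  sch <- group_by_generations(meta)
  expect_equal(sch$sizes, sizes, ignore_attr = TRUE)
  expect_equal(sch$times, as.integer(windows * 5))
})

test_that("map reader and trajectory writer", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tlength_morgan", "c1\t2.0", "c2\t1.5"), path)
  cmap <- read_chromosome_map(path)
  expect_equal(as.numeric(cmap), c(2.0, 1.5))
  expect_equal(names(cmap), c("c1", "c2"))
  writeLines(c("chrom\tlength_morgan", "c1\t-1"), path)
  expect_error(read_chromosome_map(path), "positive")
  fit <- structure(list(ne = c(1000, 1200, 1100)), class = "ne_fit")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(fit, out)
  tab <- read.table(out, header = TRUE, sep = "\t")
  expect_equal(tab$generation, 0:2)
  expect_equal(tab$ne, fit$ne, tolerance = 1e-8)
})
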