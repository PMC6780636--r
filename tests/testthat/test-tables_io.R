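test_that("a written cohort reads back to numerical identity", {
  coh <- smallCohort(seed = 1L)
  dir <- withr::local_tempdir()
  writeCohortTables(coh, dir)
  back <- readCohort(file.path(dir, "abundance.tsv"),
                     file.path(dir, "peaks.tsv"),
                     file.path(dir, "metadata.tsv"), strict = TRUE)
  expect_lt(max(abs(abundances(back) - abundances(coh))), 1e-12)
  expect_lt(max(abs(peakAreas(back) - peakAreas(coh))), 1e-9 *
              max(peakAreas(coh)))
  expect_identical(levels(sampleGroups(back)), levels(sampleGroups(coh)))
  expect_identical(rownames(sampleData(back)), rownames(sampleData(coh)))
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("count tables are renormalized to proportions on read", {
  dir <- withr::local_tempdir()
  ids <- paste0("s", 1:4)
  counts <- matrix(rpois(12, 50) + 1L, 4, 3,
                   dimnames = list(ids, paste0("g", 1:3)))
  write.table(data.frame(sample_id = ids, counts),
              file.path(dir, "ab.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pk <- matrix(rexp(8), 4, 2, dimnames = list(ids, c("p1", "p2")))
  write.table(data.frame(sample_id = ids, pk), file.path(dir, "pk.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = ids, group = c("a", "a", "b", "b"),
                   age = 50, hcq = 0, prednisone_gt5 = 0,
                   immunosuppressant = 0)
  write.table(md, file.path(dir, "md.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  coh <- readCohort(file.path(dir, "ab.tsv"), file.path(dir, "pk.tsv"),
                    file.path(dir, "md.tsv"))
  expect_equal(unname(rowSums(abundances(coh))), rep(1, 4))
  expect_equal(unname(abundances(coh)[1, ]),
               unname(counts[1, ] / sum(counts[1, ])))
})

test_that("alignment is by id intersection, strict mode names the gap", {
  dir <- withr::local_tempdir()
  mk <- function(ids, file, extra = NULL) {
    df <- data.frame(sample_id = ids, g1 = seq_along(ids),
                     g2 = rev(seq_along(ids)))
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  mk(paste0("s", 1:5), "ab.tsv")
  mk(paste0("s", 1:5), "pk.tsv")
  md <- data.frame(sample_id = paste0("s", 1:4), group = "a", age = 1,
                   hcq = 0, prednisone_gt5 = 0, immunosuppressant = 0)
  write.table(md, file.path(dir, "md.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_message(coh <- readCohort(file.path(dir, "ab.tsv"),
                                   file.path(dir, "pk.tsv"),
                                   file.path(dir, "md.tsv")), "s5")
  expect_equal(nrow(abundances(coh)), 4L)
  expect_error(readCohort(file.path(dir, "ab.tsv"), file.path(dir, "pk.tsv"),
                          file.path(dir, "md.tsv"), strict = TRUE), "s5")
})

test_that("malformed tables fail with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tg1", "s1\t0.5", "s1\t0.5"),
             file.path(dir, "dup.tsv"))
  expect_error(micromet:::.readTable(file.path(dir, "dup.tsv"), "abundance"),
               "duplicate")
  writeLines(c("sample_id\tg1\tg2", "s1\t0.5\tok", "s2\t0.5\t0.1"),
             file.path(dir, "bad.tsv"))
  expect_error(micromet:::.readTable(file.path(dir, "bad.tsv"), "abundance"),
               "non-numeric")
  writeLines(c("id\tg1", "s1\t1"), file.path(dir, "noid.tsv"))
  expect_error(micromet:::.readTable(file.path(dir, "noid.tsv"), "peaks"),
               "sample_id")
})

test_that("CSV input is accepted by sniffing", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id,g1,g2", "s1,3,1", "s2,1,3"),
             file.path(dir, "ab.csv"))
  m <- micromet:::.readTable(file.path(dir, "ab.csv"), "abundance")
  expect_equal(m["s1", "g1"], 3)
})

test_that("result writing is shape-faithful and hash-reproducible", {
  coh <- smallCohort(seed = 2L)
  G <- abundances(coh)[, 1:3]
  M <- peakAreas(coh)[, 1:4]
  res <- pminAdjust(G, M, confounderMatrix(coh), B = 20, seed = 3)
  y <- factor(rep(c("a", "b", "c"), c(4, 4, 4)))
  sc <- matrix(1 / 3, 12, 3, dimnames = list(NULL, levels(y)))
  ms <- pairwiseMetrics(y, y, sc)
  d1 <- file.path(withr::local_tempdir(), "o1")
  d2 <- file.path(withr::local_tempdir(), "o2")
  m1 <- writeResults(list(cc = res, metrics = ms, cfg = runConfig()), d1)
  m2 <- writeResults(list(cc = res, metrics = ms, cfg = runConfig()), d2)
  expect_identical(m1$md5, m2$md5)
  rmat <- read.table(file.path(d1, "cc_r.tsv"), header = TRUE, sep = "\t",
                     row.names = 1)
  expect_equal(dim(rmat), c(3L, 4L))
  mtab <- read.table(file.path(d1, "metrics_metrics.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(mtab), choose(3, 2) + 1L)  # pairs + weighted-mean row
  expect_error(writeResults(list(cc = res), d1), "exists")
  expect_true(file.exists(file.path(d1, "MANIFEST.tsv")))
})
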