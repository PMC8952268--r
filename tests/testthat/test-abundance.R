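test_that("abundance tables parse, infer mode and round-trip", {
  tab <- toy_counts()
  expect_equal(abund_mode(tab), "counts")
  expect_equal(unname(rowSums(tab)), c(4, 4))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, tmp)
  back <- read_abundance_table(tmp)
  expect_equal(unclass(back), unclass(tab))
  expect_equal(abund_mode(back), "counts")

  rel <- to_relative(tab)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_abundance_table(rel, tmp2)
  back2 <- read_abundance_table(tmp2)
  expect_equal(abund_mode(back2), "relative")
  expect_identical(unclass(back2), unclass(rel)) # bit-exact round trip

  # a second write of the re-read table is byte-identical (idempotent)
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_abundance_table(back2, tmp3)
  expect_identical(readLines(tmp2), readLines(tmp3))
})

test_that("malformed abundance input is rejected with a clear error", {
  m <- matrix(1:4, 2, dimnames = list(c("s1", "s1"), c("a1", "a2")))
  expect_error(abundance_table(m), "duplicate sample ids")
  m2 <- matrix(c(-1, 2, 3, 4), 2, dimnames = list(c("s1", "s2"), c("a1", "a2")))
  expect_error(abundance_table(m2), "negative")
  # non-integer rows that do not sum to one: ambiguous, names the row
  m3 <- matrix(c(0.2, 0.5, 0.5, 0.5), 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("a1", "a2")))
  expect_error(abundance_table(m3), "s1")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\ta1\ta2", empty)
  expect_error(read_abundance_table(empty), "no samples")
  expect_error(read_abundance_table("does/not/exist.tsv"), "not found")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  sim <- .small_sim()
  depth <- 500
  rar <- rarefy(sim$abundance, depth, seed = 7)
  expect_true(all(rowSums(rar) == depth))
  expect_true(all(unclass(rar) <= unclass(sim$abundance)))
  # deterministic given seed
  expect_identical(unclass(rarefy(sim$abundance, depth, seed = 7)),
                   unclass(rar))

  # a sample holding exactly `depth` reads is returned unchanged
  m <- matrix(c(7, 3, 500, 100), 2, byrow = TRUE,
              dimnames = list(c("low", "hi"), c("a1", "a2")))
  expect_warning(r2 <- rarefy(abundance_table(m), 600, seed = 1), "low")
  expect_equal(unclass(r2)["hi", ], c(a1 = 500, a2 = 100))

  expect_error(rarefy(sim$abundance, 0), "positive")
  expect_error(rarefy(to_relative(sim$abundance), 10), "counts-mode")
})

test_that("rarefaction draw matches the hypergeometric mean", {
  # counts [5, 5], depth 2: exhaustive enumeration of 2-draws from the
  # 10-read pool gives E[ASV1 drawn] = 2 * 5/10 = 1
  m <- matrix(c(5, 5), 1, dimnames = list("s", c("a1", "a2")))
  tab <- abundance_table(m)
  draws <- vapply(1:400, function(s) unclass(rarefy(tab, 2, seed = s))[1, "a1"], 0)
  expect_equal(mean(draws), 1, tolerance = 0.08)
  expect_true(all(draws %in% 0:2))
})

test_that("relative abundances are row closures of the counts", {
  sim <- .small_sim()
  rel <- to_relative(sim$abundance)
  expect_equal(unname(rowSums(rel)), rep(1, nrow(rel)))
  # oracle: elementwise division by the row total
  expect_equal(unclass(rel), sweep(unclass(sim$abundance), 1,
                                   rowSums(sim$abundance), "/"),
               ignore_attr = TRUE)

  expect_equal(unname(unclass(to_relative(toy_counts()))[1, ]), c(0.75, 0.25))
  one <- abundance_table(matrix(c(13518, 0), 1,
                                dimnames = list("s", c("a1", "a2"))))
  expect_equal(unname(unclass(to_relative(one))[1, ]), c(1, 0))
  zero <- matrix(c(0, 0, 1, 2), 2, byrow = TRUE,
                 dimnames = list(c("bad", "ok"), c("a1", "a2")))
  expect_error(to_relative(abundance_table(zero)), "bad")
})

test_that("productivity and yield derivations follow the C-mol accounting", {
  expect_equal(derive_productivity(0, 5), 0)
  expect_equal(derive_productivity(100, 2), 50)
  # halving the HRT doubles productivity at fixed concentration
  expect_equal(derive_productivity(80, 2), 2 * derive_productivity(80, 4))
  expect_error(derive_productivity(10, 0), "positive")

  # linearity: mean productivity of a series equals mean(conc)/hrt
  conc <- c(12, 40, 33, 8.5)
  expect_equal(mean(derive_productivity(conc, 4)), mean(conc) / 4)

  expect_equal(derive_yield(0, 100), 0)
  expect_equal(derive_yield(30, 120), 0.25)
  expect_error(derive_yield(10, 0), "positive")

  expect_equal(mmol_to_cmol(10, "C6"), 60)
  expect_equal(mmol_to_cmol(1, "xylose"), 5)
  expect_error(mmol_to_cmol(1, "glucose"), "unknown compound")
})

test_that("sampling intervals and HRT labels follow the operation schedule", {
  md <- data.frame(day = c(0, 50, 51, 100, 101, 120, 140, 141, 211))
  out <- assign_interval_and_label(md)
  expect_equal(as.character(out$interval),
               c("0-50", "0-50", "51-100", "51-100", "101-140", "101-140",
                 "101-140", "141-211", "141-211"))
  expect_equal(as.character(out$hrt_label),
               c("HRT8", "HRT8", NA, NA, NA, NA, NA, "HRT2", "HRT2"))
  expect_error(assign_interval_and_label(data.frame(day = 212)), "0-211")
  expect_error(assign_interval_and_label(data.frame(day = -1)), "0-211")
})

test_that("metadata reader derives productivities only when absent", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  md <- data.frame(sample_id = c("s1", "s2"), reactor = c("A", "B"),
                   day = c(10, 150), hrt = c(8, 2),
                   conc_C6 = c(80, 100), prod_C6 = c(11, 52))
  utils::write.table(md, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_metadata(tmp)
  expect_equal(out$prod_C6, c(11, 52)) # measured rates win
  expect_equal(as.character(out$hrt_label), c("HRT8", "HRT2"))

  md$prod_C6 <- NULL
  utils::write.table(md, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  out2 <- read_metadata(tmp)
  expect_equal(out2$prod_C6, c(10, 50)) # conc / hrt fallback

  md2 <- md; md2$hrt <- NULL
  utils::write.table(md2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(tmp), "hrt")
})
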