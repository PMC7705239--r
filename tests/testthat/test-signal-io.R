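# File formats: Bonn-style ASCII, UCI-style CSV, report CSV/JSON.

test_that("ASCII records read back in file order, skipping blanks", {
  p <- tempfile()
  writeLines(c("1.0", "-2.5", "", "  3.25  ", ""), p)
  rec <- read_bonn_record(p, "A", 0)
  expect_equal(rec$samples, c(1.0, -2.5, 3.25))
  expect_equal(rec$set_id, "A")
})

test_that("ASCII reader errors name the offending line and reject empty files", {
  p <- tempfile()
  writeLines(c("1.0", "abc", "2.0"), p)
  expect_error(read_bonn_record(p, "A", 0), "line 2")
  writeLines(character(0), p)
  expect_error(read_bonn_record(p, "A", 0), "empty")
  expect_error(read_bonn_record(tempfile(), "A", 0), "not found")
})

test_that("a 4097-line file round-trips losslessly through write and read", {
  set.seed(5)
  vals <- rnorm(4097) * 100
  p <- write_ascii_record(vals)
  rec <- read_bonn_record(p, "E", 7)
  expect_equal(length(rec$samples), 4097L)
  expect_identical(rec$samples, vals)   # bit-exact at %.17g
})

test_that("UCI labels remap to canonical sets (1=E ... 5=A)", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("X1,X2,X3,y", "0.5,1,2,1", "3,4,5,1", "6,7,8,5"), p)
  tab <- read_uci_csv(p)
  expect_equal(tab$provenance$set_id, c("E", "E", "A"))
  expect_equal(tab$labels, c(4L, 4L, 0L))   # set indices A=0..E=4
  expect_equal(tab$segments[1, ], c(0.5, 1, 2))
})

test_that("header-only UCI file yields an empty table; bad labels error", {
  p <- tempfile(fileext = ".csv")
  writeLines("X1,X2,X3,y", p)
  tab <- read_uci_csv(p)
  expect_equal(n_segments(tab), 0L)

  writeLines(c("X1,X2,X3,y", "1,2,3,6"), p)
  expect_error(read_uci_csv(p), "1..5")
  writeLines(c("X1,X2,X3,z", "1,2,3,4"), p)
  expect_error(read_uci_csv(p), "'y'")
})

test_that("UCI id column provides provenance when present", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,X1,X2,y", "S.E.4.21,1,2,1", "S.A.0.3,3,4,5"), p)
  tab <- read_uci_csv(p)
  expect_equal(tab$provenance$record_index, c(4L, 0L))
  expect_equal(tab$provenance$chunk_index, c(21L, 3L))
})

test_that("synthetic writer and readers round-trip both layouts", {
  spec <- synthetic_spec(n_records_per_set = 2, record_length = 92, seed = 3)
  recs <- generate_bonn_like(spec, sets = c("A", "E"))
  d <- file.path(tempdir(), "bonn_rt")
  write_synthetic(recs, d, "bonn_ascii")
  back <- read_bonn_dir(d, sets = c("A", "E"))
  expect_equal(length(back), 4L)
  expect_identical(back[[1]]$samples, recs[[1]]$samples)

  d2 <- file.path(tempdir(), "uci_rt")
  f <- write_synthetic(recs, d2, "uci_csv")
  tab <- read_uci_csv(f)
  expect_equal(n_segments(tab), 4 * 23)
  direct <- segment_records(recs)
  expect_identical(tab$segments, direct$segments)
  expect_equal(tab$provenance$set_id, direct$provenance$set_id)
})

test_that("reports round-trip bit-exactly and enforce completeness", {
  set.seed(9)
  folds <- matrix(runif(5 * 10), 5, 10,
                  dimnames = list(c("accuracy", "precision", "sensitivity",
                                    "specificity", "f1"), NULL))
  rep1 <- eval_report("A-E", folds)
  expect_equal(unname(rep1$mean["accuracy"]), mean(folds[1, ]))

  p <- file.path(tempdir(), "rep.csv")
  write_report(rep1, p)
  expect_true(file.exists(p))
  expect_true(file.exists(file.path(tempdir(), "rep.json")))
  back <- read_report(p)
  expect_identical(back$folds, rep1$folds)
  expect_identical(back$mean, rep1$mean)

  # constant folds give that constant as the mean
  repc <- eval_report("B-E", matrix(1, 5, 10,
                                    dimnames = list(rownames(folds), NULL)))
  expect_true(all(repc$mean == 1))

  # a missing fold is a completeness error
  folds[3, 7] <- NA
  expect_error(write_report(eval_report("A-E", folds), p), "missing fold")
})

test_that("report CSV uses the task/metric/k1..k10/mean layout in percent", {
  folds <- matrix(0.5, 5, 10,
                  dimnames = list(c("accuracy", "precision", "sensitivity",
                                    "specificity", "f1"), NULL))
  p <- file.path(tempdir(), "layout.csv")
  write_report(eval_report("CD-E", folds), p)
  df <- read.csv(p, check.names = FALSE)
  expect_equal(names(df), c("task", "metric", paste0("k", 1:10), "mean"))
  expect_equal(df$task[1], "CD-E")
  expect_equal(df$mean, rep(50, 5))
})
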