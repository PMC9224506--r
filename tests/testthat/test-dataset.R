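write_csv_fixture <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE)
  tmp
}

test_that("reading converts linear values to log10 and keeps log values as-is", {
  df <- data.frame(id = c("a", "b"), cas = c("50-00-0", ""),
                   smiles = c("C=O", "CCO"), value = c(100, 10))
  p <- write_csv_fixture(df)
  lin <- read_dataset(p, value_scale = "linear")
  expect_equal(lin$value, c(2, 1))
  logd <- read_dataset(p, value_scale = "log10")
  expect_equal(logd$value, c(100, 10))
  unlink(p)
})

test_that("parse errors name the offending row and column", {
  p <- write_csv_fixture(data.frame(id = c("a", "b"), cas = "",
                                    smiles = "C", value = c("1.0", "abc")))
  expect_error(read_dataset(p), "row 2")
  unlink(p)
  p2 <- write_csv_fixture(data.frame(id = "a", cas = "", smiles = "C",
                                     value = -5))
  expect_error(read_dataset(p2, value_scale = "linear"), "non-positive")
  unlink(p2)
  p3 <- write_csv_fixture(data.frame(id = "a", smiles = "C", value = 1))
  expect_error(read_dataset(p3), "cas")
  unlink(p3)
})

test_that("curation applies the standard rejection rules with reason codes", {
  rec <- data.frame(
    id = as.character(1:7),
    cas = c("1-1", "1-1", "", "", "", "", ""),
    smiles = c("CCO", "CCN", "[Na+].[Cl-]", "CC[Si](C)C", "CCCC", "CCCC", "C(C"),
    value = c(2.0, 1.0, 1.0, 1.0, 3.0, 2.5, 1.0),
    stringsAsFactors = FALSE
  )
  cur <- curate_dataset(rec)
  # duplicate CAS collapses to the lowest (most conservative) value
  kept_cas <- cur$kept[cur$kept$cas == "1-1", ]
  expect_equal(nrow(kept_cas), 1)
  expect_equal(kept_cas$value, 1.0)
  expect_true("duplicate" %in% cur$rejected$reason)
  # mixtures/salts and non-organic elements are rejected
  expect_equal(cur$rejected$reason[cur$rejected$id == "3"], "multi_fragment")
  expect_equal(cur$rejected$reason[cur$rejected$id == "4"], "non_organic")
  expect_equal(cur$rejected$reason[cur$rejected$id == "7"], "malformed_smiles")
  # duplicate SMILES (empty CAS) also collapse to the minimum
  kept_smi <- cur$kept[cur$kept$smiles == "CCCC", ]
  expect_equal(nrow(kept_smi), 1)
  expect_equal(kept_smi$value, 2.5)
})

test_that("paired NOAEL/LOAEL tables drop rows violating NOAEL <= LOAEL", {
  rec <- data.frame(id = c("a", "b"), cas = "", smiles = c("CCO", "CCN"),
                    value = c(1.7, 1.0), value2 = c(1.0, 1.7),
                    stringsAsFactors = FALSE)
  cur <- curate_dataset(rec)
  expect_equal(cur$kept$id, "b")
  expect_equal(cur$rejected$reason, "noael_gt_loael")
})

test_that("curation is idempotent and partitions the input", {
  set.seed(1)
  lib <- generate_library(40, seed = 13)
  rec <- data.frame(id = as.character(1:44), cas = "",
                    smiles = c(lib, "[Na+].[Cl-]", "CC[Hg]C", lib[1], lib[2]),
                    value = c(rnorm(40), 1, 1, 99, -99),
                    stringsAsFactors = FALSE)
  cur <- curate_dataset(rec)
  expect_equal(nrow(cur$kept) + nrow(cur$rejected), nrow(rec))
  expect_length(intersect(cur$kept$id, cur$rejected$id), 0)
  again <- curate_dataset(cur$kept)
  expect_identical(again$kept, cur$kept)
  expect_equal(nrow(again$rejected), 0)
})

test_that("the optional low-frequency tail trim drops sparse extreme bins", {
  rec <- data.frame(id = as.character(1:12), cas = "",
                    smiles = generate_library(12, seed = 14),
                    value = c(-3.9, rep(1, 5), rep(1.2, 5), 6.2),
                    stringsAsFactors = FALSE)
  cur <- curate_dataset(rec, tail_min_count = 2)
  expect_setequal(cur$rejected$reason, "low_frequency_tail")
  expect_equal(nrow(cur$rejected), 2)
  expect_false(any(cur$kept$value %in% c(-3.9, 6.2)))
  # off by default
  expect_equal(nrow(curate_dataset(rec)$rejected), 0)
})

test_that("write_dataset emits the curated CSV and the rejection log", {
  rec <- data.frame(id = c("a", "b"), cas = "", smiles = c("CCO", "[Na+].[Cl-]"),
                    value = c(1, 2), stringsAsFactors = FALSE)
  cur <- curate_dataset(rec)
  out <- tempfile(fileext = ".csv"); rej <- tempfile(fileext = ".csv")
  write_dataset(cur, out, rej)
  expect_equal(read.csv(out, stringsAsFactors = FALSE)$id, "a")
  rejdf <- read.csv(rej, stringsAsFactors = FALSE)
  expect_equal(rejdf$reason, "multi_fragment")
  unlink(c(out, rej))
})
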