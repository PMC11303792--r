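# Loading, cleaning, discretization and one-hot encoding of the
# clinical records table.

test_that("CSV loading parses, preserves order and accepts header dialects", {
  rec <- makeRawRecords(25, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRecordsCSV(rec, path,
                  headers = c("age", "sex", "chest pain type",
                              "resting bp s", "cholesterol",
                              "fasting blood sugar", "resting ecg",
                              "max heart rate", "exercise angina",
                              "oldpeak", "ST slope", "target"))
  got <- loadRawRecords(path)
  expect_identical(names(got), rareRules:::HEART_COLUMNS)
  expect_equal(nrow(got), 25)
  expect_equal(got$age, rec$age)
  expect_equal(got$oldpeak, rec$oldpeak)
})

test_that("CSV loading errors name the offending column or cell", {
  rec <- makeRawRecords(5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRecordsCSV(rec[, setdiff(names(rec), "oldpeak")], path)
  expect_error(loadRawRecords(path), "oldpeak")

  rec2 <- makeRawRecords(5)
  rec2$cholesterol <- as.character(rec2$cholesterol)
  rec2$cholesterol[3] <- "high"
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeRecordsCSV(rec2, path2)
  expect_error(loadRawRecords(path2), "cholesterol.*row 3|row 3.*cholesterol")

  expect_error(loadRawRecords(withr::local_tempfile()), "not found")
})

test_that("a header-only CSV yields an empty table without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeRecordsCSV(makeRawRecords(1)[0, ], path)
  got <- loadRawRecords(path)
  expect_equal(nrow(got), 0)
})

test_that("cleaning removes exactly the ST-slope-0 rows, in order", {
  rec <- makeRawRecords(10, seed = 7)
  rec$st_slope[c(4, 8)] <- 0
  out <- cleanRecords(rec)
  expect_equal(out$removed, 2)
  expect_equal(nrow(out$records), 8)
  expect_equal(out$records$age, rec$age[-c(4, 8)])

  # identity when nothing to remove
  clean <- makeRawRecords(6, seed = 1)
  out2 <- cleanRecords(clean)
  expect_equal(out2$removed, 0)
  expect_equal(out2$records, clean)

  # single offending row -> empty table
  one <- makeRawRecords(1)
  one$st_slope <- 0
  out3 <- cleanRecords(one)
  expect_equal(out3$removed, 1)
  expect_equal(nrow(out3$records), 0)
})

test_that("discretization maps values to the expected bins", {
  rec <- makeRawRecords(6, seed = 2)
  rec$age <- c(45, 72, 30, 29, 61, 60)
  rec$cholesterol <- c(0, 200, 201, 240, 241, 350)
  rec$max_heart_rate <- c(100, 101, 160, 161, 99, 180)
  rec$oldpeak <- c(2.5, 1.0, 1.1, 2.0, 0.0, -0.5)
  got <- discretizeRecords(rec)
  expect_equal(got$age, c("maged", "elderly", "young", "young",
                          "elderly", "maged"))
  expect_equal(got$cholesterol, c("lcol", "lcol", "ncol", "ncol",
                                  "hcol", "hcol"))
  expect_equal(got$max_heart_rate, c("hrlow", "hrnormal", "hrnormal",
                                     "hrhigh", "hrlow", "hrhigh"))
  expect_equal(got$oldpeak, c("peakhigh", "peaklow", "peakmoderate",
                              "peakmoderate", "peaklow", "peaklow"))
  # untouched columns
  expect_equal(got$sex, rec$sex)
})

test_that("discretization guards out-of-range values and re-application", {
  rec <- makeRawRecords(3)
  rec$age[2] <- -4
  expect_error(discretizeRecords(rec), "age.*row 2|row 2")

  ok <- discretizeRecords(makeRawRecords(3))
  expect_error(discretizeRecords(ok), "already discretized")
})

test_that("encoding is one-hot within groups and covers present categories", {
  rec <- discretizeRecords(makeRawRecords(120, seed = 11))
  ds <- encodeTransactions(rec)
  expect_s4_class(ds, "TransactionSet")
  expect_equal(nTransactions(ds), 120)
  info <- itemInfo(ds)
  mat <- transactionMatrix(ds)
  for (g in unique(info$attribute)) {
    cols <- info$item[info$attribute == g]
    expect_true(all(rowSums(mat[, cols, drop = FALSE]) == 1), label = g)
  }
  # with 120 random rows every category of the 10 attributes shows up
  expect_equal(nItems(ds), 27)
  expect_error(validObject(ds), NA)
})

test_that("encoding is local: records differing in one attribute differ only there", {
  rec <- discretizeRecords(makeRawRecords(2, seed = 5))
  rec[2, ] <- rec[1, ]
  rec$sex <- c(0, 1)
  ds <- encodeTransactions(rec)
  mat <- transactionMatrix(ds)
  sex_cols <- intersect(colnames(mat), c("F", "M"))
  other <- setdiff(colnames(mat), sex_cols)
  expect_equal(mat[1, other], mat[2, other])
  expect_false(all(mat[1, sex_cols] == mat[2, sex_cols]))
})

test_that("a minimal two-feature record encodes to its forced transaction", {
  rec <- data.frame(sex = 1, target = 1)
  ds <- encodeTransactions(rec, selectedFeatures = c("sex", "target"))
  expect_equal(sort(itemNames(ds)[transactionMatrix(ds)[1, ]]),
               c("M", "yes"))
})

test_that("unknown category labels are reported by name", {
  rec <- discretizeRecords(makeRawRecords(4))
  rec$st_slope <- c("usloping", "sideways", "flat", "dsloping")
  expect_error(encodeTransactions(rec), "sideways")
})

test_that("decode/encode round-trips a transaction set exactly", {
  rec <- discretizeRecords(makeRawRecords(40, seed = 9))
  ds <- encodeTransactions(rec)
  labels <- decodeTransactions(ds)
  ds2 <- rareRules:::encodeFromLabels(labels, heartItemVocabulary())
  expect_identical(transactionMatrix(ds2)[, itemNames(ds)],
                   transactionMatrix(ds))
})

test_that("transaction export formats round-trip content", {
  rec <- discretizeRecords(makeRawRecords(10, seed = 4))
  ds <- encodeTransactions(rec)
  csv <- withr::local_tempfile(fileext = ".csv")
  exportTransactions(ds, csv, "csv")
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(colnames(back), itemNames(ds))
  expect_equal(unname(as.matrix(back)), unname(transactionMatrix(ds)) * 1L)
  txt <- withr::local_tempfile(fileext = ".txt")
  exportTransactions(ds, txt, "itemlist")
  lines <- readLines(txt)
  expect_length(lines, 10)
  expect_setequal(strsplit(lines[1], " ")[[1]],
                  itemNames(ds)[transactionMatrix(ds)[1, ]])
})
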