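# Reading, cleaning, discretizing and encoding the 12-column combined
# heart-disease records table into a boolean TransactionSet.

# canonical column names, in table order
HEART_COLUMNS <- c("age", "sex", "chest_pain_type", "resting_bp",
                   "cholesterol", "fasting_blood_sugar", "resting_ecg",
                   "max_heart_rate", "exercise_angina", "oldpeak",
                   "st_slope", "target")

# the ten attributes retained for mining (union of the top features picked
# by five standard selectors on this dataset, plus the class)
HEART_SELECTED_FEATURES <- c("st_slope", "age", "chest_pain_type",
                             "cholesterol", "exercise_angina",
                             "fasting_blood_sugar", "max_heart_rate",
                             "oldpeak", "sex", "target")

# header dialects seen in the wild for this table; keys are the headers
# after lowercasing and stripping non-alphanumerics
.header_aliases <- c(
  age = "age",
  sex = "sex",
  chestpaintype = "chest_pain_type",
  restingbps = "resting_bp",
  restingbp = "resting_bp",
  restingbloodpressure = "resting_bp",
  cholesterol = "cholesterol",
  serumcholesterol = "cholesterol",
  fastingbloodsugar = "fasting_blood_sugar",
  restingecg = "resting_ecg",
  restingecgresults = "resting_ecg",
  maxheartrate = "max_heart_rate",
  maximumheartrateachieved = "max_heart_rate",
  exerciseangina = "exercise_angina",
  exerciseinducedangina = "exercise_angina",
  oldpeak = "oldpeak",
  stslope = "st_slope",
  slopeofthepeakexercisestsegment = "st_slope",
  target = "target",
  class = "target"
)

normalizeHeader <- function(x) {
  canon <- unname(.header_aliases[gsub("[^a-z0-9]", "", tolower(x))])
  canon[is.na(canon)] <- x[is.na(canon)]
  canon
}

#' Load the raw clinical records table
#'
#' Reads a comma-separated, UTF-8, header-rowed CSV with the twelve
#' clinical columns (age, sex, chest pain type, resting blood pressure,
#' cholesterol, fasting blood sugar, resting ECG, max heart rate,
#' exercise angina, oldpeak, ST slope, target). Header matching is case-
#' and whitespace-insensitive with a small alias table (e.g. `"ST slope"`
#' and `"st_slope"` both work).
#'
#' @param path path to the CSV file.
#' @return data.frame with canonical column names, one row per data row,
#'   numeric columns, row order preserved. May have zero rows.
#' @export
loadRawRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  names(raw) <- normalizeHeader(names(raw))
  missing_cols <- setdiff(HEART_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), HEART_COLUMNS)
  if (length(extra))
    stop("unexpected extra column(s): ", paste(extra, collapse = ", "))
  raw <- raw[, HEART_COLUMNS, drop = FALSE]
  for (col in HEART_COLUMNS) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) &
                 trimws(raw[[col]]) != "")
    if (anyNA(vals) || length(bad)) {
      row1 <- if (length(bad)) bad[1] else which(is.na(vals))[1]
      stop(sprintf("unparseable value in column '%s', row %d: '%s'",
                   col, row1, raw[[col]][row1]))
    }
    raw[[col]] <- vals
  }
  rownames(raw) <- NULL
  raw
}

#' Clean the records table
#'
#' Removes rows with an ST-slope code of 0 (not a valid slope category;
#' in the combined dataset a single such row exists) and leaves every
#' other row untouched, in order.
#'
#' @param records data.frame from [loadRawRecords()].
#' @return list with `records` (the cleaned data.frame) and `removed`
#'   (number of rows dropped).
#' @export
cleanRecords <- function(records) {
  drop <- !is.na(records$st_slope) & records$st_slope == 0
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, removed = sum(drop))
}

#' Binning scheme for the four continuous attributes
#'
#' Left-open/right-closed intervals `(a, b]` (the `right = TRUE`
#' convention of [base::cut()]); the cholesterol left edge of -1 admits
#' the 0 values present in the combined dataset.
#'
#' @return named list, one entry per continuous attribute, each with
#'   `edges` (strictly increasing numeric) and `labels`
#'   (length `length(edges) - 1`).
#' @export
heartBinningScheme <- function() {
  list(
    age = list(edges = c(0, 30, 60, Inf),
               labels = c("young", "maged", "elderly")),
    cholesterol = list(edges = c(-1, 200, 240, Inf),
                       labels = c("lcol", "ncol", "hcol")),
    max_heart_rate = list(edges = c(0, 100, 160, Inf),
                          labels = c("hrlow", "hrnormal", "hrhigh")),
    oldpeak = list(edges = c(-Inf, 1.0, 2.0, Inf),
                   labels = c("peaklow", "peakmoderate", "peakhigh"))
  )
}

# raw categorical code -> item label, per attribute
.categorical_maps <- list(
  sex = c("0" = "F", "1" = "M"),
  chest_pain_type = c("1" = "tangina", "2" = "atangina",
                      "3" = "napain", "4" = "asym"),
  fasting_blood_sugar = c("0" = "fbsugar0", "1" = "fbsugar1"),
  exercise_angina = c("0" = "exangina0", "1" = "exangina1"),
  st_slope = c("1" = "usloping", "2" = "flat", "3" = "dsloping"),
  target = c("0" = "no", "1" = "yes")
)

#' Item vocabulary for the heart-disease schema
#'
#' The 27 abbreviated item names, grouped into mutually exclusive
#' attribute groups (one group per original attribute) plus the
#' `no`/`yes` class pair.
#'
#' @return data.frame with columns `item` and `attribute`.
#' @export
heartItemVocabulary <- function() {
  groups <- list(
    age = c("young", "maged", "elderly"),
    sex = c("F", "M"),
    chest_pain_type = c("tangina", "atangina", "napain", "asym"),
    cholesterol = c("lcol", "ncol", "hcol"),
    fasting_blood_sugar = c("fbsugar0", "fbsugar1"),
    max_heart_rate = c("hrlow", "hrnormal", "hrhigh"),
    exercise_angina = c("exangina0", "exangina1"),
    oldpeak = c("peaklow", "peakmoderate", "peakhigh"),
    st_slope = c("usloping", "flat", "dsloping"),
    target = c("no", "yes")
  )
  data.frame(
    item = unlist(groups, use.names = FALSE),
    attribute = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE
  )
}

#' Discretize the continuous attributes
#'
#' Replaces each continuous column covered by `scheme` with its bin
#' label; every other column is untouched. Applying it twice errors
#' (the labeled columns are no longer numeric) rather than silently
#' corrupting data.
#'
#' @param records cleaned records data.frame.
#' @param scheme binning scheme, see [heartBinningScheme()].
#' @param right logical; `TRUE` (default) for left-open/right-closed
#'   intervals `(a, b]`.
#' @return the data.frame with labeled columns (character).
#' @export
discretizeRecords <- function(records, scheme = heartBinningScheme(),
                              right = TRUE) {
  for (attr_name in names(scheme)) {
    if (!attr_name %in% names(records)) next
    x <- records[[attr_name]]
    if (!is.numeric(x))
      stop("column '", attr_name, "' is not numeric; already discretized?")
    sc <- scheme[[attr_name]]
    lab <- as.character(cut(x, breaks = sc$edges, labels = sc$labels,
                            right = right, include.lowest = FALSE))
    if (anyNA(lab)) {
      bad <- which(is.na(lab))[1]
      stop(sprintf("value %s in column '%s' (row %d) falls outside all bins",
                   format(x[bad]), attr_name, bad))
    }
    records[[attr_name]] <- lab
  }
  records
}

# labeled data.frame (one label column per attribute) -> TransactionSet;
# shared by encodeTransactions() and the synthetic generator
encodeFromLabels <- function(labels_df, vocab) {
  attrs <- names(labels_df)
  keep <- vocab[vocab$attribute %in% attrs, , drop = FALSE]
  # only items actually present in the data get a column, except the
  # class pair, which is kept whole so the outcome is always two-valued
  present <- unique(unlist(lapply(labels_df, unique)))
  class_items <- vocab$item[vocab$attribute == "target"]
  keep <- keep[keep$item %in% present |
                 keep$item %in% class_items, , drop = FALSE]
  m <- nrow(labels_df)
  mat <- matrix(FALSE, nrow = m, ncol = nrow(keep),
                dimnames = list(NULL, keep$item))
  for (attr_name in attrs) {
    items_g <- keep$item[keep$attribute == attr_name]
    lab <- labels_df[[attr_name]]
    unknown <- setdiff(unique(lab), vocab$item[vocab$attribute == attr_name])
    if (length(unknown))
      stop(sprintf("unknown category label '%s' for attribute '%s'",
                   unknown[1], attr_name))
    for (it in items_g) mat[, it] <- lab == it
  }
  TransactionSet(mat, itemInfo = keep,
                 classItems = if ("target" %in% attrs) c("no", "yes")
                              else character(0))
}

#' One-hot encode records into a TransactionSet
#'
#' Maps each selected attribute's value to its abbreviated item name
#' (bin label for the discretized attributes, coded category otherwise)
#' and builds the boolean occurrence matrix. Only categories actually
#' present in the data receive a column; within each attribute group
#' exactly one item is true per transaction.
#'
#' @param records discretized records data.frame.
#' @param vocab item vocabulary data.frame (default
#'   [heartItemVocabulary()]).
#' @param selectedFeatures attributes to encode; default the ten-feature
#'   set used for the combined heart dataset.
#' @return a [TransactionSet-class].
#' @export
encodeTransactions <- function(records, vocab = heartItemVocabulary(),
                               selectedFeatures = HEART_SELECTED_FEATURES) {
  missing_feat <- setdiff(selectedFeatures, names(records))
  if (length(missing_feat))
    stop("records lack selected feature(s): ",
         paste(missing_feat, collapse = ", "))
  if (nrow(records) == 0L)
    stop("cannot encode an empty records table")
  labels_df <- as.data.frame(
    lapply(setNames(selectedFeatures, selectedFeatures), function(a) {
      x <- records[[a]]
      if (is.numeric(x)) {
        mp <- .categorical_maps[[a]]
        if (is.null(mp))
          stop("attribute '", a, "' is numeric but not discretized")
        lab <- unname(mp[as.character(x)])
        if (anyNA(lab)) {
          bad <- which(is.na(lab))[1]
          stop(sprintf("unknown category label '%s' for attribute '%s' (row %d)",
                       format(x[bad]), a, bad))
        }
        lab
      } else {
        as.character(x)
      }
    }), stringsAsFactors = FALSE)
  # keep vocabulary (and thus column) order canonical
  labels_df <- labels_df[, intersect(unique(vocab$attribute),
                                     selectedFeatures), drop = FALSE]
  encodeFromLabels(labels_df, vocab)
}

#' Decode a TransactionSet back to attribute labels
#'
#' Inverse of [encodeTransactions()] at the label level: one column per
#' attribute group, holding the item that is true in each transaction.
#'
#' @param ts a [TransactionSet-class].
#' @return data.frame of attribute -> label, one row per transaction.
#' @export
decodeTransactions <- function(ts) {
  info <- itemInfo(ts)
  mat <- transactionMatrix(ts)
  out <- lapply(setNames(unique(info$attribute), unique(info$attribute)),
                function(g) {
    items_g <- info$item[info$attribute == g]
    sub <- mat[, items_g, drop = FALSE]
    items_g[max.col(sub, ties.method = "first")]
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a TransactionSet to disk
#'
#' `"csv"` writes a 0/1 matrix with item-name headers; `"itemlist"`
#' writes one transaction per line, item names space-separated (the
#' common interchange format of association-rule-mining tools).
#'
#' @param ts a [TransactionSet-class].
#' @param path output file path.
#' @param format `"csv"` or `"itemlist"`.
#' @return `path`, invisibly.
#' @export
exportTransactions <- function(ts, path, format = c("csv", "itemlist")) {
  format <- match.arg(format)
  mat <- transactionMatrix(ts)
  if (format == "csv") {
    utils::write.csv(as.data.frame(mat * 1L), path, row.names = FALSE)
  } else {
    lines <- apply(mat, 1L, function(r) paste(colnames(mat)[r], collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}
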