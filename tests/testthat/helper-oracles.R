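# Independent oracles and fixture builders. Everything here deliberately
# avoids the code paths it is used to check: supports come from naive row
# scans, pattern enumeration from combn() over all subsets, rule splits
# from R-level subset enumeration and pair matching from a quadratic loop.

# random market-basket dataset (no group structure)
randomBasketTS <- function(m, n, density = 0.3, seed = 1) {
  set.seed(seed)
  mat <- matrix(stats::runif(m * n) < density, m, n,
                dimnames = list(NULL, sprintf("i%02d", seq_len(n))))
  # avoid all-empty vocabulary corner: force one occurrence of each item
  for (j in seq_len(n)) if (!any(mat[, j])) mat[sample(m, 1), j] <- TRUE
  TransactionSet(mat)
}

# small labeled clinical-style raw records table (valid codes only)
makeRawRecords <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    age = sample(20:80, n, replace = TRUE),
    sex = sample(0:1, n, replace = TRUE),
    chest_pain_type = sample(1:4, n, replace = TRUE),
    resting_bp = sample(90:200, n, replace = TRUE),
    cholesterol = sample(0:400, n, replace = TRUE),
    fasting_blood_sugar = sample(0:1, n, replace = TRUE),
    resting_ecg = sample(0:2, n, replace = TRUE),
    max_heart_rate = sample(60:202, n, replace = TRUE),
    exercise_angina = sample(0:1, n, replace = TRUE),
    oldpeak = round(stats::runif(n, 0, 5), 1),
    st_slope = sample(1:3, n, replace = TRUE),
    target = sample(0:1, n, replace = TRUE)
  )
}

writeRecordsCSV <- function(records, path,
                            headers = names(records)) {
  names(records) <- headers
  utils::write.csv(records, path, row.names = FALSE)
  path
}

# naive support: fraction of rows containing all items
oracleSupportCount <- function(mat, items) {
  sum(rowSums(mat[, items, drop = FALSE]) == length(items))
}

# exhaustive pattern table via combn over every non-empty subset
oraclePatterns <- function(mat, minCount) {
  n <- ncol(mat)
  stopifnot(n <= 14)
  out_items <- character(0)
  out_counts <- integer(0)
  for (k in seq_len(n)) {
    sets <- utils::combn(colnames(mat), k, simplify = FALSE)
    for (s in sets) {
      cnt <- oracleSupportCount(mat, s)
      if (cnt >= minCount) {
        out_items <- c(out_items, paste(sort(s), collapse = ";"))
        out_counts <- c(out_counts, cnt)
      }
    }
  }
  df <- data.frame(items = out_items, count = out_counts,
                   stringsAsFactors = FALSE)
  df[order(df$items), , drop = FALSE]
}

# canonical comparable form of a PatternSet
patternTable <- function(ps) {
  df <- as.data.frame(ps)[, c("items", "count")]
  rownames(df) <- NULL
  df[order(df$items), , drop = FALSE]
}

# all ordered rule splits of a pattern table, metrics from naive supports
oracleRules <- function(mat, pattern_items) {
  m <- nrow(mat)
  rows <- list()
  for (s in pattern_items) {
    k <- length(s)
    if (k < 2) next
    for (asize in seq_len(k - 1)) {
      ants <- utils::combn(s, asize, simplify = FALSE)
      for (a in ants) {
        y <- setdiff(s, a)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedents = paste(sort(a), collapse = ";"),
          consequent = paste(sort(y), collapse = ";"),
          suppXY = oracleSupportCount(mat, s) / m,
          suppX = oracleSupportCount(mat, a) / m,
          suppY = oracleSupportCount(mat, y) / m,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$antecedents, df$consequent), , drop = FALSE]
}

# quadratic all-pairs scan with set-based Jaccard
oraclePairScan <- function(rareAnts, freqAnts, simT, strict = FALSE) {
  hits <- list()
  for (i in seq_along(rareAnts)) {
    for (j in seq_along(freqAnts)) {
      s <- jaccardSimilarity(rareAnts[[i]], freqAnts[[j]])
      keep <- if (strict) s > simT else s >= simT
      if (keep)
        hits[[length(hits) + 1L]] <- data.frame(
          rare = paste(sort(rareAnts[[i]]), collapse = ";"),
          freq = paste(sort(freqAnts[[j]]), collapse = ";"),
          similarity = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(rare = character(0), freq = character(0),
                      similarity = numeric(0)))
  df <- do.call(rbind, hits)
  df <- unique(df)
  df[order(df$rare, df$freq), , drop = FALSE]
}

# build a typed RuleSet directly from antecedent item lists (one class
# consequent per side); metrics filled so filterStrong would keep them
makeClassRuleSet <- function(antLists, consequent, band, vocab, m = 100L) {
  n <- length(antLists)
  antMask <- vapply(antLists, function(it)
    sum(2^(match(it, vocab) - 1)), numeric(1))
  consMask <- rep(2^(match(consequent, vocab) - 1), n)
  new("RuleSet",
      antMask = antMask, consMask = consMask,
      countXY = rep(2L, n), countX = rep(2L, n), countY = rep(50L, n),
      support = rep(2 / m, n), confidence = rep(1, n),
      lift = rep(2, n), leverage = rep(0.01, n),
      conviction = rep(Inf, n), band = rep(band, n),
      type = rep(NA_integer_, n), m = as.integer(m), vocabulary = vocab,
      classItems = c("no", "yes"))
}

# vocabulary used by hand-built rule sets in tests
testVocab <- function(extra = character(0)) {
  c(sprintf("v%02d", 1:10), "no", "yes", extra)
}
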