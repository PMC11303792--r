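# Frequent and rare pattern mining. Frequent mining is FP-growth
# (compiled); rare mining is complete mining at the rare threshold
# followed by a band partition, which is output-equivalent to a dedicated
# rare-pattern traversal. A pure-R exhaustive enumerator doubles as the
# verification oracle.

# fractional threshold -> minimal absolute count. "ceiling" compares
# integer counts (count >= ceiling(th * m)); "fraction" mines at a
# conservative count and re-filters on float support downstream.
countThreshold <- function(th, m, countMode) {
  if (countMode == "ceiling") {
    max(1L, as.integer(ceiling(th * m - 1e-9)))
  } else {
    max(1L, as.integer(floor(th * m)))
  }
}

# deterministic pattern order: itemset size, then lexicographic item string
orderPatterns <- function(masks, vocabulary) {
  order(popcountMask(masks), masksToStrings(masks, vocabulary),
        method = "radix")
}

buildPatternSet <- function(masks, counts, m, vocabulary, band, thresholds) {
  o <- orderPatterns(masks, vocabulary)
  masks <- masks[o]
  counts <- counts[o]
  new("PatternSet",
      items = masksToItemList(masks, vocabulary),
      mask = masks, count = as.integer(counts), support = counts / m,
      band = band, m = as.integer(m), vocabulary = vocabulary,
      thresholds = thresholds)
}

# run FP-growth at `minCount`, return list(mask, count)
fpgrowthAtCount <- function(ds, minCount) {
  mat <- transactionMatrix(ds)
  checkMaskCapacity(ncol(mat))
  item_counts <- colSums(mat)
  keep <- which(item_counts >= minCount)
  # processing order: descending global count, ties lexicographic by name
  ord <- keep[order(-item_counts[keep], colnames(mat)[keep])]
  res <- cpp_fpgrowth(mat, as.integer(ord - 1L), as.integer(minCount))
  mask <- vapply(res$items, function(ix) sum(2^(ix - 1)), numeric(1))
  list(mask = mask, count = res$count)
}

#' Mine frequent patterns with FP-growth
#'
#' Returns exactly the itemsets whose support meets the frequent-band
#' threshold, each with its exact absolute count.
#'
#' @param ds a [TransactionSet-class].
#' @param minSup minimum support fraction in (0, 1].
#' @param countMode `"ceiling"` (default: count >= ceiling(minSup * m)) or
#'   `"fraction"` (support >= minSup compared as floats).
#' @return a [PatternSet-class] with `band = "frequent"`.
#' @export
mineFrequent <- function(ds, minSup = 0.01,
                         countMode = c("ceiling", "fraction")) {
  countMode <- match.arg(countMode)
  if (!is(ds, "TransactionSet")) stop("ds must be a TransactionSet")
  m <- nTransactions(ds)
  if (m == 0L) stop("cannot mine an empty dataset")
  if (!(minSup > 0 && minSup <= 1)) stop("minSup must lie in (0, 1]")
  minCount <- countThreshold(minSup, m, countMode)
  res <- fpgrowthAtCount(ds, minCount)
  keep <- if (countMode == "fraction") res$count / m >= minSup else
    rep(TRUE, length(res$count))
  buildPatternSet(res$mask[keep], res$count[keep], m, itemNames(ds),
                  band = "frequent",
                  thresholds = c(minSup = minSup, minCount = minCount))
}

#' Mine rare patterns
#'
#' Returns exactly the itemsets whose support lies in the rare band
#' `[minRare, minSup)`. Implemented as complete mining at `minRare`
#' followed by a band partition, so
#' `mineFrequent(minRare) = mineFrequent(minSup) + mineRare(minSup, minRare)`
#' as a disjoint union.
#'
#' @inheritParams mineFrequent
#' @param minRare minimum rare support fraction, `0 < minRare < minSup`.
#' @return a [PatternSet-class] with `band = "rare"`.
#' @export
mineRare <- function(ds, minSup = 0.01, minRare = 0.001,
                     countMode = c("ceiling", "fraction")) {
  countMode <- match.arg(countMode)
  if (!(minRare > 0 && minRare < minSup && minSup <= 1))
    stop("need 0 < minRare < minSup <= 1")
  m <- nTransactions(ds)
  if (m == 0L) stop("cannot mine an empty dataset")
  rareCount <- countThreshold(minRare, m, countMode)
  supCount <- countThreshold(minSup, m, "ceiling")
  res <- fpgrowthAtCount(ds, rareCount)
  keep <- if (countMode == "fraction") {
    res$count / m >= minRare & res$count / m < minSup
  } else {
    res$count < supCount
  }
  buildPatternSet(res$mask[keep], res$count[keep], m, itemNames(ds),
                  band = "rare",
                  thresholds = c(minSup = minSup, minRare = minRare,
                                 minCount = rareCount))
}

#' Exact support of one itemset
#'
#' @param ds a [TransactionSet-class].
#' @param items non-empty character vector of item names.
#' @return list with `items`, `count` and `support`.
#' @export
supportOf <- function(ds, items) {
  if (length(items) == 0L) stop("itemset must be non-empty")
  items <- unique(items)
  unknown <- setdiff(items, itemNames(ds))
  if (length(unknown))
    stop("unknown item name(s): ", paste(unknown, collapse = ", "))
  mat <- transactionMatrix(ds)
  cnt <- sum(rowSums(mat[, items, drop = FALSE]) == length(items))
  list(items = sort(items), count = cnt, support = cnt / nTransactions(ds))
}

#' Exhaustive pattern enumeration (verification oracle)
#'
#' Depth-first enumeration of every non-empty itemset with absolute
#' count at least `minCount`, pruned only by the (exact) anti-monotone
#' bound. Independent of the FP-growth path and intended for
#' cross-checking it on small vocabularies.
#'
#' @param ds a [TransactionSet-class] with at most 20 items.
#' @param minCount minimum absolute count (>= 1).
#' @return a [PatternSet-class] with `band = "all"`.
#' @export
bruteForcePatterns <- function(ds, minCount) {
  mat <- transactionMatrix(ds)
  n <- ncol(mat)
  if (n > 20L)
    stop("brute-force enumeration is limited to 20 items ",
         "(got ", n, "); use mineFrequent() for larger vocabularies")
  if (minCount < 1L) stop("minCount must be at least 1")
  m <- nrow(mat)
  acc_masks <- numeric(0)
  acc_counts <- integer(0)
  rec <- function(prefix_mask, tids, start) {
    for (j in seq.int(start, n)) {
      t2 <- tids & mat[, j]
      c2 <- sum(t2)
      if (c2 >= minCount) {
        msk <- prefix_mask + 2^(j - 1)
        acc_masks[length(acc_masks) + 1L] <<- msk
        acc_counts[length(acc_counts) + 1L] <<- c2
        if (j < n) rec(msk, t2, j + 1L)
      }
    }
  }
  if (minCount <= m) rec(0, rep(TRUE, m), 1L)
  buildPatternSet(acc_masks, acc_counts, m, itemNames(ds), band = "all",
                  thresholds = c(minCount = minCount))
}
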