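# Rule generation, the five interestingness metrics, strong-rule
# filtering and the four-way typing of class-consequent rules.

#' Compute the five rule metrics from supports
#'
#' Vectorized over rules. Given the support of the full rule
#' (`supp(X -> Y) = supp(X u Y)`), of the antecedent and of the
#' consequent, computes support, confidence (`suppXY / suppX`), lift
#' (`suppXY / (suppX * suppY)`), leverage (`suppXY - suppX * suppY`)
#' and conviction (`(1 - suppY) / (1 - confidence)`). Conviction is
#' `Inf` exactly when confidence is 1 and `suppY < 1`; when both the
#' confidence and `suppY` equal 1 it is reported as 1.
#'
#' @param suppXY,suppX,suppY support fractions; `suppXY` must not exceed
#'   `min(suppX, suppY)`.
#' @return data.frame with columns `support`, `confidence`, `lift`,
#'   `leverage`, `conviction`.
#' @export
computeMetrics <- function(suppXY, suppX, suppY) {
  if (any(suppX <= 0) || any(suppX > 1) || any(suppY <= 0) || any(suppY > 1))
    stop("suppX and suppY must lie in (0, 1]")
  if (any(suppXY < 0))
    stop("suppXY must be non-negative")
  if (any(suppXY > pmin(suppX, suppY) + 1e-12))
    stop("inconsistent supports: supp(X->Y) exceeds min(supp(X), supp(Y))")
  confidence <- suppXY / suppX
  lift <- suppXY / (suppX * suppY)
  leverage <- suppXY - suppX * suppY
  conviction <- ifelse(confidence >= 1,
                       ifelse(suppY < 1, Inf, 1),
                       (1 - suppY) / (1 - confidence))
  data.frame(support = suppXY, confidence = confidence, lift = lift,
             leverage = leverage, conviction = conviction)
}

#' Generate candidate association rules from mined patterns
#'
#' Every pattern with at least two items is split into every ordered
#' (antecedent, consequent) pair of non-empty disjoint subsets
#' (`2^k - 2` splits for a k-itemset), each candidate carrying exact
#' metrics and the band of its source pattern. With
#' `classConsequentOnly = TRUE` only splits whose consequent is a single
#' class item are emitted (faster; sufficient for typing, but not for
#' reproducing global rule counts).
#'
#' Sub-itemset supports are taken from the pattern set when present and
#' recomputed exactly from the data otherwise.
#'
#' @param patterns a [PatternSet-class] mined from `ds`.
#' @param ds the source [TransactionSet-class].
#' @param classConsequentOnly logical, see above.
#' @return a [RuleSet-class] (untyped; see [classifyRules()]).
#' @export
generateRules <- function(patterns, ds, classConsequentOnly = FALSE) {
  if (!identical(patterns@vocabulary, itemNames(ds)))
    stop("patterns were not mined from this dataset (vocabulary mismatch)")
  m <- nTransactions(ds)
  if (patterns@m != m)
    stop("patterns were not mined from this dataset (size mismatch)")
  cls <- classItems(ds)
  cls_idx <- match(cls, itemNames(ds))
  res <- cpp_generate_rules(patterns@mask, patterns@count,
                            transactionMatrix(ds),
                            cls_idx[1], cls_idx[2],
                            isTRUE(classConsequentOnly))
  met <- computeMetrics(res$countXY / m, res$countX / m, res$countY / m)
  band <- if (length(res$antMask)) rep(patterns@band, length(res$antMask))
          else character(0)
  new("RuleSet",
      antMask = res$antMask, consMask = res$consMask,
      countXY = res$countXY, countX = res$countX, countY = res$countY,
      support = met$support, confidence = met$confidence, lift = met$lift,
      leverage = met$leverage, conviction = met$conviction,
      band = band, type = rep(NA_integer_, length(res$antMask)),
      m = as.integer(m), vocabulary = itemNames(ds), classItems = cls)
}

#' Filter strong rules
#'
#' Retains exactly the rules exceeding every metric threshold (strict
#' inequalities: confidence > minConf, lift > minLift, leverage > minLev,
#' conviction > minConv; an infinite conviction passes) whose support is
#' band-appropriate (frequent: at least minSup; rare: within
#' `[minRare, minSup)`), under the configured count-comparison mode.
#'
#' @param rules a [RuleSet-class].
#' @param config a [MiningConfig-class].
#' @return the filtered [RuleSet-class].
#' @export
filterStrong <- function(rules, config = miningConfig()) {
  m <- rules@m
  if (config@countMode == "ceiling") {
    supCount <- countThreshold(config@minSup, m, "ceiling")
    rareCount <- countThreshold(config@minRare, m, "ceiling")
    band_ok <- ifelse(rules@band == "frequent",
                      rules@countXY >= supCount,
                      rules@countXY >= rareCount & rules@countXY < supCount)
  } else {
    band_ok <- ifelse(rules@band == "frequent",
                      rules@support >= config@minSup,
                      rules@support >= config@minRare &
                        rules@support < config@minSup)
  }
  keep <- rules@confidence > config@minConf &
    rules@lift > config@minLift &
    rules@leverage > config@minLev &
    rules@conviction > config@minConv &
    band_ok
  rules[which(keep)]
}

#' Classify rules into the four class-consequent types
#'
#' Rules whose consequent is exactly one class item receive a type by
#' (band, consequent): 1 = frequent => no, 2 = frequent => yes,
#' 3 = rare => no, 4 = rare => yes. All other rules stay untyped (NA)
#' and are ignored by the pair-matching stage.
#'
#' @param rules a [RuleSet-class] (normally strong-filtered).
#' @return the [RuleSet-class] with the type slot filled.
#' @export
classifyRules <- function(rules) {
  cls_mask <- vapply(rules@classItems, itemsToMask,
                     vocabulary = rules@vocabulary, numeric(1))
  no_mask <- cls_mask[[1]]
  yes_mask <- cls_mask[[2]]
  type <- rep(NA_integer_, length(rules))
  type[rules@band == "frequent" & rules@consMask == no_mask] <- 1L
  type[rules@band == "frequent" & rules@consMask == yes_mask] <- 2L
  type[rules@band == "rare" & rules@consMask == no_mask] <- 3L
  type[rules@band == "rare" & rules@consMask == yes_mask] <- 4L
  initialize(rules, type = type)
}

#' Extract the rules of one type
#'
#' @param rules a typed [RuleSet-class].
#' @param type integer 1-4.
#' @return the [RuleSet-class] subset.
#' @export
rulesOfType <- function(rules, type) {
  stopifnot(type %in% 1:4)
  rules[which(!is.na(rules@type) & rules@type == type)]
}

#' Export a RuleSet to CSV
#'
#' Columns: antecedents (lexicographically sorted, `;`-joined),
#' consequent, support, confidence, lift, leverage, conviction (the
#' literal string `"inf"` for infinite conviction), band, type. Rows are
#' sorted by a documented total order (band, type, antecedents,
#' consequent) so re-runs diff cleanly.
#'
#' @param rules a [RuleSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportRules <- function(rules, path) {
  df <- as.data.frame(rules)
  o <- order(df$band, df$type, df$antecedents, df$consequent,
             method = "radix")
  df <- df[o, , drop = FALSE]
  df$conviction <- ifelse(is.infinite(df$conviction), "inf",
                          format(df$conviction, digits = 12))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a PatternSet to CSV
#'
#' Columns: items (sorted, `;`-joined), count, support, band.
#'
#' @param patterns a [PatternSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportPatterns <- function(patterns, path) {
  utils::write.csv(as.data.frame(patterns), path, row.names = FALSE)
  invisible(path)
}
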