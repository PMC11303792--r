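# Matching rare disease-predicting rules against frequent
# health-predicting rules by antecedent Jaccard similarity, and
# attributing each qualifying pair to its trigger factor(s).

#' Jaccard similarity of two itemsets
#'
#' `|a n b| / |a u b|` over the distinct items of each set.
#'
#' @param a,b non-empty character vectors of item names.
#' @return similarity in `[0, 1]`.
#' @export
jaccardSimilarity <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("itemsets must be non-empty")
  a <- unique(a)
  b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Find interesting (rare, frequent) rule pairs
#'
#' Scans all (rare disease-predicting, frequent health-predicting) rule
#' pairs and keeps those whose antecedent Jaccard similarity reaches
#' `simT` (inclusive by default) - the consequents, one `yes` and one
#' `no`, are opposite by construction. Each pair is annotated with its
#' trigger items (rare antecedent minus frequent antecedent) and reverse
#' items (frequent minus rare). Output is sorted by similarity
#' descending, ties by rare-rule support ascending, then lexicographic
#' antecedent strings; identical pairs are deduplicated.
#'
#' @param rareRules a [RuleSet-class]; only its rules with the single
#'   `yes` class item as consequent (type 4) participate.
#' @param freqRules a [RuleSet-class]; only its rules with the single
#'   `no` class item as consequent (type 1) participate.
#' @param simT similarity threshold in (0, 1].
#' @param strict logical; if TRUE require similarity strictly above
#'   `simT` instead of the default inclusive comparison.
#' @param direction `"rare-yes"` (default: rare disease-predicting vs
#'   frequent health-predicting rules) or `"rare-no"` for the symmetric
#'   contrast.
#' @return a [RulePairSet-class].
#' @export
findInterestingPairs <- function(rareRules, freqRules, simT = 0.80,
                                 strict = FALSE,
                                 direction = c("rare-yes", "rare-no")) {
  direction <- match.arg(direction)
  if (!identical(rareRules@vocabulary, freqRules@vocabulary))
    stop("rule sets use different vocabularies")
  if (!(simT > 0 && simT <= 1)) stop("simT must lie in (0, 1]")
  vocab <- rareRules@vocabulary
  cls <- rareRules@classItems
  if (length(cls) != 2L)
    stop("rule sets carry no class item pair; pair matching needs one")
  yes_mask <- itemsToMask(cls[2], vocab)
  no_mask <- itemsToMask(cls[1], vocab)
  rare_cons <- if (direction == "rare-yes") yes_mask else no_mask
  freq_cons <- if (direction == "rare-yes") no_mask else yes_mask
  rare_cons_item <- if (direction == "rare-yes") cls[2] else cls[1]

  rr <- rareRules[which(rareRules@consMask == rare_cons)]
  fr <- freqRules[which(freqRules@consMask == freq_cons)]

  empty <- function() new("RulePairSet",
    rareAntMask = numeric(0), freqAntMask = numeric(0),
    similarity = numeric(0), rareSupport = numeric(0),
    freqSupport = numeric(0), rareConfidence = numeric(0),
    freqConfidence = numeric(0), triggerMask = numeric(0),
    reverseMask = numeric(0), m = rareRules@m, vocabulary = vocab,
    classItems = cls, rareConsequent = rare_cons_item, simT = simT)
  if (length(rr) == 0L || length(fr) == 0L) return(empty())

  hit <- cpp_pair_scan(rr@antMask, fr@antMask, simT, isTRUE(strict))
  if (length(hit$rareIdx) == 0L) return(empty())

  ri <- hit$rareIdx
  fi <- hit$freqIdx
  dup <- duplicated(paste(rr@antMask[ri], fr@antMask[fi]))
  ri <- ri[!dup]; fi <- fi[!dup]
  sim <- hit$similarity[!dup]

  rare_ant <- rr@antMask[ri]
  freq_ant <- fr@antMask[fi]
  trig <- maskSetDiff(rare_ant, freq_ant)
  rev_ <- maskSetDiff(freq_ant, rare_ant)
  o <- order(-sim, rr@support[ri],
             masksToStrings(rare_ant, vocab),
             masksToStrings(freq_ant, vocab), method = "radix")

  new("RulePairSet",
      rareAntMask = rare_ant[o], freqAntMask = freq_ant[o],
      similarity = sim[o],
      rareSupport = rr@support[ri][o], freqSupport = fr@support[fi][o],
      rareConfidence = rr@confidence[ri][o],
      freqConfidence = fr@confidence[fi][o],
      triggerMask = trig[o], reverseMask = rev_[o],
      m = rareRules@m, vocabulary = vocab, classItems = cls,
      rareConsequent = rare_cons_item, simT = simT)
}

#' Summarize trigger factors over interesting pairs
#'
#' Tallies, for every item, the number of interesting pairs in which it
#' appears as a trigger (a pair with several trigger items credits each
#' of them). Pairs with identical antecedents (similarity 1) fall into a
#' no-trigger bucket.
#'
#' @param pairs a [RulePairSet-class].
#' @return an object of class `"triggerSummary"`: list with `tally`
#'   (named integer, descending), `nPairs`, `nDistinctRareRules` and
#'   `nNoTrigger`.
#' @export
summarizeTriggers <- function(pairs) {
  trig_items <- masksToItemList(pairs@triggerMask, pairs@vocabulary)
  tally <- table(unlist(trig_items))
  tally <- sort(as.integer(tally) |> setNames(names(tally)),
                decreasing = TRUE)
  out <- list(
    tally = tally,
    nPairs = length(pairs),
    nDistinctRareRules = length(unique(pairs@rareAntMask)),
    nNoTrigger = sum(pairs@triggerMask == 0)
  )
  class(out) <- "triggerSummary"
  out
}

#' @export
print.triggerSummary <- function(x, ...) {
  cat("Trigger summary over", x$nPairs, "interesting pairs",
      sprintf("(%d distinct rare rules)\n", x$nDistinctRareRules))
  if (length(x$tally)) {
    for (i in seq_along(x$tally))
      cat(sprintf("  %-14s %d\n", names(x$tally)[i], x$tally[i]))
  }
  if (x$nNoTrigger > 0)
    cat("  (no trigger: ", x$nNoTrigger, " pair(s))\n", sep = "")
  invisible(x)
}

#' Export interesting pairs to CSV
#'
#' One row per pair with both antecedent sets, both consequents, both
#' supports and confidences, the similarity and the trigger items; rows
#' in the pair set's deterministic order.
#'
#' @param pairs a [RulePairSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportPairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

#' Export the 3D coordinates of interesting pairs
#'
#' Writes the (frequent-rule support, rare-rule support, similarity)
#' coordinate triples used for scatter visualisation of the pair set.
#'
#' @param pairs a [RulePairSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportPairCoordinates <- function(pairs, path) {
  df <- data.frame(frequent_support = pairs@freqSupport,
                   rare_support = pairs@rareSupport,
                   similarity = pairs@similarity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
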