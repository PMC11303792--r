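# Accessors, show, length, subsetting and as.data.frame methods.

## ---- TransactionSet ----

#' @rdname rareRules-generics
#' @export
setMethod("nTransactions", "TransactionSet", function(x) nrow(x@matrix))

#' @rdname rareRules-generics
#' @export
setMethod("nItems", "TransactionSet", function(x) ncol(x@matrix))

#' @rdname rareRules-generics
#' @export
setMethod("itemNames", "TransactionSet", function(x) colnames(x@matrix))

#' @rdname rareRules-generics
#' @export
setMethod("itemInfo", "TransactionSet", function(x) x@itemInfo)

#' @rdname rareRules-generics
#' @export
setMethod("classItems", "TransactionSet", function(x) x@classItems)

#' @rdname rareRules-generics
#' @export
setMethod("transactionMatrix", "TransactionSet", function(x) x@matrix)

setMethod("show", "TransactionSet", function(object) {
  cat("TransactionSet:", nTransactions(object), "transactions x",
      nItems(object), "items\n")
  groups <- unique(object@itemInfo$attribute)
  cat(" attribute groups:", length(groups),
      sprintf("(class: %s/%s)\n", object@classItems[1], object@classItems[2]))
})

## ---- PatternSet ----

#' @rdname rareRules-generics
#' @export
setMethod("patternItems", "PatternSet", function(x) x@items)

#' @rdname rareRules-generics
#' @export
setMethod("patternCounts", "PatternSet", function(x) x@count)

#' @rdname rareRules-generics
#' @export
setMethod("supports", "PatternSet", function(x) x@support)

#' @rdname rareRules-generics
#' @export
setMethod("band", "PatternSet", function(x) x@band)

#' @export
setMethod("length", "PatternSet", function(x) length(x@items))

setMethod("show", "PatternSet", function(object) {
  cat("PatternSet:", length(object), "patterns, band =", object@band, "\n")
  th <- object@thresholds
  cat(" thresholds:", paste(names(th), signif(th, 6), sep = "=",
                            collapse = ", "), "\n")
  cat(" m =", object@m, "transactions\n")
})

#' Convert a PatternSet to a data.frame
#'
#' Items are sorted lexicographically and `;`-joined; rows are in the
#' set's deterministic order (itemset size, then item string).
#'
#' @param x a [PatternSet-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns `items`, `count`, `support`, `band`.
#' @method as.data.frame PatternSet
#' @export
as.data.frame.PatternSet <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(
    items = masksToStrings(x@mask, x@vocabulary),
    count = x@count,
    support = x@support,
    band = if (length(x) > 0L) x@band else character(0),
    stringsAsFactors = FALSE
  )
}

## ---- RuleSet ----

#' @rdname rareRules-generics
#' @export
setMethod("antecedents", "RuleSet",
          function(x) masksToItemList(x@antMask, x@vocabulary))

#' @rdname rareRules-generics
#' @export
setMethod("consequents", "RuleSet",
          function(x) masksToItemList(x@consMask, x@vocabulary))

#' @rdname rareRules-generics
#' @export
setMethod("supports", "RuleSet", function(x) x@support)

#' @rdname rareRules-generics
#' @export
setMethod("band", "RuleSet", function(x) x@band)

#' @rdname rareRules-generics
#' @export
setMethod("ruleType", "RuleSet", function(x) x@type)

#' @rdname rareRules-generics
#' @export
setMethod("ruleMetrics", "RuleSet", function(x) {
  data.frame(support = x@support, confidence = x@confidence, lift = x@lift,
             leverage = x@leverage, conviction = x@conviction)
})

#' @export
setMethod("length", "RuleSet", function(x) length(x@antMask))

#' Subset a RuleSet
#' @param x a [RuleSet-class]; @param i logical or integer index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "RuleSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    antMask = x@antMask[i], consMask = x@consMask[i],
    countXY = x@countXY[i], countX = x@countX[i], countY = x@countY[i],
    support = x@support[i], confidence = x@confidence[i],
    lift = x@lift[i], leverage = x@leverage[i],
    conviction = x@conviction[i], band = x@band[i], type = x@type[i])
})

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet:", length(object), "rules over", length(object@vocabulary),
      "items (m =", object@m, ")\n")
  if (length(object) > 0L) {
    tb <- table(factor(object@band, levels = c("frequent", "rare")))
    cat(" bands: frequent =", tb[["frequent"]], ", rare =", tb[["rare"]], "\n")
    if (!all(is.na(object@type))) {
      tt <- table(factor(object@type, levels = 1:4))
      cat(" types: T1 =", tt[["1"]], ", T2 =", tt[["2"]],
          ", T3 =", tt[["3"]], ", T4 =", tt[["4"]], "\n")
    }
  }
})

#' Convert a RuleSet to a data.frame
#'
#' @param x a [RuleSet-class].
#' @param row.names,optional,... ignored.
#' @return data.frame with `antecedents`, `consequent`, `support`,
#'   `confidence`, `lift`, `leverage`, `conviction` (the string `"inf"` for
#'   infinite conviction when serialized via [exportRules()]), `band`, `type`.
#' @method as.data.frame RuleSet
#' @export
as.data.frame.RuleSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    antecedents = masksToStrings(x@antMask, x@vocabulary),
    consequent = masksToStrings(x@consMask, x@vocabulary),
    support = x@support,
    confidence = x@confidence,
    lift = x@lift,
    leverage = x@leverage,
    conviction = x@conviction,
    band = x@band,
    type = x@type,
    stringsAsFactors = FALSE
  )
}

## ---- RulePairSet ----

#' @export
setMethod("length", "RulePairSet", function(x) length(x@rareAntMask))

#' @rdname rareRules-generics
#' @export
setMethod("similarity", "RulePairSet", function(x) x@similarity)

#' @rdname rareRules-generics
#' @export
setMethod("triggerItems", "RulePairSet",
          function(x) masksToItemList(x@triggerMask, x@vocabulary))

setMethod("show", "RulePairSet", function(object) {
  cat("RulePairSet:", length(object), "interesting (rare, frequent) pairs",
      sprintf("at simT = %.2f\n", object@simT))
  if (length(object) > 0L) {
    cat(" similarity range:", sprintf("[%.3f, %.3f]\n",
        min(object@similarity), max(object@similarity)))
    cat(" distinct rare rules:", length(unique(object@rareAntMask)), "\n")
  }
})

#' Convert a RulePairSet to a data.frame
#'
#' One row per interesting pair, mirroring the fields a hover-card style
#' inspection needs: both antecedents, both consequents, supports,
#' confidences, similarity and trigger items.
#'
#' @param x a [RulePairSet-class].
#' @param row.names,optional,... ignored.
#' @method as.data.frame RulePairSet
#' @export
as.data.frame.RulePairSet <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    rare_antecedents = masksToStrings(x@rareAntMask, x@vocabulary),
    frequent_antecedents = masksToStrings(x@freqAntMask, x@vocabulary),
    rare_consequent = rep(x@rareConsequent, length(x)),
    frequent_consequent = rep(setdiff(x@classItems, x@rareConsequent),
                              length(x)),
    rare_support = x@rareSupport,
    frequent_support = x@freqSupport,
    rare_confidence = x@rareConfidence,
    frequent_confidence = x@freqConfidence,
    similarity = x@similarity,
    trigger_items = masksToStrings(x@triggerMask, x@vocabulary),
    reverse_items = masksToStrings(x@reverseMask, x@vocabulary),
    stringsAsFactors = FALSE
  )
}


setMethod("show", "MiningConfig", function(object) {
  cat("MiningConfig: minSup =", object@minSup, ", minRare =", object@minRare,
      ", simT =", object@simT, "\n")
  cat(" strong-rule thresholds (strict >): conf", object@minConf,
      ", lift", object@minLift, ", lev", object@minLev,
      ", conv", object@minConv, "\n")
  cat(" countMode =", object@countMode,
      ", classConsequentOnly =", object@classConsequentOnly, "\n")
})
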