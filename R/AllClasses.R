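# Central S4 containers. Items are always referred to by name; internally
# itemsets are encoded as bitmasks over the vocabulary (exact in doubles for
# up to 52 items), which keeps half-a-million-rule runs tractable.

#' TransactionSet: boolean item-occurrence matrix
#'
#' A set of `m` transactions over a vocabulary of `n` items. Items are
#' organised in mutually exclusive attribute groups (each transaction has
#' exactly one item true per group), plus one class group whose two items
#' encode the binary outcome (e.g. `"yes"`/`"no"` for heart disease).
#'
#' @slot matrix logical `m x n` matrix; column names are the item names.
#' @slot itemInfo `data.frame` with columns `item` and `attribute`, one row
#'   per item, giving the attribute group each item belongs to.
#' @slot classItems character of length 2, `c(no, yes)` item names of the
#'   class group; may be empty for class-free data.
#' @export
setClass("TransactionSet",
  representation(
    matrix = "matrix",
    itemInfo = "data.frame",
    classItems = "character"
  )
)

setValidity("TransactionSet", function(object) {
  mat <- object@matrix
  info <- object@itemInfo
  msgs <- character()
  if (!is.logical(mat)) msgs <- c(msgs, "matrix must be logical")
  if (nrow(mat) < 1L) msgs <- c(msgs, "at least one transaction is required")
  if (is.null(colnames(mat))) msgs <- c(msgs, "matrix must have item column names")
  if (anyDuplicated(colnames(mat))) msgs <- c(msgs, "item names must be unique")
  if (!all(c("item", "attribute") %in% names(info)))
    msgs <- c(msgs, "itemInfo needs columns 'item' and 'attribute'")
  if (length(msgs) == 0L && !identical(as.character(info$item), colnames(mat)))
    msgs <- c(msgs, "itemInfo$item must match matrix column names in order")
  if (!length(object@classItems) %in% c(0L, 2L))
    msgs <- c(msgs, "classItems must be empty or name two items")
  if (length(object@classItems) == 2L &&
      !all(object@classItems %in% colnames(mat)))
    msgs <- c(msgs, "classItems must name two items of the vocabulary")
  if (length(msgs) == 0L) {
    # mutual exclusivity is only meaningful for multi-item groups;
    # singleton groups are unconstrained (market-basket style) items
    for (g in unique(info$attribute[duplicated(info$attribute)])) {
      cols <- which(info$attribute == g)
      per_row <- rowSums(mat[, cols, drop = FALSE])
      if (!all(per_row == 1L)) {
        msgs <- c(msgs, sprintf(
          "attribute group '%s' is not one-hot: %d transaction(s) violate it",
          g, sum(per_row != 1L)))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TransactionSet constructor
#'
#' @param matrix logical transaction-by-item matrix with item column names.
#' @param itemInfo data.frame mapping each item to its attribute group;
#'   defaults to every item in its own group (no exclusivity constraint).
#' @param classItems length-2 character, the (no, yes) class item names;
#'   defaults to `c("no", "yes")` when both are present in the vocabulary
#'   and to none otherwise (class-free market-basket data).
#' @return A [TransactionSet-class] object.
#' @export
TransactionSet <- function(matrix, itemInfo = NULL, classItems = NULL) {
  if (is.null(colnames(matrix)))
    stop("transaction matrix must have item column names")
  if (is.null(classItems)) {
    classItems <- if (all(c("no", "yes") %in% colnames(matrix)))
      c("no", "yes") else character(0)
  }
  if (is.null(itemInfo)) {
    itemInfo <- data.frame(item = colnames(matrix),
                           attribute = colnames(matrix),
                           stringsAsFactors = FALSE)
  }
  new("TransactionSet", matrix = matrix, itemInfo = itemInfo,
      classItems = classItems)
}

#' PatternSet: mined itemsets with exact counts
#'
#' @slot items list of character vectors, one sorted itemset per pattern.
#' @slot mask numeric bitmask encoding of each itemset over `vocabulary`.
#' @slot count integer absolute occurrence counts.
#' @slot support numeric, `count / m`.
#' @slot band `"frequent"`, `"rare"` or `"all"`.
#' @slot m integer, number of transactions mined.
#' @slot vocabulary character, item vocabulary of the source data.
#' @slot thresholds named numeric, the thresholds used (`minSup`,
#'   `minRare` where applicable) and the realized count cutoffs.
#' @export
setClass("PatternSet",
  representation(
    items = "list",
    mask = "numeric",
    count = "integer",
    support = "numeric",
    band = "character",
    m = "integer",
    vocabulary = "character",
    thresholds = "numeric"
  )
)

setValidity("PatternSet", function(object) {
  msgs <- character()
  n <- length(object@items)
  if (length(object@count) != n || length(object@support) != n ||
      length(object@mask) != n)
    msgs <- c(msgs, "items, mask, count and support must have equal length")
  if (n > 0L) {
    if (any(object@count < 1L) || any(object@count > object@m))
      msgs <- c(msgs, "counts must lie in [1, m]")
    if (any(abs(object@support - object@count / object@m) > 1e-12))
      msgs <- c(msgs, "support must equal count/m")
    if (anyDuplicated(object@mask))
      msgs <- c(msgs, "duplicate itemsets are not allowed")
  }
  if (!object@band %in% c("frequent", "rare", "all"))
    msgs <- c(msgs, "band must be 'frequent', 'rare' or 'all'")
  if (length(msgs)) msgs else TRUE
})

#' RuleSet: association rules with metrics
#'
#' Antecedent and consequent itemsets are stored as bitmasks over
#' `vocabulary`; use [antecedents()] / [consequents()] to decode.
#'
#' @slot antMask,consMask numeric bitmasks of X and Y.
#' @slot countXY,countX,countY integer occurrence counts.
#' @slot support,confidence,lift,leverage,conviction numeric metric vectors
#'   (conviction may be `Inf`).
#' @slot band character per rule, `"frequent"` or `"rare"` (band of the
#'   source pattern, i.e. of X union Y).
#' @slot type integer per rule: 1 (frequent => no), 2 (frequent => yes),
#'   3 (rare => no), 4 (rare => yes), or NA when untyped.
#' @slot m integer transaction count.
#' @slot vocabulary character item vocabulary.
#' @slot classItems character(2), (no, yes) class items.
#' @export
setClass("RuleSet",
  representation(
    antMask = "numeric",
    consMask = "numeric",
    countXY = "integer",
    countX = "integer",
    countY = "integer",
    support = "numeric",
    confidence = "numeric",
    lift = "numeric",
    leverage = "numeric",
    conviction = "numeric",
    band = "character",
    type = "integer",
    m = "integer",
    vocabulary = "character",
    classItems = "character"
  )
)

setValidity("RuleSet", function(object) {
  n <- length(object@antMask)
  lens <- c(length(object@consMask), length(object@countXY),
            length(object@countX), length(object@countY),
            length(object@support), length(object@confidence),
            length(object@lift), length(object@leverage),
            length(object@conviction), length(object@band),
            length(object@type))
  msgs <- character()
  if (!all(lens == n)) msgs <- c(msgs, "all per-rule slots must have equal length")
  if (n > 0L && any(bitwAndMask(object@antMask, object@consMask) != 0))
    msgs <- c(msgs, "antecedent and consequent must be disjoint")
  if (n > 0L && (any(object@antMask == 0) || any(object@consMask == 0)))
    msgs <- c(msgs, "antecedent and consequent must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' RulePairSet: matched (rare, frequent) interesting rule pairs
#'
#' @slot rareAntMask,freqAntMask numeric antecedent bitmasks.
#' @slot similarity numeric Jaccard similarity of the antecedents.
#' @slot rareSupport,freqSupport,rareConfidence,freqConfidence numeric.
#' @slot triggerMask numeric, rare antecedent minus frequent antecedent.
#' @slot reverseMask numeric, frequent antecedent minus rare antecedent.
#' @slot m integer; @slot vocabulary character; @slot classItems character(2).
#' @slot rareConsequent character(1), the class item predicted by the rare
#'   side (`"yes"` in the default matching direction).
#' @slot simT numeric similarity threshold used.
#' @export
setClass("RulePairSet",
  representation(
    rareAntMask = "numeric",
    freqAntMask = "numeric",
    similarity = "numeric",
    rareSupport = "numeric",
    freqSupport = "numeric",
    rareConfidence = "numeric",
    freqConfidence = "numeric",
    triggerMask = "numeric",
    reverseMask = "numeric",
    m = "integer",
    vocabulary = "character",
    classItems = "character",
    rareConsequent = "character",
    simT = "numeric"
  )
)

setValidity("RulePairSet", function(object) {
  msgs <- character()
  n <- length(object@rareAntMask)
  if (length(object@freqAntMask) != n || length(object@similarity) != n)
    msgs <- c(msgs, "per-pair slots must have equal length")
  if (n > 0L) {
    if (any(object@similarity <= 0) || any(object@similarity > 1))
      msgs <- c(msgs, "similarity must lie in (0, 1]")
    bad <- object@similarity < 1 & object@triggerMask == 0 &
      object@reverseMask == 0
    if (any(bad))
      msgs <- c(msgs,
                "antecedents must differ somewhere when similarity < 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' MiningConfig: thresholds and conventions for a mining run
#'
#' Defaults follow the experimental setup used for the combined
#' heart-disease dataset: `minSup = 0.01`, `minRare = 0.001`,
#' `simT = 0.80`, and strong-rule thresholds confidence > 0.80,
#' lift > 1, leverage > 0, conviction > 1 (all strict).
#'
#' @slot minSup,minRare numeric support thresholds (fractions).
#' @slot simT numeric Jaccard similarity threshold.
#' @slot minConf,minLift,minLev,minConv numeric strong-rule thresholds,
#'   compared strictly (a rule must exceed each).
#' @slot countMode `"ceiling"` (count >= ceiling(th * m), default) or
#'   `"fraction"` (support >= th compared as floats).
#' @slot strictSim logical; if TRUE pair matching requires similarity
#'   strictly above `simT` (default FALSE: inclusive `>=`).
#' @slot classConsequentOnly logical; if TRUE rule generation only emits
#'   splits whose consequent is a single class item (faster; default FALSE
#'   enumerates every split, the reproduction convention).
#' @slot seed integer random seed for synthetic data.
#' @export
setClass("MiningConfig",
  representation(
    minSup = "numeric",
    minRare = "numeric",
    simT = "numeric",
    minConf = "numeric",
    minLift = "numeric",
    minLev = "numeric",
    minConv = "numeric",
    countMode = "character",
    strictSim = "logical",
    classConsequentOnly = "logical",
    seed = "integer"
  )
)

setValidity("MiningConfig", function(object) {
  msgs <- character()
  if (!(object@minRare > 0 && object@minRare < object@minSup &&
        object@minSup <= 1))
    msgs <- c(msgs, "need 0 < minRare < minSup <= 1")
  if (!(object@simT > 0 && object@simT <= 1))
    msgs <- c(msgs, "need 0 < simT <= 1")
  if (!object@countMode %in% c("ceiling", "fraction"))
    msgs <- c(msgs, "countMode must be 'ceiling' or 'fraction'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname MiningConfig-class
#' @param minSup,minRare,simT,minConf,minLift,minLev,minConv,countMode,strictSim,classConsequentOnly,seed
#'   see the class slots.
#' @return A [MiningConfig-class] object.
#' @export
miningConfig <- function(minSup = 0.01, minRare = 0.001, simT = 0.80,
                         minConf = 0.80, minLift = 1, minLev = 0,
                         minConv = 1, countMode = c("ceiling", "fraction"),
                         strictSim = FALSE, classConsequentOnly = FALSE,
                         seed = 1L) {
  new("MiningConfig", minSup = minSup, minRare = minRare, simT = simT,
      minConf = minConf, minLift = minLift, minLev = minLev,
      minConv = minConv, countMode = match.arg(countMode),
      strictSim = strictSim, classConsequentOnly = classConsequentOnly,
      seed = as.integer(seed))
}
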