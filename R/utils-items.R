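# Bitmask utilities. Itemsets are encoded as doubles holding integers in
# [0, 2^52): exact IEEE-754 arithmetic, vocabularies of up to 52 items.
# Bitwise ops go through 26-bit halves because base bitwAnd is 32-bit.

MASK_MAX_ITEMS <- 52L
.HALF <- 2^26

checkMaskCapacity <- function(n_items) {
  if (n_items > MASK_MAX_ITEMS)
    stop("itemset bitmask encoding supports at most ", MASK_MAX_ITEMS,
         " items; got ", n_items)
  invisible(TRUE)
}

itemsToMask <- function(items, vocabulary) {
  checkMaskCapacity(length(vocabulary))
  idx <- match(items, vocabulary)
  if (anyNA(idx)) {
    stop("unknown item name(s): ",
         paste(items[is.na(idx)], collapse = ", "))
  }
  sum(2^(idx - 1))
}

maskToItems <- function(mask, vocabulary) {
  idx <- which(bitwAndMask(mask, 2^(seq_along(vocabulary) - 1)) != 0)
  vocabulary[idx]
}

# vectorized bitwise AND / OR / difference on double-encoded masks
bitwAndMask <- function(a, b) {
  bitwAnd(as.integer(a %% .HALF), as.integer(b %% .HALF)) +
    bitwAnd(as.integer(a %/% .HALF), as.integer(b %/% .HALF)) * .HALF
}

bitwOrMask <- function(a, b) {
  bitwOr(as.integer(a %% .HALF), as.integer(b %% .HALF)) +
    bitwOr(as.integer(a %/% .HALF), as.integer(b %/% .HALF)) * .HALF
}

maskSetDiff <- function(a, b) a - bitwAndMask(a, b)

popcountMask <- function(x) cpp_popcount(as.numeric(x))

# decode many masks to "a;b;c" strings, items in lexicographic order
masksToStrings <- function(masks, vocabulary, sep = ";") {
  cpp_masks_to_strings(as.numeric(masks), vocabulary,
                       order(vocabulary, method = "radix") - 1L, sep)
}

masksToItemList <- function(masks, vocabulary) {
  lapply(masks, maskToItems, vocabulary = vocabulary)
}
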