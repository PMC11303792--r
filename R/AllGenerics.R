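#' @name rareRules-generics
#' @title Accessor generics
#' @description Accessors for the S4 containers; slot access from user code
#'   is discouraged.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname rareRules-generics
#' @export
setGeneric("nTransactions", function(x) standardGeneric("nTransactions"))

#' @rdname rareRules-generics
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname rareRules-generics
#' @export
setGeneric("itemNames", function(x) standardGeneric("itemNames"))

#' @rdname rareRules-generics
#' @export
setGeneric("itemInfo", function(x) standardGeneric("itemInfo"))

#' @rdname rareRules-generics
#' @export
setGeneric("classItems", function(x) standardGeneric("classItems"))

#' @rdname rareRules-generics
#' @export
setGeneric("transactionMatrix", function(x) standardGeneric("transactionMatrix"))

#' @rdname rareRules-generics
#' @export
setGeneric("patternItems", function(x) standardGeneric("patternItems"))

#' @rdname rareRules-generics
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))

#' @rdname rareRules-generics
#' @export
setGeneric("supports", function(x) standardGeneric("supports"))

#' @rdname rareRules-generics
#' @export
setGeneric("band", function(x) standardGeneric("band"))

#' @rdname rareRules-generics
#' @export
setGeneric("antecedents", function(x) standardGeneric("antecedents"))

#' @rdname rareRules-generics
#' @export
setGeneric("consequents", function(x) standardGeneric("consequents"))

#' @rdname rareRules-generics
#' @export
setGeneric("ruleMetrics", function(x) standardGeneric("ruleMetrics"))

#' @rdname rareRules-generics
#' @export
setGeneric("ruleType", function(x) standardGeneric("ruleType"))

#' @rdname rareRules-generics
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))

#' @rdname rareRules-generics
#' @export
setGeneric("triggerItems", function(x) standardGeneric("triggerItems"))
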