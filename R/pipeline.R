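# Three-phase pipeline driver: (1) prepare and encode, (2) mine patterns
# and extract strong rules in both bands, (3) match rare against frequent
# rules and attribute triggers. Produces a structured run report and,
# optionally, sorted artifact files.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full interesting-rule mining pipeline
#'
#' @param input one of: a path to the 12-column clinical CSV, a
#'   [TransactionSet-class], or a [SyntheticConfig-class] (the synthetic
#'   dataset is generated first).
#' @param config a [MiningConfig-class] with the thresholds; defaults to
#'   the reproduction setup (minSup 0.01, minRare 0.001, simT 0.80,
#'   confidence > 0.80, lift > 1, leverage > 0, conviction > 1).
#' @param outDir optional directory; when given, writes `patterns.csv`,
#'   `rules.csv`, `pairs.csv`, `pair_coordinates.csv` and `report.json`
#'   (all with documented total orders, so re-runs are byte-identical).
#' @return an object of class `"ruleMiningReport"` (a list of per-stage
#'   counts, thresholds and conventions) with the computed objects
#'   attached in its `objects` element (`dataset`, `frequentPatterns`,
#'   `rarePatterns`, `rules`, `pairs`, `triggers`).
#' @export
runPipeline <- function(input, config = miningConfig(), outDir = NULL) {
  validObject(config)
  rows_raw <- NA_integer_
  removed <- NA_integer_

  ds <- stage("data preparation", {
    if (is(input, "TransactionSet")) {
      input
    } else if (is(input, "SyntheticConfig")) {
      generateTransactions(input)$dataset
    } else if (is.character(input) && length(input) == 1L) {
      raw <- loadRawRecords(input)
      rows_raw <- nrow(raw)
      if (rows_raw == 0L) stop("input table has no data rows")
      cleaned <- cleanRecords(raw)
      removed <- cleaned$removed
      encodeTransactions(discretizeRecords(cleaned$records))
    } else {
      stop("input must be a file path, a TransactionSet or a SyntheticConfig")
    }
  })

  freq_pat <- stage("frequent pattern mining",
                    mineFrequent(ds, config@minSup, config@countMode))
  rare_pat <- stage("rare pattern mining",
                    mineRare(ds, config@minSup, config@minRare,
                             config@countMode))

  rules <- stage("rule generation", {
    fr <- classifyRules(filterStrong(
      generateRules(freq_pat, ds, config@classConsequentOnly), config))
    rr <- classifyRules(filterStrong(
      generateRules(rare_pat, ds, config@classConsequentOnly), config))
    concatRules(fr, rr)
  })

  t1 <- rulesOfType(rules, 1L)
  t4 <- rulesOfType(rules, 4L)
  pairs <- stage("interesting-pair matching",
                 findInterestingPairs(t4, t1, config@simT, config@strictSim))
  triggers <- summarizeTriggers(pairs)

  type_counts <- vapply(1:4, function(k)
    sum(!is.na(rules@type) & rules@type == k), integer(1))
  report <- list(
    rows_raw = rows_raw,
    rows_clean = nTransactions(ds),
    rows_removed = removed,
    n_items = nItems(ds),
    patterns = list(frequent = length(freq_pat), rare = length(rare_pat),
                    total = length(freq_pat) + length(rare_pat)),
    rules = list(frequent_strong = sum(rules@band == "frequent"),
                 rare_strong = sum(rules@band == "rare"),
                 T1 = type_counts[1], T2 = type_counts[2],
                 T3 = type_counts[3], T4 = type_counts[4]),
    interesting_pairs = length(pairs),
    distinct_rare_rules = triggers$nDistinctRareRules,
    triggers = as.list(triggers$tally),
    thresholds = list(minSup = config@minSup, minRare = config@minRare,
                      simT = config@simT, minConf = config@minConf,
                      minLift = config@minLift, minLev = config@minLev,
                      minConv = config@minConv),
    conventions = list(countMode = config@countMode,
                       strictSim = config@strictSim,
                       classConsequentOnly = config@classConsequentOnly),
    seed = config@seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(report) <- "ruleMiningReport"
  report$objects <- list(dataset = ds, frequentPatterns = freq_pat,
                         rarePatterns = rare_pat, rules = rules,
                         pairs = pairs, triggers = triggers)

  if (!is.null(outDir)) {
    stage("artifact export", {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      exportPatterns(concatPatternFrames(freq_pat, rare_pat),
                     file.path(outDir, "patterns.csv"))
      exportRules(rules, file.path(outDir, "rules.csv"))
      exportPairs(pairs, file.path(outDir, "pairs.csv"))
      exportPairCoordinates(pairs, file.path(outDir, "pair_coordinates.csv"))
      exportReport(report, file.path(outDir, "report.json"), "json")
    })
  }
  report
}

# row-bind two rule sets (same vocabulary / m)
concatRules <- function(a, b) {
  stopifnot(identical(a@vocabulary, b@vocabulary), a@m == b@m)
  new("RuleSet",
      antMask = c(a@antMask, b@antMask), consMask = c(a@consMask, b@consMask),
      countXY = c(a@countXY, b@countXY), countX = c(a@countX, b@countX),
      countY = c(a@countY, b@countY), support = c(a@support, b@support),
      confidence = c(a@confidence, b@confidence), lift = c(a@lift, b@lift),
      leverage = c(a@leverage, b@leverage),
      conviction = c(a@conviction, b@conviction),
      band = c(a@band, b@band), type = c(a@type, b@type),
      m = a@m, vocabulary = a@vocabulary, classItems = a@classItems)
}

# combined pattern export (frequent band first, then rare)
concatPatternFrames <- function(freq, rare) {
  structure(list(freq = freq, rare = rare), class = "patternFramePair")
}

#' @method as.data.frame patternFramePair
#' @export
as.data.frame.patternFramePair <- function(x, ...) {
  rbind(as.data.frame(x$freq), as.data.frame(x$rare))
}

#' Export a run report
#'
#' `"json"` writes the machine-readable report;
#' `"text"` writes a human-readable summary mirroring the count tables
#' of a mining run (type counts listed in T1-T4 order).
#'
#' @param report a `"ruleMiningReport"` from [runPipeline()].
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
exportReport <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  payload <- unclass(report)
  payload$objects <- NULL
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    lines <- c(
      "Rule mining run report",
      sprintf("  rows: raw=%s clean=%d removed=%s",
              format(payload$rows_raw), payload$rows_clean,
              format(payload$rows_removed)),
      sprintf("  items: %d", payload$n_items),
      sprintf("  patterns: frequent=%d rare=%d total=%d",
              payload$patterns$frequent, payload$patterns$rare,
              payload$patterns$total),
      sprintf("  strong rules: frequent=%d rare=%d",
              payload$rules$frequent_strong, payload$rules$rare_strong),
      sprintf("  T1=%d T2=%d T3=%d T4=%d",
              payload$rules$T1, payload$rules$T2, payload$rules$T3,
              payload$rules$T4),
      sprintf("  interesting pairs: %d (distinct rare rules: %d)",
              payload$interesting_pairs, payload$distinct_rare_rules),
      "  trigger tallies:",
      if (length(payload$triggers))
        sprintf("    %s: %d", names(payload$triggers),
                unlist(payload$triggers)) else "    (none)",
      sprintf("  thresholds: %s",
              paste(names(payload$thresholds),
                    unlist(payload$thresholds), sep = "=", collapse = " ")),
      sprintf("  conventions: %s",
              paste(names(payload$conventions),
                    unlist(payload$conventions), sep = "=", collapse = " ")),
      sprintf("  seed: %d", payload$seed)
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON run report
#'
#' @param path path written by [exportReport()] with `format = "json"`.
#' @return the report as a list (class `"ruleMiningReport"`).
#' @export
readReport <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  class(rep) <- "ruleMiningReport"
  rep
}

#' @export
print.ruleMiningReport <- function(x, ...) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  exportReport(x, tmp, "text")
  cat(readLines(tmp), sep = "\n")
  invisible(x)
}
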