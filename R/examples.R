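# Bundled worked examples from the combined heart-disease analysis:
# printed rule pairs and per-type example rules, as structured fixtures
# for regression tests and documentation. Item names use this package's
# vocabulary (see heartItemVocabulary()).

#' Worked examples from the combined heart-disease dataset
#'
#' Returns, as plain structured data, the published worked examples of
#' interesting (rare, frequent) rule pairs and of the four rule types,
#' with their printed supports, confidences and similarities. Useful as
#' regression fixtures: e.g. the antecedent Jaccard similarities can be
#' recomputed with [jaccardSimilarity()] and compared against the
#' printed values.
#'
#' @return list with elements
#'   * `m`: the cleaned transaction count (1189),
#'   * `pairs`: list of worked rule pairs, each with `frequent` and
#'     `rare` rule descriptions (antecedent, consequent and any printed
#'     support/confidence) plus the printed `similarity` (NA when not
#'     printed) and `patients` (approximate patient count implied by the
#'     frequent support, where stated),
#'   * `rules`: list of per-type example rules (`type1` .. `type4`) with
#'     their five printed metrics.
#' @export
heartWorkedExamples <- function() {
  rule <- function(antecedent, consequent, support = NA_real_,
                   confidence = NA_real_) {
    list(antecedent = antecedent, consequent = consequent,
         support = support, confidence = confidence)
  }
  pairs <- list(
    # 5-item healthy antecedent turning rare when oldpeak is high
    oldpeak_female = list(
      frequent = rule(c("hrnormal", "exangina0", "fbsugar0", "hcol", "F"),
                      "no"),
      rare = rule(c("hrnormal", "peakhigh", "exangina0", "fbsugar0",
                    "hcol", "F"), "yes"),
      similarity = 0.83, patients = NA_real_),
    # 6-item antecedent plus high oldpeak; hover-card example
    oldpeak_male = list(
      frequent = rule(c("maged", "M", "fbsugar0", "usloping", "napain",
                        "exangina0"), "no", support = 0.048,
                      confidence = 0.89),
      rare = rule(c("maged", "M", "fbsugar0", "usloping", "napain",
                    "exangina0", "peakhigh"), "yes", support = 0.003,
                  confidence = 1.0),
      similarity = 0.857, patients = NA_real_),
    # asymptomatic chest pain flipping the outcome
    asymptomatic = list(
      frequent = rule(c("peaklow", "maged", "hrhigh", "lcol", "fbsugar0"),
                      "no", support = 0.02, confidence = 0.82),
      rare = rule(c("peaklow", "maged", "hrhigh", "lcol", "fbsugar0",
                    "asym"), "yes", support = 0.004, confidence = 0.83),
      similarity = NA_real_, patients = NA_real_),
    # "rule 7": ~71 healthy patients at support 0.06, 2 at 0.002
    oldpeak_rule7 = list(
      frequent = rule(c("maged", "hrhigh", "M", "fbsugar0", "usloping",
                        "exangina0"), "no", support = 0.06),
      rare = rule(c("maged", "hrhigh", "M", "fbsugar0", "usloping",
                    "exangina0", "peakhigh"), "yes", support = 0.002),
      similarity = NA_real_, patients = 71)
  )
  typed <- function(antecedent, consequent, support, confidence, lift,
                    leverage, conviction) {
    list(antecedent = antecedent, consequent = consequent,
         support = support, confidence = confidence, lift = lift,
         leverage = leverage, conviction = conviction)
  }
  rules <- list(
    type1 = typed(c("maged", "fbsugar0", "usloping", "peaklow"), "no",
                  0.24, 0.86, 1.81, 0.11, 3.73),
    type2 = typed(c("hrnormal", "exangina1", "asym", "M"), "yes",
                  0.21, 0.92, 1.70, 0.08, 6.02),
    type3 = typed(c("fbsugar0", "tangina", "hrnormal", "exangina0",
                    "dsloping", "M"), "no",
                  0.001, 1.0, 2.11, 0.0008, Inf),
    type4 = typed(c("asym", "exangina1", "hrnormal", "flat", "ncol",
                    "elderly", "M"), "yes",
                  0.009, 1.0, 1.89, 0.004, Inf)
  )
  list(m = 1189L, pairs = pairs, rules = rules)
}

#' Locate a local copy of the combined heart-disease dataset
#'
#' The combined 1190-row, 12-column multi-source heart-disease CSV is
#' distributed by IEEE DataPort and is not bundled with this package.
#' This helper finds a user-supplied copy: an explicit `path` argument,
#' the `rareRules.heartData` option, the `RARERULES_HEART_DATA`
#' environment variable, or `heart_combined.csv` in the package's
#' `extdata` directory, in that order.
#'
#' @param path optional explicit path.
#' @return the path if a readable file is found, otherwise `NA_character_`.
#' @export
locateHeartDataset <- function(path = NULL) {
  candidates <- c(
    path,
    getOption("rareRules.heartData", default = NULL),
    Sys.getenv("RARERULES_HEART_DATA", unset = NA),
    system.file("extdata", "heart_combined.csv", package = "rareRules")
  )
  candidates <- candidates[!is.na(candidates) & nzchar(candidates)]
  hit <- candidates[file.exists(candidates)]
  if (length(hit)) hit[1] else NA_character_
}
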