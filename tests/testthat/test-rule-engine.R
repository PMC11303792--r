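# Rule generation, metric arithmetic, strong-rule filtering and typing.

test_that("metric arithmetic matches direct hand computation", {
  got <- computeMetrics(0.2, 0.25, 0.5)
  expect_equal(got$support, 0.2)
  expect_equal(got$confidence, 0.8)
  expect_equal(got$lift, 1.6)
  expect_equal(got$leverage, 0.075)
  expect_equal(got$conviction, 2.5)
})

test_that("independent antecedent and consequent give neutral metrics", {
  got <- computeMetrics(0.3 * 0.4, 0.3, 0.4)
  expect_equal(got$lift, 1)
  expect_equal(got$leverage, 0)
  expect_equal(got$conviction, 1)
})

test_that("conviction is infinite exactly for confidence-1 rules with suppY < 1", {
  expect_equal(computeMetrics(0.001, 0.001, 0.47)$conviction, Inf)
  expect_equal(computeMetrics(0.009, 0.009, 0.53)$conviction, Inf)
  # degenerate consequent covering every transaction: not infinite
  expect_equal(computeMetrics(0.2, 0.2, 1)$conviction, 1)
  expect_lt(computeMetrics(0.19, 0.2, 0.5)$conviction, Inf)
})

test_that("inconsistent supports are rejected", {
  expect_error(computeMetrics(0.3, 0.2, 0.5), "inconsistent")
  expect_error(computeMetrics(0.3, 0.5, 0.2), "inconsistent")
  expect_error(computeMetrics(0.1, 0, 0.5), "suppX")
})

test_that("rule generation enumerates every ordered split with exact metrics", {
  ts <- randomBasketTS(100, 8, density = 0.35, seed = 21)
  mat <- transactionMatrix(ts)
  ps <- mineFrequent(ts, 0.05)
  rules <- generateRules(ps, ts)
  # split counts: sum over patterns of 2^k - 2
  ks <- lengths(patternItems(ps))
  expect_equal(length(rules), sum(2^ks[ks >= 2] - 2))
  # against the R-level oracle: same rules, same supports
  got <- as.data.frame(rules)
  got <- got[order(got$antecedents, got$consequent), ]
  oracle <- oracleRules(mat, patternItems(ps))
  expect_equal(got$antecedents, oracle$antecedents)
  expect_equal(got$consequent, oracle$consequent)
  om <- computeMetrics(oracle$suppXY, oracle$suppX, oracle$suppY)
  expect_equal(got$support, om$support)
  expect_equal(got$confidence, om$confidence)
  expect_equal(got$lift, om$lift)
  expect_equal(got$leverage, om$leverage)
  expect_equal(got$conviction, om$conviction)
})

test_that("a k-item pattern yields 2^k - 2 candidate rules", {
  mat <- matrix(TRUE, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  ts <- TransactionSet(mat)
  ps <- mineFrequent(ts, 1.0)
  rules <- generateRules(ps, ts)
  df <- as.data.frame(rules)
  pair_rules <- df[df$antecedents %in% c("a", "b") &
                     df$consequent %in% c("a", "b"), ]
  expect_equal(nrow(pair_rules), 2)  # a->b and b->a
  n_items <- lengths(strsplit(df$antecedents, ";")) +
    lengths(strsplit(df$consequent, ";"))
  expect_equal(sum(n_items == 3), 6)  # 2^3 - 2 splits of {a,b,c}
})

test_that("metric identities hold to 1e-12 on mined rules", {
  ts <- randomBasketTS(150, 9, density = 0.3, seed = 31)
  rules <- generateRules(mineFrequent(ts, 0.04), ts)
  suppX <- rules@countX / rules@m
  suppY <- rules@countY / rules@m
  suppXY <- rules@countXY / rules@m
  expect_true(all(abs(rules@lift - rules@confidence / suppY) <= 1e-12))
  expect_true(all(abs(rules@leverage - (suppXY - suppX * suppY)) <= 1e-12))
  expect_true(all(rules@confidence >= suppXY - 1e-15))
  # conviction boundary behaviour: conv > 1 <=> conf > suppY (conf < 1)
  fin <- rules@confidence < 1
  expect_equal(rules@conviction[fin] > 1 + 1e-15,
               rules@confidence[fin] > suppY[fin] + 1e-15)
})

test_that("lift is symmetric in antecedent and consequent", {
  ts <- randomBasketTS(80, 7, density = 0.4, seed = 61)
  rules <- generateRules(mineFrequent(ts, 0.1), ts)
  df <- as.data.frame(rules)
  key_fwd <- paste(df$antecedents, df$consequent, sep = "|")
  key_rev <- paste(df$consequent, df$antecedents, sep = "|")
  rev_lift <- df$lift[match(key_fwd, key_rev)]
  expect_equal(df$lift, rev_lift)
})

test_that("strong-rule filtering uses strict thresholds", {
  vocab <- testVocab()
  mk <- function(confidence, lift, leverage, conviction,
                 countXY = 20L, band = "frequent") {
    new("RuleSet",
        antMask = 1, consMask = 2, countXY = countXY, countX = 25L,
        countY = 50L, support = countXY / 100, confidence = confidence,
        lift = lift, leverage = leverage, conviction = conviction,
        band = band, type = NA_integer_, m = 100L, vocabulary = vocab,
        classItems = c("no", "yes"))
  }
  cfg <- miningConfig(minSup = 0.1, minRare = 0.01)
  pass <- mk(0.85, 1.5, 0.05, 2)
  expect_length(filterStrong(pass, cfg), 1)
  expect_length(filterStrong(mk(0.80, 1.5, 0.05, 2), cfg), 0)   # conf == 0.80
  expect_length(filterStrong(mk(0.85, 1.0, 0.05, 2), cfg), 0)   # lift == 1
  expect_length(filterStrong(mk(0.85, 1.5, 0.00, 2), cfg), 0)   # lev == 0
  expect_length(filterStrong(mk(0.85, 1.5, 0.05, 1), cfg), 0)   # conv == 1
  expect_length(filterStrong(mk(1.0, 1.5, 0.05, Inf), cfg), 1)  # Inf passes
  # band-support discipline
  expect_length(filterStrong(mk(0.85, 1.5, 0.05, 2, countXY = 5L), cfg), 0)
  expect_length(filterStrong(mk(0.85, 1.5, 0.05, 2, countXY = 5L,
                                band = "rare"), cfg), 1)
  expect_length(filterStrong(mk(0.85, 1.5, 0.05, 2, countXY = 20L,
                                band = "rare"), cfg), 0)
})

test_that("typing assigns class-consequent rules by band and outcome", {
  vocab <- testVocab()
  ants <- list(c("v01", "v02"), c("v03"))
  freq_no <- classifyRules(makeClassRuleSet(ants, "no", "frequent", vocab))
  freq_yes <- classifyRules(makeClassRuleSet(ants, "yes", "frequent", vocab))
  rare_no <- classifyRules(makeClassRuleSet(ants, "no", "rare", vocab))
  rare_yes <- classifyRules(makeClassRuleSet(ants, "yes", "rare", vocab))
  expect_equal(ruleType(freq_no), c(1L, 1L))
  expect_equal(ruleType(freq_yes), c(2L, 2L))
  expect_equal(ruleType(rare_no), c(3L, 3L))
  expect_equal(ruleType(rare_yes), c(4L, 4L))

  # non-singleton class consequent stays untyped
  mixed <- makeClassRuleSet(list(c("v01")), "yes", "rare", vocab)
  mixed@consMask <- mixed@consMask + 2^(match("v05", vocab) - 1)
  expect_true(is.na(ruleType(classifyRules(mixed))))

  # non-class consequent stays untyped
  plain <- makeClassRuleSet(list(c("v01")), "no", "frequent", vocab)
  plain@consMask <- 2^(match("v06", vocab) - 1)
  expect_true(is.na(ruleType(classifyRules(plain))))
})

test_that("type sets are disjoint and nested in their bands end to end", {
  planted <- list(list(items = c("maged", "hrhigh", "M"), support = 0.08,
                       class = "no"))
  gen <- generateTransactions(heartSyntheticConfig(m = 400,
                                                   planted = planted,
                                                   seed = 17))
  ds <- gen$dataset
  cfg <- miningConfig(minSup = 0.05, minRare = 0.01,
                      classConsequentOnly = TRUE)
  freq <- classifyRules(filterStrong(
    generateRules(mineFrequent(ds, 0.05), ds, TRUE), cfg))
  rare <- classifyRules(filterStrong(
    generateRules(mineRare(ds, 0.05, 0.01), ds, TRUE), cfg))
  expect_true(all(ruleType(freq) %in% c(1L, 2L, NA)))
  expect_true(all(ruleType(rare) %in% c(3L, 4L, NA)))
  expect_true(all(band(rulesOfType(freq, 1L)) == "frequent"))
  expect_true(all(band(rulesOfType(rare, 4L)) == "rare"))
})

test_that("class-consequent-only generation matches the filtered full mode", {
  ts <- randomBasketTS(90, 6, density = 0.4, seed = 13)
  mat <- transactionMatrix(ts)
  colnames(mat)[5:6] <- c("no", "yes")
  # make the class pair one-hot so it behaves like an outcome
  mat[, "no"] <- !mat[, "yes"]
  info <- data.frame(item = colnames(mat),
                     attribute = c(colnames(mat)[1:4], "class", "class"))
  ts <- TransactionSet(mat, info)
  ps <- mineFrequent(ts, 0.05)
  full <- as.data.frame(generateRules(ps, ts))
  cls <- as.data.frame(generateRules(ps, ts, classConsequentOnly = TRUE))
  sub <- full[full$consequent %in% c("no", "yes"), ]
  o <- function(d) d[order(d$antecedents, d$consequent), , drop = FALSE]
  expect_equal(o(sub)$antecedents, o(cls)$antecedents)
  expect_equal(o(sub)$support, o(cls)$support)
})
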