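# Jaccard matching of rare against frequent antecedents, trigger
# attribution and the trigger summary.

test_that("Jaccard similarity behaves as a set similarity", {
  expect_equal(jaccardSimilarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardSimilarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccardSimilarity(c("a", "a", "b"), c("b", "a")), 1)
  expect_equal(jaccardSimilarity(letters[1:5], c(letters[1:5], "x")), 5 / 6)
  expect_equal(jaccardSimilarity(letters[1:6], c(letters[1:6], "x")), 6 / 7)
  # symmetry and range on random sets
  set.seed(3)
  for (i in 1:25) {
    a <- sample(letters, sample(1:8, 1))
    b <- sample(letters, sample(1:8, 1))
    s <- jaccardSimilarity(a, b)
    expect_equal(s, jaccardSimilarity(b, a))
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s == 1, setequal(a, b))
  }
  expect_error(jaccardSimilarity(character(0), "a"), "non-empty")
})

test_that("a one-extra-item rare antecedent pairs at k/(k+1) with its trigger", {
  vocab <- testVocab()
  freq_ant <- c("v01", "v02", "v03", "v04")
  rare_ant <- c(freq_ant, "v07")
  rare <- makeClassRuleSet(list(rare_ant), "yes", "rare", vocab)
  freq <- makeClassRuleSet(list(freq_ant), "no", "frequent", vocab)
  pairs <- findInterestingPairs(rare, freq, 0.80)
  expect_length(pairs, 1)
  expect_equal(similarity(pairs), 4 / 5)
  expect_equal(triggerItems(pairs)[[1]], "v07")
  df <- as.data.frame(pairs)
  expect_equal(df$rare_consequent, "yes")
  expect_equal(df$frequent_consequent, "no")
  # strict mode drops the boundary pair
  expect_length(findInterestingPairs(rare, freq, 0.80, strict = TRUE), 0)
})

test_that("weakly overlapping antecedents do not pair", {
  vocab <- testVocab()
  rare <- makeClassRuleSet(list(c("v01", "v02", "v05", "v06", "v07", "v08")),
                           "yes", "rare", vocab)
  freq <- makeClassRuleSet(list(c("v01", "v02", "v03", "v04", "v09", "v10")),
                           "no", "frequent", vocab)
  expect_length(findInterestingPairs(rare, freq, 0.80), 0)
})

test_that("raising the similarity threshold never adds pairs", {
  set.seed(11)
  vocab <- testVocab()
  pool <- sprintf("v%02d", 1:10)
  rare <- makeClassRuleSet(replicate(60, sample(pool, sample(3:7, 1)),
                                     simplify = FALSE), "yes", "rare", vocab)
  freq <- makeClassRuleSet(replicate(60, sample(pool, sample(3:7, 1)),
                                     simplify = FALSE), "no", "frequent",
                           vocab)
  prev <- NULL
  for (simT in c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)) {
    cur <- as.data.frame(findInterestingPairs(rare, freq, simT))
    key <- paste(cur$rare_antecedents, cur$frequent_antecedents)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- paste(
      as.data.frame(findInterestingPairs(rare, freq, simT))$rare_antecedents,
      as.data.frame(findInterestingPairs(rare, freq, simT))$frequent_antecedents)
  }
})

test_that("pair matching equals the quadratic all-pairs oracle", {
  set.seed(19)
  vocab <- testVocab()
  pool <- sprintf("v%02d", 1:10)
  rare_ants <- unique(replicate(250, sort(sample(pool, sample(3:8, 1))),
                                simplify = FALSE))
  freq_ants <- unique(replicate(250, sort(sample(pool, sample(3:8, 1))),
                                simplify = FALSE))
  rare <- makeClassRuleSet(rare_ants, "yes", "rare", vocab)
  freq <- makeClassRuleSet(freq_ants, "no", "frequent", vocab)
  for (simT in c(0.6, 0.8)) {
    got <- as.data.frame(findInterestingPairs(rare, freq, simT))
    got <- got[order(got$rare_antecedents, got$frequent_antecedents), ]
    oracle <- oraclePairScan(rare_ants, freq_ants, simT)
    expect_equal(got$rare_antecedents, oracle$rare)
    expect_equal(got$frequent_antecedents, oracle$freq)
    expect_equal(got$similarity, oracle$similarity)
  }
})

test_that("triggers partition the antecedent difference exactly", {
  set.seed(23)
  vocab <- testVocab()
  pool <- sprintf("v%02d", 1:10)
  rare_ants <- replicate(80, sample(pool, sample(4:8, 1)), simplify = FALSE)
  freq_ants <- replicate(80, sample(pool, sample(4:8, 1)), simplify = FALSE)
  rare <- makeClassRuleSet(rare_ants, "yes", "rare", vocab)
  freq <- makeClassRuleSet(freq_ants, "no", "frequent", vocab)
  pairs <- findInterestingPairs(rare, freq, 0.6)
  expect_gt(length(pairs), 0)
  df <- as.data.frame(pairs)
  for (i in seq_len(nrow(df))) {
    ra <- strsplit(df$rare_antecedents[i], ";")[[1]]
    fa <- strsplit(df$frequent_antecedents[i], ";")[[1]]
    trig <- if (nzchar(df$trigger_items[i]))
      strsplit(df$trigger_items[i], ";")[[1]] else character(0)
    rev_ <- if (nzchar(df$reverse_items[i]))
      strsplit(df$reverse_items[i], ";")[[1]] else character(0)
    expect_setequal(trig, setdiff(ra, fa))
    expect_setequal(rev_, setdiff(fa, ra))
    if (df$similarity[i] < 1) expect_gt(length(trig) + length(rev_), 0)
  }
  # output sorted by similarity descending, rare support ascending
  expect_true(all(diff(df$similarity) <= 1e-12))
})

test_that("the trigger summary tallies pairs and distinct rare rules", {
  vocab <- testVocab()
  base <- c("v01", "v02", "v03", "v04")
  rare <- makeClassRuleSet(list(c(base, "v07")), "yes", "rare", vocab)
  freq <- makeClassRuleSet(list(base, c(base, "v08")), "no", "frequent",
                           vocab)
  pairs <- findInterestingPairs(rare, freq, 0.6)
  expect_length(pairs, 2)
  summ <- summarizeTriggers(pairs)
  expect_equal(summ$nPairs, 2)
  expect_equal(summ$nDistinctRareRules, 1)  # one rare rule, two matches
  expect_equal(unname(summ$tally[["v07"]]), 2)

  single <- findInterestingPairs(rare,
                                 makeClassRuleSet(list(base), "no",
                                                  "frequent", vocab), 0.8)
  s1 <- summarizeTriggers(single)
  expect_equal(s1$nPairs, 1)
  expect_equal(as.list(s1$tally), list(v07 = 1L))
})

test_that("rules without the matching class consequents are ignored", {
  vocab <- testVocab()
  base <- c("v01", "v02", "v03", "v04", "v05")
  rare_wrong <- makeClassRuleSet(list(c(base, "v07")), "no", "rare", vocab)
  freq <- makeClassRuleSet(list(base), "no", "frequent", vocab)
  expect_length(findInterestingPairs(rare_wrong, freq, 0.8), 0)
  # and empty inputs give an empty result, not an error
  empty <- rare_wrong[integer(0)]
  expect_length(findInterestingPairs(empty, freq, 0.8), 0)
})
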