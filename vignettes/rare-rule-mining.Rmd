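---
title: "Mining unexpected rare association rules from clinical transaction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining unexpected rare association rules from clinical transaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareRules)
```

## The problem and the model

Association rule mining over boolean patient transactions is attractive in
clinical settings because every rule is directly readable: *if* a patient
shows this set of findings, *then* this outcome is observed with a stated
frequency. Frequent rules, however, mostly restate what clinicians already
know. The interesting signal often hides in **rare** rules: combinations of
findings that occur in only a handful of patients but flip the predicted
outcome relative to a well-supported "belief" rule.

`rareRules` implements that contrast mining in three phases:

1. **Encode.** A 12-column clinical records table is cleaned (rows with an
   invalid ST-slope code of 0 are dropped), the four continuous attributes
   (age, cholesterol, maximum heart rate, oldpeak — exercise-induced ST
   depression) are discretized into clinically conventional bins, and the
   ten retained attributes are one-hot encoded into a `TransactionSet`:
   a boolean matrix whose items form mutually exclusive groups per
   attribute, plus a binary `no`/`yes` outcome pair.
2. **Mine and extract.** Frequent patterns are itemsets with support
   $\mathrm{Supp}(X) = \sigma(X)/m \ge minSup$; rare patterns occupy the
   band $minRare \le \mathrm{Supp}(X) < minSup$. Every pattern with at
   least two items is split into all ordered (antecedent, consequent)
   pairs, and each candidate rule $X \Rightarrow Y$ is scored with the five
   classical metrics
   $$\mathrm{Supp}(X \Rightarrow Y) = \frac{\sigma(X \cup Y)}{m},\quad
     \mathrm{Conf} = \frac{\mathrm{Supp}(X \Rightarrow Y)}{\mathrm{Supp}(X)},\quad
     \mathrm{lift} = \frac{\mathrm{Supp}(X \Rightarrow Y)}{\mathrm{Supp}(X)\,\mathrm{Supp}(Y)},$$
   $$\mathrm{lev} = \mathrm{Supp}(X \Rightarrow Y) - \mathrm{Supp}(X)\,\mathrm{Supp}(Y),\quad
     \mathrm{conv} = \frac{1 - \mathrm{Supp}(Y)}{1 - \mathrm{Conf}}.$$
   Strong rules must *exceed* every threshold (confidence $> 0.80$,
   lift $> 1$, leverage $> 0$, conviction $> 1$; all strict). Strong rules
   whose consequent is exactly one class item are typed:
   T1 frequent $\Rightarrow$ `no`, T2 frequent $\Rightarrow$ `yes`,
   T3 rare $\Rightarrow$ `no`, T4 rare $\Rightarrow$ `yes`.
3. **Match.** Every rare disease-predicting rule (T4) is compared against
   every frequent health-predicting rule (T1) by the Jaccard similarity of
   their antecedents, $|A \cap X| / |A \cup X|$. Pairs reaching the
   similarity threshold `simT` have, by construction, opposite consequents;
   each is an *interesting* (unexpected) pair, and the items present only
   in the rare antecedent are its **trigger factors** — the findings whose
   appearance flips the predicted outcome from healthy to diseased.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `minSup` | 0.01 | frequent-band support threshold (fraction of transactions) |
| `minRare` | 0.001 | lower edge of the rare band |
| `simT` | 0.80 | antecedent Jaccard threshold for pair matching (inclusive) |
| `minConf` | 0.80 | strong-rule confidence threshold (strict `>`) |
| `minLift`, `minLev`, `minConv` | 1, 0, 1 | remaining strong-rule thresholds (strict `>`) |
| `countMode` | `"ceiling"` | threshold comparison convention, see below |
| `classConsequentOnly` | `FALSE` | restrict rule splits to single-class consequents |

The defaults are the experimental setup used for the combined multi-source
heart-disease dataset (1190 rows, 1189 after cleaning), and all of them are
recorded in every run report.

## Numerical and convention choices

* **Threshold rounding.** Support thresholds are fractions but occurrence
  counts are integers. The default `"ceiling"` mode compares integer
  counts, `count >= ceiling(th * m)` — on $m = 1189$ this makes the
  frequent cutoff 12 transactions and the rare cutoff 2. Because the
  rounding rule is a genuine convention choice, a `"fraction"` mode
  (float comparison `support >= th`) is provided, and the run report
  states which mode produced its counts. The ceiling computation guards
  against IEEE noise (`ceiling(th * m - 1e-9)`) so an exactly integral
  product is never rounded up.
* **Interval closure.** Discretization uses left-open/right-closed bins
  `(a, b]`, the convention under which the cholesterol scheme's left edge
  of $-1$ admits the 0 values present in the combined dataset; oldpeak
  exactly 1.0 therefore falls in the low bin. The flag is exposed
  (`right =` in `discretizeRecords()`).
* **Rule band.** A rule inherits the band of its source pattern, i.e. of
  $X \cup Y$ — the support printed for a rule is the support of the full
  itemset, which is also what the band thresholds are applied to.
* **Conviction at confidence 1.** Reported as `Inf` whenever
  $\mathrm{Supp}(Y) < 1$ (and serialized as the string `"inf"` in CSV
  exports); it passes the `conviction > 1` filter. In the degenerate case
  $\mathrm{Conf} = 1,\ \mathrm{Supp}(Y) = 1$ the limit is taken as 1.
* **Similarity threshold closure.** Matching is inclusive
  (`similarity >= simT`) by default with a strict-mode flag; at
  `simT = 0.80` the published worked examples (0.83, 0.857) are strictly
  above the threshold either way, so the choice is observationally
  neutral there.
* **Split enumeration.** All $2^{|P|} - 2$ ordered splits of each pattern
  are generated by default — global rule counts depend on this convention.
  `classConsequentOnly = TRUE` short-circuits to single-class-item
  consequents, which is much faster and sufficient whenever only the
  typed rules (T1–T4) and the pair matching are of interest.
* **Determinism.** Patterns, rules and pairs are sorted with documented,
  locale-independent total orders (itemset size then C-locale item
  string; similarity descending, rare support ascending, antecedent
  strings); identical inputs therefore give byte-identical exports.
* **Scale.** Itemsets are held as 52-bit masks (an error is raised beyond
  52 items — the clinical schema has 27), and FP-growth, the split
  enumeration and the all-pairs Jaccard scan run in compiled code; the
  reproduction setting (~80k patterns, ~450k candidate rules, ~25M
  candidate pairs) takes on the order of seconds.

Rare mining is implemented as complete mining at `minRare` followed by a
band partition. This is output-equivalent to a dedicated rare-pattern
traversal — the band is defined purely by support — and makes the partition
identity `frequent(minRare) = frequent(minSup) ⊎ rare(minSup, minRare)`
hold by construction, which the test suite verifies against an independent
exhaustive enumerator.

## What the synthetic generator emulates — and what it does not

`generateTransactions()` produces datasets with the heart-disease schema's
*structure*: mutually exclusive item groups per attribute, a binary class
pair, and planted itemsets with exact supports in either band. Planting is
deterministic — rows are assigned, not sampled, and background rows that
would accidentally contain a planted itemset are repaired — so a planted
pattern's band membership can never flip on a sampling fluke, and
`floor(support * m)` is realized exactly (the tests rely on this).
Background cells are drawn independently per attribute from configurable
marginals; `heartSyntheticConfig()` uses rounded, plausible marginals and
an approximate 0.53 `yes` class balance.

What the generator does **not** emulate: correlations between background
attributes (real risk factors co-occur), any dependence of the outcome on
background findings, or the continuous measurement process behind the bins
(generation happens post-discretization, at the item level). Passing tests
on synthetic data therefore demonstrate *algorithmic* correctness —
exact supports, complete mining, correct matching — not clinical validity
of any discovered rule.

## Degenerate inputs and failure modes

Empty datasets refuse to mine; empty itemsets refuse a support query;
vocabularies beyond 52 items refuse rule generation; brute-force
enumeration refuses more than 20 items. Planting demands that are jointly
infeasible (overlapping row requirements exceeding $m$, or collisions that
cannot be repaired without touching planted cells) error out before any
sampling. Pipeline errors carry the failing stage's name.

## Problem sizes used by the test suite

The suite runs entirely on synthetic and random data: the FP-growth
vs. exhaustive-enumeration equivalence uses 100 random datasets with
$m \le 200$, $n \le 15$ and count thresholds 2–8; pair matching is checked
against a quadratic scan on up to 400 rules per side; end-to-end planted
recovery uses $m = 1189$ (the cleaned size of the combined dataset) at the
default thresholds. The full reproduction of the published counts requires
the combined IEEE DataPort CSV, which is not redistributed with the
package; `locateHeartDataset()` documents how to point the suite at a
local copy, and the corresponding acceptance test reports its absence
rather than silently skipping.

## A complete run

```{r example, eval = FALSE}
freq_ant <- c("maged", "hrhigh", "M", "fbsugar0", "usloping", "exangina0")
cfg <- heartSyntheticConfig(
  m = 1189,
  planted = list(
    list(items = freq_ant, support = 0.05, class = "no"),
    list(items = c(freq_ant, "peakhigh"), support = 0.004, class = "yes")),
  seed = 101)
report <- runPipeline(cfg, miningConfig(classConsequentOnly = TRUE),
                      outDir = "run-artifacts")
report
as.data.frame(report$objects$pairs)
```

The planted pair — a healthy middle-aged male profile that becomes a rare
disease-predicting rule once high oldpeak is added — is recovered with
similarity $6/7 \approx 0.857$ and trigger item `peakhigh`.

## Known limitations

* Vocabularies above 52 items are not supported by the rule/pair stages.
* The pipeline driver matches rare⇒`yes` against frequent⇒`no`; the
  symmetric contrast is available via
  `findInterestingPairs(..., direction = "rare-no")` but is not part of
  the standard run.
* Trigger tallies credit a multi-trigger pair to each of its trigger
  items, so per-item tallies can sum to more than the pair count; the
  distinct-rare-rule count is reported alongside for disambiguation.
* The mining itself is exact; any clinical interpretation of discovered
  rules requires domain review and external validation.
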