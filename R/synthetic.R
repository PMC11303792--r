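# Synthetic transaction generator: heart-schema-like attribute groups, a
# binary class item, and deterministically planted itemsets with exact
# realized supports in the frequent or rare band. Planting assigns rows;
# only the background is sampled, so band membership never flips on a
# sampling fluke.

#' SyntheticConfig: specification of a synthetic transaction dataset
#'
#' @slot m integer transaction count.
#' @slot groups named list; one entry per (non-class) attribute group,
#'   each a named numeric vector of background category probabilities
#'   summing to 1 (names are the item labels).
#' @slot planted list of planted-pattern specs, each a list with `items`
#'   (character, at most one item per group), `support` (target fraction
#'   in (0, 1]) and `class` (`"yes"`, `"no"` or `"none"`).
#' @slot classProb numeric, background probability of the `yes` class
#'   item on non-planted rows.
#' @slot seed integer random seed.
#' @export
setClass("SyntheticConfig",
  representation(
    m = "integer",
    groups = "list",
    planted = "list",
    classProb = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (object@m < 1L) msgs <- c(msgs, "m must be positive")
  all_items <- unlist(lapply(object@groups, names))
  if (anyDuplicated(c(all_items, "no", "yes")))
    msgs <- c(msgs, "item labels must be unique across groups")
  for (g in names(object@groups)) {
    p <- object@groups[[g]]
    if (length(p) < 2L)
      msgs <- c(msgs, sprintf("group '%s' needs at least 2 categories", g))
    if (abs(sum(p) - 1) > 1e-8)
      msgs <- c(msgs, sprintf("probabilities of group '%s' must sum to 1", g))
    if (any(p < 0)) msgs <- c(msgs, sprintf("group '%s' has negative probability", g))
  }
  for (i in seq_along(object@planted)) {
    s <- object@planted[[i]]
    if (!all(c("items", "support", "class") %in% names(s))) {
      msgs <- c(msgs, sprintf("planted spec %d lacks items/support/class", i))
      next
    }
    if (!(s$support > 0 && s$support <= 1))
      msgs <- c(msgs, sprintf("planted spec %d: support must lie in (0, 1]", i))
    if (!s$class %in% c("yes", "no", "none"))
      msgs <- c(msgs, sprintf("planted spec %d: class must be yes/no/none", i))
    bad <- setdiff(s$items, all_items)
    if (length(bad))
      msgs <- c(msgs, sprintf("planted spec %d: unknown item(s) %s", i,
                              paste(bad, collapse = ", ")))
    grp <- vapply(s$items, function(it)
      names(object@groups)[vapply(object@groups,
                                  function(p) it %in% names(p), logical(1))][1],
      character(1))
    if (anyDuplicated(grp))
      msgs <- c(msgs, sprintf("planted spec %d: at most one item per group", i))
  }
  if (!(object@classProb >= 0 && object@classProb <= 1))
    msgs <- c(msgs, "classProb must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig constructor
#'
#' @param m transaction count.
#' @param groups named list of named probability vectors (see the class).
#' @param planted list of planted-pattern specs, each
#'   `list(items =, support =, class =)`.
#' @param classProb background probability of the `yes` class.
#' @param seed random seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(m, groups, planted = list(), classProb = 0.53,
                            seed = 1L) {
  planted <- lapply(planted, function(s) {
    if (is.null(s$class)) s$class <- "none"
    s
  })
  new("SyntheticConfig", m = as.integer(m), groups = groups,
      planted = planted, classProb = classProb, seed = as.integer(seed))
}

#' Heart-schema synthetic configuration
#'
#' The ten-attribute item schema of the combined heart-disease dataset
#' with rounded, plausible background marginals and a background class
#' balance of about 0.53 `yes` (approximate; documented as such).
#'
#' @param m transaction count (default 1189, the cleaned dataset size).
#' @param planted planted-pattern specs, as in [syntheticConfig()].
#' @param seed random seed.
#' @return a [SyntheticConfig-class].
#' @export
heartSyntheticConfig <- function(m = 1189, planted = list(), seed = 1L) {
  groups <- list(
    age = c(young = 0.05, maged = 0.60, elderly = 0.35),
    sex = c(F = 0.24, M = 0.76),
    chest_pain_type = c(tangina = 0.05, atangina = 0.18,
                        napain = 0.22, asym = 0.55),
    cholesterol = c(lcol = 0.30, ncol = 0.25, hcol = 0.45),
    fasting_blood_sugar = c(fbsugar0 = 0.77, fbsugar1 = 0.23),
    max_heart_rate = c(hrlow = 0.10, hrnormal = 0.60, hrhigh = 0.30),
    exercise_angina = c(exangina0 = 0.60, exangina1 = 0.40),
    oldpeak = c(peaklow = 0.55, peakmoderate = 0.25, peakhigh = 0.20),
    st_slope = c(usloping = 0.40, flat = 0.50, dsloping = 0.10)
  )
  syntheticConfig(m = m, groups = groups, planted = planted,
                  classProb = 0.53, seed = seed)
}

# group of each item label
.itemGroups <- function(groups) {
  setNames(rep(names(groups), lengths(groups)),
           unlist(lapply(groups, names)))
}

#' Generate a synthetic TransactionSet with planted itemsets
#'
#' Planting is deterministic: for each spec, exactly
#' `floor(support * m)` transactions end up containing the planted
#' itemset — rows are assigned before sampling, background rows that
#' would collide with a planted itemset are repaired, and specs are
#' processed largest-first so nested plants (a rare superset of a
#' frequent antecedent) count correctly. `class = "yes"/"no"` pins the
#' class item on the planted rows (giving confidence-1 planted rules);
#' remaining cells are drawn from the background model.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `dataset` (a [TransactionSet-class]) and `realized`
#'   (data.frame reporting target and realized support per planted spec).
#' @export
generateTransactions <- function(config) {
  validObject(config)
  m <- config@m
  groups <- config@groups
  grp_names <- names(groups)
  item_grp <- .itemGroups(groups)
  specs <- config@planted
  specs_order <- order(-vapply(specs, function(s) length(s$items),
                               integer(1)))

  lab <- matrix(NA_character_, nrow = m, ncol = length(grp_names) + 1L,
                dimnames = list(NULL, c(grp_names, "target")))
  locked <- matrix(FALSE, nrow = m, ncol = ncol(lab),
                   dimnames = dimnames(lab))
  designated <- vector("list", length(specs))

  # ---- deterministic planting (no randomness) ----
  for (si in specs_order) {
    s <- specs[[si]]
    k <- floor(s$support * m)
    want <- setNames(s$items, item_grp[s$items])  # group -> item label
    gcols <- names(want)
    if (k == 0L) { designated[[si]] <- integer(0); next }

    # rows already containing the itemset (nested plants placed earlier)
    has_all <- rep(TRUE, m)
    for (g in gcols)
      has_all <- has_all & !is.na(lab[, g]) & lab[, g] == want[[g]]
    existing <- which(has_all)
    if (length(existing) > k)
      stop(sprintf(paste0("planting infeasible: itemset of spec %d already ",
                          "occurs in %d rows, target is %d"),
                   si, length(existing), k))
    need <- k - length(existing)
    rows <- integer(0)
    if (need > 0L) {
      eligible <- rep(TRUE, m)
      for (g in gcols)
        eligible <- eligible & (is.na(lab[, g]) | lab[, g] == want[[g]])
      if (s$class != "none")
        eligible <- eligible &
          (is.na(lab[, "target"]) | lab[, "target"] == s$class)
      eligible[existing] <- FALSE
      rows <- which(eligible)[seq_len(min(need, sum(eligible)))]
      if (length(rows) < need)
        stop(sprintf("planting infeasible: spec %d needs %d more rows, only %d available",
                     si, need, length(rows)))
      for (g in gcols) {
        lab[rows, g] <- want[[g]]
        locked[rows, g] <- TRUE
      }
    }
    designated[[si]] <- sort(c(existing, rows))
    for (g in gcols) locked[designated[[si]], g] <- TRUE
    # pin the class on designated rows whose outcome is still free
    if (s$class != "none") {
      free_cls <- designated[[si]][!locked[designated[[si]], "target"]]
      lab[free_cls, "target"] <- s$class
      locked[free_cls, "target"] <- TRUE
    }
  }

  # ---- background sampling ----
  set.seed(config@seed)
  for (g in grp_names) {
    idx <- which(is.na(lab[, g]))
    if (length(idx))
      lab[idx, g] <- sample(names(groups[[g]]), length(idx), replace = TRUE,
                            prob = groups[[g]])
  }
  idx <- which(is.na(lab[, "target"]))
  if (length(idx))
    lab[idx, "target"] <- ifelse(stats::runif(length(idx)) < config@classProb,
                                 "yes", "no")

  # ---- repair accidental background copies of planted itemsets ----
  for (pass in seq_len(100L)) {
    dirty <- FALSE
    for (si in seq_along(specs)) {
      s <- specs[[si]]
      if (floor(s$support * m) == 0L) next
      gcols <- item_grp[s$items]
      has_all <- rep(TRUE, m)
      for (j in seq_along(s$items))
        has_all <- has_all & lab[, gcols[j]] == s$items[j]
      extras <- setdiff(which(has_all), designated[[si]])
      for (row in extras) {
        free <- gcols[!locked[row, gcols]]
        if (length(free) == 0L)
          stop(sprintf("planted demands jointly infeasible: spec %d collides with other plants in row %d",
                       si, row))
        g <- free[1]
        cats <- names(groups[[g]])
        cur <- match(lab[row, g], cats)
        lab[row, g] <- cats[(cur %% length(cats)) + 1L]
        dirty <- TRUE
      }
    }
    if (!dirty) break
    if (pass == 100L) stop("planting repair did not converge")
  }

  vocab <- data.frame(
    item = c(unlist(lapply(groups, names), use.names = FALSE), "no", "yes"),
    attribute = c(rep(grp_names, lengths(groups)), "target", "target"),
    stringsAsFactors = FALSE
  )
  ds <- encodeFromLabels(as.data.frame(lab, stringsAsFactors = FALSE), vocab)

  realized <- do.call(rbind, lapply(seq_along(specs), function(si) {
    s <- specs[[si]]
    k <- floor(s$support * m)
    cnt <- if (length(s$items))
      supportOf(ds, s$items)$count else NA_integer_
    data.frame(spec = si,
               items = paste(sort(s$items), collapse = ";"),
               class = s$class,
               target_support = s$support,
               planted_count = k,
               realized_count = cnt,
               realized_support = cnt / m,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(realized) && nrow(realized) &&
      any(realized$realized_count != realized$planted_count))
    stop("internal error: realized planted support deviates from target")

  list(dataset = ds, realized = realized)
}
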