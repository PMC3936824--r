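#' Interestingness measure vocabulary
#'
#' @return Character vector of measure names accepted by
#'   [rule_interestingness()] and [score_rules()]. Each has a traditional and
#'   a semantic variant, obtained by plugging the corresponding support
#'   function into the same formula.
#' @export
measure_names <- function() {
  c("support", "confidence", "lift", "conviction", "leverage",
    "jaccard", "cosine", "correlation")
}

#' Traditional (exact-match) support
#'
#' The fraction of transactions containing every item of the itemset. The
#' empty itemset is vacuously contained in every transaction.
#'
#' @param items Character vector of item identifiers.
#' @param db A [transaction database][as_transactions()].
#' @return A value in `[0, 1]`.
#' @export
itemset_support <- function(items, db) {
  if (!inherits(db, "transaction_db") || nrow(db) == 0) {
    abort("support requires a non-empty transaction database")
  }
  ti <- transaction_items(db)
  mean(map_lgl(ti, function(t) all(items %in% t)))
}

#' Semantic support
#'
#' Generalises support by matching every itemset item to its most similar
#' item in each transaction: the mean over transactions of the product over
#' itemset items of the best (clamped) similarity achieved in that
#' transaction. A transaction with no items contributes 0. With the
#' exact-match similarity this reduces exactly to traditional support.
#'
#' @inheritParams itemset_support
#' @param sim A [similarity_function()] (should be built with `clamp = TRUE`).
#' @return A value in `[0, 1]`.
#' @export
semantic_support <- function(items, db, sim) {
  if (!inherits(db, "transaction_db") || nrow(db) == 0) {
    abort("support requires a non-empty transaction database")
  }
  if (length(items) == 0) return(1)
  ti <- transaction_items(db)
  per_t <- map_dbl(ti, function(t) {
    if (length(t) == 0) return(0)
    prod(map_dbl(items, function(i) max(sim_value(sim, i, t))))
  })
  mean(per_t)
}

#' Pluggable support function
#'
#' Wraps traditional or semantic support behind a common callable contract
#' `(items, db) -> value in [0, 1]`, so every interestingness measure can be
#' computed in either mode by substitution of the support function.
#'
#' @param mode `"traditional"` or `"semantic"`.
#' @param sim A [similarity_function()]; required in semantic mode.
#' @return A function of `(items, db)` with class `support_function`.
#' @export
support_function <- function(mode = c("traditional", "semantic"), sim = NULL) {
  mode <- match.arg(mode)
  if (mode == "semantic" && is.null(sim)) {
    abort("semantic mode requires a similarity function")
  }
  f <- if (mode == "traditional") {
    function(items, db) itemset_support(items, db)
  } else {
    function(items, db) semantic_support(items, db, sim)
  }
  structure(f, class = c("support_function", "function"),
            mode = mode, sim = sim)
}

# Core measure algebra shared by rule_interestingness and score_rules.
# sx, sq, sxq are the support values of antecedent, consequent and union.
.measure_value <- function(measure, sx, sq, sxq, rule_label = "") {
  if (measure == "support") return(sxq)
  if (measure %in% c("confidence", "lift", "conviction") && sx == 0) {
    abort(paste0("zero antecedent support for rule ", rule_label))
  }
  conf <- if (sx > 0) sxq / sx else NA_real_
  switch(measure,
    confidence = conf,
    lift = conf / sq,
    conviction = if (conf >= 1) Inf else (1 - sq) / (1 - conf),
    leverage = sxq - sx * sq,
    jaccard = sxq / (sx + sq - sxq),
    cosine = if (sx * sq == 0) 0 else sxq / sqrt(sx * sq),
    correlation = {
      v <- sx * sq * (1 - sx) * (1 - sq)
      if (v <= 0) 0 else (sxq - sx * sq) / sqrt(v)
    },
    abort(paste0("unknown measure: ", measure))
  )
}

#' Interestingness of one class association rule
#'
#' Computes a measure for the rule `X -> Q` from three support evaluations
#' (`S(X)`, `S(Q)`, `S(X union Q)`) under the supplied support function, so
#' the same formulas yield the traditional and the semantic variants:
#' confidence `S(XQ)/S(X)`; lift `confidence/S(Q)`; conviction
#' `(1-S(Q))/(1-confidence)` with a `+Inf` sentinel at confidence 1;
#' leverage `S(XQ) - S(X)S(Q)`; jaccard `S(XQ)/(S(X)+S(Q)-S(XQ))`; cosine
#' `S(XQ)/sqrt(S(X)S(Q))`; correlation
#' `leverage/sqrt(S(X)S(Q)(1-S(X))(1-S(Q)))` with 0 when any variance
#' factor vanishes. The union support is evaluated on the union itemset in
#' one pass, not factored.
#'
#' @param antecedent Character vector of phenotype item identifiers.
#' @param consequent A single disease item identifier.
#' @param db A [transaction database][as_transactions()].
#' @param measure One of [measure_names()].
#' @param supp A [support_function()].
#' @return A numeric value (possibly `Inf` for conviction).
#' @export
rule_interestingness <- function(antecedent, consequent, db, measure, supp) {
  measure <- match.arg(measure, measure_names())
  sx <- supp(antecedent, db)
  sq <- supp(consequent, db)
  sxq <- supp(c(antecedent, consequent), db)
  label <- paste0("{", paste(antecedent, collapse = ";"), "} -> ", consequent)
  .measure_value(measure, sx, sq, sxq, label)
}

#' Attach interestingness scores to a rule set
#'
#' Adds one column per requested measure, preserving rule order. Support
#' evaluations are vectorised over the rule set: per-item best-match
#' similarities against each transaction are computed once and reused.
#'
#' @param rules A `rule_set` from [itemsets_to_rules()].
#' @param db A [transaction database][as_transactions()].
#' @param measures Character vector of [measure_names()].
#' @param supp A [support_function()].
#' @return `rules` with one additional numeric column per measure.
#' @export
score_rules <- function(rules, db, measures = "confidence",
                        supp = support_function("traditional")) {
  measures <- match.arg(measures, measure_names(), several.ok = TRUE)
  if (nrow(rules) == 0) {
    for (m in measures) rules[[m]] <- numeric(0)
    return(rules)
  }
  mode <- attr(supp, "mode")
  if (mode == "semantic") {
    sim <- attr(supp, "sim")
    best <- .best_match_matrix(db, sim)
    eval_support <- function(items) {
      if (length(items) == 0) return(1)
      idx <- match(items, rownames(best))
      if (anyNA(idx)) {
        # items outside the similarity universe never match anything
        return(0)
      }
      mean(apply(best[idx, , drop = FALSE], 2, prod))
    }
  } else {
    universe <- db_items(db)
    inc <- incidence_matrix(db, universe$item)
    eval_support <- function(items) {
      idx <- match(items, universe$item)
      if (anyNA(idx)) return(0)
      mean(colSums(inc[idx, , drop = FALSE]) == length(items))
    }
  }
  sx <- map_dbl(rules$antecedent, eval_support)
  sq <- map_dbl(rules$consequent, eval_support)
  sxq <- map_dbl(seq_len(nrow(rules)), function(i) {
    eval_support(c(rules$antecedent[[i]], rules$consequent[i]))
  })
  for (m in measures) {
    rules[[m]] <- map_dbl(seq_len(nrow(rules)), function(i) {
      label <- paste0("{", paste(rules$antecedent[[i]], collapse = ";"),
                      "} -> ", rules$consequent[i])
      .measure_value(m, sx[i], sq[i], sxq[i], label)
    })
  }
  rules
}

# best[i, q] = best similarity of universe item i against any item of
# transaction q (0 for empty transactions).
.best_match_matrix <- function(db, sim) {
  ti <- transaction_items(db)
  items <- sim$items
  best <- matrix(0, length(items), length(ti),
                 dimnames = list(items, db$case_id))
  for (q in seq_along(ti)) {
    t_idx <- match(intersect(ti[[q]], items), items)
    if (length(t_idx) == 0) next
    sub <- sim$matrix[, t_idx, drop = FALSE]
    best[, q] <- do.call(pmax, c(asplit(sub, 2), list(0)))
  }
  best
}
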