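#' Constrained Apriori frequent-itemset mining
#'
#' Level-wise Apriori over patient-case transactions with two constraints:
#' candidate and frequent itemsets contain at most one disease item, and
#' itemsets are capped at `max_size` items. Support is traditional
#' (exact-match) support; semantic measures are attached after discovery.
#' The minimum support is configured as an absolute case count and divided
#' by the number of transactions at run time (the `5/N` convention).
#'
#' @param db A [transaction database][as_transactions()].
#' @param min_count Minimum absolute number of supporting transactions
#'   (default 5).
#' @param max_size Maximum itemset size (default 10).
#' @return A tibble of frequent itemsets, sorted by size then
#'   lexicographically: columns `items` (list of sorted item identifiers),
#'   `size`, `n_disease` (0 or 1), `count`, `support`. The identifiers of
#'   disease items are carried in the `"disease_items"` attribute.
#' @export
mine_itemsets <- function(db, min_count = 5, max_size = 10) {
  if (!inherits(db, "transaction_db") || nrow(db) == 0) {
    abort("mining requires a non-empty transaction database")
  }
  if (min_count < 1) abort("min_count must be >= 1")
  if (max_size < 2) abort("max_size must be >= 2")
  n <- nrow(db)
  universe <- db_items(db)
  inc <- incidence_matrix(db, universe$item)
  is_disease <- universe$kind == "disease"

  frequent <- list()
  counts1 <- rowSums(inc)
  l_idx <- unname(which(counts1 >= min_count))
  level <- map(l_idx, function(i) i)       # sorted integer index vectors
  level_counts <- unname(counts1[l_idx])
  k <- 1L
  while (length(level) > 0) {
    frequent[[k]] <- list(sets = level, counts = level_counts)
    if (k >= max_size) break
    prev_keys <- new.env(hash = TRUE, parent = emptyenv())
    for (s in level) assign(paste(s, collapse = "."), TRUE, envir = prev_keys)
    # candidate generation: join frequent k-sets sharing the first k-1 items
    prefixes <- map_chr(level, function(s) paste(s[-length(s)], collapse = "."))
    cand <- list()
    for (g in split(seq_along(level), prefixes)) {
      if (length(g) < 2) next
      lasts <- map_int(level[g], function(s) s[length(s)])
      o <- order(lasts)
      g <- g[o]
      lasts <- lasts[o]
      for (i in seq_len(length(g) - 1)) {
        for (j in seq(i + 1, length(g))) {
          new <- c(level[[g[i]]], lasts[j])
          if (sum(is_disease[new]) > 1) next  # at most one disease item
          ok <- TRUE
          for (drop in seq_len(k + 1)) {      # all k-subsets must be frequent
            key <- paste(new[-drop], collapse = ".")
            if (!exists(key, envir = prev_keys, inherits = FALSE)) {
              ok <- FALSE
              break
            }
          }
          if (ok) cand[[length(cand) + 1L]] <- new
        }
      }
    }
    if (length(cand) == 0) break
    cnt <- map_dbl(cand, function(s) {
      sum(colSums(inc[s, , drop = FALSE]) == length(s))
    })
    keep <- which(cnt >= min_count)
    level <- cand[keep]
    level_counts <- cnt[keep]
    k <- k + 1L
  }

  rows <- purrr::map_dfr(seq_along(frequent), function(k) {
    f <- frequent[[k]]
    if (length(f$sets) == 0) return(tibble())
    tibble(
      items = map(f$sets, function(s) universe$item[s]),
      size = rep(as.integer(k), length(f$sets)),
      n_disease = map_int(f$sets, function(s) sum(is_disease[s])),
      count = as.integer(f$counts),
      support = f$counts / n
    )
  })
  .sort_itemsets(rows, universe$item[is_disease])
}

.sort_itemsets <- function(rows, disease_items) {
  if (nrow(rows) == 0) {
    rows <- tibble(items = list(), size = integer(), n_disease = integer(),
                   count = integer(), support = numeric())
  } else {
    key <- map_chr(rows$items, paste, collapse = "")
    rows <- rows[order(rows$size, key), ]
  }
  attr(rows, "disease_items") <- disease_items
  rows
}

#' Brute-force frequent-itemset enumeration (test oracle)
#'
#' Exhaustively enumerates every itemset over the distinct items of the
#' database (guard: at most 16 distinct items), applies the same
#' single-disease and size constraints and support threshold as
#' [mine_itemsets()], and returns the same sorted layout. Intended as an
#' independent oracle for equivalence testing.
#'
#' @inheritParams mine_itemsets
#' @return A tibble in the layout of [mine_itemsets()].
#' @export
brute_force_itemsets <- function(db, min_count = 5, max_size = 10) {
  if (!inherits(db, "transaction_db") || nrow(db) == 0) {
    abort("mining requires a non-empty transaction database")
  }
  if (min_count < 1) abort("min_count must be >= 1")
  if (max_size < 2) abort("max_size must be >= 2")
  universe <- db_items(db)
  if (nrow(universe) > 16) abort("brute-force guard: more than 16 distinct items")
  ti <- transaction_items(db)
  n <- nrow(db)
  rows <- list()
  for (k in seq_len(min(max_size, nrow(universe)))) {
    for (s in combn(seq_len(nrow(universe)), k, simplify = FALSE)) {
      kinds <- universe$kind[s]
      if (sum(kinds == "disease") > 1) next
      items <- universe$item[s]
      cnt <- sum(map_lgl(ti, function(t) all(items %in% t)))
      if (cnt >= min_count) {
        rows[[length(rows) + 1L]] <- tibble(
          items = list(items), size = as.integer(k),
          n_disease = sum(kinds == "disease"),
          count = as.integer(cnt), support = cnt / n
        )
      }
    }
  }
  .sort_itemsets(bind_rows(rows), universe$item[universe$kind == "disease"])
}

#' Partition frequent itemsets into class association rules
#'
#' Every frequent itemset containing exactly one disease item and at least
#' one phenotype item is partitioned into an antecedent (its phenotypes) and
#' a consequent (its disease). Itemsets lacking either part yield no rule.
#'
#' @param itemsets A tibble from [mine_itemsets()] or
#'   [brute_force_itemsets()].
#' @return A `rule_set` tibble with columns `antecedent` (list of sorted
#'   phenotype identifiers), `consequent` (disease identifier), `support`
#'   and `count` (traditional support of the full itemset).
#' @export
itemsets_to_rules <- function(itemsets) {
  disease_items <- attr(itemsets, "disease_items")
  if (is.null(disease_items)) {
    abort("itemsets lack the disease_items attribute; use mine_itemsets()")
  }
  keep <- itemsets$n_disease == 1 & itemsets$size >= 2
  its <- itemsets[keep, ]
  rules <- tibble(
    antecedent = map(its$items, setdiff, disease_items),
    consequent = map_chr(its$items, function(x) intersect(x, disease_items)),
    support = its$support,
    count = its$count
  )
  class(rules) <- c("rule_set", class(rules))
  rules
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d class association rules\n", nrow(x)))
  NextMethod()
}

#' Write class association rules as TSV
#'
#' Antecedent items are semicolon-joined; any score columns attached by
#' [score_rules()] are written as-is.
#'
#' @param rules A `rule_set` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  out <- as_tibble(rules) |>
    mutate(antecedent = map_chr(.data$antecedent, paste, collapse = ";"))
  readr::write_tsv(out, path)
  invisible(path)
}
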