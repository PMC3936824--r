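#' Voting configuration
#'
#' Bundles the choices that define a rule-based voting classifier: the voting
#' scheme, the interestingness measure used to pick and weight each
#' antecedent group's vote, the computation mode and the similarity used for
#' rule firing. In traditional mode firing always uses exact matching
#' (antecedent must be a subset of the case phenotypes).
#'
#' @param scheme `"simple"` (one vote per antecedent group) or `"weighted"`
#'   (each vote multiplied by the group's best measure value).
#' @param measure One of [measure_names()]; the column of the scored rule
#'   set used to rank rules within a group and to weight votes.
#' @param mode `"traditional"` or `"semantic"`.
#' @param sim A [similarity_function()] used for semantic rule firing;
#'   ignored (forced to exact) in traditional mode.
#' @param threshold Minimum antecedent match score for a rule to fire
#'   (default 0; rules fire on strictly positive exceedance).
#' @return A list of class `voting_config`.
#' @export
voting_config <- function(scheme = c("simple", "weighted"),
                          measure = "confidence",
                          mode = c("traditional", "semantic"),
                          sim = NULL, threshold = 0) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  measure <- match.arg(measure, measure_names())
  if (mode == "semantic" && is.null(sim)) {
    abort("semantic mode requires a similarity function for rule firing")
  }
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  structure(list(scheme = scheme, measure = measure, mode = mode,
                 sim = sim, threshold = threshold),
            class = "voting_config")
}

#' Fire rules on a patient case
#'
#' A rule's match score against a case is the product over its antecedent
#' items of the best similarity to any case phenotype; the rule fires when
#' the score strictly exceeds the threshold. With the exact-match similarity
#' this reduces to subset firing. The case's disease item, if present, is
#' ignored.
#'
#' @param phenotypes Character vector: the case's phenotype concepts.
#' @param rules A scored `rule_set` (see [score_rules()]).
#' @param sim A [similarity_function()], or `NULL` for exact matching.
#' @param threshold Minimum match score (exclusive), default 0.
#' @return The firing subset of `rules` with an added `match_score` column.
#' @export
fire_rules <- function(phenotypes, rules, sim = NULL, threshold = 0) {
  if (nrow(rules) == 0 || length(phenotypes) == 0) {
    out <- rules[integer(0), ]
    out$match_score <- numeric(0)
    return(out)
  }
  if (is.null(sim)) {
    score <- map_dbl(rules$antecedent, function(a) {
      as.numeric(all(a %in% phenotypes))
    })
  } else {
    known <- intersect(phenotypes, sim$items)
    score <- map_dbl(rules$antecedent, function(a) {
      if (length(known) == 0) return(0)
      prod(map_dbl(a, function(i) max(sim_value(sim, i, known))))
    })
  }
  out <- rules[score > threshold, ]
  out$match_score <- score[score > threshold]
  out
}

#' Rank candidate diagnoses for a case by rule voting
#'
#' Fired rules are grouped by antecedent; each group votes for the
#' consequent of its highest-scoring rule (measure ties break on the
#' lexicographically smallest disease identifier). Under simple voting each
#' group contributes 1; under weighted voting it contributes the group's
#' best measure value (the quality of the vote), additionally multiplied by
#' the group's match score in semantic mode. `+Inf` measure sentinels
#' (conviction at confidence 1) dominate finite weights. Disorders are
#' ranked by descending total vote, ties on lexicographic identifier.
#'
#' @param phenotypes Character vector: the case's phenotype concepts.
#' @param rules A `rule_set` scored with `config$measure`.
#' @param config A [voting_config()].
#' @return A tibble `ranking` with columns `disease` and `total_vote`,
#'   ordered best-first; zero rows when no rule fires.
#' @export
rank_diagnoses <- function(phenotypes, rules, config) {
  if (!config$measure %in% names(rules)) {
    abort(paste0("rules carry no '", config$measure, "' score; run score_rules()"))
  }
  sim <- if (config$mode == "semantic") config$sim else NULL
  fired <- fire_rules(phenotypes, rules, sim, config$threshold)
  if (nrow(fired) == 0) {
    return(tibble(disease = character(), total_vote = numeric()))
  }
  fired$measure_value <- fired[[config$measure]]
  votes <- fired |>
    as_tibble() |>
    mutate(group = map_chr(.data$antecedent, paste, collapse = ";")) |>
    group_by(.data$group) |>
    arrange(desc(.data$measure_value), .data$consequent, .by_group = TRUE) |>
    summarise(
      disease = dplyr::first(.data$consequent),
      quality = dplyr::first(.data$measure_value),
      match_score = dplyr::first(.data$match_score),
      .groups = "drop"
    ) |>
    mutate(vote = dplyr::case_when(
      config$scheme == "simple" ~ 1,
      config$mode == "semantic" ~ .data$quality * .data$match_score,
      TRUE ~ .data$quality
    ))
  votes |>
    group_by(.data$disease) |>
    summarise(total_vote = sum(.data$vote), .groups = "drop") |>
    arrange(desc(.data$total_vote), .data$disease)
}

#' Top-K prediction accuracy
#'
#' The percentage of cases whose true disorder appears among the first `k`
#' entries of the ranking (the exact concept, not a sub- or superclass).
#' Cases with an empty ranking count as misses.
#'
#' @param predictions A named list of rankings (tibbles from
#'   [rank_diagnoses()]), one per case.
#' @param truths Named character vector mapping case identifiers to their
#'   true disease concept.
#' @param k Recall cut-off.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
top_k_accuracy <- function(predictions, truths, k) {
  ids <- names(predictions)
  if (any(!ids %in% names(truths))) {
    abort("missing truth entry for some predicted case(s)")
  }
  hits <- map_lgl(ids, function(id) {
    r <- predictions[[id]]
    nrow(r) > 0 && truths[[id]] %in% utils::head(r$disease, k)
  })
  100 * mean(hits)
}

# Per-case correctness at cut-off k, as a named logical vector.
.correct_at_k <- function(predictions, truths, k) {
  ids <- names(predictions)
  setNames(map_lgl(ids, function(id) {
    r <- predictions[[id]]
    nrow(r) > 0 && truths[[id]] %in% utils::head(r$disease, k)
  }), ids)
}

# Stratified-by-diagnosis fold assignment, deterministic in seed.
.assign_folds <- function(db, folds, seed) {
  fold <- integer(nrow(db))
  withr::with_seed(seed, {
    for (d in sort(unique(db$disease))) {
      idx <- which(db$disease == d)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated evaluation of rule-based diagnosis
#'
#' Stratified k-fold cross-validation: per fold, rules are mined and scored
#' on the training split and the held-out cases are ranked by voting;
#' accuracy is reported at each recall cut-off as the mean over folds.
#' Mining always uses traditional support; the mode applies to rule scoring
#' and firing.
#'
#' @param db A [transaction database][as_transactions()]; every case must
#'   carry a diagnosis.
#' @param config A [voting_config()].
#' @param min_count,max_size Mining parameters (see [mine_itemsets()]).
#' @param folds Number of folds (default 5, an 80-20 split).
#' @param k_values Recall cut-offs to report (default 1:5).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `phr_evaluation`: a list with `per_fold`
#'   (tibble of fold x k accuracies), `accuracy_at_k` (named mean
#'   accuracies), `correct_at_k` (per-case held-out correctness, one named
#'   logical vector per k), `n_test`, `folds` and `config`.
#' @export
cross_validate <- function(db, config, min_count = 5, max_size = 10,
                           folds = 5, k_values = 1:5, seed = 1) {
  if (folds < 2) abort("folds must be >= 2")
  if (nrow(db) < folds) abort("database too small to split into folds")
  if (any(is.na(db$disease))) abort("every case must have a diagnosis")
  small <- table(db$disease) < folds
  if (any(small)) {
    warn(paste0("disease class(es) with fewer cases than folds: ",
                paste(names(small)[small], collapse = ", ")))
  }
  fold <- .assign_folds(db, folds, seed)
  truths <- setNames(db$disease, db$case_id)
  per_fold <- list()
  correct <- map(k_values, function(k) logical(0))
  names(correct) <- as.character(k_values)
  for (f in seq_len(folds)) {
    train <- db[fold != f, ]
    test <- db[fold == f, ]
    class(train) <- class(db)
    class(test) <- class(db)
    if (nrow(test) == 0) next
    rules <- itemsets_to_rules(mine_itemsets(train, min_count, max_size))
    supp <- if (config$mode == "semantic") {
      support_function("semantic", config$sim)
    } else {
      support_function("traditional")
    }
    rules <- score_rules(rules, train, config$measure, supp)
    preds <- setNames(
      map(test$phenotypes, rank_diagnoses, rules = rules, config = config),
      test$case_id
    )
    for (k in k_values) {
      ck <- .correct_at_k(preds, truths, k)
      correct[[as.character(k)]] <- c(correct[[as.character(k)]], ck)
      per_fold[[length(per_fold) + 1L]] <-
        tibble(fold = f, k = k, accuracy = 100 * mean(ck),
               n_test = nrow(test))
    }
  }
  per_fold <- bind_rows(per_fold)
  acc <- per_fold |>
    group_by(.data$k) |>
    summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  structure(
    list(per_fold = per_fold,
         accuracy_at_k = setNames(acc$accuracy, acc$k),
         correct_at_k = correct,
         n_test = nrow(db), folds = folds, config = config, seed = seed),
    class = "phr_evaluation"
  )
}

#' @export
print.phr_evaluation <- function(x, ...) {
  cat(sprintf("<phr_evaluation> %s %s voting, measure '%s', %d-fold CV, %d cases\n",
              x$config$mode, x$config$scheme, x$config$measure,
              x$folds, x$n_test))
  acc <- paste(sprintf("K=%s: %.2f%%", names(x$accuracy_at_k),
                       x$accuracy_at_k), collapse = "  ")
  cat(" ", acc, "\n")
  invisible(x)
}

#' Discordance table for two paired classifiers
#'
#' Cross-tabulates per-case correctness of two classifiers evaluated on the
#' same cases, in the 2x2 layout used by McNemar's test.
#'
#' @param correct_a,correct_b Named logical vectors of per-case correctness
#'   (identical case sets), or bare counts via the `counts` argument.
#' @param counts Optionally, a numeric vector
#'   `c(both_correct, a_only, b_only, both_wrong)` given directly.
#' @return An object of class `discordance` with fields `both_correct`,
#'   `a_only`, `b_only`, `both_wrong`.
#' @export
discordance_table <- function(correct_a = NULL, correct_b = NULL,
                              counts = NULL) {
  if (is.null(counts)) {
    if (!setequal(names(correct_a), names(correct_b))) {
      abort("classifiers were evaluated on different case sets")
    }
    correct_b <- correct_b[names(correct_a)]
    counts <- c(sum(correct_a & correct_b),
                sum(correct_a & !correct_b),
                sum(!correct_a & correct_b),
                sum(!correct_a & !correct_b))
  }
  stopifnot(length(counts) == 4)
  structure(list(both_correct = as.integer(counts[1]),
                 a_only = as.integer(counts[2]),
                 b_only = as.integer(counts[3]),
                 both_wrong = as.integer(counts[4])),
            class = "discordance")
}

#' @export
print.discordance <- function(x, ...) {
  n <- x$both_correct + x$a_only + x$b_only + x$both_wrong
  cat("<discordance> paired classification outcomes\n")
  m <- matrix(c(x$both_correct, x$a_only, x$b_only, x$both_wrong), 2, 2,
              byrow = TRUE,
              dimnames = list(c("A correct", "A wrong"),
                              c("B correct", "B wrong")))
  print(m)
  cat("Total:", n, "\n")
  invisible(x)
}

#' McNemar's test with continuity correction
#'
#' For discordant counts `b` and `c` (cases one classifier got right and the
#' other wrong), the statistic is `(max(0, |b - c| - 1))^2 / (b + c)`,
#' referred to the upper tail of the chi-squared distribution with one
#' degree of freedom. The continuity correction is clamped at zero so
#' perfect agreement never yields a positive statistic.
#'
#' @param b,c Discordant counts, or a [discordance_table()] as `b` (then its
#'   off-diagonal cells are used).
#' @return A tibble with columns `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(b, c = NULL) {
  if (inherits(b, "discordance")) {
    c <- b$b_only
    b <- b$a_only
  }
  if (b + c < 1) abort("McNemar test undefined: no discordant cases (b + c = 0)")
  stat <- max(0, abs(b - c) - 1)^2 / (b + c)
  tibble(statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = c)
}

#' Compare traditional and semantic classifiers on one cohort
#'
#' Runs the same cross-validation (identical fold assignment; each training
#' fold is mined once, since mining always uses traditional support) under
#' traditional and semantic scoring/firing, and compares per-case held-out
#' correctness at cut-off `k` with a discordance table and McNemar's test.
#'
#' @inheritParams cross_validate
#' @param sim A [similarity_function()] for the semantic classifier.
#' @param measure One of [measure_names()].
#' @param scheme Voting scheme for both classifiers.
#' @param k Recall cut-off for the paired comparison.
#' @return A list of class `phr_comparison`: `traditional` and `semantic`
#'   `phr_evaluation`s, a `discordance` table (A = traditional,
#'   B = semantic), and `mcnemar` (a tibble, or `NULL` with a
#'   `no_discordance` flag when b + c = 0).
#' @export
compare_classifiers <- function(db, sim, measure = "confidence",
                                scheme = "weighted", min_count = 5,
                                max_size = 10, folds = 5, k_values = 1:5,
                                k = 5, seed = 1) {
  cfg_t <- voting_config(scheme, measure, "traditional")
  cfg_s <- voting_config(scheme, measure, "semantic", sim = sim)
  fold <- .assign_folds(db, folds, seed)
  truths <- setNames(db$disease, db$case_id)
  evals <- list(
    traditional = list(cfg = cfg_t, per_fold = list(),
                       correct = .empty_correct(k_values)),
    semantic = list(cfg = cfg_s, per_fold = list(),
                    correct = .empty_correct(k_values))
  )
  for (f in seq_len(folds)) {
    train <- db[fold != f, ]
    test <- db[fold == f, ]
    class(train) <- class(db)
    class(test) <- class(db)
    if (nrow(test) == 0) next
    base_rules <- itemsets_to_rules(mine_itemsets(train, min_count, max_size))
    for (mode in names(evals)) {
      cfg <- evals[[mode]]$cfg
      supp <- if (mode == "semantic") {
        support_function("semantic", sim)
      } else {
        support_function("traditional")
      }
      rules <- score_rules(base_rules, train, measure, supp)
      preds <- setNames(
        map(test$phenotypes, rank_diagnoses, rules = rules, config = cfg),
        test$case_id
      )
      for (kk in k_values) {
        ck <- .correct_at_k(preds, truths, kk)
        evals[[mode]]$correct[[as.character(kk)]] <-
          c(evals[[mode]]$correct[[as.character(kk)]], ck)
        evals[[mode]]$per_fold[[length(evals[[mode]]$per_fold) + 1L]] <-
          tibble(fold = f, k = kk, accuracy = 100 * mean(ck),
                 n_test = nrow(test))
      }
    }
  }
  reports <- map(evals, function(e) {
    pf <- bind_rows(e$per_fold)
    acc <- pf |> group_by(.data$k) |>
      summarise(accuracy = mean(.data$accuracy), .groups = "drop")
    structure(
      list(per_fold = pf, accuracy_at_k = setNames(acc$accuracy, acc$k),
           correct_at_k = e$correct, n_test = nrow(db), folds = folds,
           config = e$cfg, seed = seed),
      class = "phr_evaluation"
    )
  })
  ca <- reports$traditional$correct_at_k[[as.character(k)]]
  cb <- reports$semantic$correct_at_k[[as.character(k)]]
  disc <- discordance_table(ca, cb)
  mc <- if (disc$a_only + disc$b_only >= 1) {
    mcnemar_test(disc)
  } else {
    NULL
  }
  structure(
    list(traditional = reports$traditional, semantic = reports$semantic,
         discordance = disc, mcnemar = mc,
         no_discordance = is.null(mc), k = k),
    class = "phr_comparison"
  )
}

.empty_correct <- function(k_values) {
  setNames(map(k_values, function(k) logical(0)), as.character(k_values))
}

#' @export
print.phr_comparison <- function(x, ...) {
  cat("<phr_comparison> traditional vs semantic voting\n")
  print(x$traditional)
  print(x$semantic)
  print(x$discordance)
  if (x$no_discordance) {
    cat("McNemar: no discordance (b + c = 0), test undefined\n")
  } else {
    cat(sprintf("McNemar (K=%d): statistic %.4f, p = %.3g\n",
                x$k, x$mcnemar$statistic, x$mcnemar$p_value))
  }
  invisible(x)
}
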