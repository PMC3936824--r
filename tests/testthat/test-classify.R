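test_that("rule firing uses best-match products with a threshold", {
  fx <- example_fixture()
  rules <- score_rules(itemsets_to_rules(mine_itemsets(fx$db, 1, 3)),
                       fx$db, "confidence", support_function("traditional"))
  # exact matching: antecedent subset of case phenotypes -> score 1
  fired <- fire_rules(c(fx$cf[["cf1"]], fx$cf[["cf3"]]), rules)
  expect_true(all(fired$match_score == 1))
  expect_true(all(purrr::map_lgl(fired$antecedent, function(a) {
    all(a %in% c(fx$cf[["cf1"]], fx$cf[["cf3"]]))
  })))

  # semantic firing: cf2 is a sibling of cf1, similarity 0.2
  sf <- similarity_function("custom", fx$phenotype, fx$disease)
  fired_sem <- fire_rules(fx$cf[["cf2"]], rules, sim = sf)
  one <- fired_sem[purrr::map_lgl(fired_sem$antecedent,
                                  function(a) identical(a, unname(fx$cf["cf1"]))), ]
  expect_equal(one$match_score, sim_value(sf, fx$cf[["cf1"]], fx$cf[["cf2"]]))
  expect_gt(nrow(fired_sem), 0)

  # cases with no phenotypes fire nothing
  expect_equal(nrow(fire_rules(character(), rules)), 0)
  # threshold excludes weak matches; only (near-)exact antecedents survive
  fired99 <- fire_rules(fx$cf[["cf2"]], rules, sim = sf, threshold = 0.99)
  expect_lt(nrow(fired99), nrow(fired_sem))
  expect_true(all(fired99$match_score > 0.99))
  expect_true(all(purrr::map_lgl(fired99$antecedent,
                                 function(a) identical(a, unname(fx$cf["cf2"])))))
})

test_that("voting aggregates antecedent groups per scheme", {
  rules <- tibble::tibble(
    antecedent = list("P:a", "P:b", c("P:a", "P:b"), "P:c"),
    consequent = c("D:1", "D:1", "D:2", "D:2"),
    support = rep(0.5, 4),
    count = rep(2L, 4),
    confidence = c(0.9, 0.4, 0.4, 0.4)
  )
  class(rules) <- c("rule_set", class(rules))
  cfg <- voting_config("simple", "confidence", "traditional")
  r <- rank_diagnoses(c("P:a", "P:b", "P:c"), rules, cfg)
  # groups {a}, {b} vote D:1; groups {a,b}, {c} vote D:2 -> tie 2-2,
  # broken lexicographically
  expect_equal(r$total_vote, c(2, 2))
  expect_equal(r$disease, c("D:1", "D:2"))

  cfgw <- voting_config("weighted", "confidence", "traditional")
  rw <- rank_diagnoses(c("P:a", "P:b", "P:c"), rules, cfgw)
  # D:1: 0.9 + 0.4 = 1.3; D:2: 0.4 + 0.4 = 0.8
  expect_equal(rw$disease[1], "D:1")
  expect_equal(rw$total_vote, c(1.3, 0.8))

  # weighted 0.9 vs 0.4 + 0.4 with distinct groups
  rules2 <- tibble::tibble(
    antecedent = list("P:a", "P:b", "P:c"),
    consequent = c("D:1", "D:2", "D:2"),
    support = rep(0.5, 3), count = rep(2L, 3),
    confidence = c(0.9, 0.4, 0.4)
  )
  class(rules2) <- c("rule_set", class(rules2))
  rw2 <- rank_diagnoses(c("P:a", "P:b", "P:c"), rules2, cfgw)
  expect_equal(rw2$disease, c("D:1", "D:2"))
  expect_equal(rw2$total_vote, c(0.9, 0.8))

  # a group votes for its best rule's consequent only
  rules3 <- tibble::tibble(
    antecedent = list("P:a", "P:a"),
    consequent = c("D:1", "D:2"),
    support = rep(0.5, 2), count = rep(2L, 2),
    confidence = c(0.2, 0.7)
  )
  class(rules3) <- c("rule_set", class(rules3))
  r3 <- rank_diagnoses("P:a", rules3, cfg)
  expect_equal(r3$disease, "D:2")

  # conviction sentinel dominates finite weights
  rules4 <- tibble::tibble(
    antecedent = list("P:a", "P:b"),
    consequent = c("D:1", "D:2"),
    support = rep(0.5, 2), count = rep(2L, 2),
    conviction = c(Inf, 5)
  )
  class(rules4) <- c("rule_set", class(rules4))
  r4 <- rank_diagnoses(c("P:a", "P:b"), rules4,
                       voting_config("weighted", "conviction", "traditional"))
  expect_equal(r4$disease[1], "D:1")
  expect_equal(r4$total_vote[1], Inf)

  # no fired rules -> empty ranking
  expect_equal(nrow(rank_diagnoses("P:zz", rules, cfg)), 0)
})

test_that("traditional voting equals semantic voting under exact similarity", {
  kb <- rand_kb(15, 6, 3, seed = 12)
  rules <- score_rules(itemsets_to_rules(mine_itemsets(kb$db, 1, 4)),
                       kb$db, "confidence", support_function("traditional"))
  sf <- similarity_function("exact", kb$pheno, kb$disease)
  cfg_t <- voting_config("weighted", "confidence", "traditional")
  cfg_s <- voting_config("weighted", "confidence", "semantic", sim = sf)
  cases <- withr::with_seed(30, {
    replicate(25, sample(setdiff(kb$pheno$concepts, "P:root"),
                         sample.int(4, 1)), simplify = FALSE)
  })
  for (phens in cases) {
    expect_equal(rank_diagnoses(phens, rules, cfg_t),
                 rank_diagnoses(phens, rules, cfg_s))
  }
})

test_that("top-K accuracy counts exact hits within the cut-off", {
  mk <- function(...) tibble::tibble(disease = c(...),
                                     total_vote = rev(seq_along(c(...))))
  preds <- list(c1 = mk("D:1", "D:2", "D:3"),
                c2 = mk("D:2", "D:1", "D:3"),
                c3 = mk("D:3", "D:2", "D:1"))
  truths <- c(c1 = "D:1", c2 = "D:2", c3 = "D:2")
  expect_equal(top_k_accuracy(preds, truths, 1), 100 * 2 / 3)
  expect_equal(round(top_k_accuracy(preds, truths, 1), 2), 66.67)
  expect_equal(top_k_accuracy(preds, truths, 2), 100)
  # truth always at rank 3: k = 2 -> 0, k = 3 -> 100
  preds3 <- list(c1 = mk("D:2", "D:3", "D:1"))
  expect_equal(top_k_accuracy(preds3, c(c1 = "D:1"), 2), 0)
  expect_equal(top_k_accuracy(preds3, c(c1 = "D:1"), 3), 100)
  # empty ranking is a miss
  expect_equal(top_k_accuracy(list(c1 = mk()[0, ]), c(c1 = "D:1"), 5), 0)
  expect_error(top_k_accuracy(preds, truths[1:2], 1), "missing truth")
})

test_that("cross-validation is deterministic and solves separable cohorts", {
  cfg <- synth_config(pheno_depth = 3, pheno_branching = 4, n_groups = 3,
                      n_diseases = 6, cases_per_disease = 10,
                      profile_size = 6, phenotypes_per_case_mean = 3,
                      sibling_noise_eps = 0)
  pheno <- generate_phenotype_ontology(cfg, 5)
  disease <- generate_disease_ontology(cfg, 5)
  coh <- generate_cohort(cfg, pheno, disease, 5)
  vc <- voting_config("weighted", "confidence", "traditional")
  r1 <- cross_validate(coh$db, vc, min_count = 2, max_size = 4,
                       folds = 5, k_values = c(1, 3), seed = 9)
  r2 <- cross_validate(coh$db, vc, min_count = 2, max_size = 4,
                       folds = 5, k_values = c(1, 3), seed = 9)
  expect_equal(r1$accuracy_at_k, r2$accuracy_at_k)
  expect_equal(r1$per_fold, r2$per_fold)
  # noiseless, subtree-separated profiles are (near-)perfectly classifiable
  expect_gte(r1$accuracy_at_k[["1"]], 90)
  # accuracy is nondecreasing in K
  expect_true(all(diff(r1$accuracy_at_k[order(as.integer(names(r1$accuracy_at_k)))]) >= 0))
  expect_error(cross_validate(coh$db, vc, folds = 1), "folds")
})

test_that("shuffled labels drop accuracy to chance level", {
  cfg <- synth_config(pheno_depth = 3, pheno_branching = 4, n_groups = 2,
                      n_diseases = 4, cases_per_disease = 12,
                      profile_size = 6, phenotypes_per_case_mean = 3,
                      sibling_noise_eps = 0)
  pheno <- generate_phenotype_ontology(cfg, 8)
  disease <- generate_disease_ontology(cfg, 8)
  coh <- generate_cohort(cfg, pheno, disease, 8)
  db <- coh$db
  accs <- purrr::map_dbl(1:3, function(s) {
    shuffled <- db
    withr::with_seed(s, {
      shuffled$disease <- sample(shuffled$disease)
    })
    class(shuffled) <- class(db)
    vc <- voting_config("weighted", "confidence", "traditional")
    r <- cross_validate(shuffled, vc, min_count = 2, max_size = 3,
                        folds = 4, k_values = 1, seed = s)
    r$accuracy_at_k[["1"]]
  })
  # chance level is 100 / 4 classes = 25%; allow wide Monte-Carlo tolerance
  expect_lt(mean(accs), 50)
})

test_that("discordance tables cross-tabulate paired correctness", {
  a <- c(x1 = TRUE, x2 = TRUE, x3 = FALSE, x4 = FALSE)
  b <- c(x1 = TRUE, x2 = FALSE, x3 = TRUE, x4 = FALSE)
  d <- discordance_table(a, b)
  expect_equal(d$both_correct, 1)
  expect_equal(d$a_only, 1)
  expect_equal(d$b_only, 1)
  expect_equal(d$both_wrong, 1)
  expect_error(discordance_table(a, b[1:3]), "different case sets")
  # identical classifiers have empty off-diagonals
  d2 <- discordance_table(a, a)
  expect_equal(d2$a_only + d2$b_only, 0)
  # the reference counts sum to the cohort size
  fx <- example_fixture()
  dd <- fx$discordance
  expect_equal(dd$both_correct + dd$a_only + dd$b_only + dd$both_wrong, 394)
})

test_that("McNemar statistic matches the closed form and stats::mcnemar.test", {
  r <- mcnemar_test(51, 20)
  expect_equal(r$statistic, (abs(51 - 20) - 1)^2 / 71, tolerance = 1e-12)
  expect_equal(r$statistic, 12.68, tolerance = 0.001)
  # independent oracle: the contingency-table implementation in stats
  m <- matrix(c(205, 51, 20, 118), 2, 2)
  oracle <- stats::mcnemar.test(m, correct = TRUE)
  expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, unname(oracle$p.value), tolerance = 1e-12)
  # symmetry, clamped correction, undefined case
  expect_equal(mcnemar_test(20, 51)$statistic, r$statistic)
  expect_equal(mcnemar_test(5, 5)$statistic, 0)
  expect_error(mcnemar_test(0, 0), "b \\+ c")
})

test_that("tidy, glance and autoplot expose evaluation results", {
  cfg <- synth_config(pheno_depth = 2, pheno_branching = 4, n_groups = 2,
                      n_diseases = 4, cases_per_disease = 8,
                      profile_size = 4, phenotypes_per_case_mean = 2,
                      sibling_noise_eps = 0)
  pheno <- generate_phenotype_ontology(cfg, 2)
  disease <- generate_disease_ontology(cfg, 2)
  coh <- generate_cohort(cfg, pheno, disease, 2)
  vc <- voting_config("simple", "confidence", "traditional")
  r <- cross_validate(coh$db, vc, min_count = 2, max_size = 3,
                      folds = 4, k_values = c(1, 2), seed = 4)
  td <- tidy(r)
  expect_true(all(c("fold", "k", "accuracy") %in% names(td)))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_true("accuracy_at_1" %in% names(gl))
  expect_s3_class(autoplot(r), "ggplot")

  sf <- similarity_function("custom", pheno, disease)
  cmp <- compare_classifiers(coh$db, sf, folds = 4, k_values = c(1, 2),
                             k = 2, min_count = 2, max_size = 3, seed = 4)
  expect_s3_class(glance(cmp), "tbl_df")
  expect_s3_class(autoplot(cmp), "ggplot")
  dtot <- cmp$discordance
  expect_equal(dtot$both_correct + dtot$a_only + dtot$b_only + dtot$both_wrong,
               nrow(coh$db))
})
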