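# In-code fixtures and independent oracles shared across the suite.

# A chain root -> a -> b -> c (depths 0..3).
chain_ontology <- function(kind = "phenotype") {
  ontology(
    concepts = c("root", "a", "b", "c"),
    edges = data.frame(child = c("a", "b", "c"), parent = c("root", "a", "b")),
    kind = kind
  )
}

# Random rooted DAG: node i picks one parent among earlier nodes, plus a
# second parent with probability p_extra (multiple inheritance).
rand_ontology <- function(n, seed, kind = "phenotype", p_extra = 0.2) {
  withr::with_seed(seed, {
    ids <- sprintf("T:%03d", seq_len(n))
    child <- character()
    parent <- character()
    for (i in seq(2, n)) {
      p1 <- sample.int(i - 1, 1)
      child <- c(child, ids[i])
      parent <- c(parent, ids[p1])
      if (i > 2 && runif(1) < p_extra) {
        p2 <- sample(setdiff(seq_len(i - 1), p1), 1)
        child <- c(child, ids[i])
        parent <- c(parent, ids[p2])
      }
    }
    ontology(ids, data.frame(child = child, parent = parent), kind = kind)
  })
}

# Independent ancestor-distance oracle: depth-first walk over the raw edge
# list (no igraph, no cached matrix).
oracle_ancestor_dists <- function(ont, id) {
  acc <- new.env(parent = emptyenv())
  walk <- function(node, d) {
    prev <- get0(node, envir = acc, ifnotfound = Inf)
    if (d >= prev) return(invisible())
    assign(node, d, envir = acc)
    for (p in ont$edges$parent[ont$edges$child == node]) walk(p, d + 1)
  }
  walk(id, 0)
  unlist(as.list(acc))
}

# Oracle taxonomy distance: min over common ancestors of summed ascents.
oracle_path_length <- function(ont, c1, c2) {
  d1 <- oracle_ancestor_dists(ont, c1)
  d2 <- oracle_ancestor_dists(ont, c2)
  common <- intersect(names(d1), names(d2))
  min(d1[common] + d2[common])
}

# Tiny star ontologies + a random case table for mining tests.
rand_kb <- function(n_trans, n_pheno, n_disease, seed,
                    max_phen_per_case = 4) {
  withr::with_seed(seed, {
    phen_ids <- sprintf("P:%02d", seq_len(n_pheno))
    dis_ids <- sprintf("D:%02d", seq_len(n_disease))
    pheno <- ontology(c("P:root", phen_ids),
                      data.frame(child = phen_ids, parent = "P:root"),
                      kind = "phenotype")
    disease <- ontology(c("D:root", dis_ids),
                        data.frame(child = dis_ids, parent = "D:root"),
                        kind = "disease")
    cases <- tibble::tibble(
      case_id = sprintf("c%02d", seq_len(n_trans)),
      diagnosis_id = sample(dis_ids, n_trans, replace = TRUE),
      phenotype_ids = lapply(seq_len(n_trans), function(i) {
        sample(phen_ids, sample.int(min(max_phen_per_case, n_pheno), 1))
      })
    )
    db <- suppressWarnings(as_transactions(cases, pheno, disease))
    list(pheno = pheno, disease = disease, db = db)
  })
}

# Canonical string form of an itemset tibble for equivalence checks.
itemset_keys <- function(itemsets) {
  vapply(itemsets$items, paste, character(1), collapse = ",")
}
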