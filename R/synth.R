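#' Synthetic cohort configuration
#'
#' Parameters of the synthetic ontology and cohort generators. The defaults
#' emulate a rare-skeletal-disorder referral cohort: 15 disorders with 26
#' cases each (390 cases), a phenotype hierarchy deep and wide enough to
#' carry several hundred distinct annotations, and a mean of 4.49 distinct
#' phenotypes per case.
#'
#' @param pheno_depth Depth of the synthetic phenotype tree (>= 2).
#' @param pheno_branching Children per internal node.
#' @param pheno_branching_jitter Uniform jitter (+/-) on the per-node child
#'   count; 0 gives an exact geometric tree.
#' @param n_groups Disease groups under the disease-ontology root.
#' @param n_diseases Number of disorders (>= `n_groups`).
#' @param cases_per_disease Cases simulated per disorder.
#' @param profile_size Characteristic phenotypes per disorder profile.
#' @param phenotypes_per_case_mean Target mean of distinct phenotypes per
#'   case (truncated-Poisson sampling, minimum 1).
#' @param sibling_noise_eps Probability that a sampled profile phenotype is
#'   replaced by a random same-parent sibling outside the profile - the
#'   semantic signal exact matching cannot see.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(pheno_depth = 4, pheno_branching = 5,
                         pheno_branching_jitter = 0,
                         n_groups = 5, n_diseases = 15,
                         cases_per_disease = 26, profile_size = 25,
                         phenotypes_per_case_mean = 4.49,
                         sibling_noise_eps = 0.2) {
  cfg <- list(pheno_depth = as.integer(pheno_depth),
              pheno_branching = as.integer(pheno_branching),
              pheno_branching_jitter = as.integer(pheno_branching_jitter),
              n_groups = as.integer(n_groups),
              n_diseases = as.integer(n_diseases),
              cases_per_disease = as.integer(cases_per_disease),
              profile_size = as.integer(profile_size),
              phenotypes_per_case_mean = phenotypes_per_case_mean,
              sibling_noise_eps = sibling_noise_eps)
  counts <- c("pheno_branching", "n_groups", "n_diseases",
              "cases_per_disease", "profile_size")
  if (any(unlist(cfg[counts]) < 1)) abort("all counts must be >= 1")
  if (cfg$pheno_depth < 2) abort("pheno_depth must be >= 2")
  if (cfg$sibling_noise_eps < 0 || cfg$sibling_noise_eps > 1) {
    abort("sibling_noise_eps must be in [0, 1]")
  }
  if (cfg$phenotypes_per_case_mean < 1) {
    abort("phenotypes_per_case_mean must be >= 1")
  }
  if (cfg$n_diseases < cfg$n_groups) abort("n_diseases must be >= n_groups")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic phenotype ontology
#'
#' A rooted tree of the configured depth and branching, with synthetic
#' CURIE-style identifiers, emulating the generic-to-specific shape of a
#' phenotype hierarchy. Deterministic in the seed.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return A phenotype [ontology()].
#' @export
generate_phenotype_ontology <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(seed, {
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("SP:%07d", counter)
    }
    root <- new_id()
    edges_child <- character()
    edges_parent <- character()
    frontier <- root
    for (level in seq_len(cfg$pheno_depth)) {
      next_frontier <- character()
      for (p in frontier) {
        j <- cfg$pheno_branching_jitter
        nc <- cfg$pheno_branching +
          if (j > 0) sample(seq(-j, j), 1) else 0L
        nc <- max(1L, nc)
        kids <- vapply(seq_len(nc), function(i) new_id(), character(1))
        edges_child <- c(edges_child, kids)
        edges_parent <- c(edges_parent, rep(p, nc))
        next_frontier <- c(next_frontier, kids)
      }
      frontier <- next_frontier
    }
    ids <- c(root, edges_child)
    ontology(
      concepts = ids,
      edges = data.frame(child = edges_child, parent = edges_parent),
      kind = "phenotype",
      labels = setNames(paste("synthetic phenotype", seq_along(ids)), ids)
    )
  })
}

#' Generate a synthetic disease ontology
#'
#' A shallow group-structured hierarchy of maximum depth 2: the root, group
#' concepts beneath it, and disorders distributed round-robin across groups.
#'
#' @inheritParams generate_phenotype_ontology
#' @return A disease [ontology()].
#' @export
generate_disease_ontology <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  root <- "SD:0000000"
  groups <- sprintf("SD:%07d", seq_len(cfg$n_groups))
  diseases <- sprintf("SD:%07d", 1000000L + seq_len(cfg$n_diseases))
  edges <- data.frame(
    child = c(groups, diseases),
    parent = c(rep(root, cfg$n_groups),
               groups[((seq_len(cfg$n_diseases) - 1L) %% cfg$n_groups) + 1L])
  )
  ids <- c(root, groups, diseases)
  labels <- setNames(c("synthetic disorder root",
                       paste("disorder group", seq_len(cfg$n_groups)),
                       paste("synthetic disorder", seq_len(cfg$n_diseases))),
                     ids)
  ontology(concepts = ids, edges = edges, kind = "disease", labels = labels)
}

# Leaf concepts (no children).
.ontology_leaves <- function(ont) {
  setdiff(ont$concepts, unique(ont$edges$parent))
}

# lambda of a min-1 truncated Poisson with the requested mean.
.truncated_poisson_lambda <- function(target_mean) {
  if (target_mean <= 1 + 1e-9) return(1e-8)
  uniroot(function(l) l / (1 - exp(-l)) - target_mean,
          interval = c(1e-8, target_mean * 2), tol = 1e-10)$root
}

#' Generate a synthetic annotated patient cohort
#'
#' Each disorder receives a profile of leaf phenotypes biased toward a
#' distinct subtree of the phenotype hierarchy. Each case draws a
#' truncated-Poisson number (minimum 1) of distinct phenotypes from its
#' disorder's profile; with probability `sibling_noise_eps` a drawn
#' phenotype is replaced by a random same-parent sibling outside the
#' profile. Sibling substitution leaves a semantic trace (the substitute is
#' one parent away) that exact matching cannot exploit. Deterministic in the
#' seed.
#'
#' @inheritParams generate_phenotype_ontology
#' @param pheno A phenotype [ontology()].
#' @param disease A disease [ontology()] whose leaf concepts are the
#'   disorders.
#' @return A list with elements `db` (a [transaction
#'   database][as_transactions()]) and `truth` (list with `profiles`, a
#'   named list of profile phenotype sets, and `assignments`, a named vector
#'   case id -> disorder).
#' @export
generate_cohort <- function(cfg, pheno, disease, seed = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  leaves <- sort(.ontology_leaves(pheno))
  if (cfg$profile_size > length(leaves)) {
    abort("profile_size exceeds the number of leaf phenotypes")
  }
  disorders <- sort(setdiff(.ontology_leaves(disease), disease$root))
  if (length(disorders) == 0) abort("disease ontology has no disorder concepts")
  parent_of <- setNames(pheno$edges$parent, pheno$edges$child)

  withr::with_seed(seed, {
    # bias profiles toward distinct depth-1 subtrees, drawing without
    # replacement within a subtree pool so profiles overlap minimally
    subroots <- sort(pheno$edges$child[pheno$edges$parent == pheno$root])
    leaf_sub <- map(subroots, function(s) {
      leaves[is.finite(pheno$dmat[leaves, s])]
    })
    pools <- map(leaf_sub, function(x) x[sample.int(length(x))])
    spare <- leaves[sample.int(length(leaves))]
    profiles <- list()
    for (i in seq_along(disorders)) {
      b <- ((i - 1L) %% length(subroots)) + 1L
      take <- utils::head(pools[[b]], cfg$profile_size)
      pools[[b]] <- setdiff(pools[[b]], take)
      if (length(take) < cfg$profile_size) {
        extra <- utils::head(setdiff(spare, take), cfg$profile_size - length(take))
        spare <- setdiff(spare, extra)
        take <- c(take, extra)
      }
      profiles[[disorders[i]]] <- sort(take)
    }

    lambda <- .truncated_poisson_lambda(cfg$phenotypes_per_case_mean)
    draw_n <- function() {
      u <- runif(1, min = stats::dpois(0, lambda), max = 1)
      max(1L, qpois(u, lambda))
    }
    case_rows <- list()
    cid <- 0L
    for (d in disorders) {
      prof <- profiles[[d]]
      for (j in seq_len(cfg$cases_per_disease)) {
        cid <- cid + 1L
        np <- min(draw_n(), length(prof))
        phens <- sample(prof, np)
        if (cfg$sibling_noise_eps > 0) {
          phens <- vapply(phens, function(p) {
            if (runif(1) >= cfg$sibling_noise_eps) return(p)
            sibs <- names(parent_of)[parent_of == parent_of[[p]]]
            sibs <- setdiff(sibs, c(prof, phens))
            if (length(sibs) == 0) p else sample(sibs, 1)
          }, character(1), USE.NAMES = FALSE)
        }
        case_rows[[cid]] <- tibble(
          case_id = sprintf("case_%04d", cid),
          diagnosis_id = d,
          phenotype_ids = list(unique(phens))
        )
      }
    }
    cases <- bind_rows(case_rows)
  })
  db <- suppressWarnings(as_transactions(cases, pheno, disease))
  list(db = db,
       truth = list(profiles = profiles,
                    assignments = setNames(cases$diagnosis_id, cases$case_id)))
}

#' Built-in worked-example fixture
#'
#' A small, fully fixed knowledge base used throughout the documentation and
#' tests: a macrocephaly mini-hierarchy (HP:0000256 with subtypes
#' HP:0004481, HP:0004482 and HP:0004488 under a skull-abnormality chain), a
#' short-stature / rib-abnormality branch with four clinical-feature
#' concepts (cf1 = HP:0008921, cf2 = HP:0008905 sharing the parent
#' HP:0008873; cf3 = HP:0000772; cf4 = HP:0000774 under HP:0005257, a
#' sibling of cf3), a one-disorder disease ontology (Achondroplasia in an
#' FGFR3 group), three annotated patient cases, and a reference 2x2
#' discordance table from a paired evaluation of a traditional- versus a
#' semantic-confidence classifier over a 394-case cohort.
#'
#' @return A list with elements `phenotype` and `disease` (ontologies), `db`
#'   (a 3-case transaction database), `cf` (named vector mapping cf1..cf4 to
#'   concept identifiers), `bd1` (the disorder identifier), and
#'   `discordance` (a [discordance_table()]; A = traditional, B = semantic).
#' @export
example_fixture <- function() {
  pheno <- ontology(
    concepts = c("HP:0000001", "HP:0000929", "HP:0000256", "HP:0004481",
                 "HP:0004482", "HP:0004488", "HP:0008873", "HP:0008921",
                 "HP:0008905", "HP:0000765", "HP:0000772", "HP:0005257",
                 "HP:0000774"),
    edges = data.frame(
      child = c("HP:0000929", "HP:0000256", "HP:0004481", "HP:0004482",
                "HP:0004488", "HP:0008873", "HP:0008921", "HP:0008905",
                "HP:0000765", "HP:0000772", "HP:0005257", "HP:0000774"),
      parent = c("HP:0000001", "HP:0000929", "HP:0000256", "HP:0000256",
                 "HP:0000256", "HP:0000001", "HP:0008873", "HP:0008873",
                 "HP:0000001", "HP:0000765", "HP:0000765", "HP:0005257")
    ),
    kind = "phenotype",
    labels = c(
      "HP:0000001" = "All",
      "HP:0000929" = "Abnormality of the skull",
      "HP:0000256" = "Macrocephaly",
      "HP:0004481" = "Progressive macrocephaly",
      "HP:0004482" = "Relative macrocephaly",
      "HP:0004488" = "Macrocephaly at birth",
      "HP:0008873" = "Disproportionate short-limb short stature",
      "HP:0008921" = "Neonatal short-limb short stature",
      "HP:0008905" = "Rhizomelic short stature",
      "HP:0000765" = "Abnormality of the thorax",
      "HP:0000772" = "Abnormality of the ribs",
      "HP:0005257" = "Thoracic hypoplasia",
      "HP:0000774" = "Narrow chest"
    )
  )
  disease <- ontology(
    concepts = c("BDO:0000000", "BDO:0000001", "BDO:1000001"),
    edges = data.frame(child = c("BDO:0000001", "BDO:1000001"),
                       parent = c("BDO:0000000", "BDO:0000001")),
    kind = "disease",
    labels = c("BDO:0000000" = "Bone dysplasia",
               "BDO:0000001" = "FGFR3 group",
               "BDO:1000001" = "Achondroplasia")
  )
  cf <- c(cf1 = "HP:0008921", cf2 = "HP:0008905",
          cf3 = "HP:0000772", cf4 = "HP:0000774")
  bd1 <- "BDO:1000001"
  cases <- tibble(
    case_id = c("p1", "p2", "p3"),
    diagnosis_id = bd1,
    phenotype_ids = list(c(cf[["cf1"]], cf[["cf3"]]),
                         c(cf[["cf1"]], cf[["cf4"]]),
                         c(cf[["cf2"]], cf[["cf3"]]))
  )
  db <- as_transactions(cases, pheno, disease)
  list(phenotype = pheno, disease = disease, db = db, cf = cf, bd1 = bd1,
       discordance = discordance_table(counts = c(205, 20, 51, 118)))
}
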