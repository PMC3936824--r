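#' Ontology graphs
#'
#' An `ontology` is a rooted directed acyclic graph of concepts connected by
#' subclass (`is_a`) edges, pointing from child to parent. Exactly one concept
#' (the root) has no parent, every concept reaches the root, and multiple
#' parents per child are allowed. Two kinds are distinguished: `"phenotype"`
#' ontologies (deep, HPO-style) and `"disease"` ontologies (shallow,
#' group-structured, maximum depth 2).
#'
#' @param concepts Character vector of concept identifiers (e.g. CURIEs).
#' @param labels Named character vector of human-readable names, one per
#'   concept (missing entries default to the identifier itself).
#' @param edges A data frame with columns `child` and `parent`, one row per
#'   subclass edge.
#' @param kind `"phenotype"` or `"disease"`.
#'
#' @return An object of class `ontology` with elements `concepts`, `labels`,
#'   `edges` (a tibble), `root`, `kind`, and a cached ancestor-distance matrix.
#' @examples
#' ont <- ontology(
#'   concepts = c("A", "B", "C"),
#'   edges = data.frame(child = c("B", "C"), parent = c("A", "B")),
#'   kind = "phenotype"
#' )
#' concept_depth(ont, "C")
#' @export
ontology <- function(concepts, edges, kind = c("phenotype", "disease"),
                     labels = NULL) {
  kind <- match.arg(kind)
  concepts <- as.character(concepts)
  if (length(concepts) == 0) abort("ontology must contain at least one concept")
  if (anyDuplicated(concepts)) abort("duplicate concept identifiers")
  if (any(!nzchar(concepts))) abort("empty concept identifier")
  edges <- tibble(child = as.character(edges$child),
                  parent = as.character(edges$parent))
  bad <- setdiff(c(edges$child, edges$parent), concepts)
  if (length(bad) > 0) {
    abort(paste0("subclass edge references unknown concept(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (is.null(labels)) labels <- setNames(concepts, concepts)
  lab <- setNames(concepts, concepts)
  lab[names(labels)] <- unname(labels)
  labels <- lab[concepts]

  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = concepts, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) abort("cycle detected among subclass edges")
  roots <- setdiff(concepts, edges$child)
  if (length(roots) == 0) abort("no root concept (every concept has a parent)")
  if (length(roots) > 1) {
    abort(paste0("multiple root concepts: ",
                 paste(sort(roots), collapse = ", ")))
  }
  # minimal edge counts following child -> parent edges; Inf = not an ancestor
  dmat <- igraph::distances(g, mode = "out", weights = NA)
  dmat <- dmat[concepts, concepts, drop = FALSE]
  if (any(!is.finite(dmat[, roots]))) {
    orphans <- concepts[!is.finite(dmat[, roots])]
    abort(paste0("concept(s) cannot reach the root: ",
                 paste(utils::head(orphans, 5), collapse = ", ")))
  }
  structure(
    list(concepts = concepts, labels = labels, edges = edges,
         root = roots, kind = kind, dmat = dmat),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology [%s]> %d concepts, %d subclass edges, root %s\n",
              x$kind, length(x$concepts), nrow(x$edges), x$root))
  invisible(x)
}

#' @describeIn ontology Concepts and labels as a tibble.
#' @param x An `ontology`.
#' @param ... Unused.
#' @method as_tibble ontology
#' @export
as_tibble.ontology <- function(x, ...) {
  tibble(concept = x$concepts,
         label = unname(x$labels),
         depth = concept_depth(x, x$concepts))
}

.check_concepts <- function(ont, ids) {
  missing <- setdiff(ids, ont$concepts)
  if (length(missing) > 0) {
    abort(paste0("unknown concept(s): ", paste(missing, collapse = ", ")))
  }
}

#' Concept depth
#'
#' Minimum number of subclass edges from a concept up to the root;
#' `concept_depth(ont, root)` is 0.
#'
#' @param ont An [ontology()].
#' @param id Character vector of concept identifiers.
#' @return Integer vector of depths.
#' @export
concept_depth <- function(ont, id) {
  .check_concepts(ont, id)
  as.integer(ont$dmat[id, ont$root])
}

#' Ancestors of a concept
#'
#' All concepts reachable by following child-to-parent edges, including the
#' concept itself.
#'
#' @inheritParams concept_depth
#' @param id A single concept identifier.
#' @return Named integer vector: minimal edge counts from `id` up to each
#'   ancestor (0 for the concept itself).
#' @export
ancestors <- function(ont, id) {
  .check_concepts(ont, id)
  d <- ont$dmat[id, ]
  d <- d[is.finite(d)]
  setNames(as.integer(d), names(d))
}

#' Taxonomic path length between two concepts
#'
#' The shortest path between two concepts that ascends from each to a common
#' ancestor: the minimum over common ancestors `a` of
#' `d(c1, a) + d(c2, a)`, where `d` counts subclass edges. Identical concepts
#' have path length 0.
#'
#' @inheritParams concept_depth
#' @param c1,c2 Concept identifiers.
#' @return Integer edge count.
#' @export
path_length <- function(ont, c1, c2) {
  .check_concepts(ont, c(c1, c2))
  if (c1 == c2) return(0L)
  as.integer(min(ont$dmat[c1, ] + ont$dmat[c2, ]))
}

#' Lowest common ancestor
#'
#' The deepest concept that is an ancestor of both arguments (every concept is
#' its own ancestor). Depth ties break on the lexicographically smallest
#' identifier.
#'
#' @inheritParams path_length
#' @return A concept identifier.
#' @export
lca <- function(ont, c1, c2) {
  .check_concepts(ont, c(c1, c2))
  common <- is.finite(ont$dmat[c1, ]) & is.finite(ont$dmat[c2, ])
  cand <- ont$concepts[common]
  dep <- ont$dmat[cand, ont$root]
  cand <- cand[dep == max(dep)]
  sort(cand)[1]
}

#' Corpus statistics for information content
#'
#' Per-concept annotation frequencies over a case cohort. Frequencies are
#' non-propagated: a case counts once for each concept it is annotated with
#' directly, and annotations are never expanded to ancestors. Concepts absent
#' from the cohort have frequency 0.
#'
#' @param db A [transaction database][as_transactions()], or `NULL` when
#'   `case_count` and `freq` are given directly.
#' @param case_count Total number of cases (used when `db` is `NULL`).
#' @param freq Named integer vector of per-concept case counts (used when
#'   `db` is `NULL`).
#' @return An object of class `corpus_stats` with elements `case_count` and
#'   `freq`.
#' @export
corpus_stats <- function(db = NULL, case_count = NULL, freq = NULL) {
  if (!is.null(db)) {
    stopifnot(inherits(db, "transaction_db"))
    items <- c(unlist(db$phenotypes), db$disease[!is.na(db$disease)])
    tab <- table(items)
    freq <- setNames(as.integer(tab), names(tab))
    case_count <- nrow(db)
  }
  case_count <- as.integer(case_count)
  if (is.na(case_count) || case_count < 1) abort("case_count must be >= 1")
  freq <- freq[freq > 0]
  if (any(freq > case_count)) abort("concept frequency exceeds case_count")
  structure(list(case_count = case_count, freq = freq),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> %d cases, %d annotated concepts\n",
              x$case_count, length(x$freq)))
  invisible(x)
}

concept_freq <- function(stats, id) {
  f <- unname(stats$freq[id])
  f[is.na(f)] <- 0L
  f
}

#' Information content
#'
#' `IC(c) = -ln(freq(c) / case_count)`, in nats. A concept with frequency 0
#' has undefined (infinite) information content, returned as `NA`.
#'
#' @param stats A [corpus_stats()] object.
#' @param id Character vector of concept identifiers.
#' @return Numeric vector; `NA` marks undefined IC.
#' @export
information_content <- function(stats, id) {
  f <- concept_freq(stats, id)
  ifelse(f > 0, -log(f / stats$case_count), NA_real_)
}

#' Most informative common ancestor
#'
#' Among the common ancestors of `c1` and `c2` that occur in the corpus
#' (frequency > 0), the one with the highest information content; ties break
#' on greater depth, then the lexicographically smallest identifier. An
#' identical pair with frequency > 0 is an exact match and is its own MICA.
#' Returns `NA` when no common ancestor occurs in the corpus (the
#' "completely dissimilar" outcome).
#'
#' @inheritParams path_length
#' @param stats A [corpus_stats()] object.
#' @return A concept identifier or `NA_character_`.
#' @export
mica <- function(ont, stats, c1, c2) {
  .check_concepts(ont, c(c1, c2))
  if (c1 == c2 && concept_freq(stats, c1) > 0) return(c1)
  common <- is.finite(ont$dmat[c1, ]) & is.finite(ont$dmat[c2, ])
  cand <- ont$concepts[common]
  cand <- cand[concept_freq(stats, cand) > 0]
  if (length(cand) == 0) return(NA_character_)
  ic <- information_content(stats, cand)
  cand <- cand[ic == max(ic)]
  if (length(cand) > 1) {
    dep <- ont$dmat[cand, ont$root]
    cand <- cand[dep == max(dep)]
  }
  sort(cand)[1]
}
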