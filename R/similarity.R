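#' Clamp a similarity value into the unit interval
#'
#' @param x Numeric vector.
#' @return `min(1, max(0, x))` elementwise.
#' @examples
#' clamp01(c(-0.1, 0.5, 2.19))
#' @export
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Exact-match similarity
#'
#' The indicator similarity that reduces every semantic measure to its
#' traditional twin: 1 for identical items, 0 otherwise (including items from
#' different ontologies).
#'
#' @param i1,i2 Item identifiers.
#' @return 0 or 1.
#' @export
exact_sim <- function(i1, i2) as.numeric(i1 == i2)

#' Exponential path-based semantic similarity
#'
#' The similarity of two concepts is
#' `Dist(LCA, root) / (Dist(c1, c2) + Dist(LCA, root))`, where
#' `Dist(LCA, root)` is the plain edge-count depth of their lowest common
#' ancestor and `Dist(c1, c2)` is an exponential transform of the taxonomic
#' path length `l` between them: `2^l` for phenotype ontologies and
#' `10^(l - 2)` for (shallow, depth-2) disease ontologies. For identical
#' concepts the distance is 0 (similarity 1) unless the concept is the root,
#' where it is 1 (similarity 0, avoiding 0/0). Deeper LCAs are rewarded and
#' the similarity decays exponentially with path length, so nearby siblings
#' score far above distant relatives.
#'
#' @inheritParams path_length
#' @return A value in `[0, 1]`.
#' @export
sem_sim <- function(ont, c1, c2) {
  .check_concepts(ont, c(c1, c2))
  if (c1 == c2) {
    dist <- if (c1 == ont$root) 1 else 0
  } else {
    l <- path_length(ont, c1, c2)
    dist <- if (ont$kind == "phenotype") 2^l else 10^(l - 2)
  }
  lca_depth <- concept_depth(ont, lca(ont, c1, c2))
  if (dist == 0) return(1)
  lca_depth / (dist + lca_depth)
}

#' Resnik similarity
#'
#' The information content of the most informative common ancestor. When no
#' common ancestor occurs in the corpus the concepts are completely
#' dissimilar and the similarity is 0 (the representable equivalent of the
#' infinite-IC case).
#'
#' @inheritParams mica
#' @return A nonnegative value (unbounded above).
#' @export
resnik_sim <- function(ont, stats, c1, c2) {
  m <- mica(ont, stats, c1, c2)
  if (is.na(m)) return(0)
  information_content(stats, m)
}

#' Lin similarity
#'
#' `2 * IC(MICA) / (IC(c1) + IC(c2))`. Returns 0 when either concept has
#' frequency 0 or when the MICA is undefined. Note that with non-propagated
#' frequencies the value can exceed 1 for distinct concepts whose common
#' ancestor is rarer than both; [clamp01()] is applied before the value
#' enters semantic support.
#'
#' @inheritParams mica
#' @return A nonnegative value (may exceed 1 before clamping).
#' @export
lin_sim <- function(ont, stats, c1, c2) {
  ic1 <- information_content(stats, c1)
  ic2 <- information_content(stats, c2)
  if (is.na(ic1) || is.na(ic2)) return(0)
  m <- mica(ont, stats, c1, c2)
  if (is.na(m)) return(0)
  2 * information_content(stats, m) / (ic1 + ic2)
}

#' Jiang-Conrath similarity
#'
#' Bounded inverse of the Jiang-Conrath distance
#' `d = IC(c1) + IC(c2) - 2 * IC(MICA)`: the similarity is
#' `1 / (1 + max(0, d))`. Negative distances (possible with non-propagated
#' IC) clamp to 0, and an undefined MICA or IC yields similarity 0.
#'
#' @inheritParams mica
#' @return A value in `[0, 1]`.
#' @export
jiang_conrath_sim <- function(ont, stats, c1, c2) {
  ic1 <- information_content(stats, c1)
  ic2 <- information_content(stats, c2)
  if (is.na(ic1) || is.na(ic2)) return(0)
  m <- mica(ont, stats, c1, c2)
  if (is.na(m)) return(0)
  d <- max(0, ic1 + ic2 - 2 * information_content(stats, m))
  1 / (1 + d)
}

#' Wu-Palmer similarity
#'
#' `2 * N3 / (N1 + N2 + 2 * N3)`, where `N3` is the depth of the lowest
#' common ancestor and `N1`, `N2` are the edge counts from each concept down
#' to it. Identical non-root concepts score 1; pairs whose LCA is the root
#' score 0.
#'
#' @inheritParams path_length
#' @return A value in `[0, 1]`.
#' @export
wu_palmer_sim <- function(ont, c1, c2) {
  .check_concepts(ont, c(c1, c2))
  a <- lca(ont, c1, c2)
  n3 <- concept_depth(ont, a)
  if (n3 == 0) return(0)
  n1 <- ont$dmat[c1, a]
  n2 <- ont$dmat[c2, a]
  2 * n3 / (n1 + n2 + 2 * n3)
}

#' Available similarity metrics
#'
#' @return Character vector of metric names accepted by
#'   [similarity_function()].
#' @export
similarity_metrics <- function() {
  c("exact", "custom", "resnik", "lin", "jiang_conrath", "wu_palmer")
}

# ---- vectorised pairwise machinery -----------------------------------------

# Pathlen (min-plus through common ancestors), deepest-LCA index and LCA depth
# for all concept pairs of one ontology.
.pairwise_paths <- function(ont) {
  n <- length(ont$concepts)
  dmat <- ont$dmat
  dd <- dmat[, ont$root]
  pl <- matrix(Inf, n, n, dimnames = dimnames(dmat))
  ld <- matrix(-Inf, n, n)
  lcaidx <- matrix(NA_integer_, n, n)
  # process ancestors by increasing depth; within a depth, reverse-lexicographic
  # order so the lexicographically smallest wins the >= update (deterministic tie)
  ord <- order(dd, -xtfrm(ont$concepts))
  for (a in ord) {
    desc <- dmat[, a]
    idx <- which(is.finite(desc))
    d <- desc[idx]
    s <- outer(d, d, "+")
    pl[idx, idx] <- pmin(pl[idx, idx], s)
    subL <- ld[idx, idx]
    m <- dd[a] >= subL
    subL[m] <- dd[a]
    ld[idx, idx] <- subL
    subI <- lcaidx[idx, idx]
    subI[m] <- a
    lcaidx[idx, idx] <- subI
  }
  diag(pl) <- 0
  list(pathlen = pl, lca_depth = ld, lca_idx = lcaidx, depth = dd)
}

# Max IC over corpus-present common ancestors, for all pairs; -Inf = undefined.
.pairwise_mic <- function(ont, stats) {
  n <- length(ont$concepts)
  mic <- matrix(-Inf, n, n, dimnames = dimnames(ont$dmat))
  present <- ont$concepts[concept_freq(stats, ont$concepts) > 0]
  for (a in present) {
    idx <- which(is.finite(ont$dmat[, a]))
    ic_a <- information_content(stats, a)
    mic[idx, idx] <- pmax(mic[idx, idx], ic_a)
  }
  mic
}

.sim_matrix_one <- function(ont, metric, stats) {
  n <- length(ont$concepts)
  ids <- ont$concepts
  if (metric == "exact") {
    m <- diag(1, n)
    dimnames(m) <- list(ids, ids)
    return(m)
  }
  if (metric %in% c("custom", "wu_palmer")) {
    pp <- .pairwise_paths(ont)
    if (metric == "custom") {
      dist <- if (ont$kind == "phenotype") 2^pp$pathlen else 10^(pp$pathlen - 2)
      ld <- pmax(pp$lca_depth, 0)
      m <- ld / (dist + ld)
      m[ld == 0] <- 0
      # identical concepts: distance 0 unless root (then 1, similarity 0)
      diag(m) <- 1
      ri <- match(ont$root, ids)
      m[ri, ri] <- 0
      m[!is.finite(m)] <- 0
      dimnames(m) <- list(ids, ids)
      return(m)
    }
    # wu_palmer
    n1 <- matrix(ont$dmat[cbind(rep(seq_len(n), times = n),
                                as.vector(pp$lca_idx))], n, n)
    n3 <- pp$lca_depth
    m <- 2 * n3 / (n1 + t(n1) + 2 * n3)
    m[n3 <= 0] <- 0
    dimnames(m) <- list(ids, ids)
    return(m)
  }
  # IC-based metrics
  if (is.null(stats)) abort(paste0("metric '", metric, "' requires corpus stats"))
  mic <- .pairwise_mic(ont, stats)
  ic <- information_content(stats, ids)
  freq_pos <- concept_freq(stats, ids) > 0
  if (metric == "resnik") {
    m <- mic
    m[!is.finite(m)] <- 0
    # identity with freq > 0 is an exact match: MICA is the concept itself
    d <- diag(m)
    d[freq_pos] <- ic[freq_pos]
    diag(m) <- d
    return(m)
  }
  icsum <- outer(ic, ic, "+")
  both <- outer(freq_pos, freq_pos, "&")
  if (metric == "lin") {
    m <- 2 * mic / icsum
    m[!both | !is.finite(mic)] <- 0
    diag(m) <- ifelse(freq_pos, 1, 0)
    dimnames(m) <- list(ids, ids)
    return(m)
  }
  if (metric == "jiang_conrath") {
    d <- pmax(icsum - 2 * mic, 0)
    m <- 1 / (1 + d)
    m[!both | !is.finite(mic)] <- 0
    diag(m) <- ifelse(freq_pos, 1, 0)
    dimnames(m) <- list(ids, ids)
    return(m)
  }
  abort(paste0("unknown similarity metric: ", metric))
}

#' Build a pairwise similarity function over two ontologies
#'
#' Precomputes the full item-by-item similarity matrix for a metric over the
#' concepts of a phenotype ontology and (optionally) a disease ontology.
#' Cross-ontology pairs have similarity 0 under every metric. The `"custom"`
#' metric dispatches on ontology kind: the phenotype transform `2^l` on the
#' phenotype graph and the disease transform `10^(l-2)` on the disease graph.
#'
#' @param metric One of [similarity_metrics()].
#' @param pheno A phenotype [ontology()].
#' @param disease Optionally, a disease [ontology()].
#' @param stats A [corpus_stats()] object; required for `resnik`, `lin` and
#'   `jiang_conrath`.
#' @param clamp Clamp all values into `[0, 1]` (default `TRUE`); Lin and
#'   Resnik can exceed 1 otherwise.
#' @return An object of class `similarity_function` holding the lookup
#'   matrix; use [sim_value()] to query it.
#' @export
similarity_function <- function(metric, pheno, disease = NULL, stats = NULL,
                                clamp = TRUE) {
  metric <- match.arg(metric, similarity_metrics())
  blocks <- list(.sim_matrix_one(pheno, metric, stats))
  kinds <- rep("phenotype", length(pheno$concepts))
  if (!is.null(disease)) {
    blocks <- c(blocks, list(.sim_matrix_one(disease, metric, stats)))
    kinds <- c(kinds, rep("disease", length(disease$concepts)))
  }
  ids <- unlist(map(blocks, rownames))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  off <- 0
  for (b in blocks) {
    k <- nrow(b)
    m[off + seq_len(k), off + seq_len(k)] <- b
    off <- off + k
  }
  if (clamp) m <- clamp01(m)
  structure(
    list(metric = metric, matrix = m, items = ids,
         kind = setNames(kinds, ids), clamp = clamp),
    class = "similarity_function"
  )
}

#' @export
print.similarity_function <- function(x, ...) {
  cat(sprintf("<similarity_function> metric '%s' over %d items (clamp: %s)\n",
              x$metric, length(x$items), x$clamp))
  invisible(x)
}

#' Query a similarity function
#'
#' @param sf A [similarity_function()].
#' @param i1,i2 Item identifier vectors (recycled pairwise).
#' @return Numeric vector of similarities; unknown items score 0 against
#'   everything.
#' @export
sim_value <- function(sf, i1, i2) {
  n <- max(length(i1), length(i2))
  r <- rep_len(match(i1, sf$items), n)
  c <- rep_len(match(i2, sf$items), n)
  out <- numeric(n)
  ok <- !is.na(r) & !is.na(c)
  out[ok] <- sf$matrix[cbind(r[ok], c[ok])]
  out
}

#' Pairwise similarity matrix as a tibble
#'
#' Long-format pairwise similarities for one ontology under one metric,
#' suitable for writing as TSV.
#'
#' @inheritParams similarity_function
#' @param ont An [ontology()].
#' @return A tibble with columns `concept1`, `concept2`, `similarity`.
#' @export
similarity_matrix <- function(ont, metric, stats = NULL, clamp = TRUE) {
  m <- .sim_matrix_one(ont, metric, stats)
  if (clamp) m <- clamp01(m)
  tidyr::expand_grid(concept1 = rownames(m), concept2 = colnames(m)) |>
    mutate(similarity = as.vector(t(m)))
}
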