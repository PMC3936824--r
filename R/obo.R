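#' Read an OBO 1.2 flat file
#'
#' Parses the class-subclass subset of the OBO flat-file format: `[Term]`
#' stanzas with `id:`, `name:` and `is_a:` tags. Obsolete terms
#' (`is_obsolete: true`) are skipped, as are relationship types other than
#' `is_a` and non-Term stanzas. The resulting graph is validated (acyclic,
#' single root, all `is_a` targets resolve).
#'
#' @param path Path to an OBO file.
#' @param kind `"phenotype"` or `"disease"`.
#' @return An [ontology()].
#' @seealso [write_obo()]
#' @export
read_obo <- function(path, kind = c("phenotype", "disease")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("OBO file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) {
    abort(paste0("OBO parse failure: no stanzas in ", path))
  }
  stanza_ends <- c(stanza_starts[-1] - 1L, length(lines))
  terms <- list()
  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    body <- lines[seq(stanza_starts[s] + 1L, stanza_ends[s])]
    tag_val <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ":"))]
      v <- sub(paste0("^", tag, ":\\s*"), "", v)
      sub("\\s*!.*$", "", v)  # strip trailing comments
    }
    id <- tag_val("id")
    if (length(id) == 0 || !nzchar(id[1])) {
      abort("OBO parse failure: [Term] stanza without id")
    }
    if (any(tolower(tag_val("is_obsolete")) == "true")) next
    nm <- tag_val("name")
    terms[[length(terms) + 1L]] <- list(
      id = id[1],
      name = if (length(nm) > 0) nm[1] else id[1],
      is_a = tag_val("is_a")
    )
  }
  if (length(terms) == 0) abort(paste0("OBO parse failure: no [Term] stanzas in ", path))
  ids <- map_chr(terms, "id")
  labels <- setNames(map_chr(terms, "name"), ids)
  edges <- purrr::map_dfr(terms, function(t) {
    if (length(t$is_a) == 0) return(tibble(child = character(), parent = character()))
    tibble(child = t$id, parent = t$is_a)
  })
  # drop edges into obsolete/absent parents only if they never existed: must resolve
  ontology(concepts = ids, edges = edges, kind = kind, labels = labels)
}

#' Write an ontology as an OBO 1.2 flat file
#'
#' Emits the same dialect [read_obo()] consumes, so that write followed by
#' read round-trips to an identical graph.
#'
#' @param ont An [ontology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  header <- c("format-version: 1.2", "")
  stanzas <- map(sort(ont$concepts), function(id) {
    is_a <- sort(ont$edges$parent[ont$edges$child == id])
    c("[Term]",
      paste0("id: ", id),
      paste0("name: ", ont$labels[[id]]),
      if (length(is_a) > 0) paste0("is_a: ", is_a, " ! ", ont$labels[is_a]),
      "")
  })
  writeLines(c(header, unlist(stanzas)), path)
  invisible(path)
}
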