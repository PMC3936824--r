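#' Read a patient case table
#'
#' Expects a TSV with header `case_id  diagnosis_id  phenotype_ids`, where
#' `phenotype_ids` is a comma-separated list of concept CURIEs.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `case_id`, `diagnosis_id` and a list-column
#'   `phenotype_ids`.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) abort(paste0("case table not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("case_id", "diagnosis_id", "phenotype_ids")
  if (!all(need %in% names(raw))) {
    abort(paste0("case table must have columns: ", paste(need, collapse = ", ")))
  }
  raw |>
    select(dplyr::all_of(need)) |>
    mutate(phenotype_ids = map(.data$phenotype_ids, function(s) {
      if (is.na(s) || !nzchar(s)) character() else
        unique(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
    }))
}

#' Write a patient case table
#'
#' @param cases A tibble as returned by [read_cases()], or a
#'   [transaction database][as_transactions()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  if (inherits(cases, "transaction_db")) {
    cases <- tibble(case_id = cases$case_id,
                    diagnosis_id = cases$disease,
                    phenotype_ids = cases$phenotypes)
  }
  out <- cases |>
    mutate(phenotype_ids = map_chr(.data$phenotype_ids, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Build a transaction database from annotated cases
#'
#' Each patient case becomes one transaction whose items are its (unique)
#' phenotype concepts plus at most one disease concept. Every concept
#' identifier must resolve in its ontology; cases with zero phenotypes are
#' retained with a warning.
#'
#' @param cases A tibble with columns `case_id`, `diagnosis_id`,
#'   `phenotype_ids` (list-column of character vectors), as from
#'   [read_cases()].
#' @param pheno A phenotype [ontology()].
#' @param disease A disease [ontology()].
#' @return A `transaction_db`: a tibble with columns `case_id`, `disease`
#'   and list-column `phenotypes`.
#' @export
as_transactions <- function(cases, pheno, disease) {
  if (nrow(cases) == 0) abort("empty case table")
  if (anyDuplicated(cases$case_id)) abort("duplicate case_id in case table")
  phen <- map(cases$phenotype_ids, function(p) sort(unique(as.character(p))))
  for (i in seq_along(phen)) {
    bad <- setdiff(phen[[i]], pheno$concepts)
    if (length(bad) > 0) {
      abort(paste0("case ", cases$case_id[i],
                   ": unresolvable phenotype concept(s): ",
                   paste(bad, collapse = ", ")))
    }
    if (!is.na(cases$diagnosis_id[i]) &&
        !cases$diagnosis_id[i] %in% disease$concepts) {
      abort(paste0("case ", cases$case_id[i],
                   ": unresolvable disease concept: ", cases$diagnosis_id[i]))
    }
  }
  n_empty <- sum(lengths(phen) == 0)
  if (n_empty > 0) {
    warn(paste0(n_empty, " case(s) have zero phenotype annotations (retained)"))
  }
  db <- tibble(case_id = as.character(cases$case_id),
               disease = as.character(cases$diagnosis_id),
               phenotypes = phen)
  class(db) <- c("transaction_db", class(db))
  db
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("<transaction_db> %d cases, %d distinct phenotypes, %d disorders\n",
              nrow(x), length(unique(unlist(x$phenotypes))),
              length(unique(x$disease[!is.na(x$disease)]))))
  NextMethod()
}

# All items (phenotypes + disease) of each transaction, as a list.
transaction_items <- function(db) {
  map2(db$phenotypes, db$disease,
       function(p, d) if (is.na(d)) p else c(p, d))
}

# Distinct items of the database with their kinds, lexicographically sorted.
db_items <- function(db) {
  ph <- sort(unique(unlist(db$phenotypes)))
  di <- sort(unique(db$disease[!is.na(db$disease)]))
  tibble(item = c(ph, di),
         kind = c(rep("phenotype", length(ph)), rep("disease", length(di)))) |>
    arrange(.data$item)
}

# Logical incidence matrix, items x transactions.
incidence_matrix <- function(db, items) {
  ti <- transaction_items(db)
  m <- matrix(FALSE, length(items), nrow(db),
              dimnames = list(items, db$case_id))
  for (q in seq_along(ti)) {
    m[match(intersect(ti[[q]], items), items), q] <- TRUE
  }
  m
}
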