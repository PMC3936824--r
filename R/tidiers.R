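#' Tidy a cross-validation report
#'
#' @param x A `phr_evaluation` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with one row per fold x recall cut-off: columns `fold`,
#'   `k`, `accuracy` (percent), `n_test`.
#' @method tidy phr_evaluation
#' @export
tidy.phr_evaluation <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation report
#'
#' @inheritParams tidy.phr_evaluation
#' @return A one-row tibble: mode, scheme, measure, folds, number of cases,
#'   and one `accuracy_at_<k>` column per cut-off.
#' @method glance phr_evaluation
#' @export
glance.phr_evaluation <- function(x, ...) {
  acc <- as.list(x$accuracy_at_k)
  names(acc) <- paste0("accuracy_at_", names(x$accuracy_at_k))
  dplyr::bind_cols(
    tibble(mode = x$config$mode, scheme = x$config$scheme,
           measure = x$config$measure, folds = x$folds, n = x$n_test),
    as_tibble(acc)
  )
}

#' @method tidy phr_comparison
#' @export
tidy.phr_comparison <- function(x, ...) {
  bind_rows(
    tidy(x$traditional) |> mutate(mode = "traditional"),
    tidy(x$semantic) |> mutate(mode = "semantic")
  )
}

#' @method glance phr_comparison
#' @export
glance.phr_comparison <- function(x, ...) {
  tibble(
    k = x$k,
    traditional_accuracy = x$traditional$accuracy_at_k[[as.character(x$k)]],
    semantic_accuracy = x$semantic$accuracy_at_k[[as.character(x$k)]],
    both_correct = x$discordance$both_correct,
    traditional_only = x$discordance$a_only,
    semantic_only = x$discordance$b_only,
    both_wrong = x$discordance$both_wrong,
    statistic = if (x$no_discordance) NA_real_ else x$mcnemar$statistic,
    p_value = if (x$no_discordance) NA_real_ else x$mcnemar$p_value
  )
}

#' @method tidy discordance
#' @export
tidy.discordance <- function(x, ...) {
  tibble(a_correct = c(TRUE, TRUE, FALSE, FALSE),
         b_correct = c(TRUE, FALSE, TRUE, FALSE),
         n = c(x$both_correct, x$a_only, x$b_only, x$both_wrong))
}

#' Plot a top-K accuracy curve
#'
#' Mean accuracy against the recall cut-off, with per-fold accuracies as
#' light points.
#'
#' @param object A `phr_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phr_evaluation
#' @export
autoplot.phr_evaluation <- function(object, ...) {
  pf <- object$per_fold
  acc <- tibble(k = as.integer(names(object$accuracy_at_k)),
                accuracy = unname(object$accuracy_at_k))
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_point(data = pf, alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "recall cut-off K", y = "top-K accuracy (%)",
                  title = sprintf("%s %s voting (%s)", object$config$mode,
                                  object$config$scheme,
                                  object$config$measure)) +
    ggplot2::ylim(0, 100)
}

#' Plot traditional vs semantic accuracy curves
#'
#' @param object A `phr_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phr_comparison
#' @export
autoplot.phr_comparison <- function(object, ...) {
  acc <- bind_rows(
    tibble(mode = "traditional",
           k = as.integer(names(object$traditional$accuracy_at_k)),
           accuracy = unname(object$traditional$accuracy_at_k)),
    tibble(mode = "semantic",
           k = as.integer(names(object$semantic$accuracy_at_k)),
           accuracy = unname(object$semantic$accuracy_at_k))
  )
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$k, y = .data$accuracy,
                                    colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "recall cut-off K", y = "top-K accuracy (%)",
                  colour = NULL) +
    ggplot2::ylim(0, 100)
}
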