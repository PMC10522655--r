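#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for pipeline result objects
#'
#' `tidy()` returns one row per element (clonotype, grid point,
#' clonotype-pMHC pair); `glance()` returns a one-row summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @name itrap_tidiers
NULL

#' @rdname itrap_tidiers
#' @method tidy itrap_binders
#' @export
tidy.itrap_binders <- function(x, ...) {
  as_tibble(x) |> select(-"p_values")
}

#' @rdname itrap_tidiers
#' @method glance itrap_binders
#' @export
glance.itrap_binders <- function(x, ...) {
  tibble(n_clonotypes = nrow(x),
         n_annotated = sum(!is.na(x$expected_pmhc)),
         n_gems = sum(x$n_gems))
}

#' @rdname itrap_tidiers
#' @method tidy itrap_grid_search
#' @export
tidy.itrap_grid_search <- function(x, ...) x$trace

#' @rdname itrap_tidiers
#' @method glance itrap_grid_search
#' @export
glance.itrap_grid_search <- function(x, ...) {
  tibble(umi_min_pmhc = x$thresholds$umi_min_pmhc,
         ratio_min = x$thresholds$ratio_min,
         umi_min_tcr = x$thresholds$umi_min_tcr,
         accuracy = x$accuracy,
         n_retained = x$n_retained,
         n_grid_points = nrow(x$trace))
}

#' @rdname itrap_tidiers
#' @method tidy itrap_concordance
#' @export
tidy.itrap_concordance <- function(x, ...) x$by_pair

#' @rdname itrap_tidiers
#' @method glance itrap_concordance
#' @export
glance.itrap_concordance <- function(x, ...) {
  tibble(average_pct = x$average_pct,
         average_unweighted_pct = x$average_unweighted_pct,
         n_pairs = nrow(x$by_pair))
}

#' @rdname itrap_tidiers
#' @method glance itrap_metrics
#' @export
glance.itrap_metrics <- function(x, ...) {
  tibble(retention_pct = x$retention_pct, accuracy_pct = x$accuracy_pct,
         avg_concordance_pct = x$avg_concordance_pct,
         similarity_auc_pct = x$similarity_auc_pct,
         n_gems = x$n_gems, n_clonotypes = x$n_clonotypes)
}

#' @rdname itrap_tidiers
#' @method tidy itrap_similarity_scores
#' @export
tidy.itrap_similarity_scores <- function(x, ...) {
  bind_rows(tibble(ct_id = x$ct_id, kind = "intra", score = x$intra),
            tibble(ct_id = x$ct_id, kind = "inter", score = x$inter))
}

#' @rdname itrap_tidiers
#' @method glance itrap_run
#' @export
glance.itrap_run <- function(x, ...) {
  purrr::imap(x$metrics, function(m, nm) {
    glance(m) |> mutate(stage = nm, .before = 1)
  }) |> purrr::list_rbind()
}

#' @rdname itrap_tidiers
#' @method tidy itrap_run
#' @export
tidy.itrap_run <- function(x, ...) x$log

#' Concordance-map plot of clonotype specificities
#'
#' One point per (clonotype, assigned pMHC) pair, sized by the number of
#' supporting GEMs and coloured by binding concordance — the standard visual
#' summary of how cleanly clonotypes separate into single specificities.
#'
#' @param object An `itrap_concordance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itrap_concordance
#' @export
autoplot.itrap_concordance <- function(object, ...) {
  d <- object$by_pair
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ct_id, y = .data$pmhc,
                                  size = .data$n_gems,
                                  colour = .data$concordance)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "clonotype", y = "pMHC", size = "GEMs",
                  colour = "concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Intra- versus inter-specificity similarity distributions
#'
#' @param object An `itrap_similarity_scores` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itrap_similarity_scores
#' @export
autoplot.itrap_similarity_scores <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kind, y = .data$score,
                                  fill = .data$kind)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::ylim(0, 2) +
    ggplot2::labs(x = NULL, y = "paired CDR3 similarity") +
    ggplot2::theme_minimal()
}

#' Objective surface of the threshold grid search
#'
#' Accuracy as a function of the minimum pMHC UMI, faceted over the TCR UMI
#' floor, with one line per top/second ratio cutoff.
#'
#' @param object An `itrap_grid_search` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itrap_grid_search
#' @export
autoplot.itrap_grid_search <- function(object, ...) {
  d <- object$trace
  ggplot2::ggplot(d, ggplot2::aes(x = .data$umi_min_pmhc, y = .data$accuracy,
                                  colour = factor(.data$ratio_min),
                                  group = .data$ratio_min)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~umi_min_tcr, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "min pMHC UMI", y = "accuracy", colour = "min ratio") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
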