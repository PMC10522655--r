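#' UMI threshold set
#'
#' The three data-driven cutoffs applied to every GEM: a minimum UMI for the
#' most abundant pMHC capture, a minimum ratio between the top and the
#' second-most-abundant capture (for GEMs with pMHC multiplets), and a
#' minimum UMI for each selected TCR chain.
#'
#' @param umi_min_pmhc Positive integer; minimum UMI of the top pMHC.
#' @param ratio_min Real `>= 1`; minimum top/second UMI ratio.
#' @param umi_min_tcr Non-negative integer; minimum UMI per selected chain.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(umi_min_pmhc = 5L, ratio_min = 1.2, umi_min_tcr = 1L) {
  stopifnot(umi_min_pmhc >= 1, is.finite(ratio_min), ratio_min >= 1,
            umi_min_tcr >= 0)
  structure(list(umi_min_pmhc = as.integer(umi_min_pmhc),
                 ratio_min = as.numeric(ratio_min),
                 umi_min_tcr = as.integer(umi_min_tcr)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("UMI thresholds: pMHC >= %d, top/second ratio >= %.2f, TCR chain >= %d\n",
              x$umi_min_pmhc, x$ratio_min, x$umi_min_tcr))
  invisible(x)
}

# Per-GEM summaries the filters operate on. second_umi is 0 for single
# captures; top_feature is NA when the top UMI is tied.
gem_capture_stats <- function(gems) {
  tibble(
    top_umi = purrr::map_int(gems$captures, ~ if (NROW(.x) == 0) 0L else max(.x$umi)),
    second_umi = purrr::map_int(gems$captures, function(cp) {
      if (NROW(cp) < 2) return(0L)
      sort(cp$umi, decreasing = TRUE)[2]
    }),
    n_captures = purrr::map_int(gems$captures, NROW),
    top_feature = purrr::map_chr(gems$captures, top_feature)
  )
}

# Smallest UMI among the chains a GEM presents (selected chains only;
# imputed chains carry UMI 0 and count unless exempted).
gem_tcr_min <- function(gems, exempt_imputed = FALSE) {
  ua <- gems$umi_a
  ub <- gems$umi_b
  if (exempt_imputed) {
    ua[which(gems$imputed_a)] <- NA_integer_
    ub[which(gems$imputed_b)] <- NA_integer_
  }
  pmin(ua, ub, na.rm = TRUE)
}

# Inclusive ratio comparison done in integer arithmetic: top/second >= r is
# evaluated as top * 100 >= round(r * 100) * second, avoiding float boundary
# artifacts at grid values like 1.2.
ratio_ok <- function(top, second, ratio_min) {
  top * 100L >= round(ratio_min * 100) * second
}

#' Apply UMI thresholds and assign pMHC targets
#'
#' A GEM is retained iff its top pMHC UMI meets `umi_min_pmhc`, its
#' top/second UMI ratio meets `ratio_min` (trivially satisfied for single
#' captures), and every TCR chain it presents meets `umi_min_tcr`. All
#' boundary comparisons are inclusive. Retained GEMs get
#' `assigned_pmhc = ` their top capture; a GEM whose top UMI is tied between
#' features has no unambiguous target and is removed.
#'
#' @param gems Clonotyped GEM tibble.
#' @param thresholds A [threshold_set()].
#' @param exempt_imputed Ignore imputed chains (UMI 0) in the TCR-UMI rule.
#' @return The filtered tibble with an `assigned_pmhc` column.
#' @export
apply_thresholds <- function(gems, thresholds, exempt_imputed = FALSE) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (nrow(gems) == 0) {
    gems$assigned_pmhc <- character(0)
    return(gems)
  }
  st <- gem_capture_stats(gems)
  tcr_min <- gem_tcr_min(gems, exempt_imputed)
  keep <- !is.na(st$top_feature) &
    st$top_umi >= thresholds$umi_min_pmhc &
    (st$n_captures == 1L | ratio_ok(st$top_umi, st$second_umi, thresholds$ratio_min)) &
    (is.na(tcr_min) | tcr_min >= thresholds$umi_min_tcr)
  out <- gems[keep, , drop = FALSE]
  out$assigned_pmhc <- st$top_feature[keep]
  out
}

#' Default threshold search grid
#'
#' @param umi_min_pmhc,ratio_min,umi_min_tcr Candidate values per axis.
#' @return A tibble with one row per grid point.
#' @export
threshold_grid <- function(umi_min_pmhc = 1:20,
                           ratio_min = seq(1, 3, by = 0.1),
                           umi_min_tcr = 0:5) {
  tidyr::expand_grid(umi_min_pmhc = as.integer(umi_min_pmhc),
                     ratio_min = as.numeric(ratio_min),
                     umi_min_tcr = as.integer(umi_min_tcr))
}

#' Grid search for accuracy-maximizing UMI thresholds
#'
#' Exhaustively evaluates [compute_accuracy()]-style accuracy over the GEMs
#' of binder-annotated clonotypes (the internal golden standard) under every
#' candidate threshold set, and returns the maximizer. Ties are broken by
#' (1) larger retained-GEM count, then (2) smaller thresholds in
#' lexicographic `(umi_min_pmhc, ratio_min, umi_min_tcr)` order. Grid points
#' that retain no GEM score `NA` and are never selected.
#'
#' @param gems Clonotyped GEM tibble.
#' @param binders `itrap_binders` tibble with at least one expected binder.
#' @param grid Tibble from [threshold_grid()] (default grid if omitted).
#' @param exempt_imputed Passed to the TCR-UMI rule.
#' @return A list of class `itrap_grid_search`: `thresholds` (the winning
#'   [threshold_set()]), `accuracy`, `n_retained`, and `trace` (the full
#'   objective trace, one row per grid point).
#' @export
grid_search_thresholds <- function(gems, binders, grid = threshold_grid(),
                                   exempt_imputed = FALSE) {
  if (nrow(grid) == 0) abort("Empty threshold grid", class = "itrap_usage_error")
  annotated <- binders |> filter(!is.na(.data$expected_pmhc))
  if (nrow(annotated) == 0) {
    abort("No clonotypes with an expected binder; cannot search thresholds",
          class = "itrap_usage_error")
  }
  sub <- gems |>
    filter(.data$ct_id %in% annotated$ct_id) |>
    left_join(annotated |> select("ct_id", "expected_pmhc"), by = "ct_id")

  st <- gem_capture_stats(sub)
  tcr_min <- gem_tcr_min(sub, exempt_imputed)
  tcr_min[is.na(tcr_min)] <- .Machine$integer.max  # no chains at all: rule vacuous
  assignable <- !is.na(st$top_feature)
  hit <- assignable & st$top_feature == sub$expected_pmhc
  single <- st$n_captures == 1L

  eval_point <- function(u, r, t) {
    keep <- assignable & st$top_umi >= u &
      (single | ratio_ok(st$top_umi, st$second_umi, r)) &
      tcr_min >= t
    n <- sum(keep)
    c(accuracy = if (n == 0) NA_real_ else sum(hit & keep) / n, n_retained = n)
  }
  res <- purrr::pmap(grid, function(umi_min_pmhc, ratio_min, umi_min_tcr) {
    eval_point(umi_min_pmhc, ratio_min, umi_min_tcr)
  })
  trace <- grid |>
    mutate(accuracy = purrr::map_dbl(res, "accuracy"),
           n_retained = as.integer(purrr::map_dbl(res, "n_retained")))

  cand <- trace |> filter(!is.na(.data$accuracy))
  if (nrow(cand) == 0) {
    abort("Every grid point retains zero GEMs", class = "itrap_usage_error")
  }
  best <- cand |>
    arrange(desc(.data$accuracy), desc(.data$n_retained),
            .data$umi_min_pmhc, .data$ratio_min, .data$umi_min_tcr) |>
    slice(1)
  structure(list(
    thresholds = threshold_set(best$umi_min_pmhc, best$ratio_min, best$umi_min_tcr),
    accuracy = best$accuracy,
    n_retained = best$n_retained,
    trace = trace
  ), class = "itrap_grid_search")
}

#' @export
print.itrap_grid_search <- function(x, ...) {
  print(x$thresholds)
  cat(sprintf("objective accuracy %.4f over %d retained GEMs (%d grid points)\n",
              x$accuracy, x$n_retained, nrow(x$trace)))
  invisible(x)
}
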