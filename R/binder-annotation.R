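#' Annotate the expected binder of each expanded clonotype
#'
#' For every clonotype represented by at least `min_gems` GEMs, the pMHC
#' captures of all member GEMs are pooled per feature and the feature with
#' the highest mean UMI is put forward as the candidate cognate target. The
#' candidate is declared the clonotype's *expected binder* only if a
#' one-sided rank-sum test of its UMI vector against every competing
#' feature's UMI vector is significant at `alpha` for all competitors. A
#' clonotype whose members captured a single feature is annotated to it
#' directly.
#'
#' By default each feature's UMI vector is zero-filled over all member GEMs
#' (an absent capture is a zero observation), giving every comparison the
#' full clonotype size. Set `zero_fill = FALSE` to compare only the GEMs
#' where each feature was detected; note that in that mode a competitor
#' detected in a single GEM caps the attainable one-sided p-value at
#' `1/(n1+1)`, so clonotypes with fewer than about 20 members can never
#' annotate past such a competitor at `alpha = 0.05`.
#'
#' @param gems Clonotyped GEM tibble (with `ct_id` and `captures`).
#' @param min_gems Minimum clonotype size for annotation (default 10).
#' @param alpha Significance level for the rank-sum test (default 0.05).
#' @param zero_fill Zero-fill absent captures when building UMI vectors
#'   (default `TRUE`).
#' @param exact_limit Passed to [rank_sum_test()].
#' @return A tibble of class `itrap_binders`: `ct_id`, `expected_pmhc` (NA
#'   when no feature won every comparison), `n_gems`, `n_competitors`,
#'   `max_competitor_p`, and a `p_values` list-column of per-competitor
#'   p-values.
#' @export
annotate_expected_binders <- function(gems, min_gems = 10, alpha = 0.05,
                                      zero_fill = TRUE, exact_limit = 12) {
  eligible <- gems |>
    filter(!is.na(.data$ct_id)) |>
    group_by(.data$ct_id) |>
    filter(n() >= min_gems) |>
    ungroup()

  empty <- tibble(ct_id = character(0), expected_pmhc = character(0),
                  n_gems = integer(0), n_competitors = integer(0),
                  max_competitor_p = double(0), p_values = list())
  class(empty) <- c("itrap_binders", class(empty))
  if (nrow(eligible) == 0) return(empty)

  caps <- eligible |>
    select("ct_id", "barcode_full", "captures") |>
    tidyr::unnest("captures")

  sizes <- eligible |> count(.data$ct_id, name = "n_gems")

  annotate_one <- function(ct, n_gems_ct) {
    d <- caps[caps$ct_id == ct, ]
    feats <- split(d$umi, d$feature_id)
    if (zero_fill) {
      feats <- lapply(feats, function(v) c(v, rep(0, n_gems_ct - length(v))))
    }
    means <- vapply(feats, mean, double(1))
    # candidate: highest mean; deterministic tie-break on feature id
    ord <- order(-means, names(feats))
    cand <- names(feats)[ord[1]]
    competitors <- setdiff(names(feats), cand)
    if (length(competitors) == 0) {
      return(tibble(ct_id = ct, expected_pmhc = cand, n_gems = n_gems_ct,
                    n_competitors = 0L, max_competitor_p = NA_real_,
                    p_values = list(setNames(double(0), character(0)))))
    }
    p <- vapply(competitors, function(f) {
      rank_sum_test(feats[[cand]], feats[[f]], exact_limit = exact_limit)
    }, double(1))
    expected <- if (all(p < alpha)) cand else NA_character_
    tibble(ct_id = ct, expected_pmhc = expected, n_gems = n_gems_ct,
           n_competitors = length(competitors), max_competitor_p = max(p),
           p_values = list(p))
  }

  out <- purrr::map2(sizes$ct_id, sizes$n_gems, annotate_one) |>
    purrr::list_rbind() |>
    arrange(.data$ct_id)
  class(out) <- c("itrap_binders", class(out))
  out
}

#' Assignment accuracy against expected binders
#'
#' The fraction of GEMs — among GEMs of clonotypes that have an expected
#' binder — whose most abundant pMHC capture (by UMI) is that expected
#' binder. A GEM whose top UMI is tied between several features counts as a
#' miss, even when the expected binder is among them: an ambiguous top
#' capture is not a confident assignment.
#'
#' @param gems Clonotyped GEM tibble.
#' @param binders `itrap_binders` tibble from [annotate_expected_binders()].
#' @return A list of class `itrap_accuracy`: `accuracy` (fraction in `[0,1]`,
#'   `NA` with a warning when no GEM qualifies), `n_gems` (denominator), and
#'   `by_clonotype` (tibble `ct_id, n_gems, n_match, accuracy`).
#' @export
compute_accuracy <- function(gems, binders) {
  annotated <- binders |> filter(!is.na(.data$expected_pmhc))
  sub <- gems |>
    filter(.data$ct_id %in% annotated$ct_id) |>
    left_join(annotated |> select("ct_id", "expected_pmhc"), by = "ct_id")

  if (nrow(sub) == 0) {
    warn("No GEMs belong to clonotypes with an expected binder; accuracy undefined")
    return(structure(list(accuracy = NA_real_, n_gems = 0L,
                          by_clonotype = tibble(ct_id = character(0),
                                                n_gems = integer(0),
                                                n_match = integer(0),
                                                accuracy = double(0))),
                     class = "itrap_accuracy"))
  }
  sub$match <- purrr::map2_lgl(sub$captures, sub$expected_pmhc, function(cp, exp) {
    tf <- top_feature(cp)
    !is.na(tf) && tf == exp
  })
  by_ct <- sub |>
    group_by(.data$ct_id) |>
    summarise(n_gems = n(), n_match = sum(.data$match), .groups = "drop") |>
    mutate(accuracy = .data$n_match / .data$n_gems)
  structure(list(accuracy = sum(by_ct$n_match) / sum(by_ct$n_gems),
                 n_gems = sum(by_ct$n_gems),
                 by_clonotype = by_ct),
            class = "itrap_accuracy")
}

# Unique top capture of a GEM by UMI; NA when tied or no captures.
top_feature <- function(captures) {
  if (NROW(captures) == 0) return(NA_character_)
  mx <- max(captures$umi)
  top <- captures$feature_id[captures$umi == mx]
  if (length(top) != 1) NA_character_ else top
}

#' @export
print.itrap_accuracy <- function(x, ...) {
  cat(sprintf("Assignment accuracy: %s over %d GEMs in %d annotated clonotypes\n",
              ifelse(is.na(x$accuracy), "NA", sprintf("%.4f", x$accuracy)),
              x$n_gems, nrow(x$by_clonotype)))
  invisible(x)
}
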